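test_that("suite generation is deterministic and honours the design ranges", {
  s1 <- generate_suite(4, n_points = 300, seed = 17,
                       anchor_n_stimuli = 300, anchor_n_reps = 50)
  s2 <- generate_suite(4, n_points = 300, seed = 17,
                       anchor_n_stimuli = 300, anchor_n_reps = 50)
  expect_identical(s1, s2)
  expect_identical(vapply(s1$datasets, `[[`, "", "dominant"),
                   c("up", "mult", "down", "mixed"))
  for (ds in s1$datasets) {
    p <- ds$truth$nonlinearity
    expect_true(p$beta1 >= 0.5 && p$beta1 <= 5)
    expect_true(p$beta2 >= 0.5 && p$beta2 <= 5)
    expect_true(p$beta3 >= -2 && p$beta3 <= 2)
    expect_true(p$beta4 >= 0 && p$beta4 <= 0.5)
    expect_identical(length(ds$data), 300L)
    # dominant source drawn from the [0.1, 1] x anchor band
    if (ds$dominant != "mixed") {
      lev <- c(up = ds$truth$noise$sigma_up, mult = ds$truth$noise$sigma_mult,
               down = ds$truth$noise$sigma_down)
      expect_gte(lev[[ds$dominant]], 0.1 * ds$anchors[[ds$dominant]])
      expect_lte(lev[[ds$dominant]], 1.0 * ds$anchors[[ds$dominant]])
    }
  }
  # mixture variant draws p_down in [0.3, 1]
  sm <- generate_suite(2, n_points = 200, seed = 23, variant = "mixture",
                       anchor_n_stimuli = 300, anchor_n_reps = 50)
  pds <- vapply(sm$datasets, function(d) d$truth$noise$p_down, numeric(1))
  expect_true(all(pds >= 0.3 & pds <= 1))
})

test_that("pooled suite counts match the likelihood's analytic means", {
  s <- generate_suite(2, n_points = 2500, seed = 29,
                      anchor_n_stimuli = 300, anchor_n_reps = 50)
  for (ds in s$datasets) {
    # analytic conditional mean from the pmf, averaged over this dataset's
    # inputs (subsampled for speed), vs the pooled simulated counts
    idx <- seq(1, 2500, by = 8)
    mu <- vapply(ds$data$inputs[idx], function(x) {
      pmf <- response_pmf(ds$truth, x)
      sum((seq_along(pmf$probs) - 1) * pmf$probs)
    }, numeric(1))
    vr <- var(ds$data$counts) / length(ds$data)
    expect_lt(abs(mean(ds$data$counts) - mean(mu)),
              3 * sqrt(vr) + 0.05 * mean(mu))
  }
})

test_that("noise contributions isolate sources and match brute force", {
  p <- softplus_params(1.5, 2, 0, 0.1)
  # only downstream noise: fractions (0, 0, 1)
  md <- multistage_model(p, noise_params(0, 0, 0.7))
  expect_equal(unname(noise_contribution(md, seed = 2)), c(0, 0, 1))
  # noiseless model is rejected
  m0 <- multistage_model(p, noise_params(0, 0, 0))
  expect_error(noise_contribution(m0), "noiseless")
  # brute-force double-loop oracle at higher sampling
  m <- multistage_model(p, noise_params(0.4, 0.8, 0.5))
  fr <- noise_contribution(m, n_stimuli = 1500, n_reps = 300, seed = 3)
  expect_equal(sum(fr), 1)
  brute <- vapply(c("up", "mult", "down"), function(s) {
    lv <- c(up = 0, mult = 0, down = 0)
    lv[s] <- c(up = 0.4, mult = 0.8, down = 0.5)[[s]]
    ms <- multistage_model(p, noise_params(lv[["up"]], lv[["mult"]], lv[["down"]]))
    set.seed(1000 + match(s, c("up", "mult", "down")))
    x <- rnorm(2500)
    v <- vapply(x, function(xi)
      var(as.numeric(simulate_responses(ms, rep(xi, 300)))), numeric(1))
    mean(v)
  }, numeric(1))
  expect_equal(unname(fr), unname(brute / sum(brute)), tolerance = 0.05)
})

test_that("recovery study runs end to end on a miniature suite", {
  s <- generate_suite(2, n_points = 600, seed = 37,
                      anchor_n_stimuli = 300, anchor_n_reps = 50)
  cfg <- fit_config(n_starts = 2, seed = 5, max_evals = 600)
  rep1 <- run_recovery(s, cfg)
  expect_s3_class(rep1, "recovery_report")
  expect_identical(nrow(rep1$datasets), 2L)
  expect_identical(nrow(rep1$sources), 6L)
  expect_true(all(rep1$datasets$nl_error_ms >= 0))
  expect_true(all(abs(tapply(rep1$sources$contribution,
                             rep1$sources$dataset, sum) - 1) < 1e-9))
  # relative errors reported only above the contribution cutoff
  expect_identical(rep1$sources$included, rep1$sources$contribution >= 0.2)
  # deterministic regeneration
  rep2 <- run_recovery(s, cfg)
  expect_identical(rep1$datasets, rep2$datasets)
  expect_identical(rep1$aggregates, rep2$aggregates)
})

test_that("mixture-variant recovery uses the same code path", {
  s <- generate_suite(1, n_points = 600, seed = 41, variant = "mixture",
                      anchor_n_stimuli = 300, anchor_n_reps = 50)
  cfg <- fit_config(n_starts = 2, seed = 6, max_evals = 600)
  repm <- run_recovery(s, cfg)
  expect_identical(repm$variant, "mixture")
  expect_identical(nrow(repm$datasets), 1L)
  # downstream summarized by its effective SD sqrt(p_down) * sigma_down
  tr <- s$datasets[[1]]$truth$noise
  row <- repm$sources[repm$sources$source == "down", ]
  expect_equal(row$true, sqrt(tr$p_down) * tr$sigma_down)
})

test_that("model and dataset round-trip through their serialized forms", {
  m <- multistage_model(softplus_params(1.5, 2, -0.3, 0.1),
                        noise_params(0.4, 0.8, 0.5, p_down = 0.6,
                                     variant = "mixture"),
                        history_weight = 0.25)
  fp <- tempfile(fileext = ".json")
  write_model_json(m, fp)
  m2 <- read_model_json(fp)
  expect_equal(m2, m)
  d <- binned_dataset(rnorm(50), rpois(50, 2), bin_width = 0.08)
  fc <- tempfile(fileext = ".csv")
  write_dataset_csv(d, fc)
  d2 <- read_dataset_csv(fc)
  expect_equal(d2$inputs, d$inputs)
  expect_identical(d2$counts, d$counts)
  expect_equal(d2$bin_width, 0.08)
  unlink(c(fp, fc))
})
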