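test_that("dataset validation flags bad rows and excludes fixated cells", {
  df <- data.frame(individual_id = c("a", "a", "b", "b"),
                   age_days = c(10, 10, 20, 20),
                   h0 = c(0.4, 0.4, 0.6, 0.6),
                   h = c(0.35, 1, 0.55, 0))
  dat <- heteroplasmy_dataset(df)
  expect_equal(nrow(dat), 2)
  expect_equal(attr(dat, "n_fixated"), 2)
  expect_error(heteroplasmy_dataset(df[, -4]), "missing required")
  df$h0[1] <- 1
  expect_error(heteroplasmy_dataset(df), "h0 must lie")
  df$h0[1] <- 0.4
  df$h[1] <- 1.2
  expect_error(heteroplasmy_dataset(df), "h must lie")
})

test_that("log likelihood matches Gaussian algebra on crafted records", {
  nufn <- 1.4e-4
  sch <- mouse_schedule(670, nufn)
  v0 <- developmental_norm_var(sch)
  # age chosen so Var(z) = V'(age) / (h0 (1-h0)) = 1 at h0 = 1/2
  age1 <- (0.25 - v0) / (2 * nufn)
  one <- heteroplasmy_dataset(data.frame(
    individual_id = "a", age_days = age1, h0 = 0.5, h = 0.5))
  expect_equal(log_likelihood(one, sch), -0.5 * log(2 * pi),
               tolerance = 1e-10)
  # doubling the variance at the mean costs exactly log(2)/2 per record
  age2 <- (0.5 - v0) / (2 * nufn)
  two <- heteroplasmy_dataset(data.frame(
    individual_id = "a", age_days = age2, h0 = 0.5, h = 0.5))
  expect_equal(log_likelihood(two, sch),
               -0.5 * log(2 * pi) - 0.5 * log(2), tolerance = 1e-10)
})

test_that("likelihood is invariant to record order and individual labels", {
  dat <- make_test_dataset(seed = 111, n_individuals = 10, oocytes = 8)
  sch <- mouse_schedule(670, 1.4e-4)
  ll <- log_likelihood(dat, sch)
  perm <- dat[sample(nrow(dat)), ]
  class(perm) <- class(dat)
  expect_equal(log_likelihood(perm, sch), ll)
  relab <- dat
  relab$individual_id <- paste0("x_", relab$individual_id)
  expect_equal(log_likelihood(relab, sch), ll)
})

test_that("the likelihood is maximised near the generative truth", {
  dat <- make_test_dataset(seed = 121)
  ll_true <- log_likelihood(dat, mouse_schedule(670, 1.4e-4))
  for (sch in list(mouse_schedule(100, 1.4e-4),
                   mouse_schedule(5000, 1.4e-4),
                   mouse_schedule(670, 5e-4),
                   mouse_schedule(670, 0.3e-4))) {
    expect_gt(ll_true, log_likelihood(dat, sch))
  }
  fit <- fit_ml(dat)
  expect_lt(abs(fit$point_estimates["b"] - 670) / 670, 0.3)
  expect_lt(abs(fit$point_estimates["nu_f_over_n"] - 1.4e-4) / 1.4e-4, 0.25)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
})

test_that("fits are stable across jittered starting points", {
  dat <- make_test_dataset(seed = 131, n_individuals = 20, oocytes = 20)
  fit0 <- fit_ml(dat)
  set.seed(1)
  for (i in 1:10) {
    fit <- fit_ml(dat, init = c(log(1000), log(1e-4)) +
                    stats::rnorm(2, 0, 0.3))
    expect_equal(fit$point_estimates, fit0$point_estimates,
                 tolerance = 1e-3)
  }
})

test_that("degenerate designs are flagged", {
  df <- data.frame(individual_id = rep(c("a", "b"), each = 10),
                   age_days = 100, h0 = 0.5,
                   h = plogis(stats::rnorm(20, 0, 0.5)))
  expect_warning(fit_ml(heteroplasmy_dataset(df)), "identifiable")
})

test_that("bootstrap intervals bracket the point estimate and warn on failures", {
  dat <- make_test_dataset(seed = 141, n_individuals = 12, oocytes = 12)
  fit <- fit_ml(dat)
  bf <- bootstrap_fit(dat, fit, n_boot = 100, seed = 2)
  ci <- bf$bootstrap_intervals
  expect_true(all(ci[, "lo"] <= ci[, "hi"]))
  expect_true(all(ci[, "lo"] <= fit$point_estimates &
                    fit$point_estimates <= ci[, "hi"]))
  expect_error(bootstrap_fit(dat, fit, n_boot = 50), "at least 100")
  # individual-level resampling also works
  bi <- bootstrap_fit(dat, fit, n_boot = 100, unit = "individual", seed = 3)
  expect_true(all(bi$bootstrap_intervals[, "lo"] <=
                    bi$bootstrap_intervals[, "hi"]))
})

test_that("interval width shrinks with dataset size", {
  small <- make_test_dataset(seed = 151, n_individuals = 8, oocytes = 10)
  large <- make_test_dataset(seed = 151, n_individuals = 32, oocytes = 30)
  w <- vapply(list(small, large), function(d) {
    fit <- fit_ml(d)
    bf <- suppressWarnings(bootstrap_fit(d, fit, n_boot = 100, seed = 4))
    diff(bf$bootstrap_intervals["nu_f_over_n", ])
  }, numeric(1))
  expect_lt(w[2], w[1])
})

test_that("model comparison is deterministic and ranks by AIC", {
  dat <- make_test_dataset(seed = 161, n_individuals = 16, oocytes = 15)
  tab <- compare_models(dat, c("div_turnover_amp", "div_turnover_amp"))
  expect_equal(tab$aic[1], tab$aic[2])
  tab2 <- compare_models(dat, c("div_turnover_amp", "with_selection",
                                "subsample_amp"))
  expect_equal(tab2$delta_aic[1], 0)
  expect_true(!is.unsorted(tab2$aic))
})

test_that("empirical normalised variance matches hand computation", {
  df <- data.frame(individual_id = "a", age_days = 100, h0 = 0.5,
                   h = c(0.4, 0.6))
  emp <- empirical_norm_var(heteroplasmy_dataset(df))
  expect_equal(emp$var_h, 0.02)
  expect_equal(emp$mean_h, 0.5)
  expect_equal(emp$norm_var, 0.08)
  expect_equal(emp$bottleneck_size, 12.5)
  expect_equal(emp$norm_var_se, 0.08 * sqrt(2))
  # identical measurements: zero variance, bottleneck reported missing
  dfc <- data.frame(individual_id = "a", age_days = 1, h0 = 0.5,
                    h = c(0.3, 0.3, 0.3))
  empc <- empirical_norm_var(heteroplasmy_dataset(dfc))
  expect_equal(empc$norm_var, 0)
  expect_true(is.na(empc$bottleneck_size))
  # singleton groups dropped with a warning
  dfs <- rbind(df, data.frame(individual_id = "b", age_days = 50,
                              h0 = 0.5, h = 0.5))
  expect_warning(empirical_norm_var(heteroplasmy_dataset(dfs)), "dropped")
})

test_that("the empirical estimator is first-order unbiased at small variance", {
  # many small clutches at known generative V'; the estimator on the raw
  # heteroplasmy scale carries an O(V') squashing bias from the logistic
  # transform, so it is unbiased only to first order: the relative bias
  # must be small at small V' and shrink as V' does
  rel_bias <- vapply(c(0.01, 0.1), function(nv_true) {
    set.seed(171)
    nvs <- replicate(1000, {
      z <- stats::rnorm(25, 0, sqrt(nv_true / 0.25))
      h <- inverse_transform_heteroplasmy(z, 0.5)
      var(h) / (mean(h) * (1 - mean(h)))
    })
    mean(nvs) / nv_true - 1
  }, numeric(1))
  expect_lt(abs(rel_bias[1]), 0.05)
  expect_lt(abs(rel_bias[1]), abs(rel_bias[2]))
})
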