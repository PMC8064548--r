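test_that("normalised variance, bottleneck size and parameter follow their definitions", {
  expect_equal(normalise_variance(0.05, 0.5), 0.2)
  expect_equal(normalise_variance(0, 0.3), 0)
  expect_equal(normalise_variance(0.02, 0.9), 0.02 / (0.9 * 0.1))
  expect_error(normalise_variance(0.01, 1), "strictly in")
  expect_error(normalise_variance(0.01, 0), "strictly in")

  expect_equal(bottleneck_size(0.01), 100)
  expect_equal(bottleneck_param(0.01), 0.99)
  expect_equal(bottleneck_size(1), 1)
  expect_equal(bottleneck_param(1), 0)
  expect_equal(bottleneck_size(0.002), 500)
  expect_error(bottleneck_size(0), "> 0")
})

test_that("per-mechanism contributions match their closed forms", {
  expect_equal(division_contribution(1000, 1), 0.001)
  expect_equal(division_contribution(1000, 10), 0.01)
  expect_equal(division_contribution(500, 1), 0.002)
  expect_error(division_contribution(10, 20), "exceed")

  expect_equal(turnover_contribution(1, 1, 1, 1000, 1), 0.002)
  expect_equal(turnover_contribution(1, 0, 1, 1000, 1), 0)
  expect_equal(turnover_contribution(1, 0.5, 2, 1000, 3), (1 + 3) * 0.5 * 2 / 1000)

  expect_equal(conversion_contribution(0.002, 0, 1), 0.004)
  expect_equal(conversion_contribution(0.5, 1, 3), 0)
  expect_equal(conversion_contribution(0.002, 0.3, 1), 2 * 0.002 * 0.49)

  expect_equal(subsample_contribution(1000, 100), 0.009)
  expect_equal(subsample_contribution(777, 777, 3), 0)
  expect_error(subsample_contribution(100, 200), "n2 <= n1")

  expect_equal(amplification_contribution(500, 100000), 1 / 500 - 1 / 100000)
  expect_equal(amplification_contribution(42, 42), 0)
  expect_error(amplification_contribution(200, 100), "n2 >= n1")
})

test_that("exact subsampling variance equals hypergeometric enumeration", {
  # (10, 5) at h = 1/2: exhaustive subset counting
  p <- hyper_pmf_enum(0:5, w = 5, m = 5, k = 5)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(pmf_norm_var(0:5, p, 5), 5 / 45, tolerance = 1e-12)
  expect_equal(subsample_contribution(10, 5, 1, exact = TRUE), 5 / 45)
  # exact and approximate forms converge for large pools
  expect_equal(subsample_contribution(1e5, 1e3, exact = TRUE),
               subsample_contribution(1e5, 1e3), tolerance = 2e-2)
})

test_that("amplification formula is the large-n limit of the exact urn variance", {
  expect_equal(amplification_contribution(4, 8), 0.125)
  # exact enumeration from (2,2) to 8 gives the finite-n value
  p <- polya_pmf_enum(4, w = 2, m = 2)
  nv_exact <- pmf_norm_var(2 + 0:4, p, 8)
  expect_equal(nv_exact, (8 - 4) / (8 * (4 + 1)), tolerance = 1e-12)
  # finite-n correction factor n1/(n1+1) vanishes as n1 grows
  expect_equal(nv_exact / amplification_contribution(4, 8), 4 / 5,
               tolerance = 1e-12)
  n1 <- 500
  expect_equal((2 * n1 - n1) / ((2 * n1) * (n1 + 1)) /
                 amplification_contribution(n1, 2 * n1),
               n1 / (n1 + 1), tolerance = 1e-12)
})

test_that("schedules validate, chain copy numbers and sum additively", {
  expect_equal(total_normalised_variance(odna_schedule())$norm_var, 0)

  sch <- odna_schedule(list(
    mechanism_event("turnover_epoch", 1000, duration_days = 1,
                    turnover_rate = 1, frag_fraction = 1),
    mechanism_event("division", 1000)))
  expect_equal(total_normalised_variance(sch)$norm_var, 0.003)

  expect_error(odna_schedule(list(
    mechanism_event("division", 1000),
    mechanism_event("division", 1000))), "do not chain")

  # additivity: concatenation equals sum of parts
  s1 <- odna_schedule(list(mechanism_event("division", 1000)))
  s2 <- odna_schedule(list(mechanism_event("amplify", 500, 2000)))
  both <- odna_schedule(c(s1$events, s2$events))
  expect_identical(total_normalised_variance(both)$norm_var,
                   total_normalised_variance(s1)$norm_var +
                     total_normalised_variance(s2)$norm_var)

  big <- odna_schedule(list(mechanism_event("subsample", 1000, 1)))
  expect_warning(total_normalised_variance(big), "0.5")
  huge <- odna_schedule(list(
    mechanism_event("subsample", 1000, 1),
    mechanism_event("amplify", 1, 2000)))
  expect_warning(total_normalised_variance(huge), "exceeds 1")
})

test_that("mechanism events reject inconsistent construction", {
  expect_error(mechanism_event("turnover_epoch", 1000), "duration_days > 0")
  expect_error(mechanism_event("division", 1000, duration_days = 2),
               "instantaneous")
  expect_error(mechanism_event("subsample", 100, 200), "n2 <= n1")
  expect_error(mechanism_event("amplify", 200, 100), "n2 >= n1")
  ev <- mechanism_event("division", 1000)
  expect_equal(ev$n2, 500)
})

test_that("cascade closed form reproduces the brute-force per-cycle sum", {
  grid <- expand.grid(N0 = c(100, 1000, 1e5),
                      Nk = c(100, 670, 5000),
                      k = c(1, 7, 29))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (2 * (g$Nk / g$N0)^(1 / g$k) < 1) next
    expect_equal(cascade_variance(g$N0, g$Nk, g$k),
                 cascade_brute(g$N0, g$Nk, g$k), tolerance = 1e-12)
    expect_equal(cascade_variance(g$N0, g$Nk, g$k, n_c = 5),
                 cascade_brute(g$N0, g$Nk, g$k, n_c = 5), tolerance = 1e-12)
  }
  # single constant-size cycle: division at N plus regrowth from N/2
  expect_equal(cascade_variance(1000, 1000, 1),
               1 / 1000 + (1 / 500 - 1 / 1000), tolerance = 1e-12)
  # mouse depletion phase
  expect_equal(cascade_variance(1e5, 670, 29), cascade_brute(1e5, 670, 29),
               tolerance = 1e-12)
})

test_that("selection mean is logistic in the transformed coordinate", {
  expect_equal(selection_mean(3, 0, 0.37), 0.37)
  expect_equal(selection_mean(0, 11, 0.37), 0.37)
  expect_equal(selection_mean(1, 1, 0.5), 1 / (1 + exp(-1)), tolerance = 1e-5)
  # transformed mean is exactly rho * t for any founder
  for (h0 in c(0.2, 0.5, 0.8)) {
    expect_equal(transform_heteroplasmy(selection_mean(0.3, 4, h0), h0),
                 0.3 * 4, tolerance = 1e-12)
  }
})

test_that("selection variance has the neutral limit and vanishes at t = 0", {
  sp <- selection_params(rho = 0.1, nu = 0.5, f = 1, copy_number = 1000)
  expect_equal(selection_variance(sp, 0), 0)
  # numeric rho -> 0 limit against the neutral 2 nu f t / N scaling
  sp0 <- selection_params(rho = 1e-6, nu = 1, f = 1, copy_number = 1000)
  expect_equal(selection_variance(sp0, 1), 0.25 * 2 / 1000,
               tolerance = 1e-4)
  spn <- selection_params(rho = 0, nu = 1, f = 1, copy_number = 1000)
  expect_equal(selection_variance(spn, 1), 0.25 * 0.002)
  # symmetric under sign of rho (relabelling the types)
  spp <- selection_params(rho = 0.3, nu = 1, f = 1, copy_number = 1000)
  spm <- selection_params(rho = -0.3, nu = 1, f = 1, copy_number = 1000)
  expect_equal(selection_variance(spp, 5), selection_variance(spm, 5),
               tolerance = 1e-12)
})

test_that("heteroplasmy transform round-trips and matches the logit difference", {
  expect_equal(transform_heteroplasmy(0.5, 0.5), 0)
  expect_equal(transform_heteroplasmy(0.7, 0.5), log(7 / 3))
  expect_equal(inverse_transform_heteroplasmy(
    transform_heteroplasmy(0.31, 0.42), 0.42), 0.31, tolerance = 1e-12)
  grid <- expand.grid(h = c(0.01, 0.2, 0.5, 0.77, 0.99),
                      h0 = c(0.01, 0.35, 0.5, 0.9, 0.99))
  for (i in seq_len(nrow(grid))) {
    expect_equal(inverse_transform_heteroplasmy(
      transform_heteroplasmy(grid$h[i], grid$h0[i]), grid$h0[i]),
      grid$h[i], tolerance = 1e-12)
  }
  expect_error(transform_heteroplasmy(1, 0.5), "fixated")
})

test_that("contributions are monotone in their drivers", {
  t_grid <- c(0.5, 1, 2, 4)
  expect_true(all(diff(turnover_contribution(1, 1, t_grid, 1000)) > 0))
  expect_true(all(diff(conversion_contribution(0.002, 0.2, t_grid)) > 0))
  n_grid <- c(100, 500, 1000, 5000)
  expect_true(all(diff(division_contribution(n_grid)) < 0))
  expect_true(all(diff(vapply(1:4, function(nd)
    turnover_contribution(1, 1, 1, 1000, nd), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(1, 2, 5), function(nc)
    division_contribution(1000, nc), numeric(1))) > 0))
})

test_that("variance summaries enforce realisability", {
  vs <- variance_summary(0.5, 0.05)
  expect_equal(vs$norm_var, 0.2)
  expect_equal(vs$bottleneck_size, 5)
  expect_equal(vs$bottleneck_param, 0.8)
  expect_error(variance_summary(0.5, 0.3), "outside")
})
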