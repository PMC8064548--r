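test_that("every partition conserves molecules exactly", {
  set.seed(7)
  for (i in 1:30) {
    pool <- odna_pool(sample(0:40, 1), sample(0:40, 1))
    tot <- pool$n_wild + pool$n_mut
    if (tot == 0) next
    n_out <- sample(0:tot, 1)
    for (dd in list(partition_hypergeometric(pool, n_out),
                    partition_hypergeometric(pool, n_out, n_c = 3),
                    partition_perfect(pool))) {
      expect_equal(dd[[1]]$n_wild + dd[[2]]$n_wild, pool$n_wild)
      expect_equal(dd[[1]]$n_mut + dd[[2]]$n_mut, pool$n_mut)
    }
    # the binomial comparison model conserves totals (not molecule fates)
    db <- partition_binomial(pool)
    expect_equal(db[[1]]$n_wild + db[[1]]$n_mut +
                   db[[2]]$n_wild + db[[2]]$n_mut, tot)
  }
})

test_that("hypergeometric partition takes the whole pool when asked", {
  dd <- partition_hypergeometric(odna_pool(5, 5), 10)
  expect_equal(dd[[1]]$n_wild, 5)
  expect_equal(dd[[1]]$n_mut, 5)
  expect_equal(dd[[2]]$n_wild + dd[[2]]$n_mut, 0)
  expect_error(partition_hypergeometric(odna_pool(5, 5), 11), "exceeds")
})

test_that("hypergeometric halving matches the closed-form variance, cluster size scales it", {
  set.seed(11)
  reps <- 20000
  h1 <- replicate(reps, {
    d <- partition_hypergeometric(odna_pool(500, 500), 500)
    d[[1]]$n_mut / 500
  })
  nv <- var(h1) / (mean(h1) * (1 - mean(h1)))
  se <- nv * sqrt(2 / (reps - 1))
  expect_lt(abs(nv - 1 / 999), 3.3 * se)

  h10 <- replicate(reps, {
    d <- partition_hypergeometric(odna_pool(500, 500), 500, n_c = 10)
    d[[1]]$n_mut / 500
  })
  nv10 <- var(h10) / (mean(h10) * (1 - mean(h10)))
  expect_gt(nv10 / nv, 7)
  expect_lt(nv10 / nv, 13)
})

test_that("binomial partitioning doubles the division variance to 2/n", {
  set.seed(13)
  reps <- 20000
  h1 <- replicate(reps, {
    d <- partition_binomial(odna_pool(500, 500))
    tot <- d[[1]]$n_wild + d[[1]]$n_mut
    if (tot == 0) NA_real_ else d[[1]]$n_mut / tot
  })
  h1 <- h1[!is.na(h1)]
  nv <- var(h1) / (mean(h1) * (1 - mean(h1)))
  se <- nv * sqrt(2 / (length(h1) - 1))
  expect_lt(abs(nv - 2 / 1000), 3.3 * se)
})

test_that("perfect partitioning adds no heteroplasmy variance and flips fair coins for remainders", {
  dd <- partition_perfect(odna_pool(500, 500))
  expect_equal(dd[[1]]$n_wild, 250)
  expect_equal(dd[[1]]$n_mut, 250)
  set.seed(17)
  w1 <- replicate(2000, partition_perfect(odna_pool(3, 2))[[1]]$n_wild)
  expect_setequal(unique(w1), c(1, 2))
  expect_lt(abs(mean(w1) - 1.5), 0.05)
  # even pools: zero variance increment
  h1 <- replicate(200, {
    d <- partition_perfect(odna_pool(400, 600))
    d[[1]]$n_mut / 500
  })
  expect_equal(var(h1), 0)
})

test_that("Polya amplification is absorbing at homoplasmy and beta-binomial in law", {
  p <- polya_amplify(odna_pool(1, 0), 100)
  expect_equal(c(p$n_wild, p$n_mut), c(100, 0))
  p <- polya_amplify(odna_pool(0, 3), 50)
  expect_equal(c(p$n_wild, p$n_mut), c(0, 50))
  expect_error(polya_amplify(odna_pool(0, 0), 10), "empty")
  expect_error(polya_amplify(odna_pool(5, 5), 5), ">=")

  # pmf equals full urn-history enumeration
  expect_equal(polya_pmf(0:4, 4, 2, 2), polya_pmf_enum(4, 2, 2),
               tolerance = 1e-12)
  expect_equal(polya_pmf(0:6, 6, 3, 1), polya_pmf_enum(6, 3, 1),
               tolerance = 1e-12)
  expect_equal(sum(polya_pmf(0:9, 9, 4, 7)), 1, tolerance = 1e-12)

  # sampled distribution matches the pmf ((2,2) -> 8)
  set.seed(19)
  draws <- replicate(20000, polya_amplify(odna_pool(2, 2), 8)$n_mut)
  emp <- tabulate(draws - 1, nbins = 7)[1:5] / 20000  # counts 2..6
  expect_lt(max(abs(emp - polya_pmf(0:4, 4, 2, 2))), 0.012)
})

test_that("subsampling variance increments follow the theory terms", {
  set.seed(23)
  reps <- 20000
  hs <- replicate(reps, {
    s <- subsample_pool(odna_pool(500, 500), 100)
    s$n_mut / 100
  })
  nv <- var(hs) / (mean(hs) * (1 - mean(hs)))
  expect_lt(abs(nv - 0.009) / 0.009, 4 * sqrt(2 / reps))
  # identity when keeping everything
  s <- subsample_pool(odna_pool(12, 34), 46)
  expect_equal(c(s$n_wild, s$n_mut), c(12, 34))
  # with replacement: 1/n2
  hr <- replicate(reps, {
    s <- subsample_pool(odna_pool(500, 500), 100, with_replacement = TRUE)
    s$n_mut / 100
  })
  nvr <- var(hr) / (mean(hr) * (1 - mean(hr)))
  expect_lt(abs(nvr - 0.01) / 0.01, 4 * sqrt(2 / reps))
})

test_that("homoplasmic pools stay homoplasmic through every operation", {
  set.seed(29)
  pool <- odna_pool(40, 0)
  expect_equal(partition_hypergeometric(pool, 20)[[1]]$n_mut, 0)
  expect_equal(partition_binomial(pool)[[1]]$n_mut, 0)
  expect_equal(partition_perfect(pool)[[1]]$n_mut, 0)
  expect_equal(polya_amplify(pool, 200)$n_mut, 0)
  expect_equal(subsample_pool(pool, 10)$n_mut, 0)
})

test_that("organelle spreading reduces copy-number noise but not heteroplasmy variance", {
  none <- spatial_partition_experiment(50, 0.5, "none", n_reps = 800,
                                       seed = 31)
  repu <- spatial_partition_experiment(50, 0.5, "repulsive", n_reps = 800,
                                       seed = 32)
  # binomial reference n/4 = 12.5 for the noninteracting case
  expect_lt(abs(none$var_N - 12.5) / 12.5, 0.3)
  expect_lt(repu$var_N, 0.6 * none$var_N)
  # heteroplasmy variance equivalent within combined error bands
  se <- sqrt(none$norm_var_h_se^2 + repu$norm_var_h_se^2)
  expect_lt(abs(none$norm_var_h - repu$norm_var_h), 3 * se)
})
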