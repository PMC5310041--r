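test_that("summarize_draws gives means and type-7 central intervals", {
  s <- summarize_draws(rep(3.5, 10))
  expect_equal(unlist(s), c(mean = 3.5, conf.low = 3.5, conf.high = 3.5))

  s2 <- summarize_draws(1:100)
  expect_equal(s2$mean, 50.5)
  expect_equal(s2$conf.low, 3.475)
  expect_equal(s2$conf.high, 97.525)

  set.seed(1)
  x <- rnorm(501)
  expect_equal(summarize_draws(sample(x)), summarize_draws(x))
  # the central interval always contains the median
  for (i in 1:10) {
    y <- rexp(51) - i / 3
    si <- summarize_draws(y)
    expect_lte(si$conf.low, median(y))
    expect_gte(si$conf.high, median(y))
  }
  # data-frame input summarizes column-wise
  sm <- summarize_draws(data.frame(a = 1:100, b = rep(2, 100)))
  expect_equal(sm$term, c("a", "b"))
  expect_equal(sm$mean, c(50.5, 2))
  expect_error(summarize_draws(numeric(0)), "nonempty")
})

test_that("pMCMC matches enumeration on small draw sets", {
  d <- c(-1, 1, 2, 3)
  one <- pmcmc_compare(d, 0, convention = "one_sided")
  expect_equal(one$pmcmc, 0.25)
  two <- pmcmc_compare(d, 0, convention = "doubled")
  expect_equal(two$pmcmc, 0.5)

  # all draws on one side: floored at the chain resolution
  allpos <- pmcmc_compare(rep(1, 2000) + runif(2000), 0)
  expect_equal(allpos$pmcmc, 1 / 2000)

  # symmetric difference: about half the draws oppose the mean
  set.seed(2)
  sym <- pmcmc_compare(rnorm(20000), 0)
  expect_equal(sym$pmcmc, 0.5, tolerance = 0.02)

  # reversing the contrast gives the same pMCMC
  set.seed(3)
  x <- rnorm(500, 1)
  y <- rnorm(500)
  expect_equal(pmcmc_compare(x, y)$pmcmc, pmcmc_compare(y, x)$pmcmc)
  expect_error(pmcmc_compare(numeric(0), 1), "nonempty")
})

test_that("virulence combines tolerance base and intensity as 1 - b^I", {
  # point masses: direct arithmetic
  vd <- compute_virulence(list(A = rep(log(0.963), 10)),
                          list(A = rep(5, 10)), n_resample = 100L, seed = 1L)
  expect_equal(unique(vd$virulence), 1 - 0.963^5)
  expect_equal(round(unique(vd$virulence), 4), 0.1718)

  # b = 1 (zero slope) means no fecundity loss whatever the burden
  vd0 <- compute_virulence(list(A = rep(0, 10)), list(A = rexp(10) + 1),
                           n_resample = 50L, seed = 1L)
  expect_true(all(vd0$virulence == 0))

  # zero intensity means no loss whatever the tolerance base
  vdI <- compute_virulence(list(A = rnorm(10, -0.1, 0.01)), list(A = rep(0, 10)),
                           n_resample = 50L, seed = 1L)
  expect_true(all(vdI$virulence == 0))

  expect_error(compute_virulence(list(A = -0.1), list(A = -2)), "non-negative")

  # monotone in intensity for fixed b, and in b for fixed intensity
  v_of_I <- vapply(c(0.5, 1, 2, 4, 8), function(I) 1 - 0.9^I, numeric(1))
  expect_true(all(diff(v_of_I) > 0))
  v_of_b <- vapply(c(0.5, 0.7, 0.9, 0.99), function(b) 1 - b^3, numeric(1))
  expect_true(all(diff(v_of_b) < 0))

  # resampling is seeded and sized
  a <- compute_virulence(list(A = rnorm(100, -0.05, 0.01)),
                         list(A = rexp(100) + 1), n_resample = 2000L, seed = 9L)
  b <- compute_virulence(list(A = rnorm(100, -0.05, 0.01)),
                         list(A = rexp(100) + 1), n_resample = 2000L, seed = 9L)
  expect_equal(nrow(a), 2000L)
  # different input RNG streams: only the resampling seed is shared, so
  # regenerate identical inputs for a true determinism check
  set.seed(5); bA <- rnorm(100, -0.05, 0.01); iA <- rexp(100) + 1
  a1 <- compute_virulence(list(A = bA), list(A = iA), seed = 9L)
  a2 <- compute_virulence(list(A = bA), list(A = iA), seed = 9L)
  expect_identical(a1, a2)
})

test_that("virulence summaries and comparisons work from fit objects", {
  tol <- point_tolerance_fit(log(242.4), log(322.4), log(0.963), log(0.917))
  res <- point_resistance_fit(
    zeta = c(A = qlogis(0.2), I = qlogis(0.18), O = qlogis(0.12), M = qlogis(0.14)),
    eta = c(A = log(3), I = log(2), O = log(4), M = log(2.5))
  )
  vd <- compute_virulence(tol, res, n_resample = 500L, seed = 3L)
  expect_setequal(unique(vd$morph), c("A", "I"))
  td <- tidy(vd)
  expect_equal(td$mean[td$morph == "A"], 1 - 0.963^ztpois_mean(3))
  expect_equal(td$mean[td$morph == "I"], 1 - 0.917^ztpois_mean(2))
  cmp <- virulence_compare(vd)
  expect_true(cmp$pmcmc >= 1 / 500 && cmp$pmcmc <= 1)
  # raw-rate intensity variant
  vd_raw <- compute_virulence(tol, res, n_resample = 100L, seed = 3L,
                              intensity = "lambda")
  expect_equal(unique(vd_raw$virulence[vd_raw$morph == "A"]), 1 - 0.963^3)
})

test_that("Gelman-Rubin matches the hand formula and flags divergence", {
  # identical chains: W = var(1:4) = 10/3, B = 0
  # Rhat = sqrt((N - 1) / N) = sqrt(3/4)
  expect_equal(gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4))), sqrt(3 / 4))

  # hand-computed on two offset 4-element chains
  c1 <- c(1, 2, 3, 4); c2 <- c(2, 3, 4, 6)
  W <- (var(c1) + var(c2)) / 2
  Bn <- var(c(mean(c1), mean(c2)))
  expect_equal(gelman_rubin(list(c1, c2)), sqrt((3 / 4 * W + Bn) / W))

  # long same-distribution chains converge to ~1
  set.seed(4)
  ch <- list(rnorm(5000), rnorm(5000))
  expect_gt(gelman_rubin(ch), 0.99)
  expect_lt(gelman_rubin(ch), 1.05)

  # disjoint chains must be flagged
  expect_gt(gelman_rubin(list(rnorm(200), rnorm(200, 10))), 1.1)

  expect_error(gelman_rubin(list(1:4)), "two chains")
  expect_error(gelman_rubin(list(1:4, 1:5)), "equal length")
  # matrix interface
  expect_equal(gelman_rubin(cbind(c1, c2)), gelman_rubin(list(c1, c2)))
})

test_that("autocorrelation matches known processes", {
  # perfectly alternating sequence: lag-1 autocorrelation -> -1
  n <- 2000L
  alt <- rep(c(1, -1), n / 2)
  expect_equal(autocorrelation(alt, 1L), -(n - 1) / n)
  expect_lt(autocorrelation(alt, 1L), -0.99)

  # independent draws: weak lag-1 autocorrelation
  set.seed(6)
  expect_lt(abs(autocorrelation(rnorm(2000), 1L)), 0.1)

  # AR(1) with coefficient 0.5
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), n = 10000))
  expect_equal(autocorrelation(x, 1L), 0.5, tolerance = 0.03)

  expect_equal(autocorrelation(1:10, 0L), 1)
  expect_warning(a0 <- autocorrelation(rep(2, 10), 1L), "Constant")
  expect_equal(a0, 0)
  expect_error(autocorrelation(1:5, 5L), "lag")
})

test_that("effective sample size tracks the autocorrelation structure", {
  set.seed(8)
  iid <- rnorm(2000)
  ess_iid <- effective_sample_size(iid)
  expect_gt(ess_iid, 1000)
  expect_lte(ess_iid, 2000)

  ar <- as.numeric(stats::arima.sim(list(ar = 0.5), n = 10000))
  ess_ar <- effective_sample_size(ar)   # true tau = 3
  expect_gt(ess_ar, 10000 / 5)
  expect_lt(ess_ar, 10000 / 2)

  expect_warning(ess_const <- effective_sample_size(rep(1, 50)), "Constant")
  expect_equal(ess_const, 50)
})

test_that("diagnostics agree with the coda reference implementation", {
  set.seed(10)
  chains <- list(rnorm(1000), rnorm(1000, 0.05))
  ours <- gelman_rubin(chains)
  ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
  ref <- unname(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1])
  expect_equal(ours, ref, tolerance = 0.01)

  ar <- as.numeric(stats::arima.sim(list(ar = 0.6), n = 5000))
  expect_equal(effective_sample_size(ar),
               unname(coda::effectiveSize(coda::mcmc(ar))),
               tolerance = 0.25 * 5000)
})
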