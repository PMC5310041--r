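test_that("simulation is deterministic in the config seed", {
  cfg <- small_config(seed = 11L)
  expect_identical(simulate_resistance_survey(cfg),
                   simulate_resistance_survey(cfg))
  expect_identical(simulate_fecundity_survey(cfg),
                   simulate_fecundity_survey(cfg))
  # a different seed changes the data
  expect_false(identical(simulate_resistance_survey(cfg),
                         simulate_resistance_survey(cfg, seed = 12L)))
})

test_that("hurdle zeros and truncation behave at the extremes", {
  cfg <- small_config(seed = 5L,
                      zeta = c(A = -10, I = -10, O = -10, M = -10))
  surv <- simulate_resistance_survey(cfg)
  expect_gte(mean(surv$mites == 0L), 0.999)

  cfg2 <- small_config(seed = 6L, zeta = c(A = 3, I = 3, O = 3, M = 3))
  surv2 <- simulate_resistance_survey(cfg2)
  infected <- surv2$mites[surv2$mites > 0L]
  expect_gt(length(infected), 0L)
  expect_true(all(infected >= 1L))
  expect_true(all(surv2$mites >= 0L))
})

test_that("the empirical zero fraction matches the configured probability", {
  # prevalence 0.16 with no random effects or over-dispersion:
  # zero fraction is a plain binomial frequency at 0.84
  cfg <- generator_config(
    n_populations = 8L, n_years = 5L,
    n_per_group = c(A = 125L, I = 125L, O = 125L, M = 125L),
    zeta = c(A = qlogis(0.16), I = qlogis(0.16), O = qlogis(0.16), M = qlogis(0.16)),
    s2_group_logit = 0, s2_unit_logit = 0,
    seed = 404L
  )
  surv <- simulate_resistance_survey(cfg)
  expect_equal(nrow(surv), 20000L)
  expect_lt(abs(mean(surv$mites == 0L) - 0.84), 0.01)
})

test_that("rztpois matches the truncated-Poisson moments and support", {
  set.seed(99)
  for (lam in c(0.1, 1, 5)) {
    x <- rztpois(20000L, lam)
    expect_true(all(x >= 1L))
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - ztpois_mean(lam)), 4 * se + 1e-9)
  }
  expect_error(rztpois(5, 0), "positive")
})

test_that("fecundity means follow exp(alpha) when slopes and variances vanish", {
  cfg <- small_config(
    seed = 21L,
    beta = c(A = 0, I = 0),
    s2_u0 = 0, s2_u1 = 0, cov_u01 = 0, s2_eps = 0,
    n_fec_per_group = c(A = 300L, I = 300L)
  )
  surv <- simulate_fecundity_survey(cfg)
  mA <- mean(surv$eggs[surv$phenotype == "A"])
  mI <- mean(surv$eggs[surv$phenotype == "I"])
  expect_lt(abs(mA - exp(cfg$alpha[["A"]])), 3 * sqrt(exp(cfg$alpha[["A"]]) / 2400))
  expect_lt(abs(mI - exp(cfg$alpha[["I"]])), 3 * sqrt(exp(cfg$alpha[["I"]]) / 2400))
  # no dependence on mite load
  infected <- surv$mites > 0
  expect_lt(abs(mean(surv$eggs[infected & surv$phenotype == "A"]) - mA), 10)
})

test_that("unit-level over-dispersion inflates the egg variance beyond Poisson", {
  base <- small_config(seed = 31L, s2_u0 = 0, s2_u1 = 0, cov_u01 = 0,
                       s2_eps = 0, n_fec_per_group = c(A = 200L, I = 0L))
  od <- small_config(seed = 31L, s2_u0 = 0, s2_u1 = 0, cov_u01 = 0,
                     s2_eps = 0.2, n_fec_per_group = c(A = 200L, I = 0L))
  eggs0 <- simulate_fecundity_survey(base, mites = 0L)$eggs
  eggs1 <- simulate_fecundity_survey(od, mites = 0L)$eggs
  # Poisson: var ~= mean; log-normal mixing: var >> mean
  expect_lt(var(eggs0) / mean(eggs0), 2)
  expect_gt(var(eggs1) / mean(eggs1), 10)
})

test_that("eggs are non-negative integers and uninfected females have zero mites", {
  surv <- simulate_fecundity_survey(small_config(seed = 41L))
  expect_true(all(surv$eggs >= 0L))
  expect_true(is.integer(surv$eggs))
  res <- simulate_resistance_survey(small_config(seed = 41L))
  expect_true(all(res$mites >= 0L))
  expect_true(all(is.na(res$eggs)))
})

test_that("the paper-mimic configuration encodes the reported effects", {
  cfg <- paper_mimic_config()
  expect_s3_class(validate_generator_config(cfg), "generator_config")
  # per-mite retention of morph A: 3.7% decrease
  expect_equal(round(cfg$beta[["A"]], 4), round(log(0.963), 4))
  expect_equal(round(cfg$beta[["I"]], 4), round(log(0.917), 4))
  # intercept contrast 33% on the egg scale
  expect_equal(exp(cfg$alpha[["I"]] - cfg$alpha[["A"]]), 322.4 / 242.4)
  # variance shares on the two resistance link scales
  expect_equal(cfg$s2_group_logit / (cfg$s2_group_logit + cfg$s2_unit_logit),
               0.656, tolerance = 1e-4)
  expect_equal(cfg$s2_group_log / (cfg$s2_group_log + cfg$s2_unit_log),
               0.366, tolerance = 1e-4)
  # a mostly-uninfected survey
  surv <- simulate_resistance_survey(cfg)
  zf <- mean(surv$mites == 0L)
  expect_gt(zf, 0.7)
  expect_lt(abs(zf - config_marginal_prevalence(cfg)$zero_fraction), 0.03)
})

test_that("fecundity ratio of the morphs at zero mites approaches 1.33", {
  cfg <- generator_config(n_populations = 10L, n_years = 4L,
                          n_fec_per_group = c(A = 400L, I = 400L),
                          seed = 51L)
  surv <- simulate_fecundity_survey(cfg, mites = 0L)
  ratio <- mean(surv$eggs[surv$phenotype == "I"]) /
    mean(surv$eggs[surv$phenotype == "A"])
  # group and unit log-normal effects are shared by construction across
  # morphs only in distribution, so allow Monte-Carlo spread
  expect_equal(ratio, 1.33, tolerance = 0.06)
})

test_that("config invariants are enforced", {
  expect_error(generator_config(s2_u0 = -1), "non-negative")
  expect_error(generator_config(cov_u01 = 1), "semi-definite")
  expect_error(generator_config(frac_mated = 1.5), "0, 1")
  expect_error(small_config(n_populations = 0L), "positive")
  cfg <- small_config(n_per_group = c(A = 0L, I = 0L, O = 0L, M = 0L))
  expect_error(simulate_resistance_survey(cfg), "no individuals")
})

test_that("configs round-trip through YAML", {
  cfg <- paper_mimic_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  # YAML stores ~16 significant digits
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-10)
  expect_identical(back$seed, cfg$seed)
  expect_identical(back$n_per_group, cfg$n_per_group)
})
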