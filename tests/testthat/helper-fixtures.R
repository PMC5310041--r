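# Shared fixtures for the test suite. Expensive fits are cached so that
# several test blocks can interrogate the same posterior.

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache, inherits = FALSE)
}

# A tiny hand-built survey with every record type.
tiny_survey <- function() {
  tibble::tibble(
    population = c("P1", "P1", "P1", "P2", "P2", "P2"),
    year = c(2003L, 2003L, 2004L, 2003L, 2004L, 2004L),
    phenotype = c("A", "I", "O", "M", "A", "I"),
    mites = c(0L, 3L, 10L, 0L, 2L, 0L),
    mated = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    eggs = c(200L, 150L, NA_integer_, NA_integer_, 310L, 95L)
  )
}

# Random valid survey for round-trip property tests.
random_survey <- function(n, seed) {
  set.seed(seed)
  pheno <- sample(c("A", "I", "O", "M"), n, replace = TRUE)
  female <- pheno != "M"
  mated <- female & runif(n) < 0.5
  eggs <- ifelse(mated & runif(n) < 0.8, rpois(n, 200), NA_integer_)
  tibble::tibble(
    population = sample(sprintf("P%02d", 1:5), n, replace = TRUE),
    year = sample(2003:2008, n, replace = TRUE),
    phenotype = pheno,
    mites = rpois(n, 1),
    mated = mated,
    eggs = as.integer(eggs)
  )
}

# Short schedule for desk-scale unit-test fits.
fast_schedule <- function(chains = 2L) {
  mitedef::mcmc_schedule(chains = chains, adapt = 200L, burnin = 200L,
                         iter = 1000L, thin = 2L)
}

# Very short single-chain schedule for the replicate-coverage study.
coverage_schedule <- function() {
  mitedef::mcmc_schedule(chains = 1L, adapt = 150L, burnin = 150L,
                         iter = 600L, thin = 3L)
}

# A generator config scaled down for cheap fits; `...` overrides any
# generator_config() argument.
small_config <- function(seed = 42L, ...) {
  args <- list(
    n_populations = 4L, n_years = 2L,
    n_per_group = c(A = 30L, I = 12L, O = 4L, M = 104L),
    n_fec_per_group = c(A = 25L, I = 15L),
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(mitedef::generator_config, args)
}

# Full paper-mimic fits shared by the acceptance blocks.
acceptance_tolerance_fit <- function() {
  cached("tolerance_full", {
    cfg <- mitedef::paper_mimic_config()
    surv <- mitedef::simulate_fecundity_survey(cfg)
    mitedef::fit_tolerance(surv, schedule = mitedef::mcmc_schedule(), seed = 1L)
  })
}

acceptance_resistance_fit <- function() {
  cached("resistance_full", {
    cfg <- mitedef::paper_mimic_config()
    surv <- mitedef::simulate_resistance_survey(cfg)
    mitedef::fit_resistance(surv, schedule = mitedef::mcmc_schedule(), seed = 1L)
  })
}

# Hand-built fit objects with point-mass draws, for closed-form checks of
# the posterior transforms.
point_tolerance_fit <- function(alpha_A, alpha_I, beta_A, beta_I, n = 50L) {
  structure(
    list(
      draws = tibble::tibble(
        .chain = 1L, .iteration = seq_len(n),
        alpha_A = alpha_A, alpha_I = alpha_I,
        beta_A = beta_A, beta_I = beta_I,
        s2_u0 = 0.01, s2_u1 = 0.001, cov_u01 = 0, cor_u01 = 0, s2_eps = 0.1
      ),
      morphs = c("A", "I"),
      groups = tibble::tibble(group = 1:2, population = c("P1", "P2"),
                              year = c(2003L, 2003L)),
      schedule = mitedef::mcmc_schedule(), seed = 1L,
      n_records = n, runtime = 0
    ),
    class = "tolerance_fit"
  )
}

point_resistance_fit <- function(zeta, eta, n = 50L) {
  draws <- tibble::tibble(.chain = 1L, .iteration = seq_len(n))
  for (p in names(zeta)) draws[[paste0("zeta_", p)]] <- zeta[[p]]
  for (p in names(eta)) draws[[paste0("eta_", p)]] <- eta[[p]]
  draws$s2_group_logit <- 1
  draws$s2_group_log <- 0.2
  draws$s2_unit_log <- 0.2
  structure(
    list(draws = draws, phenotypes = names(zeta),
         groups = tibble::tibble(group = 1:2, population = c("P1", "P2"),
                                 year = c(2003L, 2003L)),
         schedule = mitedef::mcmc_schedule(), seed = 1L,
         s2_unit_logit = 1, n_records = n, n_positive = n, runtime = 0),
    class = "resistance_fit"
  )
}
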