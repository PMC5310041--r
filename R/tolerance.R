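# Fecundity-tolerance model: log-linear Poisson decline of 72-h egg counts
# with mite load for the two common female morphs.
#
#   eggs_i ~ Poisson(exp(alpha_m + (beta_m + u1_g) * mites_i + u0_g + eps_i))
#   (u0_g, u1_g) ~ N2(0, Sigma_u)   unstructured 2x2 per population-by-year
#   eps_i ~ N(0, s2_eps)            additive over-dispersion
#
# Tolerance is the slope: a flatter (less negative) beta_m means the morph
# loses less fecundity per additional mite.

#' Fit the fecundity-tolerance model
#'
#' Fits the random-slope Poisson mixed model by MCMC, with morph-specific
#' intercepts and per-mite slopes, a correlated group intercept/slope pair
#' per population-by-year, and an additive unit-level over-dispersion
#' effect. The group covariance is parameterized as two standard deviations
#' with `half-t(sd_df, sd_scale)` priors and a correlation with a uniform
#' prior on (-1, 1); fixed effects get `Normal(0, fixed_sd^2)`.
#'
#' @param records Survey records of mated A/I females, `eggs` present on
#'   every row. O-females are rejected unless `allow_O = TRUE` (rarely
#'   advisable: in the field data that morph is far too sparse for a
#'   stable group-level reaction norm).
#' @param schedule An [mcmc_schedule()].
#' @param seed Integer seed.
#' @param fixed_sd,sd_scale,sd_df Prior hyperparameters (standard-deviation
#'   scale 1 by default: proportionate to log-egg-scale spreads).
#' @param allow_O Also admit O-females as a third morph level (emits a
#'   warning).
#' @return An object of class `tolerance_fit` with draws of `alpha_<m>`,
#'   `beta_<m>`, `s2_u0`, `s2_u1`, `cov_u01`, `cor_u01`, `s2_eps`, plus
#'   metadata as in [fit_resistance()].
#' @export
fit_tolerance <- function(records, schedule = mcmc_schedule(), seed = 1L,
                          fixed_sd = 10, sd_scale = 1, sd_df = 3,
                          allow_O = FALSE) {
  records <- validate_survey(records, strict = TRUE)
  morphs <- tolerance_morphs()
  if (allow_O) {
    morphs <- c(morphs, "O")
    warn("Including O-females: group-level reaction norms for this rare morph are typically unstable.")
  }
  records <- filter(records, .data$phenotype %in% morphs, .data$mated)
  if (any(is.na(records$eggs))) abort("All mated-female records must carry an egg count.")
  morphs <- morphs[morphs %in% records$phenotype]
  if (length(morphs) < 2L) {
    abort("Both morphs A and I must be present: the tolerance contrast is undefined for a single morph.")
  }
  gi <- group_index(records)
  G <- nrow(gi$groups)
  if (G < 2L) abort("Need at least two population-by-year groups.")
  mi <- match(as.character(records$phenotype), morphs)

  model <- "model {
    for (i in 1:n) {
      y[i] ~ dpois(elam[i])
      elam[i] <- exp(theta[i])
      theta[i] ~ dnorm(mu[i], tau_e)
      mu[i] <- alpha[morph[i]] + (beta[morph[i]] + u1[g[i]]) * m[i] + u0[g[i]]
    }
    for (j in 1:G) {
      z0[j] ~ dnorm(0, 1)
      z1[j] ~ dnorm(0, 1)
      u0[j] <- sd0 * z0[j]
      u1[j] <- sd1 * (rho * z0[j] + sqrt(1 - rho * rho) * z1[j])
    }
    for (k in 1:P) {
      alpha[k] ~ dnorm(0, prec_fixed)
      beta[k] ~ dnorm(0, prec_fixed)
    }
    sd0 ~ dt(0, prec_sd, df_sd) T(0,)
    sd1 ~ dt(0, prec_sd, df_sd) T(0,)
    rho ~ dunif(-1, 1)
    sd_e ~ dt(0, prec_sd, df_sd) T(0,)
    tau_e <- pow(sd_e, -2)
  }"

  mean_log_eggs <- mean(log(records$eggs + 0.5))
  t0 <- Sys.time()
  draws <- run_jags(
    model,
    data = list(y = records$eggs, morph = mi, m = records$mites,
                g = gi$index, n = nrow(records), G = G, P = length(morphs),
                prec_fixed = 1 / fixed_sd^2, prec_sd = 1 / sd_scale^2,
                df_sd = sd_df),
    params = c("alpha", "beta", "sd0", "sd1", "rho", "sd_e"),
    schedule = schedule, seed = seed,
    inits = list(theta = log(records$eggs + 0.5),
                 alpha = rep(mean_log_eggs, length(morphs)),
                 beta = rep(0, length(morphs)),
                 sd0 = 0.2, sd1 = 0.05, sd_e = 0.5)
  )
  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  nm <- names(draws)
  for (k in seq_along(morphs)) {
    nm[nm == sprintf("alpha[%d]", k)] <- paste0("alpha_", morphs[k])
    nm[nm == sprintf("beta[%d]", k)] <- paste0("beta_", morphs[k])
  }
  names(draws) <- nm
  draws$s2_u0 <- draws$sd0^2
  draws$s2_u1 <- draws$sd1^2
  draws$cov_u01 <- draws$rho * draws$sd0 * draws$sd1
  draws$cor_u01 <- draws$rho
  draws$s2_eps <- draws$sd_e^2
  draws$sd0 <- draws$sd1 <- draws$rho <- draws$sd_e <- NULL

  structure(
    list(draws = draws, morphs = morphs, groups = gi$groups,
         schedule = schedule, seed = as.integer(seed),
         n_records = nrow(records), runtime = runtime),
    class = "tolerance_fit"
  )
}

#' @export
print.tolerance_fit <- function(x, ...) {
  cat("Fecundity-tolerance fit (random-slope Poisson mixed model)\n")
  cat(sprintf("  mated females: %d, groups: %d, morphs: %s\n",
              x$n_records, nrow(x$groups), paste(x$morphs, collapse = ", ")))
  cat(sprintf("  chains: %d, kept draws: %d, runtime: %.1f s\n",
              x$schedule$chains, nrow(x$draws), x$runtime))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @method tidy tolerance_fit
#' @export
tidy.tolerance_fit <- function(x, ...) {
  draws_diagnostics(x$draws, fit_params(x))
}

#' @method glance tolerance_fit
#' @export
glance.tolerance_fit <- function(x, ...) {
  td <- tidy(x)
  tibble(n_records = x$n_records, n_groups = nrow(x$groups),
         n_draws = nrow(x$draws), chains = x$schedule$chains,
         max_rhat = max_rhat(td), min_ess = min(td$ess),
         runtime = x$runtime)
}

#' Per-mite percent decrease in fecundity
#'
#' Transforms each slope draw to the percent fecundity lost per additional
#' mite, `(1 - exp(beta)) * 100`, and summarizes. Positive values mean
#' fecundity loss.
#'
#' @param fit A `tolerance_fit`, or a data frame / named list whose
#'   elements are slope draws per morph (on the log scale).
#' @return Tibble: `morph`, `mean`, `conf.low`, `conf.high`.
#' @export
percent_decrease_per_mite <- function(fit) {
  betas <- if (inherits(fit, "tolerance_fit")) {
    setNames(lapply(fit$morphs, function(m) fit$draws[[paste0("beta_", m)]]),
             fit$morphs)
  } else {
    as.list(fit)
  }
  purrr::imap_dfr(betas, function(b, m) {
    if (any(!is.finite(b))) abort("Slope draws must be finite.")
    s <- summarize_draws((1 - exp(b)) * 100)
    tibble(morph = m, mean = s$mean,
           conf.low = s$conf.low, conf.high = s$conf.high)
  })
}

#' Morph contrast in zero-parasite fecundity
#'
#' Draw-wise contrasts of the two intercepts at mite load zero:
#' the egg-scale difference `exp(alpha_I) - exp(alpha_A)` and the ratio
#' `exp(alpha_I - alpha_A)`, each with posterior mean, central 95% CI and a
#' pMCMC for the direction of the contrast.
#'
#' @param fit A `tolerance_fit` containing morphs A and I.
#' @param convention pMCMC sidedness passed to [pmcmc_compare()].
#' @return Tibble with rows `difference` (eggs) and `ratio`
#'   (dimensionless): `term`, `mean`, `conf.low`, `conf.high`, `pmcmc`,
#'   `convention`.
#' @export
intercept_contrast <- function(fit, convention = c("one_sided", "doubled")) {
  stopifnot(inherits(fit, "tolerance_fit"))
  convention <- match.arg(convention)
  aA <- fit$draws$alpha_A
  aI <- fit$draws$alpha_I
  diff_draws <- exp(aI) - exp(aA)
  ratio_draws <- exp(aI - aA)
  s1 <- summarize_draws(diff_draws)
  s2 <- summarize_draws(ratio_draws)
  p1 <- pmcmc_compare(exp(aI), exp(aA), convention = convention)
  bind_rows(
    tibble(term = "difference", mean = s1$mean, conf.low = s1$conf.low,
           conf.high = s1$conf.high, pmcmc = p1$pmcmc, convention = convention),
    tibble(term = "ratio", mean = s2$mean, conf.low = s2$conf.low,
           conf.high = s2$conf.high, pmcmc = p1$pmcmc, convention = convention)
  )
}

#' Fitted fecundity over a mite-load grid
#'
#' Draw-wise fitted means `exp(alpha_m + beta_m * mites)` summarized per
#' grid point (fitted-mean band, not a posterior predictive band).
#'
#' @param fit A `tolerance_fit`.
#' @param mite_grid Non-negative integer grid (default 0..56, the observed
#'   field range).
#' @param morphs Morphs to predict for (default all fitted).
#' @return Tibble: `morph`, `mites`, `mean`, `conf.low`, `conf.high`.
#' @export
predict_fecundity <- function(fit, mite_grid = 0:56, morphs = NULL) {
  stopifnot(inherits(fit, "tolerance_fit"))
  if (any(mite_grid < 0)) abort("`mite_grid` must be non-negative.")
  morphs <- if (is.null(morphs)) fit$morphs else intersect(morphs, fit$morphs)
  purrr::map_dfr(morphs, function(mo) {
    a <- fit$draws[[paste0("alpha_", mo)]]
    b <- fit$draws[[paste0("beta_", mo)]]
    purrr::map_dfr(mite_grid, function(m) {
      s <- summarize_draws(exp(a + b * m))
      tibble(morph = mo, mites = m, mean = s$mean,
             conf.low = s$conf.low, conf.high = s$conf.high)
    })
  })
}

#' Variance partition of a fitted process
#'
#' Draw-wise share of latent (link-scale) variance attributable to the
#' population-by-year random effect, `s2_group / (s2_group + s2_unit)`;
#' no link-distribution variance term is added.
#'
#' For a `resistance_fit`, `process` selects the hurdle (`"logit"`, where
#' the unit variance is the fixed binary dispersion 1) or the count process
#' (`"log"`). For a `tolerance_fit` the partition is group intercept
#' variance against unit-level over-dispersion.
#'
#' @param fit A `resistance_fit` or `tolerance_fit`.
#' @param process For resistance fits: `"logit"` or `"log"`.
#' @return Tibble: `process`, `mean`, `conf.low`, `conf.high`.
#' @export
variance_partition <- function(fit, process = c("logit", "log")) {
  if (inherits(fit, "resistance_fit")) {
    process <- match.arg(process)
    ratio <- if (process == "logit") {
      fit$draws$s2_group_logit / (fit$draws$s2_group_logit + fit$s2_unit_logit)
    } else {
      fit$draws$s2_group_log / (fit$draws$s2_group_log + fit$draws$s2_unit_log)
    }
  } else if (inherits(fit, "tolerance_fit")) {
    process <- "intercept"
    ratio <- fit$draws$s2_u0 / (fit$draws$s2_u0 + fit$draws$s2_eps)
  } else {
    abort("`fit` must be a resistance_fit or tolerance_fit.")
  }
  s <- summarize_draws(ratio)
  tibble(process = process, mean = s$mean,
         conf.low = s$conf.low, conf.high = s$conf.high)
}
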