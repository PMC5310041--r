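# Zero-altered (hurdle) Poisson model for parasite resistance.
#
# Two sub-processes, each with phenotype fixed effects, a population-by-year
# group effect and additive unit-level over-dispersion on the link scale:
#   hurdle:  P(mites > 0) = plogis(zeta_p + u_g + e),  e ~ N(0, 1)
#   counts:  mites | mites > 0 ~ ZTPois(exp(eta_p + v_g + f)), f ~ N(0, s2_unit_log)
# The hurdle likelihood cannot identify a free unit-level variance from
# binary data, so it is fixed at 1 (the standard convention for additive
# over-dispersion with binary responses); the count-process unit variance
# is estimated.

#' Zero-altered Poisson log-likelihood
#'
#' Pointwise log-probability of a mite count under the hurdle model, given
#' the two linear predictors: `p = plogis(hurdle_lp)` is the probability of
#' infection and `lambda = exp(count_lp)` the rate of the zero-truncated
#' count process. For `k = 0` the log-probability is `log(1 - p)`; for
#' `k >= 1` it is `log(p) + dpois(k, lambda, log = TRUE) - log(1 - exp(-lambda))`.
#'
#' @param mites Non-negative integer count(s).
#' @param hurdle_lp,count_lp Linear predictors on the logit and log scales;
#'   recycled against `mites`.
#' @return Numeric vector of log-probabilities (finite for finite inputs).
#' @export
zap_loglik <- function(mites, hurdle_lp, count_lp) {
  n <- max(length(mites), length(hurdle_lp), length(count_lp))
  k <- rep_len(as.numeric(mites), n)
  h <- rep_len(hurdle_lp, n)
  cl <- rep_len(count_lp, n)
  if (any(k < 0 | k != floor(k))) abort("`mites` must be non-negative integers.")
  lam <- exp(cl)
  logp <- plogis(h, log.p = TRUE)                     # log p
  log1mp <- plogis(h, lower.tail = FALSE, log.p = TRUE) # log(1 - p)
  # log(1 - exp(-lambda)), stable for small lambda
  log_trunc <- ppois(0, lam, lower.tail = FALSE, log.p = TRUE)
  out <- ifelse(k == 0,
                log1mp,
                logp + dpois(k, lam, log = TRUE) - log_trunc)
  out
}

#' Mean of a zero-truncated Poisson
#'
#' Expected count among infected hosts when the untruncated rate is
#' `lambda`: `lambda / (1 - exp(-lambda))`. Numerically stable as
#' `lambda -> 0`, where the limit is 1 (an infected host carries at least
#' one mite).
#'
#' @param lambda Positive rate(s).
#' @return Numeric vector of truncated means, all `>= 1`.
#' @export
ztpois_mean <- function(lambda) {
  if (any(lambda <= 0, na.rm = TRUE)) abort("`lambda` must be positive.")
  lambda / (-expm1(-lambda))
}

#' Fit the resistance (zero-altered Poisson) model
#'
#' Fits the hurdle and zero-truncated count processes by MCMC. Both carry
#' phenotype fixed effects and a population-by-year random intercept;
#' unit-level over-dispersion is sampled as a latent normal effect on the
#' link scale (variance fixed at 1 for the binary hurdle, estimated for the
#' count process). Since the hurdle likelihood factorizes over the two
#' processes, they are sampled as two independent chains sharing the seed
#' policy, which is statistically identical to a joint sampler.
#'
#' Priors: `Normal(0, fixed_sd^2)` on fixed effects and
#' `half-t(df = sd_df, scale = sd_scale)` on random-effect and
#' over-dispersion standard deviations.
#'
#' @param records A survey data frame (all phenotypes, zero counts
#'   included).
#' @param schedule An [mcmc_schedule()].
#' @param seed Integer seed; chains are seeded deterministically from it.
#' @param fixed_sd,sd_scale,sd_df Prior hyperparameters.
#' @return An object of class `resistance_fit` with elements `draws`
#'   (tibble: `.chain`, `.iteration`, `zeta_<p>`, `eta_<p>`,
#'   `s2_group_logit`, `s2_group_log`, `s2_unit_log`), `phenotypes`,
#'   `groups`, `schedule`, `seed`, `s2_unit_logit` (the fixed value 1) and
#'   `runtime` (seconds).
#' @export
fit_resistance <- function(records, schedule = mcmc_schedule(), seed = 1L,
                           fixed_sd = 10, sd_scale = 2, sd_df = 3) {
  records <- validate_survey(records, strict = TRUE)
  ph_present <- phenotype_levels()[phenotype_levels() %in% records$phenotype]
  if (length(ph_present) < 2L) abort("Need at least two phenotype levels.")
  gi <- group_index(records)
  G <- nrow(gi$groups)
  if (G < 2L) abort("Need at least two population-by-year groups.")
  ph <- match(as.character(records$phenotype), ph_present)
  z <- as.integer(records$mites > 0L)

  hurdle_model <- "model {
    for (i in 1:n) {
      z[i] ~ dbern(ilogit(theta[i]))
      theta[i] ~ dnorm(zeta[ph[i]] + u[g[i]], 1)
    }
    for (j in 1:G) { u[j] ~ dnorm(0, tau_g) }
    for (k in 1:P) { zeta[k] ~ dnorm(0, prec_fixed) }
    sd_g ~ dt(0, prec_sd, df_sd) T(0,)
    tau_g <- pow(sd_g, -2)
  }"
  count_model <- "model {
    for (i in 1:m) {
      k[i] ~ dpois(elam[i]) T(1,)
      elam[i] <- exp(theta[i])
      theta[i] ~ dnorm(eta[ph[i]] + v[g[i]], tau_f)
      }
    for (j in 1:G) { v[j] ~ dnorm(0, tau_g) }
    for (kk in 1:P) { eta[kk] ~ dnorm(0, prec_fixed) }
    sd_g ~ dt(0, prec_sd, df_sd) T(0,)
    tau_g <- pow(sd_g, -2)
    sd_f ~ dt(0, prec_sd, df_sd) T(0,)
    tau_f <- pow(sd_f, -2)
  }"
  prec_fixed <- 1 / fixed_sd^2
  prec_sd <- 1 / sd_scale^2

  t0 <- Sys.time()
  d_h <- run_jags(
    hurdle_model,
    data = list(z = z, ph = ph, g = gi$index, n = nrow(records), G = G,
                P = length(ph_present), prec_fixed = prec_fixed,
                prec_sd = prec_sd, df_sd = sd_df),
    params = c("zeta", "sd_g"),
    schedule = schedule, seed = seed
  )
  pos <- which(records$mites > 0L)
  if (length(pos) < 2L) {
    # degenerate survey with (almost) no infections: the count process is
    # unidentified, so its draws are reported as NA; prevalence inference
    # is still valid.
    warn("Too few non-zero mite counts to fit the intensity process; count-process draws set to NA.")
    d_c <- d_h[c(".chain", ".iteration")]
    for (p in ph_present) d_c[[sprintf("eta[%d]", match(p, ph_present))]] <- NA_real_
    d_c$sd_g <- NA_real_
    d_c$sd_f <- NA_real_
  } else {
    d_c <- run_jags(
      count_model,
      data = list(k = records$mites[pos], ph = ph[pos], g = gi$index[pos],
                  m = length(pos), G = G, P = length(ph_present),
                  prec_fixed = prec_fixed, prec_sd = prec_sd, df_sd = sd_df),
      params = c("eta", "sd_g", "sd_f"),
      schedule = schedule, seed = seed + 1000L,
      inits = list(theta = log(records$mites[pos] + 0.5))
    )
  }
  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  rn <- function(d, stem, new_stems) {
    nm <- names(d)
    for (k in seq_along(ph_present)) {
      nm[nm == sprintf("%s[%d]", stem, k)] <- paste0(new_stems, "_", ph_present[k])
    }
    names(d) <- nm
    d
  }
  d_h <- rn(d_h, "zeta", "zeta")
  d_h$s2_group_logit <- d_h$sd_g^2
  d_h$sd_g <- NULL
  d_c <- rn(d_c, "eta", "eta")
  d_c$s2_group_log <- d_c$sd_g^2
  d_c$s2_unit_log <- d_c$sd_f^2
  d_c$sd_g <- NULL
  d_c$sd_f <- NULL

  draws <- left_join(d_h, d_c, by = c(".chain", ".iteration"))
  structure(
    list(draws = draws, phenotypes = ph_present, groups = gi$groups,
         schedule = schedule, seed = as.integer(seed),
         s2_unit_logit = 1, n_records = nrow(records),
         n_positive = length(pos), runtime = runtime),
    class = "resistance_fit"
  )
}

#' @export
print.resistance_fit <- function(x, ...) {
  cat("Zero-altered Poisson resistance fit\n")
  cat(sprintf("  records: %d (%d with mites), groups: %d, phenotypes: %s\n",
              x$n_records, x$n_positive, nrow(x$groups),
              paste(x$phenotypes, collapse = ", ")))
  cat(sprintf("  chains: %d, kept draws: %d, runtime: %.1f s\n",
              x$schedule$chains, nrow(x$draws), x$runtime))
  print(tidy(x), n = Inf)
  invisible(x)
}

# Parameter columns of a fit's draws tibble.
fit_params <- function(fit) {
  setdiff(names(fit$draws), c(".chain", ".iteration"))
}

#' @method tidy resistance_fit
#' @export
tidy.resistance_fit <- function(x, ...) {
  draws_diagnostics(x$draws, fit_params(x))
}

#' @method glance resistance_fit
#' @export
glance.resistance_fit <- function(x, ...) {
  td <- tidy(x)
  tibble(n_records = x$n_records, n_positive = x$n_positive,
         n_groups = nrow(x$groups), n_draws = nrow(x$draws),
         chains = x$schedule$chains,
         max_rhat = max_rhat(td), min_ess = min(td$ess),
         runtime = x$runtime)
}

#' Per-phenotype prevalence estimates
#'
#' Posterior summaries of the probability of harbouring at least one mite,
#' obtained by transforming the hurdle intercept draws through the inverse
#' logit and summarizing on the probability scale.
#'
#' @param fit A `resistance_fit`.
#' @return Tibble: `phenotype`, `mean`, `conf.low`, `conf.high`.
#' @export
prevalence_estimates <- function(fit) {
  stopifnot(inherits(fit, "resistance_fit"))
  purrr::map_dfr(fit$phenotypes, function(p) {
    s <- summarize_draws(plogis(fit$draws[[paste0("zeta_", p)]]))
    tibble(phenotype = p, mean = s$mean,
           conf.low = s$conf.low, conf.high = s$conf.high)
  })
}

#' Per-phenotype infection-intensity estimates
#'
#' Posterior summaries of the expected mite count among infected hosts.
#' By default the zero-truncated mean `lambda / (1 - exp(-lambda))` is
#' applied draw-wise to `lambda = exp(eta_p)`; `type = "lambda"` reports
#' the raw rate instead.
#'
#' @param fit A `resistance_fit`.
#' @param type `"truncated_mean"` (default) or `"lambda"`.
#' @return Tibble: `phenotype`, `mean`, `conf.low`, `conf.high`.
#' @export
intensity_estimates <- function(fit, type = c("truncated_mean", "lambda")) {
  stopifnot(inherits(fit, "resistance_fit"))
  type <- match.arg(type)
  purrr::map_dfr(fit$phenotypes, function(p) {
    lam <- exp(fit$draws[[paste0("eta_", p)]])
    val <- if (type == "truncated_mean") ztpois_mean(lam) else lam
    s <- summarize_draws(val)
    tibble(phenotype = p, mean = s$mean,
           conf.low = s$conf.low, conf.high = s$conf.high)
  })
}
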