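# Derived statistics on posterior draws: virulence by posterior
# resampling, pMCMC comparisons, credible intervals, and convergence
# diagnostics.

#' Posterior mean and central 95% credible interval
#'
#' @param draws Nonempty numeric vector of posterior draws, or a data
#'   frame / matrix whose columns are summarized separately.
#' @return A tibble with columns `mean`, `conf.low`, `conf.high` (2.5th
#'   and 97.5th empirical quantiles), one row per draw column (with a
#'   `term` column when the input has several).
#' @export
summarize_draws <- function(draws) {
  if (is.data.frame(draws) || is.matrix(draws)) {
    draws <- as.data.frame(draws)
    out <- purrr::imap_dfr(draws, function(x, nm) {
      s <- summarize_draws(x)
      tibble(term = nm, mean = s$mean, conf.low = s$conf.low,
             conf.high = s$conf.high)
    })
    return(out)
  }
  if (length(draws) == 0) abort("`draws` must be nonempty.")
  if (all(is.na(draws))) {
    return(tibble(mean = NA_real_, conf.low = NA_real_, conf.high = NA_real_))
  }
  q <- unname(quantile(draws, c(0.025, 0.975), type = 7))
  tibble(mean = mean(draws), conf.low = q[1], conf.high = q[2])
}

#' pMCMC comparison of two posterior margins
#'
#' The Bayesian tail probability used for level comparisons: the
#' proportion of draws in which the difference `x - y` opposes the sign of
#' its posterior mean, floored at `1 / n` (the resolution of the chain).
#' `convention = "one_sided"` reports that proportion as stated;
#' `"doubled"` doubles it (capped at 1), the two-sided reading.
#'
#' @param x Numeric draws of the first level.
#' @param y Numeric draws of the second level, or a scalar (e.g. 0 to test
#'   a coefficient's sign). If `x` and `y` have different lengths both are
#'   resampled with replacement to the longer length (pairing is arbitrary
#'   because the margins come from independent fits).
#' @param convention `"one_sided"` (default) or `"doubled"`.
#' @param label Contrast label carried into the result.
#' @param seed Seed used only when length-mismatched draws are resampled.
#' @return A one-row tibble: `contrast`, `mean`, `conf.low`, `conf.high`,
#'   `pmcmc`, `convention`, `n_draws`.
#' @export
pmcmc_compare <- function(x, y = 0, convention = c("one_sided", "doubled"),
                          label = "x - y", seed = 1L) {
  convention <- match.arg(convention)
  if (length(x) == 0 || length(y) == 0) abort("Draws must be nonempty.")
  if (length(y) == 1L) y <- rep(y, length(x))
  if (length(x) != length(y)) {
    n <- max(length(x), length(y))
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    x <- x[sample.int(length(x), n, replace = TRUE)]
    y <- y[sample.int(length(y), n, replace = TRUE)]
  }
  d <- x - y
  n <- length(d)
  md <- mean(d)
  p <- if (md == 0) 0.5 else mean(sign(d) == -sign(md))
  p <- max(p, 1 / n)
  if (convention == "doubled") p <- min(2 * p, 1)
  s <- summarize_draws(d)
  tibble(contrast = label, mean = md, conf.low = s$conf.low,
         conf.high = s$conf.high, pmcmc = p, convention = convention,
         n_draws = n)
}

#' Morph-specific virulence by posterior resampling
#'
#' Virulence is the proportional reduction in fecundity a morph suffers at
#' its typical parasite burden, combining tolerance and resistance:
#' `V = 1 - b^I`, where `b = exp(beta)` is the per-mite fecundity
#' retention (tolerance base) and `I` the morph's infection intensity on
#' the count scale. Because the two components come from separate model
#' fits, their marginals are independently resampled with replacement to a
#' common size and paired draw-by-draw.
#'
#' @param tolerance A `tolerance_fit`, or a data frame / named list of
#'   per-morph slope draws (`beta`, log scale).
#' @param resistance A `resistance_fit` (intensity extracted via
#'   [intensity_estimates()] transform draw-wise), or a data frame / named
#'   list of per-morph intensity draws on the count scale.
#' @param morphs Morphs to compute (default the tolerance morphs present
#'   in both inputs).
#' @param n_resample Resample size (default 2000).
#' @param seed Integer seed for the resampling.
#' @param intensity `"truncated_mean"` (default) or `"lambda"`: which
#'   intensity transform to apply when `resistance` is a fit object.
#' @return An object of class `virulence_draws`: a tibble with columns
#'   `morph`, `.draw`, `b`, `intensity`, `virulence`.
#' @export
compute_virulence <- function(tolerance, resistance, morphs = NULL,
                              n_resample = 2000L, seed = 1L,
                              intensity = c("truncated_mean", "lambda")) {
  intensity <- match.arg(intensity)
  b_draws <- if (inherits(tolerance, "tolerance_fit")) {
    setNames(lapply(tolerance$morphs,
                    function(m) exp(tolerance$draws[[paste0("beta_", m)]])),
             tolerance$morphs)
  } else {
    lapply(as.list(tolerance), exp)
  }
  i_draws <- if (inherits(resistance, "resistance_fit")) {
    setNames(lapply(resistance$phenotypes, function(p) {
      lam <- exp(resistance$draws[[paste0("eta_", p)]])
      if (intensity == "truncated_mean") ztpois_mean(lam) else lam
    }), resistance$phenotypes)
  } else {
    as.list(resistance)
  }
  if (is.null(morphs)) morphs <- intersect(names(b_draws), names(i_draws))
  if (length(morphs) == 0) abort("No morph present in both tolerance and resistance draws.")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  out <- purrr::map_dfr(morphs, function(m) {
    b <- b_draws[[m]]
    I <- i_draws[[m]]
    if (length(b) == 0 || length(I) == 0) {
      abort(paste0("Empty draws for morph ", m, "."))
    }
    if (any(I < 0)) abort("Intensity draws must be non-negative.")
    bs <- b[sample.int(length(b), n_resample, replace = TRUE)]
    is <- I[sample.int(length(I), n_resample, replace = TRUE)]
    tibble(morph = m, .draw = seq_len(n_resample), b = bs, intensity = is,
           virulence = 1 - bs^is)
  })
  class(out) <- c("virulence_draws", class(out))
  out
}

#' @method tidy virulence_draws
#' @export
tidy.virulence_draws <- function(x, ...) {
  x %>%
    group_by(.data$morph) %>%
    summarise(
      mean = mean(.data$virulence),
      conf.low = unname(quantile(.data$virulence, 0.025)),
      conf.high = unname(quantile(.data$virulence, 0.975)),
      .groups = "drop"
    )
}

#' Compare virulence between two morphs
#'
#' @param vd A `virulence_draws` object.
#' @param morph_x,morph_y Morphs to contrast.
#' @inheritParams pmcmc_compare
#' @return A one-row comparison tibble (see [pmcmc_compare()]).
#' @export
virulence_compare <- function(vd, morph_x = "A", morph_y = "I",
                              convention = c("one_sided", "doubled")) {
  stopifnot(inherits(vd, "virulence_draws"))
  vx <- vd$virulence[vd$morph == morph_x]
  vy <- vd$virulence[vd$morph == morph_y]
  pmcmc_compare(vx, vy, convention = match.arg(convention),
                label = paste0("V_", morph_x, " - V_", morph_y))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical split-free R-hat from between- and within-chain variances:
#' with `M` chains of length `N`, `W` the mean within-chain variance and
#' `B/N` the variance of chain means, the estimate is
#' `sqrt(((N - 1) / N * W + B / N) / W)`. Values near 1 indicate that the
#' chains are sampling the same distribution.
#'
#' @param chains A list of two or more equal-length numeric vectors, or a
#'   matrix with one column per chain.
#' @return The scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  chains <- lapply(chains, as.numeric)
  M <- length(chains)
  if (M < 2L) abort("Need at least two chains.")
  N <- unique(lengths(chains))
  if (length(N) != 1L) abort("Chains must have equal length.")
  if (N < 2L) abort("Chains must have length >= 2.")
  W <- mean(vapply(chains, var, numeric(1)))
  Bn <- var(vapply(chains, mean, numeric(1)))  # = B / N
  if (W == 0) return(1)
  sqrt(((N - 1) / N * W + Bn) / W)
}

#' Lag-k sample autocorrelation
#'
#' Standard autocovariance-based estimate with the 1/n normalization (as
#' in [stats::acf()]). Constant draws are defined to have autocorrelation
#' 0, with a warning.
#'
#' @param draws Numeric vector.
#' @param lag Non-negative integer lag, smaller than `length(draws)`.
#' @return Scalar autocorrelation in `[-1, 1]`.
#' @export
autocorrelation <- function(draws, lag = 1L) {
  n <- length(draws)
  lag <- as.integer(lag)
  if (lag < 0L || lag >= n) abort("`lag` must be in [0, length(draws) - 1].")
  xb <- mean(draws)
  denom <- sum((draws - xb)^2)
  if (denom == 0) {
    warn("Constant draws: autocorrelation defined as 0.")
    return(0)
  }
  if (lag == 0L) return(1)
  sum((draws[1:(n - lag)] - xb) * (draws[(1 + lag):n] - xb)) / denom
}

#' Effective sample size
#'
#' Geyer's initial-positive-sequence estimator for a single chain: the
#' integrated autocorrelation time is accumulated over pairs
#' `rho(2t) + rho(2t + 1)` for as long as the pair sums stay positive, and
#' ESS is `n` divided by that time. Constant draws return `n` with a
#' warning.
#'
#' @param draws Numeric vector of draws from one chain.
#' @return Scalar effective sample size in `(0, n]`.
#' @export
effective_sample_size <- function(draws) {
  n <- length(draws)
  if (n < 2L) return(n)
  if (var(draws) == 0) {
    warn("Constant draws: effective sample size defined as n.")
    return(n)
  }
  max_lag <- n - 1L
  rho <- as.numeric(acf(draws, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)  # rho[1] is lag 0
  tau <- 0
  t <- 0L
  repeat {
    i1 <- 2L * t + 1L       # lag 2t (1-based index)
    i2 <- 2L * t + 2L       # lag 2t + 1
    if (i1 > length(rho)) break
    pair <- rho[i1] + (if (i2 <= length(rho)) rho[i2] else 0)
    if (pair <= 0) break
    tau <- tau + 2 * pair
    t <- t + 1L
  }
  tau <- max(tau - 1, 1e-8)  # tau = -1 + 2 * sum of positive pair sums
  min(n / tau, n)
}
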