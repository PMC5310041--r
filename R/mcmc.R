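# MCMC schedules and the JAGS driver shared by both fitting modules.

#' MCMC schedule
#'
#' @param chains Number of chains (each gets its own deterministic RNG
#'   stream derived from the fit seed).
#' @param adapt Adaptation sweeps (sampler tuning, discarded).
#' @param burnin Burn-in sweeps (discarded).
#' @param iter Post-burn-in sweeps per chain.
#' @param thin Thinning interval; `iter / thin` draws are kept per chain.
#' @return An object of class `mcmc_schedule`.
#' @export
mcmc_schedule <- function(chains = 2L, adapt = 500L, burnin = 500L,
                          iter = 2500L, thin = 5L) {
  stopifnot(chains >= 1L, adapt >= 0L, burnin >= 0L, iter >= thin, thin >= 1L)
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 burnin = as.integer(burnin), iter = as.integer(iter),
                 thin = as.integer(thin)),
            class = "mcmc_schedule")
}

#' The original long schedule
#'
#' The schedule used in the field study: 2 000 000 sweeps after a burn-in
#' of 100 000, keeping every 1000th draw. Desk-scale work should use the
#' default [mcmc_schedule()] instead.
#'
#' @return An `mcmc_schedule`.
#' @export
paper_mcmc_schedule <- function() {
  mcmc_schedule(chains = 1L, adapt = 1000L, burnin = 100000L,
                iter = 2000000L, thin = 1000L)
}

# Internal JAGS driver. Compiles `model_string` with `data`, runs the
# schedule with chain c seeded deterministically as seed + c - 1, monitors
# `params`, and returns a tibble with .chain/.iteration columns. `inits`
# is a list of chain-independent initial values (RNG fields are added
# here).
run_jags <- function(model_string, data, params, schedule, seed, inits = list()) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    abort("rjags is required for model fitting.")
  }
  rjags::load.module("glm", quiet = TRUE)
  seed <- as.integer(seed)
  init_list <- lapply(seq_len(schedule$chains), function(c) {
    c(list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = seed + c - 1L),
      inits)
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             n.chains = schedule$chains,
                             n.adapt = schedule$adapt,
                             inits = init_list, quiet = TRUE)
  if (schedule$burnin > 0) update(model, schedule$burnin, progress.bar = "none")
  samp <- rjags::coda.samples(model, variable.names = params,
                              n.iter = schedule$iter, thin = schedule$thin,
                              progress.bar = "none")
  draws <- purrr::imap_dfr(as.list(samp), function(ch, i) {
    m <- as.matrix(ch)
    out <- as_tibble(m)
    out$.chain <- as.integer(i)
    out$.iteration <- seq_len(nrow(m))
    out
  })
  dplyr::relocate(draws, ".chain", ".iteration")
}

# Split a draws tibble into per-chain vectors of one parameter.
chain_split <- function(draws, param) {
  unname(split(draws[[param]], draws$.chain))
}

# Largest R-hat in a tidy table; NA when chains == 1 (no R-hat defined).
max_rhat <- function(td) {
  if (all(is.na(td$rhat))) NA_real_ else max(td$rhat, na.rm = TRUE)
}

# Shared posterior-summary + diagnostics table over the named parameter
# columns of a fit's draws tibble.
draws_diagnostics <- function(draws, params) {
  purrr::map_dfr(params, function(p) {
    ch <- chain_split(draws, p)
    s <- summarize_draws(draws[[p]])
    tibble(
      term = p,
      estimate = s$mean,
      conf.low = s$conf.low,
      conf.high = s$conf.high,
      rhat = if (length(ch) >= 2L) gelman_rubin(ch) else NA_real_,
      ess = sum(vapply(ch, effective_sample_size, numeric(1)))
    )
  })
}
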