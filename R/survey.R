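# Survey records: one row per captured damselfly.
#
# Columns (fixed order for CSV exchange):
#   population  chr   sampling site identifier
#   year        int   annual cohort (one generation per year)
#   phenotype   fct   A / I / O (female colour morphs) or M (male)
#   mites       int   water-mite count, >= 0
#   mated       lgl   caught in copula
#   eggs        int   72-h egg count; NA unless mated female

SURVEY_COLS <- c("population", "year", "phenotype", "mites", "mated", "eggs")

#' Phenotype levels
#'
#' The four phenotype classes observed in the field: the three heritable
#' female colour morphs — androchrome (`"A"`), *Infuscans* (`"I"`) and
#' *Infuscans-obsoleta* (`"O"`) — plus the monomorphic males (`"M"`).
#' Fecundity tolerance is modelled for the two common morphs `"A"` and
#' `"I"` only.
#'
#' @return Character vector of the four phenotype codes.
#' @export
phenotype_levels <- function() c("A", "I", "O", "M")

#' Female morph codes admitted by the tolerance model
#' @return Character vector `c("A", "I")`.
#' @export
tolerance_morphs <- function() c("A", "I")

#' Validate a survey data frame
#'
#' Checks the survey schema: required columns, known phenotype codes,
#' non-negative mite and egg counts, and the constraint that egg counts are
#' only present on mated female records (males and unmated females were
#' never set up for oviposition, so an egg count there is a data error).
#'
#' @param records A data frame of survey records.
#' @param strict If `TRUE` (default) any violation aborts with a message
#'   naming the offending rows; if `FALSE`, offending rows are dropped with
#'   a warning and the clean subset returned.
#' @return A validated tibble with `phenotype` as a factor over
#'   [phenotype_levels()], invisibly classified row types coerced
#'   (`year`, `mites`, `eggs` integer; `mated` logical).
#' @export
validate_survey <- function(records, strict = TRUE) {
  if (!is.data.frame(records)) {
    abort("`records` must be a data frame of survey records.")
  }
  missing_cols <- setdiff(SURVEY_COLS, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Survey is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  out <- as_tibble(records)[SURVEY_COLS]
  out$population <- as.character(out$population)
  out$year <- as.integer(out$year)
  out$phenotype <- as.character(out$phenotype)
  out$mites <- as.integer(out$mites)
  out$mated <- as.logical(out$mated)
  out$eggs <- as.integer(out$eggs)

  bad <- rep(FALSE, nrow(out))
  flag <- function(cond, what) {
    idx <- which(cond & !is.na(cond))
    if (length(idx) > 0 && strict) {
      abort(paste0("Invalid survey record(s): ", what, " at row(s) ",
                   paste(head(idx, 5L), collapse = ", "),
                   if (length(idx) > 5L) sprintf(" (and %d more)", length(idx) - 5L) else "",
                   "."))
    }
    bad[idx] <<- TRUE
  }
  flag(is.na(out$population) | out$population == "", "empty population ID")
  flag(is.na(out$year), "missing year")
  flag(!(out$phenotype %in% phenotype_levels()) | is.na(out$phenotype),
       "unknown phenotype code")
  flag(is.na(out$mites) | out$mites < 0L, "missing or negative mite count")
  flag(is.na(out$mated), "missing mated flag")
  flag(!is.na(out$eggs) & out$eggs < 0L, "negative egg count")
  flag(!is.na(out$eggs) & (out$phenotype == "M" | !out$mated | is.na(out$mated)),
       "egg count on a male or unmated record")

  if (any(bad)) {
    warn(sprintf("Dropped %d invalid survey record(s).", sum(bad)))
    out <- out[!bad, ]
  }
  out$phenotype <- factor(out$phenotype, levels = phenotype_levels())
  out
}

#' Read a survey CSV
#'
#' Reads a long-format survey table (one row per captured individual) and
#' validates it against the schema: columns `population, year, phenotype,
#' mites, mated, eggs`, with `eggs` empty for any record that is not a
#' mated female.
#'
#' @param path Path to a CSV file.
#' @inheritParams validate_survey
#' @return A validated survey tibble.
#' @export
read_survey_csv <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("Survey file not found: ", path))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      population = readr::col_character(),
      year = readr::col_integer(),
      phenotype = readr::col_character(),
      mites = readr::col_integer(),
      mated = readr::col_logical(),
      eggs = readr::col_integer()
    ),
    progress = FALSE
  )
  validate_survey(raw, strict = strict)
}

#' Write a survey CSV
#'
#' Writes records in the fixed column order with missing egg counts encoded
#' as empty fields (a zero egg count is a real observation and is written
#' as `0`). The output is deterministic: re-writing the same records gives
#' a byte-identical file.
#'
#' @param records A survey data frame (validated before writing).
#' @param path Output path.
#' @return Invisibly, the number of data rows written.
#' @export
write_survey_csv <- function(records, path) {
  records <- validate_survey(records, strict = TRUE)
  out <- records
  out$phenotype <- as.character(out$phenotype)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(nrow(out))
}

#' Summarize a survey
#'
#' Descriptive layer over a survey: per-phenotype sample sizes, prevalence
#' (fraction with at least one mite), mean mite load, plus the overall zero
#' fraction and the number of distinct population-by-year groups (the
#' random-effect levels of all models).
#'
#' @param records A survey data frame.
#' @return A list with elements `by_phenotype` (tibble: phenotype, n,
#'   n_infected, prevalence, mean_mites), `n_records`, `zero_fraction`,
#'   and `n_groups`.
#' @export
summarize_survey <- function(records) {
  records <- validate_survey(records, strict = TRUE)
  if (nrow(records) == 0) {
    abort("Cannot summarize an empty survey.")
  }
  by_ph <- records %>%
    group_by(.data$phenotype, .drop = FALSE) %>%
    summarise(
      n = dplyr::n(),
      n_infected = sum(.data$mites > 0L),
      prevalence = ifelse(dplyr::n() > 0, mean(.data$mites > 0L), NA_real_),
      mean_mites = ifelse(dplyr::n() > 0, mean(.data$mites), NA_real_),
      .groups = "drop"
    )
  list(
    by_phenotype = by_ph,
    n_records = nrow(records),
    zero_fraction = mean(records$mites == 0L),
    n_groups = nrow(distinct(records, .data$population, .data$year))
  )
}

# Internal: integer index of the population-by-year group of each record,
# plus the group table (one row per level).
group_index <- function(records) {
  key <- paste(records$population, records$year, sep = "\r")
  lev <- sort(unique(key))
  list(index = match(key, lev),
       groups = tibble(
         group = seq_along(lev),
         population = sub("\r.*$", "", lev),
         year = as.integer(sub("^.*\r", "", lev))
       ))
}
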