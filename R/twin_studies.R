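#' Classical pre-1970 schizophrenia twin studies
#'
#' Loads the packaged table of nine classical schizophrenia twin studies
#' (1934–1970): investigator, year, country, MZ and DZ concordant/total pair
#' counts, and — where the original reports state them — the cohort age range
#' and mean onset age. Concordance fractions, not their rounded decimal
#' renderings, are the authoritative inputs for all downstream algebra.
#'
#' @param path Optional path to a CSV in the same layout; defaults to the
#'   packaged fixture.
#' @return A data.frame, one row per study, with columns
#'   `investigator, year, country, mz_concordant, mz_total, dz_concordant,
#'   dz_total, age_low, age_high, mean_onset_age` (the last three may be
#'   `NA`).
#' @examples
#' twin_studies()
#' @export
twin_studies <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "twin_studies_pre1970.csv",
                        package = "mmonset", mustWork = TRUE)
  read_twin_studies_csv(path)
}

#' Read a twin-study table from CSV
#'
#' Columns required: `investigator, year, country, mz_concordant, mz_total,
#' dz_concordant, dz_total`; optional: `age_low, age_high, mean_onset_age`
#' (blank allowed). Validates count consistency (`0 <= concordant <= total`)
#' and age ordering, reporting the offending row and column.
#'
#' @param path CSV file path.
#' @return A validated data.frame (see [twin_studies()]).
#' @export
read_twin_studies_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("investigator", "year", "country", "mz_concordant", "mz_total",
           "dz_concordant", "dz_total")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("twin-study CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (opt in c("age_low", "age_high", "mean_onset_age"))
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  for (col in c("mz_concordant", "mz_total", "dz_concordant", "dz_total")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad))
      stop("invalid count in column '", col, "', row ", bad[1], call. = FALSE)
  }
  for (zg in c("mz", "dz")) {
    conc <- df[[paste0(zg, "_concordant")]]; tot <- df[[paste0(zg, "_total")]]
    bad <- which(conc > tot)
    if (length(bad))
      stop("concordant exceeds total pairs (", zg, "), row ", bad[1],
           call. = FALSE)
  }
  bad <- which(is.finite(df$age_low) & is.finite(df$age_high) &
                 df$age_low >= df$age_high)
  if (length(bad))
    stop("age_low >= age_high in row ", bad[1], call. = FALSE)
  df
}

#' Derive model quantities for one twin study
#'
#' Runs the full per-study chain: observed concordance fractions
#' `C_M = mz_concordant/mz_total`, `C_D = dz_concordant/dz_total`; the
#' model-implied prevalence `P_s = 2 C_M/(1 + C_M)`; the inherited
#' susceptibility `S_inher` from both concordances; and, when age information
#' is available, the cohort's biological clock rate and effective age:
#' \itemize{
#'   \item a reported mean onset age drives [clock_rate_from_mean_age()] and
#'     the matched age solves `P_s(t, r) = P_s`;
#'   \item a narrow age range (width <= 10 y, effectively an age cohort)
#'     drives [clock_rate_from_concordance()] at the midpoint age;
#'   \item a wide age range (or none) keeps `r = 1` and reports the
#'     [equivalent_age()] on the reference curve.
#' }
#'
#' @param record One row of a [twin_studies()] table (a list or one-row
#'   data.frame).
#' @param params Reference [mmm_params()] curve (default the pooled USA fit).
#' @param narrow_width Age-range width at or below which the cohort is
#'   treated as a single-age cohort (years, default 10).
#' @return A one-row data.frame with columns `investigator, year, c_m, c_d,
#'   p_s, s_inher, frac_unable, r, equivalent_age, method`.
#' @examples
#' tab <- twin_studies()
#' analyze_study(tab[tab$investigator == "Kallmann", ])
#' @export
analyze_study <- function(record, params = usa_model_params(),
                          narrow_width = 10) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  c_m <- record$mz_concordant / record$mz_total
  c_d <- record$dz_concordant / record$dz_total
  p_s <- invert_mz_concordance(c_m)
  s_inher <- s_inher_from_concordances(c_m, c_d)
  has_range <- is.finite(record$age_low %||% NA) &&
    is.finite(record$age_high %||% NA)
  has_tbar <- is.finite(record$mean_onset_age %||% NA)
  r <- NA_real_; eq_age <- NA_real_; method <- "reference_curve"
  if (has_tbar && has_range) {
    r <- clock_rate_from_mean_age(params, record$age_low, record$age_high,
                                  record$mean_onset_age)
    scaled <- set_clock_rate(params, r)
    eq_age <- equivalent_age(scaled, c_m)
    method <- "mean_onset_age"
  } else if (has_range &&
             (record$age_high - record$age_low) <= narrow_width) {
    age <- (record$age_low + record$age_high) / 2
    r <- clock_rate_from_concordance(params, age, c_m)
    eq_age <- age
    method <- "age_cohort"
  } else if (has_range) {
    r <- 1
    eq_age <- equivalent_age(params, c_m)
    method <- "equivalent_age"
  }
  data.frame(investigator = record$investigator, year = record$year,
             c_m = c_m, c_d = c_d, p_s = p_s, s_inher = s_inher,
             frac_unable = fraction_unable(s_inher),
             r = r, equivalent_age = eq_age, method = method,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive model quantities for a table of twin studies
#'
#' Applies [analyze_study()] to each row; a study whose solver fails yields
#' `NA` derived columns and a warning naming the study, without aborting the
#' batch. The pooled minimum of `frac_unable` across studies — the
#' conservative bound on the fraction of dizygote cotwins unable to develop
#' the disease — is attached as attribute `"min_frac_unable"`.
#'
#' @param studies A [twin_studies()]-layout data.frame (default the packaged
#'   table).
#' @inheritParams analyze_study
#' @return A data.frame with one derived row per study (see
#'   [analyze_study()]) and attribute `min_frac_unable`.
#' @examples
#' res <- analyze_twin_studies()
#' attr(res, "min_frac_unable")  # >= 0.71
#' @export
analyze_twin_studies <- function(studies = twin_studies(),
                                 params = usa_model_params(),
                                 narrow_width = 10) {
  rows <- lapply(seq_len(nrow(studies)), function(i) {
    rec <- as.list(studies[i, ])
    tryCatch(analyze_study(rec, params, narrow_width), error = function(e) {
      warning("study '", rec$investigator, "': ", conditionMessage(e),
              call. = FALSE)
      data.frame(investigator = rec$investigator, year = rec$year,
                 c_m = rec$mz_concordant / rec$mz_total,
                 c_d = rec$dz_concordant / rec$dz_total,
                 p_s = NA_real_, s_inher = NA_real_, frac_unable = NA_real_,
                 r = NA_real_, equivalent_age = NA_real_, method = "failed",
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "min_frac_unable") <- suppressWarnings(
    min(out$frac_unable, na.rm = TRUE))
  out
}
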