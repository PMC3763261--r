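#' Multimutation model parameters
#'
#' Constructs the parameter vector of the independent multimutation model
#' (MMM). A susceptible individual must accumulate `m = m1 + 1` independent,
#' exponentially timed internal changes ("mutations", not necessarily genomic)
#' before onset; `m1` of them occur at rate `k1` and the single remaining one
#' at rate `k2`. The susceptible prevalence at age `t` is
#' \deqn{P_s(t, r) = [1 - e^{-r k_1 t}]^{m_1} [1 - e^{-r k_2 t}],}
#' where `r` is a dimensionless biological clock rate that uniformly speeds up
#' (`r > 1`) or slows down (`r < 1`) all mutation rates, so that
#' `P_s(t, r) = P_s(r t, 1)`. The population prevalence is `f_s * P_s(t, r)`,
#' with `f_s` the lifetime-susceptible fraction of the birth cohort.
#'
#' Setting `k2 = k1` collapses the model to the single-rate ("3-parameter")
#' family \eqn{P_s(t) = [1 - e^{-k t}]^{m}} with `m = m1 + 1`.
#'
#' @param m1 Integer >= 0, number of mutations occurring at rate `k1`.
#'   The total mutation count is `m = m1 + 1`.
#' @param k1 Mutation rate, per year, > 0.
#' @param k2 Rate of the single remaining mutation, per year, > 0.
#'   Defaults to `k1` (single-rate model).
#' @param f_s Lifetime susceptible fraction, in \[0, 1\]. Defaults to 1
#'   (an all-susceptible cohort, as in monozygote twin analyses).
#' @param r Dimensionless clock rate, > 0. Default 1.
#' @return An object of class `"mmm_params"`: a named list with elements
#'   `m1`, `m`, `k1`, `k2`, `f_s`, `r`.
#' @examples
#' p <- mmm_params(m1 = 15, k1 = 0.10757, k2 = 0.029959, f_s = 0.0016363)
#' susceptible_prevalence(p, 41)
#' @seealso [usa_model_params()] for the reference USA first-admission fits.
#' @export
mmm_params <- function(m1, k1, k2 = k1, f_s = 1, r = 1) {
  if (length(m1) != 1L || !is.finite(m1) || m1 < 0 || m1 != round(m1))
    stop("'m1' must be a single nonnegative integer", call. = FALSE)
  for (nm in c("k1", "k2", "r")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  if (length(f_s) != 1L || !is.finite(f_s) || f_s < 0 || f_s > 1)
    stop("'f_s' must be a probability in [0, 1]", call. = FALSE)
  structure(
    list(m1 = as.integer(m1), m = as.integer(m1) + 1L,
         k1 = as.numeric(k1), k2 = as.numeric(k2),
         f_s = as.numeric(f_s), r = as.numeric(r)),
    class = "mmm_params")
}

#' @export
print.mmm_params <- function(x, digits = 6, ...) {
  cat("Multimutation model parameters\n")
  cat(sprintf("  mutations        m  = %d  (m1 = %d at rate k1, 1 at rate k2)\n",
              x$m, x$m1))
  cat(sprintf("  rates            k1 = %s /y   k2 = %s /y\n",
              format(x$k1, digits = digits), format(x$k2, digits = digits)))
  cat(sprintf("  lifetime risk    f_s = %s\n", format(x$f_s, digits = digits)))
  cat(sprintf("  clock rate       r  = %s\n", format(x$r, digits = digits)))
  invisible(x)
}

#' Replace the clock rate of a parameter set
#'
#' Returns a copy of `params` with the dimensionless clock rate set to `r`,
#' leaving all other parameters untouched. Convenience used throughout the
#' twin-cohort solvers, which vary `r` at fixed mutation rates.
#'
#' @param params An [mmm_params()] object.
#' @param r New clock rate, > 0.
#' @return An `mmm_params` object.
#' @export
set_clock_rate <- function(params, r) {
  stopifnot(inherits(params, "mmm_params"))
  mmm_params(params$m1, params$k1, params$k2, params$f_s, r)
}

#' Reference parameter sets fitted to USA first-admission data
#'
#' Parameter sets of the multimutation model fitted by least squares to the
#' classical USA schizophrenia age-at-first-hospital-admission cumulative
#' incidence curves (sex-stratified and pooled). These are the shipped
#' reference values used by the twin-study analyses; the underlying hospital
#' admission table is not redistributed.
#'
#' All 4-parameter fits share `m = 16` (`m1 = 15`); the 3-parameter male fit
#' has `m = 10` with a single rate (stored as `m1 = 9`, `k2 = k1`).
#'
#' @param cohort One of `"males+females"` (default), `"males"`, `"females"`,
#'   `"males_3p"`.
#' @return An [mmm_params()] object.
#' @examples
#' usa_model_params()               # pooled males + females, 4-parameter
#' usa_model_params("males")
#' @export
usa_model_params <- function(cohort = c("males+females", "males", "females",
                                        "males_3p")) {
  cohort <- match.arg(cohort)
  switch(cohort,
    "males+females" = mmm_params(15, 0.10757,  0.029959, 0.0016363),
    "males"         = mmm_params(15, 0.11653,  0.028465, 0.0015737),
    "females"       = mmm_params(15, 0.09859,  0.035728, 0.0016428),
    "males_3p"      = mmm_params(9,  0.08172,  0.08172,  0.00137))
}

#' Serialize model parameters to a flat key-value file
#'
#' Writes (or reads) an [mmm_params()] object as a flat key-value config with
#' keys `m`, `m1`, `k1`, `k2`, `f_s`, `r` (rates per year). The format is
#' chosen from the file extension: `.json` via jsonlite, `.yml`/`.yaml` via
#' yaml.
#'
#' @param params An [mmm_params()] object.
#' @param path File path ending in `.json`, `.yml` or `.yaml`.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   an `mmm_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "mmm_params"))
  x <- list(m = params$m, m1 = params$m1, k1 = params$k1, k2 = params$k2,
            f_s = params$f_s, r = params$r)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    stop("unsupported parameter file extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported parameter file extension: ", ext, call. = FALSE)
  }
  for (k in c("m1", "k1", "k2")) {
    if (is.null(x[[k]])) stop("parameter file missing key '", k, "'", call. = FALSE)
  }
  mmm_params(m1 = x$m1, k1 = x$k1, k2 = x$k2,
             f_s = if (is.null(x$f_s)) 1 else x$f_s,
             r = if (is.null(x$r)) 1 else x$r)
}
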