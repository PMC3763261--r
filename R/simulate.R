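#' Simulate an age-binned cumulative incidence dataset
#'
#' Generates the kind of table the fitter consumes: cumulative incidence per
#' 100,000 at the given ages, equal to `1e5 * f_s * P_s(t, r)` with optional
#' multiplicative Gaussian noise (admission counts scale with cohort size, so
#' noise is proportional), clipped to remain nondecreasing with age (running
#' maximum), which preserves the cumulative invariant.
#'
#' @param params An [mmm_params()] object (its `f_s` sets the plateau).
#' @param ages Strictly increasing ages in years (default 10–70 by 2.5 y,
#'   emulating first-admission registry age bins).
#' @param noise_sd Standard deviation of the multiplicative noise, as a
#'   fraction (0 gives the exact model curve).
#' @param seed Integer seed; the output is fully reproducible.
#' @param scale Population denominator (default 1e5).
#' @param sex_label Optional label stored in a `sex` column.
#' @return A data.frame with columns `age_years`, `cum_incidence_per_100k`
#'   (and `sex` if labelled).
#' @examples
#' d <- simulate_incidence_dataset(usa_model_params(), noise_sd = 0.02,
#'                                 seed = 7)
#' @export
simulate_incidence_dataset <- function(params, ages = seq(10, 70, by = 2.5),
                                       noise_sd = 0, seed = 1, scale = 1e5,
                                       sex_label = NULL) {
  stopifnot(inherits(params, "mmm_params"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (any(diff(ages) <= 0)) stop("'ages' must be strictly increasing",
                                 call. = FALSE)
  y <- scale * population_prevalence(params, ages)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y * (1 + stats::rnorm(length(y), 0, noise_sd))
    y <- cummax(pmax(y, 0))
  }
  out <- data.frame(age_years = ages, cum_incidence_per_100k = y)
  if (!is.null(sex_label)) out$sex <- sex_label
  out
}

#' Draw onset ages from the multimutation model
#'
#' Exact sampler for the onset-age distribution `P_s(t, r)`: the model says
#' onset happens when the last of the required mutations occurs, so an onset
#' age is the maximum of `m1` Exponential(`r k1`) waiting times and one
#' Exponential(`r k2`) waiting time. The maximum of independent waiting times
#' has exactly the product-of-CDFs distribution — no numerical inversion
#' involved.
#'
#' @param params An [mmm_params()] object.
#' @param n Number of draws.
#' @return Numeric vector of `n` onset ages in years.
#' @examples
#' set.seed(1)
#' mean(simulate_onset_age(usa_model_params(), 1000) < 41)  # ~ P_s(41)
#' @export
simulate_onset_age <- function(params, n = 1) {
  stopifnot(inherits(params, "mmm_params"))
  a <- params$r * params$k1
  b <- params$r * params$k2
  last <- stats::rexp(n, b)
  if (params$m1 == 0) return(last)
  first <- matrix(stats::rexp(n * params$m1, a), nrow = n)
  pmax(apply(first, 1, max), last)
}

#' Simulate a twin birth cohort
#'
#' Simulates `n_pairs` twin pairs under the model's core assumption: cotwin
#' onset ages are independent given susceptibility. MZ pairs are both
#' susceptible; in DZ pairs twin 1 (the eventual index twin) is susceptible
#' and twin 2 inherits susceptibility with probability `s_inher`.
#' Non-susceptible twins never have an onset age. Twins whose onset age
#' exceeds a census age are recorded as not-yet-ill at that census
#' (cross-sectional snapshot), handled by [twin_cohort_concordance()].
#'
#' @param params An [mmm_params()] object.
#' @param n_pairs Number of pairs, >= 1.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param s_inher Cotwin susceptibility probability (DZ only; ignored for
#'   MZ, where it is 1 by construction).
#' @param seed Integer seed.
#' @return An object of class `"twin_cohort"`: a list with `n_pairs`,
#'   `zygosity`, `s_inher`, `seed` and vectors `susceptible1`,
#'   `susceptible2`, `onset1`, `onset2` (`NA` for non-susceptible members).
#' @examples
#' cohort <- simulate_twin_cohort(usa_model_params(), 1000, "MZ", seed = 2)
#' twin_cohort_concordance(cohort, census_age = 41)
#' @export
simulate_twin_cohort <- function(params, n_pairs, zygosity = c("MZ", "DZ"),
                                 s_inher = 1, seed = 1) {
  stopifnot(inherits(params, "mmm_params"))
  zygosity <- match.arg(zygosity)
  if (n_pairs < 1) stop("'n_pairs' must be >= 1", call. = FALSE)
  check_prob(s_inher, "s_inher")
  set.seed(seed)
  susceptible1 <- rep(TRUE, n_pairs)
  susceptible2 <- if (zygosity == "MZ") rep(TRUE, n_pairs) else
    stats::runif(n_pairs) < s_inher
  onset1 <- simulate_onset_age(params, n_pairs)
  onset2 <- rep(NA_real_, n_pairs)
  onset2[susceptible2] <- simulate_onset_age(params, sum(susceptible2))
  structure(list(n_pairs = n_pairs, zygosity = zygosity,
                 s_inher = if (zygosity == "MZ") 1 else s_inher,
                 seed = seed,
                 susceptible1 = susceptible1, susceptible2 = susceptible2,
                 onset1 = onset1, onset2 = onset2),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("Simulated %s twin cohort: %d pairs (s_inher = %g, seed = %d)\n",
              x$zygosity, x$n_pairs, x$s_inher, x$seed))
  invisible(x)
}

#' Empirical subcohort statistics of a simulated twin cohort at a census age
#'
#' Takes the cross-sectional snapshot of a simulated cohort at `census_age`:
#' a twin is affected if susceptible and its onset age does not exceed the
#' census age. Members are randomly split into the two subcohorts (one twin
#' each, coin flip) as the study design prescribes, and the empirical state
#' frequencies, the subcohort concordance `n_ss / (n_ss + n_sx)` among
#' observed (at-least-one-affected) pairs, and the first-onset fraction are
#' returned.
#'
#' @param cohort A [simulate_twin_cohort()] result.
#' @param census_age Census age in years.
#' @param seed Seed for the random subcohort assignment.
#' @return A list with `p_ss`, `p_sx`, `p_xx` (empirical state frequencies,
#'   summing to 1), `concordance`, `n_observed` (pairs with at least one
#'   affected member), `p_first_onset`.
#' @export
twin_cohort_concordance <- function(cohort, census_age, seed = 1) {
  stopifnot(inherits(cohort, "twin_cohort"))
  set.seed(seed)
  flip <- stats::runif(cohort$n_pairs) < 0.5
  aff1 <- cohort$susceptible1 & !is.na(cohort$onset1) &
    cohort$onset1 <= census_age
  aff2 <- cohort$susceptible2 & !is.na(cohort$onset2) &
    cohort$onset2 <= census_age
  # random subcohort assignment: swap the pair order on a coin flip
  a <- ifelse(flip, aff1, aff2)
  b <- ifelse(flip, aff2, aff1)
  n_ss <- sum(a & b)
  n_sx <- sum(xor(a, b))
  n_xx <- cohort$n_pairs - n_ss - n_sx
  list(p_ss = n_ss / cohort$n_pairs,
       p_sx = n_sx / cohort$n_pairs,
       p_xx = n_xx / cohort$n_pairs,
       concordance = if (n_ss + n_sx > 0) n_ss / (n_ss + n_sx) else NA_real_,
       n_observed = n_ss + n_sx,
       p_first_onset = (n_ss + n_sx) / cohort$n_pairs)
}

#' Write a simulated twin cohort to CSV
#'
#' One row per pair: `pair_id, zygosity, susceptible1, susceptible2,
#' onset_age1, onset_age2` (onset ages blank for non-susceptible members).
#'
#' @param cohort A [simulate_twin_cohort()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_twin_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "twin_cohort"))
  df <- data.frame(pair_id = seq_len(cohort$n_pairs),
                   zygosity = cohort$zygosity,
                   susceptible1 = cohort$susceptible1,
                   susceptible2 = cohort$susceptible2,
                   onset_age1 = cohort$onset1,
                   onset_age2 = cohort$onset2)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
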