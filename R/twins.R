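#' Monozygote twin state probabilities
#'
#' For a cohort of susceptible monozygote pairs whose members each follow the
#' same onset distribution `P_s(t)`, and whose onsets are independent given
#' susceptibility, the pair at age `t` is concordant (both affected),
#' discordant (exactly one) or unaffected with probabilities
#' `p_ss = p_s^2`, `p_sx = 2 p_s (1 - p_s)`, `p_xx = (1 - p_s)^2`.
#' The first-onset distribution — the probability that at least one member of
#' the pair has had onset — is `p_first_onset = 1 - (1 - p_s)^2 =
#' p_s (2 - p_s)`.
#'
#' @param p_s Susceptible prevalence at the census age, in \[0, 1\].
#'   Vectorized.
#' @return A data.frame with columns `p_ss`, `p_sx`, `p_xx`,
#'   `p_first_onset`; the first three sum to 1 in each row.
#' @examples
#' mz_state_probabilities(susceptible_prevalence(usa_model_params(), 80))
#' @export
mz_state_probabilities <- function(p_s) {
  check_prob(p_s, "p_s")
  data.frame(p_ss = p_s^2,
             p_sx = 2 * p_s * (1 - p_s),
             p_xx = (1 - p_s)^2,
             p_first_onset = p_s * (2 - p_s))
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("'", name, "' must be a probability in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Monozygote subcohort concordance
#'
#' The fraction of the *observed* monozygote birth cohort (concordant plus
#' discordant pairs; all-unaffected pairs are invisible to a twin study) that
#' is concordant at the census age:
#' \deqn{C_M = \frac{p_{ss}}{p_{ss} + p_{sx}} = \frac{p_s}{2 - p_s}.}
#' This *subcohort* concordance is deliberately not the pairwise or
#' probandwise concordance of the broader twin literature: it is the
#' probability that randomly chosen members of the two twin subcohorts are
#' both affected, conditional on at least one being affected.
#'
#' @inheritParams mz_state_probabilities
#' @return Concordance probabilities in \[0, 1\]; `C_M(p_s) <= p_s` always.
#' @seealso [invert_mz_concordance()] for the exact inverse.
#' @export
mz_concordance <- function(p_s) {
  check_prob(p_s, "p_s")
  p_s / (2 - p_s)
}

#' Invert monozygote concordance to susceptible prevalence
#'
#' Solves `C_M = p_s / (2 - p_s)` for the prevalence:
#' `p_s = 2 C_M / (1 + C_M)`. Because a twin study measures `C_M` directly,
#' this converts an observed MZ concordance fraction into the model-predicted
#' susceptible prevalence of the cohort at its (effective) census age.
#'
#' @param c_m Observed MZ concordance, in \[0, 1\]. Vectorized.
#' @return Prevalence probabilities in \[0, 1\].
#' @examples
#' invert_mz_concordance(120 / 174)  # Kallmann: 0.816
#' @export
invert_mz_concordance <- function(c_m) {
  check_prob(c_m, "c_m")
  2 * c_m / (1 + c_m)
}

#' Dizygote subcohort concordance
#'
#' For dizygote pairs the index twin is susceptible by ascertainment while the
#' cotwin inherits susceptibility with probability `s_inher`. The concordant
#' fraction of the observed cohort is
#' \deqn{C_D = \frac{s\, p_s}{1 + s - s\, p_s},}
#' which increases with `p_s` and plateaus at `s_inher` as `p_s` approaches 1
#' (the dizygote curve saturates at `s_inher`, the monozygote curve at 1).
#'
#' @inheritParams mz_state_probabilities
#' @param s_inher Probability that the dizygote cotwin of an affected
#'   individual inherits the susceptibility, in \[0, 1\].
#' @return Concordance probabilities in \[0, `s_inher`\].
#' @export
dz_concordance <- function(p_s, s_inher) {
  check_prob(p_s, "p_s"); check_prob(s_inher, "s_inher")
  s_inher * p_s / (1 + s_inher - s_inher * p_s)
}

#' Inherited susceptibility from DZ concordance and prevalence
#'
#' Inverts the dizygote concordance formula for `s_inher` given the observed
#' DZ concordance and the cohort prevalence:
#' \deqn{S_{inher} = \frac{C_D}{p_s + (p_s - 1) C_D}.}
#' The denominator is positive only when the cohort is old enough (prevalence
#' large enough) to support the observed concordance.
#'
#' @param c_d Observed DZ concordance, in \[0, 1\].
#' @inheritParams mz_state_probabilities
#' @return `s_inher` in \[0, 1\].
#' @examples
#' s_inher_from_prevalence(3 / 33, 0.588)  # Gottesman & Shields: 0.165
#' @export
s_inher_from_prevalence <- function(c_d, p_s) {
  check_prob(c_d, "c_d"); check_prob(p_s, "p_s")
  denom <- p_s + (p_s - 1) * c_d
  if (any(denom <= 0))
    stop("nonpositive denominator: cohort prevalence too small for the ",
         "observed DZ concordance", call. = FALSE)
  c_d / denom
}

#' Inherited susceptibility from the two concordance fractions
#'
#' Model prediction of `s_inher` directly from a study's observed MZ and DZ
#' concordances, eliminating the prevalence via the MZ inversion:
#' \deqn{S_{inher} = \frac{1 + C_M}{2 C_M / C_D - 1 + C_M}.}
#'
#' @param c_m Observed MZ concordance, in (0, 1\].
#' @param c_d Observed DZ concordance, in \[0, 1\].
#' @return `s_inher` in \[0, 1\]; 0 when `c_d = 0`.
#' @examples
#' s_inher_from_concordances(120 / 174, 53 / 517)  # Kallmann: 0.129
#' @export
s_inher_from_concordances <- function(c_m, c_d) {
  check_prob(c_m, "c_m"); check_prob(c_d, "c_d")
  out <- numeric(length(c_m))
  zero <- c_d == 0
  if (any(c_m == 0 & !zero))
    stop("s_inher is undefined for c_m = 0 with positive c_d", call. = FALSE)
  out[!zero] <- (1 + c_m[!zero]) /
    (2 * c_m[!zero] / c_d[!zero] - 1 + c_m[!zero])
  out
}

#' Cohort-average monozygote concordance
#'
#' A twin study measures concordance averaged over members of many ages. With
#' an explicit age-count table the average is
#' \eqn{\sum_a C_M(t_a)\, n_a / N_T}; for a uniform age distribution over
#' \[`t_L`, `t_H`\] it is
#' \deqn{\langle C_M \rangle = \frac{1}{t_H - t_L}
#'       \int_{t_L}^{t_H} C_M(P_s(t, r))\, dt,}
#' evaluated by adaptive quadrature.
#'
#' @inheritParams susceptible_prevalence
#' @param t_L,t_H Cohort age range in years, `t_L < t_H`.
#' @param weights Optional data.frame with columns `age` and `n` giving the
#'   cohort age composition; when supplied the discrete weighted average is
#'   returned and `t_L`, `t_H` are ignored.
#' @return The average MZ concordance, a probability.
#' @examples
#' average_mz_concordance(usa_model_params(), 19, 64)  # ~0.4013
#' @export
average_mz_concordance <- function(params, t_L, t_H, weights = NULL) {
  stopifnot(inherits(params, "mmm_params"))
  if (!is.null(weights)) {
    if (!is.data.frame(weights) || nrow(weights) == 0 ||
        !all(c("age", "n") %in% names(weights)))
      stop("'weights' must be a nonempty data.frame with columns age, n",
           call. = FALSE)
    cm <- mz_concordance(susceptible_prevalence(params, weights$age))
    return(sum(cm * weights$n) / sum(weights$n))
  }
  if (!(t_L < t_H)) stop("require t_L < t_H", call. = FALSE)
  stats::integrate(function(t)
    mz_concordance(susceptible_prevalence(params, t)),
    t_L, t_H, rel.tol = 1e-10, abs.tol = 1e-12)$value / (t_H - t_L)
}

#' Age at which the model concordance reaches a target
#'
#' Solves `C_M(P_s(t, r)) = c_m_target` for the census age `t`. Because both
#' `P_s` and `C_M` are strictly increasing, the root is unique; it is located
#' by bracketed root finding ([stats::uniroot()]) on \[0, `upper`\].
#'
#' @inheritParams susceptible_prevalence
#' @param c_m_target Target MZ concordance, in (0, 1).
#' @param upper Upper bracket in years (default 200).
#' @param tol Absolute age tolerance, years.
#' @return Age in years.
#' @examples
#' equivalent_age(usa_model_params(), 10 / 24)  # ~41.0 y
#' @export
equivalent_age <- function(params, c_m_target, upper = 200, tol = 1e-9) {
  stopifnot(inherits(params, "mmm_params"))
  if (!(c_m_target > 0 && c_m_target < 1))
    stop("'c_m_target' must lie in (0, 1)", call. = FALSE)
  f <- function(t) mz_concordance(susceptible_prevalence(params, t)) -
    c_m_target
  if (f(upper) < 0)
    stop("target concordance not reached by age ", upper,
         " y on this curve", call. = FALSE)
  stats::uniroot(f, c(0, upper), tol = tol)$root
}

#' Clock rate matching an observed concordance at a known age
#'
#' For a cohort well approximated by a single age, finds the dimensionless
#' clock rate `r` such that the rescaled prevalence curve reaches the
#' prevalence implied by the observed MZ concordance at that age:
#' `P_s(age, r) = 2 c_m / (1 + c_m)`. `P_s(age, r)` is strictly increasing in
#' `r`, so the root on the bracket is unique.
#'
#' @inheritParams susceptible_prevalence
#' @param age Cohort (representative) age in years, > 0.
#' @param c_m_observed Observed MZ concordance, in (0, 1).
#' @param bracket Search interval for `r` (default `c(1e-3, 1e2)`).
#' @param tol Absolute tolerance on `r`.
#' @return The clock rate `r` (dimensionless).
#' @examples
#' clock_rate_from_concordance(usa_model_params(), 43, 11 / 80)  # ~0.631
#' @export
clock_rate_from_concordance <- function(params, age, c_m_observed,
                                        bracket = c(1e-3, 1e2), tol = 1e-9) {
  stopifnot(inherits(params, "mmm_params"))
  if (!(age > 0)) stop("'age' must be positive", call. = FALSE)
  if (!(c_m_observed > 0 && c_m_observed < 1))
    stop("'c_m_observed' must lie in (0, 1)", call. = FALSE)
  target <- invert_mz_concordance(c_m_observed)
  f <- function(r) susceptible_prevalence(set_clock_rate(params, r), age) -
    target
  if (f(bracket[1]) > 0 || f(bracket[2]) < 0)
    stop("clock rate not bracketed on [", bracket[1], ", ", bracket[2], "]",
         call. = FALSE)
  stats::uniroot(f, bracket, tol = tol)$root
}

#' Clock rate matching an observed mean onset age
#'
#' Finds the clock rate `r` such that the model's mean onset age within the
#' cohort window \[`t_L`, `t_H`\] equals the observed `t_bar_target`. The
#' windowed mean onset age is strictly decreasing in `r` (a faster clock
#' shifts onsets earlier within the window), so bracketed root finding
#' applies.
#'
#' @inheritParams mean_onset_age
#' @param t_bar_target Observed mean onset age, strictly inside
#'   (`t_L`, `t_H`).
#' @param bracket Search interval for `r` (default `c(1e-3, 1e2)`).
#' @param tol Absolute tolerance on `r`.
#' @return The clock rate `r` (dimensionless).
#' @examples
#' clock_rate_from_mean_age(usa_model_params(), 15, 45, 23.8)  # ~1.95
#' @export
clock_rate_from_mean_age <- function(params, t_L, t_H, t_bar_target,
                                     bracket = c(1e-3, 1e2), tol = 1e-9) {
  stopifnot(inherits(params, "mmm_params"))
  if (!(t_L < t_bar_target && t_bar_target < t_H))
    stop("'t_bar_target' must lie strictly inside (t_L, t_H)", call. = FALSE)
  # at extreme r the window holds no onset mass numerically. For r -> 0,
  # P_s ~ (k1 t)^m1 (k2 t) so the windowed density tends to m t^(m-1) and the
  # mean to its exact limit (m/(m+1)) (t_H^(m+1)-t_L^(m+1))/(t_H^m-t_L^m);
  # for r -> Inf the curve has saturated and the mean tends to t_L.
  # Substituting these limits keeps the bracket check truthful.
  m <- params$m
  small_r_mean <- (m / (m + 1)) * (t_H^(m + 1) - t_L^(m + 1)) /
    (t_H^m - t_L^m)
  f <- function(r) tryCatch(
    mean_onset_age(set_clock_rate(params, r), t_L, t_H) - t_bar_target,
    error = function(e) {
      saturated <- susceptible_prevalence(set_clock_rate(params, r),
                                          t_L) > 0.5
      (if (saturated) t_L else small_r_mean) - t_bar_target
    })
  if (f(bracket[1]) < 0 || f(bracket[2]) > 0)
    stop("mean onset age target not attainable on the clock-rate bracket",
         call. = FALSE)
  stats::uniroot(f, bracket, tol = tol)$root
}

#' Fraction of dizygote cotwins unable to develop the disease
#'
#' Simply `1 - s_inher`: the model-predicted fraction of dizygote cotwins of
#' affected individuals who did not inherit the susceptibility and therefore
#' cannot develop the disease despite the shared early environment. Applied
#' across a table of studies, the conservative headline figure is the
#' *minimum* over studies.
#'
#' @param s_inher Inherited-susceptibility probabilities in \[0, 1\].
#'   Vectorized.
#' @return `1 - s_inher`.
#' @export
fraction_unable <- function(s_inher) {
  check_prob(s_inher, "s_inher")
  1 - s_inher
}
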