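#' Susceptible prevalence of the multimutation model
#'
#' The probability that a susceptible individual has had disease onset by age
#' `t`, i.e. has accumulated all `m = m1 + 1` required mutations:
#' \deqn{P_s(t, r) = [1 - e^{-r k_1 t}]^{m_1} [1 - e^{-r k_2 t}].}
#' Satisfies the clock-rescaling identity `P_s(t, r) = P_s(r t, 1)`; it maps
#' 0 to 0, increases strictly on (0, Inf) and approaches 1.
#'
#' @param params An [mmm_params()] object.
#' @param t Age(s) in years, >= 0. Vectorized.
#' @return Probabilities in \[0, 1), same length as `t`.
#' @examples
#' susceptible_prevalence(usa_model_params(), c(19, 41, 64))
#' @export
susceptible_prevalence <- function(params, t) {
  stopifnot(inherits(params, "mmm_params"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("ages 't' must be finite and nonnegative", call. = FALSE)
  a <- params$r * params$k1
  b <- params$r * params$k2
  (1 - exp(-a * t))^params$m1 * (1 - exp(-b * t))
}

#' Population prevalence of the multimutation model
#'
#' Unconditional cumulative disease risk by age `t`:
#' `f_s * susceptible_prevalence(params, t)`, where `f_s` is the lifetime
#' susceptible fraction of the birth cohort.
#'
#' @inheritParams susceptible_prevalence
#' @return Probabilities in \[0, `f_s`\], same length as `t`.
#' @export
population_prevalence <- function(params, t) {
  params$f_s * susceptible_prevalence(params, t)
}

#' Incidence rate (analytic derivative of prevalence)
#'
#' The fractional incidence rate `dP/dt`, evaluated from the analytic
#' derivative of the closed-form prevalence (no finite differences):
#' \deqn{IR_s(t) = m_1 a e^{-a t} A^{m_1 - 1} B + b e^{-b t} A^{m_1}}
#' with `a = r k1`, `b = r k2`, `A = 1 - e^{-a t}`, `B = 1 - e^{-b t}`.
#' The population rate multiplies by `f_s`.
#'
#' @inheritParams susceptible_prevalence
#' @param susceptible If `TRUE` (default) return the susceptible rate
#'   `IR_s = dP_s/dt`; otherwise the population rate `f_s * IR_s`.
#' @return Rates per year, same length as `t`; zero at `t = 0` when `m >= 2`.
#' @export
incidence_rate <- function(params, t, susceptible = TRUE) {
  stopifnot(inherits(params, "mmm_params"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("ages 't' must be finite and nonnegative", call. = FALSE)
  a <- params$r * params$k1
  b <- params$r * params$k2
  m1 <- params$m1
  A <- 1 - exp(-a * t)
  B <- 1 - exp(-b * t)
  # A^(m1-1) at t=0 with m1 = 0 or 1 must not produce NaN/Inf
  Am1 <- if (m1 >= 1) A^(m1 - 1) else rep(0, length(t))
  ir <- m1 * a * exp(-a * t) * Am1 * B + b * exp(-b * t) * A^m1
  if (susceptible) ir else params$f_s * ir
}

#' Age at the peak of the incidence-rate curve
#'
#' Locates the interior maximum of the susceptible incidence rate `IR_s(t)`.
#' For `m >= 2` the rate rises from 0 at birth, peaks once and decays, so the
#' maximum is found by golden-section/parabolic search ([stats::optimize()])
#' on a bracket that provably contains it; `m = 1` (a single exponential) has
#' a monotone decreasing rate and no interior peak, which is an error.
#'
#' @inheritParams susceptible_prevalence
#' @param upper Upper end of the search bracket in years (default 500; the
#'   bracket is rescaled by `1/r` internally so the default is ample for any
#'   realistic rate).
#' @param tol Absolute tolerance on the located age, years.
#' @return The peak age in years.
#' @examples
#' peak_onset_age(usa_model_params("males"))
#' @export
peak_onset_age <- function(params, upper = 500, tol = 1e-8) {
  stopifnot(inherits(params, "mmm_params"))
  if (params$m < 2)
    stop("the incidence rate has no interior maximum when m = 1 ",
         "(monotone decreasing)", call. = FALSE)
  opt <- stats::optimize(function(t) incidence_rate(params, t),
                         interval = c(0, upper / params$r),
                         maximum = TRUE, tol = tol)
  # guard: an end-point 'maximum' means the bracket failed
  if (opt$maximum > 0.999 * upper / params$r)
    stop("failed to bracket the incidence peak; increase 'upper'",
         call. = FALSE)
  opt$maximum
}

#' Mean onset age within a cohort age window
#'
#' The mean age at which onset occurs among cohort members whose onset falls
#' inside the window \[`t_L`, `t_H`\]:
#' \deqn{\bar t = \frac{\int_{t_L}^{t_H} t\, dP_s(t, r)}
#'                     {P_s(t_H, r) - P_s(t_L, r)},}
#' computed by adaptive quadrature of `t * IR_s(t)` ([stats::integrate()]).
#' The result always lies strictly inside (`t_L`, `t_H`).
#'
#' @inheritParams susceptible_prevalence
#' @param t_L,t_H Cohort age window in years, `0 <= t_L < t_H`.
#' @return Mean onset age in years.
#' @examples
#' mean_onset_age(set_clock_rate(usa_model_params(), 1.94), 15, 45)
#' @export
mean_onset_age <- function(params, t_L, t_H) {
  stopifnot(inherits(params, "mmm_params"))
  if (!(t_L >= 0 && t_H > t_L))
    stop("require 0 <= t_L < t_H", call. = FALSE)
  denom <- susceptible_prevalence(params, t_H) -
    susceptible_prevalence(params, t_L)
  if (denom <= 0)
    stop("degenerate cohort: no onset probability mass in [t_L, t_H]",
         call. = FALSE)
  num <- stats::integrate(function(t) t * incidence_rate(params, t),
                          t_L, t_H, rel.tol = 1e-10, abs.tol = 1e-12)$value
  num / denom
}

#' Mean waiting times of the two mutation classes
#'
#' Mean time for a single mutation of each rate class to occur under the
#' clock-scaled rates: `T1 = 1/(r k1)` and `T2 = 1/(r k2)`.
#'
#' @inheritParams susceptible_prevalence
#' @return Named numeric vector `c(T1 = , T2 = )`, years.
#' @examples
#' mutation_mean_times(usa_model_params("males"))  # ~8.58 y and ~35.1 y
#' @export
mutation_mean_times <- function(params) {
  stopifnot(inherits(params, "mmm_params"))
  c(T1 = 1 / (params$r * params$k1), T2 = 1 / (params$r * params$k2))
}
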