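#' Sum-of-squares fit error on cumulative-fraction scale
#'
#' The least-squares objective of the model fit: the observed cumulative
#' incidence and the model's population prevalence are both expressed as
#' dimensionless cumulative fractions and the squared residuals summed,
#' \eqn{\chi^2 = \sum_i (x_i - d_i)^2}. Normalizing to fractions makes the
#' objective invariant to the population scale of the data (per-100,000
#' versus raw fraction).
#'
#' @param data Incidence data.frame with columns `age_years` and
#'   `cum_incidence_per_100k` (see [read_incidence_csv()]).
#' @param params An [mmm_params()] object.
#' @param scale Population denominator of the data (default 1e5).
#' @return The scalar sum of squared fraction residuals.
#' @examples
#' d <- simulate_incidence_dataset(usa_model_params(), seq(10, 70, 2.5))
#' chisq_mmm(d, usa_model_params())  # exact data: 0
#' @export
chisq_mmm <- function(data, params, scale = 1e5) {
  check_incidence(data)
  d <- data$cum_incidence_per_100k / scale
  x <- population_prevalence(params, data$age_years)
  sum((x - d)^2)
}

check_incidence <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0)
    stop("incidence data must be a nonempty data.frame", call. = FALSE)
  req <- c("age_years", "cum_incidence_per_100k")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("incidence data missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(data)
}

#' Fit the multimutation model to cumulative incidence data
#'
#' Least-squares fit of the 3- or 4-parameter multimutation model to
#' age-binned cumulative incidence observations. For every candidate integer
#' mutation count `m1` in `m1_range` the continuous rates are optimized by
#' box-constrained quasi-Newton minimization ([stats::nlminb()]) on the log
#' scale from a lattice of starting points, with the lifetime risk `f_s`
#' profiled out in closed form (the objective is linear in `f_s`, so its
#' optimum \eqn{\hat f_s = \sum g_i d_i / \sum g_i^2}, clipped to \[0, 1\],
#' is available exactly at each step); the global best over `m1` is
#' returned. A 4-parameter fit can never have a larger objective than the
#' 3-parameter fit of the same data, because the latter is the `k2 = k1`
#' boundary of the former.
#'
#' @param data Incidence data.frame with columns `age_years` (strictly
#'   increasing) and `cum_incidence_per_100k` (nondecreasing); see
#'   [read_incidence_csv()].
#' @param n_params 3 (single rate, `k2 = k1`) or 4 (two rates).
#' @param m1_range Integer candidates for `m1` (default `1:40`).
#' @param start_rates Lattice of per-year rate starting values (default
#'   log-spaced over \[0.01, 1\]).
#' @param scale Population denominator of the data (default 1e5).
#' @param jitter_sd Log-scale s.d. of optional random jitter added to each
#'   lattice start (default 0, fully deterministic).
#' @param seed Seed controlling the jitter (default 0); ignored when
#'   `jitter_sd = 0`.
#' @return An object of class `"mmm_fit"`, a list with elements `params`
#'   (an [mmm_params()] object), `chisq` (fraction-scale sum of squares),
#'   `fitted_values` (model curve at the data ages, per-100k scale),
#'   `n_params`, `converged`, `m1_profile` (best objective per candidate
#'   `m1`), `data`, `scale`. Supports `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot` and `simulate` methods.
#' @examples
#' truth <- usa_model_params()
#' d <- simulate_incidence_dataset(truth, seq(10, 70, 2.5))
#' fit <- fit_mmm(d, m1_range = 10:20)
#' coef(fit)
#' @export
fit_mmm <- function(data, n_params = 4, m1_range = 1:40,
                    start_rates = exp(seq(log(0.01), log(1), length.out = 5)),
                    scale = 1e5, jitter_sd = 0, seed = 0) {
  check_incidence(data)
  if (!n_params %in% c(3, 4)) stop("'n_params' must be 3 or 4", call. = FALSE)
  if (nrow(data) < n_params + 1)
    stop("need at least n_params + 1 data points", call. = FALSE)
  t <- data$age_years
  d <- data$cum_incidence_per_100k / scale

  # objective over log-rates for a fixed m1, f_s profiled out
  obj <- function(logk, m1) {
    k1 <- exp(logk[1])
    k2 <- if (n_params == 4) exp(logk[2]) else k1
    g <- (1 - exp(-k1 * t))^m1 * (1 - exp(-k2 * t))
    sg2 <- sum(g^2)
    fs <- if (sg2 > 0) min(1, max(0, sum(g * d) / sg2)) else 0
    sum((fs * g - d)^2)
  }

  starts <- if (n_params == 4) {
    as.matrix(expand.grid(log(start_rates), log(start_rates)))
  } else {
    matrix(log(start_rates), ncol = 1)
  }
  if (jitter_sd > 0) {
    set.seed(seed)
    starts <- starts + matrix(stats::rnorm(length(starts), 0, jitter_sd),
                              nrow(starts))
  }

  best <- NULL
  m1_profile <- stats::setNames(rep(NA_real_, length(m1_range)),
                                paste0("m1=", m1_range))
  for (i in seq_along(m1_range)) {
    m1 <- m1_range[i]
    for (s in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::nlminb(starts[s, ], obj, m1 = m1,
                      lower = log(1e-5), upper = log(10),
                      control = list(abs.tol = 1e-14, rel.tol = 1e-12,
                                     iter.max = 500)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (!is.na(m1_profile[i]))
        m1_profile[i] <- min(m1_profile[i], res$objective)
      else m1_profile[i] <- res$objective
      if (is.null(best) || res$objective < best$objective) {
        best <- res; best$m1 <- m1
      }
    }
  }
  if (is.null(best))
    stop("optimizer failed from every starting point", call. = FALSE)

  k1 <- exp(best$par[1])
  k2 <- if (n_params == 4) exp(best$par[2]) else k1
  g <- (1 - exp(-k1 * t))^best$m1 * (1 - exp(-k2 * t))
  fs <- min(1, max(0, sum(g * d) / sum(g^2)))
  params <- mmm_params(best$m1, k1, k2, fs)
  structure(
    list(params = params, chisq = best$objective,
         fitted_values = scale * fs * g, n_params = n_params,
         converged = best$convergence == 0, m1_profile = m1_profile,
         data = data, scale = scale, call = match.call()),
    class = "mmm_fit")
}

#' @export
coef.mmm_fit <- function(object, ...) {
  p <- object$params
  c(m = p$m, m1 = p$m1, k1 = p$k1, k2 = p$k2, f_s = p$f_s)
}

#' @export
print.mmm_fit <- function(x, digits = 5, ...) {
  cat(sprintf("Multimutation model fit (%d-parameter)\n", x$n_params))
  print(x$params, digits = digits)
  cat(sprintf("  chisq (fraction scale): %s on %d ages%s\n",
              format(x$chisq, digits = digits), nrow(x$data),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.mmm_fit <- function(object, ...) {
  prof <- sort(object$m1_profile)[seq_len(min(5, length(object$m1_profile)))]
  structure(list(fit = object, top_m1 = prof,
                 peak_age = tryCatch(peak_onset_age(object$params),
                                     error = function(e) NA_real_),
                 mean_times = mutation_mean_times(object$params)),
            class = "summary.mmm_fit")
}

#' @export
print.summary.mmm_fit <- function(x, digits = 5, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  incidence peak at %s y;  mutation mean times T1 = %s y, T2 = %s y\n",
              format(x$peak_age, digits = 4),
              format(x$mean_times[["T1"]], digits = 4),
              format(x$mean_times[["T2"]], digits = 4)))
  cat("  best objective by mutation count (top 5):\n")
  print(signif(x$top_m1, 4))
  invisible(x)
}

#' Predict cumulative incidence from a fitted model
#'
#' @param object An `mmm_fit` object.
#' @param newdata Optional data.frame with column `age_years`; defaults to
#'   the training ages.
#' @param type `"per100k"` (population cumulative incidence per 100,000,
#'   default), `"fraction"` (population prevalence) or `"susceptible"`
#'   (susceptible prevalence, `f_s` divided out).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mmm_fit <- function(object, newdata = NULL,
                            type = c("per100k", "fraction", "susceptible"),
                            ...) {
  type <- match.arg(type)
  ages <- if (is.null(newdata)) object$data$age_years else newdata$age_years
  switch(type,
    per100k = object$scale * population_prevalence(object$params, ages),
    fraction = population_prevalence(object$params, ages),
    susceptible = susceptible_prevalence(object$params, ages))
}

#' @export
fitted.mmm_fit <- function(object, ...) object$fitted_values

#' @export
residuals.mmm_fit <- function(object, ...) {
  object$data$cum_incidence_per_100k - object$fitted_values
}

#' Plot a fitted multimutation model over its data
#'
#' Observed cumulative incidence (points) with the fitted model curve and,
#' optionally, the fitted incidence-rate curve in a second panel.
#'
#' @param x An `mmm_fit` object.
#' @param incidence Also draw the incidence-rate panel? Default `FALSE`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mmm_fit <- function(x, incidence = FALSE, ...) {
  if (incidence) {
    old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  }
  ages <- x$data$age_years
  grid <- seq(0, max(ages) * 1.05, length.out = 400)
  graphics::plot(ages, x$data$cum_incidence_per_100k,
                 xlab = "age (years)",
                 ylab = sprintf("cumulative incidence per %g", x$scale),
                 main = "Multimutation model fit", ...)
  graphics::lines(grid, x$scale * population_prevalence(x$params, grid),
                  col = "steelblue", lwd = 2)
  if (incidence) {
    graphics::plot(grid, incidence_rate(x$params, grid), type = "l",
                   col = "firebrick", lwd = 2, xlab = "age (years)",
                   ylab = "susceptible incidence rate (/y)",
                   main = "Incidence rate")
  }
  invisible(x)
}

#' Simulate datasets from a fitted model
#'
#' Draws new synthetic incidence datasets at the training ages from the
#' fitted parameters via [simulate_incidence_dataset()].
#'
#' @param object An `mmm_fit` object.
#' @param nsim Number of datasets.
#' @param seed Integer seed (default 1).
#' @param noise_sd Multiplicative noise s.d. as a fraction (default 0.02).
#' @param ... Unused.
#' @return A list of `nsim` incidence data.frames.
#' @export
simulate.mmm_fit <- function(object, nsim = 1, seed = 1, noise_sd = 0.02,
                             ...) {
  lapply(seq_len(nsim), function(i)
    simulate_incidence_dataset(object$params, object$data$age_years,
                               noise_sd = noise_sd, seed = seed + i - 1L))
}
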