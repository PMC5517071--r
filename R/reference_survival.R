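#' Reference survival step functions
#'
#' A `survlrt_ref` object stores the reference survival function \eqn{G(t)}
#' as a right-continuous step function: survival probability 1 before the
#' first knot, then the tabulated value held from each knot to the next, and
#' the last value held beyond the final knot. All Lehmann alternatives
#' \eqn{G(t)^\Delta} used by the epistasis test are derived from this object
#' by exponentiation.
#'
#' Tabulated probabilities of exactly zero would make log-survival terms
#' infinite, so they are clamped to `floor_prob`, which defaults to half the
#' smallest positive tabulated probability.
#'
#' @param times Knot times in months; non-negative, strictly increasing.
#' @param surv Survival probabilities at the knots; non-increasing, in
#'   \[0, 1\]. Zeros are clamped to `floor_prob` with a warning.
#' @param floor_prob Smallest representable survival probability. Default
#'   half the smallest positive value of `surv`.
#' @param warn_clamp Warn when zeros are clamped (default `TRUE`).
#' @return A `survlrt_ref` object.
#' @examples
#' ref <- ref_survival(c(12, 24, 60), c(0.9, 0.7, 0.4))
#' eval_survival(ref, c(0, 12, 30, 100))
#' @export
ref_survival <- function(times, surv, floor_prob = NULL, warn_clamp = TRUE) {
  times <- as.numeric(times)
  surv <- as.numeric(surv)
  if (length(times) == 0L || length(times) != length(surv)) {
    abort("`times` and `surv` must be non-empty vectors of equal length.")
  }
  if (anyNA(times) || anyNA(surv)) abort("Reference survival cannot contain NA.")
  if (any(times < 0)) abort("Knot times must be non-negative.")
  if (is.unsorted(times, strictly = TRUE)) {
    abort("Knot times must be strictly increasing.")
  }
  if (times[1] == 0) {
    # a leading (0, 1) row restates the G(0) = 1 convention; anything else
    # would contradict it
    if (surv[1] < 1) abort("Survival at time 0 must be 1.")
    times <- times[-1]; surv <- surv[-1]
    if (length(times) == 0L) abort("Reference survival needs a knot at a positive time.")
  }
  if (any(surv > 1) || any(surv < 0)) abort("Survival probabilities must lie in [0, 1].")
  if (is.unsorted(rev(surv))) abort("Survival probabilities must be non-increasing.")
  pos <- surv[surv > 0]
  if (is.null(floor_prob)) {
    if (length(pos) == 0L) abort("All tabulated survival probabilities are zero.")
    floor_prob <- min(pos) / 2
  }
  if (floor_prob <= 0 || floor_prob > 1) abort("`floor_prob` must be in (0, 1].")
  if (any(surv == 0)) {
    if (warn_clamp) {
      warn(sprintf("%d zero survival probabilities clamped to floor_prob = %.3g.",
                   sum(surv == 0), floor_prob))
    }
    surv[surv == 0] <- floor_prob
  }
  structure(
    list(times = times, surv = surv, floor_prob = floor_prob),
    class = "survlrt_ref"
  )
}

#' @export
print.survlrt_ref <- function(x, ...) {
  cat(sprintf(
    "<survlrt_ref> %d knots on [%.4g, %.4g] months; G ranges 1 -> %.4g (floor %.3g)\n",
    length(x$times), min(x$times), max(x$times), min(x$surv), x$floor_prob
  ))
  invisible(x)
}

#' @export
#' @rdname ref_survival
#' @param x A `survlrt_ref`.
is_ref_survival <- function(x) inherits(x, "survlrt_ref")

check_ref <- function(ref) {
  if (!is_ref_survival(ref)) abort("`ref` must be a `survlrt_ref` object (see `ref_survival()`).")
  ref
}

#' Kaplan-Meier reference survival estimate
#'
#' Estimates the reference survival function with the product-limit
#' (Kaplan-Meier) estimator, via [survival::survfit()]. A terminal survival
#' probability of zero (largest observation a death) is clamped so that
#' log-survival contributions stay finite.
#'
#' @param time Event or censoring times in months, non-negative.
#' @param event Binary death indicators (1 = death observed, 0 = censored).
#' @param floor_prob Optional clamp for zero survival; default half the
#'   smallest positive estimated probability.
#' @return A `survlrt_ref` object with a knot at every distinct event time.
#' @examples
#' km_reference(c(1, 2, 3), c(1, 1, 1))
#' @export
km_reference <- function(time, event, floor_prob = NULL) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) == 0L) abort("No observations supplied.")
  if (length(event) != length(time)) abort("`time` and `event` lengths differ.")
  if (anyNA(time) || anyNA(event)) abort("NA in survival input.")
  if (any(time < 0)) abort("Times must be non-negative.")
  if (!all(event %in% c(0L, 1L))) abort("`event` must be 0/1.")
  if (sum(event) == 0L) abort("All observations censored: survival not estimable.")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  s <- fit$surv[keep]
  if (is.null(floor_prob)) {
    # with a terminal death the estimate hits 0; half the smallest positive
    # step (or half 1/n when every knot is 0, i.e. a single fatal knot)
    pos <- s[s > 0]
    floor_prob <- if (length(pos)) min(pos) / 2 else 1 / (2 * length(time))
  }
  ref_survival(fit$time[keep], s, floor_prob = floor_prob, warn_clamp = FALSE)
}

#' Evaluate a reference survival function
#'
#' `eval_survival()` returns \eqn{G(t)}; `log_survival()` returns
#' \eqn{\log G(t)} (always finite thanks to the probability floor). Both are
#' vectorised over `t` and use the right-continuous step convention:
#' \eqn{G(t) = 1} for `t` before the first knot and the last tabulated value
#' beyond the final knot.
#'
#' @param ref A `survlrt_ref`.
#' @param t Times in months, non-negative.
#' @param delta Fitness exponent \eqn{\Delta > 0}; the value returned is for
#'   the Lehmann alternative \eqn{G(t)^\Delta}.
#' @return Numeric vector of probabilities (or their logs), same length as `t`.
#' @export
eval_survival <- function(ref, t, delta = 1) {
  check_ref(ref)
  t <- as.numeric(t)
  if (anyNA(t) || any(t < 0)) abort("Evaluation times must be non-negative and non-NA.")
  if (length(delta) != 1L || !is.finite(delta) || delta <= 0) abort("`delta` must be a single positive number.")
  idx <- findInterval(t, ref$times)
  c(1, ref$surv)[idx + 1L]^delta
}

#' @rdname eval_survival
#' @export
log_survival <- function(ref, t, delta = 1) {
  delta * log(eval_survival(ref, t))
}

#' Sample survival times from a Lehmann alternative
#'
#' Inverse-transform sampling of survival times with survival function
#' \eqn{G(t)^\Delta} restricted to the reference knot grid: the returned time
#' is the smallest knot \eqn{t} with \eqn{G(t)^\Delta \le u}. Draws for which
#' even the final knot's survival exceeds `u` (probability at most
#' `floor_prob^delta`) return the final knot time.
#'
#' @param ref A `survlrt_ref`.
#' @param n Number of draws (ignored when `u` is supplied).
#' @param delta Fitness exponent \eqn{\Delta > 0}.
#' @param u Optional uniform(0,1) draws; supply to make the transform
#'   deterministic, otherwise `runif(n)` is used.
#' @return Numeric vector of times in months.
#' @examples
#' ref <- ref_survival(c(1, 2), c(0.5, 0.25))
#' sample_survival_time(ref, delta = 1, u = 0.6) # 1
#' @export
sample_survival_time <- function(ref, n = length(u), delta = 1, u = NULL) {
  check_ref(ref)
  if (length(delta) != 1L || !is.finite(delta) || delta <= 0) abort("`delta` must be a single positive number.")
  if (is.null(u)) u <- runif(n)
  if (any(u <= 0) || any(u >= 1)) abort("`u` must lie strictly in (0, 1).")
  m <- length(ref$times)
  g <- ref$surv^delta                      # decreasing along knots
  n_le <- findInterval(u, rev(g))          # knots with G^delta <= u
  j <- pmin(m - n_le + 1L, m)
  ref$times[j]
}

#' Load a tabulated reference survival function
#'
#' Reads a months/probability table (columns `months` and `p`) such as a
#' published Kaplan-Meier life table, validates monotonicity, and returns the
#' step function.
#'
#' @param path Path to a CSV file with columns `months` and `p`.
#' @param floor_prob Optional probability floor (see [ref_survival()]).
#' @return A `survlrt_ref`.
#' @export
read_reference <- function(path, floor_prob = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("months", "p") %in% names(tab))) {
    abort("Reference CSV must have columns `months` and `p`.")
  }
  tab <- dplyr::arrange(tab, .data$months)
  ref_survival(tab$months, tab$p, floor_prob = floor_prob)
}

#' @rdname read_reference
#' @param ref A `survlrt_ref` to write.
#' @export
write_reference <- function(ref, path) {
  check_ref(ref)
  readr::write_csv(tibble::tibble(months = ref$times, p = ref$surv), path)
  invisible(path)
}

#' Parametric reference survival functions for simulation
#'
#' `exp_reference()` tabulates a truncated-exponential survival law on a
#' monthly grid; `synthetic_reference()` tabulates a Weibull-type law chosen
#' to resemble all-cause mortality in an elderly cohort (median survival
#' around nine years) and is the default reference for the simulation
#' experiments. Both are synthetic constructions, not estimates from any
#' patient registry.
#'
#' @param mean_months Mean of the (untruncated) exponential, in months.
#' @param truncation_months Upper bound of the tabulated grid, default 480
#'   months (40 years).
#' @param scale,shape Weibull scale (months) and shape for
#'   `synthetic_reference()`.
#' @return A `survlrt_ref` on a monthly knot grid.
#' @export
exp_reference <- function(mean_months, truncation_months = 480) {
  if (!is.finite(mean_months) || mean_months <= 0) abort("`mean_months` must be positive.")
  tt <- seq(1, truncation_months)
  ref_survival(tt, exp(-tt / mean_months))
}

#' @rdname exp_reference
#' @export
synthetic_reference <- function(scale = 150, shape = 1.2, truncation_months = 480) {
  tt <- seq(1, truncation_months)
  ref_survival(tt, exp(-(tt / scale)^shape))
}

#' @export
#' @rdname ref_survival
#' @param object A `survlrt_ref`.
#' @param ... Unused.
autoplot.survlrt_ref <- function(object, ...) {
  df <- tibble::tibble(
    months = c(0, object$times),
    surv = c(1, object$surv)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$months, y = .data$surv)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability G(t)") +
    ggplot2::theme_minimal()
}
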