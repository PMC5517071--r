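#' Sufficient statistics for one epistasis test
#'
#' Collapses a cohort to the per-group sufficient statistics of the fitness
#' likelihood: for each of the four genotype groups \eqn{g_k} of the tested
#' epistasis type, the number of observed deaths \eqn{S_k} and the summed
#' log reference survival \eqn{H_k = \sum_i \log G(t_i)} over *all* group
#' members (deaths and censored alike), evaluated at each patient's observed
#' time. Patients whose genotype lies outside the type's quadruple are
#' excluded.
#'
#' @param cohort A data frame with columns `status` (1 = censored,
#'   0 = dead), either `time_months` or `last_follow_up_days`, and one 0/1
#'   column per gene.
#' @param genes Character vector of 2 (pairwise) or 3 (triple types) gene
#'   column names; order is meaningful (see [epistasis_types()]).
#' @param type Epistasis type label or `epistasis_type` object.
#' @param ref A `survlrt_ref` reference survival function.
#' @param keep_censored If `FALSE`, censored patients are dropped before the
#'   statistics are computed (reproduces the biased estimator studied in the
#'   simulation experiments). Default `TRUE`.
#' @return A `survlrt_groupstats` object: genotype labels, `S`, `H`, group
#'   sizes `n`, and the number of excluded patients.
#' @export
group_stats <- function(cohort, genes, type, ref, keep_censored = TRUE) {
  type <- epistasis_type(type)
  check_ref(ref)
  cohort <- as_cohort_frame(cohort, genes, arity = type$arity)
  if (!keep_censored) cohort <- cohort[cohort$status == 0L, , drop = FALSE]
  gt <- genotype_strings(cohort, genes)
  grp <- assign_groups(gt, type)
  logg <- log_survival(ref, cohort$time_months)
  S <- H <- n <- numeric(4)
  for (k in 1:4) {
    in_k <- which(!is.na(grp) & grp == k - 1L)
    n[k] <- length(in_k)
    S[k] <- sum(cohort$status[in_k] == 0L)
    H[k] <- sum(logg[in_k])
  }
  new_groupstats(S, H, n,
    genotype = type$quadruple, excluded = sum(is.na(grp)),
    type = type$name, genes = genes
  )
}

new_groupstats <- function(S, H, n = NULL, genotype = NULL, excluded = 0L,
                           type = NA_character_, genes = NULL) {
  stopifnot(length(S) == 4L, length(H) == 4L)
  if (any(S < 0) || any(S != round(S))) abort("`S` must be non-negative integer counts.")
  if (any(H > 0)) abort("`H` must be non-positive (sums of log survival probabilities).")
  structure(
    list(
      S = as.numeric(S), H = as.numeric(H),
      n = as.numeric(n %||% S), genotype = genotype %||% as.character(1:4 - 1),
      excluded = excluded, type = type, genes = genes
    ),
    class = "survlrt_groupstats"
  )
}

#' @export
print.survlrt_groupstats <- function(x, ...) {
  cat(sprintf("<survlrt_groupstats> type %s, %d excluded\n", x$type, x$excluded))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.survlrt_groupstats <- function(x, ...) {
  tibble::tibble(
    group = 0:3, genotype = x$genotype,
    n = x$n, deaths = x$S, H = x$H
  )
}

# Reason the closed-form estimators are undefined, or NULL when applicable.
# Eq. Delta_k = -S_k/H_k needs at least one death and a strictly negative H
# in every group.
applicability_reason <- function(stats) {
  bad_S <- which(stats$S == 0)
  bad_H <- which(stats$H >= 0)
  if (length(bad_S) == 0L && length(bad_H) == 0L) return(NULL)
  parts <- character(0)
  if (length(bad_S)) {
    parts <- c(parts, sprintf(
      "no deaths in genotype group(s) %s",
      paste(stats$genotype[bad_S], collapse = ", ")
    ))
  }
  if (length(bad_H)) {
    parts <- c(parts, sprintf(
      "zero log-survival mass (H = 0) in genotype group(s) %s",
      paste(stats$genotype[bad_H], collapse = ", ")
    ))
  }
  paste(parts, collapse = "; ")
}

#' Fitness log-likelihood and maximum likelihood estimators
#'
#' The log-likelihood of the four group fitness parameters is
#' \eqn{\ell(\Delta) = \sum_k [S_k \log\Delta_k + \Delta_k H_k]}. Its
#' unconstrained maximisers are \eqn{\hat\Delta_k = -S_k/H_k}
#' (`fitness_mle()`); `fitness_mle_null()` maximises under the no-epistasis
#' constraint \eqn{\Delta_0\Delta_3 = \Delta_1\Delta_2}, by default through
#' the closed-form quadratic in \eqn{\Delta_1^C} (with admissible-root
#' selection by higher log-likelihood) and falling back to numeric
#' optimisation when no closed-form root is admissible. `method = "numeric"`
#' forces the numeric route (used as an independent oracle in the tests).
#'
#' @param stats A `survlrt_groupstats` object (or anything accepted by
#'   `new_groupstats()` internals).
#' @param delta Four positive fitness values.
#' @return `fitness_loglik()`: a scalar. `fitness_mle()` and
#'   `fitness_mle_null()`: a numeric vector of four fitness values (the
#'   latter satisfying the null constraint to numerical precision).
#' @export
fitness_loglik <- function(stats, delta) {
  if (length(delta) != 4L || any(!is.finite(delta)) || any(delta <= 0)) {
    abort("`delta` must be four positive finite values.")
  }
  sum(stats$S * log(delta) + delta * stats$H)
}

#' @rdname fitness_loglik
#' @export
fitness_mle <- function(stats) {
  reason <- applicability_reason(stats)
  if (!is.null(reason)) {
    abort(paste0("Unconstrained fitness MLE undefined: ", reason),
          class = "survlrt_inapplicable")
  }
  -stats$S / stats$H
}

#' @rdname fitness_loglik
#' @param method `"closed_form"` (quadratic with numeric fallback) or
#'   `"numeric"` (direct constrained optimisation).
#' @export
fitness_mle_null <- function(stats, method = c("closed_form", "numeric")) {
  method <- match.arg(method)
  reason <- applicability_reason(stats)
  if (!is.null(reason)) {
    abort(paste0("Constrained fitness MLE undefined: ", reason),
          class = "survlrt_inapplicable")
  }
  if (method == "numeric") return(null_mle_numeric(stats))
  out <- null_mle_closed(stats)
  out %||% null_mle_numeric(stats)
}

# Closed-form constrained maximiser. Reparametrize S~0 = S0 - S3,
# S~1 = S1 + S3, S~2 = S2 + S3; then Delta1C solves
#   H1(H1H2 - H0H3) x^2 + [H1H2(2 S~1 + S~0) + H0H3(S~2 - S~1)] x
#     + H2 S~1 (S~1 + S~0) = 0,
# with back-substitutions
#   Delta2C = (S~1 - S~2 + H1 x)/H2,
#   Delta0C = -(S~0 + S~1 + H1 x)/H0,  Delta3C = x Delta2C / Delta0C.
# Among real roots giving all four parameters in (0, Inf), the one with the
# higher log-likelihood wins; exact ties go to the root closest to the
# unconstrained log Delta1. Returns NULL when no root is admissible.
null_mle_closed <- function(stats) {
  S <- stats$S; H <- stats$H
  s0 <- S[1] - S[4]; s1 <- S[2] + S[4]; s2 <- S[3] + S[4]
  A <- H[2] * (H[2] * H[3] - H[1] * H[4])
  B <- H[2] * H[3] * (2 * s1 + s0) + H[1] * H[4] * (s2 - s1)
  C <- H[3] * s1 * (s1 + s0)
  roots <- quad_roots(A, B, C)
  if (length(roots) == 0L) return(NULL)
  cands <- list()
  for (x in roots) {
    if (!is.finite(x) || x <= 0) next
    d2 <- (s1 - s2 + H[2] * x) / H[3]
    d0 <- -(s0 + s1 + H[2] * x) / H[1]
    if (!is.finite(d2) || !is.finite(d0) || d2 <= 0 || d0 <= 0) next
    d <- c(d0, x, d2, x * d2 / d0)
    if (all(is.finite(d)) && all(d > 0)) cands[[length(cands) + 1L]] <- d
  }
  if (length(cands) == 0L) return(NULL)
  if (length(cands) == 1L) return(cands[[1L]])
  ll <- vapply(cands, fitness_loglik, numeric(1), stats = stats)
  if (abs(diff(ll)) > 1e-12 * max(1, abs(ll[1]))) return(cands[[which.max(ll)]])
  d1_hat <- -S[2] / H[2]
  cands[[which.min(vapply(cands, function(d) abs(log(d[2]) - log(d1_hat)), numeric(1)))]]
}

# Numerically stable real quadratic roots; degenerates to the linear root
# when the leading coefficient vanishes.
quad_roots <- function(A, B, C) {
  if (abs(A) < 1e-300 * max(abs(B), abs(C), 1)) {
    if (B == 0) return(numeric(0))
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  q <- -(B + sign(B + (B == 0)) * sqrt(disc)) / 2
  unique(c(q / A, if (q != 0) C / q else -B / A))
}

# Constrained optimisation over log(Delta0, Delta1, Delta2) with
# Delta3 = Delta1 Delta2 / Delta0 substituted; analytic gradient.
null_mle_numeric <- function(stats) {
  S <- stats$S; H <- stats$H
  nll <- function(th) {
    d <- exp(c(th, th[2] + th[3] - th[1]))
    -sum(S * log(d) + d * H)
  }
  grad <- function(th) {
    d <- exp(c(th, th[2] + th[3] - th[1]))
    # d l / d th_k for the three free log-parameters, chain rule through d4
    g <- S[1:3] + d[1:3] * H[1:3]
    g4 <- S[4] + d[4] * H[4]
    -(g + c(-1, 1, 1) * g4)
  }
  th0 <- log(pmax(-S[1:3] / H[1:3], 1e-8))
  opt <- optim(th0, nll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  if (opt$convergence != 0) {
    opt2 <- optim(opt$par, nll, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-13))
    if (opt2$value < opt$value) opt <- opt2
  }
  if (!all(is.finite(opt$par))) {
    abort(sprintf(
      "Constrained MLE failed to converge (S = %s, H = %s).",
      paste(S, collapse = ","), paste(signif(H, 4), collapse = ",")
    ))
  }
  exp(c(opt$par, opt$par[2] + opt$par[3] - opt$par[1]))
}

#' Likelihood ratio statistic and p-value
#'
#' `lrt_statistic()` computes
#' \eqn{-2\log\lambda = 2\sum_k [S_k \log(\hat\Delta_k/\Delta_k^C) +
#' H_k(\hat\Delta_k - \Delta_k^C)]}, equal to twice the log-likelihood gap
#' between the unconstrained and null fits; tiny negative values from
#' rounding are clipped to zero. `chisq_p()` converts the statistic to an
#' upper-tail probability of the chi-squared distribution with one degree of
#' freedom (the asymptotic null law of the statistic).
#'
#' @inheritParams fitness_loglik
#' @param mle,null_mle Four positive fitness values (unconstrained and
#'   constrained fits).
#' @return A non-negative scalar; `chisq_p()` a probability.
#' @export
lrt_statistic <- function(stats, mle, null_mle) {
  if (any(mle <= 0) || any(null_mle <= 0)) abort("Fitness parameters must be positive.")
  stat <- 2 * sum(stats$S * log(mle / null_mle) + stats$H * (mle - null_mle))
  if (stat < -1e-6) {
    abort(sprintf("Likelihood ratio statistic is negative (%.3g): constrained fit beats unconstrained.", stat))
  }
  max(stat, 0)
}

#' @rdname lrt_statistic
#' @param stat Non-negative test statistic.
#' @export
chisq_p <- function(stat) {
  if (any(!is.finite(stat)) || any(stat < 0)) abort("`stat` must be non-negative.")
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Test one epistatic interaction from censored survival data
#'
#' Fits the fitness model \eqn{G_g(t) = G(t)^{\Delta_g}} over the four
#' genotype groups of the chosen epistasis type and performs the likelihood
#' ratio test of the no-epistasis null
#' \eqn{\Delta_{g_0}\Delta_{g_3} = \Delta_{g_1}\Delta_{g_2}}. The effect
#' size \eqn{\delta = \log\Delta_{g_0} - \log\Delta_{g_1} -
#' \log\Delta_{g_2} + \log\Delta_{g_3}} is computed from the unconstrained
#' estimates; \eqn{\delta < 0} indicates a negative (synthetic-lethality
#' like) interaction. When a genotype group has no deaths or no
#' log-survival mass the test is returned as inapplicable rather than an
#' error, since screens must be able to skip such configurations.
#'
#' @inheritParams group_stats
#' @return A `survlrt_test` object; see [tidy.survlrt_test()].
#' @examples
#' ref <- synthetic_reference()
#' set.seed(1)
#' coh <- simulate_cohort(n = 800, genes = c("A", "B"), type = "pairwise",
#'                        delta = c(1, exp(0.2), exp(0.3), exp(0.5)),
#'                        mut_freq = c(0.4, 0.4), censor_frac = 0.33, ref = ref)
#' fit <- test_epistasis(coh, c("A", "B"), "pairwise", ref)
#' tidy(fit)
#' @export
test_epistasis <- function(cohort, genes, type = "pairwise", ref,
                           keep_censored = TRUE) {
  type <- epistasis_type(type)
  stats <- group_stats(cohort, genes, type, ref, keep_censored = keep_censored)
  fit_from_stats(stats, genes = genes, type = type, keep_censored = keep_censored)
}

fit_from_stats <- function(stats, genes = stats$genes, type = epistasis_type(stats$type),
                           keep_censored = TRUE) {
  reason <- applicability_reason(stats)
  base <- list(
    genes = genes, type = type$name, family = type$family,
    quadruple = type$quadruple, stats = stats, keep_censored = keep_censored
  )
  if (!is.null(reason)) {
    out <- c(base, list(
      applicable = FALSE, reason = reason,
      delta_hat = rep(NA_real_, 4), delta_null = rep(NA_real_, 4),
      effect = NA_real_, stat = NA_real_, p_value = NA_real_, sign = NA_character_
    ))
    return(structure(out, class = "survlrt_test"))
  }
  mle <- fitness_mle(stats)
  null_mle <- fitness_mle_null(stats)
  stat <- lrt_statistic(stats, mle, null_mle)
  effect <- sum(c(1, -1, -1, 1) * log(mle))
  out <- c(base, list(
    applicable = TRUE, reason = NA_character_,
    delta_hat = mle, delta_null = null_mle,
    effect = effect, stat = stat, p_value = chisq_p(stat),
    sign = if (effect < 0) "negative" else "positive"
  ))
  structure(out, class = "survlrt_test")
}

#' @export
print.survlrt_test <- function(x, ...) {
  cat(sprintf("<survlrt_test> type %s on (%s)\n", x$type, paste(x$genes, collapse = ", ")))
  if (!x$applicable) {
    cat("  inapplicable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "  -2 log lambda = %.4g, p = %.3g, effect delta = %.4g (%s)\n",
    x$stat, x$p_value, x$effect, x$sign
  ))
  cat("  fitness:", paste(sprintf("D_%s = %.3g", x$quadruple, x$delta_hat), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy and glance methods for epistasis test fits
#'
#' `tidy()` returns one row per genotype group with fitness estimates under
#' the alternative and the null; `glance()` returns the one-row test summary
#' (effect size, statistic, p-value, sign, applicability).
#'
#' @param x A `survlrt_test`.
#' @param ... Unused.
#' @export
tidy.survlrt_test <- function(x, ...) {
  tibble::tibble(
    group = 0:3, genotype = x$quadruple,
    n = x$stats$n, deaths = x$stats$S, H = x$stats$H,
    delta_hat = x$delta_hat, delta_null = x$delta_null
  )
}

#' @rdname tidy.survlrt_test
#' @export
glance.survlrt_test <- function(x, ...) {
  tibble::tibble(
    genes = paste(x$genes, collapse = ":"), type = x$type, family = x$family,
    effect = x$effect, stat = x$stat, p_value = x$p_value,
    sign = x$sign, applicable = x$applicable, reason = x$reason,
    n_included = sum(x$stats$n), n_excluded = x$stats$excluded
  )
}

#' Synthetic lethality score of a test
#'
#' Signed evidence score used to rank candidate gene pairs: the test
#' statistic \eqn{-2\log\lambda} when the fitted interaction is negative,
#' its negation when positive, so that larger scores indicate more evidence
#' for synthetic lethality.
#'
#' @param fit A `survlrt_test`.
#' @param inapplicable `"error"` (default) or `"na"`: what to do when the
#'   test was not applicable.
#' @return A signed scalar.
#' @export
sl_score <- function(fit, inapplicable = c("error", "na")) {
  inapplicable <- match.arg(inapplicable)
  if (!inherits(fit, "survlrt_test")) abort("`fit` must be a `survlrt_test`.")
  if (!fit$applicable) {
    if (inapplicable == "na") return(NA_real_)
    abort(paste0("Test inapplicable: ", fit$reason))
  }
  if (fit$sign == "negative") fit$stat else -fit$stat
}

#' Plot group survival curves for a fitted test
#'
#' Kaplan-Meier style display of the fitted Lehmann alternatives
#' \eqn{G(t)^{\hat\Delta_k}} for the four genotype groups, on the reference
#' time grid.
#'
#' @param object A `survlrt_test` (applicable).
#' @param ref The `survlrt_ref` used in the fit.
#' @param ... Unused.
#' @export
autoplot.survlrt_test <- function(object, ref, ...) {
  if (!object$applicable) abort("Cannot plot an inapplicable test.")
  check_ref(ref)
  df <- purrr::map_dfr(1:4, function(k) {
    tibble::tibble(
      genotype = object$quadruple[k],
      months = c(0, ref$times),
      surv = c(1, ref$surv)^object$delta_hat[k]
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$months, y = .data$surv,
                                   colour = .data$genotype)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Time (months)", y = "Fitted survival G(t)^delta",
                  colour = "Genotype") +
    ggplot2::theme_minimal()
}
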