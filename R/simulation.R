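# Truncated exponential censoring times on [0, truncation], by inverse CDF.
rtrunc_exp <- function(n, rate, truncation) {
  if (rate <= 0) abort("Censoring rate must be positive.")
  u <- runif(n)
  -log(1 - u * (1 - exp(-rate * truncation))) / rate
}

ptrunc_exp <- function(t, rate, truncation) {
  (1 - exp(-rate * pmin(t, truncation))) / (1 - exp(-rate * truncation))
}

# P(T = t_j) on the knot grid for survival G^delta; the terminal atom absorbs
# the floor-clamped tail.
knot_pmf <- function(ref, delta) {
  q <- ref$surv^delta
  m <- length(q)
  if (m == 1L) return(1)
  c(1 - q[1], -diff(q[-m]), q[m - 1L])
}

#' Censoring rate for a target mean censored fraction
#'
#' Solves for the rate \eqn{c} of a truncated exponential censoring law
#' \eqn{Y} on \[0, `truncation`\] months such that the probability of
#' censoring, \eqn{P(Y < T)}, equals `censor_frac` when survival times
#' \eqn{T} follow \eqn{G(t)^\Delta} on the reference knot grid (a mixture
#' over several \eqn{\Delta} values is supported via `weights`). The
#' probability is computed by exact quadrature on the grid and inverted with
#' a root finder.
#'
#' @param ref A `survlrt_ref`.
#' @param censor_frac Target mean censored fraction, in (0, 1).
#' @param delta Fitness exponent(s) of the survival-time law.
#' @param weights Mixture weights over `delta` (default equal).
#' @param truncation Censoring upper bound in months, default 480 (40
#'   years).
#' @return The rate `c` (per month).
#' @export
censoring_rate <- function(ref, censor_frac, delta = 1, weights = NULL,
                           truncation = 480) {
  check_ref(ref)
  if (censor_frac <= 0 || censor_frac >= 1) abort("`censor_frac` must be in (0, 1).")
  weights <- weights %||% rep(1 / length(delta), length(delta))
  weights <- weights / sum(weights)
  p_cens <- function(rate) {
    sum(vapply(seq_along(delta), function(i) {
      pmf <- knot_pmf(ref, delta[i])
      weights[i] * sum(pmf * ptrunc_exp(ref$times, rate, truncation))
    }, numeric(1)))
  }
  # As rate -> 0 the law tends to uniform on [0, truncation]; that is the
  # smallest censored fraction a truncated exponential can produce.
  p_min <- sum(vapply(seq_along(delta), function(i) {
    pmf <- knot_pmf(ref, delta[i])
    weights[i] * sum(pmf * pmin(ref$times, truncation) / truncation)
  }, numeric(1)))
  if (censor_frac <= p_min + 1e-6) {
    abort(sprintf(
      "Censored fraction %.3g unreachable: the uniform limit already censors %.3g. Increase `truncation`.",
      censor_frac, p_min
    ))
  }
  f <- function(lr) p_cens(exp(lr)) - censor_frac
  lo <- -14; hi <- 3
  while (f(lo) > 0 && lo > -40) lo <- lo - 5
  if (f(hi) < 0) abort("Censored fraction unreachable at plausible rates.")
  exp(uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Simulate one genotype group of censored survival observations
#'
#' Survival times are drawn from \eqn{G(t)^\Delta} on the reference grid;
#' censoring times from a truncated exponential on \[0, `truncation`\]. The
#' observed time is the minimum of the two, with `status = 1` (censored)
#' when the censoring time came first.
#'
#' @param n Number of patients.
#' @param delta Fitness exponent \eqn{\Delta > 0}.
#' @param ref A `survlrt_ref`.
#' @param censor_frac Target mean censored fraction; 0 disables censoring.
#'   Ignored when `censor_rate` is given.
#' @param censor_rate Optional pre-computed censoring rate.
#' @param truncation Censoring upper bound in months.
#' @return Tibble with columns `time_months` and `status`.
#' @export
simulate_group <- function(n, delta, ref, censor_frac = 0, censor_rate = NULL,
                           truncation = 480) {
  check_ref(ref)
  if (n < 1) abort("`n` must be at least 1.")
  T_ <- sample_survival_time(ref, n, delta)
  if (is.null(censor_rate)) {
    if (censor_frac == 0) {
      return(tibble::tibble(time_months = T_, status = 0L))
    }
    censor_rate <- censoring_rate(ref, censor_frac, delta, truncation = truncation)
  }
  Y <- rtrunc_exp(n, censor_rate, truncation)
  tibble::tibble(
    time_months = pmin(T_, Y),
    status = as.integer(Y < T_)
  )
}

# Per-gene log-fitness effects implied by a quadruple: for each gene, the
# log-fitness step between the first pair of quadruple genotypes that differ
# only in that gene; genes fixed across the quadruple get 0. Used only to
# extend the fitness landscape to genotypes outside the quadruple, which the
# test excludes anyway.
derive_gene_effects <- function(type, delta) {
  bits <- do.call(rbind, lapply(strsplit(type$quadruple, ""), as.integer))
  eff <- numeric(type$arity)
  for (i in seq_len(type$arity)) {
    found <- FALSE
    for (a in 1:3) {
      for (b in (a + 1):4) {
        d <- bits[b, ] - bits[a, ]
        if (d[i] == 1L && sum(abs(d)) == 1L) {
          eff[i] <- log(delta[b]) - log(delta[a])
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  eff
}

#' Simulate a patient cohort under a fitness landscape
#'
#' Genotypes are assigned by independent per-gene carrier sampling: for each
#' gene the number of carriers is binomial with the gene's deletion
#' frequency, and that many patients are chosen at random. Each patient's
#' survival is then drawn from \eqn{G(t)^{\Delta(g)}}, where the landscape
#' \eqn{\Delta(g)} assigns the quadruple of the chosen epistasis type its
#' four fitness values (with \eqn{\log\Delta_{g_3} = \log\Delta_{g_1} +
#' \log\Delta_{g_2} + \delta} when `effect` is used) and extends
#' log-additively to the remaining genotypes. Censoring is a truncated
#' exponential tuned so the mean censored fraction matches `censor_frac`
#' given the realised genotype mixture.
#'
#' @param n Cohort size.
#' @param genes Names for the gene columns (length 2 or 3 to match `type`).
#' @param type Epistasis type label or object.
#' @param delta Four fitness values for the quadruple \eqn{(g_0, g_1, g_2,
#'   g_3)}. Default \eqn{(1, e^{0.2}, e^{0.3}, \cdot)} with the fourth set
#'   by `effect`.
#' @param effect Epistatic effect size \eqn{\delta}; used to fill
#'   `delta[4]` when that is `NA`. Default 0 (the null).
#' @param mut_freq Per-gene deletion frequencies in (0, 1). Default 0.15
#'   per gene.
#' @param censor_frac Target mean censored fraction (0 disables censoring).
#' @param ref A `survlrt_ref`. Default [synthetic_reference()].
#' @param landscape Optional full fitness map: named vector of
#'   \eqn{\Delta} values keyed by genotype string (e.g. `c("000" = 1,
#'   ...)`), overriding `delta`/`effect` for every genotype present.
#' @param truncation Censoring upper bound in months.
#' @return A cohort tibble: gene columns, `status`, `time_months`.
#' @export
simulate_cohort <- function(n, genes, type = "pairwise",
                            delta = c(1, exp(0.2), exp(0.3), NA),
                            effect = 0, mut_freq = NULL, censor_frac = 0.33,
                            ref = synthetic_reference(), landscape = NULL,
                            truncation = 480) {
  type <- epistasis_type(type)
  check_ref(ref)
  if (length(genes) != type$arity) {
    abort(sprintf("Type `%s` needs %d genes, got %d.", type$name, type$arity, length(genes)))
  }
  mut_freq <- mut_freq %||% rep(0.15, type$arity)
  if (length(mut_freq) != type$arity || any(mut_freq <= 0) || any(mut_freq >= 1)) {
    abort("`mut_freq` must give one frequency in (0, 1) per gene.")
  }
  if (is.na(delta[4])) delta[4] <- exp(log(delta[2]) + log(delta[3]) + effect)
  if (any(!is.finite(delta)) || any(delta <= 0)) abort("Fitness values must be positive.")

  geno <- matrix(0L, nrow = n, ncol = type$arity, dimnames = list(NULL, genes))
  for (i in seq_len(type$arity)) {
    k <- rbinom(1, n, mut_freq[i])
    if (k > 0) geno[sample.int(n, k), i] <- 1L
  }
  gt <- apply(geno, 1L, paste0, collapse = "")

  all_gt <- apply(expand.grid(rep(list(0:1), type$arity))[, type$arity:1, drop = FALSE],
                  1L, paste0, collapse = "")
  if (is.null(landscape)) {
    eff <- derive_gene_effects(type, delta)
    landscape <- vapply(all_gt, function(g) {
      k <- match(g, type$quadruple)
      if (!is.na(k)) return(delta[k])
      bits <- as.integer(strsplit(g, "")[[1]])
      exp(sum(bits * eff))
    }, numeric(1))
  } else {
    missing <- setdiff(unique(gt), names(landscape))
    if (length(missing)) {
      abort(sprintf("`landscape` missing genotype(s): %s.", paste(missing, collapse = ", ")))
    }
  }

  counts <- table(factor(gt, levels = names(landscape)))
  present <- counts > 0
  censor_rate <- NULL
  if (censor_frac > 0) {
    censor_rate <- censoring_rate(
      ref, censor_frac,
      delta = landscape[present],
      weights = as.numeric(counts[present]) / n,
      truncation = truncation
    )
  }
  d_pat <- landscape[gt]
  T_ <- numeric(n)
  for (d in unique(d_pat)) {
    idx <- which(d_pat == d)
    T_[idx] <- sample_survival_time(ref, length(idx), d)
  }
  if (is.null(censor_rate)) {
    time <- T_; status <- integer(n)
  } else {
    Y <- rtrunc_exp(n, censor_rate, truncation)
    time <- pmin(T_, Y); status <- as.integer(Y < T_)
  }
  empty <- setdiff(type$quadruple, unique(gt))
  if (length(empty)) {
    warn(sprintf("Quadruple genotype group(s) empty in simulated cohort: %s.",
                 paste(empty, collapse = ", ")))
  }
  dplyr::bind_cols(
    tibble::as_tibble(geno),
    tibble::tibble(status = status, time_months = time)
  )
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates single genotype groups with true fitness
#' \eqn{\Delta = 1}, estimates \eqn{\hat\Delta = -S/H}, and records the log
#' ratio \eqn{\log(\Delta_{true}/\hat\Delta)} per replicate, across sample
#' sizes and censoring levels, with censored cases either kept in the
#' estimator or dropped. Keeping them yields median log ratios near zero;
#' dropping them induces a systematic bias that grows with the censored
#' fraction.
#'
#' @param n_sizes Group sizes to simulate.
#' @param censor_fracs Mean censored fractions.
#' @param keep_censored Logical vector: estimator variants to run.
#' @param reps Replicates per cell.
#' @param ref A `survlrt_ref`.
#' @param delta_true True fitness (default 1).
#' @param truncation Censoring upper bound in months.
#' @return A `survlrt_recovery` tibble: one row per replicate and cell with
#'   `delta_hat` and `log_ratio`; `NA` estimates for degenerate replicates.
#' @seealso [summarise_recovery()], [autoplot.survlrt_recovery()]
#' @export
recovery_experiment <- function(n_sizes = c(3, 10, 30, 100, 300, 1000, 3000, 10000),
                                censor_fracs = c(0.33, 0.66),
                                keep_censored = c(TRUE, FALSE),
                                reps = 200, ref = synthetic_reference(),
                                delta_true = 1, truncation = 480) {
  check_ref(ref)
  cells <- tidyr::expand_grid(n = n_sizes, censor_frac = censor_fracs)
  out <- purrr::pmap_dfr(cells, function(n, censor_frac) {
    rate <- if (censor_frac > 0) {
      censoring_rate(ref, censor_frac, delta_true, truncation = truncation)
    } else NULL
    T_ <- matrix(sample_survival_time(ref, n * reps, delta_true), nrow = n)
    if (is.null(rate)) {
      time <- T_; cens <- matrix(FALSE, n, reps)
    } else {
      Y <- matrix(rtrunc_exp(n * reps, rate, truncation), nrow = n)
      time <- pmin(T_, Y); cens <- Y < T_
    }
    logg <- matrix(log_survival(ref, as.numeric(time)), nrow = n)
    purrr::map_dfr(keep_censored, function(keep) {
      if (keep) {
        S <- colSums(!cens); H <- colSums(logg)
      } else {
        S <- colSums(!cens); H <- colSums(logg * !cens)
      }
      d_hat <- ifelse(S > 0 & H < 0, -S / H, NA_real_)
      tibble::tibble(
        n = n, censor_frac = censor_frac, keep_censored = keep,
        rep = seq_len(reps), delta_hat = d_hat,
        log_ratio = log(delta_true) - log(d_hat)
      )
    })
  })
  class(out) <- c("survlrt_recovery", class(out))
  out
}

#' @rdname recovery_experiment
#' @param x A `survlrt_recovery` tibble.
#' @export
summarise_recovery <- function(x) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$n, .data$censor_frac, .data$keep_censored),
    reps = dplyr::n(),
    n_estimable = sum(!is.na(.data$log_ratio)),
    q25 = quantile(.data$log_ratio, 0.25, na.rm = TRUE),
    median = median(.data$log_ratio, na.rm = TRUE),
    q75 = quantile(.data$log_ratio, 0.75, na.rm = TRUE),
    .groups = "drop"
  )
}

#' @rdname recovery_experiment
#' @param object A `survlrt_recovery` tibble.
#' @param ... Unused.
#' @export
autoplot.survlrt_recovery <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    panel = sprintf("%.0f%% censored, %s", 100 * .data$censor_frac,
                    ifelse(.data$keep_censored, "kept", "removed"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n), y = .data$log_ratio)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::facet_wrap(~panel, nrow = 1) +
    ggplot2::labs(x = "Sample size", y = "log(true / estimated fitness)") +
    ggplot2::theme_minimal()
}

#' Power experiment over epistatic effect sizes
#'
#' Simulates cohorts with quadruple fitness \eqn{(1, e^{0.2}, e^{0.3},
#' e^{0.5+\delta})} across a grid of effect sizes, cohort sizes, and
#' censoring settings, runs the epistasis test on each, and records
#' p-values and rejections at level `alpha`.
#'
#' @inheritParams simulate_cohort
#' @param effects Effect sizes \eqn{\delta} to simulate.
#' @param n_sizes Cohort sizes.
#' @param censor_fracs Mean censored fractions.
#' @param keep_censored Estimator variants (logical vector).
#' @param reps Replicates per cell.
#' @param alpha Rejection level, default 0.05.
#' @return A `survlrt_power` tibble, one row per replicate and cell.
#' @export
power_experiment <- function(effects = c(-2, -1, 0, 1, 2),
                             n_sizes = c(3000, 10000),
                             censor_fracs = c(0.33, 0.66),
                             keep_censored = TRUE, reps = 50, type = "a",
                             mut_freq = NULL, ref = synthetic_reference(),
                             alpha = 0.05, truncation = 480) {
  type <- epistasis_type(type)
  genes <- paste0("g", seq_len(type$arity))
  cells <- tidyr::expand_grid(
    effect = effects, n = n_sizes, censor_frac = censor_fracs,
    keep_censored = keep_censored
  )
  out <- purrr::pmap_dfr(cells, function(effect, n, censor_frac, keep_censored) {
    res <- purrr::map_dfr(seq_len(reps), function(r) {
      coh <- suppressWarnings(simulate_cohort(
        n = n, genes = genes, type = type, effect = effect,
        mut_freq = mut_freq, censor_frac = censor_frac, ref = ref,
        truncation = truncation
      ))
      fit <- test_epistasis(coh, genes, type, ref, keep_censored = keep_censored)
      tibble::tibble(rep = r, applicable = fit$applicable,
                     p_value = fit$p_value, effect_hat = fit$effect)
    })
    dplyr::mutate(res, effect = effect, n = n, censor_frac = censor_frac,
                  keep_censored = keep_censored, reject = .data$p_value <= alpha)
  })
  out <- dplyr::relocate(out, "effect", "n", "censor_frac", "keep_censored")
  class(out) <- c("survlrt_power", class(out))
  out
}

#' @rdname power_experiment
#' @param x A `survlrt_power` tibble.
#' @export
summarise_power <- function(x) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$effect, .data$n,
                    .data$censor_frac, .data$keep_censored),
    reps = dplyr::n(),
    n_applicable = sum(.data$applicable),
    median_p = median(.data$p_value, na.rm = TRUE),
    rejection_rate = mean(.data$reject[.data$applicable], na.rm = TRUE),
    .groups = "drop"
  )
}

#' @rdname power_experiment
#' @param object A `survlrt_power` tibble.
#' @param ... Unused.
#' @export
autoplot.survlrt_power <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    panel = sprintf("%.0f%% censored, %s", 100 * .data$censor_frac,
                    ifelse(.data$keep_censored, "kept", "removed"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$effect), y = .data$p_value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0.05, colour = "grey50") +
    ggplot2::facet_grid(n ~ panel) +
    ggplot2::labs(x = "Epistatic effect size", y = "p-value") +
    ggplot2::theme_minimal()
}

#' Null calibration of the test statistic
#'
#' Simulates cohorts under the no-epistasis null (\eqn{\delta = 0}),
#' collects the likelihood ratio statistic, and compares its empirical
#' quantiles with the chi-squared distribution with one degree of freedom.
#'
#' @inheritParams power_experiment
#' @param reps Number of null replicates.
#' @param n Cohort size per replicate.
#' @param censor_frac Mean censored fraction.
#' @return A `survlrt_calibration` object: the statistics, a QQ tibble, the
#'   through-origin QQ slope over the central 1-99% quantiles, the
#'   empirical type-I error at `alpha`, and a Kolmogorov-Smirnov distance.
#' @export
null_calibration <- function(reps = 500, censor_frac = 0.66, n = 3000,
                             type = "pairwise", mut_freq = c(0.2, 0.2),
                             ref = synthetic_reference(), alpha = 0.05,
                             truncation = 480) {
  type <- epistasis_type(type)
  genes <- paste0("g", seq_len(type$arity))
  stats <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    coh <- suppressWarnings(simulate_cohort(
      n = n, genes = genes, type = type, effect = 0, mut_freq = mut_freq,
      censor_frac = censor_frac, ref = ref, truncation = truncation
    ))
    fit <- test_epistasis(coh, genes, type, ref)
    if (fit$applicable) stats[r] <- fit$stat
  }
  obs <- sort(stats[!is.na(stats)])
  m <- length(obs)
  if (m < 10) abort("Too few applicable null replicates for calibration.")
  theo <- qchisq(ppoints(m), df = 1)
  central <- theo >= qchisq(0.01, 1) & theo <= qchisq(0.99, 1)
  slope <- as.numeric(coef(lm(obs[central] ~ 0 + theo[central])))
  p_emp <- chisq_p(obs)
  ks <- max(abs(ppoints(m) - pchisq(obs, 1)))
  structure(
    list(
      stats = stats,
      qq = tibble::tibble(theoretical = theo, empirical = obs),
      slope = slope,
      type1 = mean(p_emp <= alpha),
      alpha = alpha,
      ks = ks,
      n_applicable = m, reps = reps
    ),
    class = "survlrt_calibration"
  )
}

#' @export
print.survlrt_calibration <- function(x, ...) {
  cat(sprintf(
    "<survlrt_calibration> %d/%d applicable null replicates\n  QQ slope %.3f, type-I error %.3f at alpha = %.2f, KS distance %.3f\n",
    x$n_applicable, x$reps, x$slope, x$type1, x$alpha, x$ks
  ))
  invisible(x)
}

#' @export
tidy.survlrt_calibration <- function(x, ...) x$qq

#' @export
glance.survlrt_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, type1 = x$type1, ks = x$ks,
                 n_applicable = x$n_applicable, reps = x$reps)
}

#' @rdname null_calibration
#' @param object A `survlrt_calibration`.
#' @param ... Unused.
#' @export
autoplot.survlrt_calibration <- function(object, ...) {
  ggplot2::ggplot(object$qq, ggplot2::aes(x = .data$theoretical, y = .data$empirical)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Chi-squared(1) quantiles", y = "Empirical -2 log lambda quantiles") +
    ggplot2::theme_minimal()
}
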