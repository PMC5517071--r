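test_that("group statistics sum log survival over deaths and censored alike", {
  ref <- unit_exp_ref(12)
  coh <- balanced_toy_cohort()
  st <- group_stats(coh, c("A", "B"), "pairwise", ref)
  expect_equal(st$S, rep(1, 4))
  expect_equal(st$H, rep(-3, 4)) # death at log G = -2 plus censored at -1
  expect_equal(st$n, rep(2, 4))
  expect_equal(st$excluded, 0L)

  # dropping censored cases removes their log-survival mass
  st_drop <- group_stats(coh, c("A", "B"), "pairwise", ref, keep_censored = FALSE)
  expect_equal(st_drop$S, rep(1, 4))
  expect_equal(st_drop$H, rep(-2, 4))
})

test_that("patients outside the quadruple are excluded; empty groups give zero sums", {
  ref <- unit_exp_ref(12)
  coh <- tibble::tibble(A = 0L, B = 0L, C = 1L, status = 0L, time_months = 24)
  st <- group_stats(coh, c("A", "B", "C"), "a", ref) # 001 is outside type a
  expect_equal(st$S, rep(0, 4))
  expect_equal(st$H, rep(0, 4))
  expect_equal(st$excluded, 1L)
})

test_that("group statistics match a naive per-patient loop", {
  set.seed(31)
  ref <- synthetic_reference()
  coh <- simulate_cohort(400, c("A", "B", "C"), "a", effect = -0.5,
                         mut_freq = c(0.4, 0.4, 0.3), censor_frac = 0.4, ref = ref)
  type <- epistasis_type("a")
  st <- group_stats(coh, c("A", "B", "C"), type, ref)
  for (k in 1:4) {
    S_k <- 0; H_k <- 0; n_k <- 0
    for (i in seq_len(nrow(coh))) {
      g <- paste0(coh$A[i], coh$B[i], coh$C[i])
      if (g != type$quadruple[k]) next
      n_k <- n_k + 1
      if (coh$status[i] == 0) S_k <- S_k + 1
      H_k <- H_k + log(eval_survival(ref, coh$time_months[i]))
    }
    expect_equal(st$S[k], S_k)
    expect_equal(st$H[k], H_k)
    expect_equal(st$n[k], n_k)
  }
})

test_that("log-likelihood value and gradient are correct", {
  st <- survlrt:::new_groupstats(S = c(1, 1, 1, 1), H = c(-1, -1, -1, -1))
  expect_equal(fitness_loglik(st, rep(1, 4)), -4)
  expect_error(fitness_loglik(st, c(1, 1, 1, 0)), "positive")

  set.seed(32)
  for (r in 1:20) {
    st <- random_groupstats()
    d <- rgamma(4, 2, 1) + 0.1
    eps <- 1e-6
    for (k in 1:4) {
      dp <- dm <- d
      dp[k] <- d[k] + eps; dm[k] <- d[k] - eps
      fd <- (fitness_loglik(st, dp) - fitness_loglik(st, dm)) / (2 * eps)
      expect_equal(fd, st$S[k] / d[k] + st$H[k], tolerance = 1e-4)
    }
  }
})

test_that("unconstrained MLE is -S/H and maximises the likelihood", {
  st <- survlrt:::new_groupstats(S = c(2, 2, 2, 2), H = c(-4, -4, -4, -4))
  expect_equal(fitness_mle(st), rep(0.5, 4))
  # every death at log G = -1 and no censoring makes H = -S, so MLE = 1
  st1 <- survlrt:::new_groupstats(S = c(3, 5, 2, 7), H = -c(3, 5, 2, 7))
  expect_equal(fitness_mle(st1), rep(1, 4))

  set.seed(33)
  for (r in 1:10) {
    st <- random_groupstats()
    mle <- fitness_mle(st)
    for (k in 1:4) {
      opt <- optimize(function(d) st$S[k] * log(d) + d * st$H[k],
                      c(1e-6, 100), maximum = TRUE, tol = 1e-10)
      expect_equal(mle[k], opt$maximum, tolerance = 1e-6)
    }
  }
})

test_that("missing deaths or log-survival mass make the MLE inapplicable", {
  st <- survlrt:::new_groupstats(S = c(0, 1, 1, 1), H = c(-1, -1, -1, -1))
  expect_error(fitness_mle(st), class = "survlrt_inapplicable")
  st2 <- survlrt:::new_groupstats(S = c(1, 1, 1, 1), H = c(-1, 0, -1, -1))
  expect_error(fitness_mle_null(st2), class = "survlrt_inapplicable")
})

test_that("constrained MLE equals the unconstrained one when the null holds", {
  # -S/H = (1, 2, 3, 6) satisfies D0 * D3 = D1 * D2
  st <- survlrt:::new_groupstats(S = c(4, 4, 6, 6), H = -c(4, 2, 2, 1))
  expect_equal(fitness_mle_null(st), fitness_mle(st), tolerance = 1e-9)
  expect_equal(lrt_statistic(st, fitness_mle(st), fitness_mle_null(st)), 0,
               tolerance = 1e-12)
})

test_that("closed-form constrained MLE agrees with the numeric constrained oracle", {
  set.seed(34)
  for (r in 1:200) {
    st <- random_groupstats()
    cf <- fitness_mle_null(st, method = "closed_form")
    num <- fitness_mle_null(st, method = "numeric")
    # constraint holds to near machine precision
    expect_lt(abs(log(cf[1]) + log(cf[4]) - log(cf[2]) - log(cf[3])), 1e-10)
    ll_cf <- fitness_loglik(st, cf)
    ll_num <- fitness_loglik(st, num)
    expect_gte(ll_cf, ll_num - 1e-6 * abs(ll_num))
  }
})

test_that("the statistic is twice the log-likelihood gap and never negative", {
  set.seed(35)
  for (r in 1:50) {
    st <- random_groupstats()
    mle <- fitness_mle(st)
    null_mle <- fitness_mle_null(st)
    stat <- lrt_statistic(st, mle, null_mle)
    expect_gte(stat, 0)
    expect_equal(stat, 2 * (fitness_loglik(st, mle) - fitness_loglik(st, null_mle)),
                 tolerance = 1e-8)
  }
  st <- random_groupstats()
  mle <- fitness_mle(st)
  expect_equal(lrt_statistic(st, mle, mle), 0)
})

test_that("scale equivariance: scaling H rescales the MLEs and fixes the statistic", {
  set.seed(36)
  st <- random_groupstats()
  cc <- 3.7
  st_scaled <- survlrt:::new_groupstats(S = st$S, H = cc * st$H)
  expect_equal(fitness_mle(st_scaled), fitness_mle(st) / cc)
  expect_equal(fitness_mle_null(st_scaled), fitness_mle_null(st) / cc,
               tolerance = 1e-9)
  s1 <- lrt_statistic(st, fitness_mle(st), fitness_mle_null(st))
  s2 <- lrt_statistic(st_scaled, fitness_mle(st_scaled), fitness_mle_null(st_scaled))
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("p-values are the chi-squared(1) upper tail", {
  expect_equal(chisq_p(0), 1)
  expect_equal(chisq_p(qchisq(0.95, 1)), 0.05, tolerance = 1e-10)
  expect_equal(chisq_p(3.8415), 0.05, tolerance = 1e-3)
  expect_equal(chisq_p(6.6349), 0.01, tolerance = 1e-3)
  expect_error(chisq_p(-1), "non-negative")
})

test_that("end-to-end test detects a planted negative interaction with the right sign", {
  set.seed(37)
  ref <- synthetic_reference()
  coh <- simulate_cohort(6000, c("A", "B"), "pairwise", effect = -1,
                         mut_freq = c(0.35, 0.35), censor_frac = 0.33, ref = ref)
  fit <- test_epistasis(coh, c("A", "B"), "pairwise", ref)
  expect_true(fit$applicable)
  expect_equal(fit$sign, "negative")
  expect_lt(fit$p_value, 1e-4)
  expect_lt(fit$effect, 0)
  expect_equal(fit$p_value, chisq_p(fit$stat))
  expect_equal(nrow(tidy(fit)), 4L)
  expect_equal(nrow(glance(fit)), 1L)
})

test_that("a group with no deaths yields an inapplicable result, not an error", {
  ref <- unit_exp_ref(12)
  coh <- balanced_toy_cohort()
  coh$status[coh$A == 1 & coh$B == 1] <- 1L # double deletions all censored
  fit <- test_epistasis(coh, c("A", "B"), "pairwise", ref)
  expect_false(fit$applicable)
  expect_match(fit$reason, "no deaths")
  expect_match(fit$reason, "11")
  expect_true(is.na(fit$p_value))
  expect_error(test_epistasis(coh, c("A", "ZZZ"), "pairwise", ref), "ZZZ")
})

test_that("synthetic lethality score is the signed statistic", {
  fit <- structure(list(applicable = TRUE, sign = "negative", stat = 9),
                   class = "survlrt_test")
  expect_equal(sl_score(fit), 9)
  fit$sign <- "positive"
  expect_equal(sl_score(fit), -9)
  fit$stat <- 0
  expect_equal(sl_score(fit), 0)
  fit_bad <- structure(list(applicable = FALSE, reason = "x"), class = "survlrt_test")
  expect_error(sl_score(fit_bad), "inapplicable")
  expect_true(is.na(sl_score(fit_bad, inapplicable = "na")))
})

test_that("a conditional test equals the pairwise test on the conditioned subcohort", {
  set.seed(38)
  ref <- synthetic_reference()
  coh <- simulate_cohort(3000, c("A", "B"), "pairwise", effect = -1,
                         mut_freq = c(0.35, 0.35), censor_frac = 0.4, ref = ref)
  coh$C <- 0L # third gene never deleted
  fit_a <- test_epistasis(coh, c("A", "B", "C"), "a", ref)
  fit_pw <- test_epistasis(coh[coh$C == 0, ], c("A", "B"), "pairwise", ref)
  expect_equal(fit_a$stat, fit_pw$stat)
  expect_equal(fit_a$p_value, fit_pw$p_value)
  expect_equal(fit_a$effect, fit_pw$effect)
})
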