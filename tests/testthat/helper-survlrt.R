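# Shared fixtures built in code.

# Two-knot step reference: G = 1 on [0,1), 0.5 on [1,2), 0.25 from 2 on.
two_step_ref <- function() ref_survival(c(1, 2), c(0.5, 0.25))

# Exponential reference on a monthly grid: G(t) = exp(-t/mean) exactly at
# integer months, handy for hand-computable H sums.
unit_exp_ref <- function(mean_months = 12) exp_reference(mean_months)

# Random group statistics with all four groups applicable.
random_groupstats <- function() {
  survlrt:::new_groupstats(
    S = rpois(4, 15) + 1L,
    H = -rgamma(4, shape = 5, rate = 0.3)
  )
}

# An 8-patient two-gene cohort with one death at 24 months (log G = -2) and
# one censored at 12 months (log G = -1) in each genotype group, under
# unit_exp_ref(12): S = (1,1,1,1), H = (-3,-3,-3,-3).
balanced_toy_cohort <- function() {
  gt <- c("00", "01", "10", "11")
  tibble::tibble(
    A = rep(as.integer(substr(gt, 1, 1)), each = 2),
    B = rep(as.integer(substr(gt, 2, 2)), each = 2),
    status = rep(c(0L, 1L), times = 4),
    time_months = rep(c(24, 12), times = 4)
  )
}
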