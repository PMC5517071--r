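#' Write a self-contained synthetic fixture set
#'
#' Generates and writes a small synthetic cohort, a reference survival
#' table, and a ground-truth interaction list, so examples, tests, and the
#' command-line interface can run without any external data. The cohort
#' contains a planted negative interaction between genes `A` and `B` that
#' is masked when gene `C` is mutated (so `C` acts as a biomarker), plus
#' two genes `N1`, `N2` with no survival effect. Uses the current RNG
#' state; call `set.seed()` first for reproducibility.
#'
#' @param dir Output directory (created if needed).
#' @param n Cohort size, default 2000.
#' @param effect Planted epistatic effect size for A:B given C unmutated,
#'   default -1.5.
#' @param censor_frac Mean censored fraction, default 0.5.
#' @return Invisibly, a named list of the three file paths (`cohort`,
#'   `reference`, `truth`).
#' @export
write_fixtures <- function(dir, n = 2000, effect = -1.5, censor_frac = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- synthetic_reference()
  landscape <- biomarker_landscape(effect = effect)
  coh <- simulate_cohort(
    n = n, genes = c("A", "B", "C"), type = "a",
    mut_freq = c(0.3, 0.3, 0.25), censor_frac = censor_frac,
    ref = ref, landscape = landscape
  )
  coh$N1 <- rbinom(n, 1, 0.2)
  coh$N2 <- rbinom(n, 1, 0.2)
  coh$last_follow_up_days <- round(coh$time_months * DAYS_PER_MONTH)
  coh <- dplyr::select(coh, "status", "last_follow_up_days",
                       "A", "B", "C", "N1", "N2")
  paths <- list(
    cohort = file.path(dir, "cohort.csv"),
    reference = file.path(dir, "reference.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_csv(coh, paths$cohort)
  # thin the monthly grid for a compact file; step evaluation is unchanged
  keep <- unique(c(seq(1, length(ref$times), by = 12), length(ref$times)))
  readr::write_csv(tibble::tibble(months = ref$times[keep], p = ref$surv[keep]),
                   paths$reference)
  readr::write_csv(tibble::tibble(
    gene1 = c("A", "A", "N1"), gene2 = c("B", "N1", "N2"),
    flag = c(1L, 0L, 0L)
  ), paths$truth)
  invisible(paths)
}

#' Fitness landscape with a conditional (biomarker-masked) interaction
#'
#' Builds the eight-genotype fitness map used in the biomarker simulation:
#' genes carry log-additive effects, an epistatic effect `effect` is added
#' for the double mutant of the first two genes, but only while the third
#' gene is unmutated (`masked = TRUE`); mutation of the third gene restores
#' additivity, the structure a therapeutic biomarker produces.
#'
#' @param gene_effects Per-gene log-fitness effects, default
#'   `c(0.2, 0.3, 0.1)`.
#' @param effect Epistatic effect size added on the `110` pattern, default
#'   -1.5.
#' @param masked If `FALSE`, the interaction persists under mutation of the
#'   third gene as well (no biomarker structure).
#' @return Named vector of fitness values over the eight genotypes.
#' @export
biomarker_landscape <- function(gene_effects = c(0.2, 0.3, 0.1),
                                effect = -1.5, masked = TRUE) {
  stopifnot(length(gene_effects) == 3L)
  gts <- apply(expand.grid(0:1, 0:1, 0:1)[, 3:1], 1L, paste0, collapse = "")
  vapply(setNames(gts, gts), function(g) {
    bits <- as.integer(strsplit(g, "")[[1]])
    ld <- sum(bits * gene_effects)
    if (bits[1] == 1L && bits[2] == 1L && (bits[3] == 0L || !masked)) {
      ld <- ld + effect
    }
    exp(ld)
  }, numeric(1))
}
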