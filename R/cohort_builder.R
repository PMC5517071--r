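# --- internal cohort helpers -------------------------------------------------

# Validate a cohort data frame for testing and make sure `time_months` exists.
# Cohort files record follow-up in days; the reference survival table is in
# months, so days are converted with 12/365.25 months per day.
as_cohort_frame <- function(cohort, genes = NULL, arity = NULL) {
  cohort <- tibble::as_tibble(cohort)
  if (!"status" %in% names(cohort)) abort("Cohort must have a `status` column (1 = censored, 0 = dead).")
  if (!all(cohort$status %in% c(0L, 1L))) abort("`status` must be 0/1 with no missing values.")
  if (!"time_months" %in% names(cohort)) {
    if (!"last_follow_up_days" %in% names(cohort)) {
      abort("Cohort must have a `time_months` or `last_follow_up_days` column.")
    }
    cohort$time_months <- cohort$last_follow_up_days / DAYS_PER_MONTH
  }
  if (anyNA(cohort$time_months) || any(cohort$time_months < 0)) {
    abort("Follow-up times must be non-negative and non-missing.")
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(cohort))
    if (length(missing)) {
      abort(sprintf("Gene column(s) not in cohort: %s.", paste(missing, collapse = ", ")))
    }
    if (!is.null(arity) && length(genes) != arity) {
      abort(sprintf("Expected %d gene(s) for this epistasis type, got %d.", arity, length(genes)))
    }
    for (g in genes) {
      if (!all(cohort[[g]] %in% c(0L, 1L))) {
        abort(sprintf("Gene column `%s` must be 0/1 with no missing values.", g))
      }
    }
  }
  cohort
}

genotype_strings <- function(cohort, genes) {
  bits <- lapply(cohort[genes], function(x) as.integer(x))
  do.call(paste0, bits)
}

# --- file round-tripping -----------------------------------------------------

#' Read and write cohort tables
#'
#' The cohort CSV layout has a `status` column (1 = censored, 0 = dead), a
#' `last_follow_up_days` column, an optional `cancer_type` column, and one
#' 0/1 column per gene. `read_cohort()` adds a derived `time_months` column.
#'
#' @param path File path.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path) {
  coh <- readr::read_csv(path, show_col_types = FALSE, na = "NA")
  as_cohort_frame(coh)
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  out <- dplyr::select(tibble::as_tibble(cohort), -dplyr::any_of("time_months"))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname read_cohort
#' @export
read_truth <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("gene1", "gene2", "flag") %in% names(tab))) {
    abort("Ground-truth CSV must have columns `gene1`, `gene2`, `flag`.")
  }
  tab
}

# --- building genotypes from raw copy-number and expression data -------------

#' Call gene deletions from copy-number values with an expression filter
#'
#' A gene is called deleted in a patient when its copy-number call is -1
#' (shallow) or -2 (deep). Per gene, the calls are kept only if the mRNA
#' level is concordant with loss: a one-sided rank (Wilcoxon) test that
#' expression among deletion carriers is lower, with lower-tail p-value at
#' most `alpha`; genes failing the filter have their whole column zeroed.
#'
#' @param gistic Patient-by-gene integer matrix (or data frame) of
#'   copy-number calls in \{-2, -1, 0, 1, 2\}; `NA` entries propagate to the
#'   output for downstream filtering.
#' @param expr Patient-by-gene numeric expression matrix aligned with
#'   `gistic`. May be `NULL`, in which case the concordance filter is
#'   skipped.
#' @param alpha Significance level of the concordance test, default 0.05.
#' @param compare `"rest"` compares carriers against non-carriers (default);
#'   `"all"` compares carriers against the whole population including the
#'   carriers themselves.
#' @return A patient-by-gene 0/1 matrix (with `NA` where `gistic` was `NA`).
#' @export
call_deletions <- function(gistic, expr = NULL, alpha = 0.05,
                           compare = c("rest", "all")) {
  compare <- match.arg(compare)
  gistic <- as.matrix(gistic)
  if (!is.null(expr)) {
    expr <- as.matrix(expr)
    if (!identical(dim(gistic), dim(expr))) abort("`gistic` and `expr` dimensions differ.")
    if (!is.null(colnames(gistic)) && !is.null(colnames(expr)) &&
        !identical(colnames(gistic), colnames(expr))) {
      abort("`gistic` and `expr` gene columns differ.")
    }
  }
  del <- matrix(as.integer(gistic %in% c(-1L, -2L)), nrow = nrow(gistic),
                dimnames = dimnames(gistic))
  del[is.na(gistic)] <- NA_integer_
  if (is.null(expr)) return(del)
  for (j in seq_len(ncol(del))) {
    carriers <- which(!is.na(del[, j]) & del[, j] == 1L)
    if (length(carriers) == 0L) next
    others <- if (compare == "rest") setdiff(seq_len(nrow(del)), carriers) else seq_len(nrow(del))
    ey <- expr[others, j]
    ex <- expr[carriers, j]
    ok <- length(ex[!is.na(ex)]) > 0L && length(ey[!is.na(ey)]) > 0L
    p <- if (ok) {
      suppressWarnings(wilcox.test(ex, ey, alternative = "less", exact = FALSE)$p.value)
    } else NA_real_
    if (!ok || is.na(p) || p > alpha) {
      keep_na <- is.na(del[, j])
      del[, j] <- 0L
      del[keep_na, j] <- NA_integer_
      if (!ok) {
        inform(sprintf("Gene %s: concordance test not computable; column zeroed.",
                       colnames(del)[j] %||% as.character(j)))
      }
    }
  }
  del
}

#' Filter missing values and finalise a cohort
#'
#' Applies the preprocessing rules for cohort tables: gene columns with at
#' least `gene_na_max` missing values are dropped; then patient rows with at
#' least `patient_na_max` missing genotype values, a missing `status`, or a
#' missing or negative follow-up are dropped; finally the remaining missing
#' genotype values are filled with 0.
#'
#' @param cohort Data frame with `status`, `last_follow_up_days` (or
#'   `time_months`), optional `cancer_type`, and 0/1/NA gene columns.
#' @param gene_na_max Drop a gene column when its NA count reaches this
#'   value. Default 2000.
#' @param patient_na_max Drop a patient row when its NA count reaches this
#'   value. Default 100.
#' @return A complete cohort tibble with a `time_months` column. The
#'   operation is idempotent.
#' @export
filter_missing <- function(cohort, gene_na_max = 2000, patient_na_max = 100) {
  if (gene_na_max < 1 || patient_na_max < 1) abort("NA thresholds must be positive.")
  cohort <- tibble::as_tibble(cohort)
  meta_cols <- intersect(c("status", "last_follow_up_days", "time_months", "cancer_type"),
                         names(cohort))
  gene_cols <- setdiff(names(cohort), meta_cols)
  if (!"status" %in% meta_cols) abort("Cohort must have a `status` column.")
  if (!any(c("last_follow_up_days", "time_months") %in% meta_cols)) {
    abort("Cohort must have a `last_follow_up_days` or `time_months` column.")
  }
  na_per_gene <- vapply(cohort[gene_cols], function(x) sum(is.na(x)), integer(1))
  gene_cols <- gene_cols[na_per_gene < gene_na_max]
  cohort <- cohort[intersect(names(cohort), c(meta_cols, gene_cols))]
  time_col <- if ("last_follow_up_days" %in% meta_cols) "last_follow_up_days" else "time_months"
  na_per_pat <- rowSums(is.na(cohort[gene_cols]))
  keep <- na_per_pat < patient_na_max &
    !is.na(cohort$status) & cohort$status %in% c(0, 1) &
    !is.na(cohort[[time_col]]) & cohort[[time_col]] >= 0
  cohort <- cohort[keep, , drop = FALSE]
  if (nrow(cohort) == 0L) abort("All patients removed by missing-value filtering.")
  cohort <- dplyr::mutate(cohort, dplyr::across(dplyr::all_of(gene_cols),
                                                ~ dplyr::coalesce(.x, 0L)))
  as_cohort_frame(cohort)
}

# --- baseline predictors -----------------------------------------------------

#' Absolute coexpression of a gene pair
#'
#' Absolute Pearson correlation of the two genes' expression across
#' patients; a simple baseline predictor of functional relatedness.
#'
#' @param expr Patient-by-gene expression matrix or data frame.
#' @param gene_a,gene_b Gene column names.
#' @return A value in \[0, 1\]; 0 with a warning when a gene has zero
#'   variance.
#' @export
coexpression_score <- function(expr, gene_a, gene_b) {
  expr <- as.matrix(expr)
  for (g in c(gene_a, gene_b)) {
    if (!g %in% colnames(expr)) abort(sprintf("Gene `%s` not in expression matrix.", g))
  }
  x <- expr[, gene_a]; y <- expr[, gene_b]
  ok <- complete.cases(x, y)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warn("Zero-variance gene; coexpression score set to 0.")
    return(0)
  }
  abs(cor(x[ok], y[ok]))
}

#' Mutual-exclusivity (survival-of-the-fittest style) score
#'
#' An approximate mutual-exclusivity statistic for two genes' deletion
#' patterns: the standardised deficit of observed co-deletions relative to
#' the hypergeometric expectation under independent deletion given the
#' margins. Larger positive values mean co-deletion is rarer than expected
#' (the footprint selection against a lethal double loss would leave); this
#' is a simplified stand-in for published selection-based scores and should
#' be read qualitatively.
#'
#' @param genotype Patient-by-gene 0/1 matrix or cohort data frame.
#' @param gene_a,gene_b Gene column names.
#' @return A z-like score, or `NA` when either gene is monomorphic.
#' @export
sof_score <- function(genotype, gene_a, gene_b) {
  genotype <- tibble::as_tibble(genotype)
  for (g in c(gene_a, gene_b)) {
    if (!g %in% names(genotype)) abort(sprintf("Gene `%s` not in genotype matrix.", g))
  }
  a <- as.integer(genotype[[gene_a]]); b <- as.integer(genotype[[gene_b]])
  n <- length(a); ka <- sum(a); kb <- sum(b)
  if (ka %in% c(0L, n) || kb %in% c(0L, n)) return(NA_real_)
  obs <- sum(a == 1L & b == 1L)
  mu <- ka * kb / n
  v <- ka * kb * (n - ka) * (n - kb) / (n^2 * (n - 1))
  (mu - obs) / sqrt(v)
}
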