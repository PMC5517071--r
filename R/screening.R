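#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values (a thin
#' wrapper over [stats::p.adjust()] with input validation). Output is
#' order-preserving, elementwise at least the input, and capped at 1.
#'
#' @param p Vector of p-values in \[0, 1\] (`NA` allowed, passed through).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Group genes into regions of identical deletion patterns
#'
#' Genes deleted together within one genomic region have identical columns
#' in the patient-by-gene matrix, hence identical genotype groups and
#' identical test p-values. Screens therefore test one representative per
#' region and report the full membership.
#'
#' @param genotype Cohort data frame or 0/1 matrix.
#' @param genes Gene columns to partition (default: all 0/1 columns apart
#'   from the cohort metadata columns).
#' @return Tibble with columns `gene`, `region_id`, `region_rep` (the
#'   representative: first member in input order), `region_size`.
#' @export
group_regions <- function(genotype, genes = NULL) {
  genotype <- tibble::as_tibble(genotype)
  genes <- genes %||% setdiff(
    names(genotype),
    c("status", "last_follow_up_days", "time_months", "cancer_type")
  )
  if (length(genes) == 0L) abort("No gene columns to group.")
  key <- vapply(genotype[genes], function(x) paste0(as.integer(x), collapse = ""),
                character(1))
  region_id <- match(key, unique(key))
  tibble::tibble(gene = genes, region_id = region_id) |>
    dplyr::group_by(.data$region_id) |>
    dplyr::mutate(region_rep = dplyr::first(.data$gene),
                  region_size = dplyr::n()) |>
    dplyr::ungroup()
}

#' Cancer-type bias diagnostic for one test
#'
#' In a pan-cancer cohort a genotype group dominated by a cancer type with
#' atypically long or short survival can pull the test statistic towards
#' significance. Under an even distribution of cancer types across
#' genotypes, the proportion of patients with genotype group \eqn{g} and
#' cancer type \eqn{c} should satisfy \eqn{q_{gc} = w_g v_c}, the product of
#' the marginal shares. This diagnostic cross-tabulates the patients inside
#' the four genotype groups and compares observed with expected
#' proportions; points on the `y = x` line of the companion plot indicate
#' no bias. It is a reported diagnostic, not an automatic filter.
#'
#' @inheritParams group_stats
#' @return A `survlrt_bias` object with the proportion table and a maximum
#'   absolute deviation summary.
#' @export
cancer_bias_check <- function(cohort, genes, type, ref = NULL) {
  type <- epistasis_type(type)
  cohort <- as_cohort_frame(cohort, genes, arity = type$arity)
  if (!"cancer_type" %in% names(cohort)) abort("Cohort has no `cancer_type` column.")
  if (anyNA(cohort$cancer_type)) abort("Missing cancer-type labels.")
  grp <- assign_groups(genotype_strings(cohort, genes), type)
  keep <- !is.na(grp)
  grp <- factor(grp[keep], levels = 0:3)
  ct <- factor(cohort$cancer_type[keep])
  n <- sum(keep)
  if (n == 0L) abort("No patients fall in the four genotype groups.")
  w <- table(grp) / n
  v <- table(ct) / n
  obs <- table(grp, ct) / n
  tab <- tibble::as_tibble(as.data.frame(obs, stringsAsFactors = FALSE)) |>
    dplyr::rename(group = "grp", cancer_type = "ct", observed = "Freq") |>
    dplyr::mutate(
      group = as.integer(as.character(.data$group)),
      genotype = type$quadruple[.data$group + 1L],
      expected = as.numeric(w[as.character(.data$group)]) *
        as.numeric(v[.data$cancer_type])
    ) |>
    dplyr::relocate("group", "genotype", "cancer_type", "expected", "observed")
  structure(
    list(table = tab, max_dev = max(abs(tab$observed - tab$expected)),
         n = n, type = type$name, genes = genes),
    class = "survlrt_bias"
  )
}

#' @export
print.survlrt_bias <- function(x, ...) {
  cat(sprintf(
    "<survlrt_bias> type %s on (%s): max |observed - expected| proportion = %.4f (n = %d)\n",
    x$type, paste(x$genes, collapse = ", "), x$max_dev, x$n
  ))
  invisible(x)
}

#' @export
tidy.survlrt_bias <- function(x, ...) x$table

#' @rdname cancer_bias_check
#' @param object A `survlrt_bias`.
#' @param ... Unused.
#' @export
autoplot.survlrt_bias <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$expected, y = .data$observed,
                               colour = .data$genotype)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Expected proportion w_g * v_c", y = "Observed proportion",
                  colour = "Genotype") +
    ggplot2::theme_minimal()
}

#' Screen candidate genes as biomarkers of a synthetic-lethal pair
#'
#' For an anchor pair (A, B) and each candidate third gene G, tests
#' conditional epistasis of type `a` (interaction of A and B given G not
#' mutated) and type `b` (given G mutated). A candidate is called a
#' biomarker when, after false-discovery-rate adjustment, the type-`a` test
#' is significant and negative while the type-`b` test is not significant:
#' synthetic lethality that holds only while G is intact, the signature of
#' a therapy-success marker. Candidates with identical deletion columns are
#' collapsed to one region representative before testing.
#'
#' @inheritParams group_stats
#' @param anchor_pair Two gene names (the putative synthetic-lethal pair).
#' @param candidates Candidate third genes; absent columns are skipped with
#'   a message.
#' @param alpha Significance level on adjusted p-values, default 0.05.
#' @param bh_family `"separate"` adjusts the type-a and type-b families
#'   independently (default); `"joint"` adjusts their union.
#' @return A tibble, one row per candidate gene, sorted by type-a adjusted
#'   p-value, with region membership and the `biomarker_call` flag.
#' @export
screen_biomarkers <- function(cohort, anchor_pair, candidates, ref,
                              alpha = 0.05, keep_censored = TRUE,
                              bh_family = c("separate", "joint")) {
  bh_family <- match.arg(bh_family)
  if (length(anchor_pair) != 2L) abort("`anchor_pair` must name two genes.")
  cohort <- as_cohort_frame(cohort, anchor_pair)
  absent <- setdiff(candidates, names(cohort))
  if (length(absent)) {
    inform(sprintf("Skipping candidate(s) not in cohort: %s.", paste(absent, collapse = ", ")))
    candidates <- setdiff(candidates, absent)
  }
  candidates <- setdiff(candidates, anchor_pair)
  if (length(candidates) == 0L) abort("No testable candidates.")
  regions <- group_regions(cohort, candidates)
  reps <- unique(regions$region_rep)

  one <- function(g, type) {
    fit <- test_epistasis(cohort, c(anchor_pair, g), type, ref,
                          keep_censored = keep_censored)
    gl <- glance(fit)
    tibble::tibble(candidate = g, p = gl$p_value, effect = gl$effect,
                   stat = gl$stat, sign = gl$sign, applicable = gl$applicable)
  }
  res_a <- purrr::map_dfr(reps, one, type = "a")
  res_b <- purrr::map_dfr(reps, one, type = "b")
  if (bh_family == "separate") {
    res_a$p_adj <- bh_adjust(res_a$p)
    res_b$p_adj <- bh_adjust(res_b$p)
  } else {
    adj <- bh_adjust(c(res_a$p, res_b$p))
    res_a$p_adj <- adj[seq_len(nrow(res_a))]
    res_b$p_adj <- adj[nrow(res_a) + seq_len(nrow(res_b))]
  }
  per_rep <- dplyr::left_join(
    dplyr::rename_with(res_a, ~ paste0(.x, "_a"), -"candidate"),
    dplyr::rename_with(res_b, ~ paste0(.x, "_b"), -"candidate"),
    by = "candidate"
  ) |>
    dplyr::mutate(
      biomarker_call = !is.na(.data$p_adj_a) & .data$applicable_a &
        .data$p_adj_a <= alpha & .data$sign_a == "negative" &
        (!.data$applicable_b | is.na(.data$p_adj_b) | .data$p_adj_b > alpha)
    )
  out <- dplyr::left_join(regions, per_rep,
                          by = c(region_rep = "candidate")) |>
    dplyr::arrange(.data$p_adj_a, .data$region_id, .data$gene)
  out
}

#' Rank gene pairs by synthetic-lethality evidence
#'
#' Runs the pairwise epistasis test for each candidate pair and orders
#' pairs by decreasing [sl_score()] (statistic signed towards negative
#' interactions). Inapplicable pairs are placed last with an `NA` score and
#' the reason recorded.
#'
#' @inheritParams group_stats
#' @param pairs Data frame with columns `gene1`, `gene2`.
#' @return A tibble of per-pair results sorted by score.
#' @export
rank_pairs <- function(cohort, pairs, ref, keep_censored = TRUE) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("gene1", "gene2") %in% names(pairs))) {
    abort("`pairs` must have columns `gene1` and `gene2`.")
  }
  res <- purrr::pmap_dfr(pairs[c("gene1", "gene2")], function(gene1, gene2) {
    if (!all(c(gene1, gene2) %in% names(cohort))) {
      return(tibble::tibble(gene1 = gene1, gene2 = gene2, score = NA_real_,
                            p_value = NA_real_, effect = NA_real_,
                            stat = NA_real_, sign = NA_character_,
                            applicable = FALSE, reason = "gene not in cohort"))
    }
    fit <- test_epistasis(cohort, c(gene1, gene2), "pairwise", ref,
                          keep_censored = keep_censored)
    gl <- glance(fit)
    tibble::tibble(gene1 = gene1, gene2 = gene2,
                   score = sl_score(fit, inapplicable = "na"),
                   p_value = gl$p_value, effect = gl$effect, stat = gl$stat,
                   sign = gl$sign, applicable = gl$applicable,
                   reason = gl$reason)
  })
  dplyr::arrange(res, dplyr::desc(!is.na(.data$score)), dplyr::desc(.data$score))
}

#' Rank-based ROC area under the curve
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative (Mann-Whitney normalisation), with ties counted one
#' half. Missing scores are dropped with their labels.
#'
#' @param scores Numeric prediction scores (higher = more evidence).
#' @param labels Binary truth flags (1 = positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("`scores` and `labels` lengths differ.")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  if (!all(labels %in% c(0L, 1L))) abort("`labels` must be 0/1.")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("Need at least one positive and one negative label.")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
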