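test_that("BH adjustment matches the step-up computation and its invariants", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(61)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm])[order(perm)], adj)
})

test_that("genes with identical deletion columns share a region", {
  set.seed(62)
  m <- tibble::tibble(
    g1 = rbinom(30, 1, 0.5), g2 = rbinom(30, 1, 0.5)
  )
  m$g3 <- m$g1           # co-deleted with g1
  m$g4 <- m$g1
  reg <- group_regions(m)
  expect_equal(nrow(reg), 4L)
  expect_equal(dplyr::n_distinct(reg$region_id), 2L)
  expect_equal(reg$region_id[reg$gene == "g3"], reg$region_id[reg$gene == "g1"])
  expect_equal(reg$region_size[reg$gene == "g1"], 3L)
  expect_equal(reg$region_rep[reg$gene == "g4"], "g1")
  # partition validity: each gene in exactly one region
  expect_equal(anyDuplicated(reg$gene), 0L)

  distinct <- tibble::tibble(a = c(0, 1, 0), b = c(1, 0, 0), c = c(1, 1, 0))
  expect_equal(dplyr::n_distinct(group_regions(distinct)$region_id), 3L)
})

test_that("region co-members give identical test results", {
  set.seed(63)
  ref <- synthetic_reference()
  coh <- simulate_cohort(2000, c("A", "B"), "pairwise", effect = -1,
                         mut_freq = c(0.4, 0.4), censor_frac = 0.4, ref = ref)
  coh$B2 <- coh$B
  f1 <- test_epistasis(coh, c("A", "B"), "pairwise", ref)
  f2 <- test_epistasis(coh, c("A", "B2"), "pairwise", ref)
  expect_equal(f1$p_value, f2$p_value)
  expect_equal(f1$stat, f2$stat)
})

test_that("cancer bias check compares observed with product-of-margins proportions", {
  set.seed(64)
  ref <- synthetic_reference()
  coh <- simulate_cohort(4000, c("A", "B"), "pairwise", effect = 0,
                         mut_freq = c(0.4, 0.4), censor_frac = 0.4, ref = ref)

  # single cancer type: observed equals expected exactly
  coh$cancer_type <- "BRCA"
  bias1 <- cancer_bias_check(coh, c("A", "B"), "pairwise")
  expect_lt(bias1$max_dev, 1e-12)

  # labels independent of genotype: deviation vanishes with n
  coh$cancer_type <- sample(c("x", "y", "z"), nrow(coh), TRUE)
  bias2 <- cancer_bias_check(coh, c("A", "B"), "pairwise")
  expect_lt(bias2$max_dev, 0.03)
  tab <- tidy(bias2)
  expect_equal(sum(tab$observed), 1, tolerance = 1e-12)
  expect_equal(sum(tab$expected), 1, tolerance = 1e-3)

  # constructed confounding: double mutants all from one cancer type
  coh$cancer_type[coh$A == 1 & coh$B == 1] <- "q"
  bias3 <- cancer_bias_check(coh, c("A", "B"), "pairwise")
  expect_gt(bias3$max_dev, 3 * bias2$max_dev)
  expect_s3_class(autoplot(bias3), "ggplot")

  coh$cancer_type <- NULL
  expect_error(cancer_bias_check(coh, c("A", "B"), "pairwise"), "cancer_type")
})

test_that("biomarker screen calls the gene that masks synthetic lethality", {
  set.seed(65)
  ref <- synthetic_reference()
  coh <- simulate_cohort(
    8000, c("A", "B", "C"), "a", censor_frac = 0.5,
    mut_freq = c(0.3, 0.3, 0.25), ref = ref,
    landscape = biomarker_landscape(effect = -2)
  )
  coh$NULL1 <- rbinom(nrow(coh), 1, 0.25) # survival-independent candidate
  scr <- screen_biomarkers(coh, c("A", "B"), c("C", "NULL1"), ref)
  expect_true(scr$biomarker_call[scr$gene == "C"])
  expect_false(scr$biomarker_call[scr$gene == "NULL1"])
  expect_true(all(scr$p_adj_a >= scr$p_a, na.rm = TRUE))
})

test_that("a significant but positive conditional interaction is not called", {
  set.seed(66)
  ref <- synthetic_reference()
  coh <- simulate_cohort(
    8000, c("A", "B", "C"), "a", censor_frac = 0.5,
    mut_freq = c(0.3, 0.3, 0.25), ref = ref,
    landscape = biomarker_landscape(effect = +2) # positive epistasis
  )
  scr <- screen_biomarkers(coh, c("A", "B"), "C", ref)
  expect_equal(scr$sign_a[scr$gene == "C"], "positive")
  expect_false(scr$biomarker_call[scr$gene == "C"])
})

test_that("absent candidates are skipped and joint BH family is supported", {
  set.seed(67)
  ref <- synthetic_reference()
  coh <- simulate_cohort(3000, c("A", "B", "C"), "a", censor_frac = 0.4,
                         mut_freq = c(0.3, 0.3, 0.25), ref = ref)
  expect_message(
    scr <- screen_biomarkers(coh, c("A", "B"), c("C", "GHOST"), ref,
                             bh_family = "joint"),
    "GHOST"
  )
  expect_equal(scr$gene, "C")
})

test_that("pair ranking puts a planted synthetic-lethal pair first", {
  set.seed(68)
  ref <- synthetic_reference()
  coh <- simulate_cohort(6000, c("A", "B"), "pairwise", effect = -1.5,
                         mut_freq = c(0.35, 0.35), censor_frac = 0.4, ref = ref)
  for (g in c("n1", "n2", "n3")) coh[[g]] <- rbinom(nrow(coh), 1, 0.3)
  pairs <- tibble::tibble(gene1 = c("A", "n1", "n2", "A"),
                          gene2 = c("B", "n2", "n3", "missing_gene"))
  rk <- rank_pairs(coh, pairs, ref)
  expect_equal(rk$gene1[1], "A")
  expect_equal(rk$gene2[1], "B")
  expect_gt(rk$score[1], 0)
  # missing gene lands last with a reason, not an error
  expect_false(rk$applicable[4])
  expect_match(rk$reason[4], "not in cohort")
})

test_that("ROC AUC equals exhaustive positive-negative pair counting", {
  expect_equal(roc_auc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  set.seed(69)
  for (r in 1:10) {
    s <- sample(1:6, 8, replace = TRUE) # include ties
    l <- rbinom(8, 1, 0.5)
    if (sum(l) %in% c(0, 8)) next
    pos <- s[l == 1]; neg <- s[l == 0]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(s, l), brute)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "at least one")
})

test_that("ranking on a null cohort carries no signal", {
  set.seed(70)
  ref <- synthetic_reference()
  coh <- simulate_cohort(4000, c("A", "B"), "pairwise", effect = 0,
                         mut_freq = c(0.4, 0.4), censor_frac = 0.4, ref = ref)
  for (g in paste0("g", 1:8)) coh[[g]] <- rbinom(nrow(coh), 1, 0.3)
  pairs <- tibble::tibble(gene1 = paste0("g", 1:4), gene2 = paste0("g", 5:8))
  rk <- rank_pairs(coh, pairs, ref)
  labels <- rbinom(nrow(rk), 1, 0.5)
  if (sum(labels) %in% c(0, nrow(rk))) labels[1:2] <- c(0, 1)
  auc <- roc_auc(rk$score, labels)
  expect_gte(auc, 0)
  expect_lte(auc, 1)
})
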