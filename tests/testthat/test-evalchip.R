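test_that("peak-to-gene assignment honors the 10 kb window exactly", {
  ann <- data.frame(gene_id = c("gA", "gB"),
                    chrom = c("chr1", "chr1"),
                    start = c(50000L, 200000L), end = c(52000L, 202000L),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  # summit 5,000 bp upstream of gA's start (1-based 45000 -> 0-based 44999)
  expect_identical(assign_peak_targets(
    data.frame(chrom = "chr1", summit = 44999L), ann), "gA")
  # summit exactly 10,000 bp away is still inside the window
  expect_identical(assign_peak_targets(
    data.frame(chrom = "chr1", summit = 39999L), ann), "gA")
  # 10,001 bp away: excluded (strict boundary)
  expect_identical(assign_peak_targets(
    data.frame(chrom = "chr1", summit = 39998L), ann), character(0))
  # summit inside the gene body: distance 0
  expect_identical(assign_peak_targets(
    data.frame(chrom = "chr1", summit = 51000L), ann), "gA")
  # downstream edge, strand ignored
  expect_identical(assign_peak_targets(
    data.frame(chrom = "chr1", summit = 211999L), ann), "gB")
  expect_identical(assign_peak_targets(
    data.frame(chrom = "chr2", summit = 51000L), ann), character(0))
  expect_error(assign_peak_targets(
    data.frame(chrom = "chr1", summit = -3L), ann), ">= 0")
})

test_that("peaks and annotations round-trip through BED and GFF3", {
  ann <- toy_annotation(c("g1", "g2", "g3"))
  gff <- tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, gff)
  back <- read_annotation_gff3(gff)
  expect_identical(back[order(back$gene_id), names(ann)], ann)

  peaks <- data.frame(chrom = c("chr1", "chr1"), summit = c(100L, 5000L),
                      score = c(1000, 1000), stringsAsFactors = FALSE)
  bed <- tempfile(fileext = ".bed")
  write_peaks_bed(peaks, bed)
  expect_identical(read_peaks_bed(bed)[, c("chrom", "summit")],
                   peaks[, c("chrom", "summit")])
})

test_that("AUROC and AUPR match exhaustive hand computation on the 6-gene case", {
  genes <- paste0("g", 1:6)
  scores <- c(0.9, 0.8, 0.4, 0.3, 0.2, 0.1)
  labels <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)  # positives at ranks 1,3,5
  grn <- make_edges(rep("tf", 6), genes, scores, tfs = "tf")
  truth <- positive_target_set("tf", genes[labels], genes)
  ev <- evaluate_ranking(grn, truth)
  # pairwise concordance: (3 + 2 + 1) of 9 pairs
  expect_equal(ev$auroc, 6 / 9, tolerance = 1e-12)
  # stepwise PR: precision 1, 2/3, 3/5 at the positive ranks
  expect_equal(ev$aupr, (1 + 2/3 + 3/5) / 3, tolerance = 1e-12)
  expect_equal(ev$auroc, oracle_auroc(scores, labels))
  expect_equal(ev$aupr, oracle_aupr(scores, labels))
})

test_that("separable rankings reach the AUROC extremes", {
  genes <- paste0("g", 1:8)
  grn <- make_edges(rep("tf", 8), genes, 8:1, tfs = "tf")
  top <- positive_target_set("tf", genes[1:3], genes)
  expect_equal(evaluate_ranking(grn, top)$auroc, 1)
  expect_equal(evaluate_ranking(grn, top)$aupr, 1)
  bottom <- positive_target_set("tf", genes[6:8], genes)
  expect_equal(evaluate_ranking(grn, bottom)$auroc, 0)
})

test_that("AUROC equals brute-force pairwise concordance on random tied instances", {
  set.seed(10)
  for (rep in 1:200) {
    n <- sample(5:200, 1)
    scores <- sample(round(runif(n), 2))   # rounding forces ties
    labels <- rep(FALSE, n)
    labels[sample(n, sample(seq_len(n - 1), 1))] <- TRUE
    if (!any(labels) || all(labels)) next
    expect_equal(tissueGRN:::.auroc(scores, labels),
                 oracle_auroc(scores, labels), tolerance = 1e-12)
    expect_equal(tissueGRN:::.aupr(scores, labels),
                 oracle_aupr(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation and is rank-invariant", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- runif(100)
  labels <- runif(100) < 0.3
  a <- tissueGRN:::.auroc(scores, labels)
  b <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                      direction = "<")))
  expect_equal(a, b, tolerance = 1e-12)
  # strictly monotone transformation leaves AUROC unchanged
  expect_equal(tissueGRN:::.auroc(exp(3 * scores), labels), a, tolerance = 1e-12)
})

test_that("permutation baselines sit at their analytic expectations", {
  genes <- sprintf("g%03d", 1:100)
  set.seed(4)
  grn <- make_edges(rep("tf", 100), genes, sort(rexp(100), decreasing = TRUE),
                    tfs = "tf")
  truth <- positive_target_set("tf", genes[sample(100, 20)], genes)
  pb <- permutation_baseline(grn, truth, n_perm = 2000, seed = 9)
  # AUROC: exact mean 0.5; MC sd of the mean ~ 0.0016 here, use 3x slack
  expect_equal(unname(pb["random_auroc_mean"]), 0.5, tolerance = 0.005)
  # AUPR approaches the positive prevalence (exact mean sits slightly above
  # prevalence at finite n; the enumeration test below pins it exactly)
  expect_lt(abs(unname(pb["random_aupr_mean"]) - 0.2), 0.05)
  # deterministic given the seed
  expect_identical(permutation_baseline(grn, truth, n_perm = 1, seed = 3),
                   permutation_baseline(grn, truth, n_perm = 1, seed = 3))
})

test_that("permutation-mean AUPR matches exhaustive subset enumeration", {
  genes <- paste0("g", 1:8)
  grn <- make_edges(rep("tf", 8), genes, 8:1, tfs = "tf")
  truth <- positive_target_set("tf", genes[c(2, 5, 7)], genes)
  exact <- oracle_mean_ap_random(8, 3)   # all C(8,3) subsets
  expect_equal(oracle_mean_ap_exact(8, 3), exact, tolerance = 1e-12)
  pb <- permutation_baseline(grn, truth, n_perm = 20000, seed = 1)
  expect_equal(unname(pb["random_aupr_mean"]), exact, tolerance = 0.01)
})

test_that("Fisher enrichment is exact against hypergeometric enumeration", {
  u <- sprintf("u%02d", 1:20)
  res <- fisher_overlap(u[1:10], u[1:10], u)
  expect_equal(res$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_identical(res$odds_ratio, Inf)
  expect_identical(unname(res$table[1, 1]), 10L)

  # zero overlap where overlap is expected: depletion, enrichment tail ~ 1
  res0 <- fisher_overlap(u[1:10], u[11:20], u)
  expect_gte(res0$p_value, 0.99)

  # random instances vs brute-force tail sums and fisher.test
  set.seed(21)
  for (rep in 1:50) {
    nu <- sample(10:50, 1)
    uni <- sprintf("x%02d", seq_len(nu))
    pred <- sample(uni, sample(nu, 1))
    chip <- sample(uni, sample(nu, 1))
    res <- fisher_overlap(pred, chip, uni)
    a <- length(intersect(pred, chip))
    expect_equal(res$p_value,
                 oracle_fisher_p(a, length(pred), length(chip), nu),
                 tolerance = 1e-9)
    ft <- fisher.test(res$table, alternative = "greater")
    expect_equal(res$p_value, ft$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher p-values are calibrated under independence", {
  set.seed(31)
  uni <- sprintf("g%03d", 1:200)
  p <- replicate(1000, {
    pred <- sample(uni, 40)
    chip <- sample(uni, 30)
    fisher_overlap(pred, chip, uni)$p_value
  })
  expect_lte(mean(p < 0.05), 0.07)   # conservative discrete test
})

test_that("predicted target sets are nested across network sizes", {
  set.seed(41)
  genes <- sprintf("g%03d", 1:50)
  grn <- make_edges(rep(c("tfA", "tfB"), each = 50), rep(genes, 2),
                    runif(100), tfs = c("tfA", "tfB"))
  prev <- character()
  for (k in c(5, 20, 60, 100)) {
    cur <- predicted_targets(grn, "tfA", k)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_identical(predicted_targets(grn, "tfZ", 100), character(0))
  expect_setequal(predicted_targets(grn, "tfA", nrow(grn)),
                  unique(grn$target[grn$regulator == "tfA"]))
})

test_that("size sweeps report overlap percentages and flag empty predictions", {
  genes <- sprintf("g%03d", 1:30)
  grn <- make_edges(rep("tfA", 30), genes, 30:1, tfs = "tfA")
  all_pos <- positive_target_set("tfA", genes, genes)
  sw <- size_sweep(grn, all_pos, sizes = c(5, 10, 30))
  expect_equal(sw$overlap_pct, c(100, 100, 100))
  expect_true(all(sw$defined))

  none <- positive_target_set("tfB", genes[1], genes)
  sw2 <- size_sweep(grn, none, tf = "tfB", sizes = c(5, 10))
  expect_true(all(is.na(sw2$overlap_pct)))
  expect_false(any(sw2$defined))
})
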