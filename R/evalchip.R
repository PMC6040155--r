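# Mann-Whitney AUROC with tied scores counted 1/2
.auroc <- function(scores, labels) {
  P <- sum(labels); N <- sum(!labels)
  stopifnot(P >= 1, N >= 1)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - P * (P + 1) / 2) / (P * N)
}

# step-wise precision-recall integration (average precision); tied scores are
# ordered deterministically by id so the step order is platform-stable
.aupr <- function(scores, labels, ids = seq_along(scores)) {
  P <- sum(labels)
  stopifnot(P >= 1)
  ord <- order(-scores, ids)
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab]) / P
}

.eval_report <- function(auroc, aupr, n_pos, n_uni,
                         random_auroc = NA_real_, random_aupr = NA_real_,
                         n_perm = 0L) {
  structure(list(auroc = auroc, aupr = aupr,
                 random_auroc_mean = random_auroc,
                 random_aupr_mean = random_aupr,
                 n_permutations = as.integer(n_perm),
                 n_positives = as.integer(n_pos),
                 n_universe = as.integer(n_uni)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUROC %.4f  AUPR %.4f  (%d positives / %d universe)\n",
              x$auroc, x$aupr, x$n_positives, x$n_universe))
  if (x$n_permutations > 0)
    cat(sprintf("random baseline (%d permutations): AUROC %.4f  AUPR %.4f\n",
                x$n_permutations, x$random_auroc_mean, x$random_aupr_mean))
  invisible(x)
}

# per-universe-gene scores for one TF: weight of the tf -> gene edge, 0 when
# no such edge exists (the tied zero block keeps every gene rankable)
.tf_scores <- function(grn, tf, universe) {
  sub <- grn[grn$regulator == tf, , drop = FALSE]
  s <- stats::setNames(numeric(length(universe)), universe)
  hit <- sub$target %in% universe
  s[sub$target[hit]] <- sub$weight[hit]
  s
}

#' Assign peak summits to nearby genes
#'
#' A gene is included iff the distance from some summit to the nearest point
#' of the gene span is at most `window` bp (0 when the summit lies inside the
#' span). Strand is ignored; summits are 0-based (BED convention), the
#' annotation 1-based inclusive.
#'
#' @param peaks data.frame with `chrom` and `summit` (0-based position).
#' @param annotation data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param window maximum summit-to-span distance in bp (default 10 kb).
#' @return Sorted character vector of assigned gene ids.
#' @export
assign_peak_targets <- function(peaks, annotation, window = 10000L) {
  stopifnot(all(c("chrom", "summit") %in% names(peaks)),
            all(c("gene_id", "chrom", "start", "end") %in% names(annotation)))
  if (nrow(peaks) && any(peaks$summit < 0)) stop("summit positions must be >= 0")
  if (any(annotation$start > annotation$end)) stop("malformed gene spans")
  hits <- character()
  for (ch in unique(peaks$chrom)) {
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    if (!nrow(ann)) next
    pos1 <- peaks$summit[peaks$chrom == ch] + 1L  # 0-based summit -> 1-based
    for (p in pos1) {
      d <- pmax(0L, ann$start - p, p - ann$end)
      hits <- c(hits, ann$gene_id[d <= window])
    }
  }
  sort(unique(hits))
}

#' Predicted targets of a TF in a size-limited network
#'
#' @param grn a [ranked_edges] network.
#' @param tf TF id.
#' @param k network size cutoff (edges); the prediction set is the TF's
#'   targets among the top-k edges. A TF absent from the top-k network yields
#'   an empty set.
#' @return Sorted character vector of target gene ids.
#' @export
predicted_targets <- function(grn, tf, k = nrow(grn)) {
  te <- suppressWarnings(top_edges(grn, k))
  sort(unique(te$target[te$regulator == tf]))
}

#' Evaluate a ranked network against a positive target set
#'
#' Every gene of the evaluation universe is scored by the weight of the
#' `tf -> gene` edge (0 if absent), and the ranking is summarized by AUROC
#' (Mann-Whitney concordance probability, ties counted 1/2) and AUPR
#' (step-wise precision-recall integration).
#'
#' @param grn a [ranked_edges] network.
#' @param truth a [positive_target_set()].
#' @param tf TF id (defaults to `truth$tf`).
#' @return An `eval_report` with `auroc`, `aupr`, `n_positives`, `n_universe`.
#' @export
evaluate_ranking <- function(grn, truth, tf = truth$tf) {
  stopifnot(inherits(truth, "positive_target_set"))
  uni <- truth$universe
  labels <- uni %in% truth$positives
  if (sum(labels) < 1 || sum(!labels) < 1)
    stop("need at least one positive and one negative gene in the universe")
  s <- .tf_scores(grn, tf, uni)
  .eval_report(.auroc(s, labels), .aupr(s, labels, uni),
               sum(labels), length(uni))
}

#' Permutation baseline for a scored instance
#'
#' The gene labels of the fixed score vector are permuted `n_perm` times and
#' AUROC/AUPR recomputed each time; the means estimate the random-network
#' baseline (AUROC 0.5; AUPR equal to the positive prevalence). A uniform
#' label permutation makes the positive positions a uniform random subset of
#' the fixed ranking, which is how the permutations are drawn.
#'
#' @inheritParams evaluate_ranking
#' @param n_perm number of permutations (default 10000).
#' @param seed random seed.
#' @return Named numeric vector `c(random_auroc_mean, random_aupr_mean)`.
#' @export
permutation_baseline <- function(grn, truth, tf = truth$tf, n_perm = 10000L,
                                 seed = 1L) {
  stopifnot(inherits(truth, "positive_target_set"))
  uni <- truth$universe
  P <- length(truth$positives); n <- length(uni); N <- n - P
  if (P < 1 || N < 1) stop("need at least one positive and one negative gene")
  s <- .tf_scores(grn, tf, uni)
  r <- rank(s, ties.method = "average")
  # position of each gene in the fixed descending ranking (ties by gene id)
  pos_in_order <- order(order(-s, uni))
  set.seed(seed)
  aurocs <- numeric(n_perm); auprs <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, P)
    aurocs[b] <- (sum(r[idx]) - P * (P + 1) / 2) / (P * N)
    auprs[b] <- mean(seq_len(P) / sort(pos_in_order[idx]))
  }
  c(random_auroc_mean = mean(aurocs), random_aupr_mean = mean(auprs))
}

#' Evaluate a full ranking against a ground-truth network
#'
#' Scores every candidate `TF -> gene` pair of the ground-truth gene space by
#' its weight in the inferred ranking (0 if absent) and labels it by
#' membership in the true edge set; reports AUROC/AUPR and, optionally, the
#' permutation baseline over the same pair universe.
#'
#' @param grn a [ranked_edges] network.
#' @param net a `true_network` (from [simulate_network()]).
#' @param n_perm permutations for the baseline (0 to skip).
#' @param seed random seed for the baseline.
#' @return An `eval_report`.
#' @export
evaluate_network <- function(grn, net, n_perm = 0L, seed = 1L) {
  stopifnot(inherits(net, "true_network"))
  pairs <- expand.grid(regulator = net$tf_ids, target = net$gene_ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, , drop = FALSE]
  key <- function(r, t) paste(r, t, sep = "\r")
  pk <- key(pairs$regulator, pairs$target)
  s <- stats::setNames(numeric(length(pk)), pk)
  gk <- key(grn$regulator, grn$target)
  hit <- gk %in% pk
  s[gk[hit]] <- grn$weight[hit]
  labels <- pk %in% key(net$edges$regulator, net$edges$target)
  out <- .eval_report(.auroc(s, labels), .aupr(s, labels, pk),
                      sum(labels), length(pk))
  if (n_perm > 0) {
    P <- sum(labels); n <- length(pk); N <- n - P
    r <- rank(s, ties.method = "average")
    pos_in_order <- order(order(-s, pk))
    set.seed(seed)
    aurocs <- numeric(n_perm); auprs <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n, P)
      aurocs[b] <- (sum(r[idx]) - P * (P + 1) / 2) / (P * N)
      auprs[b] <- mean(seq_len(P) / sort(pos_in_order[idx]))
    }
    out$random_auroc_mean <- mean(aurocs)
    out$random_aupr_mean <- mean(auprs)
    out$n_permutations <- as.integer(n_perm)
  }
  out
}

#' One-tail Fisher enrichment of predicted vs ChIP-confirmed targets
#'
#' Builds the 2x2 contingency table of membership in the predicted set versus
#' the ChIP set over the universe, and computes the exact one-tail
#' (enrichment) p-value from the hypergeometric tail together with the sample
#' odds ratio of the table (infinite when an off-diagonal margin cell is 0).
#'
#' @param predicted,chip character vectors, subsets of `universe`.
#' @param universe character vector of evaluable genes.
#' @return List with `table` (2x2 matrix), `odds_ratio` and `p_value`.
#' @export
fisher_overlap <- function(predicted, chip, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  predicted <- unique(predicted); chip <- unique(chip)
  if (!all(predicted %in% universe) || !all(chip %in% universe))
    stop("predicted and chip sets must be subsets of the universe")
  a <- length(intersect(predicted, chip))
  b <- length(predicted) - a
  c <- length(chip) - a
  d <- length(universe) - a - b - c
  tab <- matrix(c(a, c, b, d), 2, 2,
                dimnames = list(predicted = c("yes", "no"),
                                chip = c("yes", "no")))
  p <- stats::phyper(a - 1, length(chip), length(universe) - length(chip),
                     length(predicted), lower.tail = FALSE)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(table = tab, odds_ratio = or, p_value = p)
}

#' Prediction-overlap percentage across network sizes
#'
#' For each network size, the percentage of the TF's predicted targets that
#' are confirmed by the positive set. Sizes at which the TF has no
#' predictions report `NA` (flagged in the `defined` column): with one or two
#' predictions a percentage is still reported but is as fragile as any
#' small-n proportion.
#'
#' @param grn a [ranked_edges] network.
#' @param truth a [positive_target_set()].
#' @param tf TF id (defaults to `truth$tf`).
#' @param sizes network-size cutoffs (edges).
#' @return data.frame with `size`, `n_predicted`, `n_confirmed`,
#'   `overlap_pct`, `defined`.
#' @export
size_sweep <- function(grn, truth, tf = truth$tf,
                       sizes = c(1e5, 1e6, 1e7)) {
  stopifnot(inherits(truth, "positive_target_set"))
  rows <- lapply(sizes, function(k) {
    pred <- predicted_targets(grn, tf, k)
    npred <- length(pred)
    nconf <- length(intersect(pred, truth$positives))
    data.frame(size = k, n_predicted = npred, n_confirmed = nconf,
               overlap_pct = if (npred) 100 * nconf / npred else NA_real_,
               defined = npred > 0)
  })
  do.call(rbind, rows)
}
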