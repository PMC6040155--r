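# Independent oracles used across the suite. Each re-derives its quantity by
# brute force or by a hand-executed recipe, on a code path separate from the
# package implementation.

# --- brute-force ranking metrics ------------------------------------------

# AUROC as the fraction of (positive, negative) pairs ranked concordantly,
# ties counted 1/2 -- exhaustive double loop
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + if (p > q) 1 else if (p == q) 0.5 else 0
  conc / (length(pos) * length(neg))
}

# step-wise PR integration walked explicitly down the ranking
oracle_aupr <- function(scores, labels, ids = seq_along(scores)) {
  ord <- order(-scores, ids)
  tp <- 0; fp <- 0; ap <- 0
  for (i in ord) {
    if (labels[i]) { tp <- tp + 1; ap <- ap + tp / (tp + fp) } else fp <- fp + 1
  }
  ap / sum(labels)
}

# exact mean average precision of a uniformly random positive subset,
# by exhaustive enumeration of all C(n, P) subsets
oracle_mean_ap_random <- function(n, P) {
  subsets <- utils::combn(n, P)
  mean(apply(subsets, 2, function(idx) mean(seq_len(P) / sort(idx))))
}

# the same expectation in closed form: the j-th positive's rank follows a
# negative hypergeometric law, so E[AP] = (1/P) sum_j j * E[1/X_(j)]
oracle_mean_ap_exact <- function(n, P) {
  total <- 0
  for (j in seq_len(P)) {
    x <- j:(n - P + j)
    pr <- exp(lchoose(x - 1, j - 1) + lchoose(n - x, P - j) - lchoose(n, P))
    total <- total + sum(j / x * pr)
  }
  total / P
}

# --- Fisher / hypergeometric ----------------------------------------------

# one-tail enrichment p by summing hypergeometric point masses computed from
# explicit binomial coefficients
oracle_fisher_p <- function(a, n_pred, n_chip, n_universe) {
  kmax <- min(n_pred, n_chip)
  p <- 0
  for (k in a:kmax)
    p <- p + choose(n_chip, k) * choose(n_universe - n_chip, n_pred - k) /
      choose(n_universe, n_pred)
  p
}

# --- TMM hand recipe -------------------------------------------------------

# step-by-step trim-and-weight computation of TMM scaling factors:
# reference library by upper-quartile CPM closest to the mean upper quartile;
# M/A on genes positive in both; 30% M / 5% A two-sided rank trims;
# precision-weighted mean of remaining M; geometric-mean-1 rescaling
oracle_tmm <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  uq <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  xr <- counts[, ref]; Nr <- lib[ref]
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    x <- counts[, j]; N <- lib[j]
    M <- log2((x / N) / (xr / Nr))
    A <- 0.5 * log2((x / N) * (xr / Nr))
    w <- (N - x) / (N * x) + (Nr - xr) / (Nr * xr)
    ok <- is.finite(M) & is.finite(A) & (A > -1e10)
    M <- M[ok]; A <- A[ok]; w <- w[ok]
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[j] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# --- MCL reference ---------------------------------------------------------

# independent dense-matrix implementation of the published MCL recipe:
# no pruning, clusters read as connected components of the limit matrix's
# non-zero structure (breadth-first search), so both the iteration and the
# read-off differ from the package's code path
oracle_mcl <- function(edges, inflation = 2.5, max_iter = 500) {
  nodes <- sort(unique(c(edges$regulator, edges$target)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    r <- edges$regulator[i]; t <- edges$target[i]; w <- edges$weight[i]
    A[r, t] <- max(A[r, t], w); A[t, r] <- max(A[t, r], w)
  }
  for (i in seq_len(n)) A[i, i] <- max(A[i, ], 1e-300)
  M <- A %*% diag(1 / colSums(A))
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- M2 %*% diag(1 / colSums(M2))
    if (max(abs(M2 - M)) < 1e-10) { M <- M2; break }
    M <- M2
  }
  adj <- (M > 1e-6) | t(M > 1e-6)
  seen <- rep(FALSE, n)
  membership <- integer(n)
  cid <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    cid <- cid + 1
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      membership[v] <- cid
      queue <- c(queue, which(adj[v, ] & !seen))
    }
  }
  stats::setNames(membership, nodes)
}

# two labelings describe the same partition iff co-membership matches
same_partition <- function(a, b) {
  b <- b[names(a)]
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# --- small builders --------------------------------------------------------

make_network <- function(tf_ids, gene_ids, edges) {
  structure(list(tf_ids = tf_ids, gene_ids = gene_ids, edges = edges,
                 degree_exponent = NA_real_),
            class = "true_network")
}

make_edges <- function(regulator, target, weight, tfs = NULL) {
  ranked_edges(data.frame(regulator = regulator, target = target,
                          weight = weight, stringsAsFactors = FALSE),
               tfs = tfs)
}

small_config <- function(seed = 1, ...) {
  args <- list(n_tf = 10L, n_genes = 60L, n_samples_per_tissue = 60L,
               n_tissues = 2L, avg_targets_per_tf = 4, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
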