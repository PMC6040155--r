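#' Pairwise mutual-information matrix
#'
#' Each gene's expression is discretized into at most `bins` equal-frequency
#' bins (quantile breaks; tied quantiles are merged, so heavily tied profiles
#' get fewer effective bins) and the plug-in mutual information estimate (in
#' nats) is computed for every gene pair. The diagonal holds each gene's
#' plug-in entropy, which is the self-information `MI(x, x)`.
#'
#' @param expr gene x library expression matrix.
#' @param bins number of bins `B` (default `ceiling(sqrt(n_samples))`).
#' @return An `mi_matrix`: symmetric gene x gene matrix with attributes
#'   `bins` and `constant_genes` (genes with zero variance; their MI rows are
#'   0 and flagged).
#' @export
mi_matrix <- function(expr, bins = NULL) {
  n <- ncol(expr)
  if (n < 2L) stop("need at least 2 samples")
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  if (bins < 2L) stop("need at least 2 bins")
  G <- nrow(expr)
  genes <- rownames(expr)
  disc <- matrix(1L, G, n)
  nlev <- integer(G)
  for (g in seq_len(G)) {
    br <- unique(stats::quantile(expr[g, ], probs = seq(0, 1, length.out = bins + 1),
                                 names = FALSE, type = 7))
    if (length(br) < 2L) { nlev[g] <- 1L; next }
    disc[g, ] <- cut(expr[g, ], breaks = br, include.lowest = TRUE, labels = FALSE)
    nlev[g] <- max(disc[g, ])
  }
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  }
  H <- vapply(seq_len(G), function(g) ent(tabulate(disc[g, ], nlev[g])), numeric(1))
  mi <- matrix(0, G, G, dimnames = list(genes, genes))
  diag(mi) <- H
  for (i in seq_len(G - 1L)) {
    if (nlev[i] == 1L) next
    di <- disc[i, ]
    for (j in seq.int(i + 1L, G)) {
      if (nlev[j] == 1L) next
      joint <- tabulate(di + (disc[j, ] - 1L) * nlev[i], nlev[i] * nlev[j])
      v <- max(0, H[i] + H[j] - ent(joint))
      mi[i, j] <- mi[j, i] <- v
    }
  }
  structure(mi, bins = bins, constant_genes = genes[nlev == 1L],
            class = c("mi_matrix", "matrix", "array"))
}

# per-row background z-scores of an MI matrix (diagonal excluded from the
# background distribution); degenerate rows (sd 0) give z = 0
.mi_row_z <- function(mi) {
  G <- nrow(mi)
  z <- matrix(0, G, G, dimnames = dimnames(mi))
  for (i in seq_len(G)) {
    bg <- mi[i, -i]
    s <- stats::sd(bg)
    if (is.na(s) || s == 0) next
    z[i, ] <- (mi[i, ] - mean(bg)) / s
  }
  diag(z) <- 0
  z
}

#' CLR comparator network
#'
#' Context likelihood of relatedness: each MI value is z-scored against both
#' genes' MI background distributions, negative z set to 0, and the edge
#' score is `sqrt(z_i^2 + z_j^2)`. Scores are direction-symmetric; both
#' directed edges of a TF pair inherit the same score. Edges are restricted
#' to regulator-to-gene pairs and ranked.
#'
#' @param mi an [mi_matrix()].
#' @param regulators character vector of regulator (TF) ids.
#' @param tissue optional tissue label.
#' @return A [ranked_edges] network.
#' @export
clr_network <- function(mi, regulators, tissue = NULL) {
  genes <- rownames(mi)
  tfs <- sort(intersect(regulators, genes))
  if (!length(tfs)) stop("no regulator among the matrix genes")
  z <- .mi_row_z(mi)
  zp <- pmax(z, 0)
  score <- sqrt(zp^2 + t(zp)^2)
  idx <- expand.grid(regulator = tfs, target = genes, stringsAsFactors = FALSE)
  idx <- idx[idx$regulator != idx$target, , drop = FALSE]
  idx$weight <- score[cbind(idx$regulator, idx$target)]
  ranked_edges(idx, tfs = tfs, tissue = tissue)
}

#' MRNET comparator network
#'
#' Per-target greedy maximum-relevance minimum-redundancy forward selection
#' over the candidate regulators: at each step the regulator maximizing
#' `MI(regulator, target) - mean MI(regulator, already-selected)` is selected
#' and receives that score as its edge weight; selection stops when the best
#' score is not positive. Unselected regulators contribute no edge.
#'
#' @inheritParams clr_network
#' @return A [ranked_edges] network.
#' @export
mrnet_network <- function(mi, regulators, tissue = NULL) {
  genes <- rownames(mi)
  tfs <- sort(intersect(regulators, genes))
  if (!length(tfs)) stop("no regulator among the matrix genes")
  parts <- lapply(genes, function(tg) {
    cand <- setdiff(tfs, tg)
    if (!length(cand)) return(NULL)
    rel <- stats::setNames(mi[cand, tg], cand)
    sel <- character()
    out_r <- character(); out_w <- numeric()
    while (length(cand)) {
      red <- if (length(sel))
        rowMeans(mi[cand, sel, drop = FALSE]) else numeric(length(cand))
      sc <- rel[cand] - red
      best <- which.max(sc)  # ties: first in sorted candidate order
      if (sc[best] <= 0) break
      out_r <- c(out_r, cand[best]); out_w <- c(out_w, sc[best])
      sel <- c(sel, cand[best]); cand <- cand[-best]
    }
    if (!length(out_r)) return(NULL)
    data.frame(regulator = out_r, target = tg, weight = out_w,
               stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) stop("MRNET selected no edges")
  ranked_edges(do.call(rbind, parts), tfs = tfs, tissue = tissue)
}
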