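# one MCL step: expansion (matrix square), inflation (entrywise power),
# pruning of small entries, column renormalization
.mcl_step <- function(M, inflation, prune) {
  M <- M %*% M
  M <- M^inflation
  M[M < prune] <- 0
  cs <- colSums(M)
  dead <- cs == 0
  if (any(dead)) {           # fully pruned column: park the node on itself
    M[cbind(which(dead), which(dead))] <- 1
    cs[dead] <- 1
  }
  sweep(M, 2, cs, "/")
}

#' Markov clustering of a network
#'
#' The directed weighted network is symmetrized (undirected; weight = max of
#' the two directed weights, or 1 if `binary`), a self-loop equal to the
#' node's maximum incident weight is added, and columns are normalized to a
#' stochastic matrix. Expansion (matrix squaring) and inflation (entrywise
#' power `inflation`, column renormalization) alternate, with entries below
#' `prune` removed, until the matrix changes by less than `1e-8` or
#' `max_iter` iterations. Clusters are read off the attractor rows (nodes
#' with positive return probability); a node claimed by several attractor
#' systems is assigned to the largest module (ties to the smaller module id),
#' and unattached nodes become singletons.
#'
#' @param grn a [ranked_edges] network (or any data.frame with `regulator`,
#'   `target`, `weight`).
#' @param inflation inflation parameter (granularity; default 2.5).
#' @param prune entries below this are dropped each iteration.
#' @param max_iter iteration cap; non-convergence returns the last state with
#'   `converged = FALSE` and a warning.
#' @param binary ignore weights and cluster the binarized adjacency.
#' @param nodes optional node ids to include in addition to those with edges;
#'   isolated nodes receive a unit self-loop and end up as singletons.
#' @return A `module_partition`: list with `membership` (named integer, node
#'   -> module id; ids contiguous from 1, ordered by module size descending,
#'   ties by smallest member id), `sizes`, and `params`.
#' @export
mcl_cluster <- function(grn, inflation = 2.5, prune = 1e-5, max_iter = 200L,
                        binary = FALSE, nodes = NULL) {
  stopifnot(nrow(grn) >= 1)
  nodes <- sort(unique(c(grn$regulator, grn$target, nodes)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  w <- if (binary) rep(1, nrow(grn)) else grn$weight
  idx1 <- cbind(match(grn$regulator, nodes), match(grn$target, nodes))
  A[idx1] <- pmax(A[idx1], w)
  A[idx1[, 2:1, drop = FALSE]] <- pmax(A[idx1[, 2:1, drop = FALSE]], w)
  rowmax <- apply(A, 1, max)
  diag(A) <- ifelse(rowmax > 0, rowmax, 1)  # isolated nodes get a unit self-loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- .mcl_step(M, inflation, prune)
    if (max(abs(M2 - M)) < 1e-8) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged)
    warning(sprintf("MCL did not converge within %d iterations; returning last state",
                    max_iter))

  attractors <- which(diag(M) > prune)
  clusters <- unique(lapply(attractors, function(a) which(M[a, ] > prune)))
  # resolve nodes claimed by several clusters: keep them in the largest
  # (ties to the earlier cluster), then drop them from the others
  claimed <- integer(n)
  sizes0 <- lengths(clusters)
  ord0 <- order(-sizes0, vapply(clusters, min, integer(1)))
  for (ci in ord0) {
    mem <- clusters[[ci]]
    clusters[[ci]] <- mem[claimed[mem] == 0L]
    claimed[clusters[[ci]]] <- ci
  }
  unattached <- which(claimed == 0L)
  for (u in unattached) clusters[[length(clusters) + 1L]] <- u
  clusters <- clusters[lengths(clusters) > 0L]
  ord <- order(-lengths(clusters), vapply(clusters, min, integer(1)))
  membership <- stats::setNames(integer(n), nodes)
  for (new_id in seq_along(ord))
    membership[clusters[[ord[new_id]]]] <- new_id
  sizes <- as.integer(table(membership))
  structure(list(membership = membership, sizes = sizes,
                 params = list(inflation = inflation, prune = prune,
                               iterations = it, converged = converged)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("MCL partition: %d nodes in %d modules (inflation %.2f%s)\n",
              length(x$membership), length(x$sizes), x$params$inflation,
              if (x$params$converged) "" else ", NOT converged"))
  cat("module sizes:", utils::head(x$sizes, 10),
      if (length(x$sizes) > 10) "..." else "", "\n")
  invisible(x)
}

#' Filter modules by size
#'
#' Retains modules with strictly more than `min_size` members (the published
#' rule keeps modules with more than 10 genes, i.e. at least 11).
#'
#' @param partition a `module_partition` from [mcl_cluster()].
#' @param min_size strict size cutoff.
#' @return List with `retained` / `dropped` module ids, their counts, and the
#'   full size vector.
#' @export
filter_modules <- function(partition, min_size = 10L) {
  stopifnot(inherits(partition, "module_partition"))
  sizes <- partition$sizes
  ids <- seq_along(sizes)
  keep <- sizes > min_size
  list(retained = ids[keep], dropped = ids[!keep],
       n_retained = sum(keep), n_dropped = sum(!keep), sizes = sizes)
}
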