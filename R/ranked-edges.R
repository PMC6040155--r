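#' Ranked edge list
#'
#' The common representation of an inferred gene regulatory network (GRN): a
#' directed edge list `regulator -> target` with a non-negative importance
#' weight per edge and a total rank order. Edges are sorted by weight
#' (descending); ties are broken lexicographically by `(regulator, target)` so
#' the ranking is identical across runs and platforms.
#'
#' @param edges data.frame with columns `regulator`, `target`, `weight`.
#' @param tfs optional character vector of declared regulator (TF) ids; every
#'   edge regulator must belong to it.
#' @param tissue optional tissue label carried as an attribute.
#'
#' @return A `ranked_edges` object: the sorted data.frame with attributes
#'   `tfs` and `tissue`.
#' @export
ranked_edges <- function(edges, tfs = NULL, tissue = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("regulator", "target", "weight") %in% names(edges)))
  edges <- data.frame(regulator = as.character(edges$regulator),
                      target    = as.character(edges$target),
                      weight    = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  if (anyNA(edges$weight) || any(edges$weight < 0))
    stop("edge weights must be non-negative and non-missing")
  if (any(edges$regulator == edges$target))
    stop("self-edges are not allowed")
  key <- paste(edges$regulator, edges$target, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (regulator, target) pairs")
  if (!is.null(tfs) && !all(edges$regulator %in% tfs))
    stop("every regulator must be in the declared TF set")
  ord <- order(-edges$weight, edges$regulator, edges$target, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges,
            class  = c("ranked_edges", "data.frame"),
            tfs    = if (is.null(tfs)) unique(edges$regulator) else as.character(tfs),
            tissue = tissue)
}

#' Truncate a ranked network to its top-k edges
#'
#' Networks of different total size are made comparable by keeping only the k
#' highest-ranked edges (the published analyses use the top 1 million). The
#' rank order of the input is preserved, so `top_edges(g, a)` is always a
#' prefix of `top_edges(g, b)` for `a <= b`.
#'
#' @param grn a [ranked_edges] object.
#' @param k number of edges to keep (`k >= 0`). If `k` exceeds the number of
#'   available edges, all edges are returned with a warning.
#' @return A `ranked_edges` object with at most `k` edges.
#' @export
top_edges <- function(grn, k) {
  stopifnot(inherits(grn, "ranked_edges"))
  .stopifnot_scalar_number(k, "k", min = 0)
  n <- nrow(grn)
  if (k > n) {
    warning(sprintf("requested top %d edges but only %d available; returning all",
                    as.integer(k), n))
    k <- n
  }
  out <- as.data.frame(grn)[seq_len(k), , drop = FALSE]
  ranked_edges(out, tfs = attr(grn, "tfs"), tissue = attr(grn, "tissue"))
}

#' @export
print.ranked_edges <- function(x, ...) {
  cat(sprintf("Ranked edge list: %d edges, %d regulators, %d targets%s\n",
              nrow(x), length(unique(x$regulator)), length(unique(x$target)),
              if (!is.null(attr(x, "tissue")))
                paste0(" [", attr(x, "tissue"), "]") else ""))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
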