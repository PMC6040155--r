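.mtry <- function(k_rule, p) {
  if (identical(k_rule, "sqrt")) return(max(1L, as.integer(floor(sqrt(p)))))
  if (identical(k_rule, "all"))  return(as.integer(p))
  if (is.character(k_rule) && grepl("^fixed:", k_rule)) {
    m <- as.integer(sub("^fixed:", "", k_rule))
    if (is.na(m) || m < 1L || m > p)
      stop("fixed feature-subset size must be an integer in [1, #regulators]")
    return(m)
  }
  stop("k_rule must be 'sqrt', 'all' or 'fixed:m'")
}

#' Regulator importances for one target gene
#'
#' The core of the tree-ensemble network inference: the target's expression
#' profile (standardized to unit variance) is regressed on the candidate
#' regulators' profiles with an ensemble of `n_trees` regression trees grown
#' on bootstrap samples, with a random subset of `K` regulators considered at
#' each split (`k_rule`). A regulator's importance is the mean over trees of
#' the total variance reduction attributed to its splits, divided by the
#' sample count. The target, if itself a TF, is excluded from its own
#' candidate regulators. The random stream is derived from
#' `(seed, target id)`, so results do not depend on the order in which
#' targets are processed.
#'
#' @param expr gene x library expression matrix (typically log2(CPM + 1)).
#' @param regulators character vector of candidate regulator (TF) gene ids.
#' @param target target gene id (a row of `expr`).
#' @param n_trees number of trees (default 1000).
#' @param k_rule regulators considered per split: `"sqrt"` (default,
#'   `floor(sqrt(p))`), `"all"`, or `"fixed:m"`.
#' @param seed master seed.
#' @param min_samples minimum number of libraries required.
#' @return Named numeric vector of non-negative importances, one per candidate
#'   regulator. A zero-variance target yields all zeros with attribute
#'   `constant_target = TRUE` (flagged, not an error).
#' @export
target_importances <- function(expr, regulators, target, n_trees = 1000L,
                               k_rule = "sqrt", seed = 1L, min_samples = 10L) {
  if (!target %in% rownames(expr)) stop(sprintf("target '%s' not in matrix", target))
  cand <- sort(setdiff(intersect(regulators, rownames(expr)), target))
  if (!length(cand)) stop("no candidate regulators after excluding the target")
  if (ncol(expr) < min_samples)
    stop(sprintf("need at least %d libraries", min_samples))
  w <- stats::setNames(numeric(length(cand)), cand)
  y <- as.numeric(expr[target, ])
  s <- stats::sd(y)
  if (s == 0) {
    attr(w, "constant_target") <- TRUE
    return(w)
  }
  y <- (y - mean(y)) / s
  X <- t(expr[cand, , drop = FALSE])
  colnames(X) <- paste0("x", seq_len(ncol(X)))  # ids may be non-syntactic
  set.seed(.derive_seed(seed, paste0("target:", target)))
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                   mtry = .mtry(k_rule, length(cand)),
                                   importance = FALSE, keep.forest = FALSE)
  w[cand] <- as.numeric(rf$importance[, "IncNodePurity"]) / length(y)
  w
}

#' Infer a ranked regulatory network
#'
#' Runs [target_importances()] with every expressed gene as target and the
#' declared TF set as candidate regulators, concatenates the resulting
#' directed TF-to-target edges and ranks them globally by importance weight
#' (descending; ties broken lexicographically). Both directions between two
#' TFs are scored independently. All candidate edges are retained, so the
#' full ranking over `|TF| * |genes| - |TF in genes|` pairs is available for
#' downstream thresholding with [top_edges()].
#'
#' @inheritParams target_importances
#' @param tissue optional tissue label attached to the result.
#' @return A [ranked_edges] network.
#' @export
infer_grn <- function(expr, regulators, n_trees = 1000L, k_rule = "sqrt",
                      seed = 1L, min_samples = 10L, tissue = NULL) {
  if (!nrow(expr) || !ncol(expr)) stop("empty expression matrix")
  tfs <- sort(intersect(regulators, rownames(expr)))
  if (!length(tfs)) stop("no regulator is among the expressed genes")
  targets <- rownames(expr)
  parts <- lapply(targets, function(g) {
    w <- target_importances(expr, tfs, g, n_trees = n_trees, k_rule = k_rule,
                            seed = seed, min_samples = min_samples)
    data.frame(regulator = names(w), target = g, weight = as.numeric(w),
               stringsAsFactors = FALSE)
  })
  ranked_edges(do.call(rbind, parts), tfs = tfs, tissue = tissue)
}
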