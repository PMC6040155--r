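#' Per-TF out-degrees at a network-size cutoff
#'
#' Counts each TF's outgoing edges within the top-k network (the published
#' analyses use k = 1 million). TFs with no edge in the top k report 0.
#'
#' @param grn a [ranked_edges] network.
#' @param k_cutoff edge cutoff; `NULL` uses the whole network.
#' @param tfs TF ids to report (default: the network's declared TF set).
#' @return Named integer vector of out-degrees with attribute `cutoff`.
#' @export
out_degrees <- function(grn, k_cutoff = NULL, tfs = attr(grn, "tfs")) {
  te <- if (is.null(k_cutoff)) grn else suppressWarnings(top_edges(grn, k_cutoff))
  deg <- stats::setNames(integer(length(tfs)), sort(tfs))
  tab <- table(te$regulator)
  deg[names(tab)] <- as.integer(tab)
  attr(deg, "cutoff") <- if (is.null(k_cutoff)) nrow(grn) else k_cutoff
  deg
}

#' Degree table across tissues
#'
#' @param networks named list of [ranked_edges] networks (one per tissue).
#' @param k_cutoff per-network edge cutoff.
#' @param tfs TF ids (default: union of the networks' declared TF sets).
#' @return TF x tissue integer matrix of out-degrees.
#' @export
degree_table <- function(networks, k_cutoff = NULL,
                         tfs = sort(unique(unlist(lapply(networks, attr, "tfs"))))) {
  stopifnot(length(networks) >= 1, !is.null(names(networks)))
  cols <- lapply(networks, out_degrees, k_cutoff = k_cutoff, tfs = tfs)
  tab <- do.call(cbind, cols)
  colnames(tab) <- names(networks)
  attr(tab, "cutoff") <- attr(cols[[1]], "cutoff")
  tab
}

#' Cross-tissue variability of TF degree centrality
#'
#' `CV = 100 * sample sd / mean` of a TF's out-degree across tissues. The
#' variable-TF selection first requires a degree range (max - min) of at
#' least `min_range` and then keeps the `top_n` TFs by CV; each selected TF
#' is annotated with the tissue in which its degree is largest. TFs whose
#' mean degree is 0 have no defined CV and are excluded (flagged).
#'
#' @param table TF x tissue degree matrix (from [degree_table()]).
#' @param top_n TFs to keep after ranking by CV.
#' @param min_range minimum max-min degree difference.
#' @return List with `cv` (named vector over TFs with positive mean degree),
#'   `selected` (data.frame `tf`, `cv`, `range`, `max_tissue`), and
#'   `zero_mean_tfs` (excluded TFs).
#' @export
degree_variability <- function(table, top_n = 100L, min_range = 500L) {
  stopifnot(is.matrix(table), ncol(table) >= 2)
  mu <- rowMeans(table)
  zero <- mu == 0
  tab <- table[!zero, , drop = FALSE]
  cv <- apply(tab, 1, stats::sd) / rowMeans(tab) * 100
  rng <- apply(tab, 1, function(r) max(r) - min(r))
  eligible <- names(cv)[rng >= min_range]
  sel <- eligible[order(-cv[eligible], eligible)]
  sel <- sel[seq_len(min(top_n, length(sel)))]
  max_tissue <- colnames(tab)[apply(tab[sel, , drop = FALSE], 1, which.max)]
  list(cv = cv,
       selected = data.frame(tf = sel, cv = unname(cv[sel]),
                             range = unname(rng[sel]), max_tissue = max_tissue,
                             stringsAsFactors = FALSE),
       zero_mean_tfs = rownames(table)[zero])
}

#' Key TFs per tissue
#'
#' Key TFs are those with degree centrality strictly greater than `threshold`
#' in a tissue (the published cutoff is 2000 at the top-1M network size).
#' Also tabulates their cross-tissue sharing with [set_overlaps()].
#'
#' @param table TF x tissue degree matrix.
#' @param threshold strict degree cutoff.
#' @return List with `key_tfs` (per-tissue character vectors) and `sharing`
#'   (exclusive combination counts).
#' @export
key_tfs <- function(table, threshold = 2000L) {
  sets <- lapply(seq_len(ncol(table)), function(j)
    rownames(table)[table[, j] > threshold])
  names(sets) <- colnames(table)
  list(key_tfs = sets, sharing = set_overlaps(sets))
}

#' Directed edge overlap across tissue networks
#'
#' Intersects the top-k directed edge sets of each network over every tissue
#' combination (exclusive counts, UpSet semantics) and returns the edges
#' shared by all tissues together with their distinct regulators and targets.
#'
#' @param networks named list of [ranked_edges] networks (>= 2).
#' @param k_cutoff per-network edge cutoff; `NULL` uses whole networks.
#' @return List with `counts`, `shared_edges` (data.frame), `n_shared`,
#'   `shared_regulators`, `shared_targets`.
#' @export
edge_overlap <- function(networks, k_cutoff = NULL) {
  stopifnot(length(networks) >= 2, !is.null(names(networks)))
  keysets <- lapply(networks, function(g) {
    te <- if (is.null(k_cutoff)) g else suppressWarnings(top_edges(g, k_cutoff))
    paste(te$regulator, te$target, sep = "\r")
  })
  counts <- set_overlaps(keysets)
  shared <- Reduce(intersect, keysets)
  parts <- strsplit(shared, "\r", fixed = TRUE)
  shared_edges <- data.frame(
    regulator = vapply(parts, `[`, character(1), 1),
    target = vapply(parts, `[`, character(1), 2),
    stringsAsFactors = FALSE)
  shared_edges <- shared_edges[order(shared_edges$regulator, shared_edges$target), ,
                               drop = FALSE]
  rownames(shared_edges) <- NULL
  list(counts = counts, shared_edges = shared_edges, n_shared = length(shared),
       shared_regulators = sort(unique(shared_edges$regulator)),
       shared_targets = sort(unique(shared_edges$target)))
}

#' Regress TF degree centrality on TF expression
#'
#' Ordinary least squares of out-degree on an expression summary (mean CPM or
#' mean log2(CPM + 1)) over TFs, reporting slope, intercept, R-squared and the
#' slope p-value. Used to ask whether hub TFs are simply the highly expressed
#' ones.
#'
#' @param degrees named numeric vector of TF out-degrees.
#' @param expression named numeric vector of TF expression summaries.
#' @return A `linear_fit` list: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
degree_vs_expression <- function(degrees, expression) {
  common <- intersect(names(degrees), names(expression))
  if (length(common) < 3) stop("need at least 3 TFs with defined values")
  x <- expression[common]; y <- degrees[common]
  if (stats::sd(x) == 0) stop("zero-variance predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(common)),
            class = "linear_fit")
}

#' Power-law fit of the out-degree distribution
#'
#' The empirical frequency of each positive out-degree is regressed on the
#' degree in log-log space by least squares; the slope is the fitted
#' power-law exponent and the fit's R-squared measures how scale-free the
#' degree distribution is. Zero-degree nodes are excluded (their log is
#' undefined).
#'
#' @param degrees numeric vector of out-degrees.
#' @return A `powerlaw_fit` list: `exponent` (the slope; negative for a
#'   decaying distribution), `intercept`, `r_squared`, `n_points`.
#' @export
powerlaw_fit <- function(degrees) {
  pos <- degrees[degrees > 0]
  tab <- table(pos)
  if (length(tab) < 3) stop("need at least 3 distinct positive degrees")
  k <- as.numeric(names(tab)); f <- as.numeric(tab)
  fit <- stats::lm(log(f) ~ log(k))
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_points = length(k)),
            class = "powerlaw_fit")
}

#' Average neighborhood connectivity fit
#'
#' Treats the network as undirected, computes each node's degree and the mean
#' degree of its neighbors, averages that quantity over nodes of equal
#' degree, and fits the resulting curve against degree in log-log space by
#' least squares (the same power-law form as [powerlaw_fit()]).
#'
#' @param grn a [ranked_edges] network.
#' @param k_cutoff edge cutoff; `NULL` uses the whole network.
#' @return A `powerlaw_fit` list.
#' @export
neighborhood_connectivity_fit <- function(grn, k_cutoff = NULL) {
  te <- if (is.null(k_cutoff)) grn else suppressWarnings(top_edges(grn, k_cutoff))
  a <- c(te$regulator, te$target); b <- c(te$target, te$regulator)
  deg <- table(a)
  nbr_mean <- tapply(as.numeric(deg[b]), a, mean)
  node_deg <- as.numeric(deg[names(nbr_mean)])
  anc <- tapply(as.numeric(nbr_mean), node_deg, mean)
  if (length(anc) < 3) stop("need at least 3 distinct degrees")
  k <- as.numeric(names(anc)); v <- as.numeric(anc)
  if (any(v <= 0)) stop("non-positive connectivity values")
  fit <- stats::lm(log(v) ~ log(k))
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_points = length(k)),
            class = "powerlaw_fit")
}
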