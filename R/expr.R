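#' TMM scaling factors
#'
#' Between-library normalization factors by the trimmed mean of M-values
#' (TMM): the reference library is the one whose upper-quartile CPM is closest
#' to the mean upper quartile; per-gene log-ratio (M) and average-abundance
#' (A) statistics are computed on genes positive in both libraries, 30% of M
#' extremes and 5% of A extremes are trimmed, and the factor is the
#' precision-weighted mean of the remaining M values; factors are rescaled to
#' geometric mean 1. Computed via [edgeR::calcNormFactors()].
#'
#' @param counts gene x library matrix of non-negative integer counts.
#' @return Named numeric vector of positive scaling factors (one per library).
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0))
    stop("libraries with all-zero counts cannot be normalized")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Counts per million (CPM) and log2(CPM + 1)
#'
#' `CPM[g, j] = counts[g, j] / (library_size[j] * factor[j]) * 1e6`. With unit
#' factors every column sums to exactly 1e6; with TMM factors the column sum
#' is `1e6 / factor`. With `log_transform = TRUE` values are `log2(CPM + 1)`.
#'
#' @param counts gene x library count matrix.
#' @param factors optional named per-library scaling factors (default: all 1).
#' @param log_transform return `log2(CPM + 1)` instead of CPM.
#' @return Numeric matrix with attribute `scale` (`"CPM"` or `"log2CPM1"`).
#' @export
to_cpm <- function(counts, factors = NULL, log_transform = FALSE) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (is.null(factors)) factors <- stats::setNames(rep(1, ncol(counts)), colnames(counts))
  if (!all(colnames(counts) %in% names(factors)))
    stop("factors must cover every library")
  f <- factors[colnames(counts)]
  cpm <- sweep(counts, 2, lib * f, "/") * 1e6
  out <- if (log_transform) log2(cpm + 1) else cpm
  attr(out, "scale") <- if (log_transform) "log2CPM1" else "CPM"
  out
}

#' Call genes expressed in a tissue
#'
#' Under the default (`rule = "results"`) a gene is expressed in a tissue iff
#' its CPM exceeds `cpm_threshold` (strictly) in strictly more than
#' `fraction_threshold` of that tissue's libraries. The alternative
#' `rule = "methods"` excludes genes with CPM below the threshold in more than
#' that fraction of libraries (i.e. keeps a gene iff at most the fraction of
#' its libraries are below threshold); the two rules differ and the
#' "results" rule is the default.
#'
#' @param cpm CPM-scale matrix from [to_cpm()].
#' @param tissue_of named character vector mapping library id to tissue label.
#' @param tissue tissue to call.
#' @param cpm_threshold CPM cutoff (default 1).
#' @param fraction_threshold library-fraction cutoff (default 0.10).
#' @param rule `"results"` (default) or `"methods"`, see Details.
#' @return Sorted character vector of expressed gene ids.
#' @export
filter_expressed <- function(cpm, tissue_of, tissue, cpm_threshold = 1,
                             fraction_threshold = 0.10,
                             rule = c("results", "methods")) {
  rule <- match.arg(rule)
  libs <- names(tissue_of)[tissue_of == tissue]
  if (!length(libs)) stop(sprintf("unknown tissue label '%s'", tissue))
  if (!all(libs %in% colnames(cpm))) stop("tissue libraries missing from matrix")
  m <- cpm[, libs, drop = FALSE]
  keep <- if (rule == "results") {
    rowMeans(m > cpm_threshold) > fraction_threshold
  } else {
    rowMeans(m < cpm_threshold) <= fraction_threshold
  }
  sort(rownames(cpm)[keep])
}

#' Expressed-gene sets for every tissue
#'
#' @inheritParams filter_expressed
#' @return Named list of expressed-gene sets (one per tissue), with the
#'   thresholds recorded as attributes.
#' @export
expressed_sets <- function(cpm, tissue_of, cpm_threshold = 1,
                           fraction_threshold = 0.10,
                           rule = c("results", "methods")) {
  rule <- match.arg(rule)
  tissues <- unique(tissue_of)
  sets <- lapply(tissues, function(t)
    filter_expressed(cpm, tissue_of, t, cpm_threshold, fraction_threshold, rule))
  names(sets) <- tissues
  attr(sets, "cpm_threshold") <- cpm_threshold
  attr(sets, "fraction_threshold") <- fraction_threshold
  sets
}

#' Exclusive overlap counts over set combinations
#'
#' For every non-empty combination of the input sets, the number of elements
#' belonging to exactly that combination (UpSet-plot semantics). Counts over
#' all combinations sum to the size of the union.
#'
#' @param sets named list of character vectors.
#' @return Named integer vector; names are `&`-joined set names.
#' @export
set_overlaps <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  nm <- names(sets)
  elements <- sort(unique(unlist(sets, use.names = FALSE)))
  memb <- vapply(sets, function(s) elements %in% s, logical(length(elements)))
  if (length(elements) == 1L) memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, nm))
  combos <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(combos)), combos)
  if (length(elements)) {
    key <- apply(memb, 1, function(r) paste(nm[r], collapse = "&"))
    tab <- table(key)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Cluster tissue expression profiles
#'
#' Per-gene tissue-mean expression is z-transformed across tissues (mean 0,
#' sd 1 per gene) and clustered by agglomerative hierarchical clustering
#' (complete linkage, Euclidean distance), cut into `k_groups` groups.
#' Genes whose tissue means have zero variance cannot be z-scaled; each is
#' placed in its own additional group, numbered after `k_groups` in gene-id
#' order.
#'
#' @param expr expression matrix (typically log2(CPM + 1) scale).
#' @param tissue_of named library-to-tissue map.
#' @param genes genes to cluster (default: all rows).
#' @param k_groups number of groups to cut into.
#' @return Named integer vector: gene -> group id.
#' @export
cluster_tissue_profiles <- function(expr, tissue_of, genes = rownames(expr),
                                    k_groups = 15L) {
  genes <- sort(intersect(genes, rownames(expr)))
  if (length(genes) < k_groups)
    stop("need at least k_groups genes")
  tissues <- unique(tissue_of)
  tm <- vapply(tissues, function(t) {
    libs <- names(tissue_of)[tissue_of == t]
    rowMeans(expr[genes, libs, drop = FALSE])
  }, numeric(length(genes)))
  rownames(tm) <- genes
  sds <- apply(tm, 1, stats::sd)
  nz <- sds > 1e-12
  groups <- stats::setNames(integer(length(genes)), genes)
  if (sum(nz) >= 1L) {
    z <- (tm[nz, , drop = FALSE] - rowMeans(tm[nz, , drop = FALSE])) / sds[nz]
    k <- min(k_groups, sum(nz))
    hc <- stats::hclust(stats::dist(z), method = "complete")
    groups[nz] <- stats::cutree(hc, k = k)
  }
  if (any(!nz))
    groups[!nz] <- k_groups + seq_len(sum(!nz))
  storage.mode(groups) <- "integer"
  groups
}
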