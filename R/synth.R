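#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator: a ground-truth
#' multi-tissue regulatory network, steady-state expression with negative
#' binomial count sampling, and ChIP-like evaluation sets.
#'
#' The defaults define the standard benchmark used throughout the test suite:
#' 50 TFs among 500 genes, 4 tissues with a quarter of the regulatory edges
#' shared by all tissues, 200 RNA-Seq libraries per tissue, and TF out-degrees
#' drawn from a truncated discrete power law so the network has the heavy-tailed
#' hub structure real GRNs are expected to show.
#'
#' @param n_tf number of transcription factors (regulators).
#' @param n_genes total number of genes (TFs are the first `n_tf` of them).
#' @param n_samples_per_tissue RNA-Seq libraries simulated per tissue.
#' @param n_tissues number of tissues.
#' @param shared_edge_fraction fraction of base-network edges present in every
#'   tissue; the remainder is partitioned tissue-privately.
#' @param avg_targets_per_tf mean TF out-degree; `0` gives an empty network.
#' @param degree_exponent exponent of the truncated discrete power law the
#'   out-degrees are drawn from.
#' @param noise_sd standard deviation of the Gaussian noise added to each
#'   regulated gene's latent abundance.
#' @param link_function `"linear"` or `"sigmoid"` (logistic, centred at 0 with
#'   unit scale) applied to the weighted sum of regulator abundances.
#' @param dispersion negative binomial dispersion of the count sampling
#'   (`size = 1/dispersion`).
#' @param library_size_range min/max sequencing depth per library; depths are
#'   drawn uniformly in this range.
#' @param seed master seed; all per-tissue and per-stage random streams are
#'   derived from it by fixed offsets so each stage is independently
#'   reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tf = 50L, n_genes = 500L, n_samples_per_tissue = 200L,
                       n_tissues = 4L, shared_edge_fraction = 0.25,
                       avg_targets_per_tf = 10, degree_exponent = 1.5,
                       noise_sd = 0.25, link_function = c("linear", "sigmoid"),
                       dispersion = 0.05, library_size_range = c(2e5, 1e6),
                       seed = 1L) {
  link_function <- match.arg(link_function)
  for (nm in c("n_tf", "n_genes", "n_samples_per_tissue", "n_tissues"))
    .stopifnot_scalar_number(get(nm), nm, min = 1)
  .stopifnot_scalar_number(shared_edge_fraction, "shared_edge_fraction", 0, 1)
  .stopifnot_scalar_number(avg_targets_per_tf, "avg_targets_per_tf", min = 0)
  .stopifnot_scalar_number(degree_exponent, "degree_exponent", min = 0)
  .stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  .stopifnot_scalar_number(dispersion, "dispersion", min = 1e-12)
  stopifnot(length(library_size_range) == 2L, all(library_size_range > 0),
            library_size_range[1] <= library_size_range[2])
  if (n_tf >= n_genes) stop("n_tf must be smaller than n_genes")
  if (avg_targets_per_tf * n_tf > n_tf * (n_genes - 1))
    stop("requested edge count exceeds n_tf * (n_genes - 1)")
  structure(list(n_tf = as.integer(n_tf), n_genes = as.integer(n_genes),
                 n_samples_per_tissue = as.integer(n_samples_per_tissue),
                 n_tissues = as.integer(n_tissues),
                 shared_edge_fraction = shared_edge_fraction,
                 avg_targets_per_tf = avg_targets_per_tf,
                 degree_exponent = degree_exponent,
                 noise_sd = noise_sd, link_function = link_function,
                 dispersion = dispersion,
                 library_size_range = library_size_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Truncated discrete power-law out-degree distribution P(k) ~ k^-a on 1..K.
# K is solved so the distribution's exact mean is as close as possible to the
# requested mean; truncation never exceeds n_genes - 1 (a TF cannot regulate
# more genes than exist besides itself).
.degree_support <- function(avg, exponent, kmax_cap) {
  means <- cumsum((1:kmax_cap)^(1 - exponent)) / cumsum((1:kmax_cap)^(-exponent))
  if (avg < 1 || avg > means[kmax_cap])
    stop(sprintf("avg_targets_per_tf = %g unreachable with exponent %g and %d genes",
                 avg, exponent, kmax_cap + 1L))
  K <- which.min(abs(means - avg))
  p <- (1:K)^(-exponent)
  list(k = 1:K, p = p / sum(p), mean = means[K])
}

#' Simulate a ground-truth regulatory network
#'
#' Draws a directed TF-to-target network whose TF out-degrees follow a
#' truncated discrete power law (heavy-tailed, so hub TFs exist and the
#' topology module has signal). Edge effects are signed uniform weights.
#'
#' @param config a [sim_config].
#' @return A `true_network`: list with `tf_ids`, `gene_ids` and an `edges`
#'   data.frame (`regulator`, `target`, `effect`), plus the degree-exponent
#'   actually used. Deterministic given `config$seed`.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tf_ids   <- sprintf("TF%04d", seq_len(config$n_tf))
  gene_ids <- c(tf_ids, sprintf("G%05d", seq.int(config$n_tf + 1L, config$n_genes)))
  set.seed(.derive_seed(config$seed, "network"))
  if (config$avg_targets_per_tf == 0) {
    edges <- data.frame(regulator = character(), target = character(),
                        effect = numeric(), stringsAsFactors = FALSE)
  } else {
    sup <- .degree_support(config$avg_targets_per_tf, config$degree_exponent,
                           config$n_genes - 1L)
    deg <- sample(sup$k, config$n_tf, replace = TRUE, prob = sup$p)
    edges <- do.call(rbind, lapply(seq_len(config$n_tf), function(i) {
      tgt <- sample(setdiff(gene_ids, tf_ids[i]), deg[i])
      data.frame(regulator = tf_ids[i], target = tgt, stringsAsFactors = FALSE)
    }))
    edges$effect <- sample(c(-1, 1), nrow(edges), replace = TRUE) *
      stats::runif(nrow(edges), 0.3, 1.0)
    rownames(edges) <- NULL
  }
  structure(list(tf_ids = tf_ids, gene_ids = gene_ids, edges = edges,
                 degree_exponent = config$degree_exponent),
            class = "true_network")
}

#' @export
print.true_network <- function(x, ...) {
  cat(sprintf("True network: %d TFs, %d genes, %d edges\n",
              length(x$tf_ids), length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

#' Derive per-tissue networks from a base network
#'
#' A fraction `shared_edge_fraction` of the base edges (rounded) is present in
#' every tissue network; the remaining edges are partitioned round-robin over
#' tissues after a seeded shuffle, so each is private to exactly one tissue.
#' This emulates the observation that most regulatory edges are
#' tissue-specific while a core is shared by all tissues.
#'
#' @param base a `true_network` from [simulate_network()].
#' @param config the [sim_config] used to build it.
#' @return Named list of `n_tissues` `true_network` objects
#'   (`tissue1`, `tissue2`, ...). Deterministic given `config$seed`.
#' @export
derive_tissue_networks <- function(base, config) {
  stopifnot(inherits(base, "true_network"), inherits(config, "sim_config"))
  E <- nrow(base$edges)
  set.seed(.derive_seed(config$seed, "tissues"))
  perm <- if (E) sample.int(E) else integer()
  n_shared <- round(config$shared_edge_fraction * E)
  shared  <- perm[seq_len(n_shared)]
  private <- perm[setdiff(seq_len(E), seq_len(n_shared))]
  owner   <- rep_len(seq_len(config$n_tissues), length(private))
  nets <- lapply(seq_len(config$n_tissues), function(t) {
    idx <- sort(c(shared, private[owner == t]))
    net <- base
    net$edges <- base$edges[idx, , drop = FALSE]
    rownames(net$edges) <- NULL
    net
  })
  names(nets) <- paste0("tissue", seq_len(config$n_tissues))
  nets
}

.link_fun <- function(name) {
  switch(name,
         linear  = function(x) x,
         sigmoid = function(x) 1 / (1 + exp(-x)),
         stop("unknown link function"))
}

#' Simulate RNA-Seq counts from a network
#'
#' Latent (log-scale) abundances: regulator-free genes get independent
#' baselines `N(mu_g, 1)`; each regulated gene's latent value is the link
#' function applied to the weighted sum of its regulators' latent values,
#' plus Gaussian noise. Cycles are resolved by damped fixed-point iteration
#' (damping 0.5, at most 100 sweeps); non-convergence is an error. Counts are
#' drawn negative-binomially around per-library expected counts obtained by
#' converting latent values to relative abundances (`softmax` of the latent
#' column) times a uniformly drawn library size.
#'
#' @param net a `true_network`.
#' @param config a [sim_config].
#' @param tissue optional tissue label; it also keys the random stream so each
#'   tissue's expression is independently reproducible.
#' @return A `sim_expression` list: `counts` (gene x library integer matrix),
#'   `latent` (gene x library latent abundances), `library_sizes`, `tissue`.
#' @export
simulate_expression <- function(net, config, tissue = NULL) {
  stopifnot(inherits(net, "true_network"), inherits(config, "sim_config"))
  genes <- net$gene_ids
  G <- length(genes); n <- config$n_samples_per_tissue
  set.seed(.derive_seed(config$seed, paste0("expr:", if (is.null(tissue)) "base" else tissue)))

  regulated <- unique(net$edges$target)
  baseline  <- setdiff(genes, regulated)
  x <- matrix(0, G, n, dimnames = list(genes, NULL))
  mu_g <- stats::rnorm(length(baseline), 0, 1)
  x[baseline, ] <- mu_g + matrix(stats::rnorm(length(baseline) * n), length(baseline), n)
  eps <- matrix(stats::rnorm(length(regulated) * n, 0, config$noise_sd),
                length(regulated), n, dimnames = list(regulated, NULL))

  link <- .link_fun(config$link_function)
  if (length(regulated)) {
    W <- matrix(0, G, G, dimnames = list(genes, genes))  # W[target, regulator]
    W[cbind(net$edges$target, net$edges$regulator)] <- net$edges$effect
    for (iter in seq_len(100L)) {
      y <- link((W %*% x)[regulated, , drop = FALSE]) + eps
      delta <- max(abs(y - x[regulated, , drop = FALSE]))
      x[regulated, ] <- 0.5 * x[regulated, , drop = FALSE] + 0.5 * y
      if (delta < 1e-8) break
    }
    if (delta >= 1e-8)
      stop("steady-state iteration did not converge within 100 sweeps")
    x[regulated, ] <- y
  }

  lib_id <- paste0(if (is.null(tissue)) "s" else tissue, "_lib",
                   sprintf("%03d", seq_len(n)))
  lib_sizes <- round(stats::runif(n, config$library_size_range[1],
                                  config$library_size_range[2]))
  rel <- exp(x)
  rel <- sweep(rel, 2, colSums(rel), "/")
  mu  <- sweep(rel, 2, lib_sizes, "*")
  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / config$dispersion),
                   G, n, dimnames = list(genes, lib_id))
  colnames(x) <- lib_id
  names(lib_sizes) <- lib_id
  structure(list(counts = counts, latent = x, library_sizes = lib_sizes,
                 tissue = tissue),
            class = "sim_expression")
}

#' Simulate a complete multi-tissue dataset
#'
#' Convenience wrapper: base network, per-tissue networks, per-tissue
#' expression, and the combined count matrix with its library-to-tissue map.
#'
#' @param config a [sim_config].
#' @return List with `network`, `tissue_networks`, `expression` (per-tissue
#'   `sim_expression`), `counts` (gene x all-libraries matrix) and
#'   `tissue_of` (named character vector, library -> tissue).
#' @export
simulate_dataset <- function(config) {
  net  <- simulate_network(config)
  nets <- derive_tissue_networks(net, config)
  expr <- lapply(names(nets), function(t) simulate_expression(nets[[t]], config, tissue = t))
  names(expr) <- names(nets)
  counts <- do.call(cbind, lapply(expr, `[[`, "counts"))
  tissue_of <- stats::setNames(
    unlist(lapply(expr, function(e) rep(e$tissue, ncol(e$counts))),
           use.names = FALSE),
    colnames(counts))
  list(network = net, tissue_networks = nets, expression = expr,
       counts = counts, tissue_of = tissue_of)
}

#' Positive target set
#'
#' The evaluation gold standard: genes designated as ChIP-confirmed targets of
#' one TF, within a stated gene universe.
#'
#' @param tf TF gene identifier.
#' @param positives character vector of positive target genes.
#' @param universe character vector of all evaluable genes.
#' @return A `positive_target_set` list.
#' @export
positive_target_set <- function(tf, positives, universe) {
  positives <- sort(unique(as.character(positives)))
  universe  <- sort(unique(as.character(universe)))
  if (!all(positives %in% universe))
    stop("positives must be a subset of the universe")
  structure(list(tf = as.character(tf), positives = positives,
                 universe = universe),
            class = "positive_target_set")
}

#' Toy gene annotation
#'
#' Lays the simulated genes out on chromosomes with a fixed span and spacing.
#' The default spacing (25 kb between gene starts, 2 kb gene bodies) keeps any
#' point within 10 kb of one gene span more than 10 kb away from every other
#' gene, so peak-to-gene assignment round-trips exactly.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param gene_length span of each gene in bp.
#' @param spacing distance between successive gene starts in bp.
#' @param genes_per_chrom genes placed per chromosome.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (1-based,
#'   inclusive), `strand`.
#' @export
toy_annotation <- function(gene_ids, gene_length = 2000L, spacing = 25000L,
                           genes_per_chrom = 100L) {
  i <- seq_along(gene_ids)
  pos <- (i - 1L) %% genes_per_chrom
  start <- 20001L + pos * as.integer(spacing)
  data.frame(gene_id = as.character(gene_ids),
             chrom  = paste0("chr", (i - 1L) %/% genes_per_chrom + 1L),
             start  = start,
             end    = start + as.integer(gene_length) - 1L,
             strand = rep_len(c("+", "-"), length(i)),
             stringsAsFactors = FALSE)
}

#' Simulate a ChIP-derived positive set with controllable error
#'
#' Builds the positive target set of one TF from the ground-truth network,
#' dropping a fraction `fnr` of true targets (false negatives) and adding a
#' fraction `fpr` of non-targets (false positives), and emits one peak per
#' positive gene with its summit placed uniformly within `window` bp of the
#' gene span, so the peak-to-gene assignment rule is testable end to end.
#'
#' @param net a `true_network`.
#' @param tf TF identifier (must be in `net$tf_ids`).
#' @param fnr,fpr false-negative / false-positive rates in `[0, 1)` (exactly 1
#'   is allowed for `fnr` and empties the set).
#' @param annotation gene annotation data.frame as from [toy_annotation()].
#' @param window placement window around the gene span, bp.
#' @param seed random seed.
#' @return List with `positives` (a [positive_target_set] over `net$gene_ids`)
#'   and `peaks` (data.frame `chrom`, `summit` 0-based, `score`).
#' @export
simulate_chip_truth <- function(net, tf, fnr = 0, fpr = 0, annotation,
                                window = 10000L, seed = 1L) {
  stopifnot(inherits(net, "true_network"))
  if (!tf %in% net$tf_ids) stop(sprintf("TF '%s' not in network", tf))
  .stopifnot_scalar_number(fnr, "fnr", 0, 1)
  .stopifnot_scalar_number(fpr, "fpr", 0, 1)
  true_t <- sort(unique(net$edges$target[net$edges$regulator == tf]))
  set.seed(seed)
  n_drop <- round(fnr * length(true_t))
  kept <- if (n_drop > 0) setdiff(true_t, sample(true_t, n_drop)) else true_t
  non_t <- setdiff(net$gene_ids, c(true_t, tf))
  n_fp <- round(fpr * length(non_t))
  fps <- if (n_fp > 0) sample(non_t, n_fp) else character()
  positives <- sort(c(kept, fps))

  ann <- annotation[match(positives, annotation$gene_id), , drop = FALSE]
  if (anyNA(ann$gene_id) && length(positives))
    stop("annotation must cover every positive gene")
  if (length(positives)) {
    lo <- pmax(1L, ann$start - as.integer(window))
    hi <- ann$end + as.integer(window)
    summit1 <- lo + floor(stats::runif(length(positives)) * (hi - lo + 1L))
    peaks <- data.frame(chrom = ann$chrom, summit = as.integer(summit1 - 1L),
                        score = rep(1000, length(positives)),
                        stringsAsFactors = FALSE)
  } else {
    peaks <- data.frame(chrom = character(), summit = integer(),
                        score = numeric(), stringsAsFactors = FALSE)
  }
  list(positives = positive_target_set(tf, positives, net$gene_ids),
       peaks = peaks)
}
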