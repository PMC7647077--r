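## stage 3: region splits, differential markers, RE/REC and association tests

#' Split samples into high and low regions of a component score
#'
#' Either the `N` highest versus `N` lowest scores (`"top_bottom_N"`) or a
#' median split (samples strictly above the median are "high"). Boundary
#' ties are broken by ascending sample ID, so splits are reproducible.
#'
#' @param scores named numeric vector of per-sample component scores
#'   (names are sample IDs).
#' @param mode `"top_bottom_N"` or `"median"`.
#' @param N region size when `mode = "top_bottom_N"` (N <= n/2).
#' @return object of class `"region_split"`: list with `high_ids`,
#'   `low_ids`, `mode`, `N`.
#' @export
split_samples <- function(scores, mode = c("top_bottom_N", "median"), N = NULL) {
  mode <- match.arg(mode)
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  n <- length(scores)
  if (mode == "top_bottom_N") {
    if (is.null(N)) stop_invalid("`N` is required for a top/bottom split")
    if (N > n / 2) stop_invalid("N (%d) must be <= n/2 = %g", N, n / 2)
    ord_hi <- order(-scores, ids)               # ties: ascending sample ID
    ord_lo <- order(scores, ids)
    high <- ids[ord_hi[seq_len(N)]]
    low <- ids[ord_lo[seq_len(N)]]
  } else {
    med <- median(scores)
    if (all(scores == scores[1L]))
      warning("degenerate split: constant scores, all samples assigned low")
    high <- ids[scores > med]
    low <- setdiff(ids, high)
    N <- NULL
  }
  structure(list(high_ids = high, low_ids = low, mode = mode, N = N),
            class = "region_split")
}

#' @export
print.region_split <- function(x, ...) {
  cat(sprintf("Region split (%s): %d high, %d low samples\n",
              x$mode, length(x$high_ids), length(x$low_ids)))
  invisible(x)
}

#' Binary adjacency of a sample region
#'
#' Over the given samples, edge (target l, regulator j) is 1 if the fitted
#' coefficient is nonzero in at least one of them. The matrix is embedded
#' in the square universe of all genes (targets union regulators) and is
#' directional: rows index the regulated gene, columns the regulator.
#'
#' @param tensor a [build_network_tensor()] result (or list with
#'   `coefficients` and ID vectors).
#' @param sample_ids samples whose networks are pooled.
#' @return square 0/1 matrix over the gene universe, with a
#'   `"gene_universe"` attribute.
#' @export
binary_adjacency <- function(tensor, sample_ids) {
  if (length(sample_ids) == 0) stop_invalid("`sample_ids` must be nonempty")
  unknown <- setdiff(sample_ids, tensor$sample_ids)
  if (length(unknown) > 0)
    stop_invalid("unknown sample ID(s): %s", paste(unknown, collapse = ", "))
  genes <- sort(union(tensor$target_ids, tensor$regulator_ids))
  A <- matrix(0L, length(genes), length(genes), dimnames = list(genes, genes))
  sel <- tensor$coefficients[, , match(sample_ids, tensor$sample_ids), drop = FALSE]
  present <- apply(sel != 0, c(1L, 2L), any)
  A[match(tensor$target_ids, genes), match(tensor$regulator_ids, genes)] <-
    present + 0L
  attr(A, "gene_universe") <- genes
  A
}

#' Per-gene differential edge score between two regions
#'
#' `D = |A_high - A_low|`; each gene's score is the number of incident
#' differing edges, i.e. the sum of its row and column of `D` (each
#' differing edge counted once per endpoint, diagonal excluded).
#'
#' @param A_high,A_low binary adjacency matrices over the same gene
#'   universe.
#' @param aggregate `"incident"` (row + column) or `"row"` (regulated-gene
#'   side only).
#' @return named integer score vector over the gene universe.
#' @export
differential_edge_score <- function(A_high, A_low,
                                    aggregate = c("incident", "row")) {
  aggregate <- match.arg(aggregate)
  if (!identical(dim(A_high), dim(A_low)) ||
      !identical(rownames(A_high), rownames(A_low)))
    stop_invalid("adjacency matrices must share one gene universe")
  D <- abs(A_high - A_low)
  diag(D) <- 0
  if (aggregate == "incident") rowSums(D) + colSums(D) else rowSums(D)
}

#' Top-k marker genes by differential edge score
#'
#' @param scores named score vector (from [differential_edge_score()]).
#' @param k number of genes to return; ties broken by ascending gene ID.
#' @return character vector of k gene IDs, in descending score order.
#' @export
top_k_markers <- function(scores, k = 10) {
  if (k > length(scores))
    stop_invalid("k (%d) exceeds the number of genes (%d)", k, length(scores))
  ids <- names(scores)
  ord <- order(-scores, ids)
  ids[ord[seq_len(k)]]
}

#' Expand the target network of seed regulators
#'
#' Hop 1 collects genes regulated by any seed in at least one of the given
#' samples; hop 2 collects the targets of those targets; and so on. Returns
#' the induced directed edge list (regulator -> target).
#'
#' @param seeds character vector of seed gene IDs.
#' @param tensor a [build_network_tensor()] result.
#' @param sample_ids samples whose networks are pooled.
#' @param hops number of expansion hops (>= 1).
#' @return data.frame with columns `from` (regulator), `to` (target),
#'   `hop`.
#' @export
expand_target_network <- function(seeds, tensor, sample_ids, hops = 2) {
  if (length(seeds) == 0) stop_invalid("seed set must be nonempty")
  if (hops < 1) stop_invalid("`hops` must be >= 1")
  A <- binary_adjacency(tensor, sample_ids)
  genes <- attr(A, "gene_universe")
  unknown <- setdiff(seeds, genes)
  if (length(unknown) > 0)
    stop_invalid("seed gene(s) not in universe: %s", paste(unknown, collapse = ", "))
  edges <- list()
  frontier <- seeds
  visited_from <- character(0)
  for (h in seq_len(hops)) {
    frontier <- setdiff(frontier, visited_from)
    frontier <- frontier[frontier %in% colnames(A)]
    if (length(frontier) == 0) break
    new_targets <- character(0)
    for (g in sort(frontier)) {
      tg <- rownames(A)[A[, g] == 1]
      tg <- setdiff(tg, g)
      if (length(tg) > 0)
        edges[[length(edges) + 1L]] <-
          data.frame(from = g, to = tg, hop = h, stringsAsFactors = FALSE)
      new_targets <- union(new_targets, tg)
    }
    visited_from <- union(visited_from, frontier)
    frontier <- new_targets
  }
  if (length(edges) == 0)
    return(data.frame(from = character(0), to = character(0),
                      hop = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

#' Regulatory effect of every edge in every sample
#'
#' `RE[l, j, a] = beta_hat_jl(m_a) * x_aj`: the fitted coefficient of
#' regulator j on target l in sample a, scaled by the regulator's
#' expression in that sample — the realized strength of the edge.
#'
#' @param tensor a [build_network_tensor()] result.
#' @param data the [expression_dataset()] the tensor was fitted on.
#' @return 3D array (targets x regulators x samples) of class `"re_array"`.
#' @export
regulatory_effect <- function(tensor, data) {
  stopifnot(inherits(data, "expression_dataset"))
  if (!identical(tensor$sample_ids, data$sample_ids))
    stop_invalid("tensor and expression samples are misaligned")
  X <- data$values[tensor$regulator_ids, , drop = FALSE]   # I2 x n
  re <- tensor$coefficients
  for (a in seq_along(tensor$sample_ids))
    re[, , a] <- sweep(re[, , a, drop = FALSE][, , 1L], 2L, X[, a], "*")
  class(re) <- c("re_array", class(re))
  re
}

#' Regulatory effect change across samples
#'
#' `REC[l, j] = max_a RE[l, j, a] - min_a RE[l, j, a]`: the range of the
#' realized edge strength over samples, measuring how strongly the edge
#' depends on the modulator. Zero for edges absent in every sample.
#'
#' @param re RE array from [regulatory_effect()].
#' @return targets x regulators matrix of nonnegative changes.
#' @export
rec <- function(re) {
  if (length(dim(re)) != 3L) stop_invalid("`re` must be a 3D RE array")
  apply(re, c(1L, 2L), function(v) max(v) - min(v))
}

#' Mean regulatory effect over a sample set
#'
#' Averages RE over the listed samples; with `prune_zero_mean = TRUE`,
#' edges whose mean is exactly zero are set to `NA` (treated as absent,
#' e.g. for heatmap display).
#'
#' @param re RE array from [regulatory_effect()].
#' @param sample_ids samples to average over (positions or names of the
#'   third axis).
#' @param prune_zero_mean drop exactly-cancelling edges.
#' @return targets x regulators matrix of mean effects.
#' @export
mean_re_summary <- function(re, sample_ids, prune_zero_mean = FALSE) {
  if (length(sample_ids) == 0) stop_invalid("`sample_ids` must be nonempty")
  idx <- if (is.character(sample_ids)) {
    pos <- match(sample_ids, dimnames(re)[[3L]])
    if (anyNA(pos))
      stop_invalid("unknown sample ID(s): %s",
                   paste(sample_ids[is.na(pos)], collapse = ", "))
    pos
  } else sample_ids
  M <- apply(re[, , idx, drop = FALSE], c(1L, 2L), mean)
  if (prune_zero_mean) M[M == 0] <- NA_real_
  M
}

#' PCA biplot coordinates of the REC matrix
#'
#' Column-centred PCA of the REC matrix restricted to the marker columns:
#' marker genes get component loadings, target genes get scores, giving
#' the biplot in which markers with similar modulator-dependent regulation
#' group together. Component signs are fixed so the largest-magnitude
#' loading is positive.
#'
#' @param rec_matrix targets x regulators REC matrix (from [rec()]).
#' @param marker_genes the marker columns to analyze (>= 2).
#' @return list with `loadings` (markers x 2), `scores` (targets x 2) and
#'   `variance_explained` over all components (non-increasing, sums to 1).
#' @export
rec_pca <- function(rec_matrix, marker_genes) {
  if (length(marker_genes) < 2)
    stop_invalid("need at least 2 marker columns for a PCA, got %d",
                 length(marker_genes))
  missing <- setdiff(marker_genes, colnames(rec_matrix))
  if (length(missing) > 0)
    stop_invalid("marker gene(s) not in REC columns: %s",
                 paste(missing, collapse = ", "))
  M <- rec_matrix[, marker_genes, drop = FALSE]
  pca <- prcomp(M, center = TRUE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  keep <- seq_len(min(2L, ncol(pca$rotation)))
  for (cidx in seq_len(ncol(pca$rotation))) {
    j <- which.max(abs(pca$rotation[, cidx]))
    if (pca$rotation[j, cidx] < 0) {
      pca$rotation[, cidx] <- -pca$rotation[, cidx]
      pca$x[, cidx] <- -pca$x[, cidx]
    }
  }
  list(loadings = pca$rotation[, keep, drop = FALSE],
       scores = pca$x[, keep, drop = FALSE],
       variance_explained = ve)
}

#' Chi-squared tissue association of a sample region split
#'
#' Pearson chi-squared independence test (no continuity correction by
#' default) on the 2x2 table of membership in the given tissue versus
#' region (high/low). Significance flags at the 0.01, 0.001 and 0.0001
#' levels.
#'
#' @param tissue_labels named character vector: per-sample tissue labels
#'   (names are sample IDs covering the split).
#' @param split a [split_samples()] result.
#' @param tissue the tissue label to test.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `p_value`, `stars` (`""`, `"**"`,
#'   `"***"`, `"****"`), and the 2x2 `table`.
#' @export
tissue_association_test <- function(tissue_labels, split, tissue,
                                    correct = FALSE) {
  ids <- c(split$high_ids, split$low_ids)
  missing <- setdiff(ids, names(tissue_labels))
  if (length(missing) > 0)
    stop_invalid("unlabeled sample(s): %s", paste(missing, collapse = ", "))
  lab <- tissue_labels[ids]
  region <- factor(rep(c("high", "low"), c(length(split$high_ids),
                                           length(split$low_ids))),
                   levels = c("high", "low"))
  in_tissue <- factor(ifelse(lab == tissue, "yes", "no"),
                      levels = c("yes", "no"))
  tab <- table(in_tissue, region)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_invalid("degenerate table: an empty margin for tissue '%s'", tissue)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  p <- unname(ht$p.value)
  stars <- if (p < 1e-4) "****" else if (p < 1e-3) "***" else
    if (p < 0.01) "**" else ""
  list(statistic = unname(ht$statistic), p_value = p, stars = stars,
       table = tab)
}
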