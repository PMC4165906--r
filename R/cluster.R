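# Unsupervised structure discovery: top-variable target selection and
# agglomerative clustering of samples on Pearson correlation distance with
# average linkage (UPGMA).

#' Select the most variable targets
#'
#' Keeps the `n` targets with the largest across-sample variance (missing
#' values excluded), ties broken by target id for determinism. Row order of
#' the input is preserved in the subset.
#'
#' @param rm targets x samples matrix.
#' @param n number of targets to keep (default 500).
#' @return the subset matrix.
#' @export
top_variable <- function(rm, n = 500) {
  check_matrix(rm, "region matrix")
  if (n > nrow(rm)) stopf("n (%d) exceeds available targets (%d)", n, nrow(rm))
  v <- apply(rm, 1, stats::var, na.rm = TRUE)
  keep <- rownames(rm)[order(-v, rownames(rm))][seq_len(n)]
  rm[rownames(rm) %in% keep, , drop = FALSE]
}

#' Hierarchical clustering of samples on correlation distance
#'
#' Sample-sample distance is `1 - Pearson correlation` of their methylation
#' profiles over the supplied targets (centered correlation; range
#' \[0, 2\]), merged by average linkage (UPGMA). The tree is cut into `k`
#' clusters.
#'
#' @param rm targets x samples matrix without missing values (impute first).
#' @param k number of clusters for the cut (default 2).
#' @return a `meth_clust` object: `hclust` (merge tree), `labels` (k-cut
#'   cluster id per sample), `dist` (the distance matrix), `k`.
#' @export
cluster_samples <- function(rm, k = 2) {
  check_matrix(rm, "region matrix")
  if (ncol(rm) < 2) stopf("need >= 2 samples to cluster")
  if (anyNA(rm)) stopf("missing values present; impute before clustering")
  sds <- apply(rm, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance sample profile(s): %s",
          paste(colnames(rm)[sds == 0], collapse = ", "))
  D <- 1 - stats::cor(rm)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  labels <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, labels = labels, dist = D, k = k),
            class = "meth_clust")
}

#' @export
print.meth_clust <- function(x, ...) {
  cat(sprintf("Average-linkage clustering of %d samples (correlation distance)\n",
              length(x$labels)))
  cat("  k-cut sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.meth_clust <- function(x, ...) {
  plot(x$hclust, hang = -1, xlab = "", sub = "",
       main = "Methylation profile clustering", ...)
  invisible(x)
}

#' Export a sample dendrogram as Newick
#'
#' @param x a `meth_clust` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "meth_clust"))
  if (!requireNamespace("ape", quietly = TRUE))
    stopf("the 'ape' package is required for Newick export")
  ape::write.tree(ape::as.phylo(x$hclust), file = path)
  invisible(path)
}

#' Cross-tabulate cluster membership against a clinical variable
#'
#' Descriptive composition readout of the k-cut clusters (e.g. tissue type
#' or intrinsic subtype per cluster); no test is performed.
#'
#' @param x a `meth_clust` object.
#' @param clinical clinical data.frame with `sample_id`.
#' @param variable clinical column name (default `"tissue"`).
#' @return contingency table cluster x variable.
#' @export
cluster_composition <- function(x, clinical, variable = "tissue") {
  stopifnot(inherits(x, "meth_clust"))
  if (!variable %in% names(clinical)) stopf("no clinical column '%s'", variable)
  idx <- match(names(x$labels), clinical$sample_id)
  if (anyNA(idx)) stopf("clustered samples missing from clinical table")
  table(cluster = x$labels, clinical[[variable]][idx])
}
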