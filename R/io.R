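# Tabular input/output: beta and expression matrices, CpG annotation,
# clinical tables; probe filtering and KNN imputation for validation-style
# matrices with missing values.
#
# Dialect: tab-separated, UTF-8, "NA" (or empty cell) for missing. Matrices
# carry a header row of sample ids and a first column of feature ids.

#' Read a methylation or expression matrix from TSV
#'
#' Reads a features x samples matrix. For `kind = "beta"` every non-missing
#' value must lie in \[0, 1\] (a beta value is the methylated signal divided
#' by the total signal, i.e. the fraction of methylated molecules at a CpG);
#' out-of-range cells raise an error naming the offending probe and sample.
#'
#' @param path path to a TSV file: header row of sample ids, first column of
#'   feature ids, "NA" or empty for missing.
#' @param kind `"beta"` (range-validated) or `"expression"`.
#' @return numeric matrix with feature rownames and sample colnames; missing
#'   cells are `NA`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(0.1, 0.9, NA, 0.5), 2, 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' write_matrix(m, tf)
#' read_matrix(tf, "beta")
read_matrix <- function(path, kind = c("beta", "expression")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("matrix file '%s' needs an id column plus samples", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stopf("duplicate feature ids in '%s': %s", path,
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stopf("duplicate sample ids in '%s'", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (kind == "beta") validate_beta(m)
  m
}

validate_beta <- function(m) {
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("beta value out of [0,1]: probe '%s', sample '%s' (value %g)",
          rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
          m[bad[1, 1], bad[1, 2]])
  }
  invisible(m)
}

#' Write a matrix as TSV
#'
#' Inverse of [read_matrix()]: feature ids in the first column ("id"),
#' sample ids as header, `NA` for missing. Round-trips non-missing values
#' losslessly to at least six decimals.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  check_matrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a CpG annotation table
#'
#' Seven tab-separated columns: `probe_id`, `chromosome`, `position`
#' (1-based), `strand`, `gene` (symbol, empty for intergenic CpGs),
#' `subregion` (one of TSS1500, TSS200, 5UTR, FirstExon, Body, 3UTR,
#' Intergenic) and `tss_distance` (signed bp, negative upstream,
#' strand-oriented). A probe may appear on several rows when annotated to
#' several genes; (probe, gene) pairs must be unique.
#'
#' @param path TSV path.
#' @return data.frame with the seven columns.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  needed <- c("probe_id", "chromosome", "position", "strand", "gene",
              "subregion", "tss_distance")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stopf("annotation '%s' lacks columns: %s", path,
                          paste(miss, collapse = ", "))
  df$gene[is.na(df$gene)] <- ""
  validate_annotation(df[needed])
}

validate_annotation <- function(ann) {
  ok <- ann$subregion %in% c(SUBREGIONS, "Intergenic")
  if (!all(ok)) stopf("unknown subregion label(s): %s",
                      paste(unique(ann$subregion[!ok]), collapse = ", "))
  if (any(ann$position < 1, na.rm = TRUE)) stopf("positions must be >= 1")
  key <- paste(ann$probe_id, ann$gene)
  if (anyDuplicated(key)) stopf("duplicate (probe, gene) annotation rows")
  ann
}

#' Read a clinical table
#'
#' Expected columns: `sample_id`, `tissue` (normal/DCIS/mixed/IBC), `time`
#' (follow-up, months), `event` (breast-cancer-specific death, 0/1), and
#' optionally `er` (neg/pos), `tp53` (wt/mut), `t_status` (1/2/3or4),
#' `node` (neg/pos), `pam50`. Missing categorical entries are `NA`.
#'
#' @param path TSV path.
#' @return data.frame keyed by `sample_id`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  validate_clinical(df)
}

validate_clinical <- function(df) {
  for (col in c("sample_id", "tissue", "time", "event"))
    if (!col %in% names(df)) stopf("clinical table lacks column '%s'", col)
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in clinical table")
  if (any(df$time < 0, na.rm = TRUE)) stopf("negative follow-up time")
  if (!all(df$event %in% c(0, 1, NA))) stopf("event must be 0/1")
  df
}

#' Remove probes with too many missing values
#'
#' Retains exactly the probes whose missing fraction is less than or equal
#' to `max_missing_frac` — i.e. probes with *more* than that fraction
#' missing are removed, matching the usual >50%-missing exclusion rule for
#' validation cohorts. Probe order is preserved.
#'
#' @param m beta matrix (probes x samples).
#' @param max_missing_frac maximum tolerated missing fraction, in \[0, 1\].
#' @return the filtered matrix.
#' @export
filter_missing <- function(m, max_missing_frac = 0.5) {
  check_matrix(m, "beta matrix")
  if (max_missing_frac < 0 || max_missing_frac > 1)
    stopf("max_missing_frac must be in [0,1]")
  frac <- rowMeans(is.na(m))
  m[frac <= max_missing_frac, , drop = FALSE]
}

#' K-nearest-neighbour imputation of missing beta values
#'
#' For each missing cell, the k nearest probes (Euclidean distance over the
#' samples where both probes are observed, scaled by the overlap size) that
#' are observed at that sample supply the imputed value as their mean.
#' Observed entries are never altered. Imputed values are clipped to
#' \[0, 1\] so the matrix remains a valid beta matrix.
#'
#' @param m beta matrix with possibly missing cells; every probe needs at
#'   least one observed value.
#' @param k number of neighbours (default 10, the conventional choice for
#'   450K validation matrices). When fewer donors exist, all available are
#'   used with a warning.
#' @return matrix with no missing values.
#' @export
knn_impute <- function(m, k = 10) {
  check_matrix(m, "beta matrix")
  if (k < 1) stopf("k must be >= 1")
  if (!anyNA(m)) return(m)
  if (any(rowSums(!is.na(m)) == 0))
    stopf("probe(s) with no observed values cannot be imputed: %s",
          paste(rownames(m)[rowSums(!is.na(m)) == 0], collapse = ", "))
  obs <- !is.na(m)
  need <- which(rowSums(!obs) > 0)
  out <- m
  for (i in need) {
    di <- probe_distances(m, obs, i)
    for (s in which(!obs[i, ])) {
      donors <- which(obs[, s] & is.finite(di))
      if (length(donors) == 0)
        stopf("no donor probe observed at sample '%s'", colnames(m)[s])
      if (length(donors) < k)
        warnf("probe '%s', sample '%s': only %d neighbours available (k = %d)",
              rownames(m)[i], colnames(m)[s], length(donors), k)
      nb <- donors[order(di[donors], rownames(m)[donors])]
      nb <- nb[seq_len(min(k, length(nb)))]
      out[i, s] <- mean(m[nb, s])
    }
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# RMS distance from probe i to every other probe over shared observed
# samples; Inf when there is no overlap. Scaling by overlap size keeps
# distances comparable between probe pairs with different overlaps.
probe_distances <- function(m, obs, i) {
  diff2 <- sweep(m, 2, m[i, ], "-")^2
  shared <- obs & rep(obs[i, ], each = nrow(m))
  n_shared <- rowSums(shared)
  ss <- rowSums(diff2 * shared, na.rm = TRUE)
  d <- sqrt(ss / n_shared)
  d[n_shared == 0] <- Inf
  d[i] <- Inf
  d
}
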