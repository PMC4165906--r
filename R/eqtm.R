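# Cis methylation-expression correlation (eQTM analysis).
#
# CpG-level: every (CpG, gene) pair with the CpG within 100 kb of the gene's
# TSS is tested for non-zero Pearson correlation; region-level: each
# gene-region target against its own gene's expression. Bonferroni control
# at 0.05, with the correction factor m computed per analysis.

#' Build cis CpG-gene pairs within a TSS window
#'
#' Pairs every CpG with every gene whose TSS lies within `window` bp
#' (boundary inclusive) on the same chromosome. Distances are
#' strand-oriented: negative upstream of the TSS of that gene. For genes
#' with several TSS rows, only the nearest TSS is kept per (CpG, gene).
#'
#' @param ann CpG annotation data.frame (needs `probe_id`, `chromosome`,
#'   `position`).
#' @param tss data.frame of gene TSSs: `gene`, `chromosome`, `tss`, `strand`.
#' @param window half-width in bp (default 100,000).
#' @return data.frame (`probe_id`, `gene_id`, `tss_distance`).
#' @export
build_cis_pairs <- function(ann, tss, window = 100000) {
  if (window <= 0) stopf("window must be positive")
  for (col in c("gene", "chromosome", "tss", "strand"))
    if (!col %in% names(tss)) stopf("tss table lacks column '%s'", col)
  ann <- unique(ann[, c("probe_id", "chromosome", "position")])
  pairs <- merge(ann, tss, by = "chromosome")
  dist <- (pairs$position - pairs$tss) * ifelse(pairs$strand == "+", 1, -1)
  pairs$tss_distance <- dist
  pairs <- pairs[abs(dist) <= window, , drop = FALSE]
  if (nrow(pairs) == 0)
    return(data.frame(probe_id = character(), gene_id = character(),
                      tss_distance = numeric(), stringsAsFactors = FALSE))
  # several TSSs per gene: keep the nearest per (CpG, gene)
  key <- paste(pairs$probe_id, pairs$gene)
  ord <- order(key, abs(pairs$tss_distance))
  pairs <- pairs[ord, ][!duplicated(key[ord]), , drop = FALSE]
  out <- data.frame(probe_id = pairs$probe_id, gene_id = pairs$gene,
                    tss_distance = pairs$tss_distance,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$probe_id), , drop = FALSE]
}

# Pearson r and two-sided p (t distribution, n-2 df) for aligned columns
# x, y of a pairwise-complete matrix pair. Returns NAs when degenerate.
pearson_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n, reason = "n<3"))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "zero variance"))
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n, reason = NA_character_)
}

#' Correlate CpG methylation with gene expression over cis pairs
#'
#' Pearson correlation per pair over the shared samples with both values
#' observed (pairwise-complete); two-sided p from the t distribution with
#' n-2 df; Bonferroni correction with m = number of tested pairs.
#' Pairs with fewer than 3 complete observations or zero variance are
#' skipped (with a message) and do not count toward m.
#'
#' @param m beta matrix (probes x samples).
#' @param e expression matrix (genes x samples).
#' @param pairs data.frame from [build_cis_pairs()].
#' @param alpha Bonferroni-corrected significance level (default 0.05).
#' @return data.frame (`probe_id`, `gene_id`, `tss_distance`, `r`, `p_raw`,
#'   `p_bonferroni`, `n_used`, `significant`).
#' @export
correlate_pairs <- function(m, e, pairs, alpha = 0.05) {
  check_matrix(m, "beta matrix"); check_matrix(e, "expression matrix")
  shared <- intersect(colnames(m), colnames(e))
  if (length(shared) < 3) stopf("fewer than 3 shared samples")
  keep <- pairs$probe_id %in% rownames(m) & pairs$gene_id %in% rownames(e)
  pairs <- pairs[keep, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pearson_test(m[pairs$probe_id[i], shared], e[pairs$gene_id[i], shared])
  })
  r <- vapply(res, `[[`, numeric(1), "r")
  p <- vapply(res, `[[`, numeric(1), "p")
  n_used <- vapply(res, `[[`, numeric(1), "n")
  skipped <- is.na(r)
  if (any(skipped))
    message(sprintf("skipped %d pair(s): %s", sum(skipped),
                    paste(unique(stats::na.omit(vapply(res, `[[`, "", "reason"))),
                          collapse = "; ")))
  out <- data.frame(probe_id = pairs$probe_id, gene_id = pairs$gene_id,
                    tss_distance = pairs$tss_distance,
                    r = r, p_raw = p, n_used = n_used,
                    stringsAsFactors = FALSE)[!skipped, , drop = FALSE]
  m_tests <- nrow(out)
  out$p_bonferroni <- pmin(1, out$p_raw * m_tests)
  out$significant <- out$p_bonferroni < alpha
  attr(out, "m_tests") <- m_tests
  attr(out, "alpha") <- alpha
  rownames(out) <- NULL
  out
}

#' Correlate gene-region methylation with expression of the same gene
#'
#' One Pearson test per (gene, subregion) target against the expression of
#' the target's own gene; same p-value and Bonferroni contract as
#' [correlate_pairs()], with m = number of tested region targets. Targets
#' whose gene has no expression row are skipped with a message.
#'
#' @param rm region matrix from [collapse_regions()].
#' @param e expression matrix (genes x samples).
#' @param alpha Bonferroni-corrected significance level.
#' @return data.frame (`target`, `gene_id`, `subregion`, `r`, `p_raw`,
#'   `p_bonferroni`, `n_used`, `significant`).
#' @export
correlate_regions <- function(rm, e, alpha = 0.05) {
  check_matrix(rm, "region matrix"); check_matrix(e, "expression matrix")
  shared <- intersect(colnames(rm), colnames(e))
  if (length(shared) < 3) stopf("fewer than 3 shared samples")
  tg <- parse_targets(rownames(rm))
  has_expr <- tg$gene %in% rownames(e)
  if (any(!has_expr))
    message(sprintf("skipped %d target(s) whose gene lacks expression data",
                    sum(!has_expr)))
  idx <- which(has_expr)
  res <- lapply(idx, function(i)
    pearson_test(rm[i, shared], e[tg$gene[i], shared]))
  r <- vapply(res, `[[`, numeric(1), "r")
  p <- vapply(res, `[[`, numeric(1), "p")
  n_used <- vapply(res, `[[`, numeric(1), "n")
  skipped <- is.na(r)
  out <- data.frame(target = rownames(rm)[idx], gene_id = tg$gene[idx],
                    subregion = tg$subregion[idx],
                    r = r, p_raw = p, n_used = n_used,
                    stringsAsFactors = FALSE)[!skipped, , drop = FALSE]
  m_tests <- nrow(out)
  out$p_bonferroni <- pmin(1, out$p_raw * m_tests)
  out$significant <- out$p_bonferroni < alpha
  attr(out, "m_tests") <- m_tests
  attr(out, "alpha") <- alpha
  rownames(out) <- NULL
  out
}

#' Summarize significant correlation directions by stratum
#'
#' Counts significant positive and negative correlations per stratum
#' (functional subregion, or signed TSS-distance bins), and collects the
#' per-gene direction sets under the "at least one CpG" convention: a gene
#' belongs to the positive set when any of its pairs/targets is
#' significantly positive, and analogously for negative — the two sets may
#' overlap.
#'
#' @param results output of [correlate_pairs()] (needs a `subregion` column
#'   merged in for `by = "subregion"`) or [correlate_regions()].
#' @param by `"subregion"` or `"tss_distance_bins"`.
#' @param bin_width bin width in bp for distance bins (default 20 kb).
#' @return list: `strata` data.frame (stratum, n_positive, n_negative,
#'   fraction_positive), `genes_positive`, `genes_negative`.
#' @export
summarize_directions <- function(results, by = c("subregion", "tss_distance_bins"),
                                 bin_width = 20000) {
  by <- match.arg(by)
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(list(strata = data.frame(stratum = character(),
                                    n_positive = integer(),
                                    n_negative = integer(),
                                    fraction_positive = numeric(),
                                    stringsAsFactors = FALSE),
                genes_positive = character(), genes_negative = character()))
  }
  stratum <- if (by == "subregion") {
    if (!"subregion" %in% names(sig))
      stopf("results lack a 'subregion' column; merge annotation first")
    sig$subregion
  } else {
    if (!"tss_distance" %in% names(sig))
      stopf("results lack a 'tss_distance' column")
    paste0(floor(sig$tss_distance / bin_width) * bin_width / 1000, "kb")
  }
  pos <- tapply(sig$r > 0, stratum, sum)
  neg <- tapply(sig$r < 0, stratum, sum)
  strata <- data.frame(stratum = names(pos),
                       n_positive = as.integer(pos),
                       n_negative = as.integer(neg),
                       stringsAsFactors = FALSE)
  strata$fraction_positive <- strata$n_positive /
    pmax(1, strata$n_positive + strata$n_negative)
  gene_col <- if ("gene_id" %in% names(sig)) "gene_id" else "gene"
  list(strata = strata,
       genes_positive = sort(unique(sig[[gene_col]][sig$r > 0])),
       genes_negative = sort(unique(sig[[gene_col]][sig$r < 0])))
}
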