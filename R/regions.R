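# Gene-region collapse: summarize CpG betas per gene x functional subregion
# by the median. A gene contributes up to six targets (TSS1500, TSS200,
# 5'UTR, first exon, body, 3'UTR); intergenic CpGs are dropped.

#' Assign a CpG to a gene functional subregion
#'
#' Boundary conventions (distances strand-oriented, negative upstream,
#' upstream boundaries inclusive): 1,500–201 bp upstream of the TSS ->
#' TSS1500; 200 bp upstream through the TSS itself -> TSS200; downstream
#' CpGs are classified by their location within the gene: 5'UTR -> 5UTR,
#' first exon -> FirstExon, other exons or introns -> Body, 3'UTR -> 3UTR.
#' A CpG mapped to no gene is Intergenic.
#'
#' @param tss_distance signed bp from the TSS (negative upstream); `NA` for
#'   unmapped CpGs.
#' @param location within-gene location descriptor: one of `"5UTR"`,
#'   `"first_exon"`, `"exon"`, `"intron"`, `"3UTR"`, or `"none"` when the
#'   CpG maps to no gene. Vectorized.
#' @return character vector of subregion labels.
#' @export
#' @examples
#' assign_subregion(-700, "intron")   # TSS1500
#' assign_subregion(-100, "5UTR")     # TSS200
#' assign_subregion(2500, "intron")   # Body
assign_subregion <- function(tss_distance, location) {
  n <- max(length(tss_distance), length(location))
  tss_distance <- rep_len(tss_distance, n)
  location <- rep_len(location, n)
  known <- c("5UTR", "first_exon", "exon", "intron", "3UTR", "none")
  if (!all(location %in% known))
    stopf("unknown location descriptor(s): %s",
          paste(setdiff(unique(location), known), collapse = ", "))
  out <- character(n)
  none <- location == "none"
  out[none] <- "Intergenic"
  if (any(!none & is.na(tss_distance)))
    stopf("contradictory annotation: gene-mapped CpG without a TSS distance")
  if (any(none & !is.na(tss_distance)))
    stopf("contradictory annotation: TSS distance given for an unmapped CpG")
  d <- tss_distance[!none]
  loc <- location[!none]
  lab <- ifelse(d >= -1500 & d <= -201, "TSS1500",
         ifelse(d >= -200 & d <= 0, "TSS200",
                c("5UTR" = "5UTR", first_exon = "FirstExon", exon = "Body",
                  intron = "Body", "3UTR" = "3UTR")[loc]))
  if (any(d < -1500))
    stopf("contradictory annotation: CpG more than 1500 bp upstream is not within a gene region")
  out[!none] <- lab
  out
}

#' Collapse a beta matrix to gene-region medians
#'
#' Builds the "gene region collapsed" dataset: one target per observed
#' (gene, subregion) pair, valued as the median beta of its member CpGs per
#' sample (missing member values excluded; a target with no observed member
#' in a sample is missing there). Intergenic CpGs are dropped. A CpG
#' annotated to several genes contributes to each.
#'
#' @param m beta matrix (probes x samples).
#' @param ann annotation data.frame as from [read_annotation()]; every probe
#'   of `m` must be annotated.
#' @return targets x samples matrix with rownames `"GENE|SUBREGION"`.
#' @export
collapse_regions <- function(m, ann) {
  check_matrix(m, "beta matrix")
  missing_probes <- setdiff(rownames(m), ann$probe_id)
  if (length(missing_probes))
    stopf("probes without annotation: %s%s",
          paste(utils::head(missing_probes, 5), collapse = ", "),
          if (length(missing_probes) > 5) ", ..." else "")
  ann <- ann[ann$probe_id %in% rownames(m) &
               ann$subregion != "Intergenic" & ann$gene != "", , drop = FALSE]
  if (nrow(ann) == 0)
    stopf("no gene-annotated probes shared between matrix and annotation")
  target <- paste(ann$gene, ann$subregion, sep = "|")
  rows <- match(ann$probe_id, rownames(m))
  groups <- split(rows, target)
  out <- matrix(NA_real_, length(groups), ncol(m),
                dimnames = list(names(groups), colnames(m)))
  for (i in seq_along(groups)) {
    sub <- m[groups[[i]], , drop = FALSE]
    out[i, ] <- apply(sub, 2, stats::median, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

# Split "GENE|SUBREGION" target ids into a two-column data.frame.
parse_targets <- function(targets) {
  parts <- strsplit(targets, "|", fixed = TRUE)
  data.frame(gene = vapply(parts, `[`, "", 1),
             subregion = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}
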