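# Stage orchestration: run the analysis stages in order against TSV inputs
# or the synthetic generator, writing each stage's outputs plus a JSON run
# manifest (seeds, parameters, input checksums) for reproducibility.

#' Read a pipeline configuration file
#'
#' Plain-text YAML with optional blocks `paths` (beta, expression,
#' clinical, annotation, tss TSVs), `simulate`, `diffmeth`, `corr`,
#' `cluster`, `signature`, and top-level `seed`.
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

stage_file <- function(outdir, name) file.path(outdir, name)

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order. `simulate` generates
#' a synthetic cohort and writes its four input tables; otherwise the
#' inputs are read from `config$paths`. Stage outputs land in `outdir` as
#' TSV; a `manifest.json` records the package version, seed, stage
#' parameters, and md5 checksums of the inputs.
#'
#' Stage dependencies: `collapse` needs beta + annotation; `diffmeth`,
#' `cluster` need `collapse`; `corr` needs beta/expression; `signature`
#' needs `corr` output (pre-selection); `survival` needs `signature`.
#'
#' @param config list as from [read_pipeline_config()] (may be empty for a
#'   pure simulation run).
#' @param stages ordered subset of simulate, collapse, diffmeth, corr,
#'   cluster, signature, survival.
#' @param outdir output directory (created if needed).
#' @param seed master seed; recorded in the manifest and used for every
#'   stochastic stage.
#' @return invisible list of stage results.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "collapse", "diffmeth",
                                    "corr", "cluster", "signature",
                                    "survival"),
                         outdir = "methprog-out", seed = 1) {
  all_stages <- c("simulate", "collapse", "diffmeth", "corr", "cluster",
                  "signature", "survival")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  manifest <- list(package = "methprog",
                   version = as.character(utils::packageVersion("methprog")),
                   seed = seed, stages = stages, started = format(Sys.time()))

  inputs <- NULL
  load_inputs <- function() {
    if (!is.null(inputs)) return(inputs)
    pth <- config$paths
    if (is.null(pth))
      stopf("no input paths configured; run the 'simulate' stage first or set config$paths")
    for (f in unlist(pth)) if (!file.exists(f)) stopf("input not found: %s", f)
    manifest$input_md5 <<- as.list(tools::md5sum(unlist(pth)))
    inputs <<- list(
      beta = read_matrix(pth$beta, "beta"),
      expression = if (!is.null(pth$expression))
        read_matrix(pth$expression, "expression"),
      clinical = if (!is.null(pth$clinical)) read_clinical(pth$clinical),
      annotation = if (!is.null(pth$annotation)) read_annotation(pth$annotation),
      tss = if (!is.null(pth$tss))
        utils::read.delim(pth$tss, stringsAsFactors = FALSE))
    inputs
  }

  if ("simulate" %in% stages) {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    cohort <- simulate_cohort(do.call(simulate_config, sim_args))
    res$simulate <- cohort
    write_matrix(cohort$beta, stage_file(outdir, "beta.tsv"))
    write_matrix(cohort$expression, stage_file(outdir, "expression.tsv"))
    utils::write.table(cohort$clinical, stage_file(outdir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    utils::write.table(cohort$annotation, stage_file(outdir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    utils::write.table(cohort$tss, stage_file(outdir, "tss.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    truth <- cohort$truth
    truth$index <- as.list(truth$index)
    jsonlite::write_json(unclass(truth), stage_file(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    config$paths <- list(beta = stage_file(outdir, "beta.tsv"),
                         expression = stage_file(outdir, "expression.tsv"),
                         clinical = stage_file(outdir, "clinical.tsv"),
                         annotation = stage_file(outdir, "annotation.tsv"),
                         tss = stage_file(outdir, "tss.tsv"))
    inputs <- cohort[c("beta", "expression", "clinical", "annotation", "tss")]
  }

  if ("collapse" %in% stages) {
    inp <- load_inputs()
    if (is.null(inp$annotation)) stopf("'collapse' needs an annotation input")
    res$collapse <- collapse_regions(inp$beta, inp$annotation)
    write_matrix(res$collapse, stage_file(outdir, "regions.tsv"))
  }

  if ("diffmeth" %in% stages) {
    inp <- load_inputs()
    if (is.null(res$collapse)) stopf("run the 'collapse' stage before 'diffmeth'")
    dm_args <- config$diffmeth %||% list()
    groups <- stats::setNames(inp$clinical$tissue, inp$clinical$sample_id)
    use <- groups %in% (dm_args$groups %||% c("normal", "DCIS"))
    m <- res$collapse[, names(groups)[use], drop = FALSE]
    keep <- rowSums(is.na(m)) == 0
    res$diffmeth <- sam_test(m[keep, , drop = FALSE], groups[use],
                             n_permutations = dm_args$n_permutations %||% 100,
                             q_threshold = dm_args$q_threshold %||% 0.01,
                             median_diff_threshold =
                               dm_args$median_diff_threshold %||% 0.1,
                             seed = derive_seed(seed, 11L))
    utils::write.table(as.data.frame(res$diffmeth),
                       stage_file(outdir, "diffmeth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$diffmeth <- list(s0 = attr(res$diffmeth, "s0"),
                              seed = derive_seed(seed, 11L))
  }

  if ("corr" %in% stages) {
    inp <- load_inputs()
    if (is.null(inp$expression) || is.null(inp$tss))
      stopf("'corr' needs expression and tss inputs")
    corr_args <- config$corr %||% list()
    pairs <- build_cis_pairs(inp$annotation, inp$tss,
                             window = corr_args$window %||% 100000)
    res$corr <- correlate_pairs(inp$beta, inp$expression, pairs,
                                alpha = corr_args$alpha %||% 0.05)
    utils::write.table(res$corr, stage_file(outdir, "corr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("cluster" %in% stages) {
    if (is.null(res$collapse)) stopf("run the 'collapse' stage before 'cluster'")
    cl_args <- config$cluster %||% list()
    rm_top <- top_variable(res$collapse,
                           n = min(cl_args$top_n %||% 500, nrow(res$collapse)))
    rm_top <- rm_top[rowSums(is.na(rm_top)) == 0, , drop = FALSE]
    res$cluster <- cluster_samples(rm_top, k = cl_args$k %||% 2)
    utils::write.table(data.frame(sample_id = names(res$cluster$labels),
                                  cluster = res$cluster$labels),
                       stage_file(outdir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("signature" %in% stages) {
    inp <- load_inputs()
    if (is.null(res$corr))
      stopf("run the 'corr' stage before 'signature' (pre-selection needs it)")
    sig_args <- config$signature %||% list()
    probes <- preselect_probes(res$corr, alpha = sig_args$preselect_alpha %||% 0.05)
    cl <- inp$clinical
    x <- t(inp$beta[probes, cl$sample_id, drop = FALSE])
    res$signature <- meth_signature(
      x, cl$time, cl$event,
      n_runs = sig_args$n_runs %||% 100,
      presence_threshold = sig_args$presence_threshold %||% 0.80,
      cv_folds = sig_args$cv_folds %||% 10,
      seed = derive_seed(seed, 12L))
    if (length(res$signature$probes)) {
      utils::write.table(
        data.frame(probe_id = res$signature$probes,
                   coefficient = unname(res$signature$coefficients)),
        stage_file(outdir, "signature.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("survival" %in% stages) {
    inp <- load_inputs()
    if (is.null(res$signature)) stopf("run the 'signature' stage before 'survival'")
    risk <- predict(res$signature, inp$beta, type = "group")
    res$survival <- evaluate_signature(risk, inp$clinical)
    utils::write.table(
      cbind(covariate = names(res$survival$cox_multivariate$coef),
            as.data.frame(summary(res$survival$cox_multivariate)$table)),
      stage_file(outdir, "survival.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, stage_file(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
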