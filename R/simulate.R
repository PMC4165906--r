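# Synthetic cohort generator with planted ground truth.
#
# Emulates the data shapes of a breast cancer progression study: a 450K-style
# beta matrix over normal / DCIS / invasive (IBC) samples, a coupled
# expression matrix, a clinical table with breast-cancer-specific survival,
# and a manifest-style CpG annotation. Three kinds of signal are planted and
# recorded: group-shifted differentially methylated CpGs (normal->DCIS and
# DCIS->IBC contrasts), signed methylation->expression couplings (negative in
# promoter subregions, positive in gene body / 3'UTR), and a CpG risk
# signature whose linear index drives an exponential survival hazard.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the tissue composition of a progression series (46 normal,
#' 22 DCIS, 186 IBC) at a desk-scale probe count. Background CpGs draw their
#' means from a bimodal island-low / open-sea-high mixture with high Beta
#' precision; planted signature CpGs are variably methylated (means uniform
#' on 0.3–0.7, low precision), the regime in which a methylation marker can
#' carry prognostic information at all.
#'
#' @param n_normal,n_dcis,n_ibc samples per tissue group.
#' @param n_cpgs total probes.
#' @param n_diff_normal_dcis,n_diff_dcis_ibc planted differential CpGs for
#'   the two progression contrasts (disjoint sets).
#' @param effect_size beta shift of planted differential CpGs (fraction,
#'   in \[0, 0.5\]); the shift direction points away from the nearer boundary.
#' @param n_eqtm planted CpG–gene expression couplings, one per gene; must
#'   not exceed the number of genes.
#' @param eqtm_slope magnitude of the coupling (expression units per beta
#'   unit); the sign is negative for promoter-subregion CpGs (TSS1500,
#'   TSS200, 5'UTR, first exon) and positive for Body/3'UTR CpGs.
#' @param n_signature planted prognostic CpGs (a subset of the eQTM CpGs, so
#'   that expression-based pre-selection can retain them).
#' @param signature_coef_range magnitude range of the true signature
#'   coefficients (index units per beta unit), signs random.
#' @param log_hr_per_index_unit log hazard ratio per unit of the true index.
#' @param censor_rate target censoring fraction in \[0, 1); censoring is an
#'   independent exponential with rate `baseline_hazard * cr / (1 - cr)`.
#' @param baseline_hazard events per month at index = cohort mean; default
#'   gives a 60-month median survival.
#' @param expr_noise_sd residual SD of expression values.
#' @param dispersion_null,dispersion_signature Beta precision (a + b) of
#'   background and signature CpGs.
#' @param frac_intergenic fraction of probes not annotated to any gene.
#' @param cpgs_per_gene probes annotated per gene.
#' @param seed master seed; every derived draw is deterministic given it.
#' @return a `simulate_config` list.
#' @export
simulate_config <- function(n_normal = 46, n_dcis = 22, n_ibc = 186,
                            n_cpgs = 2000,
                            n_diff_normal_dcis = 150, n_diff_dcis_ibc = 50,
                            effect_size = 0.2,
                            n_eqtm = 100, eqtm_slope = 3,
                            n_signature = 10,
                            signature_coef_range = c(2, 4),
                            log_hr_per_index_unit = 1.5,
                            censor_rate = 0.5,
                            baseline_hazard = log(2) / 60,
                            expr_noise_sd = 0.4,
                            dispersion_null = 50, dispersion_signature = 8,
                            frac_intergenic = 0.1, cpgs_per_gene = 8,
                            seed = 1) {
  cfg <- list(n_normal = n_normal, n_dcis = n_dcis, n_ibc = n_ibc,
              n_cpgs = n_cpgs,
              n_diff_normal_dcis = n_diff_normal_dcis,
              n_diff_dcis_ibc = n_diff_dcis_ibc,
              effect_size = effect_size,
              n_eqtm = n_eqtm, eqtm_slope = eqtm_slope,
              n_signature = n_signature,
              signature_coef_range = signature_coef_range,
              log_hr_per_index_unit = log_hr_per_index_unit,
              censor_rate = censor_rate,
              baseline_hazard = baseline_hazard,
              expr_noise_sd = expr_noise_sd,
              dispersion_null = dispersion_null,
              dispersion_signature = dispersion_signature,
              frac_intergenic = frac_intergenic,
              cpgs_per_gene = cpgs_per_gene,
              seed = seed)
  counts <- c(n_normal, n_dcis, n_ibc, n_cpgs, n_diff_normal_dcis,
              n_diff_dcis_ibc, n_eqtm, n_signature)
  if (any(counts < 0)) stopf("counts must be >= 0")
  if (effect_size < 0 || effect_size > 0.5)
    stopf("effect_size must be in [0, 0.5]")
  if (censor_rate < 0 || censor_rate >= 1)
    stopf("censor_rate must be in [0, 1)")
  n_genic <- n_cpgs - round(frac_intergenic * n_cpgs)
  n_genes <- ceiling(n_genic / cpgs_per_gene)
  if (n_diff_normal_dcis + n_diff_dcis_ibc + n_eqtm > n_cpgs)
    stopf("infeasible config: planted CpG counts exceed n_cpgs")
  if (n_eqtm > n_genes)
    stopf("infeasible config: n_eqtm (%d) exceeds available genes (%d)",
          n_eqtm, n_genes)
  if (n_signature > n_eqtm)
    stopf("infeasible config: n_signature exceeds n_eqtm")
  structure(cfg, class = "simulate_config")
}

# The planted structure: annotation, baseline means, planted sets and their
# effects. Deterministic given cfg$seed; shared between cohort realizations
# so that two cohorts carry the same truth.
simulate_plan <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1L), {
    p <- cfg$n_cpgs
    probe_ids <- sprintf("cg%08d", seq_len(p))
    n_inter <- round(cfg$frac_intergenic * p)
    n_genic <- p - n_inter
    n_genes <- ceiling(n_genic / cfg$cpgs_per_gene)
    gene_ids <- sprintf("GENE%04d", seq_len(n_genes))

    gene_chr <- paste0("chr", (seq_len(n_genes) - 1L) %% 22L + 1L)
    idx_on_chr <- stats::ave(seq_len(n_genes), gene_chr, FUN = seq_along)
    gene_tss <- 1e6 + idx_on_chr * 2e5
    gene_strand <- sample(c("+", "-"), n_genes, replace = TRUE)

    genic <- seq_len(n_genic)
    gene_of <- rep(seq_len(n_genes), each = cfg$cpgs_per_gene)[genic]
    sub_of <- SUBREGIONS[(stats::ave(genic, gene_of, FUN = seq_along) - 1L) %% 6L + 1L]
    d_ranges <- list(TSS1500 = c(-1500, -201), TSS200 = c(-200, 0),
                     "5UTR" = c(1, 300), FirstExon = c(301, 600),
                     Body = c(601, 5000), "3UTR" = c(5001, 6000))
    tss_distance <- vapply(seq_along(genic), function(i) {
      r <- d_ranges[[sub_of[i]]]
      round(stats::runif(1, r[1], r[2]))
    }, numeric(1))
    strand_sign <- ifelse(gene_strand[gene_of] == "+", 1, -1)
    ann <- data.frame(
      probe_id = probe_ids,
      chromosome = c(gene_chr[gene_of],
                     paste0("chr", rep(1:22, length.out = n_inter))[seq_len(n_inter)]),
      position = c(pmax(1, gene_tss[gene_of] + strand_sign * tss_distance),
                   round(stats::runif(n_inter, 5e7, 6e7))),
      strand = c(gene_strand[gene_of], sample(c("+", "-"), n_inter, replace = TRUE)),
      gene = c(gene_ids[gene_of], rep("", n_inter)),
      subregion = c(sub_of, rep("Intergenic", n_inter)),
      tss_distance = c(tss_distance, rep(NA_real_, n_inter)),
      stringsAsFactors = FALSE)
    tss <- data.frame(gene = gene_ids, chromosome = gene_chr, tss = gene_tss,
                      strand = gene_strand, stringsAsFactors = FALSE)

    # planted sets: one eQTM CpG per gene, signature = first n_signature of
    # them; differential sets drawn from the remaining probes, disjoint
    eqtm_gene <- sample(n_genes, cfg$n_eqtm)
    eqtm_idx <- vapply(eqtm_gene, function(g) {
      cand <- genic[gene_of == g]
      cand[sample.int(length(cand), 1)]
    }, integer(1))
    sig_idx <- eqtm_idx[seq_len(cfg$n_signature)]
    rest <- setdiff(seq_len(p), eqtm_idx)
    diff_nd <- sort(sample(rest, cfg$n_diff_normal_dcis))
    rest <- setdiff(rest, diff_nd)
    diff_di <- sort(sample(rest, cfg$n_diff_dcis_ibc))

    # baseline means: bimodal background, variable signature CpGs
    low <- stats::runif(p) < 0.5
    mu <- ifelse(low, stats::rbeta(p, 2, 10), stats::rbeta(p, 10, 2))
    mu[sig_idx] <- stats::runif(length(sig_idx), 0.3, 0.7)
    nu <- rep(cfg$dispersion_null, p)
    nu[sig_idx] <- cfg$dispersion_signature

    # shift directions point away from the nearer boundary so the realized
    # group mean difference equals effect_size without clipping
    dir_nd <- ifelse(mu[diff_nd] <= 0.5, 1, -1)
    dir_di <- ifelse(mu[diff_di] <= 0.5, 1, -1)

    slope_sign <- ifelse(ann$subregion[eqtm_idx] %in% PROMOTER_SUBREGIONS, -1, 1)
    coef_mag <- stats::runif(cfg$n_signature, cfg$signature_coef_range[1],
                             cfg$signature_coef_range[2])
    sig_coef <- sample(c(-1, 1), cfg$n_signature, replace = TRUE) * coef_mag
    expr_intercept <- stats::rnorm(n_genes, 7, 1)

    list(cfg = cfg, probe_ids = probe_ids, ann = ann, tss = tss,
         gene_ids = gene_ids, mu = mu, nu = nu,
         eqtm_idx = eqtm_idx, eqtm_gene = gene_ids[eqtm_gene],
         eqtm_slope = slope_sign * cfg$eqtm_slope,
         sig_idx = sig_idx, sig_coef = sig_coef,
         diff_nd = diff_nd, dir_nd = dir_nd,
         diff_di = diff_di, dir_di = dir_di,
         expr_intercept = expr_intercept)
  })
}

# One cohort realization from a plan: sample betas, expression, clinical
# and survival. `batch_sd` adds a per-CpG cohort-level mean offset.
simulate_draw <- function(plan, seed, sample_prefix = "S", batch_sd = 0) {
  cfg <- plan$cfg
  with_seed(seed, {
    n <- cfg$n_normal + cfg$n_dcis + cfg$n_ibc
    tissue <- rep(c("normal", "DCIS", "IBC"),
                  c(cfg$n_normal, cfg$n_dcis, cfg$n_ibc))
    sample_ids <- sprintf("%s%04d", sample_prefix, seq_len(n))
    p <- cfg$n_cpgs

    mu <- matrix(plan$mu, p, n)
    if (length(plan$diff_nd)) {
      shift <- plan$dir_nd * cfg$effect_size
      mu[plan$diff_nd, tissue != "normal"] <-
        mu[plan$diff_nd, tissue != "normal"] + shift
    }
    if (length(plan$diff_di)) {
      shift <- plan$dir_di * cfg$effect_size
      mu[plan$diff_di, tissue == "IBC"] <-
        mu[plan$diff_di, tissue == "IBC"] + shift
    }
    if (batch_sd > 0) mu <- mu + stats::rnorm(p, 0, batch_sd)
    mu <- pmin(pmax(mu, 0.02), 0.98)

    nu <- matrix(plan$nu, p, n)
    beta <- matrix(stats::rbeta(p * n, c(mu) * c(nu), (1 - c(mu)) * c(nu)),
                   p, n, dimnames = list(plan$probe_ids, sample_ids))

    n_genes <- length(plan$gene_ids)
    expr <- matrix(plan$expr_intercept, n_genes, n,
                   dimnames = list(plan$gene_ids, sample_ids)) +
      matrix(stats::rnorm(n_genes * n, 0, cfg$expr_noise_sd), n_genes, n)
    if (length(plan$eqtm_idx)) {
      gi <- match(plan$eqtm_gene, plan$gene_ids)
      expr[gi, ] <- expr[gi, ] + plan$eqtm_slope * beta[plan$eqtm_idx, ]
    }

    if (length(plan$sig_idx)) {
      index <- drop(crossprod(beta[plan$sig_idx, , drop = FALSE], plan$sig_coef))
    } else {
      index <- stats::setNames(rep(0, n), sample_ids)
    }
    names(index) <- sample_ids
    lam0 <- cfg$baseline_hazard
    rate <- lam0 * exp(cfg$log_hr_per_index_unit * (index - mean(index)))
    t_event <- stats::rexp(n, rate)
    if (cfg$censor_rate > 0) {
      t_cens <- stats::rexp(n, lam0 * cfg$censor_rate / (1 - cfg$censor_rate))
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    clinical <- data.frame(
      sample_id = sample_ids, tissue = tissue,
      time = time, event = event,
      er = sample(c("pos", "neg"), n, replace = TRUE, prob = c(0.7, 0.3)),
      tp53 = sample(c("wt", "mut"), n, replace = TRUE, prob = c(0.7, 0.3)),
      t_status = sample(c("1", "2", "3or4"), n, replace = TRUE,
                        prob = c(0.4, 0.4, 0.2)),
      node = sample(c("neg", "pos"), n, replace = TRUE, prob = c(0.6, 0.4)),
      pam50 = ifelse(tissue == "normal", NA_character_,
                     sample(c("LumA", "LumB", "Her2", "Basal", "Normal"),
                            n, replace = TRUE)),
      stringsAsFactors = FALSE)

    truth <- structure(list(
      diff_normal_dcis = data.frame(probe_id = plan$probe_ids[plan$diff_nd],
                                    direction = plan$dir_nd,
                                    stringsAsFactors = FALSE),
      diff_dcis_ibc = data.frame(probe_id = plan$probe_ids[plan$diff_di],
                                 direction = plan$dir_di,
                                 stringsAsFactors = FALSE),
      eqtm = data.frame(probe_id = plan$probe_ids[plan$eqtm_idx],
                        gene = plan$eqtm_gene, slope = plan$eqtm_slope,
                        stringsAsFactors = FALSE),
      signature = data.frame(probe_id = plan$probe_ids[plan$sig_idx],
                             coefficient = plan$sig_coef,
                             stringsAsFactors = FALSE),
      index = index), class = "planted_truth")

    structure(list(beta = beta, expression = expr, clinical = clinical,
                   annotation = plan$ann, tss = plan$tss, truth = truth,
                   config = cfg),
              class = "meth_cohort")
  })
}

#' Simulate a synthetic methylation cohort with planted ground truth
#'
#' Generates a beta matrix, a coupled expression matrix, a clinical table
#' with survival, a manifest-style CpG annotation, a gene TSS table, and a
#' `truth` record of everything planted. Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulate_config()].
#' @return a `meth_cohort` list: `beta` (probes x samples), `expression`
#'   (genes x samples), `clinical`, `annotation`, `tss`, `truth`, `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulate_config(n_normal = 10, n_dcis = 5,
#'                                           n_ibc = 10, n_cpgs = 200,
#'                                           n_diff_normal_dcis = 10,
#'                                           n_diff_dcis_ibc = 5,
#'                                           n_eqtm = 10, n_signature = 3))
#' dim(cohort$beta)
simulate_cohort <- function(cfg = simulate_config()) {
  stopifnot(inherits(cfg, "simulate_config"))
  plan <- simulate_plan(cfg)
  simulate_draw(plan, derive_seed(cfg$seed, 2L))
}

#' Simulate two cohorts sharing the same planted truth
#'
#' Emulates a dual-cohort design (e.g. fresh-frozen discovery plus FFPE
#' validation): one planted structure, two independent sample realizations
#' with an additive per-CpG batch offset per cohort. Used to exercise
#' two-cohort concordance filtering of differential methylation calls.
#'
#' @param cfg a [simulate_config()].
#' @param batch_sd SD of the per-CpG cohort-level mean offset (beta units).
#' @return list of two `meth_cohort` objects (`a`, `b`) with identical
#'   `truth$diff_*` tables.
#' @export
simulate_two_cohorts <- function(cfg = simulate_config(), batch_sd = 0.02) {
  stopifnot(inherits(cfg, "simulate_config"))
  plan <- simulate_plan(cfg)
  list(a = simulate_draw(plan, derive_seed(cfg$seed, 101L), "A", batch_sd),
       b = simulate_draw(plan, derive_seed(cfg$seed, 102L), "B", batch_sd))
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat("Synthetic methylation cohort\n")
  cat(sprintf("  %d probes x %d samples (%s)\n", nrow(x$beta), ncol(x$beta),
              paste(sprintf("%d %s", table(x$clinical$tissue)[unique(x$clinical$tissue)],
                            unique(x$clinical$tissue)), collapse = ", ")))
  cat(sprintf("  planted: %d + %d differential CpGs, %d eQTM pairs, %d signature CpGs\n",
              nrow(x$truth$diff_normal_dcis), nrow(x$truth$diff_dcis_ibc),
              nrow(x$truth$eqtm), nrow(x$truth$signature)))
  invisible(x)
}
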