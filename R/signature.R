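# Consensus Lasso-Cox prognostic signature.
#
# Procedure: (1) pre-select CpGs whose methylation correlates with the
# expression of a nearby gene at nominal p < 0.05; (2) fit an L1-penalized
# Cox model to the pre-selected betas, repeating the cross-validated fit
# 100 times with fresh random fold assignments; (3) keep the probes present
# (nonzero) in at least 80% of the runs, with coefficients averaged over
# the runs where the probe was present; (4) score patients with the linear
# risk index index_i = sum_g beta_g * X_gi and dichotomize at the training
# median, carried unchanged to validation cohorts.

#' Pre-select probes by expression correlation
#'
#' Keeps the probes with at least one cis correlation at nominal (raw)
#' p < `alpha` — the "any significant pair" rule.
#'
#' @param corr output of [correlate_pairs()] on the same cohort.
#' @param alpha nominal p-value threshold (default 0.05).
#' @return character vector of probe ids.
#' @export
preselect_probes <- function(corr, alpha = 0.05) {
  if (!all(c("probe_id", "p_raw") %in% names(corr)))
    stopf("corr must carry probe_id and p_raw columns")
  sel <- sort(unique(corr$probe_id[corr$p_raw < alpha]))
  if (length(sel) == 0)
    stopf("no probe passed pre-selection at alpha = %g; increase alpha", alpha)
  sel
}

#' L1-penalized Cox regression at a fixed penalty
#'
#' Coordinate-descent fit of the Lasso Cox partial likelihood (via glmnet)
#' at the requested `lambda`, with exact zeros from soft-thresholding. The
#' penalty is applied on the raw beta scale (`standardize = FALSE` by
#' default) so that coefficients share the units of the risk index formula.
#' At `lambda = 0` the fit coincides with the unpenalized partial-likelihood
#' maximizer.
#'
#' @param x samples x probes matrix (no missing values).
#' @param time,event survival outcome.
#' @param lambda penalty weight (>= 0).
#' @param standardize standardize columns internally before penalization
#'   (coefficients are always returned on the raw scale).
#' @return named coefficient vector (exact zeros included).
#' @export
lasso_cox <- function(x, time, event, lambda, standardize = FALSE) {
  if (anyNA(x)) stopf("missing values in x")
  if (lambda < 0) stopf("lambda must be >= 0")
  check_surv(time, event)
  y <- cbind(time = time, status = event)
  # warm-started path descending to the requested lambda keeps the
  # coordinate descent stable even at (near-)zero penalty
  lam_max <- max(glmnet::glmnet(x, y, family = "cox",
                                standardize = standardize,
                                nlambda = 5)$lambda, lambda * 2, 1e-3)
  path <- exp(seq(log(lam_max), log(max(lambda, lam_max * 1e-5)),
                  length.out = 30))
  path[length(path)] <- lambda
  fit <- glmnet::glmnet(x, y, family = "cox", standardize = standardize,
                        lambda = path, thresh = 1e-14, maxit = 10^6)
  if (fit$jerr != 0) warnf("glmnet convergence flag %d", fit$jerr)
  cf <- glmnet::coef.glmnet(fit, s = lambda, exact = TRUE, x = x, y = y,
                            standardize = standardize, thresh = 1e-14,
                            maxit = 10^6)
  stats::setNames(as.numeric(cf), rownames(cf))
}

# Aggregate per-run supports and coefficients into the consensus signature.
# support: runs x probes logical; coefs: runs x probes numeric.
# A probe is a member when its presence fraction is >= threshold (the
# 80-of-100 boundary is inclusive); its coefficient is the mean over the
# runs where it was nonzero.
consensus_aggregate <- function(support, coefs, presence_threshold) {
  presence <- colMeans(support)
  member <- presence >= presence_threshold - 1e-12
  coefficients <- vapply(which(member), function(j)
    mean(coefs[support[, j], j]), numeric(1))
  list(probes = colnames(support)[member],
       coefficients = stats::setNames(coefficients,
                                      colnames(support)[member]),
       presence = presence)
}

#' Fit a consensus Lasso-Cox methylation signature
#'
#' The central fitting function of the package. Runs `n_runs` repetitions
#' of cross-validated L1-penalized Cox regression on the probe betas; the
#' only randomness across runs is the fold reassignment. Each run selects
#' its penalty by `lambda_rule` and records the nonzero probe set. Probes
#' present in at least `presence_threshold` of the runs form the signature;
#' their coefficients are the means over the runs where they were present.
#' The training risk index and its median cut are stored so the signature
#' can be applied unchanged to validation cohorts.
#'
#' @param x samples x probes beta matrix (pre-selected; no missing values).
#' @param time,event survival outcome (breast-cancer-specific death).
#' @param n_runs repetitions (default 100).
#' @param presence_threshold presence fraction for membership (default 0.80).
#' @param cv_folds folds per run (default 10); the number of events must be
#'   at least `cv_folds`.
#' @param lambda_rule `"lambda.1se"` (default; the sparsest penalty within
#'   one standard error of the minimum cross-validated deviance) or
#'   `"lambda.min"`.
#' @param standardize penalize on a standardized scale (default `FALSE`:
#'   the penalty acts on raw beta units, matching the index formula).
#' @param nlambda,lambda_min_ratio shared penalty path (computed once on
#'   the full data and reused across runs).
#' @param seed master seed; per-run fold seeds are derived from it.
#' @return a `meth_signature` object: `probes`, `coefficients`, `presence`
#'   (per input probe), `index` (training), `cut` (training median),
#'   `groups` (training risk groups), `config`.
#' @export
meth_signature <- function(x, time, event, n_runs = 100,
                           presence_threshold = 0.80, cv_folds = 10,
                           lambda_rule = c("lambda.1se", "lambda.min"),
                           standardize = FALSE,
                           nlambda = 50, lambda_min_ratio = 0.05,
                           seed = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  if (anyNA(x)) stopf("missing values in x; impute first")
  check_surv(time, event)
  if (n_runs < 1) stopf("n_runs must be >= 1")
  if (presence_threshold <= 0 || presence_threshold > 1)
    stopf("presence_threshold must be in (0, 1]")
  if (sum(event) < cv_folds)
    stopf("need at least cv_folds (%d) events, have %d", cv_folds, sum(event))
  if (is.null(colnames(x))) stopf("x needs probe column names")
  n <- nrow(x)
  y <- cbind(time = time, status = event)
  path <- glmnet::glmnet(x, y, family = "cox", standardize = standardize,
                         nlambda = nlambda,
                         lambda.min.ratio = lambda_min_ratio)$lambda
  support <- matrix(FALSE, n_runs, ncol(x), dimnames = list(NULL, colnames(x)))
  coefs <- matrix(0, n_runs, ncol(x))
  for (r in seq_len(n_runs)) {
    foldid <- with_seed(derive_seed(seed, r),
                        sample(rep(seq_len(cv_folds), length.out = n)))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                            lambda = path, standardize = standardize)
    cf <- as.numeric(glmnet::coef.glmnet(cv, s = lambda_rule))
    support[r, ] <- cf != 0
    coefs[r, ] <- cf
  }
  cons <- consensus_aggregate(support, coefs, presence_threshold)
  if (length(cons$probes) == 0)
    warnf("no probe reached the presence threshold: empty signature")
  index <- if (length(cons$probes)) {
    drop(x[, cons$probes, drop = FALSE] %*% cons$coefficients)
  } else {
    stats::setNames(rep(0, n), rownames(x))
  }
  names(index) <- rownames(x)
  cut <- stats::median(index)
  obj <- list(probes = cons$probes, coefficients = cons$coefficients,
              presence = cons$presence, index = index, cut = cut,
              n = n, n_event = sum(event),
              config = list(n_runs = n_runs,
                            presence_threshold = presence_threshold,
                            cv_folds = cv_folds, lambda_rule = lambda_rule,
                            standardize = standardize, nlambda = nlambda,
                            lambda_min_ratio = lambda_min_ratio,
                            seed = seed))
  class(obj) <- "meth_signature"
  obj
}

#' @export
print.meth_signature <- function(x, ...) {
  cat(sprintf("Consensus Lasso-Cox methylation signature: %d CpGs (%d runs, presence >= %.0f%%)\n",
              length(x$probes), x$config$n_runs,
              100 * x$config$presence_threshold))
  if (length(x$probes)) {
    tab <- data.frame(coefficient = round(x$coefficients, 4),
                      presence = x$presence[x$probes],
                      row.names = x$probes)
    print(tab)
  }
  cat(sprintf("training: n = %d, events = %d, median index cut = %.4f\n",
              x$n, x$n_event, x$cut))
  invisible(x)
}

#' @export
summary.meth_signature <- function(object, ...) {
  print(object)
  cat("\nProbes closest to the presence threshold:\n")
  near <- sort(object$presence, decreasing = TRUE)
  print(round(utils::head(near[near > 0], 15), 3))
  invisible(object)
}

#' @export
coef.meth_signature <- function(object, ...) object$coefficients

#' @export
plot.meth_signature <- function(x, ...) {
  if (!length(x$probes)) { message("empty signature"); return(invisible(x)) }
  ord <- order(x$coefficients)
  graphics::barplot(x$coefficients[ord], horiz = TRUE, las = 1,
                    names.arg = x$probes[ord],
                    xlab = "coefficient (index units per beta unit)",
                    main = "Consensus signature", ...)
  invisible(x)
}

#' Apply a signature to new samples
#'
#' @param object a `meth_signature`.
#' @param newdata beta matrix, probes x samples (all signature probes must
#'   be present).
#' @param type `"index"` (linear risk index) or `"group"` (high/low at the
#'   stored training cut).
#' @param cut override the dichotomization cut (default: training median).
#' @param ... unused.
#' @return numeric index vector or a risk-group data.frame (see
#'   [assign_risk_groups()]).
#' @export
predict.meth_signature <- function(object, newdata,
                                   type = c("index", "group"),
                                   cut = NULL, ...) {
  type <- match.arg(type)
  idx <- compute_index(newdata, object)
  if (type == "index") return(idx)
  assign_risk_groups(idx, cut = cut %||% object$cut)
}

#' Linear risk index
#'
#' `index_i = sum_g beta_g * X_gi`: the exact linear combination of the
#' signature coefficients with the raw beta values — no centering or
#' rescaling.
#'
#' @param m beta matrix, probes x samples.
#' @param signature a `meth_signature` or a named coefficient vector.
#' @return named numeric vector, one index per sample.
#' @export
#' @examples
#' m <- matrix(c(1, 1), 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
#' compute_index(m, c(cg1 = 0.5, cg2 = -0.2))  # 0.3
compute_index <- function(m, signature) {
  cf <- if (inherits(signature, "meth_signature")) signature$coefficients
        else signature
  if (is.null(names(cf)) || length(cf) == 0)
    stopf("signature must be a non-empty named coefficient vector")
  check_matrix(m, "beta matrix")
  missing <- setdiff(names(cf), rownames(m))
  if (length(missing))
    stopf("signature probe(s) absent from matrix: %s",
          paste(missing, collapse = ", "))
  drop(crossprod(m[names(cf), , drop = FALSE], cf))
}

#' Dichotomize a risk index into high- and low-risk groups
#'
#' High risk = index above the cut, low risk = at or below. The default cut
#' is the median of the supplied indices; a numeric cut (e.g. a training
#' median carried to a validation cohort) is used as-is.
#'
#' @param index named numeric index vector (>= 2 samples).
#' @param cut `"median"` or a numeric value.
#' @return data.frame (`sample_id`, `index`, `group` factor low/high) with
#'   attribute `cut`.
#' @export
assign_risk_groups <- function(index, cut = "median") {
  if (length(index) < 2) stopf("need >= 2 samples")
  cut_value <- if (identical(cut, "median")) stats::median(index)
               else as.numeric(cut)
  group <- factor(ifelse(index > cut_value, "high", "low"),
                  levels = c("low", "high"))
  if (length(unique(group)) == 1)
    warnf("all samples fall in one risk group")
  out <- data.frame(sample_id = names(index) %||% seq_along(index),
                    index = unname(index), group = group,
                    stringsAsFactors = FALSE)
  attr(out, "cut") <- cut_value
  out
}

#' Evaluate a risk classification against clinical outcome
#'
#' Kaplan-Meier curves and log-rank p for the high/low groups, the
#' univariate hazard ratio of high vs low risk, a multivariate Cox model
#' adjusting for ER status, TP53 mutation, T status (indicators for level 2
#' and "3 or 4" against reference 1) and lymph node status, the
#' proportional-hazards diagnostic, and the four-stratum node x risk
#' stratification.
#'
#' @param risk risk-group data.frame from [assign_risk_groups()].
#' @param clinical clinical table sharing `sample_id`.
#' @param covariates adjustment columns present in `clinical` (subset of
#'   er, tp53, t_status, node); missing covariate values are handled
#'   complete-case with a message.
#' @return a `signature_eval` list: `km`, `logrank`, `cox_univariate`,
#'   `cox_multivariate`, `ph`, `node_strata` (KM + log-rank over the four
#'   node x risk strata, when `node` is available).
#' @export
evaluate_signature <- function(risk, clinical,
                               covariates = c("er", "tp53", "t_status", "node")) {
  df <- merge(risk, clinical, by = "sample_id")
  if (nrow(df) < 2) stopf("risk table and clinical table share too few samples")
  km <- km_fit(df$time, df$event, df$group)
  lr <- logrank_test(df$time, df$event, df$group)
  uni <- cox_fit(df$time, df$event,
                 matrix(as.integer(df$group == "high"), ncol = 1,
                        dimnames = list(NULL, "risk_high")))
  covariates <- intersect(covariates, names(clinical))
  multi <- NULL
  if (length(covariates)) {
    X <- data.frame(row.names = seq_len(nrow(df)))
    if ("er" %in% covariates) X$er_pos <- as.integer(df$er == "pos")
    if ("tp53" %in% covariates) X$tp53_mut <- as.integer(df$tp53 == "mut")
    if ("t_status" %in% covariates) {
      X$t2 <- as.integer(df$t_status == "2")
      X$t3or4 <- as.integer(df$t_status == "3or4")
    }
    if ("node" %in% covariates) X$node_pos <- as.integer(df$node == "pos")
    X$risk_high <- as.integer(df$group == "high")
    multi <- cox_fit(df$time, df$event, as.matrix(X))
  }
  ph <- if (!is.null(multi) && multi$converged) ph_check(multi) else NULL
  node_strata <- NULL
  if ("node" %in% names(df)) {
    strat <- interaction(ifelse(df$node == "pos", "node+", "node-"),
                         df$group, sep = "/", drop = TRUE)
    ok <- !is.na(df$node)
    if (length(unique(strat[ok])) >= 2) {
      node_strata <- list(
        km = km_fit(df$time[ok], df$event[ok], strat[ok]),
        logrank = logrank_test(df$time[ok], df$event[ok],
                               as.character(strat[ok])))
    }
  }
  structure(list(km = km, logrank = lr, cox_univariate = uni,
                 cox_multivariate = multi, ph = ph,
                 node_strata = node_strata, n = nrow(df)),
            class = "signature_eval")
}

#' @export
print.signature_eval <- function(x, ...) {
  cat(sprintf("Signature evaluation on %d samples\n", x$n))
  cat(sprintf("  log-rank (high vs low): chi-square = %.3g, p = %.3g\n",
              x$logrank$statistic, x$logrank$p_value))
  cat(sprintf("  univariate HR (high vs low): %.3g (95%% CI %.3g-%.3g)\n",
              x$cox_univariate$hr, x$cox_univariate$ci_lower,
              x$cox_univariate$ci_upper))
  if (!is.null(x$cox_multivariate)) {
    cat("  adjusted model:\n")
    print(x$cox_multivariate)
  }
  if (!is.null(x$node_strata))
    cat(sprintf("  node x risk strata log-rank p = %.3g\n",
                x$node_strata$logrank$p_value))
  invisible(x)
}

#' Read a signature coefficient table
#'
#' Two tab-separated columns, `probe_id` and `coefficient` — the layout in
#' which published CpG signatures are printed. The package ships an
#' 18-CpG breast cancer prognostic methylation signature at
#' `system.file("extdata", "signature18.tsv", package = "methprog")`.
#'
#' @param path TSV path.
#' @return named coefficient vector.
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "coefficient") %in% names(df)))
    stopf("signature file needs columns probe_id, coefficient")
  stats::setNames(df$coefficient, df$probe_id)
}
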