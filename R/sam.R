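# SAM-style permutation differential methylation.
#
# Moderated statistic d = (difference in group means) / (pooled SE + s0),
# with the fudge factor s0 chosen over a percentile grid to stabilize the
# spread of d across the range of per-target standard errors; q-values from
# label permutations (expected false-call count over permutations at each |d|
# cutoff, then monotonized). A target is *called* only when both the FDR
# threshold (q < 0.01) and the effect threshold (|difference of group
# medians| >= 0.1) hold.

# per-target means / SSQ by group; values: targets x samples.
# Group order is canonical (C-locale sort) so the sign convention of the
# two-class statistic does not depend on sample order, and swapping the two
# group labels flips the sign of d.
group_stats <- function(values, labels) {
  labs <- sort(unique(labels), method = "radix")
  ns <- vapply(labs, function(l) sum(labels == l), integer(1))
  if (any(ns < 2)) stopf("each group needs >= 2 samples (group '%s' has %d)",
                         labs[which.min(ns)], min(ns))
  means <- vapply(labs, function(l) rowMeans(values[, labels == l, drop = FALSE]),
                  numeric(nrow(values)))
  ss <- vapply(labs, function(l) {
    v <- values[, labels == l, drop = FALSE]
    rowSums((v - rowMeans(v))^2)
  }, numeric(nrow(values)))
  if (nrow(values) == 1) { means <- rbind(means); ss <- rbind(ss) }
  list(labels = labs, n = ns, means = means, ss = ss)
}

#' SAM moderated statistic
#'
#' Two-class: `d = (mean2 - mean1) / (s + s0)` with `s` the pooled standard
#' error of the difference. Multiclass: an F-like ratio
#' `sqrt(between-group mean square) / (pooled within-group SD + s0)`.
#'
#' @param values targets x samples numeric matrix.
#' @param labels group label per sample (2 groups for `two_class`).
#' @param s0 fudge factor added to the denominator (same units as `s`).
#' @param mode `"two_class"` or `"multiclass"`.
#' @return list with per-target `d` and `s`.
#' @export
sam_statistic <- function(values, labels, s0 = 0,
                          mode = c("two_class", "multiclass")) {
  mode <- match.arg(mode)
  gs <- group_stats(values, labels)
  K <- length(gs$labels)
  N <- sum(gs$n)
  if (mode == "two_class") {
    if (K != 2) stopf("two_class mode needs exactly 2 groups, got %d", K)
    pooled_var <- (gs$ss[, 1] + gs$ss[, 2]) / (N - 2)
    s <- sqrt((1 / gs$n[1] + 1 / gs$n[2]) * pooled_var)
    d <- (gs$means[, 2] - gs$means[, 1]) / (s + s0)
  } else {
    if (K < 2) stopf("multiclass mode needs >= 2 groups")
    grand <- as.vector(gs$means %*% gs$n) / N
    between <- rowSums(sweep((gs$means - grand)^2, 2, gs$n, "*")) / (K - 1)
    s <- sqrt(rowSums(gs$ss) / (N - K))
    d <- sqrt(between) / (s + s0)
  }
  d[is.nan(d)] <- 0  # zero difference over zero spread
  list(d = unname(d), s = unname(s))
}

#' Estimate the SAM fudge factor s0
#'
#' Follows the standard SAM convention: candidate s0 values are the
#' percentiles \{0, 5, ..., 95\} of the per-target standard errors `s`; for
#' each candidate, targets are binned into quantile windows of `s` and the
#' coefficient of variation of `mad(d)` across windows is computed; the
#' candidate minimizing that CV is chosen.
#'
#' @param values targets x samples matrix (>= 10 targets).
#' @param labels group labels.
#' @param mode as in [sam_statistic()].
#' @param n_windows number of s-quantile windows (default 10, reduced when
#'   targets are few).
#' @return scalar s0 (>= 0).
#' @export
estimate_s0 <- function(values, labels, mode = c("two_class", "multiclass"),
                        n_windows = 10) {
  mode <- match.arg(mode)
  if (nrow(values) < 10) stopf("s0 estimation needs >= 10 targets")
  base <- sam_statistic(values, labels, s0 = 0, mode = mode)
  s <- base$s
  if (all(s < .Machine$double.eps)) {
    warnf("all-constant data: s0 set to 0")
    return(0)
  }
  num <- base$d * s  # numerator of d, reused for every candidate
  cand <- unique(stats::quantile(s, seq(0, 0.95, by = 0.05), names = FALSE))
  nw <- max(2, min(n_windows, floor(nrow(values) / 5)))
  breaks <- unique(stats::quantile(s, seq(0, 1, length.out = nw + 1),
                                   names = FALSE))
  win <- cut(s, breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(a) {
    d_a <- num / (s + a)
    mads <- tapply(d_a, win, stats::mad)
    mads <- mads[!is.na(mads)]
    if (mean(mads) < .Machine$double.eps) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  if (all(!is.finite(cv))) return(0)
  # smallest candidate within 5% of the minimal CV: when the profile is
  # flat (homoscedastic data) this resolves the tie toward no moderation
  cand[which(cv <= min(cv) * 1.05)[1]]
}

# all two-group label assignments (as label vectors) when enumerable
enumerate_two_class <- function(labels) {
  labs <- unique(labels)
  n1 <- sum(labels == labs[1])
  idx <- utils::combn(length(labels), n1)
  lapply(seq_len(ncol(idx)), function(j) {
    out <- rep(labs[2], length(labels))
    out[idx[, j]] <- labs[1]
    out
  })
}

#' SAM differential methylation test
#'
#' Computes the moderated statistic, permutation q-values, group medians and
#' the dual-threshold call flag. q-values: for each target's `|d|`, the
#' expected false-call count is the number of permuted `|d*|` values at or
#' above it, averaged across permutations, divided by the observed count at
#' that cutoff, capped at 1, and monotonized so q never increases with
#' `|d|`. (Averaging, rather than the median count, keeps the estimate
#' strictly positive under the complete null, where the median collapses to
#' zero for the top-ranked target about half the time.)
#' When fewer distinct label arrangements exist than `n_permutations`
#' (two-class), all are enumerated.
#'
#' @param m targets x samples matrix (betas or region medians).
#' @param groups group label per sample (named vector or aligned to columns).
#' @param n_permutations label permutations (default 100).
#' @param q_threshold FDR threshold (default 0.01).
#' @param median_diff_threshold minimum absolute difference of group medians
#'   (default 0.1 beta units); in multiclass mode, the maximum pairwise
#'   median difference is used.
#' @param mode `"two_class"` or `"multiclass"`.
#' @param s0 fudge factor; estimated via [estimate_s0()] when `NULL`.
#' @param seed permutation seed, recorded in the result.
#' @return a `sam_result` data.frame (target, d, s, q_value, group medians,
#'   median_diff, called) with attributes `s0`, `seed`, `n_permutations`,
#'   `enumerated`, `mode`, `groups`.
#' @export
sam_test <- function(m, groups, n_permutations = 100, q_threshold = 0.01,
                     median_diff_threshold = 0.1,
                     mode = c("two_class", "multiclass"),
                     s0 = NULL, seed = NULL) {
  mode <- match.arg(mode)
  check_matrix(m, "value matrix")
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  if (length(groups) != ncol(m)) stopf("groups must label every sample")
  if (anyNA(m)) stopf("missing values in matrix; impute or filter first")
  if (q_threshold <= 0 || q_threshold >= 1 ||
      median_diff_threshold <= 0 || median_diff_threshold >= 1)
    stopf("thresholds must be in (0, 1)")
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  groups <- as.character(groups)
  labs <- sort(unique(groups), method = "radix")  # same order as the statistic
  if (mode == "two_class" && length(labs) != 2)
    stopf("two_class mode needs exactly 2 group labels")

  if (is.null(s0)) s0 <- if (nrow(m) >= 10) estimate_s0(m, groups, mode) else 0
  obs <- sam_statistic(m, groups, s0, mode)

  # group medians and the effect filter
  med <- vapply(labs, function(l)
    apply(m[, groups == l, drop = FALSE], 1, stats::median),
    numeric(nrow(m)))
  if (nrow(m) == 1) med <- rbind(med)
  if (mode == "two_class") {
    median_diff <- med[, 2] - med[, 1]
  } else {
    # signed maximum pairwise difference of group medians
    median_diff <- apply(med, 1, function(x) {
      rng <- range(x)
      if (which.max(x) > which.min(x)) rng[2] - rng[1] else rng[1] - rng[2]
    })
  }

  # permutation null of |d|; permutations are drawn against a canonical
  # (sorted) sample order so q-values are invariant to column order
  can <- order(colnames(m))
  mc <- m[, can, drop = FALSE]
  groups_c <- groups[can]
  enumerated <- FALSE
  if (mode == "two_class" &&
      choose(ncol(m), sum(groups == labs[1])) <= n_permutations) {
    perms <- enumerate_two_class(groups_c)
    enumerated <- TRUE
    message(sprintf("enumerating all %d label arrangements", length(perms)))
  } else {
    perms <- with_seed(seed, lapply(seq_len(n_permutations),
                                    function(i) sample(groups_c)))
  }
  abs_obs <- abs(obs$d)
  counts <- vapply(perms, function(pl) {
    dp <- abs(sam_statistic(mc, pl, s0, mode)$d)
    sp <- sort(dp)
    length(sp) - findInterval(abs_obs, sp, left.open = TRUE)
  }, numeric(length(abs_obs)))
  if (length(abs_obs) == 1) counts <- rbind(counts)
  false_calls <- rowMeans(counts)
  sp_obs <- sort(abs_obs)
  n_called <- length(abs_obs) - findInterval(abs_obs, sp_obs, left.open = TRUE)
  q <- pmin(1, false_calls / n_called)
  # monotonize: q non-increasing in |d|
  ord <- order(abs_obs, decreasing = TRUE)
  q[ord] <- cummax(q[ord])

  called <- q < q_threshold & abs(median_diff) >= median_diff_threshold
  res <- data.frame(target = rownames(m), d = obs$d, s = obs$s,
                    q_value = q, median_diff = unname(median_diff),
                    called = called, stringsAsFactors = FALSE,
                    row.names = NULL)
  medians <- as.data.frame(med)
  names(medians) <- paste0("median_", labs)
  res <- cbind(res, medians)
  attr(res, "s0") <- s0
  attr(res, "seed") <- seed
  attr(res, "n_permutations") <- length(perms)
  attr(res, "enumerated") <- enumerated
  attr(res, "mode") <- mode
  attr(res, "groups") <- labs
  class(res) <- c("sam_result", "data.frame")
  res
}

#' Concordant differential methylation calls between two cohorts
#'
#' Intersection of the called targets of two analyses, kept only when the
#' direction (sign of the median difference) agrees. This is the
#' dual-cohort filter: only loci significant in both datasets, with the
#' same direction of change, are reported.
#'
#' @param a,b `sam_result` objects sharing a target id namespace.
#' @return data.frame (`target`, `direction` with +1 hyper / -1 hypo in the
#'   second group relative to the first).
#' @export
concordant_calls <- function(a, b) {
  ca <- a[a$called, c("target", "median_diff")]
  cb <- b[b$called, c("target", "median_diff")]
  mg <- merge(ca, cb, by = "target", suffixes = c("_a", "_b"))
  keep <- sign(mg$median_diff_a) == sign(mg$median_diff_b) &
    mg$median_diff_a != 0
  data.frame(target = mg$target[keep],
             direction = sign(mg$median_diff_a[keep]),
             stringsAsFactors = FALSE)
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("SAM differential methylation (%s): %d targets, %d called\n",
              attr(x, "mode"), nrow(x), sum(x$called)))
  cat(sprintf("  s0 = %.4g, %d permutations%s\n", attr(x, "s0"),
              attr(x, "n_permutations"),
              if (isTRUE(attr(x, "enumerated"))) " (exhaustive)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more targets\n", nrow(x) - 10))
  invisible(x)
}
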