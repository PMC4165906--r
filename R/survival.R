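# Survival machinery implemented from first principles: Kaplan-Meier
# product-limit estimator, the K-group log-rank test, Cox proportional
# hazards by Newton-Raphson on the Efron-corrected partial likelihood, and
# a proportional-hazards diagnostic based on scaled Schoenfeld residuals.
# Breast-cancer-specific death is the sole event type; other endings are
# treated as censoring by the caller.

check_surv <- function(time, event) {
  if (length(time) != length(event)) stopf("time and event lengths differ")
  if (any(is.na(time)) || any(is.na(event))) stopf("missing time/event values")
  if (any(time < 0)) stopf("negative survival times")
  if (!all(event %in% c(0, 1))) stopf("event must be 0/1")
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimator
#'
#' One survival curve per group, with simultaneous handling of tied event
#' times. On fully observed data the estimate equals the empirical survival
#' function.
#'
#' @param time follow-up times (>= 0).
#' @param event 1 = event, 0 = censored.
#' @param group optional group label per subject (single curve when `NULL`).
#' @return a `km_fit` object: list of per-group data.frames (`time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`).
#' @export
km_fit <- function(time, event, group = NULL) {
  check_surv(time, event)
  if (length(time) == 0) stopf("empty group")
  if (is.null(group)) group <- rep("all", length(time))
  if (length(group) != length(time)) stopf("group length mismatch")
  curves <- lapply(split(seq_along(time), group), function(idx) {
    if (length(idx) == 0) stopf("empty group")
    tt <- time[idx]; ee <- event[idx]
    ut <- sort(unique(tt))
    n_risk <- vapply(ut, function(u) sum(tt >= u), numeric(1))
    n_event <- vapply(ut, function(u) sum(tt == u & ee == 1), numeric(1))
    n_censor <- vapply(ut, function(u) sum(tt == u & ee == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(time = ut, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, surv = surv)
  })
  structure(list(curves = curves, groups = names(curves)), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  for (g in x$groups) {
    cv <- x$curves[[g]]
    cat(sprintf("%s: n = %d, events = %d, final S(t) = %.3f\n",
                g, cv$n_risk[1], sum(cv$n_event), cv$surv[nrow(cv)]))
  }
  invisible(x)
}

#' @export
plot.km_fit <- function(x, col = seq_along(x$groups), xlab = "Time",
                        ylab = "Survival probability", ...) {
  plot(NULL, xlim = c(0, max(vapply(x$curves, function(cv) max(cv$time), 1))),
       ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(x$groups)) {
    cv <- x$curves[[x$groups[i]]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)), col = col[i],
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = x$groups, col = col, lty = 1,
                   bty = "n")
  invisible(x)
}

# per-distinct-event-time bookkeeping shared by logrank
risk_table <- function(time, event, group) {
  labs <- sort(unique(group))
  et <- sort(unique(time[event == 1]))
  list(labs = labs, event_times = et,
       n_at_risk = vapply(labs, function(g)
         vapply(et, function(u) sum(time >= u & group == g), numeric(1)),
         numeric(length(et))),
       n_events = vapply(labs, function(g)
         vapply(et, function(u) sum(time == u & event == 1 & group == g),
                numeric(1)),
         numeric(length(et))))
}

#' Log-rank test
#'
#' Standard observed-versus-expected test over the shared distinct event
#' times, with the hypergeometric variance (including the tie-correction
#' factor (n-d)/(n-1) at each event time); chi-square on K-1 df.
#'
#' @param time,event as in [km_fit()].
#' @param group group label per subject (>= 2 groups).
#' @return a `logrank_test` list: `statistic`, `df`, `p_value`, `observed`,
#'   `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  group <- as.character(group)
  labs <- sort(unique(group))
  K <- length(labs)
  if (K < 2) stopf("log-rank needs >= 2 groups")
  if (sum(event) == 0) {
    warnf("no events: log-rank p set to 1")
    return(structure(list(statistic = 0, df = K - 1L, p_value = 1,
                          observed = stats::setNames(rep(0, K), labs),
                          expected = stats::setNames(rep(0, K), labs)),
                     class = "logrank_test"))
  }
  rt <- risk_table(time, event, group)
  nm <- matrix(rt$n_at_risk, ncol = K)   # event-times x groups
  dm <- matrix(rt$n_events, ncol = K)
  nj <- rowSums(nm); dj <- rowSums(dm)
  E <- sweep(nm / nj, 1, dj, "*")
  O <- colSums(dm); Eg <- colSums(E)
  # covariance of O - E over the first K-1 groups
  tie <- ifelse(nj > 1, (nj - dj) / (nj - 1), 0)
  V <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in seq_len(K)) {
    pk <- nm[, k] / nj; pl <- nm[, l] / nj
    V[k, l] <- sum(dj * tie * ((if (k == l) pk else 0) - pk * pl))
  }
  z <- (O - Eg)[-K]
  Vk <- V[-K, -K, drop = FALSE]
  stat <- tryCatch(drop(t(z) %*% solve(Vk, z)), error = function(e) {
    s <- svd(Vk); pos <- s$d > max(s$d) * 1e-10
    drop(t(z) %*% s$v[, pos, drop = FALSE] %*%
           ((t(s$u[, pos, drop = FALSE]) %*% z) / s$d[pos]))
  })
  structure(list(statistic = stat, df = K - 1L,
                 p_value = stats::pchisq(stat, K - 1, lower.tail = FALSE),
                 observed = stats::setNames(O, labs),
                 expected = stats::setNames(Eg, labs)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  print(data.frame(observed = x$observed, expected = round(x$expected, 2)))
  invisible(x)
}

# Efron partial likelihood, score and information at beta.
# Data must be pre-sorted by increasing time.
cox_eval <- function(beta, tt, ee, X) {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  theta <- exp(eta)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  ut <- unique(tt)  # ascending
  for (u in rev(ut)) {
    idx <- which(tt == u)
    thx <- theta[idx]
    Xu <- X[idx, , drop = FALSE]
    S0 <- S0 + sum(thx)
    S1 <- S1 + drop(crossprod(Xu, thx))
    S2 <- S2 + crossprod(Xu * sqrt(thx))
    D <- idx[ee[idx] == 1]
    d <- length(D)
    if (d == 0) next
    thd <- theta[D]
    Xd <- X[D, , drop = FALSE]
    Sd0 <- sum(thd)
    Sd1 <- drop(crossprod(Xd, thd))
    Sd2 <- crossprod(Xd * sqrt(thd))
    ll <- ll + sum(eta[D])
    U <- U + colSums(Xd)
    for (l in seq_len(d) - 1) {
      f <- l / d
      phi0 <- S0 - f * Sd0
      phi1 <- S1 - f * Sd1
      phi2 <- S2 - f * Sd2
      ll <- ll - log(phi0)
      mu <- phi1 / phi0
      U <- U - mu
      I <- I + phi2 / phi0 - tcrossprod(mu)
    }
  }
  list(loglik = ll, U = U, I = I)
}

#' Cox proportional hazards regression
#'
#' Newton-Raphson maximization of the partial likelihood with the Efron
#' correction for tied event times; standard errors from the observed
#' information, Wald confidence intervals, and the score test evaluated at
#' the null (which equals the log-rank statistic for a single binary
#' covariate on tie-free data).
#'
#' @param time,event as in [km_fit()].
#' @param x covariate matrix (n x p) or data.frame (factors expanded to
#'   treatment-coded indicators). Rows with missing covariates are dropped
#'   (complete-case) with a message.
#' @param max_iter Newton-Raphson iteration cap (default 100).
#' @param tol convergence tolerance on the log-likelihood change.
#' @return a `cox_fit` object: `coef`, `se`, `var`, `hr`, `ci_lower`,
#'   `ci_upper`, `z`, `p_value`, `loglik` (null, final), `score_test`,
#'   `n`, `n_event`, `iter`, `converged`, `monotone` (separation flag).
#' @export
cox_fit <- function(time, event, x, max_iter = 100, tol = 1e-9) {
  if (is.data.frame(x)) {
    x <- stats::model.matrix(~ ., data = x)[, -1, drop = FALSE]
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  cc <- stats::complete.cases(x)
  if (!all(cc)) {
    message(sprintf("dropping %d row(s) with missing covariates", sum(!cc)))
    time <- time[cc]; event <- event[cc]; x <- x[cc, , drop = FALSE]
  }
  check_surv(time, event)
  if (qr(scale(x, scale = FALSE))$rank < ncol(x))
    stopf("covariate matrix is not of full rank")
  ord <- order(time)
  tt <- time[ord]; ee <- event[ord]; X <- x[ord, , drop = FALSE]
  p <- ncol(X)
  beta <- numeric(p)
  ev <- cox_eval(beta, tt, ee, X)
  ll0 <- ev$loglik
  score_test <- tryCatch(drop(t(ev$U) %*% solve(ev$I, ev$U)),
                         error = function(e) NA_real_)
  converged <- FALSE; iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- solve(ev$I, ev$U)
    new_beta <- beta + step
    new_ev <- cox_eval(new_beta, tt, ee, X)
    halvings <- 0
    while (!is.finite(new_ev$loglik) || new_ev$loglik < ev$loglik - 1e-12) {
      halvings <- halvings + 1
      if (halvings > 25) break
      step <- step / 2
      new_beta <- beta + step
      new_ev <- cox_eval(new_beta, tt, ee, X)
    }
    delta <- new_ev$loglik - ev$loglik
    beta <- new_beta; ev <- new_ev
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  monotone <- any(abs(beta) > 15)
  if (!converged) warnf("Cox fit did not converge in %d iterations", max_iter)
  if (monotone) warnf("possible monotone likelihood (separation): |coef| > 15")
  V <- solve(ev$I)
  se <- sqrt(diag(V))
  zq <- stats::qnorm(0.975)
  fit <- list(coef = stats::setNames(beta, colnames(X)),
              se = stats::setNames(se, colnames(X)),
              var = V,
              hr = exp(beta),
              ci_lower = exp(beta - zq * se),
              ci_upper = exp(beta + zq * se),
              z = beta / se,
              p_value = 2 * stats::pnorm(-abs(beta / se)),
              loglik = c(null = ll0, final = ev$loglik),
              score_test = score_test,
              n = length(tt), n_event = sum(ee),
              iter = iter, converged = converged, monotone = monotone,
              data = list(time = tt, event = ee, x = X))
  class(fit) <- "cox_fit"
  fit
}

#' @export
coef.cox_fit <- function(object, ...) object$coef

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional hazards (Efron ties): n = %d, events = %d\n",
              x$n, x$n_event))
  tab <- data.frame(HR = x$hr,
                    `CI95` = sprintf("%.*g-%.*g", digits, x$ci_lower,
                                     digits, x$ci_upper),
                    p = signif(x$p_value, 3),
                    check.names = FALSE, row.names = names(x$coef))
  print(tab)
  if (!x$converged) cat("  (not converged)\n")
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, ...) {
  tab <- data.frame(coef = object$coef, se = object$se, z = object$z,
                    HR = object$hr, ci_lower = object$ci_lower,
                    ci_upper = object$ci_upper, p_value = object$p_value,
                    row.names = names(object$coef))
  structure(list(table = tab, loglik = object$loglik,
                 score_test = object$score_test, n = object$n,
                 n_event = object$n_event, converged = object$converged),
            class = "summary.cox_fit")
}

#' @export
print.summary.cox_fit <- function(x, ...) {
  print(x$table)
  cat(sprintf("loglik: %.3f (null %.3f); score test %.4g; n = %d, events = %d\n",
              x$loglik["final"], x$loglik["null"], x$score_test, x$n,
              x$n_event))
  invisible(x)
}

#' Predict linear risk scores from a Cox fit
#'
#' @param object a `cox_fit`.
#' @param newdata covariate matrix with the fitted columns; defaults to the
#'   training covariates.
#' @param ... unused.
#' @return linear predictor per subject (log-hazard scale, uncentered).
#' @export
predict.cox_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$data$x else {
    if (is.data.frame(newdata))
      newdata <- stats::model.matrix(~ ., data = newdata)[, -1, drop = FALSE]
    newdata[, names(object$coef), drop = FALSE]
  }
  drop(X %*% object$coef)
}

#' Residuals of a Cox fit
#'
#' Schoenfeld residuals (per event, Efron-averaged within tied times) or
#' martingale residuals (Breslow baseline hazard).
#'
#' @param object a `cox_fit`.
#' @param type `"schoenfeld"` or `"martingale"`.
#' @param ... unused.
#' @return matrix (events x covariates) for Schoenfeld; vector for
#'   martingale (ordered by increasing time).
#' @export
residuals.cox_fit <- function(object, type = c("schoenfeld", "martingale"),
                              ...) {
  type <- match.arg(type)
  tt <- object$data$time; ee <- object$data$event; X <- object$data$x
  theta <- exp(drop(X %*% object$coef))
  p <- ncol(X)
  ut <- unique(tt)
  S0 <- 0; S1 <- numeric(p)
  if (type == "schoenfeld") {
    out <- NULL; out_t <- numeric(0)
    for (u in rev(ut)) {
      idx <- which(tt == u)
      S0 <- S0 + sum(theta[idx])
      S1 <- S1 + drop(crossprod(X[idx, , drop = FALSE], theta[idx]))
      D <- idx[ee[idx] == 1]
      d <- length(D)
      if (d == 0) next
      thd <- theta[D]
      Sd0 <- sum(thd)
      Sd1 <- drop(crossprod(X[D, , drop = FALSE], thd))
      xbar <- rowMeans(matrix(vapply(seq_len(d) - 1, function(l)
        (S1 - (l / d) * Sd1) / (S0 - (l / d) * Sd0), numeric(p)), nrow = p))
      out <- rbind(X[D, , drop = FALSE] - rep(xbar, each = d), out)
      out_t <- c(rep(u, d), out_t)
    }
    colnames(out) <- colnames(X)
    attr(out, "time") <- out_t
    out
  } else {
    # cumulative Breslow hazard at each subject's end time
    haz <- numeric(length(ut))
    S0v <- numeric(length(ut))
    for (i in rev(seq_along(ut))) {
      idx <- which(tt == ut[i])
      S0 <- S0 + sum(theta[idx])
      S0v[i] <- S0
    }
    dcount <- vapply(ut, function(u) sum(tt == u & ee == 1), numeric(1))
    Lambda0 <- cumsum(dcount / S0v)
    ee - theta * Lambda0[match(tt, ut)]
  }
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' Per-covariate slope test of the scaled Schoenfeld residuals against a
#' transform of event time (default: the Kaplan-Meier transform
#' `1 - S(t-)`), plus a global chi-square over all covariates — the
#' Grambsch-Therneau construction.
#'
#' @param fit a converged `cox_fit`.
#' @param transform `"km"` (default), `"identity"` or `"rank"`.
#' @return a `ph_check` data.frame with one row per covariate plus a GLOBAL
#'   row: `rho` (correlation with transformed time; `NA` for GLOBAL),
#'   `chisq`, `df`, `p_value`.
#' @export
ph_check <- function(fit, transform = c("km", "identity", "rank")) {
  stopifnot(inherits(fit, "cox_fit"))
  transform <- match.arg(transform)
  p <- length(fit$coef)
  if (p == 0 || is.null(fit$data$x) || ncol(fit$data$x) == 0) {
    return(structure(data.frame(rho = numeric(), chisq = numeric(),
                                df = integer(), p_value = numeric()),
                     class = c("ph_check", "data.frame")))
  }
  S <- residuals(fit, "schoenfeld")
  et <- attr(S, "time")
  d <- nrow(S)
  g <- switch(transform,
              identity = et,
              rank = rank(et),
              km = {
                km <- km_fit(fit$data$time, fit$data$event)$curves[[1]]
                sv <- c(1, km$surv)  # left-continuous S(t-)
                1 - sv[match(et, km$time)]
              })
  x <- g - mean(g)
  V <- fit$var
  r2 <- S %*% V * d  # scaled Schoenfeld residuals (up to the +beta shift)
  num <- drop(crossprod(x, r2))
  chisq <- num^2 / (d * diag(V) * sum(x^2))
  rho <- suppressWarnings(stats::cor(x, r2))
  u <- drop(crossprod(S, x))
  chisq_g <- drop(t(u) %*% V %*% u) * d / sum(x^2)
  out <- data.frame(
    rho = c(drop(rho), NA),
    chisq = c(chisq, chisq_g),
    df = c(rep(1L, p), p),
    p_value = stats::pchisq(c(chisq, chisq_g), c(rep(1, p), p),
                            lower.tail = FALSE),
    row.names = c(names(fit$coef), "GLOBAL"))
  structure(out, class = c("ph_check", "data.frame"))
}

#' @export
print.ph_check <- function(x, ...) {
  cat("Proportional hazards check (scaled Schoenfeld residuals):\n")
  print.data.frame(round(as.data.frame(x), 4))
  invisible(x)
}
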