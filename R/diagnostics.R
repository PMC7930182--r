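#' Build a 2x2 confusion table
#'
#' Cross-tabulates binary test decisions against true responder status.
#' `tp` counts predicted-positive responders, `fp` predicted-positive
#' non-responders, `fn` predicted-negative responders, `tn`
#' predicted-negative non-responders.
#'
#' @param decision Logical vector, `TRUE` = test positive.
#' @param responder Logical vector, `TRUE` = responder (CR/PR).
#' @return A list of class `cx3_confusion` with fields `tp`, `fp`, `fn`,
#'   `tn`, `n`.
#' @export
confusion_table <- function(decision, responder) {
  keep <- !is.na(decision) & !is.na(responder)
  decision <- decision[keep]; responder <- responder[keep]
  if (length(decision) == 0) cx3_abort("no evaluable observations")
  if (length(decision) != length(responder)) {
    cx3_abort("`decision` and `responder` must have equal length")
  }
  out <- list(
    tp = sum(decision & responder), fp = sum(decision & !responder),
    fn = sum(!decision & responder), tn = sum(!decision & !responder)
  )
  out$n <- out$tp + out$fp + out$fn + out$tn
  structure(out, class = "cx3_confusion")
}

as_confusion <- function(x) {
  if (inherits(x, "cx3_confusion")) return(x)
  if (is.numeric(x) && length(x) == 4) {
    out <- list(tp = x[[1]], fp = x[[2]], fn = x[[3]], tn = x[[4]])
    out$n <- sum(x)
    return(structure(out, class = "cx3_confusion"))
  }
  cx3_abort("expected a cx3_confusion or a numeric (tp, fp, fn, tn)")
}

#' @export
print.cx3_confusion <- function(x, ...) {
  cat(sprintf("<cx3_confusion> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  invisible(x)
}

#' Diagnostic performance rates with Jeffreys intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)` and accuracy `(tp+tn)/n`, each with a Jeffreys 95%
#' interval. A rate with a zero denominator is reported as `NA` with an `NA`
#' interval; the others are still returned.
#'
#' @param ct A [confusion_table()] or numeric `(tp, fp, fn, tn)`.
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `metric`, `x`, `n`, `estimate`, `lower`,
#'   `upper`.
#' @examples
#' diagnostic_rates(c(12, 3, 1, 20))
#' @export
diagnostic_rates <- function(ct, level = 0.95) {
  ct <- as_confusion(ct)
  defs <- list(
    sensitivity = c(ct$tp, ct$tp + ct$fn),
    specificity = c(ct$tn, ct$tn + ct$fp),
    ppv = c(ct$tp, ct$tp + ct$fp),
    npv = c(ct$tn, ct$tn + ct$fn),
    accuracy = c(ct$tp + ct$tn, ct$n)
  )
  rows <- lapply(names(defs), function(m) {
    x <- defs[[m]][1]; n <- defs[[m]][2]
    if (n == 0) {
      tibble(metric = m, x = x, n = n, estimate = NA_real_,
             lower = NA_real_, upper = NA_real_)
    } else {
      ci <- jeffreys_interval(x, n, level)
      tibble(metric = m, x = x, n = n, estimate = x / n,
             lower = ci[1], upper = ci[2])
    }
  })
  dplyr::bind_rows(rows)
}

#' Jeffreys interval for a binomial proportion
#'
#' Central interval from the quantiles of `Beta(x + 1/2, n - x + 1/2)` (the
#' Jeffreys prior posterior). By the usual boundary convention the lower
#' limit is forced to 0 when `x = 0` and the upper to 1 when `x = n`.
#'
#' @param x Number of successes.
#' @param n Number of trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @return `c(lower, upper)`.
#' @export
jeffreys_interval <- function(x, n, level = 0.95) {
  if (n < 1 || x < 0 || x > n) cx3_abort("need 0 <= x <= n and n >= 1")
  if (level <= 0 || level >= 1) cx3_abort("`level` must be in (0, 1)")
  alpha <- (1 - level) / 2
  lower <- if (x == 0) 0 else qbeta(alpha, x + 0.5, n - x + 0.5)
  upper <- if (x == n) 1 else qbeta(1 - alpha, x + 0.5, n - x + 0.5)
  c(lower = lower, upper = upper)
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (tp * tn) / (fp * fn)` with the Woolf (log) interval
#' `exp(log OR +/- z * sqrt(1/tp + 1/fp + 1/fn + 1/tn))`, using the exact
#' normal quantile. When any cell is zero, 0.5 is added to all four cells
#' (Haldane-Anscombe) and the result is flagged.
#'
#' @inheritParams diagnostic_rates
#' @return A list with `or`, `lower`, `upper`, `haldane` (continuity flag).
#' @examples
#' odds_ratio_woolf(c(5, 1, 5, 16)) # or = 16, lower ~ 1.5
#' @export
odds_ratio_woolf <- function(ct, level = 0.95) {
  ct <- as_confusion(ct)
  cells <- c(ct$tp, ct$fp, ct$fn, ct$tn)
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / cells))
  list(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
       haldane = haldane)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table (the
#' standard two-sided definition, with a relative tolerance of 1e-7 on the
#' comparison).
#'
#' @inheritParams diagnostic_rates
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(ct) {
  ct <- as_confusion(ct)
  m <- ct$tp + ct$fn          # responders
  nn <- ct$fp + ct$tn         # non-responders
  k <- ct$tp + ct$fp          # predicted positive
  if (ct$n < 1) cx3_abort("empty table")
  support <- max(0, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  p_obs <- dhyper(ct$tp, m, nn, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Empirical ROC curve and AUC
#'
#' The empirical AUC is the probability that a random responder scores above
#' a random non-responder, counting ties as one half, computed over all
#' pairs. ROC points are generated at every threshold between distinct
#' observed scores with the positivity rule `score >= threshold`.
#'
#' @param scores Continuous scores, higher = more responder-like.
#' @param responder Logical responder labels.
#' @return A list with `auc` and `roc`, a tibble of `threshold`, `fpr`,
#'   `tpr` (including the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(scores, responder) {
  keep <- !is.na(scores) & !is.na(responder)
  scores <- scores[keep]; responder <- responder[keep]
  n1 <- sum(responder); n0 <- sum(!responder)
  if (n1 == 0 || n0 == 0) cx3_abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[responder]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- tibble(
    threshold = c(Inf, thr),
    tpr = vapply(c(Inf, thr), function(t) mean(scores[responder] >= t), 0),
    fpr = vapply(c(Inf, thr), function(t) mean(scores[!responder] >= t), 0)
  )
  list(auc = auc, roc = roc)
}

#' DeLong confidence interval for the empirical AUC
#'
#' Wald interval on the AUC using DeLong's structural-components variance,
#' truncated to `[0, 1]`. When the variance is degenerate (perfect or null
#' separation within components) the interval collapses to the point and is
#' flagged.
#'
#' @inheritParams roc_auc
#' @param level Confidence level, default 0.95.
#' @return A list with `auc`, `lower`, `upper`, `se`, `degenerate`.
#' @export
delong_ci <- function(scores, responder, level = 0.95) {
  keep <- !is.na(scores) & !is.na(responder)
  scores <- scores[keep]; responder <- responder[keep]
  x <- scores[responder]; y <- scores[!responder]
  n1 <- length(x); n0 <- length(y)
  if (n1 < 1 || n0 < 1) cx3_abort("both classes must be present")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)   # structural components over responders
  v01 <- colMeans(psi)   # ... over non-responders
  var_auc <- if (n1 > 1) stats::var(v10) / n1 else 0
  var_auc <- var_auc + if (n0 > 1) stats::var(v01) / n0 else 0
  se <- sqrt(var_auc)
  degenerate <- !is.finite(se) || se == 0
  z <- qnorm(1 - (1 - level) / 2)
  list(
    auc = auc,
    lower = max(0, auc - if (degenerate) 0 else z * se),
    upper = min(1, auc + if (degenerate) 0 else z * se),
    se = se, degenerate = degenerate
  )
}

#' Youden-optimal cut-point
#'
#' Searches the distinct observed scores as candidate cutoffs under the rule
#' `score >= cutoff` is positive, and returns the cutoff maximizing
#' `J = sensitivity + specificity - 1`. Ties are broken toward the smallest
#' cutoff (maximizing sensitivity); set `tie = "largest"` for the opposite
#' convention.
#'
#' @inheritParams roc_auc
#' @param tie `"smallest"` (default) or `"largest"` tie-break.
#' @return A list with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(scores, responder, tie = c("smallest", "largest")) {
  tie <- match.arg(tie)
  keep <- !is.na(scores) & !is.na(responder)
  scores <- scores[keep]; responder <- responder[keep]
  if (!any(responder) || all(responder)) cx3_abort("both classes must be present")
  n1 <- sum(responder); n0 <- sum(!responder)
  cand <- sort(unique(scores))
  tp <- vapply(cand, function(c) sum(scores[responder] >= c), 0L)
  tn <- vapply(cand, function(c) sum(scores[!responder] < c), 0L)
  # J compared in integer arithmetic so ties are exact, not float-noise
  jnum <- tp * n0 + tn * n1
  best <- if (tie == "smallest") which.max(jnum) else {
    length(jnum) + 1 - which.max(rev(jnum))
  }
  list(cutoff = cand[best], sensitivity = tp[best] / n1,
       specificity = tn[best] / n0, j = jnum[best] / (n1 * n0) - 1)
}

#' Univariate logistic regression of response on a score
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' [stats::glm()]). Perfect separation -- disjoint score ranges between the
#' classes -- is detected up front and flagged; in that case no coefficients
#' are returned and the empirical ROC should be used directly. Because the
#' fitted probability is a monotone transform of the score, the ROC (and
#' AUC) of the fitted probabilities equals that of the raw scores whenever
#' the slope is positive.
#'
#' @inheritParams roc_auc
#' @return A list with `separated`, and when not separated: `intercept`,
#'   `slope`, `fitted` (probabilities), `converged`.
#' @export
logistic_fit <- function(scores, responder) {
  keep <- !is.na(scores) & !is.na(responder)
  scores <- scores[keep]; responder <- responder[keep]
  if (!any(responder) || all(responder)) cx3_abort("both classes must be present")
  if (max(scores[!responder]) < min(scores[responder]) ||
      max(scores[responder]) < min(scores[!responder])) {
    return(list(separated = TRUE, intercept = NA_real_, slope = NA_real_,
                fitted = rep(NA_real_, length(scores)), converged = FALSE))
  }
  fit <- suppressWarnings(
    glm(responder ~ scores, family = binomial(), control = list(epsilon = 1e-10, maxit = 100))
  )
  list(separated = FALSE,
       intercept = unname(stats::coef(fit)[1]), slope = unname(stats::coef(fit)[2]),
       fitted = unname(stats::fitted(fit)), converged = fit$converged)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. The U statistic is reported for group
#' A. When both groups have at most 8 observations the two-sided p-value is
#' computed by exact enumeration over all assignments of the pooled values
#' (valid under ties; `p = min(1, 2 * min(P(U <= u), P(U >= u)))`); otherwise
#' the tie-corrected normal approximation with continuity correction is used.
#'
#' @param a,b Numeric vectors for the two groups.
#' @return A list with `u`, `p`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) cx3_abort("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled, ties.method = "average")
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na <= 8 && nb <= 8) {
    sets <- combn(na + nb, na)
    us <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    n <- na + nb
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  list(u = u, p = p, method = method)
}

#' Full diagnostic report for a score against responder status
#'
#' Assembles, for one landmark: the confusion table at `cutoff`, all five
#' rates with Jeffreys intervals, the Woolf odds-ratio interval, two-sided
#' Fisher p, empirical AUC with DeLong interval, the Youden-optimal
#' cut-point, and the logistic fit.
#'
#' @inheritParams roc_auc
#' @param cutoff Decision cutoff on the score scale, default 20.
#' @param level Confidence level, default 0.95.
#' @return A list of class `cx3_diagnostic_report`.
#' @export
diagnostic_report <- function(scores, responder, cutoff = 20, level = 0.95) {
  keep <- !is.na(scores) & !is.na(responder)
  scores <- scores[keep]; responder <- responder[keep]
  ct <- confusion_table(classify_score(scores, cutoff), responder)
  structure(list(
    cutoff = cutoff, level = level, n = ct$n,
    confusion = ct,
    rates = diagnostic_rates(ct, level),
    odds_ratio = odds_ratio_woolf(ct, level),
    fisher_p = fisher_exact(ct),
    auc = delong_ci(scores, responder, level),
    youden = youden_cutoff(scores, responder),
    logistic = logistic_fit(scores, responder)
  ), class = "cx3_diagnostic_report")
}

#' @export
print.cx3_diagnostic_report <- function(x, ...) {
  cat(sprintf("<cx3_diagnostic_report> n=%d, cutoff=%g\n", x$n, x$cutoff))
  print(x$confusion)
  r <- x$rates
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-11s %5.1f%% (%d/%d) [%.1f, %.1f]\n", r$metric[i],
                100 * r$estimate[i], r$x[i], r$n[i],
                100 * r$lower[i], 100 * r$upper[i]))
  }
  cat(sprintf("  OR %.1f [%.1f, %.1f]%s, Fisher p = %.4g\n",
              x$odds_ratio$or, x$odds_ratio$lower, x$odds_ratio$upper,
              if (x$odds_ratio$haldane) " (Haldane +0.5)" else "", x$fisher_p))
  cat(sprintf("  AUC %.3f [%.3f, %.3f]; Youden cutoff %.2f\n",
              x$auc$auc, x$auc$lower, x$auc$upper, x$youden$cutoff))
  invisible(x)
}
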