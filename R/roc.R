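#' Empirical ROC curve with AUC and DeLong confidence interval
#'
#' Higher scores are assumed to indicate the positive class. Sensitivity and
#' specificity are evaluated at every distinct score (predicted positive
#' when `score >= threshold`, plus a `+Inf` endpoint). The AUC is the
#' Mann-Whitney statistic: the fraction of (positive, negative) pairs where
#' the positive scores higher, ties counting one half — identical to the
#' trapezoidal area. The default CI uses the DeLong placement variance; a
#' stratified bootstrap is available.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, `TRUE` = positive class.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param level confidence level (default 0.95).
#' @param nboot bootstrap replicates when `ci_method = "bootstrap"`.
#' @param direction `"higher"` (default: higher score = positive),
#'   `"lower"` (scores are negated first), or `"auto"` (orientation chosen so
#'   the AUC is at least 0.5, as common for single markers whose sign is not
#'   known a priori; the choice is recorded in `direction`).
#' @return object of class `roc_result`: `thresholds` (ascending),
#'   `sensitivity`, `specificity`, `auc`, `auc_var`, `ci`, `ci_method`,
#'   `direction`, `n_pos`, `n_neg`, and the (`scores`, `labels`) used
#'   (after any negation).
#' @export
roc_curve <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                      level = 0.95, nboot = 2000,
                      direction = c("higher", "lower", "auto")) {
  ci_method <- match.arg(ci_method)
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  if (direction == "auto") {
    direction <- if (auc_mw(scores, labels) >= 0.5) "higher" else "lower"
  }
  if (direction == "lower") scores <- -scores
  thresholds <- c(sort(unique(scores)), Inf)
  sens <- vapply(thresholds, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(scores[!labels] < t), numeric(1))

  auc <- auc_mw(scores, labels)
  v <- delong_components(scores, labels)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (ci_method == "delong") {
    ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(v$var)))
  } else {
    pos <- scores[labels]; neg <- scores[!labels]
    boots <- vapply(seq_len(nboot), function(b) {
      auc_mw(c(sample(pos, n_pos, TRUE), sample(neg, n_neg, TRUE)),
             c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
    }, numeric(1))
    ci <- unname(stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  structure(
    list(thresholds = thresholds, sensitivity = sens, specificity = spec,
         auc = auc, auc_var = v$var, ci = ci, ci_method = ci_method,
         level = level, direction = direction, n_pos = n_pos, n_neg = n_neg,
         scores = scores, labels = labels),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f (%d%% CI %.3f-%.3f, %s), %d pos / %d neg\n",
              x$auc, round(100 * x$level), x$ci[1L], x$ci[2L], x$ci_method,
              x$n_pos, x$n_neg))
  invisible(x)
}

# Mann-Whitney AUC with ties counted 1/2 (rank formula)
auc_mw <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong placement values and AUC variance
delong_components <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                numeric(1))
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  list(v10 = v10, v01 = v01, var = s10 / m + s01 / n)
}

#' Paired DeLong test for the difference of two correlated AUCs
#'
#' Both score vectors must be evaluated on the same subjects (same labels).
#'
#' @param scores1,scores2 numeric score vectors.
#' @param labels logical vector, `TRUE` = positive.
#' @return list with `auc1`, `auc2`, `difference`, `se`, `z`, `p_value`.
#' @export
delong_paired_test <- function(scores1, scores2, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores1) & !is.na(scores2) & !is.na(labels)
  scores1 <- scores1[ok]; scores2 <- scores2[ok]; labels <- labels[ok]
  a1 <- auc_mw(scores1, labels); a2 <- auc_mw(scores2, labels)
  c1 <- delong_components(scores1, labels)
  c2 <- delong_components(scores2, labels)
  m <- sum(labels); n <- sum(!labels)
  cov10 <- if (m > 1) stats::cov(c1$v10, c2$v10) else 0
  cov01 <- if (n > 1) stats::cov(c1$v01, c2$v01) else 0
  var_diff <- c1$var + c2$var - 2 * (cov10 / m + cov01 / n)
  se <- sqrt(max(var_diff, 0))
  z <- if (se == 0) 0 else (a1 - a2) / se
  p <- if (se == 0 && a1 == a2) 1 else 2 * stats::pnorm(-abs(z))
  list(auc1 = a1, auc2 = a2, difference = a1 - a2, se = se, z = z,
       p_value = p)
}

#' Select an operating point on a ROC curve
#'
#' @param roc a `roc_result`.
#' @param rule `"youden"` (maximize sensitivity + specificity - 1),
#'   `"fixed_specificity"` (maximize sensitivity subject to specificity >=
#'   `value`), or `"fixed_sensitivity"` (maximize specificity subject to
#'   sensitivity >= `value`). Ties are broken toward higher specificity.
#' @param value the constraint for the fixed rules.
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden`, and
#'   the confusion counts `tp`, `fp`, `tn`, `fn` at that threshold.
#' @export
operating_point <- function(roc, rule = c("youden", "fixed_specificity",
                                          "fixed_sensitivity"),
                            value = NULL) {
  stopifnot(inherits(roc, "roc_result"))
  rule <- match.arg(rule)
  sens <- roc$sensitivity; spec <- roc$specificity
  if (rule == "youden") {
    j <- sens + spec - 1
    best <- which(j == max(j))
  } else {
    if (is.null(value)) stop("fixed rules need `value`", call. = FALSE)
    if (rule == "fixed_specificity") {
      cand <- which(spec >= value)
      if (!length(cand)) {
        stop(sprintf("specificity %.3f unattainable; best achievable is %.3f",
                     value, max(spec)), call. = FALSE)
      }
      best <- cand[sens[cand] == max(sens[cand])]
    } else {
      cand <- which(sens >= value)
      if (!length(cand)) {
        stop(sprintf("sensitivity %.3f unattainable; best achievable is %.3f",
                     value, max(sens)), call. = FALSE)
      }
      best <- cand[spec[cand] == max(spec[cand])]
    }
  }
  pick <- best[which.max(spec[best])]
  thr <- roc$thresholds[pick]
  pred <- roc$scores >= thr
  list(threshold = thr, sensitivity = sens[pick], specificity = spec[pick],
       youden = sens[pick] + spec[pick] - 1,
       tp = sum(pred & roc$labels), fp = sum(pred & !roc$labels),
       tn = sum(!pred & !roc$labels), fn = sum(!pred & roc$labels))
}
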