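#' Fit a logistic multi-marker panel
#'
#' Maximum-likelihood logistic regression of a binary outcome on the log2
#' relative quantities of the selected markers; the panel score is the
#' linear predictor. Complete separation is flagged but the score is still
#' returned (its ranking, hence the ROC curve, remains usable). Collinear
#' (aliased) markers are dropped with a warning, leaving the score
#' unchanged.
#'
#' @param em an `expression_matrix`.
#' @param marker_ids assay ids forming the panel.
#' @param outcome logical (or 0/1) vector aligned to `em$sample_ids`.
#' @param seed recorded in the model metadata (the fit is deterministic).
#' @param cv `"none"` (in-sample scores, the default) or `"loo"` to also
#'   compute leave-one-out cross-validated scores; with 3 predictors on a few
#'   dozen subjects in-sample AUC is optimistic, so both are exposed.
#' @return object of class `panel_model`: `marker_ids`, `coefficients`
#'   (intercept first), `score` (named, in-sample linear predictor),
#'   `score_loo` (or `NULL`), `subjects`, `outcome`, `converged`, `flag`,
#'   `seed`.
#' @export
fit_panel <- function(em, marker_ids, outcome, seed = NULL,
                      cv = c("none", "loo")) {
  stopifnot(inherits(em, "expression_matrix"))
  cv <- match.arg(cv)
  missing_ids <- setdiff(marker_ids, em$assay_ids)
  if (length(missing_ids)) {
    stop("markers not in matrix: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  outcome <- as.logical(outcome)
  if (length(outcome) != length(em$sample_ids)) {
    stop("outcome must align with samples", call. = FALSE)
  }
  x <- t(em$log2_rq[marker_ids, , drop = FALSE])
  colnames(x) <- marker_ids
  ok <- stats::complete.cases(x) & !is.na(outcome)
  x <- x[ok, , drop = FALSE]
  y <- outcome[ok]
  subjects <- em$sample_ids[ok]
  if (!any(y) || all(y)) {
    stop("outcome must have both classes", call. = FALSE)
  }
  df <- data.frame(y = y, x, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  coefs <- stats::coef(fit)
  aliased <- names(coefs)[is.na(coefs)]
  if (length(aliased)) {
    warning("collinear marker(s) dropped from the panel fit: ",
            paste(gsub("`", "", aliased), collapse = ", "), call. = FALSE)
  }
  flag <- "ok"
  finite <- coefs[!is.na(coefs)]
  # a residual deviance of ~0 means the scores separate the classes exactly
  if (!fit$converged || separated || any(abs(finite[-1L]) > 15) ||
      fit$deviance < 1e-6) {
    flag <- "separation"
  }
  score <- stats::setNames(as.numeric(predict(fit, type = "link")), subjects)

  score_loo <- NULL
  if (cv == "loo") {
    score_loo <- stats::setNames(rep(NA_real_, length(y)), subjects)
    for (i in seq_along(y)) {
      train <- df[-i, , drop = FALSE]
      if (!any(train$y) || all(train$y)) next
      f <- suppressWarnings(
        stats::glm(y ~ ., data = train, family = stats::binomial())
      )
      score_loo[i] <- as.numeric(
        predict(f, newdata = df[i, , drop = FALSE], type = "link")
      )
    }
  }
  structure(
    list(marker_ids = marker_ids, coefficients = coefs, score = score,
         score_loo = score_loo, subjects = subjects, outcome = y,
         converged = fit$converged, flag = flag, seed = seed),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("panel_model: %d marker(s) [%s], %d subjects, flag: %s\n",
              length(x$marker_ids), paste(x$marker_ids, collapse = ", "),
              length(x$subjects), x$flag))
  invisible(x)
}

#' Compare a single marker against a panel, with and without the marker
#'
#' Computes ROC AUCs (with DeLong CIs) for the marker alone, the panel, and
#' the panel refitted with the marker added, and a paired DeLong test of
#' whether the addition changes the AUC.
#'
#' @param em an `expression_matrix`.
#' @param marker one assay id (or the name of a clinical score passed via
#'   `marker_scores`).
#' @param panel a `panel_model` from [fit_panel()].
#' @param outcome logical vector aligned to `em$sample_ids`.
#' @param marker_scores optional numeric vector aligned to `em$sample_ids`
#'   to use as the marker (e.g. serum free testosterone) instead of an assay
#'   row.
#' @param alpha significance level for the improvement call.
#' @return list with `roc_marker`, `roc_panel`, `roc_combined`
#'   (`roc_result`s), `delong` (paired test combined vs panel), `improved`
#'   (logical at `alpha`).
#' @export
compare_marker_vs_panel <- function(em, marker, panel, outcome,
                                    marker_scores = NULL, alpha = 0.05) {
  stopifnot(inherits(em, "expression_matrix"), inherits(panel, "panel_model"))
  outcome <- as.logical(outcome)
  if (is.null(marker_scores)) {
    if (!marker %in% em$assay_ids) {
      stop("marker not in matrix: ", marker, call. = FALSE)
    }
    marker_scores <- em$log2_rq[marker, ]
  }
  idx <- match(panel$subjects, em$sample_ids)
  mscore <- marker_scores[idx]
  shared <- !is.na(mscore)
  subj <- panel$subjects[shared]
  y <- panel$outcome[shared]

  # refit panel + marker on the shared subjects
  x <- t(em$log2_rq[panel$marker_ids, idx[shared], drop = FALSE])
  df <- data.frame(y = y, x, added_marker = mscore[shared],
                   check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial())
  )
  combined_score <- as.numeric(predict(fit, type = "link"))

  roc_marker <- roc_curve(mscore[shared], y)
  roc_panel <- roc_curve(panel$score[shared], y)
  roc_combined <- roc_curve(combined_score, y)
  test <- delong_paired_test(combined_score, panel$score[shared], y)
  list(
    marker = marker,
    roc_marker = roc_marker, roc_panel = roc_panel,
    roc_combined = roc_combined, delong = test,
    improved = (test$p_value < alpha) && (test$difference > 0),
    n = length(subj)
  )
}
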