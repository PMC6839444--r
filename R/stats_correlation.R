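#' Simple and partial Pearson correlation
#'
#' The partial correlation controlling for covariates is the Pearson
#' correlation of the least-squares residuals of `x` and `y` on
#' `[1, covariates]`; its p-value uses a t reference with `n - k - 2`
#' degrees of freedom (k covariates). Observations with any missing value
#' among `x`, `y` and the covariates are dropped (pairwise-complete policy,
#' recorded via `n`).
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of control variables (e.g. age, BMI),
#'   or `NULL` for a simple correlation only.
#' @return data.frame with `r`, `p`, `r_adjusted`, `p_adjusted`, `n`, `k`
#'   (`r_adjusted`/`p_adjusted` are `NA` without covariates).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    z <- NULL
    ok <- stats::complete.cases(x, y)
  } else {
    z <- as.matrix(covariates)
    ok <- stats::complete.cases(x, y, z)
  }
  x <- x[ok]; y <- y[ok]
  if (!is.null(z)) z <- z[ok, , drop = FALSE]
  n <- length(x)
  k <- if (is.null(z)) 0L else ncol(z)
  if (n <= k + 2L) {
    stop("need n > k + 2 complete observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  p <- cor_p(r, n - 2L)
  r_adj <- NA_real_; p_adj <- NA_real_
  if (!is.null(z)) {
    design <- cbind(1, z)
    rx <- stats::lm.fit(design, x)$residuals
    ry <- stats::lm.fit(design, y)$residuals
    if (stats::sd(rx) < .Machine$double.eps^0.5 * max(1, stats::sd(x)) ||
        stats::sd(ry) < .Machine$double.eps^0.5 * max(1, stats::sd(y))) {
      stop("undefined partial correlation: zero residual variance ",
           "(a variable is collinear with the covariates)", call. = FALSE)
    }
    r_adj <- stats::cor(rx, ry)
    p_adj <- cor_p(r_adj, n - k - 2L)
  }
  data.frame(r = r, p = p, r_adjusted = r_adj, p_adjusted = p_adj,
             n = n, k = k)
}

cor_p <- function(r, df) {
  if (df < 1L) return(NA_real_)
  r <- min(1, max(-1, r))
  if (abs(r) == 1) return(0)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

#' Correlate clinical variables with marker levels
#'
#' Convenience wrapper running [partial_correlation()] for every requested
#' (clinical variable, assay) pair on log2 relative quantities.
#'
#' @param em an `expression_matrix`.
#' @param clinical data.frame aligned to `em$sample_ids` (same order).
#' @param variables clinical column names to correlate.
#' @param assays assay ids (default: all).
#' @param covariates column names used as controls (default age and BMI).
#' @return data.frame with one row per pair: `variable`, `assay_id`, `r`,
#'   `p`, `r_adjusted`, `p_adjusted`, `n`.
#' @export
correlate_clinical <- function(em, clinical, variables,
                               assays = em$assay_ids,
                               covariates = c("age", "bmi")) {
  stopifnot(inherits(em, "expression_matrix"))
  covs <- clinical[, covariates, drop = FALSE]
  rows <- list()
  for (v in variables) {
    for (a in assays) {
      res <- tryCatch(
        partial_correlation(clinical[[v]], em$log2_rq[a, ], covs),
        error = function(e) NULL
      )
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(variable = v, assay_id = a,
                         stringsAsFactors = FALSE), res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise correlation and hierarchical clustering of abundant assays
#'
#' Computes the pairwise Pearson correlation matrix of the `top_k` most
#' abundant assays on log2 values (pairwise-complete observations) and cuts
#' an average-linkage hierarchical clustering of `1 - r` at a configurable
#' height. Constant assays are excluded with a warning.
#'
#' @param em an `expression_matrix` or `normalized_matrix` (for the latter,
#'   abundance ranks by mean -dCt).
#' @param top_k number of assays to keep by abundance (>= 2).
#' @param method linkage passed to [stats::hclust()].
#' @param cut_height tree cut height on the `1 - r` scale (default 0.5).
#' @return list with `correlation` (matrix), `clusters` (named integer
#'   vector), `order` (assay ids used).
#' @export
correlation_cluster <- function(em, top_k = 50, method = "average",
                                cut_height = 0.5) {
  if (inherits(em, "normalized_matrix")) {
    values <- -em$dct
  } else if (inherits(em, "expression_matrix")) {
    values <- em$log2_rq
  } else {
    values <- as.matrix(em)
  }
  if (top_k < 2L) stop("top_k must be >= 2", call. = FALSE)
  sds <- apply(values, 1L, stats::sd, na.rm = TRUE)
  constant <- !is.na(sds) & sds == 0
  if (any(constant)) {
    warning(sum(constant), " constant assay(s) excluded from clustering")
    values <- values[!constant, , drop = FALSE]
  }
  abundance <- rowMeans(values, na.rm = TRUE)
  keep <- order(abundance, decreasing = TRUE)[seq_len(min(top_k, nrow(values)))]
  v <- values[keep, , drop = FALSE]
  r <- stats::cor(t(v), use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = method)
  clusters <- stats::cutree(hc, h = cut_height)
  list(correlation = r, clusters = clusters, order = rownames(v),
       hclust = hc)
}
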