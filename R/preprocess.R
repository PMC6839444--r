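#' Filter assays by detection frequency
#'
#' Mirrors the common qPCR-array inclusion rule "present in at least k
#' (f percent) of the samples". A well counts as detected when its Ct is
#' present and at or below the matrix's detection limit. The applied
#' threshold is the stricter of the absolute and relative criteria:
#' `max(min_samples, ceiling(min_fraction * n_samples))`.
#'
#' @param m a [ct_matrix()].
#' @param min_samples absolute minimum number of detected samples (default 10).
#' @param min_fraction minimum detected fraction of samples (default 0.15).
#' @return A list with `matrix` (the filtered [ct_matrix()], in which wells
#'   above the detection limit have been set to missing), and `report`, a list
#'   with `n_input`, `n_retained`, `n_removed`, `threshold`, per-assay
#'   `detected_counts`, the retained/removed assay ids and
#'   `percent_retained`.
#' @export
detection_filter <- function(m, min_samples = 10, min_fraction = 0.15) {
  stopifnot(inherits(m, "ct_matrix"))
  if (nrow(m$ct) == 0L || ncol(m$ct) == 0L) {
    stop("empty Ct matrix", call. = FALSE)
  }
  if (min_samples < 1 && !(min_fraction > 0 && min_fraction <= 1)) {
    stop("need min_samples >= 1 or min_fraction in (0, 1]", call. = FALSE)
  }
  n_samples <- ncol(m$ct)
  threshold <- max(min_samples, ceiling(min_fraction * n_samples))
  det <- detected_mask(m)
  counts <- rowSums(det)
  keep <- counts >= threshold
  ct <- m$ct
  ct[!det] <- NA_real_  # undetected wells (incl. Ct > limit) become missing
  out <- ct_matrix(ct[keep, , drop = FALSE],
                   assay_ids = m$assay_ids[keep],
                   sample_ids = m$sample_ids,
                   detection_limit = m$detection_limit)
  report <- list(
    n_input = nrow(m$ct),
    n_retained = sum(keep),
    n_removed = sum(!keep),
    threshold = threshold,
    detected_counts = stats::setNames(counts, m$assay_ids),
    retained = m$assay_ids[keep],
    removed = m$assay_ids[!keep],
    percent_retained = 100 * sum(keep) / nrow(m$ct)
  )
  list(matrix = out, report = report)
}

#' Global mean normalization of a Ct matrix
#'
#' Subtracts from each sample a per-sample normalization factor: the
#' arithmetic mean Ct of that sample's detected assays (`"per_sample_detected"`,
#' the classical global-mean method for miRNA arrays) or the mean over the set
#' of assays detected in every sample (`"common_detected"`). The result is a
#' dCt matrix in cycles; by construction the mean dCt over each sample's basis
#' set is zero, so any per-sample additive offset (pipetting, input amount) is
#' removed exactly.
#'
#' @param m a [ct_matrix()] that already passed [detection_filter()].
#' @param mean_basis `"per_sample_detected"` or `"common_detected"`.
#' @return An object of class `normalized_matrix`: list with `dct`
#'   (assay x sample), `sample_offsets`, `assay_ids`, `sample_ids`,
#'   `mean_basis`.
#' @export
global_mean_normalize <- function(m,
                                  mean_basis = c("per_sample_detected",
                                                 "common_detected")) {
  stopifnot(inherits(m, "ct_matrix"))
  mean_basis <- match.arg(mean_basis)
  det <- detected_mask(m)
  if (mean_basis == "common_detected") {
    common <- rowSums(det) == ncol(det)
    if (!any(common)) {
      stop("no assay is detected in every sample; cannot use common_detected",
           call. = FALSE)
    }
    basis <- det & common  # columns of `common` assays only
  } else {
    basis <- det
  }
  n_basis <- colSums(basis)
  if (any(n_basis == 0L)) {
    stop("sample(s) with zero detected assays: ",
         paste(m$sample_ids[n_basis == 0L], collapse = ", "), call. = FALSE)
  }
  ctb <- m$ct
  ctb[!basis] <- NA_real_
  offsets <- colMeans(ctb, na.rm = TRUE)
  ct <- m$ct
  ct[!det] <- NA_real_
  dct <- sweep(ct, 2L, offsets, "-")
  structure(
    list(dct = dct, sample_offsets = stats::setNames(offsets, m$sample_ids),
         assay_ids = m$assay_ids, sample_ids = m$sample_ids,
         mean_basis = mean_basis, basis = basis),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d assays x %d samples (basis: %s)\n",
              nrow(x$dct), ncol(x$dct), x$mean_basis))
  invisible(x)
}

#' Relative quantities by the 2^-ddCt method
#'
#' Centers each assay's dCt on the mean over a reference group and
#' exponentiates: `rq = 2^-(dct - mean(dct[reference]))`. The geometric mean
#' of `rq` over the reference samples with data is 1 for every assay.
#'
#' @param nm a `normalized_matrix` from [global_mean_normalize()].
#' @param reference_samples character vector of sample ids forming the
#'   reference (calibrator) group.
#' @return An object of class `expression_matrix`: list with `rq`
#'   (assay x sample, linear scale), `log2_rq`, `reference_samples`,
#'   `assay_ids`, `sample_ids`. Assays with no reference-group data get
#'   all-missing rq with a warning.
#' @export
relative_quantity <- function(nm, reference_samples) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (!length(reference_samples)) {
    stop("reference sample set is empty", call. = FALSE)
  }
  missing_ids <- setdiff(reference_samples, nm$sample_ids)
  if (length(missing_ids)) {
    stop("reference samples not in matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  ref <- nm$dct[, nm$sample_ids %in% reference_samples, drop = FALSE]
  ref_mean <- rowMeans(ref, na.rm = TRUE)
  no_ref <- !is.finite(ref_mean)
  if (any(no_ref)) {
    warning(sum(no_ref), " assay(s) have no reference-group data; rq missing")
    ref_mean[no_ref] <- NA_real_
  }
  ddct <- sweep(nm$dct, 1L, ref_mean, "-")
  structure(
    list(rq = 2^(-ddct), log2_rq = -ddct,
         reference_samples = reference_samples,
         assay_ids = nm$assay_ids, sample_ids = nm$sample_ids),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d assays x %d samples (%d reference samples)\n",
              nrow(x$rq), ncol(x$rq), length(x$reference_samples)))
  invisible(x)
}

#' Per-assay coefficient of variation
#'
#' CV = SD / mean over a sample subset. The default scale is the linear
#' relative quantity; `scale = "ct"` computes sd/mean of the Ct (or dCt)
#' values instead — the two are not comparable and the choice is recorded in
#' the result.
#'
#' @param em an `expression_matrix` (or, with `scale = "ct"`, a [ct_matrix()]
#'   / `normalized_matrix`).
#' @param sample_subset sample ids to use; default all samples.
#' @param scale `"rq"` (linear relative quantities) or `"ct"`.
#' @return data.frame with `assay_id`, `cv` (fraction; `NA` when fewer than 2
#'   observations), `n`; attribute `"scale"` records the scale used.
#' @export
assay_cv <- function(em, sample_subset = NULL, scale = c("rq", "ct")) {
  scale <- match.arg(scale)
  if (scale == "rq") {
    stopifnot(inherits(em, "expression_matrix"))
    values <- em$rq
  } else if (inherits(em, "ct_matrix")) {
    values <- em$ct
  } else if (inherits(em, "normalized_matrix")) {
    values <- em$dct
  } else {
    values <- em$rq
  }
  ids <- rownames(values)
  if (is.null(sample_subset)) sample_subset <- colnames(values)
  if (!length(sample_subset)) stop("empty sample subset", call. = FALSE)
  bad <- setdiff(sample_subset, colnames(values))
  if (length(bad)) {
    stop("unknown samples in subset: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  v <- values[, sample_subset, drop = FALSE]
  n <- rowSums(!is.na(v))
  mu <- rowMeans(v, na.rm = TRUE)
  sd_ <- apply(v, 1L, stats::sd, na.rm = TRUE)
  cv <- ifelse(n >= 2, sd_ / mu, NA_real_)
  out <- data.frame(assay_id = ids, cv = cv, n = n,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  out
}

#' Reference-assay stability by intra-/inter-group variance decomposition
#'
#' Ranks candidate normalizer assays by combined within-group and
#' between-group expression variability, in the spirit of model-based
#' reference-gene selection (NormFinder). For each scored assay the values
#' are optionally centered per sample (subtracting the sample's mean over the
#' scored assays, which removes sample-loading effects and makes the score
#' invariant to per-sample additive shifts); then
#' \itemize{
#'   \item intra: pooled within-group variance
#'     `sum_g (n_g - 1) s^2_g / (N - G)`,
#'   \item inter: sample-size-weighted squared deviation of group means from
#'     the overall mean, `sum_g n_g (m_g - m)^2 / N`,
#'   \item stability = `sqrt(intra + inter)` (cycles; lower = more stable).
#' }
#' Assays with any missing value among the scored samples are excluded with a
#' warning rather than imputed.
#'
#' @param x a `normalized_matrix`, [ct_matrix()], or plain assay x sample
#'   numeric matrix.
#' @param group_labels factor/character of length `n_samples`.
#' @param center_samples subtract per-sample means over scored assays first.
#'   Default `TRUE` for a raw [ct_matrix()] (which still carries sample
#'   loading effects) and `FALSE` otherwise.
#' @return data.frame sorted by ascending stability with columns `assay_id`,
#'   `stability`, `intra_var`, `inter_var`, `rank`.
#' @export
normfinder_stability <- function(x, group_labels, center_samples = NULL) {
  if (inherits(x, "normalized_matrix")) {
    values <- x$dct
    if (is.null(center_samples)) center_samples <- FALSE
  } else if (inherits(x, "ct_matrix")) {
    values <- x$ct
    values[!detected_mask(x)] <- NA_real_
    if (is.null(center_samples)) center_samples <- TRUE
  } else {
    values <- as.matrix(x)
    if (is.null(center_samples)) center_samples <- FALSE
  }
  g <- as.factor(group_labels)
  if (length(g) != ncol(values)) {
    stop("group_labels length must equal number of samples", call. = FALSE)
  }
  if (nlevels(droplevels(g)) < 2L) stop("need >= 2 groups", call. = FALSE)
  g <- droplevels(g)
  if (any(table(g) < 2L)) {
    stop("every group needs >= 2 samples; too small: ",
         paste(names(which(table(g) < 2L)), collapse = ", "), call. = FALSE)
  }
  complete <- rowSums(is.na(values)) == 0L
  if (sum(complete) < 3L) {
    stop("need >= 3 assays with complete data to score stability",
         call. = FALSE)
  }
  if (any(!complete)) {
    warning(sum(!complete), " assay(s) with missing values excluded from scoring")
  }
  z <- values[complete, , drop = FALSE]
  if (center_samples) z <- sweep(z, 2L, colMeans(z), "-")

  N <- ncol(z)
  G <- nlevels(g)
  n_g <- tabulate(g)
  group_means <- t(apply(z, 1L, function(row) tapply(row, g, mean)))
  overall <- as.vector(group_means %*% n_g) / N
  inter <- as.vector(((group_means - overall)^2) %*% n_g) / N
  within_ss <- rowSums(vapply(seq_len(G), function(k) {
    cols <- which(as.integer(g) == k)
    rowSums((z[, cols, drop = FALSE] - group_means[, k])^2)
  }, numeric(nrow(z))))
  intra <- within_ss / (N - G)

  out <- data.frame(
    assay_id = rownames(z),
    stability = sqrt(intra + inter),
    intra_var = intra,
    inter_var = inter,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(out$stability, out$assay_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Absolute quantification by the standard-curve method
#'
#' Fits `Ct = slope * log10(quantity) + intercept` to a dilution series by
#' least squares and inverts unknown Ct values through the fitted line. The
#' amplification efficiency is `10^(-1/slope) - 1` (1 = perfect doubling per
#' cycle).
#'
#' @param standards data.frame/list with components `log10_quantity` and `ct`
#'   (at least 3 points spanning at least 2 log10 units), or a 2-column matrix.
#' @param unknowns numeric vector of Ct values to quantify (may be empty).
#' @return list with `curve` (class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`) and `quantities` (linear scale, same length
#'   as `unknowns`).
#' @export
standard_curve_quantify <- function(standards, unknowns = numeric()) {
  if (is.matrix(standards)) {
    standards <- list(log10_quantity = standards[, 1L], ct = standards[, 2L])
  }
  lq <- as.numeric(standards$log10_quantity)
  ct <- as.numeric(standards$ct)
  if (length(lq) < 3L || length(lq) != length(ct)) {
    stop("need >= 3 (log10 quantity, Ct) standards", call. = FALSE)
  }
  if (diff(range(lq)) < 2) {
    stop("standards must span >= 2 log10 units", call. = FALSE)
  }
  fit <- stats::lm(ct ~ lq)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope >= 0) {
    stop("calibration error: standard-curve slope must be negative (got ",
         format(slope), ")", call. = FALSE)
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)  # silent on perfect fits
  curve <- structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         efficiency = 10^(-1 / slope) - 1),
    class = "standard_curve"
  )
  quantities <- 10^((unknowns - intercept) / slope)
  list(curve = curve, quantities = quantities)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: slope %.4f cycles/log10, intercept %.3f, R^2 %.4f, efficiency %.1f%%\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency
  ))
  invisible(x)
}
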