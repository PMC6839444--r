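#' Construct a Ct matrix
#'
#' A `ct_matrix` holds raw qPCR cycle-threshold values as an assay x sample
#' numeric matrix with `NA` for undetermined wells, plus the detection limit
#' in cycles. Ct values above the detection limit are kept in the matrix but
#' are treated as undetected by [detection_filter()] and
#' [global_mean_normalize()].
#'
#' @param ct numeric matrix, assays in rows, samples in columns. `NA` marks
#'   undetermined wells.
#' @param assay_ids,sample_ids identifiers; default taken from `dimnames(ct)`.
#' @param detection_limit cycles; Ct values above this are considered
#'   undetected (default 35).
#' @return An object of class `ct_matrix`.
#' @export
ct_matrix <- function(ct, assay_ids = rownames(ct), sample_ids = colnames(ct),
                      detection_limit = 35) {
  if (!is.matrix(ct) || !is.numeric(ct)) {
    stop("`ct` must be a numeric matrix (assays x samples)", call. = FALSE)
  }
  if (is.null(assay_ids)) assay_ids <- sprintf("assay_%d", seq_len(nrow(ct)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%d", seq_len(ncol(ct)))
  assay_ids <- as.character(assay_ids)
  sample_ids <- as.character(sample_ids)
  if (length(assay_ids) != nrow(ct)) {
    stop("length(assay_ids) must equal nrow(ct)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(ct)) {
    stop("length(sample_ids) must equal ncol(ct)", call. = FALSE)
  }
  if (anyDuplicated(assay_ids)) stop("duplicate assay ids", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  present <- ct[!is.na(ct)]
  if (length(present) && (any(present <= 0) || any(present > 50))) {
    stop("present Ct values must be > 0 and <= 50 cycles", call. = FALSE)
  }
  if (!is.numeric(detection_limit) || length(detection_limit) != 1L ||
      detection_limit <= 0) {
    stop("`detection_limit` must be a single positive number", call. = FALSE)
  }
  dimnames(ct) <- list(assay_ids, sample_ids)
  structure(
    list(ct = ct, assay_ids = assay_ids, sample_ids = sample_ids,
         detection_limit = detection_limit),
    class = "ct_matrix"
  )
}

#' @export
print.ct_matrix <- function(x, ...) {
  det <- detected_mask(x)
  cat(sprintf(
    "ct_matrix: %d assays x %d samples, detection limit %g cycles, %.1f%% detected\n",
    nrow(x$ct), ncol(x$ct), x$detection_limit, 100 * mean(det)
  ))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

# logical matrix: well has a usable Ct (present and at or below the limit)
detected_mask <- function(m) {
  !is.na(m$ct) & m$ct <= m$detection_limit
}

#' Read a Ct table from delimited text
#'
#' Long tables need columns `sample_id`, `assay_id`, `ct`; wide tables have
#' one `assay_id` column and one column per sample. Cells equal to
#' `"Undetermined"`, `"NA"`, `""` (case-insensitive) become missing.
#'
#' @param path file path of a TSV/CSV table.
#' @param dialect `"long"` or `"wide"`.
#' @param sep field separator; default `"\t"`, use `","` for CSV.
#' @param detection_limit passed to [ct_matrix()].
#' @return A [ct_matrix()].
#' @export
parse_ct_table <- function(path, dialect = c("long", "wide"), sep = "\t",
                           detection_limit = 35) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (dialect == "long") {
    need <- c("sample_id", "assay_id", "ct")
    if (!all(need %in% names(df))) {
      stop("long Ct table must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    key <- paste(df$sample_id, df$assay_id, sep = "\r")
    if (anyDuplicated(key)) {
      first <- key[duplicated(key)][1L]
      stop("duplicate (sample, assay) pair: ",
           gsub("\r", " / ", first, fixed = TRUE), call. = FALSE)
    }
    ctv <- parse_ct_cells(df$ct, path)
    assays <- unique(df$assay_id)
    samples <- unique(df$sample_id)
    mat <- matrix(NA_real_, length(assays), length(samples),
                  dimnames = list(assays, samples))
    mat[cbind(match(df$assay_id, assays), match(df$sample_id, samples))] <- ctv
  } else {
    if (!"assay_id" %in% names(df)) {
      stop("wide Ct table must have an `assay_id` column", call. = FALSE)
    }
    if (anyDuplicated(df$assay_id)) {
      stop("duplicate assay id in wide table: ",
           df$assay_id[duplicated(df$assay_id)][1L], call. = FALSE)
    }
    samples <- setdiff(names(df), "assay_id")
    if (!length(samples)) stop("wide table has no sample columns", call. = FALSE)
    mat <- vapply(samples, function(s) parse_ct_cells(df[[s]], path),
                  numeric(nrow(df)))
    mat <- matrix(mat, nrow = nrow(df), dimnames = list(df$assay_id, samples))
  }
  ct_matrix(mat, detection_limit = detection_limit)
}

parse_ct_cells <- function(x, path) {
  x <- trimws(x)
  missing <- is.na(x) | tolower(x) %in% c("undetermined", "na", "nan", "")
  out <- rep(NA_real_, length(x))
  parsed <- suppressWarnings(as.numeric(x[!missing]))
  if (anyNA(parsed)) {
    bad <- which(!missing)[which(is.na(parsed))[1L]]
    stop(sprintf("malformed Ct value '%s' at data row %d of %s",
                 x[!missing][which(is.na(parsed))[1L]], bad, path),
         call. = FALSE)
  }
  out[!missing] <- parsed
  out
}

#' Write a Ct matrix to delimited text
#'
#' @param m a [ct_matrix()].
#' @param path output file.
#' @param dialect `"long"` or `"wide"`.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(m, path, dialect = c("wide", "long"), sep = "\t") {
  stopifnot(inherits(m, "ct_matrix"))
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    df <- data.frame(assay_id = m$assay_ids, m$ct, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      sample_id = rep(m$sample_ids, each = nrow(m$ct)),
      assay_id = rep(m$assay_ids, times = ncol(m$ct)),
      ct = as.vector(m$ct),
      stringsAsFactors = FALSE
    )
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "Undetermined")
  invisible(path)
}
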