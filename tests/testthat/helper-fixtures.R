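# shared fixture builders (all data generated in code; no files)

# small, fast three-group cohort configuration
small_config <- function(seed = 1, ...) {
  cohort_config(
    n_per_group = c(control = 8, normo_pcos = 8, hyper_pcos = 8),
    n_assays = 40, frac_detectable = 0.75,
    cluster_specs = list(), seed = seed, ...
  )
}

# expression_matrix straight from a log2 matrix (reference geometric mean
# already centered elsewhere; for unit tests of downstream statistics)
make_em <- function(log2_values, assay_ids = NULL, sample_ids = NULL) {
  log2_values <- as.matrix(log2_values)
  if (is.null(assay_ids)) assay_ids <- paste0("a", seq_len(nrow(log2_values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(log2_values)))
  dimnames(log2_values) <- list(assay_ids, sample_ids)
  structure(
    list(rq = 2^log2_values, log2_rq = log2_values,
         reference_samples = sample_ids,
         assay_ids = assay_ids, sample_ids = sample_ids),
    class = "expression_matrix"
  )
}

# normalized_matrix straight from a dCt matrix
make_nm <- function(dct, assay_ids = NULL, sample_ids = NULL) {
  dct <- as.matrix(dct)
  if (is.null(assay_ids)) assay_ids <- paste0("a", seq_len(nrow(dct)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(dct)))
  dimnames(dct) <- list(assay_ids, sample_ids)
  structure(
    list(dct = dct, sample_offsets = rep(0, ncol(dct)),
         assay_ids = assay_ids, sample_ids = sample_ids,
         mean_basis = "per_sample_detected"),
    class = "normalized_matrix"
  )
}

# deterministic Ct matrix with prescribed per-assay detected counts
ct_with_detected_counts <- function(counts, n_samples, detection_limit = 35) {
  n_assays <- length(counts)
  ct <- matrix(NA_real_, n_assays, n_samples)
  for (i in seq_len(n_assays)) {
    if (counts[i] > 0) ct[i, seq_len(counts[i])] <- 20 + (i %% 10)
  }
  ct_matrix(ct, assay_ids = sprintf("a%04d", seq_len(n_assays)),
            sample_ids = sprintf("s%03d", seq_len(n_samples)),
            detection_limit = detection_limit)
}

# end-to-end planted-effect estimate: simulate, preprocess, mean log2 diff
estimate_log2fc <- function(config) {
  sim <- simulate_cohort(config)
  filt <- detection_filter(sim$ct, min_samples = 2, min_fraction = 0.15)
  nm <- global_mean_normalize(filt$matrix)
  strata <- sim$truth$strata
  em <- relative_quantity(nm, names(strata)[strata == "control"])
  eff <- sim$truth$effects
  eff$estimated <- NA_real_
  for (k in seq_len(nrow(eff))) {
    a <- eff$assay_id[k]
    if (!a %in% em$assay_ids) next
    v <- em$log2_rq[a, ]
    eff$estimated[k] <- mean(v[strata == eff$group[k]], na.rm = TRUE) -
      mean(v[strata == "control"], na.rm = TRUE)
  }
  eff
}
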