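#' Default per-group clinical variable distributions
#'
#' Location/scale parameters per group for each clinical variable of a
#' three-group serum-biomarker case-control design (healthy controls,
#' normoandrogenic PCOS, hyperandrogenic PCOS). Skewed variables use a
#' log-normal family parameterized by median and interquartile range; roughly
#' symmetric ones use a normal family with mean and SD. Values mirror the
#' published baseline characteristics of such cohorts; waist circumference
#' and blood pressure are not tabulated in the motivating study and are set
#' to realistic values that reproduce its metabolic-syndrome prevalence
#' (about 5% in controls and normoandrogenic PCOS, about a third of
#' hyperandrogenic PCOS).
#'
#' @return Named list; each element is a list with `family`
#'   (`"normal"`/`"lognormal"`) and a 3 x 2 matrix `params` (rows control,
#'   normo_pcos, hyper_pcos; columns location, scale).
#' @export
default_clinical_params <- function() {
  spec <- list(
    # variable            family        control        normo          hyper
    age                = c("normal",     27, 5.6,       29, 5.2,       27, 4.4),
    bmi                = c("lognormal",  25.0, 6.9,     23.8, 4.7,     28.4, 6.2),
    waist              = c("lognormal",  79, 16,        77, 14,        90, 18),
    systolic_bp        = c("normal",     118, 11,       117, 11,       125, 13),
    diastolic_bp       = c("normal",     75, 8,         75, 8,         81, 9),
    total_t            = c("lognormal",  1.1, 0.5,      1.9, 1.1,      3.7, 2.3),
    shbg               = c("lognormal",  71.0, 36.3,    88.0, 53,      46.0, 36),
    dheas              = c("normal",     5291, 1949,    4642, 1644,    7554, 2393),
    androstenedione    = c("lognormal",  4.4, 2.5,      5.4, 2.5,      10.1, 4.3),
    fasting_glucose    = c("lognormal",  5.0, 0.5,      5.1, 0.4,      5.2, 0.6),
    fasting_insulin    = c("lognormal",  7.7, 5.5,      6.2, 5.6,      8.8, 8.8),
    c_peptide          = c("lognormal",  605, 260,      470, 270,      680, 390),
    total_cholesterol  = c("lognormal",  4.4, 1.1,      4.4, 1.3,      4.3, 0.7),
    ldl                = c("normal",     2.6, 0.8,      2.5, 0.7,      2.4, 0.7),
    hdl                = c("lognormal",  1.6, 0.4,      1.6, 0.5,      1.4, 0.4),
    triglycerides      = c("lognormal",  0.6, 0.2,      0.6, 0.3,      1.0, 0.8)
  )
  lapply(spec, function(v) {
    params <- matrix(as.numeric(v[-1L]), nrow = 3, byrow = TRUE,
                     dimnames = list(c("control", "normo_pcos", "hyper_pcos"),
                                     c("location", "scale")))
    list(family = v[[1L]], params = params)
  })
}

#' Default planted miRNA group effects
#'
#' Linear fold changes relative to controls for the markers the pipeline's
#' default panel tracks: modest 1.2-1.6x increases (miR-485-3p, miR-1290,
#' miR-20a-5p up to 2x in the hyperandrogenic group), 1.4-2.9x decreases
#' (miR-139-3p, miR-433-3p, miR-361-5p down to 2.9x), and markers raised in
#' the normoandrogenic group only (miR-34b-3p, miR-1225-3p).
#'
#' @return data.frame with `assay_id`, `fold_normo`, `fold_hyper` (linear
#'   scale, control fixed at 1).
#' @export
default_effect_specs <- function() {
  data.frame(
    assay_id = c("miR-485-3p", "miR-1290", "miR-20a-5p", "miR-139-3p",
                 "miR-433-3p", "miR-361-5p", "miR-34b-3p", "miR-1225-3p",
                 "miR-21-3p", "miR-572", "miR-143-3p", "miR-7-1-3p"),
    fold_normo = c(1.3, 1.3, 1.2, 1 / 1.7, 1.0, 1 / 1.7, 1.4, 1.4,
                   1 / 1.7, 1 / 1.8, 1 / 1.4, 1.3),
    fold_hyper = c(1.2, 1.6, 2.0, 1 / 1.9, 0.5, 1 / 2.9, 1 / 1.3, 1 / 1.2,
                   1 / 1.7, 1 / 1.8, 1 / 1.4, 1.3),
    stringsAsFactors = FALSE
  )
}

#' Default planted metabolic-syndrome marker effects
#'
#' Per-subject Ct shifts applied to subjects whose generated clinical values
#' satisfy the metabolic-syndrome rule, giving the three default panel
#' markers single-marker discrimination around AUC 0.8-0.92 at the default
#' noise level (1 cycle).
#'
#' @return data.frame with `assay_id`, `fold_mets` (linear fold in MetS
#'   subjects vs others).
#' @export
default_mets_effect_specs <- function() {
  data.frame(
    assay_id = c("miR-361-5p", "miR-1225-3p", "miR-34b-3p"),
    fold_mets = c(2^-2.0, 2^-1.4, 2^1.2),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic qPCR-array cohort
#'
#' Describes the generative model for a three-group serum miRNA case-control
#' study: Ct values are simulated on the log2 (cycle) scale as
#' `base + sample offset - log2(group fold) - log2(MetS fold) + correlated
#' noise`, with a configurable fraction of assays detectable and the rest
#' missing at random with low assay-specific detection probabilities.
#'
#' @param n_per_group named integer vector `(control, normo_pcos,
#'   hyper_pcos)`; default `c(20, 23, 19)`.
#' @param n_assays number of assays on the array (default 750).
#' @param frac_detectable fraction of assays detectable in serum (default
#'   303/750).
#' @param effect_specs data.frame as [default_effect_specs()]; `NULL` for
#'   none.
#' @param mets_effect_specs data.frame as [default_mets_effect_specs()];
#'   `NULL` for none.
#' @param cluster_specs list of `list(assays = <ids or indices>, corr = rho)`
#'   giving correlated assay clusters via a shared latent factor; the default
#'   (`"auto"`) builds one 30-assay and one 11-assay cluster with rho 0.6
#'   among abundant unaffected assays, mirroring the intercorrelation
#'   structure reported for highly expressed circulating miRNAs.
#' @param ct_noise_sd per-subject biological + technical noise SD in cycles
#'   (default 1.0, which keeps sd/mean on the Ct scale under 5%).
#' @param sample_offset_sd SD of the per-sample additive loading offset in
#'   cycles (default 0.5); removed by global mean normalization.
#' @param base_ct_range range of base Ct for detectable assays (default
#'   c(12, 33)).
#' @param detection_limit cycles (default 35).
#' @param detect_prob_range range of per-assay detection probabilities for
#'   undetectable assays (default c(0, 0.05)).
#' @param clinical_params as [default_clinical_params()].
#' @param seed integer seed; all generator functions are deterministic given
#'   the config.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(control = 20, normo_pcos = 23,
                                          hyper_pcos = 19),
                          n_assays = 750,
                          frac_detectable = 303 / 750,
                          effect_specs = default_effect_specs(),
                          mets_effect_specs = default_mets_effect_specs(),
                          cluster_specs = "auto",
                          ct_noise_sd = 1.0,
                          sample_offset_sd = 0.5,
                          base_ct_range = c(12, 33),
                          detection_limit = 35,
                          detect_prob_range = c(0, 0.05),
                          clinical_params = default_clinical_params(),
                          seed = 1L) {
  groups <- c("control", "normo_pcos", "hyper_pcos")
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  n_per_group <- n_per_group[groups]
  config_error <- function(field, msg) {
    stop(sprintf("invalid cohort config: field `%s` %s", field, msg),
         call. = FALSE)
  }
  if (anyNA(n_per_group) || any(n_per_group < 2)) {
    config_error("n_per_group", "must name control/normo_pcos/hyper_pcos, each >= 2")
  }
  if (n_assays < 1) config_error("n_assays", "must be >= 1")
  if (!(frac_detectable > 0 && frac_detectable <= 1)) {
    config_error("frac_detectable", "must be in (0, 1]")
  }
  if (ct_noise_sd < 0) config_error("ct_noise_sd", "must be >= 0")
  if (sample_offset_sd < 0) config_error("sample_offset_sd", "must be >= 0")
  if (length(base_ct_range) != 2L || diff(base_ct_range) < 0) {
    config_error("base_ct_range", "must be (min, max)")
  }

  named <- if (is.null(effect_specs)) character() else effect_specs$assay_id
  named <- union(named, if (is.null(mets_effect_specs)) character()
                 else mets_effect_specs$assay_id)
  if (length(named) > n_assays) {
    config_error("effect_specs", "names more assays than n_assays")
  }
  n_sim <- n_assays - length(named)
  assay_ids <- c(named, sprintf("miR-sim-%04d", seq_len(n_sim)))

  if (!is.null(effect_specs)) {
    if (any(effect_specs$fold_normo <= 0) || any(effect_specs$fold_hyper <= 0)) {
      config_error("effect_specs", "fold changes must be > 0")
    }
  }
  if (!is.null(mets_effect_specs) && any(mets_effect_specs$fold_mets <= 0)) {
    config_error("mets_effect_specs", "fold changes must be > 0")
  }

  n_detectable <- as.integer(max(1, round(frac_detectable * n_assays)))
  if (identical(cluster_specs, "auto")) {
    # clusters among the first simulated (unaffected, detectable) assays
    avail <- setdiff(assay_ids[seq_len(min(n_detectable, n_assays))], named)
    cluster_specs <- list()
    if (length(avail) >= 41L) {
      cluster_specs <- list(list(assays = avail[1:30], corr = 0.6),
                            list(assays = avail[31:41], corr = 0.6))
    }
  }
  for (cl in cluster_specs) {
    if (!(cl$corr >= 0 && cl$corr < 1)) {
      config_error("cluster_specs", "correlations must be in [0, 1)")
    }
    if (is.numeric(cl$assays) && any(cl$assays > n_assays)) {
      config_error("cluster_specs", "assay indices exceed n_assays")
    }
  }
  for (v in names(clinical_params)) {
    if (any(clinical_params[[v]]$params[, "scale"] < 0)) {
      config_error(paste0("clinical_params$", v), "has negative scale")
    }
  }

  structure(
    list(n_per_group = n_per_group, n_assays = n_assays,
         frac_detectable = frac_detectable, n_detectable = n_detectable,
         assay_ids = assay_ids, effect_specs = effect_specs,
         mets_effect_specs = mets_effect_specs, cluster_specs = cluster_specs,
         ct_noise_sd = ct_noise_sd, sample_offset_sd = sample_offset_sd,
         base_ct_range = base_ct_range, detection_limit = detection_limit,
         detect_prob_range = detect_prob_range,
         clinical_params = clinical_params, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "cohort_config: %d subjects (%s), %d assays (%d detectable), seed %d\n",
    sum(x$n_per_group),
    paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group), collapse = ", "),
    x$n_assays, x$n_detectable, x$seed
  ))
  invisible(x)
}

# solve log-normal sdlog from median m and IQR w (exact closed form)
lognormal_sdlog <- function(median, iqr) {
  if (median <= 0) stop("log-normal median must be positive", call. = FALSE)
  ratio <- iqr / median
  u <- (ratio + sqrt(ratio^2 + 4)) / 2
  log(u) / stats::qnorm(0.75)
}

draw_clinical_variable <- function(n, family, location, scale) {
  if (family == "normal") {
    stats::rnorm(n, location, scale)
  } else if (family == "lognormal") {
    stats::rlnorm(n, log(location), lognormal_sdlog(location, scale))
  } else {
    stop("unknown distribution family: ", family, call. = FALSE)
  }
}

#' Generate a synthetic clinical table
#'
#' Draws raw per-subject clinical variables from the configured per-group
#' distributions. Only raw values are emitted; derived variables (free
#' testosterone, HOMA-IR, metabolic syndrome, androgen stratum) are computed
#' downstream by [derive_clinical()]. Deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @return data.frame with `subject_id`, `group` (`control`/`pcos`),
#'   `stratum_true` (the planted three-level group), and one column per
#'   configured clinical variable.
#' @export
generate_clinical_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  strata <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(strata)
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = ifelse(strata == "control", "control", "pcos"),
    stratum_true = strata,
    stringsAsFactors = FALSE
  )
  for (v in names(config$clinical_params)) {
    p <- config$clinical_params[[v]]
    vals <- numeric(n)
    for (g in rownames(p$params)) {
      idx <- strata == g
      if (!any(idx)) next
      vals[idx] <- draw_clinical_variable(sum(idx), p$family,
                                          p$params[g, "location"],
                                          p$params[g, "scale"])
    }
    out[[v]] <- vals
  }
  attr(out, "seed") <- config$seed
  out
}

#' Generate a synthetic Ct matrix with ground truth
#'
#' Simulates the assay x sample Ct matrix: detectable assays get a base Ct in
#' `base_ct_range`, per-sample additive offsets, group effects of
#' `-log2(fold)` cycles, optional MetS-linked effects, cluster-correlated
#' noise (shared latent factor per cluster) and independent Gaussian noise.
#' Undetectable assays sit near the detection limit and are missing at random
#' with a low assay-specific detection probability. Deterministic given the
#' config seed.
#'
#' @param config a [cohort_config()].
#' @param mets_status optional logical vector (one per subject) used for the
#'   MetS-linked effects; when `NULL` and `mets_effect_specs` are configured,
#'   it is derived by generating the clinical table and applying the
#'   metabolic-syndrome rule to the generated values.
#' @return list with `matrix` (a [ct_matrix()]) and `truth` (class
#'   `cohort_truth`): per-assay base Ct and detectability, the planted effect
#'   tables in log2 units, cluster assignment, the MetS status used, and the
#'   seed.
#' @export
generate_ct_matrix <- function(config, mets_status = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(mets_status) && !is.null(config$mets_effect_specs)) {
    clin <- generate_clinical_table(config)
    mets_status <- classify_mets(clin$waist, clin$systolic_bp,
                                 clin$diastolic_bp, clin$fasting_glucose,
                                 clin$hdl, clin$triglycerides)$mets
  }
  strata <- rep(names(config$n_per_group), config$n_per_group)
  n_samples <- length(strata)
  if (is.null(mets_status)) mets_status <- rep(FALSE, n_samples)
  if (length(mets_status) != n_samples) {
    stop("mets_status length must equal the number of subjects", call. = FALSE)
  }
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  set.seed(config$seed + 1000003L)
  n_assays <- config$n_assays
  assay_ids <- config$assay_ids

  # detectable set: planted-effect assays first, then the leading simulated ones
  named <- unique(c(
    if (!is.null(config$effect_specs)) config$effect_specs$assay_id,
    if (!is.null(config$mets_effect_specs)) config$mets_effect_specs$assay_id
  ))
  detectable <- rep(FALSE, n_assays)
  detectable[match(named, assay_ids)] <- TRUE
  extra <- which(!detectable)[seq_len(max(0L, config$n_detectable - sum(detectable)))]
  detectable[extra] <- TRUE

  base_ct <- numeric(n_assays)
  base_ct[detectable] <- stats::runif(sum(detectable),
                                      config$base_ct_range[1L],
                                      config$base_ct_range[2L])
  base_ct[!detectable] <- stats::runif(sum(!detectable),
                                       config$detection_limit - 2,
                                       config$detection_limit + 5)

  # planted effects in Ct cycles (negative shift = higher expression)
  effect_ct <- matrix(0, n_assays, n_samples)
  log2fc <- NULL
  if (!is.null(config$effect_specs)) {
    es <- config$effect_specs
    rows <- match(es$assay_id, assay_ids)
    for (k in seq_len(nrow(es))) {
      effect_ct[rows[k], strata == "normo_pcos"] <- -log2(es$fold_normo[k])
      effect_ct[rows[k], strata == "hyper_pcos"] <- -log2(es$fold_hyper[k])
    }
    log2fc <- data.frame(
      assay_id = rep(es$assay_id, 2L),
      group = rep(c("normo_pcos", "hyper_pcos"), each = nrow(es)),
      log2_fold_change = c(log2(es$fold_normo), log2(es$fold_hyper)),
      stringsAsFactors = FALSE
    )
  }
  mets_log2fc <- NULL
  if (!is.null(config$mets_effect_specs)) {
    ms <- config$mets_effect_specs
    rows <- match(ms$assay_id, assay_ids)
    for (k in seq_len(nrow(ms))) {
      effect_ct[rows[k], mets_status %in% TRUE] <-
        effect_ct[rows[k], mets_status %in% TRUE] - log2(ms$fold_mets[k])
    }
    mets_log2fc <- data.frame(assay_id = ms$assay_id,
                              log2_fold_change = log2(ms$fold_mets),
                              stringsAsFactors = FALSE)
  }

  # correlated noise: shared latent factor per cluster
  noise <- matrix(stats::rnorm(n_assays * n_samples), n_assays, n_samples)
  cluster_of <- rep(NA_integer_, n_assays)
  for (k in seq_along(config$cluster_specs)) {
    cl <- config$cluster_specs[[k]]
    rows <- if (is.numeric(cl$assays)) cl$assays else match(cl$assays, assay_ids)
    rows <- rows[!is.na(rows)]
    if (!length(rows)) next
    cluster_of[rows] <- k
    factor_j <- stats::rnorm(n_samples)
    noise[rows, ] <- sqrt(cl$corr) * matrix(factor_j, length(rows), n_samples,
                                            byrow = TRUE) +
      sqrt(1 - cl$corr) * noise[rows, , drop = FALSE]
  }
  noise <- noise * config$ct_noise_sd

  offsets <- stats::rnorm(n_samples, 0, config$sample_offset_sd)
  ct <- base_ct + effect_ct + noise +
    matrix(offsets, n_assays, n_samples, byrow = TRUE)

  # undetectable assays: missing at random, assay-specific detection probability
  detect_prob <- rep(1, n_assays)
  detect_prob[!detectable] <- stats::runif(sum(!detectable),
                                           config$detect_prob_range[1L],
                                           config$detect_prob_range[2L])
  present <- matrix(stats::runif(n_assays * n_samples), n_assays, n_samples) <=
    detect_prob
  ct[!present] <- NA_real_
  ct[!is.na(ct) & ct > 50] <- 50
  ct[!is.na(ct) & ct <= 0] <- 0.01

  m <- ct_matrix(ct, assay_ids = assay_ids, sample_ids = sample_ids,
                 detection_limit = config$detection_limit)
  truth <- structure(
    list(base_ct = stats::setNames(base_ct, assay_ids),
         detectable = stats::setNames(detectable, assay_ids),
         detectable_ids = assay_ids[detectable],
         effects = log2fc, mets_effects = mets_log2fc,
         cluster = stats::setNames(cluster_of, assay_ids),
         strata = stats::setNames(strata, sample_ids),
         mets_status = stats::setNames(mets_status, sample_ids),
         sample_offsets = stats::setNames(offsets, sample_ids),
         seed = config$seed),
    class = "cohort_truth"
  )
  list(matrix = m, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Generates the clinical table, applies the metabolic-syndrome rule to the
#' generated values (so MetS prevalence is an emergent property of the
#' clinical distributions, not a planted label), and simulates the Ct matrix
#' with MetS-linked marker effects tied to those same subjects.
#'
#' @param config a [cohort_config()].
#' @return list with `ct` (a [ct_matrix()]), `clinical` (data.frame),
#'   `truth` (`cohort_truth`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  clinical <- generate_clinical_table(config)
  mets <- classify_mets(clinical$waist, clinical$systolic_bp,
                        clinical$diastolic_bp, clinical$fasting_glucose,
                        clinical$hdl, clinical$triglycerides)$mets
  gen <- generate_ct_matrix(config, mets_status = mets)
  list(ct = gen$matrix, clinical = clinical, truth = gen$truth)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the Ct matrix in wide and long TSV form, the clinical table as CSV,
#' and the ground truth as JSON (all stamped with the seed).
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ct_wide = file.path(dir, "ct_wide.tsv"),
    ct_long = file.path(dir, "ct_long.tsv"),
    clinical = file.path(dir, "clinical.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_ct_table(cohort$ct, paths[["ct_wide"]], dialect = "wide")
  write_ct_table(cohort$ct, paths[["ct_long"]], dialect = "long")
  utils::write.csv(cohort$clinical, paths[["clinical"]], row.names = FALSE)
  truth <- cohort$truth
  truth_json <- list(
    seed = truth$seed,
    detectable_ids = truth$detectable_ids,
    effects = truth$effects,
    mets_effects = truth$mets_effects,
    mets_status = as.list(truth$mets_status),
    strata = as.list(truth$strata)
  )
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
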