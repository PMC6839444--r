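#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Exactly one input route
#' must be supplied: a synthetic [cohort_config()] (`cohort`), or paths to a
#' Ct table and a clinical table.
#'
#' @param cohort a [cohort_config()], or `NULL` when reading files.
#' @param ct_path,clinical_path input files (`ct_dialect` = `"long"`/`"wide"`).
#' @param ct_dialect dialect of `ct_path`.
#' @param min_samples,min_fraction detection-filter thresholds (defaults 10
#'   and 0.15: "present in at least 10 (15%) of the samples").
#' @param detection_limit Ct cycles above which a well counts undetected.
#' @param mean_basis basis for [global_mean_normalize()].
#' @param alpha significance level.
#' @param covariates clinical columns used as adjustment covariates.
#' @param var_equal classical Student t (default) vs Welch.
#' @param fdr add Benjamini-Hochberg columns (off by default).
#' @param panel_markers assay ids for the MetS panel.
#' @param panel_outcome clinical column holding the panel's binary outcome.
#' @param within_group restrict the panel analysis to this `group` value.
#' @param ci_method AUC CI method.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param seed integer master seed.
#' @param make_plots emit volcano and ROC plots (PNG) next to the tables.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, ct_path = NULL,
                            clinical_path = NULL, ct_dialect = "long",
                            min_samples = 10, min_fraction = 0.15,
                            detection_limit = 35,
                            mean_basis = "per_sample_detected",
                            alpha = 0.05, covariates = c("age", "bmi"),
                            var_equal = TRUE, fdr = FALSE,
                            panel_markers = c("miR-361-5p", "miR-1225-3p",
                                              "miR-34b-3p"),
                            panel_outcome = "mets", within_group = "pcos",
                            ci_method = "delong", out_dir = NULL,
                            seed = 1L, make_plots = FALSE) {
  synthetic <- !is.null(cohort)
  files <- !is.null(ct_path) || !is.null(clinical_path)
  if (synthetic == files) {
    stop("supply exactly one of `cohort` or (`ct_path` + `clinical_path`)",
         call. = FALSE)
  }
  if (files && (is.null(ct_path) || is.null(clinical_path))) {
    stop("file input needs both `ct_path` and `clinical_path`", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(
    list(cohort = cohort, ct_path = ct_path, clinical_path = clinical_path,
         ct_dialect = ct_dialect, min_samples = min_samples,
         min_fraction = min_fraction, detection_limit = detection_limit,
         mean_basis = mean_basis, alpha = alpha, covariates = covariates,
         var_equal = var_equal, fdr = fdr, panel_markers = panel_markers,
         panel_outcome = panel_outcome, within_group = within_group,
         ci_method = ci_method, out_dir = out_dir, seed = as.integer(seed),
         make_plots = make_plots),
    class = "pipeline_config"
  )
}

# rolling polynomial hash of the deparsed config, for reproducibility stamping
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Validate a JSON pipeline configuration file
#'
#' Schema-checks a flat JSON config, rejecting unknown keys and out-of-range
#' values; all violations are reported, not just the first. Valid keys are
#' expanded with defaults and echoed back.
#'
#' @param path JSON file.
#' @return list with `diagnostics` (character vector, empty when valid) and
#'   `config` (the expanded [pipeline_config()], or `NULL` when invalid).
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- list(
    synthetic = "logical", n_per_group = "numeric", n_assays = "numeric",
    frac_detectable = "numeric", ct_noise_sd = "numeric", seed = "numeric",
    ct_path = "character", clinical_path = "character",
    ct_dialect = "character", min_samples = "numeric",
    min_fraction = "numeric", detection_limit = "numeric",
    mean_basis = "character", alpha = "numeric", covariates = "character",
    var_equal = "logical", fdr = "logical", panel_markers = "character",
    panel_outcome = "character", within_group = "character",
    ci_method = "character", out_dir = "character", make_plots = "logical"
  )
  diag <- character()
  unknown <- setdiff(names(raw), names(known))
  if (length(unknown)) {
    diag <- c(diag, paste0("unknown key: ", unknown))
  }
  for (key in intersect(names(raw), names(known))) {
    if (!inherits(raw[[key]], known[[key]]) &&
        !(known[[key]] == "numeric" && is.numeric(raw[[key]]))) {
      diag <- c(diag, sprintf("key `%s` must be %s", key, known[[key]]))
    }
  }
  num_in <- function(key, lo, hi, open = TRUE) {
    if (!is.null(raw[[key]]) && is.numeric(raw[[key]])) {
      bad <- if (open) any(raw[[key]] <= lo | raw[[key]] >= hi)
             else any(raw[[key]] < lo | raw[[key]] > hi)
      if (bad) {
        diag <<- c(diag, sprintf("key `%s` out of range (%g, %g)",
                                 key, lo, hi))
      }
    }
  }
  num_in("alpha", 0, 1)
  num_in("min_fraction", 0, 1)
  num_in("frac_detectable", 0, 1)
  if (!is.null(raw$mean_basis) &&
      !raw$mean_basis %in% c("per_sample_detected", "common_detected")) {
    diag <- c(diag, "key `mean_basis` must be per_sample_detected or common_detected")
  }
  if (!is.null(raw$ct_dialect) && !raw$ct_dialect %in% c("long", "wide")) {
    diag <- c(diag, "key `ct_dialect` must be long or wide")
  }
  synthetic <- isTRUE(raw$synthetic)
  if (!synthetic && (is.null(raw$ct_path) || is.null(raw$clinical_path))) {
    diag <- c(diag,
              "need either synthetic=true or both ct_path and clinical_path")
  }
  if (length(diag)) return(list(diagnostics = diag, config = NULL))

  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  cohort <- NULL
  if (synthetic) {
    args <- list(seed = seed)
    for (key in c("n_per_group", "n_assays", "frac_detectable",
                  "ct_noise_sd")) {
      if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
    }
    cohort <- do.call(cohort_config, args)
  }
  passthrough <- intersect(names(raw),
                           c("ct_path", "clinical_path", "ct_dialect",
                             "min_samples", "min_fraction", "detection_limit",
                             "mean_basis", "alpha", "covariates", "var_equal",
                             "fdr", "panel_markers", "panel_outcome",
                             "within_group", "ci_method", "out_dir",
                             "make_plots"))
  cfg <- do.call(pipeline_config,
                 c(list(cohort = cohort, seed = seed), raw[passthrough]))
  list(diagnostics = character(), config = cfg)
}

#' Run the full analysis pipeline
#'
#' Executes: input (simulate or parse) -> clinical derivation and androgen
#' stratification -> detection filter -> global mean normalization -> 2^-ddCt
#' quantification -> two-group and three-group differential statistics with
#' covariate adjustment -> volcano table -> clinical correlations -> MetS
#' contingency (Fisher) -> single-marker ROCs and the logistic panel. All
#' tables are written under `out_dir` (when set) along with a JSON run
#' report; every artifact carries the config hash and seed. Deterministic
#' given the config.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report`: list with `stages` (named record
#'   counts satisfying retained + removed = input at each filter), `tables`
#'   (the result objects), `config_hash`, `seed`, `warnings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  warns <- character()
  note <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  stages <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- input ------------------------------------------------------------
  if (!is.null(config$cohort)) {
    sim <- run_stage("simulate", simulate_cohort(config$cohort))
    ct <- sim$ct; clinical <- sim$clinical; truth <- sim$truth
  } else {
    ct <- run_stage("parse", parse_ct_table(config$ct_path,
                                            dialect = config$ct_dialect,
                                            detection_limit = config$detection_limit))
    clinical <- run_stage("parse", utils::read.csv(config$clinical_path,
                                                   stringsAsFactors = FALSE))
    truth <- NULL
  }
  if (!identical(clinical$subject_id, ct$sample_ids)) {
    clinical <- clinical[match(ct$sample_ids, clinical$subject_id), ]
    if (anyNA(clinical$subject_id)) {
      stop("pipeline stage `input` failed: clinical table does not cover all samples",
           call. = FALSE)
    }
  }
  stages$input <- list(n_assays = nrow(ct$ct), n_samples = ncol(ct$ct))

  # -- clinical derivation ----------------------------------------------
  clinical <- run_stage("clinical", note(derive_clinical(clinical)))
  stages$clinical <- list(
    n_subjects = nrow(clinical),
    n_mets = sum(clinical$mets, na.rm = TRUE),
    strata = as.list(table(clinical$androgen_stratum))
  )

  # -- preprocessing ----------------------------------------------------
  filt <- run_stage("filter", detection_filter(ct, config$min_samples,
                                               config$min_fraction))
  stages$filter <- list(input = filt$report$n_input,
                        retained = filt$report$n_retained,
                        removed = filt$report$n_removed,
                        threshold = filt$report$threshold,
                        percent_retained = filt$report$percent_retained)
  nm <- run_stage("normalize", global_mean_normalize(filt$matrix,
                                                     config$mean_basis))
  ref_samples <- clinical$subject_id[clinical$group == "control"]
  em <- run_stage("quantify", note(relative_quantity(nm, ref_samples)))
  stages$quantify <- list(n_assays = nrow(em$rq),
                          n_reference = length(ref_samples))

  # -- statistics -------------------------------------------------------
  covs <- clinical[, config$covariates, drop = FALSE]
  diff2 <- run_stage("differential_2group",
                     note(two_group_differential(em, clinical$group,
                                                 covariates = covs,
                                                 case = "pcos",
                                                 var_equal = config$var_equal,
                                                 fdr = config$fdr)))
  volcano <- volcano_table(diff2, config$alpha)
  stages$differential_2group <- list(
    n_tested = nrow(diff2),
    n_significant = sum(volcano$significant),
    n_up = sum(volcano$direction == "up"),
    n_down = sum(volcano$direction == "down")
  )
  diff3 <- run_stage("differential_3group",
                     note(three_group_differential(em,
                                                   clinical$androgen_stratum,
                                                   covariates = covs,
                                                   fdr = config$fdr)))
  stages$differential_3group <- list(
    n_tested = nrow(diff3),
    n_significant = sum(diff3$p_value < config$alpha, na.rm = TRUE)
  )

  corr_assays <- union(config$panel_markers,
                       utils::head(volcano$assay_id[volcano$significant], 30))
  corr_assays <- intersect(corr_assays, em$assay_ids)
  corr_vars <- intersect(
    c("total_t", "free_t", "shbg", "dheas", "androstenedione",
      "fasting_glucose", "fasting_insulin", "homa_ir", "total_cholesterol",
      "hdl", "triglycerides"),
    names(clinical)
  )
  correlations <- run_stage("correlations",
                            note(correlate_clinical(em, clinical, corr_vars,
                                                    assays = corr_assays,
                                                    covariates = config$covariates)))
  stages$correlations <- list(n_pairs = nrow(correlations))

  # MetS contingency across androgen strata (Fisher)
  mets_tab <- table(stratum = clinical$androgen_stratum,
                    mets = factor(clinical$mets, c(FALSE, TRUE)))
  fisher_nh <- if (all(c("normo_pcos", "hyper_pcos") %in% rownames(mets_tab))) {
    note(fisher_exact_2x2(mets_tab[c("normo_pcos", "hyper_pcos"),
                                   c("TRUE", "FALSE")]))
  } else NULL
  stages$mets <- list(counts = as.list(as.data.frame(mets_tab)$Freq))

  # -- biomarker panel --------------------------------------------------
  panel_out <- NULL
  within <- clinical$group == config$within_group
  outcome_all <- clinical[[config$panel_outcome]]
  markers <- intersect(config$panel_markers, em$assay_ids)
  if (length(markers) && sum(outcome_all[within], na.rm = TRUE) >= 2 &&
      sum(!outcome_all[within], na.rm = TRUE) >= 2) {
    sub_em <- subset_samples(em, within)
    outcome <- outcome_all[within]
    # individual markers can be unusable (e.g. informative missingness
    # wiping out one class); record them as NULL rather than aborting
    single_rocs <- lapply(markers, function(mk) {
      tryCatch(note(roc_curve(sub_em$log2_rq[mk, ], outcome,
                              ci_method = config$ci_method,
                              direction = "auto")),
               error = function(e) NULL)
    })
    names(single_rocs) <- markers
    panel_out <- tryCatch({
      panel <- note(fit_panel(sub_em, markers, outcome, seed = config$seed))
      roc_panel <- note(roc_curve(panel$score, panel$outcome,
                                  ci_method = config$ci_method))
      op <- operating_point(roc_panel, "youden")
      free_t_cmp <- if ("free_t" %in% names(clinical)) {
        tryCatch(
          note(compare_marker_vs_panel(sub_em, "free_t", panel, outcome,
                                       marker_scores = clinical$free_t[within],
                                       alpha = config$alpha)),
          error = function(e) NULL
        )
      } else NULL
      list(markers = markers, single_rocs = single_rocs, panel = panel,
           roc = roc_panel, operating_point = op,
           free_t_comparison = free_t_cmp)
    }, error = function(e) {
      warns <<- c(warns, paste("panel stage:", conditionMessage(e)))
      NULL
    })
    if (!is.null(panel_out)) {
      stages$panel <- list(
        n_subjects = length(panel_out$panel$subjects),
        n_pos = panel_out$roc$n_pos, n_neg = panel_out$roc$n_neg,
        auc_panel = panel_out$roc$auc,
        auc_single = vapply(single_rocs, function(r) {
          if (is.null(r)) NA_real_ else r$auc
        }, numeric(1))
      )
    } else {
      stages$panel <- list(skipped = "panel not estimable on this cohort")
    }
  } else {
    stages$panel <- list(skipped = "markers absent or outcome class missing")
  }

  report <- structure(
    list(package_version = as.character(utils::packageVersion("pcosmir")),
         seed = config$seed, config_hash = config_hash(config),
         stages = stages, warnings = warns,
         tables = list(clinical = clinical, filter_report = filt$report,
                       differential_2group = diff2,
                       differential_3group = diff3, volcano = volcano,
                       correlations = correlations, mets_table = mets_tab,
                       fisher_normo_vs_hyper = fisher_nh,
                       panel = panel_out, truth = truth)),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) {
    write_run_outputs(report, em, config)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (seed %d, config %s)\n", x$seed, x$config_hash))
  f <- x$stages$filter
  cat(sprintf("  filter: %d -> %d retained (%.1f%%), %d removed\n",
              f$input, f$retained, f$percent_retained, f$removed))
  d <- x$stages$differential_2group
  cat(sprintf("  two-group: %d tested, %d significant (%d up / %d down)\n",
              d$n_tested, d$n_significant, d$n_up, d$n_down))
  if (!is.null(x$stages$panel$auc_panel)) {
    cat(sprintf("  panel AUC: %.3f (singles: %s)\n", x$stages$panel$auc_panel,
                paste(sprintf("%.3f", x$stages$panel$auc_single),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Restrict an expression matrix to a subset of samples
#'
#' @param em an `expression_matrix`.
#' @param keep logical vector or sample ids.
#' @return an `expression_matrix` over the kept samples.
#' @export
subset_samples <- function(em, keep) {
  if (is.character(keep)) keep <- em$sample_ids %in% keep
  structure(
    list(rq = em$rq[, keep, drop = FALSE],
         log2_rq = em$log2_rq[, keep, drop = FALSE],
         reference_samples = intersect(em$reference_samples,
                                       em$sample_ids[keep]),
         assay_ids = em$assay_ids, sample_ids = em$sample_ids[keep]),
    class = "expression_matrix"
  )
}

write_run_outputs <- function(report, em, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# config %s seed %d", report$config_hash, report$seed)
  tsv <- function(df, name) {
    path <- file.path(config$out_dir, name)
    writeLines(stamp, path)
    suppressWarnings(
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE)
    )
    path
  }
  t <- report$tables
  tsv(t$clinical, "clinical_derived.tsv")
  tsv(t$differential_2group, "differential_2group.tsv")
  tsv(t$differential_3group, "differential_3group.tsv")
  tsv(t$volcano, "volcano.tsv")
  tsv(t$correlations, "correlations.tsv")
  if (!is.null(t$panel)) {
    pull <- function(field, i = 1L) {
      vapply(t$panel$single_rocs, function(r) {
        if (is.null(r)) NA_real_ else r[[field]][i]
      }, numeric(1))
    }
    aucs <- data.frame(
      marker = c(t$panel$markers, "panel"),
      auc = c(pull("auc"), t$panel$roc$auc),
      ci_lower = c(pull("ci", 1L), t$panel$roc$ci[1]),
      ci_upper = c(pull("ci", 2L), t$panel$roc$ci[2]),
      stringsAsFactors = FALSE
    )
    tsv(aucs, "panel_auc.tsv")
    roc_df <- data.frame(threshold = t$panel$roc$thresholds,
                         sensitivity = t$panel$roc$sensitivity,
                         specificity = t$panel$roc$specificity)
    tsv(roc_df, "panel_roc_coordinates.tsv")
    jsonlite::write_json(
      list(markers = t$panel$markers,
           coefficients = as.list(t$panel$panel$coefficients),
           seed = report$seed, config = report$config_hash),
      file.path(config$out_dir, "panel_model.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  jsonlite::write_json(
    list(package_version = report$package_version, seed = report$seed,
         config_hash = report$config_hash, stages = report$stages,
         warnings = report$warnings),
    file.path(config$out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  if (isTRUE(config$make_plots)) {
    try({
      grDevices::png(file.path(config$out_dir, "volcano.png"), 700, 600)
      plot_volcano(t$volcano, config$alpha)
      grDevices::dev.off()
    }, silent = TRUE)
    if (!is.null(t$panel)) {
      try({
        grDevices::png(file.path(config$out_dir, "roc.png"), 700, 600)
        plot_roc(t$panel$roc, main = "MetS panel ROC")
        grDevices::dev.off()
      }, silent = TRUE)
    }
  }
  invisible(config$out_dir)
}

#' Basic volcano plot
#'
#' @param volcano table from [volcano_table()].
#' @param alpha significance line.
#' @export
plot_volcano <- function(volcano, alpha = 0.05) {
  graphics::plot(volcano$log2_fold_change, volcano$neg_log10_p,
                 pch = ifelse(volcano$significant, 19, 1),
                 col = ifelse(volcano$significant, "firebrick", "grey40"),
                 xlab = "log2 fold change", ylab = "-log10 p-value",
                 main = "Volcano plot")
  graphics::abline(h = -log10(alpha), lty = 2)
  invisible(NULL)
}

#' Basic ROC plot
#'
#' @param roc a `roc_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_roc <- function(roc, ...) {
  ord <- order(1 - roc$specificity, roc$sensitivity)
  graphics::plot(c(0, (1 - roc$specificity)[ord], 1),
                 c(0, roc$sensitivity[ord], 1), type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", sprintf("AUC %.3f", roc$auc), bty = "n")
  invisible(NULL)
}
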