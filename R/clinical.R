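#' Free testosterone by the mass-action (Vermeulen) method
#'
#' Solves the two-ligand binding equilibrium of testosterone with SHBG
#' (association constant `k_shbg` = 1e9 L/mol) and albumin
#' (`k_albumin` = 3.6e4 L/mol; albumin binding treated as non-saturable).
#' With `N = 1 + k_albumin * [albumin]` the free concentration `FT` solves
#' `k_shbg * N * FT^2 + (N + k_shbg * (SHBG - T)) * FT - T = 0`,
#' and the positive quadratic root is returned. The result satisfies the
#' mass balance `FT + albumin-bound + SHBG-bound = T` to 1e-9 relative.
#'
#' @param total_t total testosterone, nmol/L.
#' @param shbg sex hormone binding globulin, nmol/L.
#' @param albumin serum albumin, g/L (default 43; converted via 69,000 g/mol).
#' @param k_shbg,k_albumin association constants, L/mol.
#' @return free testosterone, nmol/L (vectorized over inputs).
#' @export
free_testosterone <- function(total_t, shbg, albumin = 43,
                              k_shbg = 1e9, k_albumin = 3.6e4) {
  if (any(total_t < 0, na.rm = TRUE) || any(shbg < 0, na.rm = TRUE) ||
      any(albumin < 0, na.rm = TRUE)) {
    stop("total_t, shbg and albumin must be non-negative", call. = FALSE)
  }
  t_mol <- total_t * 1e-9
  shbg_mol <- shbg * 1e-9
  alb_mol <- albumin / 69000
  n_alb <- 1 + k_albumin * alb_mol
  if (any(n_alb + k_shbg * shbg_mol <= 0)) {
    stop("total binding capacity must be positive", call. = FALSE)
  }
  a <- k_shbg * n_alb
  b <- n_alb + k_shbg * (shbg_mol - t_mol)
  disc <- b^2 + 4 * a * t_mol
  if (any(disc < 0, na.rm = TRUE)) {
    stop("no positive root for the binding equilibrium", call. = FALSE)
  }
  ft <- (-b + sqrt(disc)) / (2 * a)
  ft[!is.na(total_t) & total_t == 0] <- 0
  ft * 1e9
}

#' HOMA-IR insulin-resistance index
#'
#' `HOMA-IR = fasting insulin (mU/L) * fasting glucose (mmol/L) / 22.5`.
#'
#' @param fasting_insulin mU/L.
#' @param fasting_glucose mmol/L.
#' @return HOMA-IR (mU.mmol.L^-2), vectorized.
#' @export
homa_ir <- function(fasting_insulin, fasting_glucose) {
  if (any(fasting_insulin < 0, na.rm = TRUE) ||
      any(fasting_glucose < 0, na.rm = TRUE)) {
    stop("insulin and glucose must be non-negative", call. = FALSE)
  }
  fasting_insulin * fasting_glucose / 22.5
}

#' Metabolic syndrome by the IDF rule
#'
#' A subject is positive when at least three of the five criteria hold
#' (female cut-offs): waist >= 80 cm; systolic BP >= 130 or diastolic
#' BP >= 85 mmHg; fasting glucose >= 5.6 mmol/L; HDL < 1.3 mmol/L;
#' triglycerides >= 1.7 mmol/L. Elevated criteria use `>=`, HDL uses
#' strict `<`, exactly as printed in the consensus definition.
#'
#' @param waist cm.
#' @param systolic,diastolic mmHg.
#' @param glucose fasting plasma glucose, mmol/L.
#' @param hdl HDL cholesterol, mmol/L.
#' @param triglycerides mmol/L.
#' @return data.frame (one row per subject) with logical flag columns
#'   `waist_flag`, `bp_flag`, `glucose_flag`, `hdl_flag`, `tg_flag`,
#'   integer `n_criteria` and logical `mets`. With missing components `mets`
#'   is `NA` and `missing_fields` names them.
#' @export
classify_mets <- function(waist, systolic, diastolic, glucose, hdl,
                          triglycerides) {
  n <- max(length(waist), length(systolic), length(diastolic),
           length(glucose), length(hdl), length(triglycerides))
  rec <- function(x) rep_len(as.numeric(x), n)
  waist <- rec(waist); systolic <- rec(systolic); diastolic <- rec(diastolic)
  glucose <- rec(glucose); hdl <- rec(hdl); triglycerides <- rec(triglycerides)

  flags <- cbind(
    waist_flag = waist >= 80,
    bp_flag = systolic >= 130 | diastolic >= 85,
    glucose_flag = glucose >= 5.6,
    hdl_flag = hdl < 1.3,
    tg_flag = triglycerides >= 1.7
  )
  n_crit <- rowSums(flags)
  mets <- n_crit >= 3
  missing_fields <- apply(
    cbind(waist = is.na(waist),
          bp = is.na(systolic) | is.na(diastolic),
          glucose = is.na(glucose), hdl = is.na(hdl),
          triglycerides = is.na(triglycerides)),
    1L, function(miss) paste(names(miss)[miss], collapse = ",")
  )
  # any missing component -> indeterminate, with the fields named
  data.frame(flags, n_criteria = n_crit, mets = mets,
             missing_fields = missing_fields,
             stringsAsFactors = FALSE)
}

#' Stratify PCOS subjects by biochemical hyperandrogenism
#'
#' PCOS subjects with free testosterone strictly above the threshold
#' (default 0.034 nmol/L, a reference 95th percentile for women) become
#' `"hyper_pcos"`, other PCOS subjects `"normo_pcos"`; controls are left
#' unchanged. A free T exactly at the threshold is normoandrogenic.
#'
#' @param group character/factor, `"control"` or `"pcos"` per subject.
#' @param free_t free testosterone, nmol/L.
#' @param threshold nmol/L, default 0.034.
#' @return character vector in `{"control", "normo_pcos", "hyper_pcos"}`.
#' @export
stratify_androgen <- function(group, free_t, threshold = 0.034) {
  group <- as.character(group)
  bad <- setdiff(unique(group), c("control", "pcos"))
  if (length(bad)) {
    stop("group must be 'control' or 'pcos'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(group == "pcos" & is.na(free_t))) {
    stop("free_t missing for PCOS subject(s); compute it first", call. = FALSE)
  }
  out <- group
  out[group == "pcos"] <- ifelse(free_t[group == "pcos"] > threshold,
                                 "hyper_pcos", "normo_pcos")
  out
}

#' Append derived clinical variables to a clinical table
#'
#' Computes free testosterone, HOMA-IR, the IDF metabolic-syndrome call and
#' the androgen stratum, appending columns (`free_t`, `homa_ir`, `mets`,
#' per-criterion flags, `androgen_stratum`) without overwriting inputs.
#'
#' @param clinical data.frame with columns `subject_id`, `group`
#'   (control/pcos), `total_t`, `shbg`, `fasting_insulin`, `fasting_glucose`,
#'   `waist`, `systolic_bp`, `diastolic_bp`, `hdl`, `triglycerides`, and
#'   optionally `albumin` (default 43 g/L).
#' @param ft_threshold free-T stratification threshold, nmol/L.
#' @return the input data.frame with derived columns appended; attribute
#'   `"binding_constants"` records the mass-action constants used.
#' @export
derive_clinical <- function(clinical, ft_threshold = 0.034) {
  need <- c("subject_id", "group", "total_t", "shbg", "fasting_insulin",
            "fasting_glucose", "waist", "systolic_bp", "diastolic_bp",
            "hdl", "triglycerides")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) {
    stop("clinical table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  albumin <- if ("albumin" %in% names(clinical)) clinical$albumin else 43
  out <- clinical
  out$free_t <- free_testosterone(clinical$total_t, clinical$shbg, albumin)
  out$homa_ir <- homa_ir(clinical$fasting_insulin, clinical$fasting_glucose)
  mets <- classify_mets(clinical$waist, clinical$systolic_bp,
                        clinical$diastolic_bp, clinical$fasting_glucose,
                        clinical$hdl, clinical$triglycerides)
  out <- cbind(out, mets[, c("waist_flag", "bp_flag", "glucose_flag",
                             "hdl_flag", "tg_flag", "n_criteria", "mets")])
  out$androgen_stratum <- stratify_androgen(clinical$group, out$free_t,
                                            ft_threshold)
  attr(out, "binding_constants") <-
    c(k_shbg = 1e9, k_albumin = 3.6e4, albumin_mw = 69000)
  out
}
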