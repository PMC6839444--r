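#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests departure from a normal distribution with mean and SD estimated
#' from the data (the classical software default). The statistic is the
#' exact sup-difference between the empirical CDF and the fitted normal CDF.
#' With estimated parameters the asymptotic Kolmogorov p-value is
#' conservative; `lilliefors = TRUE` calibrates the p-value by Monte Carlo
#' under the estimated-parameter null instead.
#'
#' @param values numeric vector, >= 5 non-missing observations.
#' @param lilliefors use a Monte Carlo (Lilliefors-corrected) p-value.
#' @param nsim Monte Carlo replicates for `lilliefors = TRUE`.
#' @return list with `statistic`, `p_value`, `n`, `method`.
#' @export
ks_normality <- function(values, lilliefors = FALSE, nsim = 2000) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 5L) stop("need >= 5 observations for the KS test", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate (constant) sample: normality test undefined",
         call. = FALSE)
  }
  d_stat <- function(x) {
    n <- length(x)
    f <- stats::pnorm(sort(x), mean(x), stats::sd(x))
    max(seq_len(n) / n - f, f - (seq_len(n) - 1) / n)
  }
  d <- d_stat(x)
  if (lilliefors) {
    sims <- vapply(seq_len(nsim), function(i) d_stat(stats::rnorm(n)),
                   numeric(1))
    p <- (sum(sims >= d) + 1) / (nsim + 1)
    method <- "lilliefors_mc"
  } else {
    # asymptotic Kolmogorov tail: Q(t) = 2 * sum (-1)^(k-1) exp(-2 k^2 t^2)
    t <- sqrt(n) * d
    k <- seq_len(100)
    p <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
    method <- "ks_estimated_params"
  }
  list(statistic = d, p_value = p, n = n, method = method)
}

#' Log2-transform relative quantities
#'
#' @param em an `expression_matrix` from [relative_quantity()].
#' @param policy `"always"` (log2 everything) or `"if_nonnormal"` (log2 only
#'   assays whose linear rq fail [ks_normality()] at `alpha`).
#' @param alpha significance level for the normality screen.
#' @return assay x sample numeric matrix; attribute `"transformed"` is a
#'   named logical recording the per-assay decision.
#' @export
log2_transform <- function(em, policy = c("always", "if_nonnormal"),
                           alpha = 0.05) {
  stopifnot(inherits(em, "expression_matrix"))
  policy <- match.arg(policy)
  if (any(em$rq <= 0, na.rm = TRUE)) {
    stop("relative quantities must be positive", call. = FALSE)
  }
  if (policy == "always") {
    out <- em$log2_rq
    transformed <- stats::setNames(rep(TRUE, nrow(out)), em$assay_ids)
  } else {
    out <- em$rq
    transformed <- stats::setNames(rep(FALSE, nrow(out)), em$assay_ids)
    for (i in seq_len(nrow(out))) {
      v <- out[i, ]
      v <- v[!is.na(v)]
      if (length(v) < 5L || stats::sd(v) == 0) next
      if (ks_normality(v)$p_value < alpha) {
        out[i, ] <- log2(out[i, ])
        transformed[i] <- TRUE
      }
    }
  }
  attr(out, "transformed") <- transformed
  out
}

# ---- logistic helpers -------------------------------------------------------

wald_or <- function(beta, se, level = 0.95) {
  beta <- unname(beta); se <- unname(se)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(beta), lower = exp(beta - z * se), upper = exp(beta + z * se),
    p = 2 * stats::pnorm(-abs(beta / se)))
}

# binary logistic for one marker + covariates; detects separation
logistic_marker <- function(y, x, covariates = NULL) {
  df <- data.frame(y = y, x = x)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  out <- c(or = NA_real_, lower = NA_real_, upper = NA_real_, p = NA_real_)
  flag <- "ok"
  fit <- tryCatch(
    suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial())),
    error = function(e) NULL
  )
  if (is.null(fit)) return(list(est = out, flag = "fit_error"))
  beta <- stats::coef(fit)["x"]
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))["x"], error = function(e) NA)
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 1e3 ||
      !fit$converged) {
    flag <- "separation"
  } else {
    out <- wald_or(beta, se)
  }
  list(est = out, flag = flag)
}

#' Two-group differential analysis of an expression matrix
#'
#' Per assay: Student's t-test (equal-variance by default, Welch by flag) on
#' log2 relative quantities, linear fold change `2^(mean case - mean
#' control)`, and a covariate-adjusted binary logistic regression of
#' case/control status on the assay's log2 values (odds ratio per log2 unit
#' with Wald 95% CI). Regressions are complete-case; t-tests use all
#' non-missing values per group.
#'
#' @param em an `expression_matrix`.
#' @param labels character/factor over samples; see `case`/`control`.
#' @param covariates optional data.frame (e.g. age, BMI), rows aligned to
#'   `em$sample_ids`.
#' @param case,control the two label values; by default `control` is
#'   `"control"` and `case` the other level.
#' @param var_equal classical Student t (default) or Welch when `FALSE`.
#' @param fdr add Benjamini-Hochberg adjusted p-values (off by default; the
#'   design is exploratory and per-assay p-values are reported unadjusted).
#' @return data.frame, one row per assay: group means (log2), `fold_change`,
#'   `t_stat`, `p_value`, `test`, `or_adjusted` + CI + `or_p`, `flag`.
#' @export
two_group_differential <- function(em, labels, covariates = NULL,
                                   case = NULL, control = "control",
                                   var_equal = TRUE, fdr = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  labels <- as.character(labels)
  if (length(labels) != length(em$sample_ids)) {
    stop("labels must align with samples", call. = FALSE)
  }
  if (is.null(case)) case <- setdiff(unique(labels), control)[1L]
  idx_case <- labels == case
  idx_ctrl <- labels == control
  if (sum(idx_case) < 2L || sum(idx_ctrl) < 2L) {
    stop("both groups need >= 2 samples", call. = FALSE)
  }
  x <- em$log2_rq
  y <- as.integer(idx_case)[idx_case | idx_ctrl]
  test_name <- if (var_equal) "student_t" else "welch_t"

  rows <- lapply(seq_len(nrow(x)), function(i) {
    a <- x[i, idx_case]; a <- a[!is.na(a)]
    b <- x[i, idx_ctrl]; b <- b[!is.na(b)]
    flag <- "ok"
    if (length(a) < 2L || length(b) < 2L) {
      tt <- c(NA_real_, NA_real_); flag <- "insufficient_data"
    } else if (stats::sd(c(a, b)) == 0) {
      tt <- c(0, 1); flag <- "zero_variance"
      warning("zero-variance assay: ", em$assay_ids[i], call. = FALSE)
    } else {
      fit <- stats::t.test(a, b, var.equal = var_equal)
      tt <- c(unname(fit$statistic), fit$p.value)
    }
    lg <- logistic_marker(y, x[i, idx_case | idx_ctrl],
                          if (is.null(covariates)) NULL
                          else covariates[idx_case | idx_ctrl, , drop = FALSE])
    if (flag == "ok" && lg$flag != "ok") flag <- lg$flag
    data.frame(
      assay_id = em$assay_ids[i],
      n_case = length(a), n_control = length(b),
      mean_case = mean(a), mean_control = mean(b),
      fold_change = 2^(mean(a) - mean(b)),
      t_stat = tt[1L], p_value = tt[2L], test = test_name,
      or_adjusted = unname(lg$est["or"]),
      or_lower = unname(lg$est["lower"]),
      or_upper = unname(lg$est["upper"]),
      or_p = unname(lg$est["p"]),
      flag = flag, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (fdr) out$p_bh <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Three-group differential analysis
#'
#' Per assay: one-way ANOVA on log2 relative quantities with Tukey HSD
#' pairwise p-values for the three contrasts, and a baseline-category
#' multinomial logistic regression (controls as baseline) of group membership
#' on the assay's log2 values plus covariates, reporting per-category odds
#' ratios with Wald 95% CIs.
#'
#' @param em an `expression_matrix`.
#' @param labels character/factor over samples with three levels; `baseline`
#'   names the reference category (default `"control"`).
#' @param covariates optional data.frame aligned to samples.
#' @param baseline reference category for the multinomial model.
#' @param fdr add Benjamini-Hochberg adjusted ANOVA p-values.
#' @return data.frame, one row per assay: `f_stat`, `p_value`, Tukey
#'   pairwise p columns (`tukey_<a>_vs_<b>`), per-category `or_<level>` with
#'   CI and p, `flag`.
#' @export
three_group_differential <- function(em, labels, covariates = NULL,
                                     baseline = "control", fdr = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  g <- factor(as.character(labels))
  if (length(g) != length(em$sample_ids)) {
    stop("labels must align with samples", call. = FALSE)
  }
  if (!baseline %in% levels(g)) {
    stop("baseline level not found in labels", call. = FALSE)
  }
  g <- stats::relevel(g, baseline)
  if (nlevels(g) != 3L) stop("need exactly three groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
  others <- levels(g)[-1L]
  x <- em$log2_rq

  rows <- lapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    ok <- !is.na(v)
    flag <- "ok"
    f_stat <- NA_real_; p <- NA_real_
    tukey <- stats::setNames(rep(NA_real_, 3L),
                             c(paste0("tukey_", others[1L], "_vs_", baseline),
                               paste0("tukey_", others[2L], "_vs_", baseline),
                               paste0("tukey_", others[2L], "_vs_", others[1L])))
    if (all(table(g[ok]) >= 2L) && sum(ok) >= 4L) {
      if (stats::sd(v[ok]) == 0) {
        f_stat <- 0; p <- 1; tukey[] <- 1; flag <- "zero_variance"
        warning("zero-variance assay: ", em$assay_ids[i], call. = FALSE)
      } else {
        fit <- stats::aov(v[ok] ~ g[ok])
        an <- summary(fit)[[1L]]
        f_stat <- an[["F value"]][1L]
        p <- an[["Pr(>F)"]][1L]
        th <- stats::TukeyHSD(fit)[[1L]]
        contrast <- function(a, b) {
          hit <- rownames(th) %in% c(paste0(a, "-", b), paste0(b, "-", a))
          if (any(hit)) th[hit, "p adj"][1L] else NA_real_
        }
        tukey[1L] <- contrast(others[1L], baseline)
        tukey[2L] <- contrast(others[2L], baseline)
        tukey[3L] <- contrast(others[2L], others[1L])
      }
    } else {
      flag <- "insufficient_data"
    }

    covs <- if (is.null(covariates)) NULL else covariates[, , drop = FALSE]
    mfit <- multinomial_marker(g, v, covs)
    if (flag == "ok" && mfit$flag != "ok") flag <- mfit$flag
    or_cols <- list()
    for (lev in others) {
      est <- mfit$est[[lev]]
      or_cols[[paste0("or_", lev)]] <- unname(est["or"])
      or_cols[[paste0("or_", lev, "_lower")]] <- unname(est["lower"])
      or_cols[[paste0("or_", lev, "_upper")]] <- unname(est["upper"])
      or_cols[[paste0("or_", lev, "_p")]] <- unname(est["p"])
    }
    cbind(
      data.frame(assay_id = em$assay_ids[i], f_stat = f_stat, p_value = p,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(tukey)),
      as.data.frame(or_cols),
      data.frame(flag = flag, stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  if (fdr) out$p_bh <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Volcano-plot table
#'
#' One row per assay with `log2_fold_change`, `neg_log10_p` and a
#' significance flag at `alpha` (default 0.05; the conventional volcano line
#' sits at -log10(0.05) = 1.30).
#'
#' @param results output of [two_group_differential()].
#' @param alpha significance level.
#' @return data.frame with `assay_id`, `log2_fold_change`, `neg_log10_p`,
#'   `significant`, `direction` (`"up"`/`"down"`/`"none"`).
#' @export
volcano_table <- function(results, alpha = 0.05) {
  if (!nrow(results)) stop("no differential results supplied", call. = FALSE)
  lfc <- log2(results$fold_change)
  sig <- !is.na(results$p_value) & results$p_value < alpha
  data.frame(
    assay_id = results$assay_id,
    log2_fold_change = lfc,
    neg_log10_p = -log10(results$p_value),
    significant = sig,
    direction = ifelse(!sig, "none", ifelse(lfc > 0, "up", "down")),
    stringsAsFactors = FALSE
  )
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing the hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed
#' one; the odds ratio is the conditional maximum-likelihood estimate under
#' the noncentral hypergeometric model.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `p_value`, `odds_ratio`, `table`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  a <- tab[1L, 1L]
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L]); c2 <- sum(tab[, 2L])
  if (any(c(r1, r2, c1, c2) == 0)) {
    warning("zero margin: p-value 1 by convention")
    return(list(p_value = 1, odds_ratio = NA_real_, table = tab))
  }
  support <- max(0L, r1 - c2):min(r1, c1)
  probs <- stats::dhyper(support, c1, c2, r1)
  obs <- stats::dhyper(a, c1, c2, r1)
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  list(p_value = min(1, p), odds_ratio = conditional_or(a, c1, c2, r1),
       table = tab)
}

# conditional MLE of the odds ratio: solve E_psi[K] = a for the noncentral
# hypergeometric distribution on the table's support
conditional_or <- function(a, c1, c2, r1) {
  support <- max(0L, r1 - c2):min(r1, c1)
  if (length(support) == 1L) return(NA_real_)
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  logw0 <- stats::dhyper(support, c1, c2, r1, log = TRUE)
  mean_k <- function(log_psi) {
    logw <- logw0 + support * log_psi
    w <- exp(logw - max(logw))
    sum(support * w) / sum(w) - a
  }
  exp(stats::uniroot(mean_k, c(-35, 35), tol = 1e-12)$root)
}

#' Effect size (Cohen's d) from a fold change and relative SD
#'
#' `d = (fold_change - 1) / relative_sd`, the standardized effect a linear
#' fold change represents when the between-subject SD is expressed relative
#' to the control mean.
#'
#' @param fold_change linear fold change (> 0).
#' @param relative_sd SD relative to the control mean (> 0).
#' @return Cohen's d.
#' @export
cohens_d_from_fold <- function(fold_change, relative_sd) {
  if (any(relative_sd <= 0)) {
    stop("relative_sd must be positive", call. = FALSE)
  }
  (fold_change - 1) / relative_sd
}

#' Power of the two-sample t-test
#'
#' Computed from the noncentral t distribution with `n1 + n2 - 2` degrees of
#' freedom and noncentrality `d * sqrt(n1 * n2 / (n1 + n2))`; handles unequal
#' group sizes, unlike `stats::power.t.test()`.
#'
#' @param d standardized effect size (Cohen's d), >= 0.
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level in (0, 1).
#' @param sidedness `"two"` (default) or `"one"`.
#' @return power in (0, 1).
#' @export
power_two_sample_t <- function(d, n1, n2, alpha = 0.05,
                               sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (d < 0) stop("d must be >= 0", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("n1 and n2 must be >= 2", call. = FALSE)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (sidedness == "two") {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp)
  }
}
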