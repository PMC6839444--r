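#' Baseline-category multinomial logistic regression
#'
#' Maximum-likelihood fit of a multinomial logit model with the first factor
#' level as baseline: for category `c != baseline`,
#' `log P(y = c) / P(y = baseline) = X b_c`. Fitted by BFGS on the
#' log-likelihood with analytic gradient; Wald standard errors come from the
#' inverse observed information (numerical Hessian at the optimum).
#'
#' @param y factor response; the first level is the baseline category.
#' @param x numeric model matrix WITHOUT intercept column (one row per
#'   observation), or a vector for a single predictor.
#' @return list with `coefficients` and `se` ((p+1) x (K-1) matrices, rows
#'   intercept + predictors, columns non-baseline categories), `logLik`,
#'   `converged`, `flag` (`"ok"` or `"separation"`).
#' @export
fit_multinomial <- function(y, x) {
  y <- droplevels(as.factor(y))
  k <- nlevels(y)
  if (k < 2L) stop("response needs >= 2 categories", call. = FALSE)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- stats::complete.cases(x) & !is.na(y)
  y <- y[keep]
  x <- x[keep, , drop = FALSE]
  x1 <- cbind(`(Intercept)` = 1, x)
  p1 <- ncol(x1)
  yi <- as.integer(y)
  ymat <- matrix(0, length(y), k)
  ymat[cbind(seq_along(y), yi)] <- 1

  nll <- function(par) {
    b <- matrix(par, p1, k - 1L)
    eta <- cbind(0, x1 %*% b)
    m <- apply(eta, 1L, max)
    lse <- m + log(rowSums(exp(eta - m)))
    -sum(eta[cbind(seq_along(yi), yi)] - lse)
  }
  grad <- function(par) {
    b <- matrix(par, p1, k - 1L)
    eta <- cbind(0, x1 %*% b)
    m <- apply(eta, 1L, max)
    pr <- exp(eta - m)
    pr <- pr / rowSums(pr)
    g <- t(x1) %*% (pr[, -1L, drop = FALSE] - ymat[, -1L, drop = FALSE])
    as.vector(g)
  }

  opt <- stats::optim(rep(0, p1 * (k - 1L)), nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  b <- matrix(opt$par, p1, k - 1L,
              dimnames = list(colnames(x1), levels(y)[-1L]))
  hess <- stats::optimHess(opt$par, nll, grad)
  se <- matrix(NA_real_, p1, k - 1L, dimnames = dimnames(b))
  flag <- if (opt$convergence == 0) "ok" else "separation"
  vc <- tryCatch(solve(hess), error = function(e) NULL)
  if (!is.null(vc) && all(diag(vc) > 0)) {
    se[] <- sqrt(diag(vc))
  } else {
    flag <- "separation"
  }
  if (any(abs(b) > 15)) flag <- "separation"
  list(coefficients = b, se = se, logLik = -opt$value,
       converged = opt$convergence == 0, flag = flag)
}

# per-assay multinomial OR for one marker (+ covariates); baseline = first level
multinomial_marker <- function(g, v, covariates = NULL) {
  x <- cbind(x = v)
  if (!is.null(covariates)) x <- cbind(x, as.matrix(covariates))
  others <- levels(g)[-1L]
  empty <- stats::setNames(rep(NA_real_, 4L), c("or", "lower", "upper", "p"))
  est <- stats::setNames(rep(list(empty), length(others)), others)
  fit <- tryCatch(fit_multinomial(g, x), error = function(e) NULL)
  if (is.null(fit)) return(list(est = est, flag = "fit_error"))
  for (lev in others) {
    beta <- fit$coefficients["x", lev]
    se <- fit$se["x", lev]
    if (is.finite(beta) && is.finite(se) && fit$flag == "ok") {
      est[[lev]] <- wald_or(beta, se)
    }
  }
  list(est = est, flag = fit$flag)
}
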