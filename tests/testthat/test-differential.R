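test_that("KS statistic equals the hand-computed sup difference", {
  x <- c(1.2, -0.4, 0.3, 2.1, -1.5)
  res <- ks_normality(x)
  xs <- sort(x)
  f <- pnorm(xs, mean(x), sd(x))
  oracle <- max(c((1:5) / 5 - f, f - (0:4) / 5))
  expect_equal(res$statistic, oracle, tolerance = 1e-12)
  expect_error(ks_normality(rep(1, 6)), "degenerate")
  expect_error(ks_normality(c(1, 2, 3)), ">= 5")
})

test_that("Lilliefors-calibrated KS rejects at ~alpha under the null", {
  set.seed(51)
  rejections <- vapply(seq_len(200), function(i) {
    ks_normality(rnorm(40), lilliefors = TRUE, nsim = 250)$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rate - 0.05), 3.5 * se)
})

test_that("log2 transform follows its policy", {
  em <- make_em(matrix(c(0, 1, 2, 3), 1, 4))
  out <- log2_transform(em, "always")
  expect_equal(unname(out[1, ]), c(0, 1, 2, 3))
  # near-normal linear rq stays untouched under if_nonnormal
  set.seed(52)
  em2 <- make_em(matrix(log2(rnorm(40, mean = 20, sd = 0.5)), 2, 20))
  out2 <- log2_transform(em2, "if_nonnormal")
  expect_false(any(attr(out2, "transformed")))
  expect_equal(out2[1, ], em2$rq[1, ])
  # strongly skewed rq gets transformed
  set.seed(53)
  em3 <- make_em(matrix(log2(exp(rnorm(60, 0, 2))), 2, 30))
  out3 <- log2_transform(em3, "if_nonnormal")
  expect_true(any(attr(out3, "transformed")))
})

test_that("two-group differential handles identities and degenerate assays", {
  vals <- rbind(same = rep(c(1, 2, 3, 4), 2),
                flat = rep(1, 8))
  em <- make_em(vals)
  labels <- rep(c("control", "pcos"), each = 4)
  res <- suppressWarnings(two_group_differential(em, labels, case = "pcos"))
  expect_equal(res$fold_change[1], 1)
  expect_equal(res$p_value[1], 1)
  expect_equal(abs(res$t_stat[1]), 0)
  expect_equal(res$p_value[2], 1)
  expect_identical(res$flag[2], "zero_variance")
})

test_that("logistic OR with a binary predictor equals the cross-product ratio", {
  # counts a,b,c,d: case/exposed etc.
  a <- 9; b <- 5; c <- 4; d <- 12
  x <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  y <- c(rep(1, a + b), rep(0, c + d))
  em <- make_em(matrix(x, 1, length(x)))
  labels <- ifelse(y == 1, "pcos", "control")
  res <- two_group_differential(em, labels, case = "pcos")
  expect_equal(res$or_adjusted, (a * d) / (b * c), tolerance = 1e-6)
})

test_that("planted log-OR 0.69 is covered by the Wald 95% CI at nominal rate", {
  true_or <- exp(0.69)
  covered <- vapply(seq_len(500), function(i) {
    set.seed(6000 + i)
    x <- rnorm(62)
    p <- plogis(-0.3 + 0.69 * x)
    y <- rbinom(62, 1, p)
    if (sum(y) < 2 || sum(1 - y) < 2) return(NA)
    em <- make_em(matrix(x, 1, 62))
    labels <- ifelse(y == 1, "pcos", "control")
    res <- two_group_differential(em, labels, case = "pcos")
    if (res$flag != "ok") return(NA)
    res$or_lower <= true_or && true_or <= res$or_upper
  }, logical(1))
  rate <- mean(covered, na.rm = TRUE)
  expect_gte(rate, 0.93)
  expect_lte(rate, 0.97)
})

test_that("three-group ANOVA and Tukey match a brute-force oracle", {
  set.seed(54)
  g <- rep(c("control", "normo_pcos", "hyper_pcos"), each = 5)
  v <- rnorm(15) + rep(c(0, 0.5, 1.2), each = 5)
  em <- make_em(matrix(v, 1, 15))
  res <- three_group_differential(em, g)

  # explicit sums-of-squares oracle
  means <- tapply(v, g, mean)
  grand <- mean(v)
  ss_between <- sum(5 * (means - grand)^2)
  ss_within <- sum((v - means[g])^2)
  f_oracle <- (ss_between / 2) / (ss_within / 12)
  expect_equal(res$f_stat, f_oracle, tolerance = 1e-9)
  expect_equal(res$p_value, pf(f_oracle, 2, 12, lower.tail = FALSE),
               tolerance = 1e-9)

  # studentized-range oracle for each Tukey contrast
  mse <- ss_within / 12
  tukey_p <- function(a, b) {
    q <- abs(means[a] - means[b]) / sqrt(mse / 5)
    ptukey(q, nmeans = 3, df = 12, lower.tail = FALSE)
  }
  expect_equal(res$tukey_normo_pcos_vs_control,
               unname(tukey_p("normo_pcos", "control")), tolerance = 1e-6)
  expect_equal(res$tukey_hyper_pcos_vs_control,
               unname(tukey_p("hyper_pcos", "control")), tolerance = 1e-6)
  expect_equal(res$tukey_normo_pcos_vs_hyper_pcos,
               unname(tukey_p("hyper_pcos", "normo_pcos")), tolerance = 1e-6)
})

test_that("identical groups give F = 0 and all Tukey p = 1", {
  v <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("control", "normo_pcos", "hyper_pcos"), each = 4)
  em <- make_em(matrix(v, 1, 12))
  res <- three_group_differential(em, g)
  expect_equal(res$f_stat, 0, tolerance = 1e-12)
  expect_equal(res$tukey_normo_pcos_vs_control, 1, tolerance = 1e-9)
  expect_equal(res$tukey_normo_pcos_vs_hyper_pcos, 1, tolerance = 1e-9)
})

test_that("multinomial fit reduces to binary logistic with two categories", {
  set.seed(55)
  x <- cbind(x1 = rnorm(80), x2 = rnorm(80))
  eta <- -0.2 + 0.8 * x[, 1] - 0.5 * x[, 2]
  y <- rbinom(80, 1, plogis(eta))
  fit <- fit_multinomial(factor(y, levels = c(0, 1)), x)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients[, 1]), unname(coef(ref)),
               tolerance = 1e-5)
  expect_equal(unname(fit$se[, 1]),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
})

test_that("multinomial OR recovers a planted three-group signal", {
  set.seed(56)
  n <- 300
  x <- rnorm(n)
  # planted log-odds 1.0 for normo, 2.0 for hyper (vs control baseline)
  eta1 <- -0.5 + 1.0 * x
  eta2 <- -1.0 + 2.0 * x
  denom <- 1 + exp(eta1) + exp(eta2)
  u <- runif(n)
  p1 <- exp(eta1) / denom
  p2 <- exp(eta2) / denom
  g <- ifelse(u < p1, "normo_pcos", ifelse(u < p1 + p2, "hyper_pcos",
                                           "control"))
  g <- relevel(factor(g), "control")
  fit <- fit_multinomial(g, cbind(x = x))
  expect_equal(unname(fit$coefficients["x", "normo_pcos"]), 1.0,
               tolerance = 0.35)
  expect_equal(unname(fit$coefficients["x", "hyper_pcos"]), 2.0,
               tolerance = 0.45)
  expect_identical(fit$flag, "ok")
})

test_that("volcano table maps p-values and folds onto plot coordinates", {
  res <- data.frame(assay_id = c("a", "b", "c"),
                    fold_change = c(0.5, 2, 1.1),
                    p_value = c(0.05, 0.01, 0.5))
  v <- volcano_table(res, alpha = 0.05)
  expect_equal(v$neg_log10_p[1], -log10(0.05), tolerance = 1e-9)
  expect_equal(v$neg_log10_p[1], 1.301, tolerance = 1e-3)
  expect_equal(v$log2_fold_change[1], -1)
  expect_identical(v$significant, c(FALSE, TRUE, FALSE))
  expect_identical(v$direction, c("none", "up", "none"))
  # counts equal a direct filter oracle
  set.seed(57)
  res2 <- data.frame(assay_id = paste0("m", 1:200),
                     fold_change = exp(rnorm(200)),
                     p_value = runif(200))
  v2 <- volcano_table(res2, alpha = 0.05)
  expect_identical(sum(v2$significant), sum(res2$p_value < 0.05))
  expect_identical(sum(v2$direction == "up"),
                   sum(res2$p_value < 0.05 & res2$fold_change > 1))
})

test_that("Fisher exact matches hypergeometric enumeration and is symmetric", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p_value, 1)
  # the normo-vs-hyper MetS table
  tab <- matrix(c(1, 22, 6, 13), 2, 2, byrow = TRUE)
  res <- fisher_exact_2x2(tab)
  # full enumeration oracle
  enum_p <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
    support <- max(0, r1 - c2):min(r1, c1)
    probs <- vapply(support, function(k) {
      choose(c1, k) * choose(c2, r1 - k) / choose(c1 + c2, r1)
    }, numeric(1))
    obs <- probs[support == tab[1, 1]]
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  expect_equal(res$p_value, enum_p(tab), tolerance = 1e-12)
  expect_equal(res$p_value, fisher.test(tab)$p.value, tolerance = 1e-9)
  # transpose invariance
  expect_equal(fisher_exact_2x2(t(tab))$p_value, res$p_value,
               tolerance = 1e-12)
  expect_warning(z <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2,
                                              byrow = TRUE)),
                 "zero margin")
  expect_equal(z$p_value, 1)
})

test_that("Fisher exact equals enumeration across random tables (margins <= 30)", {
  set.seed(58)
  for (i in 1:60) {
    tab <- matrix(rpois(4, sample(1:7, 1)), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    mine <- fisher_exact_2x2(tab)
    ref <- fisher.test(tab)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    if (is.finite(mine$odds_ratio) && mine$odds_ratio > 0) {
      expect_equal(mine$odds_ratio, unname(ref$estimate), tolerance = 1e-3)
    }
  }
})

test_that("effect-size and power arithmetic follow their formulas", {
  expect_identical(cohens_d_from_fold(1.5, 0.4), 1.25)
  expect_identical(cohens_d_from_fold(1.0, 0.7), 0)
  expect_identical(cohens_d_from_fold(2.0, 0.5), 2)
  expect_error(cohens_d_from_fold(1.5, 0), "positive")

  expect_equal(power_two_sample_t(0, 20, 42), 0.05, tolerance = 1e-9)
  expect_gt(power_two_sample_t(1.25, 20, 42), 0.90)
  # monotone in d and n
  d_seq <- vapply(seq(0.1, 2, by = 0.1), power_two_sample_t, numeric(1),
                  n1 = 10, n2 = 10)
  expect_true(all(diff(d_seq) > 0))
  n_seq <- vapply(seq(5, 60, by = 5), function(n) {
    power_two_sample_t(0.8, n, n)
  }, numeric(1))
  expect_true(all(diff(n_seq) > 0))
  expect_error(power_two_sample_t(1, 20, 42, alpha = 1.2), "alpha")
})

test_that("null p-values are uniform across simulated assays", {
  set.seed(59)
  em <- make_em(matrix(rnorm(500 * 24), 500, 24))
  labels <- rep(c("control", "pcos"), each = 12)
  res <- two_group_differential(em, labels, case = "pcos")
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})
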