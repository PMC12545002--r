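test_that("ICC matches the brute-force ANOVA oracle on a fixed matrix", {
  x <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), nrow = 6, byrow = TRUE)[, 1:3]
  fit <- icc_absolute(x)
  expect_equal(fit$icc, icc_bruteforce(x), tolerance = 1e-10)
  fit_a <- icc_absolute(x, form = "average")
  expect_equal(fit_a$icc, icc_bruteforce(x, "average"), tolerance = 1e-10)
  # CI brackets the estimate; p small for structured data
  expect_lt(fit$conf.low, fit$icc)
  expect_gt(fit$conf.high, fit$icc)
})

test_that("ICC is 1 for raters identical across cases, ~0 for pure noise", {
  v <- c(3, 7, 1, 9, 4, 6)
  expect_equal(icc_absolute(cbind(v, v, v))$icc, 1)
  set.seed(1)
  noise <- matrix(rnorm(500 * 4), 500, 4)
  expect_lt(abs(icc_absolute(noise)$icc), 0.1)
})

test_that("zero between-case variance returns a degeneracy flag, not an error", {
  x <- matrix(5, 10, 3)
  fit <- icc_absolute(x)
  expect_true(fit$degenerate)
  expect_equal(fit$icc, 0)
})

test_that("Fleiss' kappa matches exhaustive definitional computation", {
  set.seed(7)
  x <- matrix(sample(0:2, 40, replace = TRUE), 10, 4)
  fit <- fleiss_kappa(x)
  # definitional oracle: per-case agreement, mean, chance from category props
  k <- ncol(x); n <- nrow(x)
  cats <- sort(unique(as.vector(x)))
  p_i <- apply(x, 1, function(r) {
    cnt <- table(factor(r, levels = cats))
    (sum(cnt^2) - k) / (k * (k - 1))
  })
  p_j <- as.vector(table(factor(x, levels = cats))) / (n * k)
  kappa_oracle <- (mean(p_i) - sum(p_j^2)) / (1 - sum(p_j^2))
  expect_equal(fit$kappa, kappa_oracle, tolerance = 1e-12)
})

test_that("Fleiss' kappa saturates, degrades to chance, and flags degeneracy", {
  truth <- rep(c(0, 1), 10)
  expect_equal(fleiss_kappa(cbind(truth, truth, truth))$kappa, 1)
  set.seed(2)
  rnd <- matrix(sample(0:1, 2000 * 4, replace = TRUE), 2000, 4)
  expect_lt(abs(fleiss_kappa(rnd)$kappa), 0.05)
  expect_true(fleiss_kappa(matrix(1, 10, 3))$degenerate)
})

test_that("Fleiss' kappa is invariant to category relabeling and rater order", {
  set.seed(8)
  x <- matrix(sample(0:1, 60, replace = TRUE), 15, 4)
  base <- fleiss_kappa(x)$kappa
  expect_equal(fleiss_kappa(1 - x)$kappa, base)
  expect_equal(fleiss_kappa(x[, c(3, 1, 4, 2)])$kappa, base)
})

test_that("McNemar reproduces its formula and boundary behaviour", {
  expect_equal(mcnemar_paired(b = 5, c = 5, method = "asymptotic")$statistic, 0)
  expect_equal(mcnemar_paired(b = 5, c = 5, method = "asymptotic")$p.value, 1)
  fit <- mcnemar_paired(b = 10, c = 2, method = "asymptotic")
  expect_equal(fit$statistic, 16 / 3)
  expect_equal(fit$p.value, pchisq(16 / 3, 1, lower.tail = FALSE))
  # exact two-sided binomial on one discordant pair
  expect_equal(mcnemar_paired(b = 1, c = 0, method = "exact")$p.value, 1)
  # zero discordance
  z <- mcnemar_paired(b = 0, c = 0)
  expect_true(z$zero_discordance)
  expect_equal(z$p.value, 1)
  # agrees with stats::mcnemar.test on call vectors (uncorrected)
  set.seed(3)
  a <- rbinom(200, 1, 0.4); b2 <- rbinom(200, 1, 0.5)
  fit2 <- mcnemar_paired(a, b2, method = "asymptotic")
  ref <- stats::mcnemar.test(table(factor(a, 0:1), factor(b2, 0:1)),
                             correct = FALSE)
  expect_equal(fit2$statistic, unname(ref$statistic))
  expect_equal(fit2$p.value, ref$p.value)
})

test_that("Cochran-Armitage matches definitional summation on a fixture", {
  counts <- trend_table(rbind(benign = c(20, 15, 10, 5),
                              malignant = c(1, 2, 4, 8)))
  fit <- cochran_armitage(counts)
  # independent direct summation of T and Var(T)
  s <- 1:4
  n_k <- c(21, 17, 14, 13); n1k <- c(1, 2, 4, 8); N <- sum(n_k)
  p1 <- sum(n1k) / N
  T_ <- sum(s * (n1k - n_k * p1))
  V <- p1 * (1 - p1) * (sum(n_k * s^2) - sum(n_k * s)^2 / N)
  expect_equal(fit$z, T_ / sqrt(V), tolerance = 1e-10)
  expect_equal(fit$p.value, 2 * pnorm(-abs(T_ / sqrt(V))), tolerance = 1e-10)
})

test_that("Cochran-Armitage is null at equal proportions and antisymmetric", {
  flat <- trend_table(rbind(c(30, 20, 10, 40), c(15, 10, 5, 20)))
  expect_equal(cochran_armitage(flat)$z, 0, tolerance = 1e-12)
  counts <- trend_table(rbind(c(20, 15, 10, 5), c(1, 2, 4, 8)))
  z_fwd <- cochran_armitage(counts)$z
  expect_equal(cochran_armitage(counts, scores = 4:1)$z, -z_fwd)
  # affine rescaling of scores leaves z unchanged
  expect_equal(cochran_armitage(counts, scores = 2.5 * (1:4) + 7)$z, z_fwd,
               tolerance = 1e-12)
  # single-outcome table: zero variance flag
  degen <- trend_table(rbind(c(5, 5, 5, 5), c(0, 0, 0, 0)))
  expect_true(cochran_armitage(degen)$zero_variance)
})

test_that("diagnostic metrics reproduce hand arithmetic on a confusion matrix", {
  # TP = 5, FP = 10, FN = 5, TN = 40
  truth <- c(rep(1, 10), rep(0, 50))
  calls <- c(rep(1, 5), rep(0, 5), rep(1, 10), rep(0, 40))
  dm <- tidy(diagnostic_metrics(calls, truth))
  est <- function(m) unname(dm$estimate[dm$metric == m])
  expect_equal(est("sensitivity"), 0.5)
  expect_equal(est("specificity"), 0.8)
  expect_equal(est("ppv"), 1 / 3)
  expect_equal(est("npv"), 8 / 9)
  expect_equal(est("youden"), 0.3)
  expect_equal(est("auc"), (0.5 + 0.8) / 2)
  # Clopper-Pearson CI agrees with binom.test
  ci <- dm[dm$metric == "sensitivity", ]
  ref <- binom.test(5, 10)$conf.int
  expect_equal(c(ci$conf.low, ci$conf.high), as.vector(ref))
})

test_that("perfect calls saturate every metric", {
  truth <- rep(c(0, 1), 25)
  dm <- tidy(diagnostic_metrics(truth, truth))
  expect_equal(dm$estimate[dm$metric != "youden"], rep(1, 6))
  expect_equal(dm$estimate[dm$metric == "youden"], 1)
  expect_error(diagnostic_metrics(truth, rep(1, 50)), "both classes")
})

test_that("binary-call AUC equals (Se + Sp)/2 for every random table", {
  # property over random operating points and prevalences
  set.seed(14)
  for (trial in 1:50) {
    rt <- make_ratings(n_cases = sample(30:120, 1), n_raters = sample(2:5, 1),
                       prevalence = runif(1, 0.15, 0.85),
                       sens = runif(1, 0.05, 0.95),
                       spec = runif(1, 0.05, 0.95),
                       seed = sample.int(1e6, 1))
    p <- pool_ratings(rt)
    if (length(unique(p$truth)) < 2) next
    se <- mean(p$calls[p$truth == 1] == 1)
    sp <- mean(p$calls[p$truth == 0] == 0)
    expect_equal(auc_mw(p$calls, p$truth)$auc, (se + sp) / 2,
                 tolerance = 1e-12)
  }
})

test_that("DeLong agrees with pROC on continuous paired scores", {
  skip_if_not_installed("pROC")
  set.seed(21)
  truth <- rbinom(150, 1, 0.4)
  a <- truth + rnorm(150)
  b <- truth + rnorm(150, sd = 2)
  fit <- delong_compare(a, b, truth)
  suppressMessages({
    ra <- pROC::roc(truth, a, quiet = TRUE)
    rb <- pROC::roc(truth, b, quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  })
  expect_equal(fit$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-10)
  expect_equal(fit$auc_b, as.numeric(pROC::auc(rb)), tolerance = 1e-10)
  expect_equal(fit$p.value, ref$p.value, tolerance = 1e-8)
})

test_that("DeLong boundary cases: identical scores and perfect ranking", {
  set.seed(22)
  truth <- rbinom(80, 1, 0.5)
  s <- rnorm(80)
  fit <- delong_compare(s, s, truth)
  expect_true(fit$zero_variance)
  expect_equal(fit$p.value, 1)
  expect_equal(fit$difference, 0)
  expect_equal(auc_mw(truth, truth)$auc, 1)
})

test_that("Cohen's kappa is 1 on identical calls and ~0 on independent ones", {
  x <- rep(c(0, 1), 30)
  expect_equal(cohen_kappa(x, x)$estimate, 1)
  set.seed(5)
  expect_lt(abs(cohen_kappa(rbinom(2000, 1, 0.5),
                            rbinom(2000, 1, 0.5))$estimate), 0.06)
})

test_that("cohort proportion tables compute percentages against the right denominators", {
  counts <- data.frame(item = c("total", "pos", "neg", "pos_sub"),
                       count = c(62, 11, 51, 9),
                       denominator = c("total", "total", "total", "pos"))
  out <- cohort_proportions(counts)
  expect_equal(out$pct[out$item == "pos"], 17.7)
  expect_equal(out$pct[out$item == "neg"], 82.3)
  expect_equal(out$pct[out$item == "pos_sub"], 81.8)
})
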