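## Reader-study statistics: two-way random absolute-agreement ICC, Fleiss'
## and Cohen's kappa, McNemar's paired test, the Cochran-Armitage trend test,
## binary-call diagnostic metrics with exact CIs, Mann-Whitney AUC and the
## DeLong test. All implemented from their definitional formulas; base R
## supplies the reference distributions.

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC under the two-way random-effects ANOVA model (rows = cases, columns =
#' raters), absolute-agreement definition. Single-measure form:
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' and the average-measure form `ICC(A,k)` via the Spearman-Brown relation.
#' The 95% CI uses the F-distribution method (McGraw & Wong); the p-value
#' tests `H0: ICC = 0` with `F = MS_R / MS_E` on `(n-1, (n-1)(k-1))` df.
#'
#' @param ratings cases x raters numeric matrix (or a `ratings_table` /
#'   data frame with `rater_*` columns); complete, `n >= 2`, `k >= 2`.
#' @param form `"single"` (default) or `"average"`.
#' @param conf_level confidence level, default 0.95.
#' @return An `icc_fit` list: `icc`, `conf.low`, `conf.high`, `p.value`,
#'   `ms` (mean squares), `n`, `k`, `form`, `degenerate` (TRUE when the
#'   between-case variance is zero, in which case `icc = 0`).
#' @export
icc_absolute <- function(ratings, form = c("single", "average"),
                         conf_level = 0.95) {
  form <- match.arg(form)
  x <- if (is.matrix(ratings)) ratings else ratings_matrix(ratings)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("ratings must be complete", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 cases and >= 2 raters", call. = FALSE)

  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  degenerate <- msr <= .Machine$double.eps * max(1, mse, msc)
  if (degenerate) {
    icc <- 0
    ci <- c(NA_real_, NA_real_)
    p <- NA_real_
  } else {
    icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    alpha <- 1 - conf_level
    # McGraw & Wong F-based interval for ICC(A,1)
    a <- (k * icc1) / (n * (1 - icc1))
    b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    p <- stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
    if (form == "average") {
      sb <- function(r) r * k / (1 + (k - 1) * r)
      icc <- sb(icc1); ci <- c(sb(lo), sb(hi))
    } else {
      icc <- icc1; ci <- c(lo, hi)
    }
  }
  structure(list(icc = icc, conf.low = ci[1], conf.high = ci[2], p.value = p,
                 ms = c(msr = msr, msc = msc, mse = mse), n = n, k = k,
                 form = form, conf_level = conf_level,
                 degenerate = degenerate),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(A,%s) = %.3f", if (x$form == "single") "1" else "k", x$icc))
  if (!x$degenerate) {
    cat(sprintf(" (%d%% CI %.3f-%.3f), p = %.3g",
                round(100 * x$conf_level), x$conf.low, x$conf.high, x$p.value))
  } else {
    cat(" [degenerate: zero between-case variance]")
  }
  cat(sprintf("  [n = %d cases, k = %d raters]\n", x$n, x$k))
  invisible(x)
}

#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(estimate = x$icc, conf.low = x$conf.low,
                 conf.high = x$conf.high, p.value = x$p.value,
                 form = x$form, degenerate = x$degenerate)
}

#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, msr = x$ms[["msr"]], msc = x$ms[["msc"]],
                 mse = x$ms[["mse"]])
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement for `n` cases each rated by `k` raters:
#' per-case agreement \eqn{P_i}, overall \eqn{\bar P}, chance agreement
#' \eqn{P_e = \sum_j p_j^2}, and
#' \eqn{\kappa = (\bar P - P_e)/(1 - P_e)}, with the large-sample standard
#' error and normal CI.
#'
#' @param ratings cases x raters categorical matrix (or `ratings_table`).
#' @param conf_level confidence level, default 0.95.
#' @return A `fleiss_fit` list: `kappa`, `se`, `conf.low`, `conf.high`, `z`,
#'   `p.value`, `p_bar`, `p_e`, `degenerate` (all ratings one category).
#' @export
fleiss_kappa <- function(ratings, conf_level = 0.95) {
  x <- if (is.matrix(ratings)) ratings else ratings_matrix(ratings)
  if (anyNA(x)) stop("ratings must be complete", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 cases and >= 2 raters", call. = FALSE)
  cats <- sort(unique(as.vector(x)))
  nij <- vapply(cats, function(cc) rowSums(x == cc), double(n))
  if (is.null(dim(nij))) nij <- matrix(nij, nrow = n)
  p_j <- colSums(nij) / (n * k)
  p_i <- (rowSums(nij^2) - k) / (k * (k - 1))
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (1 - p_e < .Machine$double.eps) {
    return(structure(list(kappa = NA_real_, se = NA_real_,
                          conf.low = NA_real_, conf.high = NA_real_,
                          z = NA_real_, p.value = NA_real_,
                          p_bar = p_bar, p_e = p_e, n = n, k = k,
                          degenerate = TRUE),
                     class = "fleiss_fit"))
  }
  kappa <- (p_bar - p_e) / (1 - p_e)
  se <- sqrt(2 * (p_e - (2 * k - 3) * p_e^2 + 2 * (k - 2) * sum(p_j^3))) /
    ((1 - p_e) * sqrt(n * k * (k - 1)))
  z <- kappa / se
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, se = se,
                 conf.low = kappa - zq * se, conf.high = kappa + zq * se,
                 z = z, p.value = 2 * stats::pnorm(-abs(z)),
                 p_bar = p_bar, p_e = p_e, n = n, k = k, degenerate = FALSE),
            class = "fleiss_fit")
}

#' @export
print.fleiss_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Fleiss' kappa undefined: all ratings in a single category\n")
  } else {
    cat(sprintf("Fleiss' kappa = %.3f (SE %.3f, CI %.3f-%.3f), z = %.2f, p = %.3g\n",
                x$kappa, x$se, x$conf.low, x$conf.high, x$z, x$p.value))
  }
  invisible(x)
}

#' @export
tidy.fleiss_fit <- function(x, ...) {
  tibble::tibble(estimate = x$kappa, std.error = x$se, conf.low = x$conf.low,
                 conf.high = x$conf.high, statistic = x$z, p.value = x$p.value,
                 degenerate = x$degenerate)
}

#' Cohen's kappa for two raters
#'
#' @param x,y paired categorical calls.
#' @param conf_level confidence level.
#' @return A tibble: estimate, std.error, conf.low, conf.high.
#' @export
cohen_kappa <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  cats <- sort(unique(c(x, y)))
  po <- mean(x == y)
  pe <- sum(vapply(cats, function(cc) mean(x == cc) * mean(y == cc), 0))
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(estimate = kappa, std.error = se,
                 conf.low = kappa - zq * se, conf.high = kappa + zq * se)
}

#' McNemar's test for paired binary outcomes
#'
#' Compares paired binary decisions (e.g. diagnoses with vs without map
#' assistance) through the discordant counts `b` (first positive only) and
#' `c` (second positive only). The asymptotic statistic is
#' `(b - c)^2 / (b + c)` (uncorrected by default; a continuity-corrected
#' variant is available); the exact test is the two-sided binomial on `b`
#' out of `b + c`. `method = "auto"` uses the exact test when `b + c < 25`.
#'
#' @param a,b_calls paired binary vectors, or supply `b` and `c` directly.
#' @param b,c discordant counts (alternative to `a`/`b_calls`).
#' @param method `"auto"`, `"asymptotic"`, `"corrected"`, or `"exact"`.
#' @return An `mcnemar_fit`: `statistic` (NA for exact), `p.value`, `b`, `c`,
#'   `method`, `zero_discordance` flag (p = 1 when `b + c = 0`).
#' @export
mcnemar_paired <- function(a = NULL, b_calls = NULL, b = NULL, c = NULL,
                           method = c("auto", "asymptotic", "corrected",
                                      "exact")) {
  method <- match.arg(method)
  if (is.null(b) || is.null(c)) {
    stopifnot(length(a) == length(b_calls))
    b <- sum(a == 1 & b_calls == 0)
    c <- sum(a == 0 & b_calls == 1)
  }
  if (b + c == 0) {
    return(structure(list(statistic = 0, p.value = 1, b = b, c = c,
                          method = method, zero_discordance = TRUE),
                     class = "mcnemar_fit"))
  }
  if (method == "auto") method <- if (b + c < 25) "exact" else "asymptotic"
  if (method == "exact") {
    p <- stats::binom.test(b, b + c, 0.5)$p.value
    stat <- NA_real_
  } else {
    num <- if (method == "corrected") (abs(b - c) - 1)^2 else (b - c)^2
    stat <- num / (b + c)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, p.value = p, b = b, c = c, method = method,
                 zero_discordance = FALSE),
            class = "mcnemar_fit")
}

#' @export
print.mcnemar_fit <- function(x, ...) {
  cat(sprintf("McNemar (%s): b = %d, c = %d", x$method, x$b, x$c))
  if (!is.na(x$statistic)) cat(sprintf(", chi2 = %.3f", x$statistic))
  cat(sprintf(", p = %.4g\n", x$p.value))
  invisible(x)
}

#' @export
tidy.mcnemar_fit <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value, b = x$b,
                 c = x$c, method = x$method)
}

#' Cochran-Armitage test for trend
#'
#' Tests for a monotone trend in a binary outcome across ordered categories.
#' With column totals \eqn{n_k}, outcome-row counts \eqn{n_{1k}}, scores
#' \eqn{s_k}, and pooled proportion \eqn{\bar p_1}:
#' \deqn{T = \sum_k s_k (n_{1k} - n_k \bar p_1), \quad
#'       Var(T) = \bar p_1 (1 - \bar p_1)
#'       \left(\sum_k n_k s_k^2 - (\sum_k n_k s_k)^2 / N\right)}
#' and `z = T / sqrt(Var(T))` referred to the standard normal (two-sided).
#' The trend row is row 2 (malignant) of a [trend_table()].
#'
#' @param table a [trend_table()] or plain 2 x K count matrix.
#' @param scores optional scores overriding the table's (default `1..K`).
#' @return A `trend_fit`: `z`, `p.value`, `statistic` (T), `variance`,
#'   `zero_variance` flag (all cases in one row; p undefined).
#' @export
cochran_armitage <- function(table, scores = NULL) {
  if (!inherits(table, "trend_table")) table <- trend_table(table)
  if (is.null(scores)) scores <- attr(table, "scores")
  counts <- unclass(table)
  stopifnot(length(scores) == ncol(counts))
  n_k <- colSums(counts)
  n1k <- counts[2, ]                      # malignant row
  N <- sum(n_k)
  p1 <- sum(n1k) / N
  if (p1 <= 0 || p1 >= 1) {
    return(structure(list(z = NA_real_, p.value = NA_real_,
                          statistic = NA_real_, variance = 0,
                          zero_variance = TRUE),
                     class = "trend_fit"))
  }
  T_ <- sum(scores * (n1k - n_k * p1))
  v <- p1 * (1 - p1) * (sum(n_k * scores^2) - sum(n_k * scores)^2 / N)
  z <- T_ / sqrt(v)
  structure(list(z = z, p.value = 2 * stats::pnorm(-abs(z)), statistic = T_,
                 variance = v, zero_variance = FALSE),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  if (x$zero_variance) {
    cat("Cochran-Armitage: zero variance (single-outcome table), p undefined\n")
  } else {
    cat(sprintf("Cochran-Armitage trend: Z = %.4f, p = %.4g\n", x$z, x$p.value))
  }
  invisible(x)
}

#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(statistic = x$z, p.value = x$p.value,
                 zero_variance = x$zero_variance)
}

## ---- ROC / AUC --------------------------------------------------------------

# Placement values: V10[i] = mean_j psi(x_i, y_j), V01[j] likewise, with
# psi = 1 (x > y), 1/2 (tie), 0 (x < y). Vectorized through ranks.
placements <- function(scores, truth) {
  x <- scores[truth == 1]; y <- scores[truth == 0]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Mann-Whitney AUC with DeLong standard error
#'
#' Nonparametric AUC (ties count one half) with the DeLong placement-value
#' variance and normal-approximation CI.
#'
#' @param scores per-case scores (binary calls are valid scores).
#' @param truth per-case binary truth (1 = positive); both classes required.
#' @param conf_level confidence level.
#' @return A tibble: `auc`, `std.error`, `conf.low`, `conf.high` (clamped to
#'   `[0, 1]`), `n_pos`, `n_neg`.
#' @export
auc_mw <- function(scores, truth, conf_level = 0.95) {
  stopifnot(length(scores) == length(truth))
  if (length(unique(truth)) < 2) {
    stop("truth must contain both classes", call. = FALSE)
  }
  pl <- placements(scores, truth)
  m <- length(pl$v10); n <- length(pl$v01)
  se <- sqrt(stats::var(pl$v10) / m + stats::var(pl$v01) / n)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(auc = pl$auc, std.error = se,
                 conf.low = max(0, pl$auc - zq * se),
                 conf.high = min(1, pl$auc + zq * se),
                 n_pos = m, n_neg = n)
}

#' DeLong test comparing two paired AUCs
#'
#' Both score vectors must be measured on the same cases. The covariance of
#' the two AUC estimates comes from the paired placement values; the test
#' statistic is the AUC difference over its standard error, referred to the
#' standard normal (two-sided).
#'
#' @param scores_a,scores_b paired per-case scores.
#' @param truth binary truth (1 = positive).
#' @return A `delong_fit`: `auc_a`, `auc_b`, `difference`, `std.error`, `z`,
#'   `p.value`, `var_a`, `var_b`, `covariance`, `zero_variance` flag (p = 1
#'   when the estimated variance of the difference is zero, e.g. identical
#'   score vectors).
#' @export
delong_compare <- function(scores_a, scores_b, truth) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(truth))
  if (length(unique(truth)) < 2) {
    stop("truth must contain both classes", call. = FALSE)
  }
  pa <- placements(scores_a, truth)
  pb <- placements(scores_b, truth)
  m <- length(pa$v10); n <- length(pa$v01)
  var_a <- stats::var(pa$v10) / m + stats::var(pa$v01) / n
  var_b <- stats::var(pb$v10) / m + stats::var(pb$v01) / n
  cov_ab <- stats::cov(pa$v10, pb$v10) / m + stats::cov(pa$v01, pb$v01) / n
  v <- var_a + var_b - 2 * cov_ab
  if (v <= .Machine$double.eps) {
    return(structure(list(auc_a = pa$auc, auc_b = pb$auc,
                          difference = pa$auc - pb$auc, std.error = 0,
                          z = NA_real_, p.value = 1, var_a = var_a,
                          var_b = var_b, covariance = cov_ab,
                          zero_variance = TRUE),
                     class = "delong_fit"))
  }
  z <- (pa$auc - pb$auc) / sqrt(v)
  structure(list(auc_a = pa$auc, auc_b = pb$auc,
                 difference = pa$auc - pb$auc, std.error = sqrt(v), z = z,
                 p.value = 2 * stats::pnorm(-abs(z)), var_a = var_a,
                 var_b = var_b, covariance = cov_ab, zero_variance = FALSE),
            class = "delong_fit")
}

#' @export
print.delong_fit <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.3f vs %.3f, diff %.3f, z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$difference,
              if (is.na(x$z)) 0 else x$z, x$p.value,
              if (x$zero_variance) " [zero variance]" else ""))
  invisible(x)
}

#' @export
tidy.delong_fit <- function(x, ...) {
  tibble::tibble(auc_a = x$auc_a, auc_b = x$auc_b, estimate = x$difference,
                 std.error = x$std.error, statistic = x$z, p.value = x$p.value)
}

# Wilson score interval
wilson_ci <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

prop_ci <- function(x, n, method, conf_level) {
  if (n == 0) return(c(NA_real_, NA_real_))
  if (method == "wilson") wilson_ci(x, n, conf_level)
  else as.vector(stats::binom.test(x, n,
                                   conf.level = conf_level)$conf.int)
}

#' Diagnostic performance of binary calls against pathology
#'
#' Sensitivity, specificity, PPV, NPV and accuracy with two-sided CIs
#' (Clopper-Pearson exact by default, Wilson optional), Youden's
#' `J = Se + Sp - 1`, and the single-operating-point AUC. For binary calls
#' the Mann-Whitney AUC equals `(Se + Sp)/2` exactly (the trapezoid over the
#' one operating point); its CI is DeLong's.
#'
#' @param calls per-case binary calls (1 = malignant). May pool several
#'   raters' calls (with `truth` replicated accordingly).
#' @param truth per-case binary pathology (1 = malignant); both classes
#'   required.
#' @param ci_method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @param conf_level confidence level, default 0.95.
#' @return A `diagnostic_metrics` object; `tidy()` gives a tibble with one
#'   row per metric (`sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`,
#'   `auc`, `youden`).
#' @export
diagnostic_metrics <- function(calls, truth,
                               ci_method = c("clopper-pearson", "wilson"),
                               conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(calls) == length(truth))
  if (length(unique(truth)) < 2) {
    stop("truth must contain both classes", call. = FALSE)
  }
  tp <- sum(calls == 1 & truth == 1); fn <- sum(calls == 0 & truth == 1)
  tn <- sum(calls == 0 & truth == 0); fp <- sum(calls == 1 & truth == 0)
  est <- c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
           ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
           accuracy = (tp + tn) / length(calls))
  num <- c(tp, tn, tp, tn, tp + tn)
  den <- c(tp + fn, tn + fp, tp + fp, tn + fn, length(calls))
  cis <- t(mapply(prop_ci, num, den,
                  MoreArgs = list(method = ci_method,
                                  conf_level = conf_level)))
  auc <- auc_mw(calls, truth, conf_level)
  metrics <- tibble::tibble(
    metric = c(names(est), "auc", "youden"),
    estimate = unname(c(est, auc$auc,
                        est[["sensitivity"]] + est[["specificity"]] - 1)),
    conf.low = c(cis[, 1], auc$conf.low, NA_real_),
    conf.high = c(cis[, 2], auc$conf.high, NA_real_))
  structure(list(metrics = metrics,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 ci_method = ci_method, conf_level = conf_level),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat("<diagnostic_metrics> (CI:", x$ci_method, ")\n")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.diagnostic_metrics <- function(x, ...) x$metrics

#' @export
glance.diagnostic_metrics <- function(x, ...) {
  tibble::as_tibble(as.list(x$confusion))
}
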