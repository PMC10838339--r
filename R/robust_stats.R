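#' ROUT outlier detection for a single sample (constant model)
#'
#' FDR-controlled outlier detection in the style of robust regression and
#' outlier removal, specialized to a location-only model: a robust location is
#' fitted by an iterated Tukey-biweight M-estimator, the robust standard
#' deviation of the residuals (RSDR) is taken as the 68.27th percentile of the
#' absolute residuals with an n/(n-1) small-sample correction, each residual
#' gets a two-sided Student-t tail probability (n-1 df), and outliers are
#' declared scanning from the most extreme residual inward while
#' p < Q * (n - j + 1) / n for the j-th most extreme value.
#'
#' @param values numeric vector, length >= 3.
#' @param Q target false discovery rate, in (0, 0.5); 0.01 is the 1% ROUT test.
#' @return a list of class `rout_result`: `values`, `Q`, `location`, `rsdr`,
#'   `outlier_idx` (indices into `values`), `retained` (values kept).
#' @export
rout_outliers <- function(values, Q = 0.01) {
  if (!is.numeric(values) || anyNA(values)) stop("values must be numeric, no NA")
  n <- length(values)
  if (n < 3L) stop("too few values (need >= 3)")
  if (Q <= 0 || Q >= 0.5) stop("Q must be in (0, 0.5)")
  mu <- tukey_biweight_location(values)
  r <- values - mu
  rsdr <- unname(stats::quantile(abs(r), 0.6827, type = 7)) * n / (n - 1)
  if (rsdr <= 0) {
    # more than ~68% of values sit exactly at the location: any non-zero
    # residual is infinitely extreme relative to the (zero) robust scale
    p <- ifelse(abs(r) > 0, 0, 1)
  } else {
    p <- 2 * stats::pt(-abs(r) / rsdr, df = n - 1)
  }
  ord <- order(abs(r), decreasing = TRUE)
  flagged <- integer(0)
  for (j in seq_len(n)) {
    if (p[ord[j]] < Q * (n - j + 1) / n) flagged <- c(flagged, ord[j]) else break
  }
  structure(
    list(values = values, Q = Q, location = mu, rsdr = rsdr,
         outlier_idx = sort(flagged),
         retained = if (length(flagged)) values[-flagged] else values),
    class = "rout_result")
}

# Iterated Tukey-biweight location; tuning constant 4.685 on the MAD scale.
tukey_biweight_location <- function(x, c = 4.685, tol = 1e-8, max_iter = 100L) {
  mu <- stats::median(x)
  s <- stats::mad(x)
  if (s <= 0) return(mu)
  for (i in seq_len(max_iter)) {
    u <- (x - mu) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) <= 0) break
    mu_new <- sum(w * x) / sum(w)
    if (abs(mu_new - mu) < tol) {
      mu <- mu_new
      break
    }
    mu <- mu_new
  }
  mu
}

#' Remove ROUT outliers from a vector
#'
#' Convenience wrapper around [rout_outliers()] returning the retained values
#' with the number removed as an attribute.
#'
#' @inheritParams rout_outliers
#' @return numeric vector of retained values; attribute `n_removed`.
#' @export
remove_outliers <- function(values, Q = 0.01) {
  res <- rout_outliers(values, Q)
  out <- res$retained
  attr(out, "n_removed") <- length(res$outlier_idx)
  out
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness z-statistic (D'Agostino 1970) and the kurtosis
#' z-statistic (Anscombe-Glynn 1983) into K2 = z_s^2 + z_k^2, referred to a
#' chi-squared distribution with 2 df.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `statistic` (K2) and `p.value`.
#' @export
dagostino_pearson_test <- function(x) {
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test needs n >= 8")
  if (stats::var(x) == 0) stop("constant input")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness z
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  zk <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  k2 <- zs^2 + zk^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

# Normality check with the sample-size dispatch used throughout:
# D'Agostino-Pearson for n >= 10, Shapiro-Wilk for n < 10.
# Degenerate (constant) samples are reported as non-normal with p = 0.
normality_check <- function(x) {
  n <- length(x)
  method <- if (n >= 10L) "D'Agostino-Pearson" else "Shapiro-Wilk"
  p <- if (stats::var(x) == 0) {
    0
  } else if (n >= 10L) {
    dagostino_pearson_test(x)$p.value
  } else {
    stats::shapiro.test(x)$p.value
  }
  list(method = method, p.value = p, n = n)
}

test_dispatch_result <- function(test, statistic, p, normality, n, estimates) {
  structure(list(test = test, statistic = unname(statistic), p.value = p,
                 normality = normality, n = n, estimates = estimates),
            class = "itgact_test")
}

#' @export
print.itgact_test <- function(x, ...) {
  cat(x$test, ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p.value, 4), "\n", sep = "")
  for (nm in names(x$normality))
    cat("  normality [", nm, "]: ", x$normality[[nm]]$method,
        ", p = ", signif(x$normality[[nm]]$p.value, 4), "\n", sep = "")
  invisible(x)
}

#' Two-group comparison with normality-dispatched test choice
#'
#' Normality of each group (of the paired differences when `paired = TRUE`)
#' is assessed by the D'Agostino-Pearson test for n >= 10 or Shapiro-Wilk for
#' n < 10, at alpha = 0.05. If all checks pass, a two-tailed t test is used
#' (unpaired with pooled variance, or paired); otherwise Mann-Whitney
#' (unpaired) or the Wilcoxon matched-pairs signed-rank test (paired).
#'
#' @param a,b numeric vectors (each n >= 3; equal length when paired).
#' @param paired paired comparison of b against a.
#' @return an `itgact_test` list: test name, statistic, two-sided p,
#'   per-group normality results, group sizes, group means/medians.
#' @export
two_group_test <- function(a, b, paired = FALSE) {
  if (length(a) < 3L || length(b) < 3L) stop("each group needs n >= 3")
  if (paired && length(a) != length(b)) stop("paired groups must have equal length")
  estimates <- list(mean_a = mean(a), mean_b = mean(b),
                    median_a = stats::median(a), median_b = stats::median(b))
  if (paired) {
    d <- b - a
    norm <- list(differences = normality_check(d))
    if (all(d == 0))
      return(test_dispatch_result("paired t", 0, 1, norm,
                                  c(length(a), length(b)), estimates))
    if (norm$differences$p.value > 0.05) {
      tt <- stats::t.test(b, a, paired = TRUE)
      return(test_dispatch_result("paired t", tt$statistic, tt$p.value, norm,
                                  c(length(a), length(b)), estimates))
    }
    wt <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE))
    return(test_dispatch_result("Wilcoxon", wt$statistic, wt$p.value, norm,
                                c(length(a), length(b)), estimates))
  }
  norm <- list(a = normality_check(a), b = normality_check(b))
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(test_dispatch_result("unpaired t", 0, 1, norm,
                                c(length(a), length(b)), estimates))
  if (norm$a$p.value > 0.05 && norm$b$p.value > 0.05) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    test_dispatch_result("unpaired t", tt$statistic, tt$p.value, norm,
                         c(length(a), length(b)), estimates)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    test_dispatch_result("Mann-Whitney", wt$statistic, wt$p.value, norm,
                         c(length(a), length(b)), estimates)
  }
}

#' One-sample comparison against a reference value
#'
#' Same normality dispatch as [two_group_test()], applied to
#' `values - null_value`; used for relative readouts normalized to a
#' reference condition. Chooses a two-tailed one-sample t test or the
#' one-sample Wilcoxon signed-rank test.
#'
#' @param values numeric vector, n >= 3.
#' @param null_value reference value under the null.
#' @return an `itgact_test` list.
#' @export
one_sample_test <- function(values, null_value = 0) {
  if (length(values) < 3L) stop("need n >= 3")
  d <- values - null_value
  norm <- list(values = normality_check(d))
  estimates <- list(mean = mean(values), median = stats::median(values))
  if (all(d == 0))
    return(test_dispatch_result("one-sample t", 0, 1, norm, length(values), estimates))
  if (norm$values$p.value > 0.05) {
    tt <- stats::t.test(values, mu = null_value)
    test_dispatch_result("one-sample t", tt$statistic, tt$p.value, norm,
                         length(values), estimates)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values, mu = null_value))
    test_dispatch_result("one-sample Wilcoxon", wt$statistic, wt$p.value, norm,
                         length(values), estimates)
  }
}
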