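#' One-sided Welch t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom,
#' returned as a one-row tibble. Missing values are dropped per vector.
#' Degenerate inputs (fewer than 2 usable values per group) yield a row with
#' `pvalue = NA`, treated as non-significant downstream.
#'
#' @param x,y Numeric vectors.
#' @param alternative `"greater"` tests mean(x) > mean(y); `"less"` the
#'   reverse.
#' @return Tibble with columns `statistic`, `df`, `pvalue`, `n1`, `n2`.
#' @examples
#' welch_t_one_sided(c(0.9, 0.8, 0.85), c(0.1, 0.2, 0.15), "greater")
#' @export
welch_t_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    return(tibble(statistic = NA_real_, df = NA_real_, pvalue = NA_real_,
                  n1 = n1, n2 = n2))
  }
  res <- welch_from_moments(mean(x), stats::var(x), n1,
                            mean(y), stats::var(y), n2, alternative)
  tibble(statistic = res$statistic, df = res$df, pvalue = res$pvalue,
         n1 = n1, n2 = n2)
}

# vectorised Welch test from group moments; handles zero-variance pairs
welch_from_moments <- function(m1, v1, n1, m2, v2, n2,
                               alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # both groups constant: t is 0/0 -> equal means give t = 0, p = 0.5;
  # unequal means give a saturated one-sided p in the observed direction
  degenerate <- !is.na(se2) & se2 == 0
  if (any(degenerate)) {
    eq <- degenerate & (m1 == m2)
    tstat[eq] <- 0
    df[eq] <- n1[eq] + n2[eq] - 2
    gt <- degenerate & (m1 > m2)
    lt <- degenerate & (m1 < m2)
    tstat[gt] <- Inf
    tstat[lt] <- -Inf
    df[gt | lt] <- pmax(1, n1[gt | lt] + n2[gt | lt] - 2)
  }
  p <- if (alternative == "greater") {
    pt(tstat, df, lower.tail = FALSE)
  } else {
    pt(tstat, df, lower.tail = TRUE)
  }
  # p-values live in (0, 1]: floor at the smallest representable positive
  p <- pmax(p, .Machine$double.xmin)
  list(statistic = tstat, df = df, pvalue = p)
}

#' One-sided Mann-Whitney U test
#'
#' Rank-sum test on `x` versus `y`. The p-value is exact (via
#' [stats::wilcox.test()]) when `n1 + n2 <= 12` and there are no ties,
#' otherwise a normal approximation with tie and continuity corrections is
#' used. The statistic is U for `x`, i.e. the number of (x, y) pairs with
#' x > y (+ 1/2 per tie).
#'
#' @inheritParams welch_t_one_sided
#' @param alternative `"greater"`: x stochastically larger than y.
#' @return Tibble with `statistic`, `pvalue`, `n1`, `n2`, `exact`.
#' @examples
#' mann_whitney_one_sided(c(1, 2, 3), c(4, 5, 6), "less") # exact p = 1/20
#' @export
mann_whitney_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) {
    return(tibble(statistic = NA_real_, pvalue = NA_real_,
                  n1 = n1, n2 = n2, exact = NA))
  }
  ustat <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  if (length(unique(c(x, y))) == 1L) {
    # every value tied across both groups: no evidence either way
    return(tibble(statistic = ustat, pvalue = 1, n1 = n1, n2 = n2,
                  exact = FALSE))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (n1 + n2 <= 12L) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = use_exact,
                correct = TRUE)
  )
  tibble(statistic = ustat, pvalue = min(max(wt$p.value, .Machine$double.xmin), 1),
         n1 = n1, n2 = n2, exact = use_exact)
}

# fast batch Mann-Whitney p-values used inside the permutation machinery.
# xu, xm: matrices (rows = draws) of expression values of the two groups.
# Ties counted 1/2; normal approximation with continuity correction, no tie
# term in the variance (values are continuous in practice).
mw_batch_p <- function(xu, xm, alternative = c("greater", "less"),
                       ties = TRUE) {
  alternative <- match.arg(alternative)
  n1 <- ncol(xu)
  n2 <- ncol(xm)
  if (n1 * n2 <= 5000) {
    # one expanded comparison: column j of xu against every column of xm
    big_u <- xu[, rep(seq_len(n1), each = n2), drop = FALSE]
    big_m <- xm[, rep(seq_len(n2), times = n1), drop = FALSE]
    u <- rowSums(big_u > big_m)
    if (ties) u <- u + 0.5 * rowSums(big_u == big_m)
  } else {
    u <- numeric(nrow(xu))
    for (j in seq_len(n1)) {
      a <- xu[, j]
      u <- u + rowSums(a > xm)
      if (ties) u <- u + 0.5 * rowSums(a == xm)
    }
  }
  mu <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  cc <- 0.5
  z <- if (alternative == "greater") (u - mu - cc) / sigma else (u - mu + cc) / sigma
  p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE) else pnorm(z)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Fisher's exact test with odds ratio and 95% confidence interval
#'
#' Exact hypergeometric p-value for a 2x2 table of foreground/background
#' feature counts. The odds ratio is the sample odds ratio `(a*d)/(b*c)`
#' with the Haldane-Anscombe +0.5 correction applied to every cell if (and
#' only if) any cell is zero; the 95% CI is the Woolf log-normal interval on
#' the (possibly corrected) counts.
#'
#' @param a,b Foreground counts with / without the feature.
#' @param c,d Background counts with / without the feature.
#' @param alternative `"greater"` (enrichment) or `"two.sided"`.
#' @return Tibble with `a`, `b`, `c`, `d`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `pvalue`.
#' @examples
#' fisher_exact_enrichment(8, 2, 10, 80)$odds_ratio # 32
#' @export
fisher_exact_enrichment <- function(a, b, c, d,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (sum(counts) == 0) abort("all-zero 2x2 table")
  p <- fisher_p(a, b, c, d, alternative)
  corrected <- counts + if (any(counts == 0)) 0.5 else 0
  or <- (corrected[["a"]] * corrected[["d"]]) / (corrected[["b"]] * corrected[["c"]])
  se <- sqrt(sum(1 / corrected))
  z <- qnorm(0.975)
  tibble(a = a, b = b, c = c, d = d,
         odds_ratio = unname(or),
         ci_low = unname(exp(log(or) - z * se)),
         ci_high = unname(exp(log(or) + z * se)),
         pvalue = p)
}

# exact hypergeometric p; vectorised over equal-length count vectors
fisher_p <- function(a, b, c, d, alternative = "greater") {
  m <- a + c   # feature-positive total
  n <- b + d   # feature-negative total
  k <- a + b   # foreground size
  if (alternative == "greater") {
    p <- phyper(a - 1, m, n, k, lower.tail = FALSE)
  } else {
    p <- vapply(seq_along(a), function(i) {
      lo <- max(0, k[i] - n[i])
      hi <- min(k[i], m[i])
      dens <- dhyper(lo:hi, m[i], n[i], k[i])
      obs <- dhyper(a[i], m[i], n[i], k[i])
      sum(dens[dens <= obs * (1 + 1e-7)])
    }, numeric(1))
  }
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. Missing values pass through
#' unchanged and do not count towards the number of tests.
#'
#' @param pvalues Numeric vector of p-values in (0, 1]; NAs allowed.
#' @return Adjusted p-values in the input order, clipped at 1.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.002))
#' @export
bh_adjust <- function(pvalues) {
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] <= 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Empirical permutation p-value
#'
#' Add-one smoothed rank of an observed statistic within a permutation null:
#' `(1 + #null at least as extreme) / (R + 1)`. Ties count as "as extreme",
#' and the result can never be 0.
#'
#' @param observed Observed statistic.
#' @param null_values Vector of the same statistic under the null (length R).
#' @param smaller_is_better If `TRUE` (e.g. the statistic is a p-value),
#'   "at least as extreme" means `<= observed`.
#' @return A single p-value in `[1/(R+1), 1]`.
#' @examples
#' empirical_p(0.0001, runif(999)) # 0.001 when the observed beats all nulls
#' @export
empirical_p <- function(observed, null_values, smaller_is_better = TRUE) {
  null_values <- null_values[!is.na(null_values)]
  if (length(null_values) == 0) abort("empty permutation null")
  hits <- if (smaller_is_better) sum(null_values <= observed)
          else sum(null_values >= observed)
  (1 + hits) / (length(null_values) + 1)
}
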