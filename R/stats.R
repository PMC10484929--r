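# Small-sample rank statistics: exact Mann-Whitney U by enumeration of the
# null distribution, Friedman omnibus with Dunn's Bonferroni-adjusted
# post-hoc, Shapiro-Wilk delegation, and median [IQR] / mean (s.d.)
# summaries.

#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Counts, for each attainable value u = 0..n1*n2, the number of group
#' labelings yielding U = u, out of choose(n1+n2, n1) equally likely ones
#' (no ties). Counting uses the standard recursion
#' N(m, n, u) = N(m-1, n, u-n) + N(m, n-1, u).
#'
#' @param n1,n2 group sizes.
#' @return numeric vector of length n1*n2 + 1: counts for u = 0, 1, ...,
#'   with `sum(counts) == choose(n1+n2, n1)`.
#' @export
mw_exact_distribution <- function(n1, n2) {
  assert_that(n1 >= 1 && n2 >= 1, "group sizes must be >= 1")
  # f[[j+1]] holds counts over u for (i, j) as i grows
  umax <- n1 * n2
  # dp over i = 0..n1; for each i a matrix over (j, u)
  prev <- matrix(0, n2 + 1L, umax + 1L)
  prev[, 1L] <- 1  # i = 0: U must be 0 for any j
  for (i in seq_len(n1)) {
    cur <- matrix(0, n2 + 1L, umax + 1L)
    cur[1L, 1L] <- 1  # j = 0
    for (j in seq_len(n2)) {
      shifted <- c(rep(0, j), prev[j + 1L, seq_len(umax + 1L - j)])
      cur[j + 1L, ] <- shifted + cur[j, ]
    }
    prev <- cur
  }
  counts <- prev[n2 + 1L, ]
  names(counts) <- 0:umax
  counts
}

#' Two-tailed Mann-Whitney U test with exact small-sample p-value
#'
#' U is defined as the number of (x, y) pairs with x < y, counting ties as
#' one half. For tie-free samples with n1 + n2 <= `exact_limit` the two-sided
#' p-value is exact: 2 * min(P(U <= u), P(U >= u)), capped at 1, with the
#' null distribution obtained by enumeration ([mw_exact_distribution()]).
#' Otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used and flagged in `method`.
#'
#' @param x,y numeric samples (independent groups).
#' @param exact_limit maximum n1 + n2 for exact enumeration (default 25).
#' @return list of class `mw_test` with fields `U`, `n1`, `n2`,
#'   `p_two_sided`, `method`.
#' @examples
#' # complete separation at n = 6 and 10: smallest attainable p
#' mann_whitney_exact(1:6, 7:16)$p_two_sided  # == 2 / choose(16, 6)
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 25L) {
  x <- as.numeric(x); y <- as.numeric(y)
  assert_that(length(x) >= 1 && length(y) >= 1, "both samples must be non-empty")
  assert_that(all(is.finite(c(x, y))), "samples must be finite")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(n1)])
  # rx - n1(n1+1)/2 counts pairs with y < x (+ half-ties); U counts x < y
  u <- n1 * n2 - (rx - n1 * (n1 + 1) / 2)
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 + n2 <= exact_limit) {
    counts <- mw_exact_distribution(n1, n2)
    total <- sum(counts)
    lo <- sum(counts[seq_len(u + 1L)])          # P(U <= u) * total
    hi <- sum(counts[(u + 1L):length(counts)])  # P(U >= u) * total
    p <- min(1, 2 * min(lo, hi) / total)
    method <- "exact"
  } else {
    n <- n1 + n2
    tab <- table(c(x, y))
    tiecorr <- sum(tab^3 - tab)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecorr / (n * (n - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal-approx"
  }
  structure(list(U = u, n1 = n1, n2 = n2, p_two_sided = p, method = method),
            class = "mw_test")
}

#' Exact two-sided p-value for a stated U value
#'
#' Convenience wrapper used when only the U statistic and group sizes are
#' known (e.g. recomputing a published p-value).
#' @param u observed U.
#' @param n1,n2 group sizes.
#' @return two-sided exact p-value.
#' @export
mw_exact_p <- function(u, n1, n2) {
  counts <- mw_exact_distribution(n1, n2)
  assert_that(u >= 0 && u <= n1 * n2 && u == round(u), "U out of range")
  total <- sum(counts)
  lo <- sum(counts[seq_len(u + 1L)])
  hi <- sum(counts[(u + 1L):length(counts)])
  min(1, 2 * min(lo, hi) / total)
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.3g [%s]\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' Friedman test with Dunn's post-hoc (Bonferroni-adjusted)
#'
#' Rows are blocks (e.g. animals), columns the k paired conditions. Ranks are
#' assigned within rows (mid-ranks on ties). The omnibus statistic is
#' chi2 = 12 / (n k (k+1)) * sum(Rj^2) - 3 n (k+1) on k - 1 degrees of
#' freedom. Dunn's pairwise z uses the mean-rank difference divided by
#' sqrt(k (k+1) / (6 n)); two-sided p-values are Bonferroni-adjusted over
#' all k (k-1) / 2 pairs.
#'
#' @param data numeric n x k matrix, no missing cells.
#' @return list of class `friedman_dunn` with `chi2`, `df`, `p_omnibus` and a
#'   `pairwise` data.frame (i, j, mean_rank_diff, z, p_unadjusted, p_adjusted).
#' @export
friedman_dunn <- function(data) {
  data <- as.matrix(data)
  assert_that(ncol(data) >= 3, "need k >= 3 conditions")
  assert_that(nrow(data) >= 2, "need n >= 2 blocks")
  assert_that(all(is.finite(data)), "missing or non-finite cells are not allowed")
  n <- nrow(data); k <- ncol(data)
  ranks <- t(apply(data, 1, rank))
  rs <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rs^2) - 3 * n * (k + 1)
  p_omni <- pchisq(chi2, df = k - 1, lower.tail = FALSE)
  mean_ranks <- rs / n
  se <- sqrt(k * (k + 1) / (6 * n))
  m <- k * (k - 1) / 2
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  pw <- data.frame(
    i = pairs[, 1], j = pairs[, 2],
    mean_rank_diff = mean_ranks[pairs[, 2]] - mean_ranks[pairs[, 1]]
  )
  pw$z <- abs(pw$mean_rank_diff) / se
  pw$p_unadjusted <- 2 * pnorm(-pw$z)
  pw$p_adjusted <- pmin(1, m * pw$p_unadjusted)
  structure(list(chi2 = chi2, df = k - 1, p_omnibus = p_omni,
                 mean_ranks = mean_ranks, pairwise = pw, n = n, k = k),
            class = "friedman_dunn")
}

#' @export
print.friedman_dunn <- function(x, ...) {
  cat(sprintf("Friedman chi2 = %.4g on %d df, p = %.3g (n = %d, k = %d)\n",
              x$chi2, x$df, x$p_omnibus, x$n, x$k))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper around [stats::shapiro.test()] with explicit handling of
#' degenerate (constant) samples.
#' @param x numeric sample, 3 <= n <= 2000.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(x) {
  x <- as.numeric(x)
  assert_that(length(x) >= 3 && length(x) <= 2000,
              "Shapiro-Wilk requires 3 <= n <= 2000")
  if (diff(range(x)) == 0)
    stop_brainfrac("sample is constant; normality is degenerate/undefined")
  s <- shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Summarise a sample as median [IQR] or mean (s.d.)
#'
#' Quartiles use linear interpolation between order statistics
#' (quantile type 7); the standard deviation uses the n - 1 denominator.
#'
#' @param x numeric sample, n >= 1.
#' @param mode "median_iqr" (default) or "mean_sd".
#' @return list with `mode`, `center`, `lo`, `hi` (quartiles, or center -/+ sd),
#'   `n`, and a preformatted `label`.
#' @export
summarize_sample <- function(x, mode = c("median_iqr", "mean_sd")) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  assert_that(length(x) >= 1, "empty sample")
  assert_that(all(is.finite(x)), "sample must be finite")
  if (mode == "median_iqr") {
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    out <- list(mode = mode, center = q[2], lo = q[1], hi = q[3], n = length(x))
    out$label <- sprintf("%.3g [%.3g-%.3g]", q[2], q[1], q[3])
  } else {
    m <- mean(x)
    s <- if (length(x) > 1) sd(x) else NA_real_
    out <- list(mode = mode, center = m, lo = m - s, hi = m + s, n = length(x))
    out$label <- sprintf("%.3g (%.3g)", m, s)
  }
  out
}
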