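#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Computes the exact hypergeometric p-value for a 2x2 contingency table with
#' fixed margins. The default two-sided p sums the probabilities of all tables
#' (with the observed margins) whose probability does not exceed that of the
#' observed table -- the minimum-likelihood convention used by most software.
#' One-tailed p-values are available through \code{alternative}, matching the
#' output of classical web calculators that report both tails.
#'
#' @param table 2x2 integer matrix, or a vector \code{c(a, b, c, d)} filled
#'   row-wise.
#' @param alternative "two.sided" (default), "less" or "greater"; tails refer
#'   to the \code{[1,1]} cell with margins fixed.
#' @return The p-value as a single numeric.
#' @examples
#' fisher_exact_2x2(matrix(c(9, 30, 45, 76), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.vector(t(as.matrix(table)))
  if (length(x) != 4L) stop("'table' must be 2x2")
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  m <- a + c_          # first-column margin
  n <- b + d           # second-column margin
  k <- a + b           # first-row margin
  if (m + n == 0L) stop("table has no observations")
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  p <- switch(alternative,
    two.sided = sum(probs[probs <= pobs * (1 + 1e-7)]),
    less      = stats::phyper(a, m, n, k),
    greater   = stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
  )
  min(1, p)
}

#' One-degree-of-freedom goodness-of-fit chi-square for inside/outside counts
#'
#' Compares observed inside/outside counts with their expectations, as used to
#' test whether genomic elements are over-represented inside breakpoint
#' association windows. With \code{correction = TRUE} (default) the Yates
#' continuity correction is applied, clamping \eqn{|O - E| - 0.5} at zero so
#' the statistic is never negative when observed equals expected.
#'
#' @param obs_in,obs_out observed counts inside / outside.
#' @param exp_in,exp_out expected counts (must be positive).
#' @param correction apply the continuity correction (default TRUE).
#' @return list with \code{statistic} and \code{p.value} (upper tail, 1 df).
#' @export
chisq_gof_1df <- function(obs_in, obs_out, exp_in, exp_out, correction = TRUE) {
  if (any(c(exp_in, exp_out) <= 0)) stop("expected counts must be positive")
  if (any(c(obs_in, obs_out) < 0)) stop("observed counts must be non-negative")
  o <- c(obs_in, obs_out); e <- c(exp_in, exp_out)
  dev <- abs(o - e)
  if (correction) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / e)
  list(statistic = stat, p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value by enumeration of the rank-sum null distribution when the
#' smaller sample has at most \code{exact_max} observations and there are no
#' ties; otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max largest min(n, m) for which the exact path is taken.
#' @return list with \code{statistic} (U for x), \code{p.value}, \code{method}.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && min(n, m) <= exact_max) {
    # exact two-sided p: the null distribution of U is symmetric about nm/2,
    # so double the smaller tail
    p <- 2 * stats::pwilcox(min(u, n * m - u), n, m)
    return(list(statistic = u, p.value = min(1, p), method = "exact"))
  }
  mu <- n * m / 2
  tie_tab <- table(r)
  sigma2 <- n * m / 12 * ((n + m + 1) - sum(tie_tab^3 - tie_tab) /
                            ((n + m) * (n + m - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p.value = 1, method = "normal"))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(0, z)
  list(statistic = u, p.value = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
       method = "normal")
}

#' Hochberg-Benjamini step-up multiple-testing correction
#'
#' Controls the false discovery rate across a family of tests: p-values are
#' sorted ascending and the largest k with p(k) <= k*q/m defines the rejection
#' set (every p-value at or below p(k) is flagged).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param q target FDR level (default 0.05).
#' @return logical vector of rejection flags, in the input order.
#' @examples
#' hochberg_benjamini(c(0.001, 0.01, 0.02, 0.9))
#' @export
hochberg_benjamini <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p_values)
  s <- sort(p_values)
  ok <- which(s <= seq_len(m) * q / m)
  if (length(ok) == 0) return(rep(FALSE, m))
  p_values <= s[max(ok)]
}

#' Crossover rate from sectored-colony counts
#'
#' In the colony-sectoring assay a reciprocal crossover produces a red/white
#' sectored colony only when the two recombinant chromosomes segregate into
#' different daughter cells, which happens half the time; the crossover rate
#' is therefore twice the sectored-colony frequency. The binomial confidence
#' interval on the frequency (Clopper-Pearson) is propagated by doubling.
#'
#' @param n_sectored number of red/white sectored colonies.
#' @param n_total total colonies scored (> 0).
#' @param level confidence level (default 0.95).
#' @return list with \code{frequency}, \code{rate}, \code{ci_lo}, \code{ci_hi}.
#' @export
crossover_rate <- function(n_sectored, n_total, level = 0.95) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_sectored < 0 || n_sectored > n_total) stop("n_sectored out of range")
  f <- n_sectored / n_total
  a <- (1 - level) / 2
  lo <- if (n_sectored == 0) 0 else stats::qbeta(a, n_sectored, n_total - n_sectored + 1)
  hi <- if (n_sectored == n_total) 1 else stats::qbeta(1 - a, n_sectored + 1, n_total - n_sectored)
  list(frequency = f, rate = 2 * f, ci_lo = 2 * lo, ci_hi = 2 * hi)
}

#' Sample median with a distribution-free confidence interval
#'
#' The confidence interval is derived from binomial order statistics: the
#' interval \code{(x[(j)], x[(k)])} covers the population median with
#' probability \code{P(j <= B < k)} for \code{B ~ Binomial(n, 1/2)}; the
#' tightest symmetric pair achieving at least \code{level} is used.
#'
#' @param values numeric vector (non-empty).
#' @param level confidence level (default 0.95).
#' @return list with \code{median}, \code{ci_lo}, \code{ci_hi}.
#' @export
median_with_ci <- function(values, level = 0.95) {
  if (length(values) == 0) stop("empty input")
  x <- sort(values)
  n <- length(x)
  med <- stats::median(x)
  if (n == 1) return(list(median = med, ci_lo = x[1], ci_hi = x[1]))
  # largest j such that the order-statistic interval [x_(j), x_(n-j+1)]
  # has coverage >= level
  j <- stats::qbinom((1 - level) / 2, n, 0.5)
  while (j > 0 &&
         (stats::pbinom(n - j, n, 0.5) - stats::pbinom(j - 1, n, 0.5)) < level)
    j <- j - 1
  if (j < 1) j <- 1
  list(median = med, ci_lo = x[j], ci_hi = x[n - j + 1])
}
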