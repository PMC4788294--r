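# independent oracle: hypergeometric table probability from log-binomials,
# avoiding dhyper (which the implementation uses)
table_prob <- function(a, m, n, k) {
  exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
}
fisher_enum <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, table_prob, 0, m, n, k)
  pobs <- table_prob(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

test_that("Fisher exact matches full hypergeometric enumeration on small tables", {
  set.seed(11)
  for (rep in 1:50) {
    x <- as.vector(stats::rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    expect_equal(fisher_exact_2x2(x), fisher_enum(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher exact reproduces published contingency comparisons", {
  # SCB/DSCB split in hyper-Rec strains (9/30) vs wild type (45/76)
  p1 <- fisher_exact_2x2(matrix(c(9, 30, 45, 76), 2, byrow = TRUE))
  expect_equal(round(p1, 2), 0.12)
  expect_equal(p1, stats::fisher.test(matrix(c(9, 30, 45, 76), 2))$p.value,
               tolerance = 1e-9)
  # simple/complex tract split: the published value corresponds to the
  # one-tailed hypergeometric p (the classical calculators report both tails)
  tbl <- matrix(c(17, 25, 82, 39), 2, byrow = TRUE)
  expect_equal(round(fisher_exact_2x2(tbl, "less"), 3), 0.002)
  expect_equal(round(fisher_exact_2x2(tbl), 3), 0.003)
  expect_equal(fisher_exact_2x2(c(5, 5, 5, 5)), 1)
})

test_that("Fisher exact is invariant under transposition and row/column swaps", {
  set.seed(12)
  for (rep in 1:20) {
    x <- matrix(sample(0:15, 4, TRUE), 2)
    p <- fisher_exact_2x2(x)
    expect_equal(fisher_exact_2x2(t(x)), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(x[2:1, 2:1]), p, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "non-negative")
})

test_that("chi-square goodness of fit matches the closed two-cell form and published values", {
  # uncorrected statistic has the closed form (O-E)^2 (1/E_in + 1/E_out)
  set.seed(13)
  for (rep in 1:20) {
    N <- sample(500:5e4, 1)
    e_in <- runif(1, 5, 200); e_out <- N - e_in
    o_in <- rpois(1, e_in); o_out <- N - o_in
    g <- chisq_gof_1df(o_in, o_out, e_in, e_out, correction = FALSE)
    expect_equal(g$statistic, (o_in - e_in)^2 * (1 / e_in + 1 / e_out),
                 tolerance = 1e-12)
  }
  # published gamma-H2AX, ARS and weakly-transcribed-gene rows
  expect_equal(round(chisq_gof_1df(234, 27028, 189, 27073)$p.value, 4), 0.0012)
  expect_equal(round(chisq_gof_1df(69, 13175, 92, 13152)$p.value, 3), 0.019)
  expect_equal(round(chisq_gof_1df(118, 13298, 93, 13323)$p.value, 2), 0.01)
  # obs = exp gives statistic 0, p 1 (clamped correction)
  g0 <- chisq_gof_1df(50, 950, 50, 950)
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p.value, 1)
  # statistic 1.90 by hand for obs (60, 940) vs exp (50, 950)
  g1 <- chisq_gof_1df(60, 940, 50, 950)
  expect_equal(g1$statistic, 9.5^2 / 50 + 9.5^2 / 950, tolerance = 1e-12)
  expect_equal(round(g1$p.value, 3), 0.168)
  expect_error(chisq_gof_1df(1, 2, 0, 3), "positive")
})

# permutation oracle for the rank-sum test: enumerate every assignment of
# ranks to the x-sample
mw_enum <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(i) sum(r[i])) - n * (n + 1) / 2
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

test_that("Mann-Whitney exact path agrees with permutation enumeration", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$p.value, 1 / 3, tolerance = 1e-12)
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    v <- sample(1000, n + m)  # distinct values: no ties
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    expect_equal(mann_whitney(x, y)$p.value, mw_enum(x, y), tolerance = 1e-9)
  }
})

test_that("Mann-Whitney approximation path is sane and symmetric", {
  set.seed(15)
  x <- rlnorm(30, log(18.2), 0.8)
  y <- rlnorm(9, log(7.9), 1.0)
  res <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-9)
  z <- c(5, 5, 7, 7, 9, 9, 11, 11, 13)
  expect_equal(mann_whitney(z, z)$p.value, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

# brute-force step-up evaluation straight from the definition
bh_brute <- function(p, q) {
  m <- length(p)
  s <- sort(p)
  k_set <- which(vapply(seq_len(m), function(k) s[k] <= k * q / m, NA))
  if (length(k_set) == 0) return(rep(FALSE, m))
  p <= s[max(k_set)]
}

test_that("step-up FDR correction equals brute-force evaluation of its definition", {
  set.seed(16)
  grid <- seq(0.01, 1, by = 0.01)
  for (rep in 1:200) {
    p <- sample(grid, sample(1:6, 1), replace = TRUE)
    expect_identical(hochberg_benjamini(p, 0.05), bh_brute(p, 0.05))
  }
  expect_identical(hochberg_benjamini(c(0.001, 0.01, 0.02, 0.9)),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(hochberg_benjamini(0.04), TRUE)
  expect_error(hochberg_benjamini(c(0.1, 0)), "0, 1")
})

test_that("crossover rate doubles the sectored-colony frequency with a binomial CI", {
  r <- crossover_rate(25, 1e5)
  expect_equal(r$rate, 5.0e-4)
  expect_equal(r$rate, 2 * r$frequency)
  r0 <- crossover_rate(0, 1000)
  expect_equal(r0$rate, 0)
  expect_gt(r0$ci_hi, 0)
  # published wild-type sector frequency 3.3e-6 implies rate 6.6e-6
  expect_equal(crossover_rate(33, 1e7)$rate, 6.6e-6)
  expect_error(crossover_rate(1, 0), "positive")
})

test_that("median CI uses symmetric binomial order statistics with coverage >= level", {
  expect_equal(median_with_ci(5), list(median = 5, ci_lo = 5, ci_hi = 5))
  # oracle: enumerate symmetric order-statistic pairs by direct binomial sums
  coverage <- function(j, n) sum(dbinom(j:(n - j), n, 0.5))
  for (n in c(8, 9, 20, 101)) {
    x <- sort(rnorm(n))
    ci <- median_with_ci(x)
    j <- match(ci$ci_lo, x)
    expect_equal(ci$ci_hi, x[n - j + 1])
    expect_gte(coverage(j, n), 0.95)
    if (j + 1 <= n - j) expect_lt(coverage(j + 1, n), 0.95)
  }
})
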