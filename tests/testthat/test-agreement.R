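test_that("Bland-Altman reproduces the hand-computed fixture", {
  ba <- bland_altman(c(10, 20, 30), c(12, 19, 31))
  expect_equal(ba$mean_diff, -2 / 3)
  expect_equal(ba$sd_diff, sd(c(-2, 1, -1)))
  expect_equal(ba$loa_low, -2 / 3 - 1.959964 * ba$sd_diff, tolerance = 1e-6)
  expect_equal(ba$loa_high, -2 / 3 + 1.959964 * ba$sd_diff, tolerance = 1e-6)
  expect_true(ba$loa_low < ba$mean_diff && ba$mean_diff < ba$loa_high)
})

test_that("Bland-Altman translation and degenerate-agreement behaviour", {
  set.seed(2)
  a <- rnorm(25, 10); b <- a + rnorm(25, 0, 0.5)
  ba0 <- bland_altman(a, b)
  ba1 <- bland_altman(a, b + 3)
  expect_equal(ba1$mean_diff, ba0$mean_diff - 3)
  expect_equal(ba1$sd_diff, ba0$sd_diff)

  eq <- bland_altman(a, a)
  expect_equal(eq$mean_diff, 0)
  expect_equal(c(eq$loa_low, eq$loa_high), c(0, 0))
  expect_true(is.na(eq$h0_p))
  expect_match(eq$note, "zero difference variance")
})

test_that("Passing-Bablok recovers the identity line and matches the exhaustive oracle", {
  pb <- passing_bablok(1:10, 1:10 + 0)
  expect_equal(pb$slope, 1)
  expect_equal(pb$intercept, 0)

  set.seed(14)
  for (n in c(7, 10, 13, 15)) {
    a <- round(runif(n, 1, 60), 2)
    b <- round(1.2 * a + rnorm(n, 0, 3), 2)
    pb <- passing_bablok(a, b)
    expect_equal(pb$slope, pb_oracle_slope(a, b))
    expect_true(pb$slope_ci[1] <= pb$slope && pb$slope <= pb$slope_ci[2])
  }
})

test_that("swapping the methods inverts the Passing-Bablok slope", {
  # with an odd number of pairwise slopes the shifted median maps exactly
  set.seed(3)
  a <- runif(11, 5, 50); b <- 1.3 * a + rnorm(11, 0, 2)
  s_ab <- passing_bablok(a, b)$slope
  s_ba <- passing_bablok(b, a)$slope
  expect_equal(s_ba, 1 / s_ab, tolerance = 1e-12)
})

test_that("Passing-Bablok rejects datasets dominated by identical points", {
  expect_error(passing_bablok(rep(1, 6), rep(2, 6)), "identical point pairs")
})

test_that("Cusum linearity: exact lines give p near 1, curvature is detected, scaling is neutral", {
  pb <- passing_bablok(1:20, 2 * (1:20) + 1)
  expect_equal(cusum_linearity(pb)$p_value, 1)

  set.seed(9)
  hits <- 0; nrep <- 20
  for (r in seq_len(nrep)) {
    x <- runif(50, 0, 10)
    y <- x^2 + rnorm(50, 0, 1)
    p <- cusum_linearity(passing_bablok(x, y))$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / nrep, 0.8)

  x <- runif(30, 1, 20); y <- 1.1 * x + rnorm(30, 0, 0.5)
  p1 <- cusum_linearity(passing_bablok(x, y))$p_value
  p2 <- cusum_linearity(passing_bablok(10 * x, 10 * y))$p_value
  expect_equal(p1, p2)
})

test_that("Mann-Whitney exact p matches full permutation enumeration", {
  g1 <- c(1, 2, 3); g2 <- c(10, 11, 12)
  got <- mann_whitney(g1, g2)
  expect_equal(got$U, 0)

  # enumerate all C(6,3) group assignments of the pooled data
  pooled <- c(g1, g2)
  obs_u <- 0
  us <- apply(combn(6, 3), 2, function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  })
  # two-sided exact p: probability of a U at least as extreme as observed
  n_u <- length(us)
  p_exact <- sum(us <= obs_u | us >= (9 - obs_u)) / n_u
  expect_equal(got$p_value, p_exact)   # = 0.1
  expect_equal(got$p_value, 0.1)
  expect_true(got$exact)
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(4)
  g1 <- runif(8, 1, 5); g2 <- runif(9, 2, 7)
  p0 <- mann_whitney(g1, g2)$p_value
  expect_equal(mann_whitney(exp(g1), exp(g2))$p_value, p0)
  expect_equal(mann_whitney(g1^3, g2^3)$p_value, p0)
  m <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(m$p_value, 1)
  expect_error(mann_whitney(numeric(0), g2), "non-empty")
})

test_that("ICC(2,1) matches the ANOVA mean-squares route on a toy table", {
  ratings <- matrix(c(9, 2, 5, 8, 6, 7,
                      10, 4, 6, 7, 8, 9), ncol = 2)
  got <- icc(ratings)

  # independent route: mean squares from aov()
  df <- data.frame(
    y = as.vector(ratings),
    subject = factor(rep(1:6, 2)),
    rater = factor(rep(1:2, each = 6))
  )
  ms <- summary(aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 2
  expected <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(got$icc, expected)
  expect_true(got$conf_low <= got$icc && got$icc <= got$conf_high)
})

test_that("ICC edge cases: perfect duplicates, constant shifts, degenerate input", {
  set.seed(6)
  r1 <- rnorm(10, 50, 10)
  expect_equal(icc(cbind(r1, r1))$icc, 1)
  # a constant offset between raters lowers absolute-agreement ICC
  expect_lt(icc(cbind(r1, r1 + 5))$icc, 1)
  expect_lt(icc(cbind(r1, r1 + 5))$icc, icc(cbind(r1, r1 + 0.5))$icc)
  expect_error(icc(matrix(3, 6, 2)), "constant")
  expect_error(icc(cbind(r1[1:3], r1[1:3])), "at least 5 subjects")
})

test_that("limits of agreement cover about 95 percent of Gaussian differences", {
  set.seed(123)
  n <- 10000
  a <- rnorm(n, 50, 5); b <- a + rnorm(n, 0.2, 1.5)
  ba <- bland_altman(a, b)
  inside <- mean(ba$data$diff >= ba$loa_low & ba$data$diff <= ba$loa_high)
  expect_gt(inside, 0.93); expect_lt(inside, 0.97)
})
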