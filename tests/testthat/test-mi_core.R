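test_that("discretize maps values to equal-width bins", {
  ## constant vector: everything in bin 0, one occupied level
  d0 <- discretize(c(5, 5, 5, 5), 2)
  expect_equal(d0$bins, rep(0L, 4))
  expect_equal(d0$n_levels, 1L)

  ## hand arithmetic: width 1.5, edges 0 / 1.5 / 3
  expect_equal(discretize(c(0, 1, 2, 3), 2)$bins, c(0L, 0L, 1L, 1L))

  ## d = 2 equals a midpoint threshold comparison, any vector
  set.seed(5)
  for (r in 1:20) {
    v <- rnorm(sample(5:40, 1))
    mid <- (min(v) + max(v)) / 2
    expect_equal(discretize(v, 2)$bins, as.integer(v > mid | v == max(v)))
  }

  ## edges bracket the data, top value lands in the top bin
  v <- runif(30); dg <- discretize(v, 7)
  expect_true(all(dg$bins >= 0 & dg$bins <= 6))
  expect_equal(dg$bins[which.max(v)], 6L)
  expect_true(all(diff(dg$edges) > 0))

  expect_error(discretize(numeric(0), 2), "empty")
  expect_error(discretize(c(1, 2), 1), "d must be >= 2")
  expect_error(discretize(c(1, NA), 2), "impute")
})

test_that("MI and conditional MI match brute-force oracles to 1e-12", {
  set.seed(17)
  for (r in 1:100) {
    n <- sample(10:50, 1)
    x <- sample.int(sample(2:5, 1), n, replace = TRUE)
    y <- sample.int(sample(2:5, 1), n, replace = TRUE)
    z <- sample.int(sample(2:3, 1), n, replace = TRUE)
    expect_equal(mutual_information(x, y), oracle_mi(x, y), tolerance = 1e-12)
    expect_equal(conditional_mutual_information(x, y, z), oracle_cmi(x, y, z),
                 tolerance = 1e-12)
  }
})

test_that("MI basics: identity, independence, symmetry, bounds", {
  y <- rep(0:1, 50)
  expect_equal(mutual_information(y, y), 1.0)           # fair binary, X = Y
  expect_equal(mutual_information(rep(1, 100), y), 0.0) # constant X
  set.seed(23)
  for (r in 1:25) {
    x <- sample.int(4, 30, replace = TRUE)
    w <- sample.int(3, 30, replace = TRUE)
    expect_gte(mutual_information(x, w), 0)
    expect_equal(mutual_information(x, w), mutual_information(w, x))
    expect_lte(mutual_information(x, w),
               min(entropy_bits(x), entropy_bits(w)) + 1e-12)
    z <- sample.int(2, 30, replace = TRUE)
    expect_gte(conditional_mutual_information(x, w, z), -1e-12)
    expect_equal(conditional_mutual_information(x, w, z),
                 conditional_mutual_information(w, x, z))
  }
})

test_that("XOR: marginally independent, conditionally deterministic", {
  ## exhaustive 4-outcome population
  a <- rep(c(0L, 0L, 1L, 1L), 25)
  b <- rep(c(0L, 1L, 0L, 1L), 25)
  cl <- as.integer(xor(a, b))
  expect_equal(mutual_information(a, cl), 0.0)
  expect_equal(mutual_information(b, cl), 0.0)
  expect_equal(conditional_mutual_information(a, b, cl), 1.0)
})

test_that("bias terms follow the closed forms", {
  expect_equal(relevance_bias(1, 2, 50), 0)
  expect_equal(relevance_bias(2, 1, 50), 0)
  expect_equal(relevance_bias(2, 2, 100), 0.0072135, tolerance = 1e-5)
  expect_equal(relevance_bias(2, 2, 100) / relevance_bias(2, 2, 200), 2)
  expect_equal(complementary_bias(1, 3, 2, 80), 0)
  expect_equal(complementary_bias(2, 2, 2, 100), 0.0144270, tolerance = 1e-5)
  ## algebraic identity: complementary = relevance with J as "classes", times K
  expect_equal(complementary_bias(3, 4, 2, 60),
               relevance_bias(3, 4, 60) * 2)
})

test_that("chi-squared critical value sits on the corrected bit scale", {
  expect_equal(chi2_critical_mi(1, 0.05, 100), 0.020495, tolerance = 1e-4)
  ## j_rel > critical is the raw-scale chi-squared test
  set.seed(31)
  y <- rep(0:1, each = 50)
  for (r in 1:30) {
    x <- rnorm(100)
    jr <- j_rel(x, y, 3)
    df <- attr(jr, "df")
    lhs <- jr > chi2_critical_mi(df, 0.05, 100)
    raw_mi <- as.numeric(jr) + relevance_bias(attr(jr, "n_levels"), 2, 100)
    rhs <- 2 * 100 * log(2) * raw_mi > qchisq(0.95, df)
    expect_equal(lhs, rhs)
  }
  ## monotone in df, decreasing in N; alpha -> 1 limit is -df/(2N ln 2)
  expect_true(chi2_critical_mi(4, 0.05, 100) > chi2_critical_mi(1, 0.05, 100))
  expect_true(chi2_critical_mi(2, 0.05, 50) > chi2_critical_mi(2, 0.05, 500))
  expect_equal(chi2_critical_mi(3, 1 - 1e-12, 100),
               -3 / (200 * log(2)), tolerance = 1e-6)
  expect_error(chi2_critical_mi(0, 0.05, 100), "df")
  ## literal scale keeps the uncorrected quantile
  expect_equal(chi2_critical_mi(2, 0.05, 100, scale = "literal") -
                 chi2_critical_mi(2, 0.05, 100), 2 / (200 * log(2)))
})

test_that("j_rel composes discretization, MI and bias", {
  y <- rep(0:1, each = 50)
  ## gene identical to the labels: 1 bit minus the I=K=2 bias
  expect_equal(as.numeric(j_rel(as.numeric(y), y, 2)), 1 - 0.0072135,
               tolerance = 1e-5)
  expect_equal(as.numeric(j_rel(rep(2.5, 100), y, 4)), 0)
  ## j_rel never exceeds the uncorrected MI
  set.seed(41)
  for (r in 1:20) {
    x <- rnorm(60); yy <- sample(0:1, 60, replace = TRUE)
    d <- sample(2:6, 1)
    expect_lte(as.numeric(j_rel(x, yy, d)),
               mutual_information(discretize(x, d), yy) + 1e-12)
  }
})

test_that("j_mgs adds the mean corrected complementary term", {
  set.seed(43)
  n <- 100
  y <- rep(0:1, each = n / 2)
  g <- rnorm(n) + y
  ## degenerate partner: constant gene contributes 0 - 0
  const <- discretize(rep(1, n), 2)
  expect_equal(as.numeric(j_mgs(g, y, 2, list(const))),
               as.numeric(j_rel(g, y, 2)))
  expect_error(j_mgs(g, y, 2, list()), "non-empty")

  ## XOR pair: relevance ~ 0, complementary ~ 1 bit
  a <- rbinom(2000, 1, 0.5)
  ylab <- rbinom(2000, 1, 0.5)
  b <- as.integer(xor(a, ylab))
  jm <- j_mgs(a + rnorm(2000, 0, 0.01), ylab, 2,
              list(discretize(b + rnorm(2000, 0, 0.01), 2)))
  expect_equal(as.numeric(jm), 1.0, tolerance = 0.05)

  ## random small instances match a naive recomputation via the oracles
  for (r in 1:30) {
    nn <- sample(20:40, 1)
    yy <- sample(0:1, nn, replace = TRUE)
    if (length(unique(yy)) < 2) next
    x <- rnorm(nn)
    parts <- lapply(1:2, function(i) discretize(rnorm(nn), sample(2:4, 1)))
    d <- sample(2:4, 1)
    got <- as.numeric(j_mgs(x, yy, d, parts))
    dg <- discretize(x, d)
    K <- 2; N <- nn
    rel <- oracle_mi(dg$bins, yy) - relevance_bias(dg$n_levels, K, N)
    comp <- vapply(parts, function(p)
      oracle_cmi(dg$bins, p$bins, yy) -
        complementary_bias(dg$n_levels, p$n_levels, K, N), 0)
    expect_equal(got, rel + mean(comp), tolerance = 1e-12)
  }
})

test_that("null calibration: the corrected relevance test has size alpha", {
  ## independent gene/label pairs; per-level chi-squared test, d = 2 and 3
  set.seed(47)
  n <- 100; reps <- 400
  y <- rep(0:1, each = n / 2)
  rej <- 0; jvals <- numeric(reps)
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    jr <- j_rel(x, y, 2)
    jvals[r] <- jr
    if (jr > chi2_critical_mi(attr(jr, "df"), 0.05, n)) rej <- rej + 1
  }
  band <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rej / reps - 0.05), band)
  ## bias correction centers the null
  expect_lt(abs(mean(jvals)), 3 * sd(jvals) / sqrt(reps))
})
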