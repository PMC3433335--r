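test_that("Welch-Satterthwaite matches hand-computed cases", {
  # equal-variance case: N * df exactly
  expect_equal(welchSatterthwaite(rep(1 / 10, 10), rep(1, 10), rep(4, 10)),
               40)
  expect_equal(welchSatterthwaite(0.3, 2, 7), 7)
  expect_equal(welchSatterthwaite(c(0.5, 0.5), c(1, 2), c(2, 10)),
               1.5625 / 0.13125)
  expect_error(welchSatterthwaite(numeric(), numeric(), numeric()), "empty")
  expect_error(welchSatterthwaite(1, -1, 5), "positive")
})

test_that("the analytic Strength interval matches its closed form", {
  m <- mkMatched(c(1, 1), c(1, 1), sd = 1, df = 10)
  r <- strengthCi(m, alpha = 0.05)
  expect_equal(scoreValue(r), 1)
  expect_equal(r@effDf, 20)
  half <- qt(0.975, 20) * sqrt(0.5)
  expect_equal(unname(confint2(r)), c(1 - half, 1 + half), tolerance = 1e-12)
  # quantile monotonicity: alpha = 0.5 gives a narrower interval
  r50 <- strengthCi(m, alpha = 0.5)
  expect_lt(r50@ciHigh - r50@ciLow, r@ciHigh - r@ciLow)
  # sd -> 0 collapses to the point score
  m0 <- mkMatched(c(1, 1), c(1, 1), sd = 1e-12, df = 10)
  r0 <- strengthCi(m0)
  expect_equal(unname(confint2(r0)), c(1, 1), tolerance = 1e-9)
})

test_that("gamma weights reduce to 1 at fdr = 0 and match finite differences", {
  g <- gammaWeights(beta = c(1, -2), sd = c(0.5, 0.5), df = c(10, 10),
                    p = c(0.01, 0.001), fdr = c(0, 0))
  expect_equal(g, c(1, 1))
  # finite-difference oracle: d/dbeta of fndr(beta) * beta, holding the BH
  # adjustment factor fdr/p fixed
  set.seed(21)
  for (r in 1:10) {
    n <- 5
    beta <- rnorm(n, mean = 1.2, sd = 0.3) * sample(c(-1, 1), n, TRUE)
    sd <- runif(n, 0.2, 0.5)
    df <- sample(5:30, n, TRUE)
    p <- 2 * pt(abs(beta / sd), df, lower.tail = FALSE)
    fdr <- p * runif(n, 1, 3)  # BH factor in [1, 3], kept clear of 1
    stopifnot(all(fdr < 0.95))
    g <- gammaWeights(beta, sd, df, p, fdr)
    eps <- 1e-6
    fd <- vapply(seq_len(n), function(i) {
      f <- function(b) {
        pb <- 2 * pt(abs(b / sd[i]), df[i], lower.tail = FALSE)
        (1 - (fdr[i] / p[i]) * pb) * b
      }
      (f(beta[i] + eps) - f(beta[i] - eps)) / (2 * eps)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-4)
  }
  expect_error(gammaWeights(1, 1, 10, 0, 0.5), "undefined")
})

test_that("gpiCi reduces to sqrt(N)-scaled strengthCi when fdr = 0", {
  set.seed(22)
  n <- 8
  m <- mkMatched(sample(c(-1, 1), n, TRUE), rnorm(n), sd = runif(n, 0.3, 1),
                 df = 10, p = runif(n, 0.2, 0.9), fdr = 0)
  g <- gpiCi(m)
  s <- strengthCi(m)
  expect_equal(scoreValue(g), sqrt(n) * scoreValue(s), tolerance = 1e-12)
  expect_equal(g@effDf, s@effDf, tolerance = 1e-12)
  expect_equal(g@ciHigh - g@ciLow, sqrt(n) * (s@ciHigh - s@ciLow),
               tolerance = 1e-12)
  # sd -> 0: zero-width interval at the GPI value
  m0 <- mkMatched(c(1, 1), c(1, 2), sd = 1e-12, df = 10, p = c(0.5, 0.5),
                  fdr = c(0.5, 0.5))
  r0 <- gpiCi(m0)
  expect_equal(unname(confint2(r0)), rep(scoreValue(r0), 2), tolerance = 1e-9)
})

test_that("the parametric bootstrap is seeded, degenerate at sd = 0, and guarded", {
  m0 <- mkMatched(c(1, -1), c(0.5, -0.3), sd = 1e-12)
  r <- bootstrapCi(m0, "strength", B = 200, seed = 5)
  expect_equal(unname(confint2(r)), rep(scoreValue(r), 2), tolerance = 1e-8)
  m <- mkMatched(c(1, -1), c(0.5, -0.3), sd = 0.2)
  r1 <- bootstrapCi(m, "strength", B = 200, seed = 9)
  r2 <- bootstrapCi(m, "strength", B = 200, seed = 9)
  expect_identical(confint2(r1), confint2(r2))
  expect_error(bootstrapCi(m, "strength", B = 50), "at least 100")
  expect_error(bootstrapCi(mkMatched(1, 1), "strength", B = 200), "'sd'")
})

test_that("bootstrap and analytic Strength intervals agree on matched inputs", {
  set.seed(23)
  n <- 50
  m <- mkMatched(sample(c(-1, 1), n, TRUE), rnorm(n, 0.5), sd = 0.4, df = 10)
  an <- strengthCi(m)
  bo <- bootstrapCi(m, "strength", B = 4000, seed = 24)
  expect_equal(scoreValue(bo), scoreValue(an))
  wa <- an@ciHigh - an@ciLow
  wb <- bo@ciHigh - bo@ciLow
  expect_lt(abs(wb / wa - 1), 0.05)
  expect_lt(abs(bo@ciLow - an@ciLow), 0.05 * wa)
})

test_that("MASS and EPI bootstraps resample coherently", {
  set.seed(25)
  n <- 30
  beta <- rnorm(n, 1)
  base <- 2^rnorm(n, 7, 1.5)
  m <- mkMatched(rep(1, n), beta, sd = 0.3,
                 treated = base * 2^(beta / 2), control = base * 2^(-beta / 2))
  rm <- bootstrapCi(m, "mass", B = 500, seed = 26)
  expect_true(rm@ciLow <= rm@ciHigh)
  expect_true(rm@ciLow > 0)  # strong coherent signal: interval excludes 0
  re <- bootstrapCi(m, "epi", B = 200, seed = 27)
  expect_true(re@ciLow <= re@ciHigh)
  expect_lte(abs(re@value), 15)
})

test_that("cadres are consecutive controller-ranked blocks with merged remainder", {
  counts <- setNames(rep(c(30, 20, 10, 5, 1), each = 50),
                     sprintf("g%03d", 1:250))
  ci <- buildCadres(counts, names(counts), cadreSize = 100)
  expect_identical(lengths(cadres(ci)), c(100L, 150L))
  # the first cadre holds the highest-controller genes
  expect_true(all(counts[cadres(ci)[[1]]] >= 20))
  ci2 <- buildCadres(counts[1:100], names(counts)[1:100], 100)
  expect_identical(lengths(cadres(ci2)), 100L)
  ci3 <- buildCadres(counts[1:199], names(counts)[1:199], 100)
  expect_identical(lengths(cadres(ci3)), 199L)
  expect_error(buildCadres(counts[1:50], names(counts)[1:50], 100), "fewer")
  # partition property
  expect_setequal(unlist(cadres(ci)), names(counts))
  expect_identical(anyDuplicated(unlist(cadres(ci))), 0L)
})
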