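test_that("the synthetic universe is seeded with geometric controller counts", {
  spec <- syntheticSpec(nBackground = 1000, seed = 41)
  u1 <- generateUniverse(spec)
  u2 <- generateUniverse(spec)
  expect_identical(u1, u2)
  expect_length(u1$genes, 1000)
  expect_true(all(u1$counts >= 0))
  # mean within 3 standard errors of the configured geometric mean
  se <- sqrt(spec$controllerMean * (1 + spec$controllerMean) / 1000)
  expect_lt(abs(mean(u1$counts) - spec$controllerMean), 3 * se)
  expect_error(syntheticSpec(nBackground = 100), "at least 200")
})

test_that("generated HYPs have the requested size and sign mix", {
  spec <- syntheticSpec(nBackground = 500, nDownstream = 80,
                        fracNegative = 0.25, seed = 42)
  uni <- generateUniverse(spec)
  h <- generateHyp(spec, uni)
  expect_identical(hypSize(h), 80L)
  expect_identical(sum(downstreamSigns(h) == -1L), 20L)
  expect_identical(anyDuplicated(downstreamGenes(h)), 0L)
  expect_identical(downstreamGenes(generateHyp(spec, uni)),
                   downstreamGenes(h))
})

test_that("generated contrasts satisfy the Contrast invariants and round-trip", {
  spec <- syntheticSpec(nBackground = 400, nDownstream = 50, seed = 43)
  uni <- generateUniverse(spec)
  h <- generateHyp(spec, uni)
  x <- generateContrast(h, uni, spec)
  d <- contrastData(x)
  expect_identical(nrow(d), 400L)
  expect_true(all(d$sd > 0))
  expect_true(all(d$p >= 0 & d$p <= 1))
  expect_true(all(d$treated >= 0 & d$control >= 0))
  # log2(treated/control) = beta exactly
  expect_equal(log2(d$treated / d$control), d$beta, tolerance = 1e-9)
  f <- tempfile(fileext = ".tsv")
  writeContrast(x, f)
  expect_equal(contrastData(readContrast(f))$beta, d$beta)
})

test_that("background p-values are uniform and the null Strength is centered", {
  spec <- syntheticSpec(nBackground = 2000, nDownstream = 100,
                        amplitude = 0, seed = 44)
  uni <- generateUniverse(spec)
  h <- generateHyp(spec, uni)
  x <- generateContrast(h, uni, spec)
  bg <- contrastData(x)$p[!contrastData(x)$gene %in% downstreamGenes(h)]
  expect_gt(ks.test(bg, "punif")$p.value, 0.01)
  # null calibration at reduced scale (the acceptance suite runs 1000 reps)
  seeds <- 4500 + 1:200
  vals <- vapply(seeds, function(s) {
    xs <- generateContrast(h, uni, spec, seed = s)
    scoreValue(npaStrength(alignHypContrast(h, xs)))
  }, numeric(1))
  mcSe <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * mcSe)
})

test_that("Strength recovers a nonzero amplitude by linearity", {
  spec <- syntheticSpec(nBackground = 300, nDownstream = 60, amplitude = 1,
                        seed = 45)
  uni <- generateUniverse(spec)
  h <- generateHyp(spec, uni)
  vals <- vapply(4600 + 1:200, function(s) {
    xs <- generateContrast(h, uni, spec, seed = s)
    scoreValue(npaStrength(alignHypContrast(h, xs)))
  }, numeric(1))
  mcSe <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * mcSe)
})

test_that("score ranking across contrasts follows the true amplitude at low noise", {
  spec <- syntheticSpec(nBackground = 300, nDownstream = 40,
                        noiseSd = 0.01, seed = 46)
  uni <- generateUniverse(spec)
  h <- generateHyp(spec, uni)
  amps <- seq(0, 2, by = 0.5)
  scores <- vapply(seq_along(amps), function(i) {
    xs <- generateContrast(h, uni, spec, seed = 460 + i, amplitude = amps[i])
    scoreValue(npaStrength(alignHypContrast(h, xs)))
  }, numeric(1))
  expect_identical(order(scores), order(amps))
})

test_that("robustness experiment returns Spearman 1 when nothing is removed", {
  spec <- syntheticSpec(nBackground = 300, nDownstream = 40, seed = 47)
  uni <- generateUniverse(spec)
  h <- generateHyp(spec, uni)
  contrasts <- lapply(1:4, function(i)
    generateContrast(h, uni, spec, seed = 470 + i,
                     amplitude = 0.5 * i, name = paste0("c", i)))
  r <- robustnessExperiment(h, contrasts, "strength", fractionRemoved = 0,
                            nRep = 5, seed = 48)
  expect_identical(r$correlations, rep(1, 5))
  r1 <- robustnessExperiment(h, contrasts, "strength", 0.2, nRep = 10,
                             seed = 49)
  r2 <- robustnessExperiment(h, contrasts, "strength", 0.2, nRep = 10,
                             seed = 49)
  expect_identical(r1, r2)
  expect_error(robustnessExperiment(h, contrasts[1:2], "strength"),
               "at least 3")
})

test_that("the synthetic HYP stand-ins reproduce the published structure", {
  paths <- syntheticHypSet()
  hs <- suppressMessages(lapply(paths, readHyp))
  expect_identical(vapply(hs, hypSize, integer(1)),
                   c(nfkb = 155L, ikk = 992L, tnf = 1741L, e2f1 = 80L))
  expect_identical(hypOverlap(hs$tnf, hs$e2f1), 32L)
  # NF-kB stand-in: 247 curation statements over 155 genes
  expect_identical(sum(lengths(evidence(hs$nfkb))), 247L)
  # ambiguous fractions stay below the 10% the framework tolerates
  fracAmb <- vapply(hs, function(h)
    length(droppedAmbiguous(h)) /
      (hypSize(h) + length(droppedAmbiguous(h))), numeric(1))
  expect_true(all(fracAmb < 0.10))
})
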