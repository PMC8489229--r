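# Noise variance, signal amplitude and FSC estimation.

test_that("noise variance reproduces the algebraic identities", {
  lay <- binnedLayout()
  sc <- makeBins(lay, 5)
  f1 <- randCoeffs(lay, seed = 1)
  expect_equal(noiseVariance(f1, f1, sc), rep(0, sc@nBins))
  f2 <- setCoeffs(lay, -f1@coeffs)
  p1 <- tapply(Mod(f1@coeffs)^2, f1@binId, mean)
  expect_equal(unname(noiseVariance(f1, f2, sc)), as.vector(p1),
               tolerance = 1e-12)
  # symmetry
  g <- randCoeffs(lay, seed = 2)
  expect_identical(noiseVariance(f1, g, sc), noiseVariance(g, f1, sc))
  expect_error(noiseVariance(f1, randCoeffs(binnedLayout(c(16, 16, 16), 16),
                                            seed = 1), sc),
               "different grids")
})

test_that("simulated noise variance is recovered from half maps", {
  # independent complex Gaussian noise of variance v per half -> sigma_n^2
  # = v/2 in the averaged map
  lay <- binnedLayout(c(24, 24, 24), 24, dMin = 2, nBins = 4)
  sc <- makeBins(fourierLayout(c(24, 24, 24), 24, dMin = 2), 4)
  v <- 3
  f1 <- randCoeffs(lay, sd = sqrt(v), seed = 11)
  f2 <- randCoeffs(lay, sd = sqrt(v), seed = 12)
  sn <- noiseVariance(f1, f2, sc)
  sel <- sc@counts >= 2000
  expect_true(any(sel))
  expect_true(all(abs(sn[sel] / (v / 2) - 1) < 0.05))
})

test_that("FSC identities: self-correlation, symmetry, null level", {
  lay <- binnedLayout()
  sc <- makeBins(lay, 5)
  f1 <- randCoeffs(lay, seed = 3)
  expect_equal(fscBins(f1, f1, sc), rep(1, sc@nBins), tolerance = 1e-12)
  # half-to-full arithmetic
  expect_equal(fscFullFromHalf(1 / 3), 0.5)
  expect_equal(fscFullFromHalf(1), 1)
  # independent pure-noise halves stay within 3/sqrt(N) almost always
  hits <- 0; total <- 0
  for (seed in 1:6) {
    a <- randCoeffs(lay, seed = 100 + seed)
    b <- randCoeffs(lay, seed = 200 + seed)
    f <- fscBins(a, b, sc)
    ok <- abs(f) < 3 / sqrt(sc@counts)
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gte(hits / total, 0.95)
})

test_that("zero-power bins report missing FSC, not zero", {
  lay <- binnedLayout()
  sc <- makeBins(lay, 5)
  z <- setCoeffs(lay, rep(0i, length(lay@coeffs)))
  f <- fscBins(z, z, sc)
  expect_true(all(is.na(f)))
})

test_that("signal amplitude proxy satisfies the variance bookkeeping", {
  lay <- binnedLayout()
  sc <- makeBins(lay, 5)
  fo <- randCoeffs(lay, sd = 2, seed = 4)
  # noiseless: k sigma_T = <|Fo|^2>^(1/2)
  sig <- signalAmplitude(fo, rep(0, sc@nBins), sc)
  expect_equal(sig$kSigmaT, sqrt(sig$meanFo2), tolerance = 1e-12)
  # pure-noise bin clips at zero
  sig2 <- signalAmplitude(fo, sig$meanFo2 * 1.1, sc)
  expect_true(all(sig2$kSigmaT == 0))
  expect_true(all(sig2$clipped))
  # consistency: (k sigma_T)^2 + sigma_n^2 = <|Fo|^2> within clipping
  sn <- sig$meanFo2 * 0.4
  sig3 <- signalAmplitude(fo, sn, sc)
  expect_equal(sig3$kSigmaT^2 + sn, sig3$meanFo2, tolerance = 1e-12)
})

test_that("blurred-signal simulation recovers k sigma_T per bin", {
  fx <- sharedSim()
  sim <- fx$sim
  # coarse rebinning keeps every bin above 2000 coefficients
  layout <- fourierLayout(dim(sim$half1@values), sim$half1@cell, dMin = 1.8)
  bins <- makeBins(layout, 3)
  f1 <- assignBins(fftMap(sim$half1, dMin = 1.8), bins)
  f2 <- assignBins(fftMap(sim$half2, dMin = 1.8), bins)
  fo <- setCoeffs(f1, (f1@coeffs + f2@coeffs) / 2)
  sn <- noiseVariance(f1, f2, bins)
  ks <- signalAmplitude(fo, sn, bins)$kSigmaT
  # truth on the same bins, from the recorded blurred signal
  blurred <- sim$truth$k * sim$truth$fT@coeffs
  ksTrue <- sqrt(as.vector(tapply(Mod(blurred)^2, f1@binId, mean)))
  sel <- bins@counts >= 2000
  expect_true(any(sel))
  expect_true(all(abs(ks[sel] / ksTrue[sel] - 1) < 0.05))
  # both computation routes of (k sigma_T)^2 agree where FSC_full defined
  fh <- fscBins(f1, f2, bins)
  meanFo2 <- signalAmplitude(fo, sn, bins)$meanFo2
  alt <- sqrt(pmax(0, fscFullFromHalf(fh) * meanFo2))
  expect_equal(ks[sel], alt[sel], tolerance = 0.02)
})

test_that("extra independent noise degrades expected FSC monotonically", {
  lay <- binnedLayout(c(16, 16, 16), 16, dMin = 2, nBins = 3)
  sc <- makeBins(fourierLayout(c(16, 16, 16), 16, dMin = 2), 3)
  base <- randCoeffs(lay, sd = 2, seed = 31)
  m0 <- m1 <- 0
  for (seed in 1:20) {
    n1 <- randCoeffs(lay, sd = 1, seed = 1000 + seed)
    n2 <- randCoeffs(lay, sd = 1, seed = 2000 + seed)
    e1 <- randCoeffs(lay, sd = 1, seed = 3000 + seed)
    e2 <- randCoeffs(lay, sd = 1, seed = 4000 + seed)
    a <- setCoeffs(lay, base@coeffs + n1@coeffs)
    b <- setCoeffs(lay, base@coeffs + n2@coeffs)
    a2 <- setCoeffs(lay, a@coeffs + e1@coeffs)
    b2 <- setCoeffs(lay, b@coeffs + e2@coeffs)
    m0 <- m0 + mean(fscBins(a, b, sc))
    m1 <- m1 + mean(fscBins(a2, b2, sc))
  }
  expect_lt(m1, m0)
})

test_that("map-model FSC average weights shells by coefficient count", {
  lay <- binnedLayout()
  sc <- makeBins(lay, 5)
  fo <- randCoeffs(lay, seed = 6)
  r <- fscModel(fo, fo, sc)
  expect_equal(r$average, 1, tolerance = 1e-12)
  # scale invariance of the correlation
  r2 <- fscModel(fo, setCoeffs(lay, 0.37 * fo@coeffs), sc)
  expect_equal(r2$fsc, rep(1, sc@nBins), tolerance = 1e-12)
  # weighted-average arithmetic: N = (100, 300), FSC = (1.0, 0.5) -> 0.625
  expect_equal(sum(c(100, 300) * c(1, 0.5)) / sum(c(100, 300)), 0.625)
  g <- randCoeffs(lay, seed = 7)
  rg <- fscModel(fo, g, sc)
  expect_equal(rg$average,
               sum(sc@counts * rg$fsc) / sum(sc@counts), tolerance = 1e-12)
})

test_that("the stats table carries all per-bin quantities", {
  fx <- sharedSim()
  sim <- fx$sim
  bins <- sim$truth$bins
  f1 <- assignBins(fftMap(sim$half1, dMin = 1.8), bins)
  f2 <- assignBins(fftMap(sim$half2, dMin = 1.8), bins)
  lay <- assignBins(fourierLayout(dim(sim$half1@values), sim$half1@cell,
                                  dMin = 1.8), bins)
  fc <- calcFc(fx$model, lay)
  st <- binStats(f1, f2, bins, fc = fc)
  expect_true(all(c("sigmaN2", "kSigmaT", "fscHalf", "fscFull", "D",
                    "sigmaF2", "fscModel") %in% names(st)))
  expect_equal(st$fscFull, fscFullFromHalf(st$fscHalf), tolerance = 1e-12)
  expect_true(all(st$sigmaN2 >= 0, na.rm = TRUE))
  expect_true(all(st$kSigmaT^2 <= st$meanFo2 + 1e-9, na.rm = TRUE))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeStatsTable(st, p)
  back <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(nrow(back), bins@nBins)
})
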