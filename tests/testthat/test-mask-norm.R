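# Masking, sharpen-mask-unsharpen, trimming and masked-variance
# normalization.

test_that("model mask equals the discrete ball around a single atom", {
  g <- mapGrid(array(0, c(20, 20, 20)), cell = 20)
  mod <- atomicModel("C", 10, 10, 10, box = 20)
  mask <- modelMask(mod, g, radius = 3)
  ix <- as.matrix(expand.grid(0:19, 0:19, 0:19))
  inBall <- rowSums(sweep(ix, 2, c(10, 10, 10))^2) <= 9
  expect_equal(sum(mask@values), sum(inBall))
  # radius 0: only voxels within half a voxel of the centre
  m0 <- modelMask(mod, g, radius = 0)
  expect_equal(sum(m0@values), 1)
  # two distant atoms: volumes add
  mod2 <- atomicModel(c("C", "C"), c(5, 15), c(5, 15), c(5, 15), box = 20)
  m2 <- modelMask(mod2, g, radius = 2)
  single <- modelMask(atomicModel("C", 5, 5, 5, box = 20), g, radius = 2)
  expect_equal(sum(m2@values), 2 * sum(single@values))
})

test_that("sharpen-mask-unsharpen with b = 0 is plain masking", {
  m <- randMap(c(16, 16, 16), cell = 16, seed = 3)
  mask <- mapGrid(array(rep(c(1, 0), each = 2048), c(16, 16, 16)), 16)
  smu <- sharpenMaskUnsharpen(m, m, 0, mask)
  expect_equal(smu$full@values, m@values * mask@values, tolerance = 1e-12)
})

test_that("an identity mask makes sharpen-mask-unsharpen the identity", {
  m <- randMap(c(16, 16, 16), cell = 16, seed = 4)
  ones <- mapGrid(array(1, c(16, 16, 16)), 16)
  smu <- sharpenMaskUnsharpen(m, m, 37, ones)
  expect_lt(max(abs(smu$full@values - m@values)) / max(abs(m@values)), 1e-5)
  # overflow guard
  expect_error(sharpenMaskUnsharpen(m, m, -4000, ones), "overflow")
})

test_that("sharpening before masking retains more signal than masking", {
  # blurred atom near the mask edge: the processed map keeps nearly the
  # atom's full integrated density, plain masking deletes the tails
  mod <- makeToyModel(1, box = 24, seed = 1)
  mod@atoms$b <- 80
  mod@atoms$x <- 14  # off-centre so the 3 A mask cuts into the tails
  lay <- fourierLayout(c(32, 32, 32), 24)
  dens <- mapFromFourier(calcFc(mod, lay))
  maskMod <- mod; maskMod@atoms$x <- 12  # atom near this mask's edge
  mask <- modelMask(maskMod, dens, radius = 3)
  smu <- sharpenMaskUnsharpen(dens, dens, 80, mask)
  retainedSMU <- sum(smu$full@values)
  retainedPlain <- sum(dens@values * mask@values)
  expect_gt(retainedSMU, retainedPlain)
  # and the processed map is closer to the unmasked original
  expect_lt(sum((smu$full@values - dens@values)^2),
            sum((dens@values * mask@values - dens@values)^2))
})

test_that("trimming round-trips values and absolute coordinates", {
  m <- randMap(c(64, 64, 64), cell = 64, seed = 6, origin = c(-32, -32, -32))
  mask <- mapGrid(array(0, c(64, 64, 64)), 64, originShift = c(-32, -32, -32))
  mask@values[28:37, 28:37, 28:37] <- 1
  tr <- trimBox(m, mask, padding = 5)
  expect_true(all(dim(tr$maps@values) >= 20))
  dims <- dim(tr$maps@values)
  for (d in dims) {
    x <- d
    for (p in c(2, 3, 5, 7)) while (x %% p == 0) x <- x / p
    expect_equal(x, 1)
  }
  # absolute coordinate of a voxel is unchanged
  lo <- tr$shift$startIndex
  expect_equal(tr$maps@originShift, m@originShift + lo * voxelSize(m))
  back <- untrimMap(tr$maps, tr$shift)
  expect_identical(back@values[(lo[1] + 1):(lo[1] + dims[1]),
                               (lo[2] + 1):(lo[2] + dims[2]),
                               (lo[3] + 1):(lo[3] + dims[3])],
                   tr$maps@values)
  expect_equal(back@originShift, m@originShift)
  # mask covering everything: identity
  full <- mapGrid(array(1, c(16, 16, 16)), 16)
  m2 <- randMap(c(16, 16, 16), cell = 16)
  tr2 <- suppressWarnings(trimBox(m2, full))
  expect_identical(tr2$maps@values, m2@values)
  expect_equal(tr2$shift$startIndex, c(0L, 0L, 0L))
})

test_that("symmetry translations recomputed after a shift match", {
  ops <- pointGroupOps("C4", center = c(32, 32, 32))
  mod <- makeToyModel(4, box = 64, seed = 7)
  shift <- c(10, 6, 4)
  ex1 <- expandModel(mod, ops)
  modS <- mod
  modS@atoms$x <- mod@atoms$x - shift[1]
  modS@atoms$y <- mod@atoms$y - shift[2]
  modS@atoms$z <- mod@atoms$z - shift[3]
  ex2 <- expandModel(modS, shiftOps(ops, shift))
  expect_equal(ex2@atoms$x + shift[1], ex1@atoms$x, tolerance = 1e-9)
  expect_equal(ex2@atoms$y + shift[2], ex1@atoms$y, tolerance = 1e-9)
  expect_equal(ex2@atoms$z + shift[3], ex1@atoms$z, tolerance = 1e-9)
})

test_that("masked moments: worked example and identities", {
  m <- mapGrid(array(c(2, -2, 0, 0, 0, 0, 0, 0), c(2, 2, 2)), 2)
  mask <- mapGrid(array(c(1, 1, 0, 0, 0, 0, 0, 0), c(2, 2, 2)), 2)
  mm <- maskedMoments(m, mask)
  expect_equal(mm$f, 0.25)
  # canonical 1D example: mask over the first two of four values
  m4 <- mapGrid(array(c(2, -2, 0, 0), c(4, 1, 1)), c(4, 1, 1))
  k4 <- mapGrid(array(c(1, 1, 0, 0), c(4, 1, 1)), c(4, 1, 1))
  mm4 <- maskedMoments(m4, k4)
  expect_equal(mm4$f, 0.5)
  expect_equal(mm4$muTotal, 0)
  expect_equal(mm4$varTotal, 2)
  expect_equal(mm4$varMask, 4)
  expect_equal(mm4$varMaskDirect, 4)
  # f = 1: mask moments equal total moments
  ones <- mapGrid(array(1, c(4, 1, 1)), c(4, 1, 1))
  mmF <- maskedMoments(m4, ones)
  expect_equal(mmF$varMask, mmF$varTotal)
  expect_equal(mmF$muMask, mmF$muTotal)
  expect_error(maskedMoments(m4, mapGrid(array(0, c(4, 1, 1)),
                                         c(4, 1, 1))), "empty")
})

test_that("formula route equals direct route on random map/mask pairs", {
  worst <- 0
  for (seed in 1:25) {
    set.seed(seed)
    dims <- sample(4:16, 3, replace = TRUE)
    m <- mapGrid(array(rnorm(prod(dims), mean = runif(1, -2, 2)), dims),
                 cell = dims)
    mask <- mapGrid(array(as.numeric(runif(prod(dims)) < 0.4), dims),
                    cell = dims)
    if (sum(mask@values) == 0) mask@values[1] <- 1
    mm <- maskedMoments(m, mask)
    worst <- max(worst,
                 abs(mm$varMask - mm$varMaskDirect) / max(mm$varMaskDirect,
                                                          1e-12),
                 abs(mm$muMask - mm$muMaskDirect) /
                   max(abs(mm$muMaskDirect), 1e-12))
    # mean-zero identity: var_mask * f = var_total exactly
    mz <- m
    mz@values[mask@values > 0.5] <-
      mz@values[mask@values > 0.5] - mm$muMaskDirect
    mmz <- maskedMoments(mz, mask)
    expect_equal(mmz$varMask * mmz$f,
                 mmz$varTotal + mmz$muTotal^2, tolerance = 1e-10)
  }
  expect_lt(worst, 1e-10)
})

test_that("normalization is idempotent in scale and box independent", {
  fx <- sharedSim()
  mod <- fx$model
  g <- mapGrid(array(0, c(32, 32, 32)), 32)
  mask <- modelMask(mod, g, radius = 3)
  set.seed(9)
  m <- mapGrid(array(rnorm(32^3), c(32, 32, 32)), 32)
  n1 <- normalizeMap(m, mask)
  # scaling the input does not change the output
  m10 <- m; m10@values <- m@values * 10
  n2 <- normalizeMap(m10, mask)
  expect_equal(n1@values, n2@values, tolerance = 1e-12)
  # already unit variance in mask: unchanged
  n3 <- normalizeMap(n1, mask)
  expect_equal(n3@values, n1@values, tolerance = 1e-10)
  # same signal in a larger box: identical in-mask values after
  # normalization
  big <- mapGrid(array(0, c(96, 96, 96)), 96)
  big@values[33:64, 33:64, 33:64] <- m@values
  bigMask <- mapGrid(array(0, c(96, 96, 96)), 96)
  bigMask@values[33:64, 33:64, 33:64] <- mask@values
  nb <- normalizeMap(big, bigMask)
  expect_equal(nb@values[33:64, 33:64, 33:64][mask@values > 0.5],
               n1@values[mask@values > 0.5], tolerance = 1e-6)
})
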