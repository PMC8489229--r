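# Point-group operators, expansion, special positions, ADP symmetry.

test_that("group orders and closure hold for all supported symbols", {
  orders <- c(C1 = 1, C2 = 2, C4 = 4, D3 = 6, T = 12, O = 24, I = 60)
  for (sym in names(orders)) {
    ops <- pointGroupOps(sym, center = c(5, 5, 5))
    expect_equal(length(ops@R), unname(orders[sym]), label = sym)
    # closure: every pairwise product is a member
    for (j in seq_along(ops@R)) for (k in seq_along(ops@R)) {
      p <- ops@R[[j]] %*% ops@R[[k]]
      dmin <- min(vapply(ops@R, function(q) max(abs(q - p)), numeric(1)))
      expect_lt(dmin, 1e-8)
    }
    # identity present, orthonormal, proper
    hasId <- any(vapply(ops@R, function(q) max(abs(q - diag(3))) < 1e-10,
                        logical(1)))
    expect_true(hasId, label = sym)
    expect_true(all(vapply(ops@R, function(q) abs(det(q) - 1) < 1e-8,
                           logical(1))))
  }
  expect_error(pointGroupOps("Q5"), "unknown point-group")
})

test_that("C1 is a single identity with zero translation", {
  ops <- pointGroupOps("C1", center = c(7, 8, 9))
  expect_equal(length(ops@R), 1L)
  expect_equal(ops@R[[1]], diag(3))
  expect_equal(as.vector(ops@t), c(0, 0, 0))
})

test_that("translations place the symmetry origin at the box centre", {
  c0 <- c(10, 12, 14)
  ops <- pointGroupOps("C2", center = c0)
  # the centre must be a fixed point of every operator
  for (j in seq_along(ops@R))
    expect_equal(as.vector(ops@R[[j]] %*% c0 + ops@t[, j]), c0,
                 tolerance = 1e-12)
})

test_that("model expansion transforms positions and tensors correctly", {
  mod <- makeToyModel(3, box = 20, seed = 1)
  expect_equal(expandModel(mod, pointGroupOps("C1"))@atoms[, c("x", "y", "z")],
               mod@atoms[, c("x", "y", "z")])
  # isotropic tensor is rotation invariant
  iso <- mod
  iso@atoms$b11 <- iso@atoms$b22 <- iso@atoms$b33 <- 15
  iso@atoms$b12 <- iso@atoms$b13 <- iso@atoms$b23 <- 0
  ex <- expandModel(iso, pointGroupOps("C4", center = c(10, 10, 10)))
  expect_true(all(abs(ex@atoms$b11 - 15) < 1e-12))
  expect_true(all(abs(ex@atoms$b12) < 1e-12))
  # random anisotropic tensor under C4: eigenvalues and trace preserved
  an <- mod
  an@atoms[1, c("b11", "b22", "b33", "b12", "b13", "b23")] <-
    c(30, 20, 10, 4, -2, 1)
  exA <- expandModel(an, pointGroupOps("C4", center = c(10, 10, 10)))
  B0 <- matrix(c(30, 4, -2, 4, 20, 1, -2, 1, 10), 3, 3)
  for (j in 1:4) {
    row <- exA@atoms[(j - 1) * 3 + 1, ]
    Bj <- matrix(c(row$b11, row$b12, row$b13, row$b12, row$b22, row$b23,
                   row$b13, row$b23, row$b33), 3, 3)
    expect_equal(sort(eigen(Bj)$values), sort(eigen(B0)$values),
                 tolerance = 1e-10)
    expect_equal(sum(diag(Bj)), sum(diag(B0)), tolerance = 1e-10)
  }
  # chains acquire operator suffixes
  expect_true(all(grepl("_[1-4]$", exA@atoms$chain)))
})

test_that("special positions are detected with the distance criterion", {
  ops <- pointGroupOps("C2", center = c(10, 10, 10))
  mod <- atomicModel(c("C", "N", "O"),
                     x = c(10, 10.1, 15), y = c(10, 10, 10),
                     z = c(12, 12, 12), box = 20)
  sp <- findSpecialPositions(mod, ops, epsilon = 0.25)
  expect_equal(sp$special$atom, c(1L, 2L))   # exact and 0.2 A off the axis
  expect_equal(sp$special$stabilizerSize, c(2L, 2L))
  expect_equal(sp$special$multiplicity, c(1, 1))
  # occupancy adjustment divides by the stabilizer order
  spA <- findSpecialPositions(mod, ops, adjustOccupancy = TRUE)
  expect_equal(spA$model@atoms$occ, c(0.5, 0.5, 1))
})

test_that("projection onto a special position is exact and idempotent", {
  ops <- pointGroupOps("C2", center = c(10, 10, 10))
  x <- c(10.1, 10, 12)
  sub <- cryodiff:::.subsetOps(ops, 1:2)
  pr <- projectSpecial(x, sub)
  expect_equal(pr$x, c(10, 10, 12))
  pr2 <- projectSpecial(pr$x, sub)
  expect_lt(max(abs(pr2$x - pr$x)), 1e-12)
  # already-invariant atom is a fixed point
  expect_equal(projectSpecial(c(10, 10, 5), sub)$x, c(10, 10, 5))
  # tensor symmetrization: invariant under every stabilizer element
  B <- matrix(c(30, 4, -2, 4, 20, 1, -2, 1, 10), 3, 3)
  prB <- projectSpecial(pr$x, sub, B = B)$B
  for (j in 1:2)
    expect_lt(max(abs(sub@R[[j]] %*% prB %*% t(sub@R[[j]]) - prB)), 1e-10)
  prB2 <- projectSpecial(pr$x, sub, B = prB)$B
  expect_lt(max(abs(prB2 - prB)), 1e-12)
})

test_that("restraint residuals match hand algebra and vanish after projection", {
  ops <- pointGroupOps("C2", center = c(10, 10, 10))
  sub <- cryodiff:::.subsetOps(ops, 1:2)
  delta <- 0.1; sigmaX <- 0.02
  r <- specialRestraintResiduals(c(10 + delta, 10, 12), sub,
                                 sigmaX = sigmaX)
  expect_equal(r$positional, (2 * delta)^2 / sigmaX^2, tolerance = 1e-12)
  pr <- projectSpecial(c(10 + delta, 10, 12), sub)
  B <- matrix(c(30, 4, -2, 4, 20, 1, -2, 1, 10), 3, 3)
  prB <- projectSpecial(pr$x, sub, B = B)$B
  r2 <- specialRestraintResiduals(pr$x, sub, B = prB)
  expect_lt(r2$positional, 1e-18)
  expect_lt(r2$adp, 1e-18)
  # isotropic tensors have zero ADP residual under any subgroup
  r3 <- specialRestraintResiduals(c(11, 10, 12), sub, B = diag(3) * 17)
  expect_equal(r3$adp, 0)
})

test_that("a non-closed stabilizer raises an informative error", {
  # D2 about z: an atom close to the z axis but also near (not within
  # epsilon of) other images cannot arise; instead force the pathology by
  # a large epsilon that catches an incomplete element subset under D3
  ops <- pointGroupOps("D3", center = c(0, 0, 0))
  # point whose epsilon-ball catches two 2-folds but not their C3 product
  mod <- atomicModel("C", x = 3, y = 1.6, z = 0, box = 10)
  expect_error(findSpecialPositions(mod, ops, epsilon = 3.7),
               "not closed")
})

test_that("Fc of a projected expanded model is invariant under the group", {
  ops <- pointGroupOps("C3", center = c(10, 10, 10))
  mod <- makeToyModel(3, box = 20, seed = 5)
  lay <- binnedLayout(c(20, 20, 20), 20, dMin = 2.5, nBins = 4)
  f <- calcFc(mod, lay, ops = ops)
  # applying any group operator to the whole expanded model leaves Fc fixed
  ex <- expandModel(mod, ops)
  j <- 2
  rot <- ex
  xyz <- cbind(ex@atoms$x, ex@atoms$y, ex@atoms$z) %*% t(ops@R[[j]])
  rot@atoms$x <- xyz[, 1] + ops@t[1, j]
  rot@atoms$y <- xyz[, 2] + ops@t[2, j]
  rot@atoms$z <- xyz[, 3] + ops@t[3, j]
  f2 <- calcFc(rot, lay)
  expect_lt(max(Mod(f@coeffs - f2@coeffs)), 1e-6 * max(Mod(f@coeffs)))
})

test_that("occupancy is conserved through special-position adjustment", {
  ops <- pointGroupOps("C4", center = c(10, 10, 10))
  mod <- atomicModel(c("C", "O"), x = c(10, 14), y = c(10, 11),
                     z = c(8, 9), box = 20)
  adj <- findSpecialPositions(mod, ops, adjustOccupancy = TRUE)$model
  ex <- expandModel(adj, ops)
  # electron count: the axial atom contributes once (4 copies x occ/4),
  # the general atom four times
  expect_equal(sum(ex@atoms$occ * ex@atoms$Z), 6 + 4 * 8)
  # dedupe emits coincident copies once, conserving the total
  exD <- expandModel(adj, ops, dedupe = TRUE, tol = 1e-6)
  expect_equal(sum(exD@atoms$occ * exD@atoms$Z), 6 + 4 * 8)
  expect_equal(nrow(exD@atoms), 1 + 4)
})

test_that("symmetry records serialize as MTRIX and mmCIF", {
  ops <- pointGroupOps("C2", center = c(5, 5, 5))
  mt <- symmetryRecords(ops, "mtrix")
  expect_length(mt, 6)
  expect_true(all(grepl("^MTRIX[123]", mt)))
  cf <- symmetryRecords(ops, "mmcif")
  expect_true(any(grepl("_struct_ncs_oper.matrix", cf)))
  # MTRIX written ahead of coordinates by writeModel
  p <- withr::local_tempfile(fileext = ".pdb")
  writeModel(makeToyModel(2, box = 10, seed = 1), p, ops = ops)
  lines <- readLines(p)
  expect_true(grepl("^MTRIX1", lines[1]))
})
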