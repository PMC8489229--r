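# Synthetic ground-truth generator: toy atomic models and paired half maps
# obeying the observation model F_o = k F_T + F_n, with per-coefficient
# independent complex Gaussian noise added on the Hermitian-unique half
# grid (self-conjugate coefficients receive real noise of the same total
# variance), so the reconstructed maps are exactly real and the implied
# full-map noise variance is half the per-half variance.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a toy atomic model
#'
#' Atoms are placed uniformly inside the central 60% of the box with a
#' minimum pairwise separation (doubled between heavy-atom pairs); B values
#' are drawn uniformly from \code{bRange}.  Optionally each carbon gets a
#' riding-style hydrogen at 1.0 Angstrom in a random direction, sharing the
#' parent's B.  Fully deterministic given \code{seed}.
#'
#' @param nAtoms number of heavy atoms (>= 1).
#' @param elements element symbols cycled over the atoms.
#' @param box box edge in Angstrom (scalar or length 3).
#' @param seed integer seed.
#' @param withHydrogens add one hydrogen per carbon (default FALSE).
#' @param bRange range of isotropic B values (default c(10, 40)).
#' @param minSep minimum separation in Angstrom (default 1.5; heavy pairs
#'   use twice this).
#' @return an \linkS4class{AtomicModel} with the box recorded
#' @export
makeToyModel <- function(nAtoms, elements = c("C", "N", "O"), box = 24,
                         seed = 1, withHydrogens = FALSE,
                         bRange = c(10, 40), minSep = 1.5) {
  stopifnot(nAtoms >= 1)
  if (length(box) == 1L) box <- rep(box, 3L)
  span <- 0.6 * box
  if (nAtoms > 1 && prod(span) < nAtoms * (4 / 3) * pi * minSep^3)
    stop("box too small for the requested atom count and separation")
  .withSeed(seed, {
    if (nAtoms == 1L) {
      xyz <- matrix(box / 2, 1, 3)
    } else {
      xyz <- matrix(NA_real_, nAtoms, 3)
      for (i in seq_len(nAtoms)) {
        for (try in 1:2000) {
          p <- box / 2 + (runif(3) - 0.5) * span
          if (i == 1) break
          d <- sqrt(rowSums(sweep(xyz[seq_len(i - 1), , drop = FALSE],
                                  2, p)^2))
          if (all(d >= 2 * minSep)) break
          if (try == 2000)
            stop("box too small for the separation constraint")
        }
        xyz[i, ] <- p
      }
    }
    el <- rep_len(elements, nAtoms)
    b <- runif(nAtoms, bRange[1], bRange[2])
    m <- atomicModel(el, xyz[, 1], xyz[, 2], xyz[, 3], b = b,
                     resid = "TOY", box = box)
    if (withHydrogens) {
      ci <- which(el == "C")
      if (length(ci)) {
        u <- matrix(rnorm(3 * length(ci)), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        hx <- xyz[ci, , drop = FALSE] + u
        a <- m@atoms
        h <- .emptyAtomCols(length(ci))
        h$element <- "H"; h$Z <- 1
        h$x <- hx[, 1]; h$y <- hx[, 2]; h$z <- hx[, 3]
        h$b <- b[ci]; h$chain <- "A"
        h$resno <- a$resno[ci]; h$resid <- "TOY"
        h$name <- paste0("H", seq_along(ci))
        m@atoms <- rbind(a, h)
      }
    }
    m
  })
}

#' Simulate a pair of half maps with known ground truth
#'
#' The true coefficients are \code{F_T = calcFc(model, ops)}; each half map
#' is \code{k(s) F_T + noise} with \code{k(s) = exp(-bBlur |s|^2/4)} and
#' independent zero-mean complex Gaussian noise of variance
#' \code{noiseLevel} per half-map coefficient.  The implied noise variance
#' of the averaged full map, \code{noiseLevel/2}, is recorded per bin in
#' the ground truth.  Regenerating with the same seed gives identical
#' results.
#'
#' @param model an \linkS4class{AtomicModel}; its \code{box} (or
#'   \code{cell}) defines the grid extent.
#' @param bBlur overall Gaussian blurring B in Angstrom^2 (default 60).
#' @param noiseLevel per-half-coefficient noise variance: a scalar, a
#'   per-bin vector, or NULL for the default, which sets a flat noise
#'   floor such that the half-map FSC is 0.143 in the highest-resolution
#'   bin -- the gold-standard convention for a map whose cutoff matches
#'   the resolution the data support (FSC near 1 at low resolution,
#'   decaying to the criterion at the cutoff).
#' @param dMin resolution cutoff in Angstrom.
#' @param ops optional \linkS4class{SymOpSet} applied to the model (the
#'   map is then symmetric under it).
#' @param seed integer seed.
#' @param cell box edge lengths (defaults to the model's box).
#' @param dims grid dimensions (default: FFT-friendly, voxel <= dMin/3).
#' @param nBins bin count for the recorded ground truth.
#' @return list(half1, half2 = \linkS4class{MapGrid}s, truth = list(fT,
#'   k per coefficient, bBlur, noiseLevel, sigmaN2True per bin, bins,
#'   seed, symbol))
#' @export
simulateHalfMaps <- function(model, bBlur = 60, noiseLevel = NULL,
                             dMin = 2, ops = NULL, seed = 1,
                             cell = NULL, dims = NULL, nBins = NULL) {
  if (is.null(cell)) cell <- model@box
  if (any(is.na(cell))) stop("model has no box; supply cell explicitly")
  if (length(cell) == 1L) cell <- rep(cell, 3L)
  if (is.null(dims))
    dims <- vapply(ceiling(cell / (dMin / 3)), .nextGoodSize, integer(1))
  if (dMin < 2 * max(cell / dims) - 1e-9)
    stop("dMin is below the Nyquist limit of the chosen grid")
  layout <- fourierLayout(dims, cell, dMin = dMin)
  bins <- makeBins(layout, nBins = nBins)
  layout <- assignBins(layout, bins)
  fT <- calcFc(model, layout, ops = ops)
  k <- exp(-bBlur * layout@sNorm^2 / 4)
  signal <- k * fT@coeffs
  if (is.null(noiseLevel)) {
    # FSC_half = P/(P+v) = 0.143 in the top bin  =>  v = 6 P_top
    ptop <- mean(Re(signal * Conj(signal))[layout@binId == bins@nBins])
    noiseLevel <- 6 * ptop
  }
  v <- if (length(noiseLevel) == 1L) rep(noiseLevel, bins@nBins)
       else noiseLevel
  stopifnot(length(v) == bins@nBins, all(v >= 0))
  vc <- v[layout@binId]
  .withSeed(seed, {
    mkNoise <- function() {
      n <- length(signal)
      e <- complex(real = rnorm(n, sd = sqrt(vc / 2)),
                   imaginary = rnorm(n, sd = sqrt(vc / 2)))
      sc <- layout@selfConj
      e[sc] <- complex(real = rnorm(sum(sc), sd = sqrt(vc[sc])),
                       imaginary = 0)
      e
    }
    f1 <- setCoeffs(layout, signal + mkNoise())
    f2 <- setCoeffs(layout, signal + mkNoise())
    list(half1 = mapFromFourier(f1), half2 = mapFromFourier(f2),
         truth = list(fT = fT, k = k, bBlur = bBlur, noiseLevel = v,
                      sigmaN2True = v / 2,
                      kSigmaTTrue = sqrt(.binMean(Re(signal * Conj(signal)),
                                                  layout@binId, bins@nBins)),
                      bins = bins, seed = seed,
                      symbol = if (is.null(ops)) "C1" else ops@symbol))
  })
}
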