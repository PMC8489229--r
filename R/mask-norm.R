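# Model-based masking, sharpen-mask-unsharpen preprocessing, box trimming
# with exact coordinate bookkeeping, and masked-variance normalization.
#
# The masked-moment identities: with n voxels in total, m inside the mask
# (f = m/n) and zeros outside,
#   mu_mask  = mu_total / f
#   var_mask = (var_total + mu_total^2)/f - mu_total^2/f^2
# which explains why the r.m.s.d. of a map depends on the (arbitrary) box
# size, and motivates normalizing difference maps by sd within the mask.

#' Binary mask from atom positions
#'
#' Voxels within \code{radius} of any atom are set to 1.  An optional
#' raised-cosine soft edge of width \code{softWidth} can be applied outside
#' the hard radius.
#'
#' @param model an \linkS4class{AtomicModel} (symmetry-expand first if
#'   needed).
#' @param grid a \linkS4class{MapGrid} defining the target grid.
#' @param radius mask radius in Angstrom (default 3).
#' @param softWidth raised-cosine edge width in Angstrom (default 0 =
#'   hard).
#' @return a \linkS4class{MapGrid} with values in [0, 1]
#' @export
modelMask <- function(model, grid, radius = 3, softWidth = 0) {
  a <- model@atoms
  if (nrow(a) < 1L) stop("cannot build a mask from an empty model")
  dims <- dim(grid@values)
  vox <- grid@cell / dims
  mask <- array(0, dims)
  rmax <- radius + softWidth
  for (i in seq_len(nrow(a))) {
    x <- c(a$x[i], a$y[i], a$z[i]) - grid@originShift
    lo <- pmax(1L, as.integer(floor((x - rmax) / vox)) + 1L)
    hi <- pmin(dims, as.integer(ceiling((x + rmax) / vox)) + 1L)
    if (any(lo > hi)) next
    gx <- (lo[1]:hi[1] - 1L) * vox[1] - x[1]
    gy <- (lo[2]:hi[2] - 1L) * vox[2] - x[2]
    gz <- (lo[3]:hi[3] - 1L) * vox[3] - x[3]
    d2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
    sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    if (softWidth > 0) {
      d <- sqrt(d2)
      w <- ifelse(d <= radius, 1,
                  ifelse(d >= rmax, 0,
                         0.5 * (1 + cos(pi * (d - radius) / softWidth))))
      mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmax(sub, w)
    } else {
      mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
        pmax(sub, (d2 <= radius^2) * 1)
    }
  }
  mapGrid(mask, grid@cell, grid@originShift)
}

.applyBFourier <- function(map, bFactor) {
  # multiply Fourier coefficients by exp(-bFactor |s|^2/4) on the full grid
  dims <- dim(map@values)
  mv <- .millerVectors(dims)
  s2 <- (mv$h / map@cell[1])^2 + (mv$k / map@cell[2])^2 +
    (mv$l / map@cell[3])^2
  arg <- -bFactor * s2 / 4
  if (max(arg) > 700)
    stop(sprintf(
      "sharpening overflow (exp argument %.0f); lower |B| or raise d_min",
      max(arg)))
  A <- fft(map@values, inverse = TRUE) * exp(arg)
  out <- map
  out@values <- Re(fft(A)) / prod(dims)
  out
}

#' Sharpen, mask, unsharpen two half maps and average
#'
#' Each half map is sharpened by \code{exp(+B|s|^2/4)}, multiplied by the
#' mask in real space, then blurred back by \code{exp(-B|s|^2/4)}.
#' Sharpening before masking keeps the spread-out tails of the blurred
#' atomic signal inside the mask instead of cutting them away.  The
#' processed halves are averaged into the full target map.
#'
#' @param half1,half2 \linkS4class{MapGrid}s.
#' @param bOverall overall sharpening B in Angstrom^2.
#' @param mask \linkS4class{MapGrid} on the same grid.
#' @return list(half1, half2, full) of \linkS4class{MapGrid}s
#' @export
sharpenMaskUnsharpen <- function(half1, half2, bOverall, mask) {
  stopifnot(identical(dim(half1@values), dim(mask@values)),
            identical(dim(half2@values), dim(mask@values)),
            is.finite(bOverall))
  proc <- function(h) {
    sh <- .applyBFourier(h, -bOverall)   # sharpen: exp(+B s^2/4)
    sh@values <- sh@values * mask@values
    .applyBFourier(sh, bOverall)         # unsharpen
  }
  h1 <- proc(half1); h2 <- proc(half2)
  full <- h1
  full@values <- (h1@values + h2@values) / 2
  list(half1 = h1, half2 = h2, full = full)
}

#' Trim maps to the bounding box of a mask
#'
#' The minimal axis-aligned bounding box of the mask, grown by
#' \code{padding} Angstrom and snapped up to FFT-friendly dimensions
#' (largest prime factor 7), is cut from each map.  The returned shift
#' record restores absolute coordinates exactly and re-derives symmetry
#' translations for the shifted frame (see \code{\link{shiftOps}}).
#'
#' @param maps a \linkS4class{MapGrid} or list of them (same grid).
#' @param mask \linkS4class{MapGrid}; voxels > 0.5 define the region.
#' @param padding padding in Angstrom (default 5).
#' @return list(maps = trimmed list, shift = record with startIndex
#'   (0-based), dims, shiftAng, originalDims, originalOrigin)
#' @export
trimBox <- function(maps, mask, padding = 5) {
  single <- is(maps, "MapGrid")
  if (single) maps <- list(maps)
  dims <- dim(mask@values)
  vox <- mask@cell / dims
  idx <- which(mask@values > 0.5, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  if (any(lo == 1L) || any(hi == dims))
    warning("mask touches the box edge; trimming may wrap density")
  pad <- ceiling(padding / vox)
  lo <- pmax(1L, lo - pad); hi <- pmin(dims, hi + pad)
  want <- pmin(dims, vapply(hi - lo + 1L, .nextGoodSize, integer(1)))
  # grow the window to the snapped size, clamped inside the grid
  lo <- pmax(1L, pmin(lo, dims - want + 1L))
  hi <- lo + want - 1L
  trim <- function(m) {
    out <- m
    out@values <- m@values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                           drop = FALSE]
    out@cell <- want * vox
    out@originShift <- m@originShift + (lo - 1L) * vox
    out
  }
  shifted <- lapply(maps, trim)
  rec <- list(startIndex = as.integer(lo - 1L), dims = as.integer(want),
              shiftAng = (lo - 1L) * vox, originalDims = as.integer(dims),
              originalOrigin = mask@originShift)
  list(maps = if (single) shifted[[1]] else shifted, shift = rec)
}

#' Restore a trimmed map into its original box
#'
#' Voxels outside the trimmed region are filled with \code{fill}.  The
#' round trip \code{untrimMap(trimBox(...))} preserves voxel values
#' bit-exactly inside the trimmed region and absolute coordinates exactly.
#'
#' @param map trimmed \linkS4class{MapGrid}.
#' @param shift the shift record from \code{\link{trimBox}}.
#' @param fill fill value outside the trimmed block (default 0).
#' @return a \linkS4class{MapGrid} in the original frame
#' @export
untrimMap <- function(map, shift, fill = 0) {
  dims <- shift$originalDims
  vox <- map@cell / dim(map@values)
  out <- array(fill, dims)
  lo <- shift$startIndex + 1L
  hi <- shift$startIndex + dim(map@values)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- map@values
  mapGrid(out, dims * vox, shift$originalOrigin)
}

#' Serialize a trim shift record as JSON
#' @param shift record from \code{\link{trimBox}}.
#' @param path output path.
#' @return \code{path}, invisibly
#' @export
writeShiftRecord <- function(shift, path) {
  jsonlite::write_json(shift, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Masked moments of a map, by correction formula and directly
#'
#' Computes the total mean/variance of the zero-outside map and corrects
#' them to in-mask moments via \code{mu_mask = mu_total/f},
#' \code{var_mask = (var_total + mu_total^2)/f - mu_total^2/f^2}; also
#' computes both directly over in-mask voxels.  The two routes agree to
#' rounding; both are returned.  Variances are population variances
#' (divide by the count), for which the identities are exact.
#'
#' @param map a \linkS4class{MapGrid}.
#' @param mask binary \linkS4class{MapGrid} on the same grid.
#' @return list(n, m, f, muTotal, varTotal, muMask, varMask, muMaskDirect,
#'   varMaskDirect)
#' @export
maskedMoments <- function(map, mask) {
  stopifnot(identical(dim(map@values), dim(mask@values)))
  inMask <- mask@values > 0.5
  n <- length(map@values); m <- sum(inMask)
  if (m == 0L) stop("mask is empty (f = 0)")
  f <- m / n
  v0 <- map@values * (inMask * 1)
  muT <- mean(v0)
  varT <- mean(v0^2) - muT^2
  muM <- muT / f
  varM <- (varT + muT^2) / f - muT^2 / f^2
  x <- map@values[inMask]
  muD <- mean(x)
  varD <- mean(x^2) - muD^2
  list(n = n, m = m, f = f, muTotal = muT, varTotal = varT,
       muMask = muM, varMask = varM, muMaskDirect = muD,
       varMaskDirect = varD)
}

#' Normalize a map by its masked standard deviation
#'
#' Divides the map by \code{sqrt(var_mask)} so in-mask values are in sigma
#' units (the in-mask sd of the output is 1 when the in-mask mean is 0).
#' The result is flagged sigma-scaled for peak detection; the output is
#' independent of how much empty box surrounds the signal.
#'
#' @param map a \linkS4class{MapGrid}.
#' @param mask binary \linkS4class{MapGrid}.
#' @return a sigma-scaled \linkS4class{MapGrid}
#' @export
normalizeMap <- function(map, mask) {
  mm <- maskedMoments(map, mask)
  if (mm$varMask <= 0) stop("masked variance is zero; cannot normalize")
  out <- map
  out@values <- map@values / sqrt(mm$varMask)
  out@sigmaScaled <- TRUE
  out
}
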