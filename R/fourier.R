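# Forward/inverse transforms, Hermitian-unique coefficient bookkeeping and
# resolution binning.  Convention (fixed once, used everywhere):
#   F(h) = sum_g m(g) exp(+2 pi i h.g/N) * voxelVolume
# so F(0) = sum(map) * voxelVolume, and the inverse is
#   m(g) = Re sum_h F(h) exp(-2 pi i h.g/N) / V,   V = prod(cell).

#' Construct a MapGrid
#'
#' @param values numeric 3D array.
#' @param cell box edge lengths in Angstrom (length 3 or scalar).
#' @param originShift Angstrom offset of the first voxel (default 0).
#' @return a \linkS4class{MapGrid}
#' @export
mapGrid <- function(values, cell, originShift = c(0, 0, 0)) {
  if (length(cell) == 1L) cell <- rep(cell, 3L)
  new("MapGrid", values = values, cell = as.numeric(cell),
      originShift = as.numeric(originShift))
}

# signed grid index per axis position 0..n-1
.signedIndex <- function(n) {
  i <- 0:(n - 1L)
  ifelse(i <= n / 2, i, i - n)
}

# per-axis vectors of signed miller index, replicated over the full grid in
# R's column-major (first index fastest) order
.millerVectors <- function(dims) {
  h1 <- .signedIndex(dims[1]); h2 <- .signedIndex(dims[2])
  h3 <- .signedIndex(dims[3])
  list(h = rep(h1, times = dims[2] * dims[3]),
       k = rep(rep(h2, each = dims[1]), times = dims[3]),
       l = rep(h3, each = dims[1] * dims[2]))
}

# linear index (1-based) of the Friedel mate of each grid point
.conjLinearIndex <- function(dims) {
  c1 <- c(0L, rev(seq_len(dims[1] - 1L)))  # (n - i) mod n
  c2 <- c(0L, rev(seq_len(dims[2] - 1L)))
  c3 <- c(0L, rev(seq_len(dims[3] - 1L)))
  i1 <- rep(c1, times = dims[2] * dims[3])
  i2 <- rep(rep(c2, each = dims[1]), times = dims[3])
  i3 <- rep(c3, each = dims[1] * dims[2])
  1L + i1 + dims[1] * (i2 + dims[2] * i3)
}

.fourierFromArray <- function(A, dims, cell, originShift, dMin) {
  mv <- .millerVectors(dims)
  s1 <- mv$h / cell[1]; s2 <- mv$k / cell[2]; s3 <- mv$l / cell[3]
  sn <- sqrt(s1 * s1 + s2 * s2 + s3 * s3)
  lin <- seq_len(prod(dims))
  conj <- .conjLinearIndex(dims)
  keep <- lin <= conj
  if (is.finite(dMin)) keep <- keep & sn <= 1 / dMin + 1e-12
  idx <- lin[keep]
  co <- if (is.null(A)) complex(length(idx)) else A[idx]
  sc <- conj[keep] == idx
  co[sc] <- complex(real = Re(co[sc]), imaginary = 0)
  new("FourierSet", coeffs = co,
      miller = cbind(h = mv$h[keep], k = mv$k[keep], l = mv$l[keep]),
      index = idx, conjIndex = conj[keep], selfConj = sc,
      sNorm = sn[keep], binId = rep(NA_integer_, length(idx)),
      dMin = dMin, dims = as.integer(dims), cell = cell,
      originShift = originShift)
}

#' Forward Fourier transform of a map
#'
#' Transforms a real-space \linkS4class{MapGrid} to its Hermitian-unique
#' Fourier coefficients, optionally applying a high-resolution cutoff.
#'
#' @param map a \linkS4class{MapGrid}.
#' @param dMin high-resolution cutoff in Angstrom; coefficients with
#'   \code{|s| > 1/dMin} are dropped.  \code{Inf} (default) keeps all.
#' @return a \linkS4class{FourierSet}
#' @export
fftMap <- function(map, dMin = Inf) {
  stopifnot(is(map, "MapGrid"))
  dims <- dim(map@values)
  if (is.finite(dMin) && dMin < 2 * max(map@cell / dims) - 1e-9)
    stop(sprintf(
      "dMin = %.3f A is below the Nyquist limit %.3f A of this grid",
      dMin, 2 * max(map@cell / dims)))
  voxVol <- prod(map@cell / dims)
  A <- fft(map@values, inverse = TRUE) * voxVol
  .fourierFromArray(A, dims, map@cell, map@originShift, dMin)
}

#' Empty Fourier layout (template) on a given grid
#'
#' @param dims integer length-3 grid dimensions.
#' @param cell box edge lengths in Angstrom.
#' @param originShift Angstrom offset of the grid start.
#' @param dMin high-resolution cutoff in Angstrom.
#' @return a \linkS4class{FourierSet} with zero coefficients
#' @export
fourierLayout <- function(dims, cell, originShift = c(0, 0, 0), dMin = Inf) {
  if (length(cell) == 1L) cell <- rep(cell, 3L)
  .fourierFromArray(NULL, as.integer(dims), as.numeric(cell),
                    as.numeric(originShift), dMin)
}

#' Inverse transform of a FourierSet to a real-space map
#'
#' Conjugate mates are filled in from the stored unique half before the
#' inverse FFT, so the result is exactly real up to rounding.
#'
#' @param fs a \linkS4class{FourierSet}.
#' @return a \linkS4class{MapGrid}
#' @export
mapFromFourier <- function(fs) {
  stopifnot(is(fs, "FourierSet"))
  A <- array(0i, dim = fs@dims)
  A[fs@conjIndex] <- Conj(fs@coeffs)
  A[fs@index] <- fs@coeffs
  V <- prod(fs@cell)
  mapGrid(Re(fft(A)) / V, fs@cell, fs@originShift)
}

#' Replace the coefficients of a FourierSet
#'
#' @param fs a \linkS4class{FourierSet} supplying the layout.
#' @param x complex vector of the same length as \code{coeffs(fs)}.
#' @return a \linkS4class{FourierSet}
#' @export
setCoeffs <- function(fs, x) {
  stopifnot(length(x) == length(fs@coeffs))
  x <- as.complex(x)
  x[fs@selfConj] <- complex(real = Re(x[fs@selfConj]), imaginary = 0)
  fs@coeffs <- x
  fs
}

#' Dump Fourier coefficients as a text table
#'
#' Writes h, k, l, real, imag, sNorm and bin as tab-separated text.
#'
#' @param fs a \linkS4class{FourierSet}.
#' @param path output path.
#' @return \code{path}, invisibly
#' @export
writeCoeffTable <- function(fs, path) {
  df <- data.frame(h = fs@miller[, 1], k = fs@miller[, 2],
                   l = fs@miller[, 3], real = Re(fs@coeffs),
                   imag = Im(fs@coeffs), sNorm = fs@sNorm, bin = fs@binId)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.nextGoodSize <- function(n) {
  smooth7 <- function(m) {
    for (p in c(2, 3, 5, 7)) while (m %% p == 0) m <- m / p
    m == 1
  }
  while (!smooth7(n)) n <- n + 1L
  as.integer(n)
}

#' Resolution bins for a FourierSet
#'
#' Bins are equally spaced in |s| from 0 to the cutoff (the maximum |s|
#' present when no cutoff was applied).  Sparse high-resolution bins with
#' fewer than \code{minCount} coefficients are merged into their lower-|s|
#' neighbour so variance estimates stay stable.  A coefficient exactly on an
#' interior edge is assigned to the lower-|s| bin.
#'
#' @param fs a \linkS4class{FourierSet}.
#' @param nBins target number of bins; default \code{max(10, min(dims)/4)}.
#' @param minCount minimum coefficients per bin before merging (default 50).
#' @return a \linkS4class{BinScheme}
#' @export
makeBins <- function(fs, nBins = NULL, minCount = 50L) {
  stopifnot(is(fs, "FourierSet"))
  if (is.null(nBins)) nBins <- max(10L, round(min(fs@dims) / 4))
  nBins <- as.integer(nBins)
  stopifnot(nBins >= 1L)
  smax <- if (is.finite(fs@dMin)) 1 / fs@dMin else max(fs@sNorm)
  edges <- seq(0, smax, length.out = nBins + 1L)
  assign <- function(edges) {
    b <- findInterval(fs@sNorm, edges, left.open = TRUE)
    b[fs@sNorm <= edges[1] + 1e-15] <- 1L
    pmin.int(b, length(edges) - 1L)
  }
  b <- assign(edges)
  counts <- tabulate(b, nbins = length(edges) - 1L)
  # merge sparse bins into a neighbour: high-resolution bins downward, the
  # (tiny) lowest-|s| bin upward
  while (length(edges) > 2L && any(counts < minCount)) {
    j <- max(which(counts < minCount))
    edges <- if (j == 1L) edges[-2L] else edges[-j]
    b <- assign(edges)
    counts <- tabulate(b, nbins = length(edges) - 1L)
  }
  if (length(edges) > 2L && any(counts == 0L))
    warning("empty resolution bins remain after merging")
  if (nBins > 1L && length(edges) == 2L)
    warning("all coefficients fall in a single bin")
  mids <- (head(edges, -1L) + edges[-1L]) / 2
  new("BinScheme", nBins = length(edges) - 1L, edges = edges,
      counts = as.integer(counts), sCenter = mids)
}

#' Assign bin ids from a BinScheme to a FourierSet
#'
#' @param fs a \linkS4class{FourierSet}.
#' @param scheme a \linkS4class{BinScheme}.
#' @return \code{fs} with \code{binId} populated
#' @export
assignBins <- function(fs, scheme) {
  stopifnot(is(fs, "FourierSet"), is(scheme, "BinScheme"))
  b <- findInterval(fs@sNorm, scheme@edges, left.open = TRUE)
  b[fs@sNorm <= scheme@edges[1] + 1e-15] <- 1L
  fs@binId <- pmin.int(b, scheme@nBins)
  fs
}

# per-bin mean of a numeric vector, NA for empty bins
.binMean <- function(x, bin, nBins) {
  s <- rowsum(x, bin, reorder = TRUE)
  n <- tabulate(bin, nbins = nBins)
  out <- rep(NA_real_, nBins)
  out[as.integer(rownames(s))] <- s[, 1]
  out / ifelse(n > 0, n, NA)
}

.binSum <- function(x, bin, nBins) {
  s <- rowsum(x, bin, reorder = TRUE)
  out <- rep(0, nBins)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

.sameLayout <- function(f1, f2) {
  identical(f1@dims, f2@dims) && isTRUE(all.equal(f1@cell, f2@cell)) &&
    length(f1@coeffs) == length(f2@coeffs) &&
    isTRUE(all.equal(f1@dMin, f2@dMin))
}
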