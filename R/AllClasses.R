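#' cryodiff: weighted difference maps for cryo-EM single-particle analysis
#'
#' Core containers are S4 classes: \linkS4class{MapGrid} for real-space
#' volumes, \linkS4class{FourierSet} for complex Fourier coefficients on the
#' Hermitian-unique half grid, \linkS4class{BinScheme} for resolution bins,
#' \linkS4class{AtomicModel} for coordinate models and
#' \linkS4class{SymOpSet} for point-group operators.
#'
#' @import methods
#' @importFrom stats fft rnorm runif sd lm coef residuals setNames
#' @importFrom utils head read.table write.table
#' @name cryodiff-package
#' @keywords internal
NULL

#' Real-space density volume on an orthogonal grid
#'
#' A scalar field on an \code{N1 x N2 x N3} grid inside an orthogonal box.
#' The first array index is the fastest-varying (X) axis, matching the
#' canonical MRC layout used throughout the package.  \code{originShift} is
#' the Cartesian offset (in Angstrom) of the first voxel relative to the
#' absolute (deposited) frame, so trimming and untrimming can restore
#' absolute coordinates exactly.
#'
#' @slot values numeric 3D array of density values.
#' @slot cell numeric length-3, box edge lengths in Angstrom.
#' @slot originShift numeric length-3, Angstrom offset of the grid start.
#' @slot sigmaScaled logical flag; \code{TRUE} after masked-variance
#'   normalization, so peak search can interpret values as sigma units.
#' @exportClass MapGrid
setClass("MapGrid",
  representation(values = "array", cell = "numeric",
                 originShift = "numeric", sigmaScaled = "logical"),
  prototype(sigmaScaled = FALSE),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (length(object@cell) != 3L || any(object@cell <= 0))
      msg <- c(msg, "cell must be 3 positive lengths (Angstrom)")
    if (length(object@originShift) != 3L)
      msg <- c(msg, "originShift must have length 3")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "map values must be finite")
    if (length(msg)) msg else TRUE
  })

#' Fourier coefficients on the Hermitian-unique half grid
#'
#' Complex coefficients of a real map, stored once per Friedel pair.
#' \code{miller} holds signed integer grid indices (h,k,l); \code{index} and
#' \code{conjIndex} are linear indices into the full FFT array for the
#' coefficient and its conjugate mate.  Coefficients beyond the resolution
#' cutoff \code{1/dMin} are excluded at construction.
#'
#' The stored coefficient convention is volume weighted:
#' \code{F(0) = sum(map) * voxelVolume}, i.e. F approximates the continuous
#' integral of density times \code{exp(+2 pi i s.x)} with the phase origin
#' at the grid start.  Only ratios of coefficients enter the statistics, so
#' any consistent convention would do; this one is fixed here once.
#'
#' @slot coeffs complex vector of coefficients.
#' @slot miller integer matrix (n x 3) of signed grid indices.
#' @slot index,conjIndex integer linear indices into the full FFT grid.
#' @slot selfConj logical; TRUE where the coefficient is its own Friedel
#'   mate (must then be real).
#' @slot sNorm numeric |s| in 1/Angstrom.
#' @slot binId integer resolution-bin assignment (NA until assigned).
#' @slot dMin numeric high-resolution cutoff in Angstrom (Inf = none).
#' @slot dims integer full-grid dimensions.
#' @slot cell,originShift numeric, as in \linkS4class{MapGrid}.
#' @exportClass FourierSet
setClass("FourierSet",
  representation(coeffs = "complex", miller = "matrix", index = "integer",
                 conjIndex = "integer", selfConj = "logical",
                 sNorm = "numeric", binId = "integer", dMin = "numeric",
                 dims = "integer", cell = "numeric", originShift = "numeric"),
  validity = function(object) {
    n <- length(object@coeffs)
    msg <- character()
    if (nrow(object@miller) != n || length(object@sNorm) != n ||
        length(object@index) != n || length(object@binId) != n)
      msg <- c(msg, "per-coefficient slots must have equal length")
    if (length(object@dims) != 3L)
      msg <- c(msg, "dims must have length 3")
    if (length(msg)) msg else TRUE
  })

#' Resolution-bin scheme
#'
#' Equal-width bins in |s| from 0 to the cutoff, possibly with sparse
#' high-resolution bins merged downward so each bin keeps a minimum
#' coefficient count.  A coefficient exactly on an interior edge belongs to
#' the lower-|s| bin.
#'
#' @slot nBins integer number of bins.
#' @slot edges numeric strictly increasing |s| boundaries (length nBins+1).
#' @slot counts integer coefficients per bin.
#' @slot sCenter numeric bin-center |s| in 1/Angstrom.
#' @exportClass BinScheme
setClass("BinScheme",
  representation(nBins = "integer", edges = "numeric", counts = "integer",
                 sCenter = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@edges) != object@nBins + 1L)
      msg <- c(msg, "edges must have length nBins + 1")
    if (any(diff(object@edges) <= 0))
      msg <- c(msg, "edges must be strictly increasing")
    if (length(object@counts) != object@nBins)
      msg <- c(msg, "counts must have length nBins")
    if (length(msg)) msg else TRUE
  })

#' Atomic model
#'
#' An ordered atom table with element, Cartesian position (Angstrom),
#' occupancy, isotropic B (Angstrom^2) or anisotropic tensor entries
#' (b11..b23, NA when isotropic), the nucleus offset (dx,dy,dz) relative to
#' the electron-cloud centre (nonzero only for hydrogens), and a flag for
#' rotatable hydrogens (hydroxyl/sulfhydryl/carboxyl), which are excluded
#' from hydrogen-peak statistics.
#'
#' @slot atoms data.frame with columns element, Z, x, y, z, occ, b,
#'   b11, b22, b33, b12, b13, b23, dx, dy, dz, rotatableH, chain, resno,
#'   resid, name.
#' @slot box numeric length-3 bounding box hint in Angstrom (NA if unknown).
#' @exportClass AtomicModel
setClass("AtomicModel",
  representation(atoms = "data.frame", box = "numeric"),
  prototype(box = rep(NA_real_, 3)),
  validity = function(object) {
    need <- c("element", "Z", "x", "y", "z", "occ", "b",
              "b11", "b22", "b33", "b12", "b13", "b23",
              "dx", "dy", "dz", "rotatableH", "chain", "resno", "resid",
              "name")
    msg <- character()
    if (!all(need %in% names(object@atoms)))
      msg <- c(msg, paste("atoms is missing columns:",
                          paste(setdiff(need, names(object@atoms)),
                                collapse = ", ")))
    else {
      if (nrow(object@atoms) < 1L) msg <- c(msg, "model must be non-empty")
      if (any(object@atoms$Z < 1)) msg <- c(msg, "atomic numbers must be >= 1")
      iso <- is.na(object@atoms$b11)
      if (any(object@atoms$b[iso] < 0))
        msg <- c(msg, "isotropic B must be >= 0")
      off <- sqrt(object@atoms$dx^2 + object@atoms$dy^2 + object@atoms$dz^2)
      if (any(off > 0.5 + 1e-9))
        msg <- c(msg, "nucleus offsets must not exceed 0.5 Angstrom")
    }
    if (length(msg)) msg else TRUE
  })

#' Point-group operator set
#'
#' Proper rotations (det +1) with translations \code{t_j = (I - R_j) c}
#' about the symmetry origin \code{c} (by convention the centre of the box).
#' The set always contains the identity and is closed under composition
#' within tolerance.
#'
#' @slot R list of 3x3 orthonormal rotation matrices.
#' @slot t numeric 3 x n matrix of translations in Angstrom.
#' @slot symbol character point-group symbol (e.g. "C2", "D3", "O").
#' @slot center numeric length-3 symmetry origin in Angstrom.
#' @exportClass SymOpSet
setClass("SymOpSet",
  representation(R = "list", t = "matrix", symbol = "character",
                 center = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@t) != length(object@R))
      msg <- c(msg, "t must have one column per rotation")
    orth <- vapply(object@R, function(Rj)
      max(abs(crossprod(Rj) - diag(3))), numeric(1))
    dets <- vapply(object@R, det, numeric(1))
    if (length(orth) && max(orth) > 1e-8)
      msg <- c(msg, "rotations must be orthonormal")
    if (length(dets) && max(abs(dets - 1)) > 1e-8)
      msg <- c(msg, "rotations must be proper (det +1)")
    if (length(msg)) msg else TRUE
  })
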