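#' @rdname MapGrid-class
#' @param object,x a cryodiff object
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname MapGrid-class
#' @export
setGeneric("cellDims", function(x) standardGeneric("cellDims"))
#' @rdname MapGrid-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname MapGrid-class
#' @export
setGeneric("originShift", function(x) standardGeneric("originShift"))
#' @rdname FourierSet-class
#' @export
setGeneric("coeffs", function(x) standardGeneric("coeffs"))
#' @rdname FourierSet-class
#' @export
setGeneric("millerIndices", function(x) standardGeneric("millerIndices"))
#' @rdname FourierSet-class
#' @export
setGeneric("sNorm", function(x) standardGeneric("sNorm"))
#' @rdname FourierSet-class
#' @export
setGeneric("binIds", function(x) standardGeneric("binIds"))
#' @rdname AtomicModel-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname AtomicModel-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname SymOpSet-class
#' @export
setGeneric("operators", function(x) standardGeneric("operators"))

#' @rdname MapGrid-class
setMethod("mapValues", "MapGrid", function(x) x@values)
#' @rdname MapGrid-class
setMethod("cellDims", "MapGrid", function(x) x@cell)
#' @rdname MapGrid-class
setMethod("voxelSize", "MapGrid", function(x) x@cell / dim(x@values))
#' @rdname MapGrid-class
setMethod("originShift", "MapGrid", function(x) x@originShift)
#' @rdname FourierSet-class
setMethod("coeffs", "FourierSet", function(x) x@coeffs)
#' @rdname FourierSet-class
setMethod("millerIndices", "FourierSet", function(x) x@miller)
#' @rdname FourierSet-class
setMethod("sNorm", "FourierSet", function(x) x@sNorm)
#' @rdname FourierSet-class
setMethod("binIds", "FourierSet", function(x) x@binId)
#' @rdname FourierSet-class
setMethod("cellDims", "FourierSet", function(x) x@cell)
#' @rdname FourierSet-class
setMethod("originShift", "FourierSet", function(x) x@originShift)
#' @rdname AtomicModel-class
setMethod("atoms", "AtomicModel", function(x) x@atoms)
#' @rdname AtomicModel-class
setMethod("nAtoms", "AtomicModel", function(x) nrow(x@atoms))
#' @rdname SymOpSet-class
setMethod("operators", "SymOpSet", function(x)
  list(R = x@R, t = x@t, symbol = x@symbol, center = x@center))
#' @rdname SymOpSet-class
#' @export
setMethod("length", "SymOpSet", function(x) length(x@R))

setMethod("show", "MapGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("MapGrid %dx%dx%d, cell %.2f x %.2f x %.2f A, voxel %.3f A\n",
              d[1], d[2], d[3], object@cell[1], object@cell[2],
              object@cell[3], object@cell[1] / d[1]))
  cat(sprintf("  origin shift (%.2f, %.2f, %.2f) A; range [%.3g, %.3g]%s\n",
              object@originShift[1], object@originShift[2],
              object@originShift[3], min(object@values), max(object@values),
              if (isTRUE(object@sigmaScaled)) " (sigma scaled)" else ""))
})

setMethod("show", "FourierSet", function(object) {
  cat(sprintf(
    "FourierSet: %d unique coefficients, grid %dx%dx%d, d_min %.2f A\n",
    length(object@coeffs), object@dims[1], object@dims[2], object@dims[3],
    object@dMin))
  nb <- sum(!is.na(unique(object@binId)))
  cat(sprintf("  |s| in [%.4g, %.4g] 1/A; %s\n", min(object@sNorm),
              max(object@sNorm),
              if (nb > 0) sprintf("%d bins assigned", nb) else "bins unassigned"))
})

setMethod("show", "BinScheme", function(object) {
  cat(sprintf("BinScheme: %d bins, |s| in [0, %.4g] 1/A, %d coefficients\n",
              object@nBins, max(object@edges), sum(object@counts)))
})

setMethod("show", "AtomicModel", function(object) {
  a <- object@atoms
  cat(sprintf("AtomicModel: %d atoms (%s)\n", nrow(a),
              paste(names(sort(table(a$element), decreasing = TRUE)),
                    sort(table(a$element), decreasing = TRUE),
                    sep = ":", collapse = " ")))
})

setMethod("show", "SymOpSet", function(object) {
  cat(sprintf("SymOpSet %s: %d operators, centre (%.2f, %.2f, %.2f) A\n",
              object@symbol, length(object@R), object@center[1],
              object@center[2], object@center[3]))
})
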