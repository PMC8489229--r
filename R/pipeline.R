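# End-to-end map-calculation workflow: trim -> sharpen-mask-unsharpen ->
# F_c -> per-bin statistics -> weighted & sharpened Fo-Fc and normalized
# expected maps -> masked-variance normalization.  Atomic refinement is
# external to this package: the pipeline expects an already-refined model
# (the difference map is only sensible when ADPs are properly refined).

#' Run the Fo-Fc map-calculation workflow
#'
#' @param half1,half2 \linkS4class{MapGrid}s or MRC file paths of the two
#'   unsharpened, unweighted half maps.
#' @param model an \linkS4class{AtomicModel} or PDB/mmCIF path (asymmetric
#'   unit if \code{pointgroup} is not "C1").
#' @param mask optional \linkS4class{MapGrid} or MRC path; default: model
#'   mask of radius \code{maskRadius} from the (expanded) atoms.
#' @param pointgroup point-group symbol (default "C1"); the symmetry
#'   origin is the centre of the box.
#' @param resolution high-resolution cutoff in Angstrom (required).
#' @param nBins resolution bin count (default: automatic).
#' @param bOverall sharpening B in Angstrom^2; estimated from a zero-ADP
#'   model copy when NULL.
#' @param omit integer/logical atom selection removed from F_c for an omit
#'   map.  Scale statistics (D, sigma_f^2) are estimated against the
#'   omitted model by default, so the unexplained omit signal carries
#'   weight; \code{statsWithFullModel = TRUE} runs the stats pass with the
#'   full model instead (which can clip sigma_f^2 to zero when the model
#'   explains the signal completely).
#' @param normalize divide output maps by the masked sigma (default TRUE).
#' @param trim trim maps to the mask bounding box for the heavy transforms
#'   and restore the original frame on output (default TRUE).
#' @param maskRadius model-mask radius in Angstrom (default 3).
#' @param statsWithFullModel see \code{omit}.
#' @param outDir optional directory: writes diffmap_fofc.mrc,
#'   diffmap_normalized_fo.mrc, stats.tsv, run_summary.json (file
#'   checksums included in the summary).
#' @param verbose print progress to stderr.
#' @return list(fofc, expected = \linkS4class{MapGrid}s in the original
#'   frame, stats, bOverall, bins, ops, maskStats, summary)
#' @export
runFoFc <- function(half1, half2, model, mask = NULL, pointgroup = "C1",
                    resolution, nBins = NULL, bOverall = NULL, omit = NULL,
                    normalize = TRUE, trim = TRUE, maskRadius = 3,
                    statsWithFullModel = FALSE, outDir = NULL,
                    verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.character(half1)) half1 <- readMRC(half1)
  if (is.character(half2)) half2 <- readMRC(half2)
  if (is.character(model)) model <- readModel(model)
  if (is.character(mask)) mask <- readMRC(mask)
  stopifnot(is(half1, "MapGrid"), is(half2, "MapGrid"),
            identical(dim(half1@values), dim(half2@values)))
  if (missing(resolution)) stop("a resolution cutoff is required")

  center <- half1@originShift + half1@cell / 2
  ops <- pointGroupOps(pointgroup, center = center)
  expanded <- if (length(ops@R) > 1L) expandModel(model, ops) else model
  say(sprintf("point group %s: %d operator(s)", ops@symbol, length(ops@R)))

  userMask <- !is.null(mask)
  if (!userMask) mask <- modelMask(expanded, half1, radius = maskRadius)

  if (trim) {
    tr <- trimBox(list(half1, half2, mask), mask)
    half1 <- tr$maps[[1]]; half2 <- tr$maps[[2]]; mask <- tr$maps[[3]]
    shiftRec <- tr$shift
    say(sprintf("trimmed to %s", paste(dim(half1@values), collapse = "x")))
  } else shiftRec <- NULL

  dims <- dim(half1@values)
  layout <- fourierLayout(dims, half1@cell, half1@originShift,
                          dMin = resolution)
  bins <- makeBins(layout, nBins = nBins)
  layout <- assignBins(layout, bins)

  fcFull <- calcFc(model, layout, ops = ops, method = "auto")

  if (is.null(bOverall)) {
    f1r <- assignBins(fftMap(half1, dMin = resolution), bins)
    f2r <- assignBins(fftMap(half2, dMin = resolution), bins)
    foRaw <- setCoeffs(f1r, (f1r@coeffs + f2r@coeffs) / 2)
    fc0 <- calcFc(setBFactors(model, 0), layout, ops = ops, method = "auto")
    bOverall <- estimateOverallB(foRaw, fc0, bins)$bOverall
    say(sprintf("estimated overall B = %.1f A^2", bOverall))
  }

  smu <- sharpenMaskUnsharpen(half1, half2, bOverall, mask)
  f1 <- assignBins(fftMap(smu$half1, dMin = resolution), bins)
  f2 <- assignBins(fftMap(smu$half2, dMin = resolution), bins)
  fo <- setCoeffs(f1, (f1@coeffs + f2@coeffs) / 2)

  stats <- binStats(f1, f2, bins, fc = fcFull)
  if (!is.null(omit)) {
    omitted <- omitAtoms(model, omit)
    fcOmit <- calcFc(omitted, layout, ops = ops, method = "auto")
    if (!statsWithFullModel) {
      sigmaN2 <- noiseVariance(f1, f2, bins)
      sc <- estimateScales(fo, fcOmit, sigmaN2, bins)
      stats$D <- sc$D; stats$sigmaF2 <- sc$sigmaF2; stats$S <- sc$S
    }
    fcUsed <- fcOmit
  } else fcUsed <- fcFull

  dF <- fofcCoeffs(fo, fcUsed, stats)
  eF <- expectedMapCoeffs(fo, stats)
  fofcMap <- mapFromFourier(dF)
  expMap <- mapFromFourier(eF)

  maskStats <- maskedMoments(fofcMap, mask)
  if (normalize) {
    if (maskStats$varMask > 0) fofcMap <- normalizeMap(fofcMap, mask)
    else warning("Fo-Fc map has zero masked variance; left unnormalized")
    expMap <- normalizeMap(expMap, mask)
  }

  if (trim) {
    sigma1 <- fofcMap@sigmaScaled; sigma2 <- expMap@sigmaScaled
    fofcMap <- untrimMap(fofcMap, shiftRec)
    expMap <- untrimMap(expMap, shiftRec)
    fofcMap@sigmaScaled <- sigma1; expMap@sigmaScaled <- sigma2
  }

  summary <- list(pointgroup = ops@symbol, nOps = length(ops@R),
                  resolution = resolution, nBins = bins@nBins,
                  bOverall = bOverall, normalized = normalize,
                  maskFraction = maskStats$f, userMask = userMask,
                  omit = if (is.null(omit)) integer(0) else as.integer(omit),
                  trimmed = trim,
                  trimDims = if (trim) shiftRec$dims else dim(half1@values))
  out <- list(fofc = fofcMap, expected = expMap, stats = stats,
              bOverall = bOverall, bins = bins, ops = ops,
              maskStats = maskStats, summary = summary)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- c(fofc = file.path(outDir, "diffmap_fofc.mrc"),
               expected = file.path(outDir, "diffmap_normalized_fo.mrc"),
               stats = file.path(outDir, "stats.tsv"))
    writeMRC(fofcMap, files["fofc"])
    writeMRC(expMap, files["expected"])
    writeStatsTable(stats, files["stats"])
    summary$outputs <- lapply(seq_along(files), function(i)
      list(path = unname(files[i]),
           md5 = unname(tools::md5sum(files[i]))))
    jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    out$summary <- summary
  }
  out
}
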