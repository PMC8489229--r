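# Signed peak detection in sigma-scaled difference maps and association of
# positive peaks with hydrogen positions.

.neighborOffsets <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

.findPeaksOneSign <- function(v, threshold, vox, origin) {
  dims <- dim(v)
  cand <- which(v > threshold)
  if (!length(cand)) return(NULL)
  ai <- arrayInd(cand, dims)
  # peaks within half a voxel of the border are discarded
  inner <- ai[, 1] > 1 & ai[, 1] < dims[1] &
    ai[, 2] > 1 & ai[, 2] < dims[2] & ai[, 3] > 1 & ai[, 3] < dims[3]
  cand <- cand[inner]; ai <- ai[inner, , drop = FALSE]
  if (!length(cand)) return(NULL)
  isMax <- rep(TRUE, length(cand))
  for (r in seq_len(nrow(.neighborOffsets))) {
    off <- .neighborOffsets[r, ]
    ni <- cbind(ai[, 1] + off[1], ai[, 2] + off[2], ai[, 3] + off[3])
    lin <- ni[, 1] + dims[1] * (ni[, 2] - 1L + dims[2] * (ni[, 3] - 1L))
    isMax <- isMax & v[cand] >= v[lin]
    # strict on at least the self-comparison handled below
  }
  cand <- cand[isMax]; ai <- ai[isMax, , drop = FALSE]
  if (!length(cand)) return(NULL)
  pos <- matrix(0, length(cand), 3)
  hgt <- numeric(length(cand))
  for (p in seq_along(cand)) {
    i <- ai[p, ]
    f0 <- v[i[1], i[2], i[3]]
    h <- f0
    offv <- numeric(3)
    for (axis in 1:3) {
      im <- i; ip <- i
      im[axis] <- im[axis] - 1L; ip[axis] <- ip[axis] + 1L
      fm <- v[im[1], im[2], im[3]]; fp <- v[ip[1], ip[2], ip[3]]
      den <- fm - 2 * f0 + fp
      if (den < 0) {               # proper curvature: 3-point quadratic
        o <- (fm - fp) / (2 * den)
        o <- max(-0.5, min(0.5, o))
        offv[axis] <- o
        h <- h - (fm - fp)^2 / (8 * den)  # per-axis quadratic increment
      }
    }
    pos[p, ] <- origin + (i - 1 + offv) * vox
    hgt[p] <- h
  }
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], height = hgt)
}

#' Find signed peaks in a (sigma-scaled) map
#'
#' Local extrema over the 26-neighborhood exceeding the threshold, with
#' sub-voxel refinement by a 3-point quadratic per axis.  If the map
#' carries no normalization record a warning is emitted and the whole-map
#' standard deviation is used as the sigma unit.
#'
#' @param map a \linkS4class{MapGrid}, ideally from
#'   \code{\link{normalizeMap}}.
#' @param thresholdSigma detection threshold in sigma units (> 0).
#' @param sign "both" (default), "positive" or "negative".
#' @param model optional \linkS4class{AtomicModel}; peaks are annotated
#'   with their nearest atom and distance.
#' @return data.frame (x, y, z, height, sign[, nearestAtom, nearestDist])
#'   sorted by |height| descending
#' @export
findPeaks <- function(map, thresholdSigma, sign = c("both", "positive",
                                                    "negative"),
                      model = NULL) {
  sign <- match.arg(sign)
  stopifnot(thresholdSigma > 0)
  v <- map@values
  if (!isTRUE(map@sigmaScaled)) {
    warning("map carries no normalization record; using whole-map sigma")
    s <- sd(as.vector(v))
    if (s == 0)
      return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                        height = numeric(), sign = character()))
    v <- v / s
  }
  vox <- map@cell / dim(v)
  res <- list()
  if (sign %in% c("both", "positive")) {
    p <- .findPeaksOneSign(v, thresholdSigma, vox, map@originShift)
    if (!is.null(p)) { p$sign <- "+"; res <- c(res, list(p)) }
  }
  if (sign %in% c("both", "negative")) {
    p <- .findPeaksOneSign(-v, thresholdSigma, vox, map@originShift)
    if (!is.null(p)) { p$height <- -p$height; p$sign <- "-"
      res <- c(res, list(p)) }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(x = numeric(), y = numeric(), z = numeric(),
               height = numeric(), sign = character())
  out <- out[order(-abs(out$height)), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(model) && nrow(out)) {
    a <- model@atoms
    ni <- integer(nrow(out)); nd <- numeric(nrow(out))
    for (p in seq_len(nrow(out))) {
      d2 <- (a$x - out$x[p])^2 + (a$y - out$y[p])^2 + (a$z - out$z[p])^2
      ni[p] <- which.min(d2); nd[p] <- sqrt(min(d2))
    }
    out$nearestAtom <- paste0(a$element[ni], "/", a$chain[ni], a$resno[ni],
                              "/", a$name[ni])
    out$nearestDist <- nd
  }
  out
}

#' Match positive difference peaks to hydrogen positions
#'
#' Each peak is assigned to its nearest hydrogen; a hydrogen counts as
#' detected when at least one assigned peak lies within \code{maxDist}.
#' Rotatable hydrogens (hydroxyl/sulfhydryl/carboxyl, several potential
#' minima) are excluded from both numerator and denominator of the primary
#' ratio; the all-hydrogen convention is reported alongside.
#'
#' @param peaks data.frame from \code{\link{findPeaks}} (positive peaks are
#'   used).
#' @param model an \linkS4class{AtomicModel} with explicit hydrogens.
#' @param maxDist association cutoff in Angstrom (default 0.3).
#' @return list(ratio, ratioAllH, nEligible, nDetected, perH = data.frame)
#' @export
matchHydrogens <- function(peaks, model, maxDist = 0.3) {
  a <- model@atoms
  hIdx <- which(a$element == "H")
  if (!length(hIdx)) stop("model contains no hydrogens")
  pk <- peaks[peaks$sign == "+", , drop = FALSE]
  detected <- rep(FALSE, length(hIdx))
  bestDist <- rep(NA_real_, length(hIdx))
  if (nrow(pk)) {
    for (p in seq_len(nrow(pk))) {
      d2 <- (a$x[hIdx] - pk$x[p])^2 + (a$y[hIdx] - pk$y[p])^2 +
        (a$z[hIdx] - pk$z[p])^2
      j <- which.min(d2)            # a peak matches at most its nearest H
      d <- sqrt(d2[j])
      if (d < maxDist) {
        detected[j] <- TRUE
        bestDist[j] <- min(bestDist[j], d, na.rm = TRUE)
      }
    }
  }
  eligible <- !a$rotatableH[hIdx]
  perH <- data.frame(atom = hIdx, chain = a$chain[hIdx],
                     resno = a$resno[hIdx], name = a$name[hIdx],
                     rotatable = a$rotatableH[hIdx],
                     detected = detected, peakDist = bestDist)
  list(ratio = if (any(eligible)) mean(detected[eligible]) else NA_real_,
       ratioAllH = mean(detected),
       nEligible = sum(eligible), nDetected = sum(detected & eligible),
       perH = perH)
}

#' Write a peak list as tab-separated text
#' @param peaks data.frame from \code{\link{findPeaks}}.
#' @param path output path.
#' @return \code{path}, invisibly
#' @export
writePeakList <- function(peaks, path) {
  write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
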