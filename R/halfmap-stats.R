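# Per-resolution-bin statistics from two half maps: noise variance,
# signal-amplitude proxy k*sigma_T, and Fourier shell correlations.
#
# Model per Fourier coefficient: F_o = k F_T + F_n with independent
# zero-mean complex Gaussian noise of variance sigma_n^2 in the averaged
# full map F_o = (F_o1 + F_o2)/2, so that
#   sigma_n^2(i) = < |F_o1 - F_o2|^2 > / 4   per bin i.

.checkSame <- function(f1, f2)
  if (!.sameLayout(f1, f2))
    stop("Fourier sets are on different grids or cutoffs")

.checkBinned <- function(fs)
  if (anyNA(fs@binId)) stop("FourierSet has unassigned bins; call assignBins()")

#' Per-bin noise variance from two half maps
#'
#' @param f1,f2 \linkS4class{FourierSet}s of the two half maps (same grid,
#'   same cutoff, bins assigned).
#' @param bins a \linkS4class{BinScheme}.
#' @return numeric vector, noise variance of the full map per bin
#' @export
noiseVariance <- function(f1, f2, bins) {
  .checkSame(f1, f2); .checkBinned(f1)
  d <- f1@coeffs - f2@coeffs
  .binMean(Re(d * Conj(d)) / 4, f1@binId, bins@nBins)
}

#' Fourier shell correlation between two coefficient sets
#'
#' \code{FSC(i) = Re sum F1 conj(F2) / (sum|F1|^2 sum|F2|^2)^(1/2)} per
#' bin.  Bins with zero power in either input are reported as NA (the
#' correlation is undefined there), never as 0.
#'
#' @param f1,f2 \linkS4class{FourierSet}s on the same layout.
#' @param bins a \linkS4class{BinScheme}.
#' @return numeric vector of per-bin correlations in [-1, 1]
#' @export
fscBins <- function(f1, f2, bins) {
  .checkSame(f1, f2); .checkBinned(f1)
  num <- .binSum(Re(f1@coeffs * Conj(f2@coeffs)), f1@binId, bins@nBins)
  p1 <- .binSum(Re(f1@coeffs * Conj(f1@coeffs)), f1@binId, bins@nBins)
  p2 <- .binSum(Re(f2@coeffs * Conj(f2@coeffs)), f2@binId, bins@nBins)
  ifelse(p1 > 0 & p2 > 0, num / sqrt(p1 * p2), NA_real_)
}

#' Full-map FSC from half-map FSC
#'
#' The correlation of the averaged map with the true signal relates to the
#' half-map correlation as \code{FSC_full = 2 FSC_half / (1 + FSC_half)}.
#'
#' @param fscHalf numeric vector of half-map FSC values.
#' @return numeric vector of full-map FSC values
#' @export
fscFullFromHalf <- function(fscHalf) 2 * fscHalf / (1 + fscHalf)

#' Per-bin signal amplitude proxy k*sigma_T
#'
#' \code{(k sigma_T)^2(i) = max(0, <|F_o|^2>_i - sigma_n^2(i))}, the
#' variance of the blurred true signal; equivalently
#' \code{FSC_full * <|F_o|^2>} where the FSC is defined.  Negative
#' differences are clipped to zero and flagged.
#'
#' @param fo \linkS4class{FourierSet} of the averaged full map.
#' @param sigmaN2 per-bin noise variance.
#' @param bins a \linkS4class{BinScheme}.
#' @return list(kSigmaT =, meanFo2 =, clipped = logical per bin)
#' @export
signalAmplitude <- function(fo, sigmaN2, bins) {
  .checkBinned(fo)
  meanFo2 <- .binMean(Re(fo@coeffs * Conj(fo@coeffs)), fo@binId, bins@nBins)
  diff <- meanFo2 - sigmaN2
  list(kSigmaT = sqrt(pmax(0, diff)), meanFo2 = meanFo2,
       clipped = !is.na(diff) & diff < 0)
}

#' Map-model FSC and its coefficient-weighted average
#'
#' The scalar summary is \code{sum N_i FSC_i / sum N_i}, the average of the
#' map-model FSC weighted by the number of Fourier coefficients per shell,
#' used to monitor refinement.
#'
#' @param fo,fc \linkS4class{FourierSet}s (observed and calculated).
#' @param bins a \linkS4class{BinScheme}.
#' @return list(fsc = per-bin, average = scalar)
#' @export
fscModel <- function(fo, fc, bins) {
  f <- fscBins(fo, fc, bins)
  ok <- !is.na(f)
  list(fsc = f,
       average = sum(bins@counts[ok] * f[ok]) / sum(bins@counts[ok]))
}

#' Assemble the per-bin statistics table
#'
#' Computes all half-map statistics (and, when a model transform is given,
#' the maximum-likelihood D and sigma_f^2 scales plus map-model FSC) into
#' one data frame, the central quantity driving map weighting.
#'
#' @param f1,f2 \linkS4class{FourierSet}s of the half maps, bins assigned.
#' @param bins a \linkS4class{BinScheme}.
#' @param fc optional \linkS4class{FourierSet} from the atomic model.
#' @return data.frame with columns bin, sCenter, d, n, sigmaN2, meanFo2,
#'   kSigmaT, fscHalf, fscFull, D, sigmaF2, S, fscModel (NA where not
#'   computed); bins with fewer than 10 coefficients report NA statistics
#' @export
binStats <- function(f1, f2, bins, fc = NULL) {
  .checkSame(f1, f2); .checkBinned(f1)
  fo <- setCoeffs(f1, (f1@coeffs + f2@coeffs) / 2)
  sigmaN2 <- noiseVariance(f1, f2, bins)
  sig <- signalAmplitude(fo, sigmaN2, bins)
  fh <- fscBins(f1, f2, bins)
  st <- data.frame(
    bin = seq_len(bins@nBins), sCenter = bins@sCenter,
    d = ifelse(bins@sCenter > 0, 1 / bins@sCenter, Inf),
    n = bins@counts, sigmaN2 = sigmaN2, meanFo2 = sig$meanFo2,
    kSigmaT = sig$kSigmaT, kSigmaTClipped = sig$clipped,
    fscHalf = fh, fscFull = fscFullFromHalf(fh),
    D = NA_real_, sigmaF2 = NA_real_, S = NA_real_,
    sigmaF2Clipped = FALSE, fscModel = NA_real_)
  if (!is.null(fc)) {
    sc <- estimateScales(fo, fc, sigmaN2, bins)
    st$D <- sc$D; st$sigmaF2 <- sc$sigmaF2; st$S <- sc$S
    st$sigmaF2Clipped <- sc$clipped
    st$fscModel <- fscModel(fo, fc, bins)$fsc
  }
  sparse <- st$n < 10L
  st[sparse, c("sigmaN2", "meanFo2", "kSigmaT", "fscHalf", "fscFull",
               "D", "sigmaF2", "S", "fscModel")] <- NA_real_
  st
}

#' Write a statistics table as TSV or JSON
#'
#' @param stats data.frame from \code{\link{binStats}}.
#' @param path output path.
#' @param format "tsv" or "json".
#' @return \code{path}, invisibly
#' @export
writeStatsTable <- function(stats, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv")
    write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  else
    jsonlite::write_json(stats, path, dataframe = "columns", digits = NA,
                         na = "null")
  invisible(path)
}
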