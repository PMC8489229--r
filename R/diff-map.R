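# Posterior-based map coefficients: the weighted & sharpened Fo-Fc
# difference coefficients, the model-free normalized expected map, and the
# full posterior mean/variance.  The unknown blur k is replaced by the
# signal-amplitude proxy k*sigma_T, which gives the best sharpening for a
# region blurred by the average B.

.statsPerCoeff <- function(fo, stats, cols) {
  .checkBinned(fo)
  used <- sort(unique(fo@binId))
  for (cc in cols) {
    bad <- used[!is.finite(stats[[cc]][used])]
    # kSigmaT = 0 / undefined D are handled downstream, not errors
    if (cc %in% c("sigmaN2", "sigmaF2", "kSigmaT") && length(bad))
      stop(sprintf("missing %s for populated bin(s) %s", cc,
                   paste(bad, collapse = ", ")))
  }
  lapply(setNames(cols, cols), function(cc) stats[[cc]][fo@binId])
}

#' Weighted and sharpened Fo-Fc difference coefficients
#'
#' \deqn{\Delta F(s) = \frac{\sigma_f^2}{\sigma_f^2 + \sigma_n^2}
#'   \frac{F_o - D F_c}{k\sigma_T}}
#' per the resolution bin of \code{s}.  The variance weight suppresses
#' bins where the residual signal is noise-dominated, and the division by
#' the signal amplitude sharpens.  Bins where \code{k sigma_T} was clipped
#' to zero, or where D is undefined, produce zero coefficients with a
#' warning (zeroing, rather than leaving unsharpened, avoids amplifying
#' pure noise).
#'
#' @param fo,fc \linkS4class{FourierSet}s with bins assigned.
#' @param stats data.frame from \code{\link{binStats}} with D, sigmaF2,
#'   sigmaN2, kSigmaT populated.
#' @return a \linkS4class{FourierSet} of difference coefficients
#' @export
fofcCoeffs <- function(fo, fc, stats) {
  .checkSame(fo, fc)
  p <- .statsPerCoeff(fo, stats, c("sigmaN2", "sigmaF2", "kSigmaT", "D"))
  S <- p$sigmaF2 + p$sigmaN2
  w <- ifelse(S > 0, p$sigmaF2 / S, 0)
  dead <- !(p$kSigmaT > 0) | !is.finite(p$D)
  if (any(dead))
    warning(sprintf(
      "%d coefficient(s) in bins with zero signal or undefined D set to 0",
      sum(dead)))
  dF <- ifelse(dead, 0i, w * (fo@coeffs - p$D * fc@coeffs) /
                 ifelse(dead, 1, p$kSigmaT))
  setCoeffs(fo, dF)
}

#' Normalized expected-map coefficients (model free)
#'
#' The posterior expectation in the absence of a model (D = 0):
#' \deqn{\frac{(k\sigma_T)^2}{(k\sigma_T)^2 + \sigma_n^2}
#'   \frac{F_o}{k\sigma_T} = FSC_{full} \frac{F_o}{k\sigma_T},}
#' algebraically \eqn{FSC_{full}^{1/2} E} with E the bin-normalized
#' structure factor.  Pure-noise bins get weight 0.  The output is
#' independent of any model.
#'
#' @param fo \linkS4class{FourierSet} with bins assigned.
#' @param stats data.frame with kSigmaT and sigmaN2 per bin.
#' @return a \linkS4class{FourierSet}
#' @export
expectedMapCoeffs <- function(fo, stats) {
  p <- .statsPerCoeff(fo, stats, c("sigmaN2", "kSigmaT"))
  k2 <- p$kSigmaT^2
  denom <- k2 + p$sigmaN2
  w <- ifelse(denom > 0, k2 / denom, 0)
  co <- ifelse(p$kSigmaT > 0, w * fo@coeffs / ifelse(p$kSigmaT > 0,
                                                     p$kSigmaT, 1), 0i)
  setCoeffs(fo, co)
}

#' Posterior mean and variance of the (scaled) true map coefficients
#'
#' The posterior of the blurred true signal \code{k F_T} given the
#' observation and the model is a complex Gaussian with precision-weighted
#' mean
#' \deqn{m = \frac{\sigma_f^2 F_o + \sigma_n^2 D F_c}
#'              {\sigma_f^2 + \sigma_n^2}}
#' and variance \eqn{\sigma_f^2 \sigma_n^2 / (\sigma_f^2 + \sigma_n^2)};
#' both are divided by the proxy \code{k sigma_T} for output on the
#' normalized scale.  Reduces to \code{\link{expectedMapCoeffs}} when D = 0
#' and to \code{F_o / k sigma_T} when the noise vanishes.
#'
#' @param fo,fc \linkS4class{FourierSet}s with bins assigned.
#' @param stats data.frame with D, sigmaF2, sigmaN2, kSigmaT per bin.
#' @return list(coeffs = \linkS4class{FourierSet}, variance = per-bin
#'   posterior variance on the normalized scale)
#' @export
posteriorCoeffs <- function(fo, fc, stats) {
  .checkSame(fo, fc)
  p <- .statsPerCoeff(fo, stats, c("sigmaN2", "sigmaF2", "kSigmaT", "D"))
  S <- p$sigmaF2 + p$sigmaN2
  wData <- ifelse(S > 0, p$sigmaF2 / S, ifelse(p$sigmaN2 == 0, 1, 0))
  D <- ifelse(is.finite(p$D), p$D, 0)
  m <- wData * fo@coeffs + (1 - wData) * D * fc@coeffs
  dead <- !(p$kSigmaT > 0)
  co <- ifelse(dead, 0i, m / ifelse(dead, 1, p$kSigmaT))
  k2 <- stats$kSigmaT^2
  Sb <- stats$sigmaF2 + stats$sigmaN2
  v <- ifelse(k2 > 0 & Sb > 0,
              (stats$sigmaF2 * stats$sigmaN2 / Sb) / k2, 0)
  list(coeffs = setCoeffs(fo, co), variance = v)
}
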