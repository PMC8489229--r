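# Maximum-likelihood scaling between observed and calculated structure
# factors.  Per coefficient the observation is modelled as a 2D (complex)
# Gaussian centred on D F_c with total variance S = sigma_f^2 + sigma_n^2
# (Luzzati model error plus reconstruction noise); D and S are estimated in
# resolution bins by maximizing the joint likelihood.

#' Log-likelihood of observed coefficients given the model
#'
#' \deqn{\log L = -\sum_i [ N_i \ln(\pi S_i) + \sum_{s \in i}
#'   |F_o - D_i F_c|^2 / S_i ]}
#' with \eqn{S_i = \sigma_f^2(i) + \sigma_n^2(i)}.
#'
#' @param fo,fc \linkS4class{FourierSet}s with bins assigned.
#' @param stats data.frame with columns bin, D, sigmaF2, sigmaN2 (e.g. from
#'   \code{\link{binStats}}).
#' @return scalar log-likelihood
#' @export
logLikelihood <- function(fo, fc, stats) {
  .checkSame(fo, fc); .checkBinned(fo)
  S <- stats$sigmaF2 + stats$sigmaN2
  used <- sort(unique(fo@binId))
  if (any(!is.finite(S[used]) | S[used] <= 0))
    stop(sprintf("total variance S <= 0 in bin(s) %s",
                 paste(stats$bin[used][!is.finite(S[used]) | S[used] <= 0],
                       collapse = ", ")))
  D <- stats$D[fo@binId]
  r <- fo@coeffs - D * fc@coeffs
  n <- tabulate(fo@binId, nbins = nrow(stats))
  -sum(n[used] * log(pi * S[used])) -
    sum(Re(r * Conj(r)) / S[fo@binId])
}

#' Joint maximum-likelihood estimates of D and the variances per bin
#'
#' The analytic maximizers of the binned complex-Gaussian likelihood:
#' \deqn{D_i = \sum Re(F_o \bar F_c) / \sum |F_c|^2, \qquad
#'       S_i = \langle |F_o - D_i F_c|^2 \rangle_i,}
#' with the unexplained-signal variance recovered as
#' \eqn{\sigma_f^2 = \max(0, S_i - \sigma_n^2(i))} (clipped bins flagged).
#' Bins with zero model power have undefined D and are flagged for
#' exclusion from map coefficients.
#'
#' @param fo,fc \linkS4class{FourierSet}s with bins assigned.
#' @param sigmaN2 per-bin noise variance.
#' @param bins a \linkS4class{BinScheme}.
#' @return list(D, S, sigmaF2, clipped, undefined) per bin
#' @export
estimateScales <- function(fo, fc, sigmaN2, bins) {
  .checkSame(fo, fc); .checkBinned(fo)
  nB <- bins@nBins
  cross <- .binSum(Re(fo@coeffs * Conj(fc@coeffs)), fo@binId, nB)
  pc <- .binSum(Re(fc@coeffs * Conj(fc@coeffs)), fo@binId, nB)
  D <- ifelse(pc > 0, cross / pc, NA_real_)
  r <- fo@coeffs - ifelse(is.na(D[fo@binId]), 0, D[fo@binId]) * fc@coeffs
  S <- .binMean(Re(r * Conj(r)), fo@binId, nB)
  S[is.na(D)] <- NA_real_
  if (anyNA(D) && any(tabulate(fo@binId, nB) > 0 & is.na(D)))
    warning("bins with zero model power: D undefined, bins flagged")
  sigmaF2 <- pmax(0, S - sigmaN2)
  list(D = D, S = S, sigmaF2 = sigmaF2,
       clipped = !is.na(S) & (S - sigmaN2) < 0, undefined = is.na(D))
}

#' Overall sharpening B from observed and zero-ADP model amplitudes
#'
#' Least-squares slope of \code{ln(<|F_o|>_i / <|F_c|>_i)} against
#' \code{-|s|^2/4} over bins with positive mean amplitudes; \code{F_c} must
#' come from a copy of the model with all ADPs set to zero, so the slope is
#' the overall isotropic blurring of the observed map.
#'
#' @param fo \linkS4class{FourierSet} of the observed full map.
#' @param fcZeroAdp \linkS4class{FourierSet} from the zero-ADP model, on
#'   the same layout and binning.
#' @param bins a \linkS4class{BinScheme}.
#' @return list(bOverall in Angstrom^2, fit = lm object,
#'   residuals, binsUsed)
#' @export
estimateOverallB <- function(fo, fcZeroAdp, bins) {
  .checkSame(fo, fcZeroAdp); .checkBinned(fo)
  ao <- .binMean(Mod(fo@coeffs), fo@binId, bins@nBins)
  ac <- .binMean(Mod(fcZeroAdp@coeffs), fo@binId, bins@nBins)
  ok <- !is.na(ao) & !is.na(ac) & ao > 0 & ac > 0 & bins@sCenter > 0
  if (sum(ok) < 3L)
    stop("fewer than 3 usable bins for B estimation; supply B explicitly")
  y <- log(ao[ok] / ac[ok])
  x <- -bins@sCenter[ok]^2 / 4
  fit <- lm(y ~ x)
  list(bOverall = unname(coef(fit)[2]), fit = fit,
       residuals = residuals(fit), binsUsed = which(ok))
}
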