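# Atomic scattering factors.
#
# X-ray factors use the standard International-Tables 4-Gaussian
# parameterization f_x(s) = sum_i a_i exp(-b_i s^2/4) + c with s = 1/d.
# Electron factors for the density-sampling route use the 5-Gaussian
# parameterization of the electron scattering factor (International Tables
# Vol. C, 4.3.2.2).  The primary route converts X-ray factors with the
# Mott-Bethe formula; the 5-Gaussian table is kept as an independent
# cross-check and as the real-space sampling path.

# a1..a4, b1..b4, c  (X-ray, 4 Gaussians + constant)
.it92 <- list(
  H  = list(Z = 1,  a = c(0.493002, 0.322912, 0.140191, 0.04081),
            b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038),
  C  = list(Z = 6,  a = c(2.31, 1.02, 1.5886, 0.865),
            b = c(20.8439, 10.2075, 0.5687, 51.6512), c = 0.2156),
  N  = list(Z = 7,  a = c(12.2126, 3.1322, 2.0125, 1.1663),
            b = c(0.0057, 9.8933, 28.9975, 0.5826), c = -11.529),
  O  = list(Z = 8,  a = c(3.0485, 2.2868, 1.5463, 0.867),
            b = c(13.2771, 5.7011, 0.3239, 32.9089), c = 0.2508),
  F  = list(Z = 9,  a = c(3.5392, 2.6412, 1.517, 1.0243),
            b = c(10.2825, 4.2944, 0.2615, 26.1476), c = 0.2776),
  Na = list(Z = 11, a = c(4.7626, 3.1736, 1.2674, 1.1128),
            b = c(3.285, 8.8422, 0.3136, 129.424), c = 0.676),
  Mg = list(Z = 12, a = c(5.4204, 2.1735, 1.2269, 2.3073),
            b = c(2.8275, 79.2611, 0.3808, 7.1937), c = 0.8584),
  P  = list(Z = 15, a = c(6.4345, 4.1791, 1.78, 1.4908),
            b = c(1.9067, 27.157, 0.526, 68.1645), c = 1.1149),
  S  = list(Z = 16, a = c(6.9053, 5.2034, 1.4379, 1.5863),
            b = c(1.4679, 22.2151, 0.2536, 56.172), c = 0.8669),
  Cl = list(Z = 17, a = c(11.4604, 7.1964, 6.2556, 1.6455),
            b = c(0.0104, 1.1662, 18.5194, 47.7784), c = -9.5574),
  K  = list(Z = 19, a = c(8.2186, 7.4398, 1.0519, 0.8659),
            b = c(12.7949, 0.7748, 213.187, 41.6841), c = 1.4228),
  Ca = list(Z = 20, a = c(8.6266, 7.3873, 1.5899, 1.0211),
            b = c(10.4421, 0.6599, 85.7484, 178.437), c = 1.3751),
  Mn = list(Z = 25, a = c(11.2819, 7.3573, 3.0193, 2.2441),
            b = c(5.3409, 0.3432, 17.8674, 83.7543), c = 1.0896),
  Fe = list(Z = 26, a = c(11.7695, 7.3573, 3.5222, 2.3045),
            b = c(4.7611, 0.3072, 15.3535, 76.8805), c = 1.0369),
  Co = list(Z = 27, a = c(12.2841, 7.3409, 4.0034, 2.3488),
            b = c(4.2791, 0.2784, 13.5359, 71.1692), c = 1.0118),
  Ni = list(Z = 28, a = c(12.8376, 7.292, 4.4438, 2.38),
            b = c(3.8785, 0.2565, 12.1763, 66.3421), c = 1.0341),
  Cu = list(Z = 29, a = c(13.338, 7.1676, 5.6158, 1.6735),
            b = c(3.5828, 0.247, 11.3966, 64.8126), c = 1.191),
  Zn = list(Z = 30, a = c(14.0743, 7.0318, 5.1652, 2.41),
            b = c(3.2655, 0.2333, 10.3163, 58.7097), c = 1.3041),
  Se = list(Z = 34, a = c(17.0006, 5.8196, 3.9731, 4.3543),
            b = c(2.4098, 0.2726, 15.2372, 43.8163), c = 2.8409),
  Br = list(Z = 35, a = c(17.1789, 5.2358, 5.6377, 3.9851),
            b = c(2.1723, 16.5796, 0.2609, 41.4328), c = 2.9557),
  I  = list(Z = 53, a = c(20.1472, 18.9949, 7.5138, 2.2735),
            b = c(4.347, 0.3814, 27.766, 66.8776), c = 4.0712))

# a1..a5, b1..b5 (electron, 5 Gaussians)
.peng <- list(
  H  = list(a = c(0.0349, 0.1201, 0.197, 0.0573, 0.1195),
            b = c(0.5347, 3.5867, 12.3471, 18.9525, 38.6269)),
  C  = list(a = c(0.0893, 0.2563, 0.757, 1.0487, 0.3575),
            b = c(0.2465, 1.71, 6.4094, 18.6113, 50.2523)),
  N  = list(a = c(0.1022, 0.3219, 0.7982, 0.8197, 0.1715),
            b = c(0.2451, 1.7481, 6.1925, 17.3894, 48.1431)),
  O  = list(a = c(0.0974, 0.2921, 0.691, 0.699, 0.2039),
            b = c(0.2067, 1.3815, 4.6943, 12.7105, 32.4726)),
  F  = list(a = c(0.1083, 0.3175, 0.6487, 0.5846, 0.1421),
            b = c(0.2057, 1.3439, 4.2788, 11.3932, 28.7881)),
  Na = list(a = c(0.2142, 0.6853, 0.7692, 1.6589, 1.4482),
            b = c(0.3334, 2.3446, 10.083, 48.3037, 138.27)),
  Mg = list(a = c(0.2314, 0.6866, 0.9677, 2.1882, 1.1339),
            b = c(0.3278, 2.272, 10.9241, 39.2898, 101.9748)),
  P  = list(a = c(0.2548, 0.6106, 1.4541, 2.3204, 0.8477),
            b = c(0.2908, 1.874, 8.5176, 24.3434, 63.2996)),
  S  = list(a = c(0.2497, 0.5628, 1.3899, 2.1865, 0.7715),
            b = c(0.2681, 1.6711, 7.0267, 19.5377, 50.3888)),
  Cl = list(a = c(0.2443, 0.5397, 1.3919, 2.0197, 0.6621),
            b = c(0.2468, 1.5242, 6.1537, 16.6687, 42.3086)),
  K  = list(a = c(0.4115, 1.4031, 2.2784, 2.6742, 2.2162),
            b = c(0.3703, 3.3874, 13.1029, 68.9592, 194.4329)),
  Ca = list(a = c(0.4054, 1.388, 2.1602, 3.7532, 2.2063),
            b = c(0.3499, 3.0991, 11.9608, 53.9353, 142.3892)),
  Mn = list(a = c(0.3796, 1.2094, 1.7815, 2.542, 1.5937),
            b = c(0.2699, 2.0455, 7.4726, 31.0604, 91.5622)),
  Fe = list(a = c(0.3946, 1.2725, 1.7031, 2.314, 1.4795),
            b = c(0.2717, 2.0443, 7.6007, 29.9714, 86.2265)),
  Co = list(a = c(0.4118, 1.3161, 1.6493, 2.193, 1.283),
            b = c(0.2742, 2.0372, 7.7205, 29.968, 84.9383)),
  Ni = list(a = c(0.386, 1.1765, 1.5451, 2.073, 1.3814),
            b = c(0.2478, 1.766, 6.3107, 25.2204, 74.3146)),
  Cu = list(a = c(0.4314, 1.3208, 1.5236, 1.4671, 0.8562),
            b = c(0.2694, 1.9223, 7.3474, 28.9892, 90.6246)),
  Zn = list(a = c(0.4288, 1.2646, 1.4472, 1.8294, 1.0934),
            b = c(0.2593, 1.7998, 6.75, 25.586, 73.5284)),
  Se = list(a = c(0.4477, 1.1678, 1.5843, 2.8087, 1.1956),
            b = c(0.2405, 1.5442, 6.3231, 19.461, 52.0233)),
  Br = list(a = c(0.4798, 1.1948, 1.8695, 2.6953, 0.8203),
            b = c(0.2504, 1.5963, 6.9653, 19.8492, 50.3233)),
  I  = list(a = c(0.7047, 1.9484, 2.594, 4.1526, 1.5057),
            b = c(0.2455, 1.8638, 6.7639, 21.8007, 56.4395)))

# Mott-Bethe physical constant 1/(2 pi^2 a0), a0 = Bohr radius in Angstrom.
# Stated here once, to 6 significant figures: 0.0957346 A^-1 e^-1.
.mottBetheConst <- 1 / (2 * pi^2 * 0.529177210903)

.ffEntry <- function(element) {
  e <- .it92[[as.character(element)]]
  if (is.null(e))
    stop(sprintf("unknown element '%s'; supported: %s", element,
                 paste(names(.it92), collapse = ", ")))
  e
}

#' Atomic number of an element symbol
#' @param element element symbol (e.g. "C").
#' @return integer atomic number
#' @export
atomicNumber <- function(element)
  vapply(element, function(e) .ffEntry(e)$Z, numeric(1))

#' X-ray atomic form factor
#'
#' Sum-of-Gaussians X-ray scattering factor \code{f_x(s)} of a neutral
#' atom, with \code{s = |s| = 1/d} in 1/Angstrom.  \code{f_x(0) = Z} within
#' the accuracy of the tabulation.
#'
#' @param element element symbol.
#' @param s scattering-vector magnitude |s| in 1/Angstrom (vectorized).
#' @return numeric amplitude in electrons
#' @export
xrayFormFactor <- function(element, s) {
  e <- .ffEntry(element)
  stopifnot(all(s >= 0))
  out <- rep(e$c, length(s))
  for (i in seq_along(e$a)) out <- out + e$a[i] * exp(-e$b[i] * s^2 / 4)
  out
}

# Z - f_x computed without cancellation, with f_x implicitly renormalized so
# that f_x(0) = Z exactly (the tabulated a_i + c misses Z by < 0.01 e, which
# would otherwise blow up under the 1/s^2 of Mott-Bethe at small s).
.zMinusFx <- function(e, s) {
  out <- numeric(length(s))
  for (i in seq_along(e$a)) out <- out - e$a[i] * expm1(-e$b[i] * s^2 / 4)
  out
}

#' Electron scattering factor via the Mott-Bethe formula
#'
#' Converts the X-ray factor to an electron scattering factor,
#' \deqn{f_e(s) = C (Z e^{2\pi i s^T \Delta x} - f_x(|s|)) / |s|^2}
#' with \eqn{C = 1/(2\pi^2 a_0)} and an optional nucleus offset
#' \eqn{\Delta x} relative to the electron-cloud centre (used for hydrogen,
#' whose electron is pulled towards the parent atom).  The result is
#' multiplied by the Debye-Waller factor \code{exp(-B|s|^2/4)} (or
#' \code{exp(-s^T B s / 4)} for an anisotropic tensor).
#'
#' The phase sign matches this package's transform convention
#' \code{F = integral rho(x) exp(+2 pi i s.x) dx}: the nucleus term sits at
#' the cloud centre plus \code{dx}.  At \code{|s| = 0} the series limit
#' \code{C sum(a_i b_i)/4} is used (the offset phase vanishes there), never
#' a division by zero.
#'
#' @param element element symbol.
#' @param svec matrix (n x 3) of reciprocal vectors in 1/Angstrom, or a
#'   numeric vector of |s| magnitudes (then \code{dx} must be zero).
#' @param dx nucleus offset in Angstrom (length 3; default zero).
#' @param B isotropic ADP in Angstrom^2, or a 3x3 symmetric tensor.
#' @return complex amplitudes (real when \code{dx} is zero)
#' @export
mottBetheFactor <- function(element, svec, dx = c(0, 0, 0), B = 0) {
  e <- .ffEntry(element)
  if (is.null(dim(svec))) {
    if (any(dx != 0))
      stop("a nonzero nucleus offset needs full reciprocal vectors")
    svec <- cbind(svec, 0, 0)
  }
  s2 <- rowSums(svec^2)
  sn <- sqrt(s2)
  limit0 <- sum(e$a * e$b) / 4
  num <- complex(real = .zMinusFx(e, sn))
  if (any(dx != 0)) {
    phase <- 2 * pi * as.vector(svec %*% dx)
    num <- num + e$Z * (complex(modulus = 1, argument = phase) - 1)
  }
  f <- ifelse(s2 > 0, num / ifelse(s2 > 0, s2, 1), limit0)
  if (is.matrix(B)) {
    q <- rowSums((svec %*% B) * svec)
    dw <- exp(-q / 4)
  } else dw <- exp(-B * s2 / 4)
  .mottBetheConst * f * dw
}

#' Electron scattering factor from the 5-Gaussian tabulation
#'
#' Independent parameterization of the electron scattering factor, used for
#' the real-space density-sampling route of \code{\link{calcFc}} and as a
#' cross-check of the Mott-Bethe route.  No nucleus-offset support.
#'
#' @param element element symbol.
#' @param s |s| in 1/Angstrom (vectorized).
#' @param B isotropic ADP in Angstrom^2.
#' @return numeric amplitudes
#' @export
electronFormFactor <- function(element, s, B = 0) {
  e <- .peng[[as.character(element)]]
  if (is.null(e))
    stop(sprintf("no 5-Gaussian electron factor for element '%s'", element))
  out <- numeric(length(s))
  for (i in seq_along(e$a)) out <- out + e$a[i] * exp(-(e$b[i] + B) * s^2 / 4)
  out
}
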