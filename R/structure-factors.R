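# Electron structure factors from an atomic model.
#
# Default route: direct summation of Mott-Bethe factors over the
# Hermitian-unique coefficients (exact within the form-factor tables, with
# anisotropic ADPs and nucleus offsets).  Fallback/validation route:
# sampling 5-Gaussian atomic densities on the real-space grid followed by
# an FFT, used automatically above `gridThreshold` atom-copies and
# available for cross-checking (no nucleus-offset support there; bin
# agreement between routes is asserted in the test suite).

#' Electron structure factors of an atomic model
#'
#' \deqn{F_c(s) = \sum_j \sum_{atoms} occ \; f_e(s; Z, \Delta x, B_j')
#'   \exp(2\pi i s^T (R_j x + t_j))}
#' over the operators of \code{ops} (identity if omitted), on the grid and
#' cutoff of \code{layout}.  Anisotropic tensors are rotated per operator.
#' The phase origin is the grid start of the layout, consistent with
#' \code{\link{fftMap}}.
#'
#' @param model an \linkS4class{AtomicModel} (asymmetric unit if \code{ops}
#'   given).
#' @param layout a \linkS4class{FourierSet} template (e.g. from
#'   \code{\link{fourierLayout}} or \code{\link{fftMap}}).
#' @param ops optional \linkS4class{SymOpSet}.
#' @param method "direct" (default), "grid", or "auto" (direct up to
#'   \code{gridThreshold} atom-copies).
#' @param gridThreshold atom-copy count above which "auto" switches to the
#'   grid route (default 10000).
#' @return a \linkS4class{FourierSet} of calculated coefficients
#' @export
calcFc <- function(model, layout, ops = NULL,
                   method = c("direct", "grid", "auto"),
                   gridThreshold = 10000L) {
  method <- match.arg(method)
  if (!is.null(ops) && length(ops@R) > 1L)
    model <- expandModel(model, ops)
  a <- model@atoms
  if (method == "auto")
    method <- if (nrow(a) <= gridThreshold) "direct" else "grid"
  lo <- layout@originShift
  box <- layout@cell
  dist <- pmax(pmax(lo[1] - a$x, a$x - lo[1] - box[1]),
               pmax(lo[2] - a$y, a$y - lo[2] - box[2]),
               pmax(lo[3] - a$z, a$z - lo[3] - box[3]))
  if (any(dist > 3))
    warning(sprintf("atom(s) %s lie > 3 A outside the box",
                    paste(head(which(dist > 3), 5), collapse = ", ")))
  if (method == "direct") .calcFcDirect(a, layout) else .calcFcGrid(a, layout)
}

.calcFcDirect <- function(a, layout) {
  cell <- layout@cell
  sv <- cbind(layout@miller[, 1] / cell[1], layout@miller[, 2] / cell[2],
              layout@miller[, 3] / cell[3])
  F <- complex(length(layout@coeffs))
  for (i in seq_len(nrow(a))) {
    B <- if (is.na(a$b11[i])) a$b[i] else .tensorOf(a[i, ])
    fe <- mottBetheFactor(a$element[i], sv,
                          dx = c(a$dx[i], a$dy[i], a$dz[i]), B = B)
    frac <- (c(a$x[i], a$y[i], a$z[i]) - layout@originShift)
    phase <- 2 * pi * (sv %*% frac)
    F <- F + a$occ[i] * fe * complex(modulus = 1, argument = phase)
  }
  setCoeffs(layout, F)
}

.calcFcGrid <- function(a, layout) {
  dims <- layout@dims
  cell <- layout@cell
  vox <- cell / dims
  rho <- array(0, dims)
  for (i in seq_len(nrow(a))) {
    e <- .peng[[a$element[i]]]
    if (is.null(e))
      stop(sprintf("no density parameterization for element '%s'",
                   a$element[i]))
    Biso <- if (is.na(a$b11[i])) a$b[i] else
      (a$b11[i] + a$b22[i] + a$b33[i]) / 3
    btot <- e$b + Biso
    rmax <- max(sqrt(18 * btot) / (2 * pi))
    x <- c(a$x[i], a$y[i], a$z[i]) - layout@originShift
    loI <- pmax(1L, as.integer(floor((x - rmax) / vox)) + 1L)
    hiI <- pmin(dims, as.integer(ceiling((x + rmax) / vox)) + 1L)
    if (any(loI > hiI)) next
    gx <- (loI[1]:hiI[1] - 1L) * vox[1] - x[1]
    gy <- (loI[2]:hiI[2] - 1L) * vox[2] - x[2]
    gz <- (loI[3]:hiI[3] - 1L) * vox[3] - x[3]
    r2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
    dens <- 0
    for (g in seq_along(e$a))
      dens <- dens + e$a[g] * (4 * pi / btot[g])^1.5 *
        exp(-4 * pi^2 * r2 / btot[g])
    rho[loI[1]:hiI[1], loI[2]:hiI[2], loI[3]:hiI[3]] <-
      rho[loI[1]:hiI[1], loI[2]:hiI[2], loI[3]:hiI[3]] + a$occ[i] * dens
  }
  fs <- fftMap(mapGrid(rho, cell, layout@originShift), dMin = layout@dMin)
  fs@binId <- layout@binId
  fs
}
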