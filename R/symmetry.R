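# Point-group operators, model expansion, special positions and ADP
# symmetrization.  Axis conventions (documented, test-locked): Cn about +z;
# Dn adds a 2-fold along +x; T with 2-folds on the coordinate axes and
# 3-folds on the body diagonals; O with 4-folds on the coordinate axes;
# I in the 5-fold-on-z orientation (two opposite vertices on z).

.rotAxis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c + s * K + (1 - c) * tcrossprod(u)
}

.opClose <- function(gens, tol = 1e-9, cap = 200L) {
  ops <- list(diag(3))
  added <- TRUE
  while (added) {
    added <- FALSE
    for (g in c(gens, ops)) for (o in ops) {
      p <- g %*% o
      new <- all(vapply(ops, function(q) max(abs(q - p)) > tol, logical(1)))
      if (new) {
        ops[[length(ops) + 1L]] <- p
        added <- TRUE
        if (length(ops) > cap) stop("operator closure did not converge")
      }
    }
  }
  ops
}

.groupRotations <- function(symbol) {
  sym <- toupper(trimws(symbol))
  if (grepl("^C[0-9]+$", sym)) {
    n <- as.integer(substring(sym, 2))
    if (n < 1) stop("Cn requires n >= 1")
    return(lapply(0:(n - 1), function(k) .rotAxis(c(0, 0, 1), 2 * pi * k / n)))
  }
  if (grepl("^D[0-9]+$", sym)) {
    n <- as.integer(substring(sym, 2))
    if (n < 1) stop("Dn requires n >= 1")
    cn <- lapply(0:(n - 1), function(k) .rotAxis(c(0, 0, 1), 2 * pi * k / n))
    flip <- .rotAxis(c(1, 0, 0), pi)
    return(c(cn, lapply(cn, function(R) flip %*% R)))
  }
  if (sym == "T")
    return(.opClose(list(.rotAxis(c(0, 0, 1), pi),
                         .rotAxis(c(1, 1, 1), 2 * pi / 3))))
  if (sym == "O")
    return(.opClose(list(.rotAxis(c(0, 0, 1), pi / 2),
                         .rotAxis(c(1, 1, 1), 2 * pi / 3))))
  if (sym == "I") {
    # second 5-fold axis at the adjacent icosahedral vertex,
    # polar angle arccos(1/sqrt(5)) from +z
    ct <- 1 / sqrt(5); st <- sqrt(1 - ct^2)
    return(.opClose(list(.rotAxis(c(0, 0, 1), 2 * pi / 5),
                         .rotAxis(c(st, 0, ct), 2 * pi / 5)), cap = 400L))
  }
  stop(sprintf(
    "unknown point-group symbol '%s'; accepted: Cn, Dn, T, O, I", symbol))
}

#' Point-group operators from a symbol
#'
#' Generates the rotation operators of Cn, Dn, T, O or I about the given
#' symmetry origin (by convention the centre of the reconstruction box).
#' Translations are \code{t_j = (I - R_j) c}.
#'
#' @param symbol point-group symbol ("C1", "C4", "D3", "T", "O", "I", ...).
#' @param center symmetry origin in Angstrom (length 3).
#' @return a \linkS4class{SymOpSet}
#' @export
pointGroupOps <- function(symbol, center = c(0, 0, 0)) {
  Rs <- .groupRotations(symbol)
  center <- as.numeric(center)
  t <- vapply(Rs, function(R) as.vector((diag(3) - R) %*% center),
              numeric(3))
  new("SymOpSet", R = Rs, t = matrix(t, nrow = 3), symbol = toupper(symbol),
      center = center)
}

#' Re-centre operators after a box shift
#'
#' When the model and maps are moved by \code{-shift} (e.g. after
#' trimming), the translation of each operator in the new local frame is
#' \code{t_j' = t_j + (R_j - I) shift}, which is the same set of operators
#' about the shifted centre.  Rotations are unchanged.
#'
#' @param ops a \linkS4class{SymOpSet}.
#' @param shift Angstrom vector subtracted from all coordinates.
#' @return a \linkS4class{SymOpSet} in the shifted frame
#' @export
shiftOps <- function(ops, shift) {
  shift <- as.numeric(shift)
  for (j in seq_along(ops@R))
    ops@t[, j] <- ops@t[, j] + as.vector((ops@R[[j]] - diag(3)) %*% shift)
  ops@center <- ops@center - shift
  ops
}

.applyOp <- function(R, t, xyz) sweep(xyz %*% t(R), 2, -t)

#' Expand an asymmetric-unit model by point-group operators
#'
#' Each atom is copied under each operator: \code{x' = R_j x + t_j};
#' anisotropic tensors transform as \code{B' = R_j B R_j^T} (isotropic B is
#' rotation invariant).  Chains are suffixed with the operator number.  With
#' \code{dedupe = TRUE}, copies of special-position atoms that coincide
#' within \code{tol} are emitted once (occupancies summed); the default
#' keeps all copies, which double-counts correctly when occupancies were
#' divided by the stabilizer order beforehand.
#'
#' @param model an \linkS4class{AtomicModel} (asymmetric unit).
#' @param ops a \linkS4class{SymOpSet}.
#' @param dedupe collapse coincident symmetry copies (default FALSE).
#' @param tol coincidence tolerance in Angstrom.
#' @return the expanded \linkS4class{AtomicModel}
#' @export
expandModel <- function(model, ops, dedupe = FALSE, tol = 1e-6) {
  a <- model@atoms
  pieces <- vector("list", length(ops@R))
  for (j in seq_along(ops@R)) {
    aj <- a
    xyz <- .applyOp(ops@R[[j]], ops@t[, j], cbind(a$x, a$y, a$z))
    aj$x <- xyz[, 1]; aj$y <- xyz[, 2]; aj$z <- xyz[, 3]
    if (any(a$dx != 0 | a$dy != 0 | a$dz != 0)) {
      dxyz <- cbind(a$dx, a$dy, a$dz) %*% t(ops@R[[j]])
      aj$dx <- dxyz[, 1]; aj$dy <- dxyz[, 2]; aj$dz <- dxyz[, 3]
    }
    aniso <- which(!is.na(a$b11))
    for (i in aniso) {
      B <- .tensorOf(a[i, ])
      Bp <- ops@R[[j]] %*% B %*% t(ops@R[[j]])
      aj[i, c("b11", "b22", "b33", "b12", "b13", "b23")] <-
        c(Bp[1, 1], Bp[2, 2], Bp[3, 3], Bp[1, 2], Bp[1, 3], Bp[2, 3])
    }
    if (length(ops@R) > 1L) aj$chain <- paste0(a$chain, "_", j)
    pieces[[j]] <- aj
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (dedupe && length(ops@R) > 1L) {
    key <- round(cbind(out$x, out$y, out$z) / tol)
    grp <- match(paste(key[, 1], key[, 2], key[, 3],
                       rep(seq_len(nrow(a)), length(ops@R))),
                 unique(paste(key[, 1], key[, 2], key[, 3],
                              rep(seq_len(nrow(a)), length(ops@R)))))
    occ <- rowsum(out$occ, grp)
    first <- !duplicated(grp)
    out <- out[first, , drop = FALSE]
    out$occ <- occ[, 1]
    rownames(out) <- NULL
  }
  new("AtomicModel", atoms = out, box = model@box)
}

.tensorOf <- function(row)
  matrix(c(row$b11, row$b12, row$b13,
           row$b12, row$b22, row$b23,
           row$b13, row$b23, row$b33), 3, 3)

#' Detect atoms on special positions
#'
#' An atom sits on a special position when
#' \code{|x - (R_j x + t_j)| < epsilon} for some non-identity operator.
#' The stabilizing operators must form a subgroup (closure is verified;
#' failure is an error naming the atom).  Site multiplicity is
#' \code{|ops| / |subgroup|}.  With \code{adjustOccupancy = TRUE} the
#' occupancy of each special atom is divided by its stabilizer order, so a
#' full symmetry expansion double-counts correctly.
#'
#' @param model an \linkS4class{AtomicModel}.
#' @param ops a \linkS4class{SymOpSet}.
#' @param epsilon tolerance in Angstrom (default 0.25).
#' @param adjustOccupancy divide occupancies of special atoms by their
#'   stabilizer order (default FALSE).
#' @return a list with \code{model} (possibly occupancy-adjusted) and
#'   \code{special}, a data.frame (atom, stabilizerSize, multiplicity,
#'   occAdjusted) with the stabilizing operator indices in
#'   \code{attr(,"stabilizers")}
#' @export
findSpecialPositions <- function(model, ops, epsilon = 0.25,
                                 adjustOccupancy = FALSE) {
  a <- model@atoms
  nops <- length(ops@R)
  recs <- list(); stabs <- list()
  # which member of ops equals R_j R_k (ops is closed)
  prodIndex <- function(j, k) {
    p <- ops@R[[j]] %*% ops@R[[k]]
    for (m in seq_len(nops)) if (max(abs(ops@R[[m]] - p)) < 1e-8) return(m)
    NA_integer_
  }
  for (i in seq_len(nrow(a))) {
    x <- c(a$x[i], a$y[i], a$z[i])
    d <- vapply(seq_len(nops), function(j)
      sqrt(sum((x - (ops@R[[j]] %*% x + ops@t[, j]))^2)), numeric(1))
    stab <- which(d < epsilon)
    if (length(stab) <= 1L) next
    for (j in stab) for (k in stab) {
      m <- prodIndex(j, k)
      if (is.na(m) || !(m %in% stab))
        stop(sprintf(
          "stabilizer of atom %d (%s %s%d %s) is not closed within %.3g A",
          i, a$element[i], a$chain[i], a$resno[i], a$name[i], epsilon))
    }
    recs[[length(recs) + 1L]] <- data.frame(
      atom = i, stabilizerSize = length(stab),
      multiplicity = nops / length(stab),
      occAdjusted = adjustOccupancy)
    stabs[[length(stabs) + 1L]] <- stab
    if (adjustOccupancy)
      model@atoms$occ[i] <- a$occ[i] / length(stab)
  }
  special <- if (length(recs)) do.call(rbind, recs) else
    data.frame(atom = integer(), stabilizerSize = integer(),
               multiplicity = numeric(), occAdjusted = logical())
  attr(special, "stabilizers") <- stabs
  list(model = model, special = special)
}

.subsetOps <- function(ops, idx) {
  new("SymOpSet", R = ops@R[idx],
      t = ops@t[, idx, drop = FALSE],
      symbol = paste0(ops@symbol, "|stab"), center = ops@center)
}

#' Project an atom exactly onto its special position
#'
#' Coordinates are replaced by the stabilizer average
#' \code{(1/|G|) sum_j (R_j x + t_j)} and an anisotropic tensor by
#' \code{(1/|G|) sum_j R_j B R_j^T}.  The projection is idempotent and the
#' result is exactly invariant under the stabilizer.
#'
#' @param x Cartesian position (length 3).
#' @param subgroup a \linkS4class{SymOpSet} (the stabilizer).
#' @param B optional 3x3 anisotropic tensor to symmetrize.
#' @return list with \code{x} and (if given) \code{B}
#' @export
projectSpecial <- function(x, subgroup, B = NULL) {
  n <- length(subgroup@R)
  xs <- rowMeans(vapply(seq_len(n), function(j)
    as.vector(subgroup@R[[j]] %*% x + subgroup@t[, j]), numeric(3)))
  out <- list(x = xs)
  if (!is.null(B)) {
    Bs <- Reduce(`+`, lapply(subgroup@R, function(R) R %*% B %*% t(R))) / n
    out$B <- (Bs + t(Bs)) / 2
  }
  out
}

#' Special-position restraint residuals
#'
#' Positional residual \code{sum_j |x - (R_j x + t_j)|^2 / sigma_x^2} and
#' ADP residual \code{sum_j ||B - R_j B R_j^T||_F^2 / sigma_B^2} over all
#' stabilizer elements.  Both vanish for projected atoms; isotropic ADPs
#' give a zero ADP residual under any subgroup.
#'
#' @param x Cartesian position.
#' @param subgroup a \linkS4class{SymOpSet}.
#' @param sigmaX positional weight in Angstrom (> 0).
#' @param sigmaB ADP weight in Angstrom^2 (> 0).
#' @param B optional 3x3 anisotropic tensor (isotropic if NULL).
#' @return list(positional =, adp =)
#' @export
specialRestraintResiduals <- function(x, subgroup, sigmaX = 0.01,
                                      sigmaB = 0.5, B = NULL) {
  stopifnot(sigmaX > 0, sigmaB > 0)
  pos <- sum(vapply(seq_along(subgroup@R), function(j)
    sum((x - (subgroup@R[[j]] %*% x + subgroup@t[, j]))^2), numeric(1)))
  adp <- 0
  if (!is.null(B))
    adp <- sum(vapply(subgroup@R, function(R)
      sum((B - R %*% B %*% t(R))^2), numeric(1)))
  list(positional = pos / sigmaX^2, adp = adp / sigmaB^2)
}

#' Symmetry annotation records
#'
#' Formats operators as PDB MTRIX records or as an mmCIF
#' \code{_struct_ncs_oper} loop, for writing alongside an asymmetric-unit
#' model.
#'
#' @param ops a \linkS4class{SymOpSet}.
#' @param format "mtrix" or "mmcif".
#' @return character vector of record lines
#' @export
symmetryRecords <- function(ops, format = c("mtrix", "mmcif")) {
  format <- match.arg(format)
  n <- length(ops@R)
  if (format == "mtrix") {
    out <- character(0)
    for (j in seq_len(n)) {
      R <- ops@R[[j]]; t <- ops@t[, j]
      for (r in 1:3)
        out <- c(out, sprintf("MTRIX%d %3d%10.6f%10.6f%10.6f     %10.5f",
                              r, j, R[r, 1], R[r, 2], R[r, 3], t[r]))
    }
    return(out)
  }
  hdr <- c("loop_", "_struct_ncs_oper.id", "_struct_ncs_oper.code",
           paste0("_struct_ncs_oper.matrix[", rep(1:3, each = 3), "][",
                  rep(1:3, 3), "]"),
           paste0("_struct_ncs_oper.vector[", 1:3, "]"))
  rows <- vapply(seq_len(n), function(j) {
    R <- ops@R[[j]]
    paste(c(j, if (j == 1) "given" else "generate",
            sprintf("%.6f", as.vector(t(R))),
            sprintf("%.5f", ops@t[, j])), collapse = " ")
  }, character(1))
  c(hdr, rows)
}
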