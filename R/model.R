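# Atomic models: construction, PDB/mmCIF reading (via bio3d, plus a small
# fixed-width ANISOU supplement, which bio3d drops), and PDB writing with
# MTRIX symmetry records.

.emptyAtomCols <- function(n) {
  data.frame(element = character(n), Z = numeric(n), x = numeric(n),
             y = numeric(n), z = numeric(n), occ = rep(1, n),
             b = rep(20, n), b11 = NA_real_, b22 = NA_real_, b33 = NA_real_,
             b12 = NA_real_, b13 = NA_real_, b23 = NA_real_,
             dx = 0, dy = 0, dz = 0, rotatableH = FALSE,
             chain = rep("A", n), resno = seq_len(n),
             resid = rep("LIG", n), name = character(n),
             stringsAsFactors = FALSE)
}

#' Construct an atomic model
#'
#' @param element character vector of element symbols.
#' @param x,y,z Cartesian coordinates in Angstrom.
#' @param occ occupancies (default 1).
#' @param b isotropic B values in Angstrom^2 (default 20).
#' @param chain,resno,resid,name optional labels.
#' @param box optional bounding box hint in Angstrom.
#' @return an \linkS4class{AtomicModel}
#' @export
atomicModel <- function(element, x, y, z, occ = 1, b = 20, chain = "A",
                        resno = NULL, resid = "LIG", name = NULL,
                        box = rep(NA_real_, 3)) {
  n <- length(x)
  a <- .emptyAtomCols(n)
  a$element <- as.character(element)
  a$Z <- atomicNumber(a$element)
  a$x <- x; a$y <- y; a$z <- z
  a$occ <- rep_len(occ, n); a$b <- rep_len(b, n)
  a$chain <- rep_len(chain, n)
  a$resno <- if (is.null(resno)) seq_len(n) else rep_len(resno, n)
  a$resid <- rep_len(resid, n)
  a$name <- if (is.null(name)) a$element else rep_len(name, n)
  if (length(box) == 1L) box <- rep(box, 3L)
  new("AtomicModel", atoms = a, box = as.numeric(box))
}

# PDB v3.3 element inference from the atom-name column when the element
# column is absent or blank: columns 13-14 hold the (right-justified)
# element; a leading digit marks hydrogens like 1HB2.
.elementFromName <- function(name) {
  nm <- toupper(trimws(name))
  twoLetter <- c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR", "SE",
                 "CU", "NI", "CO")
  vapply(nm, function(s) {
    if (grepl("^[0-9]", s)) return("H")
    two <- substr(s, 1, 2)
    if (nchar(s) > 1 && two %in% twoLetter)
      return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

# parent-atom names whose hydrogens have several potential minima
# (hydroxyl / sulfhydryl / carboxyl); user-extensible via options()
.rotatableParents <- function()
  getOption("cryodiff.rotatableParents",
            c("OG", "OG1", "OH", "SG", "OXT", "OD1", "OD2", "OE1", "OE2"))

.markRotatableH <- function(a) {
  isH <- a$element == "H"
  if (!any(isH)) return(a)
  heavy <- which(!isH)
  rot <- .rotatableParents()
  for (i in which(isH)) {
    d2 <- (a$x[heavy] - a$x[i])^2 + (a$y[heavy] - a$y[i])^2 +
      (a$z[heavy] - a$z[i])^2
    p <- heavy[which.min(d2)]
    if (length(p) && min(d2) < 1.6^2 && toupper(a$name[p]) %in% rot)
      a$rotatableH[i] <- TRUE
  }
  a
}

#' Read an atomic model from PDB or mmCIF
#'
#' Coordinates, occupancies and B values are read with \pkg{bio3d};
#' anisotropic ADPs are collected from ANISOU records (PDB input) and
#' converted from U (A^2) to B (A^2) via \code{B = 8 pi^2 U}.  Elements are
#' inferred from atom names by PDB v3.3 rules when the element column is
#' blank.  Hydrogens bonded to hydroxyl/sulfhydryl/carboxyl parents are
#' flagged as rotatable.
#'
#' @param path path to a .pdb or .cif/.mmcif file.
#' @return an \linkS4class{AtomicModel}
#' @export
readModel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
         else bio3d::read.pdb(path)
  at <- pdb$atom
  n <- nrow(at)
  if (n < 1L) stop("model contains no atoms: ", path)
  a <- .emptyAtomCols(n)
  elem <- trimws(at$elesy)
  blank <- is.na(elem) | elem == ""
  if (any(blank)) elem[blank] <- .elementFromName(at$elety[blank])
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substring(elem, 2)))
  a$element <- elem
  a$Z <- atomicNumber(elem)
  a$x <- at$x; a$y <- at$y; a$z <- at$z
  a$occ <- ifelse(is.na(at$o), 1, at$o)
  a$b <- ifelse(is.na(at$b), 20, at$b)
  a$chain <- ifelse(is.na(at$chain), "A", at$chain)
  a$resno <- at$resno
  a$resid <- at$resid
  a$name <- at$elety
  if (ext == "pdb" || ext == "") {
    an <- .readAnisou(path)
    if (nrow(an)) {
      key <- paste(a$chain, a$resno, a$name)
      m <- match(paste(an$chain, an$resno, an$name), key)
      ok <- !is.na(m)
      for (cc in c("b11", "b22", "b33", "b12", "b13", "b23"))
        a[[cc]][m[ok]] <- an[[cc]][ok]
    }
  }
  a <- .markRotatableH(a)
  new("AtomicModel", atoms = a, box = rep(NA_real_, 3))
}

.readAnisou <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ANISOU")]
  if (!length(lines))
    return(data.frame(chain = character(), resno = integer(),
                      name = character(), b11 = numeric(), b22 = numeric(),
                      b33 = numeric(), b12 = numeric(), b13 = numeric(),
                      b23 = numeric()))
  u <- function(lo, hi) as.numeric(substr(lines, lo, hi))
  conv <- 8 * pi^2 * 1e-4  # U*1e4 -> B
  data.frame(chain = trimws(substr(lines, 22, 22)),
             resno = as.integer(substr(lines, 23, 26)),
             name = trimws(substr(lines, 13, 16)),
             b11 = u(29, 35) * conv, b22 = u(36, 42) * conv,
             b33 = u(43, 49) * conv, b12 = u(50, 56) * conv,
             b13 = u(57, 63) * conv, b23 = u(64, 70) * conv,
             stringsAsFactors = FALSE)
}

#' Write an atomic model as PDB, optionally with MTRIX symmetry records
#'
#' @param model an \linkS4class{AtomicModel}.
#' @param path output path.
#' @param ops optional \linkS4class{SymOpSet} written as MTRIX records (the
#'   asymmetric-unit convention: operators that regenerate the full
#'   assembly).
#' @return \code{path}, invisibly
#' @export
writeModel <- function(model, path, ops = NULL) {
  a <- model@atoms
  out <- character(0)
  if (!is.null(ops)) out <- c(out, symmetryRecords(ops, "mtrix"))
  iso <- is.na(a$b11)
  for (i in seq_len(nrow(a))) {
    nm <- a$name[i]
    nmfmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else substr(nm, 1, 4)
    out <- c(out, sprintf(
      "ATOM  %5d %s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i %% 100000, nmfmt, substr(a$resid[i], 1, 3),
      substr(a$chain[i], 1, 2), a$resno[i] %% 10000,
      a$x[i], a$y[i], a$z[i], a$occ[i], a$b[i], toupper(a$element[i])))
    if (!iso[i]) {
      u <- round(c(a$b11[i], a$b22[i], a$b33[i], a$b12[i], a$b13[i],
                   a$b23[i]) / (8 * pi^2) * 1e4)
      out <- c(out, sprintf(
        "ANISOU%5d %s %-3s%2s%4d  %7d%7d%7d%7d%7d%7d      %2s",
        i %% 100000, nmfmt, substr(a$resid[i], 1, 3),
        substr(a$chain[i], 1, 2), a$resno[i] %% 10000,
        u[1], u[2], u[3], u[4], u[5], u[6], toupper(a$element[i])))
    }
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Set all isotropic B values of a model
#'
#' Used e.g. to build the zero-ADP copy against which the overall
#' sharpening B is estimated.
#'
#' @param model an \linkS4class{AtomicModel}.
#' @param b new isotropic B in Angstrom^2 (scalar or per atom).
#' @return the modified model (anisotropic tensors are cleared)
#' @export
setBFactors <- function(model, b) {
  model@atoms$b <- rep_len(b, nrow(model@atoms))
  model@atoms[c("b11", "b22", "b33", "b12", "b13", "b23")] <- NA_real_
  model
}

#' Drop selected atoms from a model (omit selection)
#'
#' @param model an \linkS4class{AtomicModel}.
#' @param which integer indices, or a logical vector, of atoms to omit.
#' @return the reduced model
#' @export
omitAtoms <- function(model, which) {
  keep <- setdiff(seq_len(nrow(model@atoms)),
                  if (is.logical(which)) base::which(which) else which)
  if (!length(keep)) stop("omit selection removes every atom")
  model@atoms <- model@atoms[keep, , drop = FALSE]
  rownames(model@atoms) <- NULL
  model
}

#' Apply a nucleus offset to hydrogens along the parent-to-H direction
#'
#' Interprets the stored hydrogen positions as nucleus positions, moves the
#' stored (electron-cloud) centre towards the parent atom by
#' \code{magnitude}, and records the compensating nucleus offset so the
#' Mott-Bethe factor places the proton at the original position.
#'
#' @param model an \linkS4class{AtomicModel} with explicit hydrogens.
#' @param magnitude shift in Angstrom (typical 0.1-0.2; default 0 = off).
#' @return the modified model
#' @export
setHNucleusOffset <- function(model, magnitude = 0) {
  a <- model@atoms
  isH <- a$element == "H"
  if (!any(isH) || magnitude == 0) return(model)
  heavy <- which(!isH)
  for (i in which(isH)) {
    d2 <- (a$x[heavy] - a$x[i])^2 + (a$y[heavy] - a$y[i])^2 +
      (a$z[heavy] - a$z[i])^2
    p <- heavy[which.min(d2)]
    u <- c(a$x[i] - a$x[p], a$y[i] - a$y[p], a$z[i] - a$z[p])
    u <- u / sqrt(sum(u^2))
    a$x[i] <- a$x[i] - magnitude * u[1]
    a$y[i] <- a$y[i] - magnitude * u[2]
    a$z[i] <- a$z[i] - magnitude * u[3]
    a$dx[i] <- magnitude * u[1]
    a$dy[i] <- magnitude * u[2]
    a$dz[i] <- magnitude * u[3]
  }
  model@atoms <- a
  model
}
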