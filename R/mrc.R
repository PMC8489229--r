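# MRC/CCP4 2014 volume format.  Modes 0 (int8), 1 (int16) and 2 (float32)
# are read; mode 2 is written.  Any mapc/mapr/maps axis permutation is
# canonicalized to X-fastest on read.  Little-endian byte order is assumed
# (the format's machine stamp is written accordingly).

#' Read an MRC/CCP4 map
#'
#' The origin of the grid relative to the absolute frame is taken from the
#' ORIGIN header fields when nonzero, otherwise from
#' \code{nxstart/nystart/nzstart} times the voxel size.
#'
#' @param path path to an MRC/CCP4 file.
#' @return a \linkS4class{MapGrid}
#' @export
readMRC <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nxyz <- hdr[1:3]; mode <- hdr[4]; nstart <- hdr[5:7]; mxyz <- hdr[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  axmap <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  stats3 <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", n = 25, size = 4, endian = "little"))
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  magic <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", n = 1, size = 4, endian = "little"))
  invisible(readBin(con, "numeric", n = 1, size = 4, endian = "little"))
  invisible(readBin(con, "integer", n = 1, size = 4, endian = "little"))
  invisible(readBin(con, "raw", n = 800))
  if (!identical(substr(magic, 1, 3), "MAP"))
    stop("malformed MRC header: MAP magic word missing in field 53")
  if (any(nxyz <= 0) || any(mxyz <= 0))
    stop("malformed MRC header: non-positive grid dimensions (NX/NY/NZ)")
  if (!mode %in% c(0L, 1L, 2L))
    stop(sprintf("unsupported MRC mode %d (field MODE); modes 0/1/2 supported",
                 mode))
  if (max(abs(cellb - 90)) > 1e-3)
    stop("unsupported geometry: cell angles (CELLB) must be 90 degrees")
  if (!setequal(axmap, 1:3))
    stop("malformed MRC header: MAPC/MAPR/MAPS must be a permutation of 1:3")
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  n <- prod(nxyz)
  dat <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"))
  if (length(dat) < n)
    stop(sprintf("truncated MRC file: expected %d data values, found %d",
                 n, length(dat)))
  A <- array(as.numeric(dat), dim = nxyz)
  # axis k of the stored array corresponds to crystal axis axmap[k];
  # permute so array axis k is crystal axis k (X fastest)
  perm <- match(1:3, axmap)
  A <- aperm(A, perm)
  dims <- dim(A)
  nstartXYZ <- nstart[perm]
  vox <- cella / mxyz
  voxXYZ <- vox  # cella is already in crystal-axis (X,Y,Z) order
  shift <- if (any(abs(origin) > 1e-6)) origin else nstartXYZ * voxXYZ
  mapGrid(A, cell = dims * voxXYZ, originShift = shift)
}

#' Write a map in MRC/CCP4 2014 format (mode 2)
#'
#' Written X-fastest with the voxel size and origin preserved; the origin is
#' stored both in the ORIGIN fields and, when it is an integral number of
#' voxels, in \code{nxstart/nystart/nzstart}.
#'
#' @param map a \linkS4class{MapGrid}.
#' @param path output file path.
#' @return \code{path}, invisibly
#' @export
writeMRC <- function(map, path) {
  stopifnot(is(map, "MapGrid"))
  dims <- dim(map@values)
  vox <- map@cell / dims
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  nstart <- map@originShift / vox
  nstart <- ifelse(abs(nstart - round(nstart)) < 1e-6, round(nstart), 0)
  v <- map@values
  wInt(dims); wInt(2L); wInt(nstart); wInt(dims)
  wFlt(map@cell); wFlt(c(90, 90, 90))
  wInt(1:3)
  wFlt(c(min(v), max(v), mean(v)))
  wInt(1L); wInt(0L)
  wInt(integer(25))
  wFlt(map@originShift)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
  wFlt(sd(as.vector(v)))
  wInt(1L)
  lab <- charToRaw(formatC("cryodiff", width = -80))
  writeBin(c(lab, raw(800 - length(lab))), con)
  wFlt(as.vector(v))
  invisible(path)
}
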