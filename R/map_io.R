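#' Density map on a unit-cell grid
#'
#' A `map_grid` samples a periodic scalar field on an `na x nb x nc` grid
#' covering one unit cell: voxel `(i, j, k)` (zero-based) sits at fractional
#' coordinate `origin + (i/na, j/nb, k/nc)`.  The grid is periodic: index
#' `na` wraps to 0.
#'
#' @param values 3D numeric array (na x nb x nc).
#' @param cell unit cell `(a, b, c, alpha, beta, gamma)`.
#' @param origin fractional coordinate of voxel (0, 0, 0).
#' @return object of class `map_grid`.
#' @export
map_grid <- function(values, cell, origin = c(0, 0, 0)) {
  validate_cell(cell)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  structure(list(values = values, cell = as.numeric(cell),
                 origin = as.numeric(origin)),
            class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<map_grid> %d x %d x %d voxels, cell %.2f %.2f %.2f A, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$cell[1], x$cell[2], x$cell[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Write a map in CCP4/MRC 2014 format
#'
#' Single-volume float32 map covering one full unit cell, axis order
#' column = a, row = b, section = c, little-endian, readable by standard
#' viewers (Coot, ChimeraX, PyMOL).
#'
#' @param map a [map_grid()].
#' @param path output file.
#' @export
write_map <- function(map, path) {
  v <- map$values
  d <- dim(v)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # NX NY NZ (columns, rows, sections)
  wi(2)                      # MODE 2 = float32
  wi(round(map$origin * d))  # NXSTART NYSTART NZSTART
  wi(d)                      # MX MY MZ: sampling along cell edges
  wf(map$cell[1:3])          # CELLA
  wf(map$cell[4:6])          # CELLB
  wi(c(1, 2, 3))             # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))   # DMIN DMAX DMEAN
  wi(1)                      # ISPG (P1)
  wi(0)                      # NSYMBT
  wi(rep(0L, 25))            # EXTRA (words 26-50... reserved block)
  wf(c(0, 0, 0))             # ORIGIN (MRC convention, unused for cryst maps)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(as.numeric(v)))                      # RMS
  wi(0)                      # NLABL
  writeBin(raw(800), con)    # labels
  wf(as.numeric(v))          # data, column (= a axis) fastest
  invisible(path)
}

#' Read a CCP4/MRC map written by [write_map()]
#'
#' Supports mode-2 maps with axis order 1,2,3 and full-cell sampling
#' (`MX,MY,MZ` equal to the stored dimensions), which is what [write_map()]
#' produces.
#'
#' @param path map file.
#' @return a [map_grid()].
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) maps supported")
  nstart <- ri(3)
  m <- ri(3)
  cella <- rf(3); cellb <- rf(3)
  axes <- ri(3)
  if (!identical(axes, c(1L, 2L, 3L))) stop("only axis order 1,2,3 supported")
  if (!identical(m, d)) stop("map does not cover exactly one unit cell")
  seek(con, 1024)
  v <- rf(prod(d))
  map_grid(array(v, dim = d), c(cella, cellb), origin = nstart / d)
}
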