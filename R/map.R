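#' Density maps
#'
#' A `density_map` is a real-valued periodic grid sampling one unit cell on
#' fractional coordinates, 0-based grid indices, x fastest. Grid point
#' `(i, j, k)` sits at fractional position `(i/nx, j/ny, k/nz)`.
#'
#' @param grid Numeric 3D array, every dimension `>= 2`.
#' @param cell A [unit_cell()].
#' @return An object of class `density_map` with fields `grid` and `cell`.
#' @export
density_map <- function(grid, cell) {
  stopifnot(inherits(cell, "unit_cell"))
  if (!is.array(grid) || length(dim(grid)) != 3)
    stop("grid must be a 3D array")
  if (any(dim(grid) < 2)) stop("grid dimensions must all be >= 2")
  if (!all(is.finite(grid))) stop("grid contains non-finite values")
  structure(list(grid = grid, cell = cell), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("density_map %dx%dx%d  mean=%.4g sd=%.4g min=%.4g max=%.4g\n",
              d[1], d[2], d[3], mean(x$grid), stats::sd(as.vector(x$grid)),
              min(x$grid), max(x$grid)))
  invisible(x)
}

sg_number <- function(name) switch(name, P1 = 1L, P21 = 4L, P63 = 173L, 0L)

#' Write a density map in CCP4/MRC format
#'
#' Mode-2 (32-bit float) volume, little-endian, axis order x fastest, full
#' unit cell. Readable by standard crystallographic viewers; a round trip
#' through [read_map()] reproduces the grid to float precision.
#'
#' @param map A [density_map()] (or, for label/mask export, an integer or
#'   logical array wrapped in one).
#' @param path Output file path.
#' @param sg Optional [spacegroup()] used to set the header's space-group
#'   number (defaults to P1).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, sg = NULL) {
  stopifnot(inherits(map, "density_map"))
  g <- map$grid
  d <- dim(g)
  cellp <- c(map$cell$a, map$cell$b, map$cell$c,
             map$cell$alpha, map$cell$beta, map$cell$gamma)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                          # NC NR NS
  wi(2L)                         # MODE 2 = float32
  wi(c(0L, 0L, 0L))              # start
  wi(d)                          # sampling MX MY MZ
  wf(cellp)                      # CELLA, CELLB
  wi(c(1L, 2L, 3L))              # MAPC MAPR MAPS
  wf(c(min(g), max(g), mean(g))) # DMIN DMAX DMEAN
  wi(if (is.null(sg)) 1L else sg_number(sg$name))  # ISPG
  wi(0L)                         # NSYMBT
  wi(rep(0L, 25))                # EXTRA (words 26-50)
  wf(c(0, 0, 0))                 # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(as.vector(g)))    # RMS
  wi(1L)                         # NLABL
  lab <- formatC("density map written by amtkit", width = -80)
  writeChar(paste(rep(lab, 1), collapse = ""), con, nchars = 80, eos = NULL)
  writeChar(strrep(" ", 720), con, nchars = 720, eos = NULL)
  wf(as.vector(g))
  invisible(path)
}

#' Read a CCP4/MRC mode-2 map
#'
#' Minimal reader for volumes written by [write_map()] (mode 2, axis order
#' 1,2,3, little-endian).
#'
#' @param path File path.
#' @return A [density_map()].
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported map mode ", mode, " (only mode 2)")
  ri(3)                          # start
  ri(3)                          # sampling
  cellp <- rf(6)
  axes <- ri(3)
  if (!identical(axes, c(1L, 2L, 3L))) stop("unsupported axis order")
  rf(3)                          # min/max/mean
  ri(1)                          # ISPG
  nsym <- ri(1)
  seek(con, 1024 + nsym)
  g <- rf(prod(d))
  density_map(array(g, dim = d),
              unit_cell(cellp[1], cellp[2], cellp[3],
                        cellp[4], cellp[5], cellp[6]))
}
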