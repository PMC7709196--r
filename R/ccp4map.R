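#' Write a density grid as a CCP4/MRC map file
#'
#' Mode-2 (float) map covering the full unit cell, axis order X, Y, Z.
#' Intended for visual inspection of difference maps and shift-field
#' magnitudes; flag-gated in the CLI.
#'
#' @param grid A `density_grid`.
#' @param path Output path.
#' @param spacegroup_number ISPG header word (default 1, P 1).
#' @export
write_ccp4_map <- function(grid, path, spacegroup_number = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  v <- grid$values
  dm <- grid$dim
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dm)                                   # NC NR NS
  wi(2L)                                   # MODE float
  wi(c(0L, 0L, 0L))                        # start
  wi(dm)                                   # intervals
  wf(c(grid$cell$a, grid$cell$b, grid$cell$c,
       grid$cell$alpha, grid$cell$beta, grid$cell$gamma))
  wi(c(1L, 2L, 3L))                        # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))
  wi(spacegroup_number)
  wi(0L)                                   # NSYMBT
  wi(rep(0L, 25))                          # extra
  wf(c(0, 0, 0))                           # origin
  writeChar("MAP ", con, 4, eos = NULL)
  wi(16708L)                               # little-endian machine stamp
  wf(stats::sd(as.vector(v)))
  wi(0L)                                   # NLABL
  writeBin(raw(800), con)                  # labels
  wf(as.vector(v))
  invisible(path)
}

#' Read a CCP4/MRC map written by [write_ccp4_map()]
#'
#' Supports the subset this package writes: mode 2, zero start, full-cell
#' extent, axis order X, Y, Z.
#'
#' @param path Path to the map file.
#' @return A `density_grid`.
#' @export
read_ccp4_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dm <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported map mode ", mode)
  start <- ri(3)
  if (any(start != 0)) stop("nonzero map start not supported")
  ri(3)                                    # intervals (== dm here)
  cellv <- rf(6)
  axes <- ri(3)
  if (!all(axes == 1:3)) stop("unsupported axis order")
  rf(3); ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  vals <- rf(prod(dm))
  cell <- do.call(unit_cell, as.list(cellv))
  density_grid(cell, dm, array(vals, dm))
}
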