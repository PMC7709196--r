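#' Smallest FFT-efficient size >= n (products of 2, 3, 5)
#' @param n Positive integer.
#' @export
fft_friendly <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Choose a map grid for a cell and resolution
#'
#' Grid spacing along each axis is at most d / (2 * oversample); with the
#' default oversample of 1.5 this gives ~d/3 spacing (a 1 Angstrom grid for
#' 3 Angstrom data). Dimensions are rounded up to FFT-efficient sizes.
#'
#' @param cell A `unit_cell`.
#' @param d Resolution in Angstroms (> 0).
#' @param oversample Oversampling rate relative to the Nyquist spacing d/2
#'   (>= 1).
#' @return Object of class `grid_spec`: list with `dim` (nu, nv, nw), `d`,
#'   `oversample` and target `spacing`.
#' @export
choose_grid <- function(cell, d, oversample = 1.5) {
  stopifnot(d > 0, oversample >= 1)
  spacing <- d / (2 * oversample)
  dims <- vapply(c(cell$a, cell$b, cell$c),
                 function(e) fft_friendly(e / spacing), integer(1))
  structure(list(dim = dims, d = d, oversample = oversample,
                 spacing = spacing), class = "grid_spec")
}

#' Periodic density grid over the unit cell
#'
#' @param cell A `unit_cell`.
#' @param dim Integer vector (nu, nv, nw), each >= 2.
#' @param values Optional 3D array of matching shape (default zeros).
#' @return Object of class `density_grid`; grid point (i,j,k) (zero-based)
#'   maps to fractional coordinate (i/nu, j/nv, k/nw).
#' @export
density_grid <- function(cell, dim, values = NULL) {
  dim <- as.integer(if (inherits(dim, "grid_spec")) dim$dim else dim)
  stopifnot(length(dim) == 3, all(dim >= 2))
  if (is.null(values)) values <- array(0, dim)
  stopifnot(all(base::dim(values) == dim))
  structure(list(cell = cell, dim = dim, values = values),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density grid %d x %d x %d, range [%.4g, %.4g]\n",
              x$dim[1], x$dim[2], x$dim[3], min(x$values), max(x$values)))
  invisible(x)
}

# place Friedel-completed coefficients into a complex FFT array
coeff_array <- function(hkl, coeff, dim) {
  hkl <- rbind2mat(hkl)
  hmax <- apply(abs(hkl), 2, max)
  if (any(dim < 2 * hmax + 1))
    stop(sprintf("grid %dx%dx%d below Nyquist for |h|max = (%d,%d,%d)",
                 dim[1], dim[2], dim[3], hmax[1], hmax[2], hmax[3]))
  arr <- array(0i, dim)
  ip <- hkl %% matrix(dim, nrow(hkl), 3, byrow = TRUE)
  im <- (-hkl) %% matrix(dim, nrow(hkl), 3, byrow = TRUE)
  arr[ip + 1L] <- coeff
  arr[im + 1L] <- Conj(coeff)
  arr
}

# real Fourier synthesis rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x),
# Friedel-completed from the unique half set
synth_real <- function(cell, hkl, coeff, dim) {
  arr <- coeff_array(hkl, coeff, dim)
  density_grid(cell, dim, Re(stats::fft(arr)) / cell$volume)
}

# inverse: F(h) = (V/N) * conj-transform of the sampled density
sf_from_grid <- function(grid, hkl) {
  hkl <- rbind2mat(hkl)
  Farr <- stats::fft(grid$values, inverse = TRUE) *
    (grid$cell$volume / prod(grid$dim))
  idx <- hkl %% matrix(grid$dim, nrow(hkl), 3, byrow = TRUE)
  Farr[idx + 1L]
}

#' Trilinear interpolation on a periodic grid
#'
#' @param grid A `density_grid` (or plain 3D array with `dim` supplied by the
#'   caller via a grid object).
#' @param frac Matrix (n x 3) or vector of fractional coordinates; wrapped
#'   periodically.
#' @return Numeric vector of interpolated values.
#' @export
interp_grid <- function(grid, frac) {
  interp_array(grid$values, grid$dim, frac)
}

interp_array <- function(values, dim, frac) {
  frac <- rbind2mat(frac)
  g <- wrap_frac(frac) * matrix(dim, nrow(frac), 3, byrow = TRUE)
  i0 <- floor(g)
  t <- g - i0
  out <- numeric(nrow(frac))
  nu <- dim[1]; nv <- dim[2]; nw <- dim[3]
  for (du in 0:1) for (dv in 0:1) for (dw in 0:1) {
    wgt <- (if (du) t[, 1] else 1 - t[, 1]) *
           (if (dv) t[, 2] else 1 - t[, 2]) *
           (if (dw) t[, 3] else 1 - t[, 3])
    ii <- (i0[, 1] + du) %% nu
    jj <- (i0[, 2] + dv) %% nv
    kk <- (i0[, 3] + dw) %% nw
    out <- out + wgt * values[1L + ii + nu * (jj + nv * kk)]
  }
  out
}
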