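#' Triclinic unit cell
#'
#' Constructs a unit-cell object holding the cell constants together with the
#' derived orthogonalization matrix (fractional -> orthogonal Angstroms, PDB
#' convention: a along x, b in the xy plane), its inverse, and the cell volume.
#'
#' @param a,b,c Cell edge lengths in Angstroms (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` with fields `a,b,c,alpha,beta,gamma`,
#'   `orth` (3x3), `frac` (3x3 inverse) and `volume` (cubic Angstroms).
#' @examples
#' cl <- unit_cell(20, 30, 40, 90, 100, 90)
#' cl$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("unit cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  vf2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vf2 <= 0) stop("unit cell angles are geometrically impossible")
  vf <- sqrt(vf2)
  orth <- matrix(c(a, b * cg, c * cb,
                   0, b * sg, c * (ca - cb * cg) / sg,
                   0, 0,      c * vf / sg),
                 nrow = 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 orth = orth, frac = solve(orth),
                 volume = a * b * c * vf),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Convert fractional coordinates to orthogonal Angstroms
#'
#' @param cell A `unit_cell`.
#' @param x Numeric matrix (n x 3) or length-3 vector of fractional coordinates.
#' @return Matrix (n x 3) of orthogonal coordinates in Angstroms.
#' @export
frac_to_orth <- function(cell, x) {
  x <- rbind2mat(x)
  x %*% t(cell$orth)
}

#' Convert orthogonal Angstrom coordinates to fractional
#' @inheritParams frac_to_orth
#' @param x Numeric matrix (n x 3) or length-3 vector of orthogonal coordinates.
#' @return Matrix (n x 3) of fractional coordinates (not wrapped).
#' @export
orth_to_frac <- function(cell, x) {
  x <- rbind2mat(x)
  x %*% t(cell$frac)
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' Wrap fractional coordinates into [0, 1)
#' @param x Numeric vector/matrix of fractional coordinates.
#' @export
wrap_frac <- function(x) x - floor(x)

#' Resolution (d-spacing) of Miller indices
#'
#' Computes d = 1/|s| from the cell's reciprocal metric, where the scattering
#' vector is s = A^-T h for orthogonalization matrix A.
#'
#' @param cell A `unit_cell`.
#' @param hkl Integer matrix (n x 3) of Miller indices.
#' @return Numeric vector of d-spacings in Angstroms (Inf for (0,0,0)).
#' @export
d_spacing <- function(cell, hkl) {
  hkl <- rbind2mat(hkl)
  s <- hkl %*% cell$frac          # row vectors: t(s) = t(h) %*% A^-1
  1 / sqrt(rowSums(s * s))
}

#' Inverse-square resolution 1/d^2 of Miller indices
#' @inheritParams d_spacing
#' @export
inv_d2 <- function(cell, hkl) {
  hkl <- rbind2mat(hkl)
  s <- hkl %*% cell$frac
  rowSums(s * s)
}
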