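# independent oracles, deliberately coded with different algorithms than the
# implementation they check

# direct-space circular convolution by explicit summation over the kernel
oracle_circular_convolution <- function(a, b) {
  dm <- dim(a)
  out <- array(0, dm)
  idx <- which(b != 0, arr.ind = TRUE) - 1L   # sum only over kernel support
  for (r in seq_len(nrow(idx))) {
    sh <- idx[r, ]
    w <- b[sh[1] + 1L, sh[2] + 1L, sh[3] + 1L]
    rolled <- a[((seq_len(dm[1]) - 1L - sh[1]) %% dm[1]) + 1L,
                ((seq_len(dm[2]) - 1L - sh[2]) %% dm[2]) + 1L,
                ((seq_len(dm[3]) - 1L - sh[3]) %% dm[3]) + 1L]
    out <- out + w * rolled
  }
  out
}

# scalar, index-by-index trilinear interpolation with periodic wrap
oracle_trilinear <- function(values, frac) {
  dm <- dim(values)
  vapply(seq_len(nrow(frac)), function(p) {
    g <- (frac[p, ] %% 1) * dm
    i0 <- floor(g); t <- g - i0
    acc <- 0
    for (du in 0:1) for (dv in 0:1) for (dw in 0:1) {
      w <- prod(ifelse(c(du, dv, dw) == 1, t, 1 - t))
      acc <- acc + w * values[((i0[1] + du) %% dm[1]) + 1,
                              ((i0[2] + dv) %% dm[2]) + 1,
                              ((i0[3] + dw) %% dm[3]) + 1]
    }
    acc
  }, numeric(1))
}

# explicit weighted least squares at one grid point: weights are the kernel
# values centred on that point, predictors the gradient maps, response the
# difference map; solves the normal equations densely
oracle_wls_at_point <- function(dmap, grads, kernel, point) {
  dm <- dim(dmap)
  w <- kernel[((seq_len(dm[1]) - point[1]) %% dm[1]) + 1L,
              ((seq_len(dm[2]) - point[2]) %% dm[2]) + 1L,
              ((seq_len(dm[3]) - point[3]) %% dm[3]) + 1L]
  X <- vapply(grads, as.vector, numeric(prod(dm)))
  wv <- as.vector(w); yv <- as.vector(dmap)
  A <- crossprod(X, wv * X)
  solve(A, crossprod(X, wv * yv))
}

# Needleman-Wunsch global alignment score, match +1 / mismatch -1 / gap -2
oracle_nw_score <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- -2 * (0:n); F[1, ] <- -2 * (0:m)
  for (i in 1:n) for (j in 1:m) {
    F[i + 1, j + 1] <- max(F[i, j] + ifelse(a[i] == b[j], 1, -1),
                           F[i, j + 1] - 2, F[i + 1, j] - 2)
  }
  F[n + 1, m + 1]
}

# triclinic cell volume / d-spacing closed forms
oracle_cell_volume <- function(a, b, c, al, be, ga) {
  ca <- cos(al * pi / 180); cb <- cos(be * pi / 180); cg <- cos(ga * pi / 180)
  a * b * c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

oracle_d_spacing <- function(a, b, c, al, be, ga, h, k, l) {
  ca <- cos(al * pi / 180); cb <- cos(be * pi / 180); cg <- cos(ga * pi / 180)
  sa <- sin(al * pi / 180); sb <- sin(be * pi / 180); sg <- sin(ga * pi / 180)
  V <- oracle_cell_volume(a, b, c, al, be, ga)
  s2 <- (h^2 * b^2 * c^2 * sa^2 + k^2 * a^2 * c^2 * sb^2 + l^2 * a^2 * b^2 * sg^2 +
           2 * h * k * a * b * c^2 * (ca * cb - cg) +
           2 * k * l * a^2 * b * c * (cb * cg - ca) +
           2 * h * l * a * b^2 * c * (ca * cg - cb)) / V^2
  1 / sqrt(s2)
}

# figure of merit for an acentric reflection by direct phase-space quadrature:
# m = <cos dphi> under p(dphi) proportional to exp(X cos dphi)
oracle_fom_acentric <- function(X) {
  num <- stats::integrate(function(p) cos(p) * exp(X * (cos(p) - 1)),
                          -pi, pi, rel.tol = 1e-12)$value
  den <- stats::integrate(function(p) exp(X * (cos(p) - 1)),
                          -pi, pi, rel.tol = 1e-12)$value
  num / den
}
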