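test_that("kernel has the correct profile, support and normalization", {
  cl <- unit_cell(40, 40, 40)
  k <- build_kernel(c(40, 40, 40), cl, 12)
  v <- k$values
  expect_equal(which.max(v), 1)                 # peak at the origin voxel
  expect_equal(sum(v), 1, tolerance = 1e-12)
  # every point at r >= r0 is exactly zero; inside follows 1 - (r/r0)^2
  idx <- which(v >= 0, arr.ind = TRUE) - 1L
  df <- idx / 40
  df <- df - round(df)
  r <- sqrt(rowSums((df %*% t(cl$orth))^2))
  w_expected <- pmax(0, 1 - (r / 12)^2)
  expect_equal(as.vector(v) * sum(w_expected), w_expected, tolerance = 1e-9)
  expect_true(all(v[r >= 12] == 0))
  expect_error(build_kernel(c(8, 8, 8), cl, -1), "positive")
  expect_warning(build_kernel(c(20, 20, 20), unit_cell(20, 20, 20), 12),
                 "wraps")
})

test_that("kernel distances are minimum-image even in oblique cells", {
  cl <- unit_cell(25, 25, 25, 75, 100, 85)
  k <- build_kernel(c(20, 20, 20), cl, 10)
  v <- k$values
  # symmetry under inversion through the origin (w(r) even)
  inv <- v[c(1, 20:2), c(1, 20:2), c(1, 20:2)]
  expect_equal(v, inv, tolerance = 1e-12)
})

test_that("convolution satisfies delta and constant identities", {
  cl <- unit_cell(16, 16, 16)
  kern <- build_kernel(c(16, 16, 16), cl, 5)
  delta <- density_grid(cl, c(16, 16, 16))
  delta$values[1, 1, 1] <- 1
  expect_equal(convolve_map(delta, kern)$values, kern$values, tolerance = 1e-12)
  const <- density_grid(cl, c(16, 16, 16), array(3.7, c(16, 16, 16)))
  expect_equal(convolve_map(const, kern)$values, const$values, tolerance = 1e-10)
  expect_error(convolve_map(density_grid(cl, c(8, 8, 8)), kern), "differ")
})

test_that("FFT convolution matches brute-force circular convolution", {
  set.seed(21)
  cl <- unit_cell(16, 16, 16)
  a <- density_grid(cl, c(16, 16, 16), array(rnorm(16^3), c(16, 16, 16)))
  kern <- build_kernel(c(16, 16, 16), cl, 4)
  got <- convolve_map(a, kern)$values
  want <- oracle_circular_convolution(a$values, kern$values)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-8)
})

test_that("regression fields obey the zero and constant-predictor limits", {
  cl <- unit_cell(16, 16, 16)
  dm <- c(16, 16, 16)
  kern <- build_kernel(dm, cl, 5)
  zero <- density_grid(cl, dm)
  g <- list(u = density_grid(cl, dm, array(rnorm(prod(dm)), dm)))
  fz <- build_regression_fields(zero, g, FALSE, kern)
  expect_true(all(abs(fz$residual[[1]]) < 1e-14))
  # constant predictor with zero gradients: unit normal field, smoothed diff
  set.seed(2)
  dmap <- density_grid(cl, dm, array(rnorm(prod(dm)), dm))
  g0 <- list(u = density_grid(cl, dm))
  fc <- build_regression_fields(dmap, g0, TRUE, kern)
  expect_equal(fc$labels, c("u", "const"))
  expect_equal(fc$normal[["2.2"]], array(1, dm), tolerance = 1e-10)
  expect_equal(fc$residual[[2]], convolve_map(dmap, kern)$values,
               tolerance = 1e-12)
})

test_that("smoothed normal fields equal direct kernel-weighted sums", {
  set.seed(31)
  cl <- unit_cell(16, 16, 16)
  dm <- c(16, 16, 16)
  kern <- build_kernel(dm, cl, 5)
  gu <- array(rnorm(prod(dm)), dm)
  gv <- array(rnorm(prod(dm)), dm)
  dmap <- density_grid(cl, dm, array(rnorm(prod(dm)), dm))
  fields <- build_regression_fields(dmap,
    list(u = density_grid(cl, dm, gu), v = density_grid(cl, dm, gv)),
    FALSE, kern)
  for (pt in list(c(1, 1, 1), c(5, 9, 14), c(16, 2, 7))) {
    w <- kern$values[((seq_len(16) - pt[1]) %% 16) + 1,
                     ((seq_len(16) - pt[2]) %% 16) + 1,
                     ((seq_len(16) - pt[3]) %% 16) + 1]
    expect_equal(fields$normal[["1.2"]][pt[1], pt[2], pt[3]],
                 sum(w * gu * gv), tolerance = 1e-10)
    expect_equal(fields$residual[[1]][pt[1], pt[2], pt[3]],
                 sum(w * dmap$values * gu), tolerance = 1e-10)
  }
})

planted_fields <- function(n, dm = c(6, 6, 6), seed = 13) {
  set.seed(seed)
  nvox <- prod(dm)
  cl <- unit_cell(12, 12, 12)
  normal <- list()
  Ns <- array(0, c(nvox, n, n))
  for (v in 1:nvox) {
    A <- matrix(rnorm(n * n), n)
    Ns[v, , ] <- crossprod(A) + diag(n) * 0.1   # SPD
  }
  for (i in 1:n) for (j in i:n)
    normal[[paste(i, j, sep = ".")]] <- array(Ns[, i, j], dm)
  residual <- lapply(1:n, function(i) array(rnorm(nvox), dm))
  list(fields = structure(list(labels = letters[1:n], n = n,
                               residual = residual, normal = normal,
                               dim = dm, cell = cl),
                          class = "regression_fields"),
       Ns = Ns)
}

test_that("per-voxel solve matches a dense-solver oracle on planted SPD systems", {
  for (n in c(1, 2, 3, 4)) {
    pf <- planted_fields(n)
    sf <- solve_shift_field(pf$fields, ridge_fraction = 0)
    x <- matrix(sf$values, ncol = n)
    for (v in sample(prod(pf$fields$dim), 12)) {
      rv <- vapply(pf$fields$residual, function(r) as.vector(r)[v], numeric(1))
      expect_equal(x[v, ], as.vector(solve(pf$Ns[v, , , drop = TRUE] +
                                             diag(0, n), rv)),
                   tolerance = 1e-10)
    }
  }
})

test_that("degenerate voxels produce zero, finite shifts", {
  pf <- planted_fields(3)
  # flatten one voxel's normal matrix to ~zero
  for (nm in names(pf$fields$normal)) pf$fields$normal[[nm]][2, 2, 2] <- 1e-20
  for (i in 1:3) pf$fields$residual[[i]][2, 2, 2] <- 5
  sf <- solve_shift_field(pf$fields)
  expect_true(all(is.finite(sf$values)))
  expect_equal(as.vector(sf$values[2, 2, 2, ]), c(0, 0, 0))
  # all-zero residual gives an all-zero field
  pf0 <- planted_fields(3)
  for (i in 1:3) pf0$fields$residual[[i]][] <- 0
  expect_true(all(solve_shift_field(pf0$fields)$values == 0))
})

test_that("shift-field interpolation is exact on nodes and linear segments", {
  cl <- unit_cell(10, 10, 10)
  dm <- c(10, 10, 10)
  vals <- array(rnorm(prod(dm)), dm)
  sf <- structure(list(cell = cl, dim = dm, labels = "u",
                       values = array(vals, c(dm, 1))), class = "shift_field")
  expect_equal(unname(interpolate_shift(sf, c(0.3, 0.5, 0.7))[1, "u"]),
               vals[4, 6, 8])
  # linear ramp along u between nodes 2 and 3: exact at the midpoint
  ramp <- array(rep(seq_len(10), 100), dm)
  sfr <- structure(list(cell = cl, dim = dm, labels = "u",
                        values = array(ramp, c(dm, 1))), class = "shift_field")
  expect_equal(unname(interpolate_shift(sfr, c(0.15, 0.4, 0.6))[1, "u"]), 2.5)
})

test_that("interpolation matches an independently coded oracle", {
  set.seed(17)
  cl <- unit_cell(9, 11, 13)
  dm <- c(9, 10, 12)
  vals <- array(rnorm(prod(dm)), dm)
  sf <- structure(list(cell = cl, dim = dm, labels = "u",
                       values = array(vals, c(dm, 1))), class = "shift_field")
  pts <- matrix(runif(3000, -1, 2), ncol = 3)
  got <- interpolate_shift(sf, pts)[, 1]
  expect_lt(max(abs(got - oracle_trilinear(vals, pts))), 1e-12)
})

test_that("applying shifts updates, wraps and ignores the constant term", {
  f <- helix_p1()
  m <- f$truth
  dm <- c(8, 8, 8)
  zero_sf <- structure(list(cell = m$cell, dim = dm, labels = c("u", "v", "w"),
                            values = array(0, c(dm, 3))), class = "shift_field")
  expect_equal(apply_shifts(m, zero_sf)$model$atoms, m$atoms)
  uni <- zero_sf
  uni$values[, , , 1] <- 0.01
  shifted <- apply_shifts(m, uni)$model
  expect_equal(shifted$atoms$u, wrap_frac(m$atoms$u + 0.01), tolerance = 1e-12)
  expect_equal(shifted$atoms$v, m$atoms$v)
  # periodic wrap at the cell edge
  m2 <- m
  m2$atoms$u[1] <- 0.995
  expect_equal(apply_shifts(m2, uni)$model$atoms$u[1], 0.005, tolerance = 1e-12)
  # constant component never touches atoms
  wc <- structure(list(cell = m$cell, dim = dm,
                       labels = c("u", "v", "w", "const"),
                       values = array(c(rep(0, 3 * prod(dm)),
                                        rep(9, prod(dm))), c(dm, 4))),
                  class = "shift_field")
  expect_equal(apply_shifts(m, wc)$model$atoms, m$atoms)
})

test_that("one cycle on self-consistent data produces negligible shifts", {
  f <- helix_p1bar()
  cyc <- suppressWarnings(shift_field_cycle(f$truth, f$refl, 6, 24))
  expect_lt(cyc$stats$max_shift, 0.05)
  expect_lt(cyc$stats$r_work, 1e-6)
})

test_that("one cycle pulls a translated model back toward the truth", {
  f <- helix_p1bar()
  pert <- perturb_model(f$truth, "rigid_translation", 1.0,
                        direction = c(1, 1, 0))
  cyc <- suppressWarnings(shift_field_cycle(pert, f$refl, 6, 24))
  sh <- interpolate_shift(cyc$shift_field, model_frac(pert))
  mo <- colMeans(frac_to_orth(f$truth$cell, sh[, 1:3]))
  tv <- -c(1, 1, 0) / sqrt(2)
  # mean shift opposes the applied offset and is a substantial fraction of it
  cosang <- sum(mo * tv) / sqrt(sum(mo^2) * sum(tv^2))
  expect_gt(cosang, 0.5)
  expect_gt(sqrt(sum(mo^2)), 0.15)
  expect_lt(matched_rmsd(f$truth, cyc$model), matched_rmsd(f$truth, pert))
})

test_that("an empty truncated set aborts the cycle with a clear error", {
  f <- helix_p1bar()
  expect_error(suppressWarnings(shift_field_cycle(f$truth, f$refl, 100, 24)),
               "no data at this resolution")
})

test_that("with the constant predictor, a difference-map offset leaves coordinates unchanged", {
  f <- helix_p1()
  rs <- truncate_resolution(f$refl, 6)
  fc <- scale_fobs_fcalc(rs, calc_structure_factors(f$truth, rs))$fc
  grid <- choose_grid(f$truth$cell, 6)
  pert <- perturb_model(f$truth, "random_jitter", 0.5, seed = 6)
  dmap <- synthesize_map(
    list(hkl = fc$hkl,
         f = fc$f - calc_structure_factors(pert, rs)$f, cell = rs$cell),
    grid, cell = rs$cell)
  grads <- gradient_maps(calc_structure_factors(pert, rs), grid, "coords")
  kern <- suppressWarnings(build_kernel(grid, rs$cell, 15))
  base <- solve_shift_field(build_regression_fields(dmap, grads, TRUE, kern),
                            ridge_fraction = 0)
  dmap2 <- dmap
  dmap2$values <- dmap$values + 0.37 * max(abs(dmap$values))
  offs <- solve_shift_field(build_regression_fields(dmap2, grads, TRUE, kern),
                            ridge_fraction = 0)
  for (k in 1:3)
    expect_lt(max(abs(offs$values[, , , k] - base$values[, , , k])), 1e-8)
  # the constant component absorbs the offset
  expect_gt(mean(offs$values[, , , 4] - base$values[, , , 4]), 0)
})

test_that("growing kernels drive the shift field toward spatial uniformity", {
  f <- helix_p1bar()
  pert <- perturb_model(f$truth, "rigid_translation", 0.8,
                        direction = c(1, 0, 0))
  spreads <- vapply(c(8, 16, 60), function(r0) {
    cyc <- suppressWarnings(shift_field_cycle(pert, f$refl, 6, r0))
    max(vapply(1:3, function(k) diff(range(cyc$shift_field$values[, , , k])),
               numeric(1)))
  }, numeric(1))
  expect_lt(spreads[2], spreads[1])
  expect_lt(spreads[3], 0.25 * spreads[1])
})

test_that("normal-matrix diagonals stay nonnegative after smoothing", {
  f <- helix_p1()
  rs <- truncate_resolution(f$refl, 6)
  fc <- calc_structure_factors(f$truth, rs)
  grid <- choose_grid(f$truth$cell, 6)
  grads <- gradient_maps(fc, grid, "coords")
  kern <- build_kernel(grid, f$truth$cell, 8)
  dmap <- synthesize_map(fc, grid)
  fields <- build_regression_fields(dmap, grads, FALSE, kern)
  for (i in 1:3) {
    dg <- fields$normal[[paste(i, i, sep = ".")]]
    expect_gt(min(dg), -1e-10 * max(dg))
  }
})
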