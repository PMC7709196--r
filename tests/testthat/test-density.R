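test_that("grid choice honours spacing and FFT-efficiency rules", {
  cl <- unit_cell(30, 30, 30)
  g <- choose_grid(cl, 3)                       # default oversample 1.5
  expect_true(all(g$dim >= 30))                 # spacing <= 1 A at d = 3
  expect_true(all(30 / g$dim <= 1 + 1e-12))
  g2 <- choose_grid(cl, 1.5)
  expect_true(all(g2$dim >= 2 * g$dim - 2))     # halving d ~ doubles dims
  expect_equal(fft_friendly(17), 18)            # 2 * 3^2
  expect_equal(fft_friendly(30), 30)
  for (n in c(7, 11, 23, 97)) {
    m <- fft_friendly(n)
    expect_gte(m, n)
    r <- m; for (p in c(2, 3, 5)) while (r %% p == 0) r <- r / p
    expect_equal(r, 1)
  }
})

test_that("form factors are positive and decreasing for light elements", {
  s2 <- seq(0, 1 / 1.5^2, length.out = 50)      # to 1.5 A resolution
  for (el in c("H", "C", "N", "O", "S", "P")) {
    f <- scatter_factor(el, s2)
    expect_true(all(f > 0))
    expect_true(all(diff(f) < 0))
  }
  expect_error(scatter_factor("Xx", 0.1), "Xx")
})

make_point_model <- function(frac, b = 0, element = "C", cl = unit_cell(20, 20, 20)) {
  atomic_model(cl, symmetry_ops("P 1"),
               data.frame(element = element, u = frac[1], v = frac[2],
                          w = frac[3], occ = 1, b_iso = b, chain = "A",
                          resno = 1, resname = "ALA", atom_name = "CA"))
}

small_set <- function(cl, dmin = 3) {
  hmax <- ceiling(20 / dmin)
  g <- expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = 0:hmax)
  g <- g[g$l > 0 | (g$l == 0 & g$k > 0) | (g$l == 0 & g$k == 0 & g$h > 0), ]
  g <- g[d_spacing(cl, as.matrix(g)) >= dmin, ]
  reflection_set(cl, symmetry_ops("P 1"),
                 data.frame(g, fobs = 1, sigf = 0, free = FALSE))
}

test_that("structure factors of an atom at the origin are real and f-valued", {
  m <- make_point_model(c(0, 0, 0))
  rs <- small_set(m$cell)
  fc <- calc_structure_factors(m, rs)
  expect_lt(max(abs(Arg(fc$f))), 1e-12)
  expect_equal(Mod(fc$f), scatter_factor("C", fc$s2), tolerance = 1e-12)
})

test_that("an atom at (1/2,0,0) flips the phase of F(1,0,0)", {
  m <- make_point_model(c(0.5, 0, 0))
  rs <- small_set(m$cell)
  fc <- calc_structure_factors(m, rs)
  i100 <- which(rs$refl$h == 1 & rs$refl$k == 0 & rs$refl$l == 0)
  expect_equal(abs(Arg(fc$f[i100])), pi, tolerance = 1e-12)
})

test_that("translating a model multiplies F by the phase factor", {
  f <- helix_p1()
  rs <- truncate_resolution(f$refl, 4)
  fc <- calc_structure_factors(f$truth, rs)
  t <- c(0.017, -0.031, 0.009)
  m2 <- f$truth
  m2$atoms[, c("u", "v", "w")] <- wrap_frac(model_frac(f$truth) +
    matrix(t, n_atoms(f$truth), 3, byrow = TRUE))
  fc2 <- calc_structure_factors(m2, rs)
  pred <- fc$f * exp(2i * pi * as.vector(hkl_matrix(rs) %*% t))
  expect_lt(max(Mod(fc2$f - pred)) / max(Mod(fc$f)), 1e-10)
})

test_that("FFT structure-factor path agrees with direct summation", {
  set.seed(9)
  cl <- unit_cell(18, 22, 20)
  atoms <- data.frame(element = c("C", "N", "O", "C", "S"),
                      u = runif(5), v = runif(5), w = runif(5),
                      occ = 1, b_iso = c(15, 20, 25, 30, 18), chain = "A",
                      resno = 1:5, resname = "ALA", atom_name = "CA")
  m <- atomic_model(cl, symmetry_ops("P 1"), atoms)
  rs <- small_set(cl, 3)
  fd <- calc_structure_factors(m, rs, method = "direct")
  ff <- calc_structure_factors(m, rs, method = "fft")
  expect_lt(max(Mod(fd$f - ff$f)) / max(Mod(fd$f)), 1e-4)
})

test_that("bulk-solvent correction has the documented limits", {
  f <- helix_p1()
  rs <- truncate_resolution(f$refl, 5)
  fc <- calc_structure_factors(f$truth, rs)
  expect_equal(apply_bulk_solvent(fc, 0, 46)$f, fc$f)
  expect_true(all(Mod(apply_bulk_solvent(fc, 1, 0)$f) < 1e-12))
  att <- Mod(apply_bulk_solvent(fc, 0.35, 46)$f) / Mod(fc$f)
  expect_true(all(att > 0.64 & att < 1))        # 1 - k exp(..) in (0.65, 1)
  # the correction tends to unity at high scattering angle
  hi <- fc; hi$s2 <- c(0, 1); hi$f <- complex(real = c(1, 1))
  expect_gt(Mod(apply_bulk_solvent(hi, 0.35, 46)$f[2]), 0.9999)
  expect_equal(Mod(apply_bulk_solvent(hi, 0.35, 46)$f[1]), 0.65)
})

test_that("amplitude scaling recovers exact k and B", {
  f <- helix_p1()
  rs <- truncate_resolution(f$refl, 4)
  fc <- calc_structure_factors(f$truth, rs)
  r2 <- rs
  r2$refl$fobs <- 2 * Mod(fc$f)
  sc <- scale_fobs_fcalc(r2, fc)
  expect_equal(sc$k, 2, tolerance = 1e-9)
  expect_equal(sc$b_overall, 0, tolerance = 1e-7)
  r2$refl$fobs <- Mod(fc$f) * exp(-10 * fc$s2 / 4)
  sc <- scale_fobs_fcalc(r2, fc)
  expect_equal(sc$k, 1, tolerance = 1e-9)
  expect_equal(sc$b_overall, 10, tolerance = 1e-7)
  # noisy case: recovery within fit uncertainty
  set.seed(2)
  r2$refl$fobs <- 1.7 * Mod(fc$f) * exp(-6 * fc$s2 / 4) *
    exp(rnorm(nrow(r2$refl), sd = 0.05))
  sc <- scale_fobs_fcalc(r2, fc)
  expect_equal(sc$k, 1.7, tolerance = 0.05)
  expect_equal(sc$b_overall, 6, tolerance = 0.8)
})

test_that("map synthesis reproduces single-term Fourier series", {
  cl <- unit_cell(20, 20, 20)
  fc0 <- list(hkl = matrix(c(1, 0, 0), 1), f = complex(real = 0), cell = cl)
  expect_true(all(synthesize_map(fc0, c(8, 8, 8))$values == 0))
  fc1 <- list(hkl = matrix(c(1, 0, 0), 1), f = complex(real = 1), cell = cl)
  mp <- synthesize_map(fc1, c(16, 8, 8))
  expected <- 2 * cos(2 * pi * (0:15) / 16) / cl$volume
  expect_equal(mp$values[, 1, 1], expected, tolerance = 1e-12)
  expect_error(synthesize_map(fc1, c(2, 2, 2)), "Nyquist")
})

test_that("an isolated atom is a local density maximum in the synthesized map", {
  m <- make_point_model(c(0.337, 0.612, 0.148), b = 20)
  rs <- small_set(m$cell, 3)
  mp <- synthesize_map(calc_structure_factors(m, rs), choose_grid(m$cell, 3))
  ctr <- round(model_frac(m)[1, ] * mp$dim) %% mp$dim
  neigh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  vals <- apply(neigh, 1, function(s) {
    i <- (ctr + s) %% mp$dim
    mp$values[i[1] + 1, i[2] + 1, i[3] + 1]
  })
  expect_equal(which.max(vals), 14L)             # centre of the 27-neighbourhood
  expect_equal(max(vals), max(mp$values))        # and the global peak
})

test_that("Parseval consistency holds on a complete closed set", {
  cl <- unit_cell(12, 12, 12)
  m <- make_point_model(c(0.3, 0.6, 0.1), b = 30, cl = cl)
  hmax <- 2
  g <- expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = 0:hmax)
  g <- g[g$l > 0 | (g$l == 0 & g$k > 0) | (g$l == 0 & g$k == 0 & g$h > 0), ]
  rs <- reflection_set(cl, symmetry_ops("P 1"),
                       data.frame(g, fobs = 1, sigf = 0, free = FALSE))
  fc <- calc_structure_factors(m, rs)
  dim <- rep(2 * hmax + 2, 3)
  mp <- synthesize_map(fc, dim)
  # sum over full sphere (Friedel mates double every term; F000 omitted on
  # both sides since the map has zero mean)
  lhs <- 2 * sum(Mod(fc$f)^2)
  rhs <- cl$volume^2 * sum(mp$values^2) / prod(dim)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("gradient maps match finite-difference density derivatives", {
  f <- helix_p1()
  rs <- truncate_resolution(f$refl, 6)
  fc <- calc_structure_factors(f$truth, rs)
  grid <- choose_grid(f$truth$cell, 6)
  grads <- gradient_maps(fc, grid, "coords")
  du <- 1e-4
  for (k in 1:3) {
    m2 <- f$truth
    fr <- model_frac(m2); fr[, k] <- fr[, k] + du
    m2$atoms[, c("u", "v", "w")] <- wrap_frac(fr)
    fd <- (synthesize_map(calc_structure_factors(m2, rs), grid)$values -
             synthesize_map(fc, grid)$values) / du
    gk <- grads[[k]]$values
    expect_lt(max(abs(fd - gk)) / max(abs(gk)), 1e-3)
  }
  # biso gradient against finite difference in B
  gb <- gradient_maps(fc, grid, "biso")$biso$values
  db <- 1e-3
  m3 <- f$truth
  m3$atoms$b_iso <- m3$atoms$b_iso + db
  fdb <- (synthesize_map(calc_structure_factors(m3, rs), grid)$values -
            synthesize_map(fc, grid)$values) / db
  expect_lt(max(abs(fdb - gb)) / max(abs(gb)), 1e-3)
  expect_error(gradient_maps(fc, grid, "torsion"))
})

test_that("zero coefficients give zero gradient maps", {
  cl <- unit_cell(20, 20, 20)
  fc0 <- list(hkl = matrix(c(1, 0, 0), 1), f = complex(real = 0), cell = cl,
              s2 = 1 / 400)
  g <- gradient_maps(fc0, c(8, 8, 8), "coords")
  expect_true(all(vapply(g, function(x) all(x$values == 0), logical(1))))
})
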