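#' Regression-sphere smoothing kernel
#'
#' Builds the map of the kernel w(r) = 1 - (r/r0)^2 for r < r0 (else 0),
#' centred on the grid origin with periodic wrapping, where r is the
#' orthogonal distance computed under the minimum-image convention (exact
#' also for oblique cells, via a 27-image search). The kernel is normalized
#' to unit sum; the raw nonzero-point count is kept in the
#' `"nonzero_points"` attribute. Convolution with this kernel implements
#' exactly the distance weighting of the local regression: there is no
#' second weighting scheme.
#'
#' @param grid A `grid_spec` or integer dimensions.
#' @param cell A `unit_cell`.
#' @param r0 Regression-sphere radius in Angstroms (> grid spacing; a
#'   warning is issued when 2 r0 exceeds the shortest cell edge, where the
#'   sphere wraps onto itself).
#' @return A `density_grid` holding the normalized kernel.
#' @export
build_kernel <- function(grid, cell, r0) {
  if (r0 <= 0) stop("kernel radius r0 must be positive")
  dim <- if (inherits(grid, "grid_spec")) grid$dim else as.integer(grid)
  if (2 * r0 > min(cell$a, cell$b, cell$c))
    warning(sprintf("kernel radius %.1f A wraps onto itself (shortest cell edge %.1f A)",
                    r0, min(cell$a, cell$b, cell$c)))
  fu <- (seq_len(dim[1]) - 1) / dim[1]
  fv <- (seq_len(dim[2]) - 1) / dim[2]
  fw <- (seq_len(dim[3]) - 1) / dim[3]
  df <- cbind(rep(fu, times = dim[2] * dim[3]),
              rep(rep(fv, each = dim[1]), times = dim[3]),
              rep(fw, each = dim[1] * dim[2]))
  df <- df - round(df)                      # principal image
  r2 <- rowSums((df %*% t(cell$orth))^2)
  for (su in -1:1) for (sv in -1:1) for (sw in -1:1) {
    if (su == 0 && sv == 0 && sw == 0) next
    sh <- matrix(c(su, sv, sw), nrow(df), 3, byrow = TRUE)
    r2 <- pmin(r2, rowSums(((df + sh) %*% t(cell$orth))^2))
  }
  w <- pmax(0, 1 - r2 / r0^2)
  nz <- sum(w > 0)
  g <- density_grid(cell, dim, array(w / sum(w), dim))
  attr(g, "nonzero_points") <- nz
  g
}

#' Periodic (circular) convolution of two maps via FFT
#'
#' @param map,kernel `density_grid`s on the same grid.
#' @return A `density_grid` holding the circular convolution.
#' @export
convolve_map <- function(map, kernel) {
  if (!all(map$dim == kernel$dim))
    stop("map and kernel grids differ: ", paste(map$dim, collapse = "x"),
         " vs ", paste(kernel$dim, collapse = "x"))
  vals <- Re(stats::fft(stats::fft(map$values) * stats::fft(kernel$values),
                        inverse = TRUE)) / prod(map$dim)
  density_grid(map$cell, map$dim, vals)
}

#' Residual-vector and normal-matrix fields
#'
#' Forms the per-voxel weighted-least-squares system of the local
#' regression: the predictors are the gradient maps (plus, optionally, a
#' constant map), the residual fields are the smoothed products of the
#' difference map with each predictor, and the normal fields are the
#' smoothed pairwise predictor products. Products are taken pointwise
#' before smoothing, so the kernel convolution is the regression's
#' distance weighting.
#'
#' @param diff `density_grid` holding the difference map.
#' @param gradients Named list of gradient `density_grid`s (predictors).
#' @param include_const Add a constant predictor (absorbs a roughly
#'   constant offset between model density and observations).
#' @param kernel Unit-sum smoothing kernel from [build_kernel()].
#' @return Object of class `regression_fields`: `labels`, `n`, `residual`
#'   (list of arrays), `normal` (list of arrays keyed "i.j", i <= j), plus
#'   grid bookkeeping.
#' @export
build_regression_fields <- function(diff, gradients, include_const = FALSE,
                                    kernel) {
  preds <- lapply(gradients, function(g) g$values)
  labels <- names(gradients)
  if (include_const) {
    preds <- c(preds, list(array(1, diff$dim)))
    labels <- c(labels, "const")
  }
  n <- length(preds)
  kf <- stats::fft(kernel$values)
  smooth <- function(a)
    Re(stats::fft(stats::fft(a) * kf, inverse = TRUE)) / prod(diff$dim)
  residual <- lapply(preds, function(g) smooth(diff$values * g))
  normal <- list()
  for (i in seq_len(n)) for (j in i:n)
    normal[[paste(i, j, sep = ".")]] <- smooth(preds[[i]] * preds[[j]])
  structure(list(labels = labels, n = n, residual = residual, normal = normal,
                 dim = diff$dim, cell = diff$cell),
            class = "regression_fields")
}

#' Solve the per-voxel regression for the shift field
#'
#' At every grid point solves (N + lambda I) dx = r, where N is the local
#' normal matrix, r the local residual vector and
#' lambda = ridge_fraction * max(diag N) at that point. Points whose
#' diagonal maximum falls below `floor_fraction` of the global maximum
#' (flat solvent, empty regions) get a zero shift, making the solve total.
#'
#' @param fields A `regression_fields` object.
#' @param ridge_fraction Relative ridge (default 1e-6; bias negligible).
#' @param floor_fraction Absolute-floor fraction of the global diagonal
#'   maximum below which the voxel is zeroed (default 1e-12).
#' @return Object of class `shift_field`: 4-D array `values`
#'   (nu x nv x nw x n) plus `labels`, finite everywhere.
#' @export
solve_shift_field <- function(fields, ridge_fraction = 1e-6,
                              floor_fraction = 1e-12) {
  n <- fields$n
  dm <- fields$dim
  nvox <- prod(dm)
  N <- function(i, j) as.vector(fields$normal[[paste(min(i, j), max(i, j), sep = ".")]])
  r <- lapply(fields$residual, as.vector)
  dmax <- N(1, 1)
  if (n > 1) for (i in 2:n) dmax <- pmax(dmax, N(i, i))
  gmax <- max(dmax)
  active <- gmax > 0 & dmax >= floor_fraction * max(gmax, 0)
  lam <- ridge_fraction * dmax
  x <- matrix(0, nvox, n)
  if (any(active)) {
    if (n == 1) {
      x[active, 1] <- r[[1]][active] / (N(1, 1)[active] + lam[active])
    } else if (n == 2) {
      A <- N(1, 1) + lam; B <- N(1, 2); D <- N(2, 2) + lam
      det <- A * D - B^2
      ok <- active & is.finite(det) & det > 0
      x[ok, 1] <- (D[ok] * r[[1]][ok] - B[ok] * r[[2]][ok]) / det[ok]
      x[ok, 2] <- (A[ok] * r[[2]][ok] - B[ok] * r[[1]][ok]) / det[ok]
    } else if (n == 3) {
      A <- N(1, 1) + lam; B <- N(1, 2); C <- N(1, 3)
      D <- N(2, 2) + lam; E <- N(2, 3); G <- N(3, 3) + lam
      a11 <- D * G - E^2;  a12 <- C * E - B * G;  a13 <- B * E - C * D
      a22 <- A * G - C^2;  a23 <- B * C - A * E;  a33 <- A * D - B^2
      det <- A * a11 + B * a12 + C * a13
      ok <- active & is.finite(det) & det > 0
      x[ok, 1] <- (a11[ok] * r[[1]][ok] + a12[ok] * r[[2]][ok] + a13[ok] * r[[3]][ok]) / det[ok]
      x[ok, 2] <- (a12[ok] * r[[1]][ok] + a22[ok] * r[[2]][ok] + a23[ok] * r[[3]][ok]) / det[ok]
      x[ok, 3] <- (a13[ok] * r[[1]][ok] + a23[ok] * r[[2]][ok] + a33[ok] * r[[3]][ok]) / det[ok]
    } else {
      Nm <- matrix(0, n, n)
      rv <- numeric(n)
      for (v in which(active)) {
        for (i in 1:n) for (j in i:n) {
          Nm[i, j] <- Nm[j, i] <- N(i, j)[v]
        }
        diag(Nm) <- diag(Nm) + lam[v]
        rv[] <- vapply(r, `[`, numeric(1), v)
        sol <- tryCatch(solve(Nm, rv), error = function(e) rep(0, n))
        x[v, ] <- sol
      }
    }
  }
  x[!is.finite(x)] <- 0
  structure(list(cell = fields$cell, dim = dm, labels = fields$labels,
                 values = array(x, c(dm, n))),
            class = "shift_field")
}

#' Interpolate the shift field at fractional positions
#'
#' Trilinear interpolation of each shift component, periodic in all axes.
#'
#' @param sf A `shift_field`.
#' @param frac Matrix (n x 3) or length-3 vector of fractional coordinates.
#' @return Matrix (n_points x n_components), columns named by `sf$labels`.
#' @export
interpolate_shift <- function(sf, frac) {
  frac <- rbind2mat(frac)
  out <- matrix(0, nrow(frac), length(sf$labels),
                dimnames = list(NULL, sf$labels))
  for (p in seq_along(sf$labels)) {
    comp <- array(sf$values[, , , p], sf$dim)
    out[, p] <- interp_array(comp, sf$dim, frac)
  }
  out
}

#' Apply an interpolated shift field to a model
#'
#' Coordinate components (u, v, w; fractional) are added to the atomic
#' fractional coordinates (wrapped); a `biso` component is added to the
#' atomic B factors with a floor `b_min`. A `const` component is never
#' applied to atoms.
#'
#' @param model An `atomic_model`.
#' @param sf A `shift_field`.
#' @param scale Multiplier on the shifts (default 1: full shifts).
#' @param b_min Floor for B factors in biso mode (Angstrom^2).
#' @param center_axes Logical 3-vector: subtract the mean coordinate shift
#'   along these (polar) axes before applying, pinning the floating origin
#'   (see [polar_axes()]). Default: no centering.
#' @return List with `model` (the updated `atomic_model`) and `shift_orth`
#'   (matrix of applied orthogonal coordinate shifts in Angstroms, zero
#'   rows when no coordinate components are present).
#' @export
apply_shifts <- function(model, sf, scale = 1, b_min = 1,
                         center_axes = c(FALSE, FALSE, FALSE)) {
  shifts <- interpolate_shift(sf, model_frac(model)) * scale
  at <- model$atoms
  dorth <- matrix(0, nrow(at), 3)
  if (all(c("u", "v", "w") %in% sf$labels)) {
    dfrac <- shifts[, c("u", "v", "w"), drop = FALSE]
    for (k in which(center_axes)) dfrac[, k] <- dfrac[, k] - mean(dfrac[, k])
    at[, c("u", "v", "w")] <- wrap_frac(as.matrix(at[, c("u", "v", "w")]) + dfrac)
    dorth <- frac_to_orth(model$cell, dfrac) - frac_to_orth(model$cell, 0 * dfrac)
  }
  if ("biso" %in% sf$labels)
    at$b_iso <- pmax(b_min, at$b_iso + shifts[, "biso"])
  list(model = atomic_model(model$cell, model$sym, at), shift_orth = dorth)
}

#' One cycle of shift-field refinement
#'
#' Executes the full per-cycle pipeline at one resolution: truncate the data,
#' compute scaled calculated structure factors (optional bulk solvent),
#' estimate sigma-A and build likelihood-weighted difference coefficients,
#' synthesize the difference and gradient maps, form and smooth the
#' regression fields, solve for the shift field, and apply the interpolated
#' shifts to the atoms.
#'
#' @param model An `atomic_model`.
#' @param refl A `reflection_set` (full data; truncated internally).
#' @param d_cycle Working resolution for this cycle (Angstroms).
#' @param r0 Regression-sphere radius (Angstroms).
#' @param options List of options as produced by [refinement_config()];
#'   missing entries take the defaults.
#' @return List with `model` (updated) and `stats` (one-row data.frame:
#'   d, r0, n_refl, r_work, r_free, mean and max orthogonal shift in
#'   Angstroms).
#' @export
shift_field_cycle <- function(model, refl, d_cycle, r0,
                              options = refinement_config()) {
  o <- utils::modifyList(refinement_config(), options)
  rs <- suppressWarnings(truncate_resolution(refl, d_cycle))
  if (!nrow(rs$refl)) stop("no data at this resolution (d >= ", d_cycle, " A)")
  fc <- calc_structure_factors(model, rs, hydrogens = o$hydrogens)
  if (o$solvent) fc <- apply_bulk_solvent(fc, o$k_sol, o$b_sol)
  sc <- scale_fobs_fcalc(rs, fc)
  fc <- sc$fc
  rf <- r_factors(rs, fc)
  nb <- max(2L, min(o$nbins, nrow(rs$refl) %/% 20L))
  bins <- resolution_bins(rs$refl$d, nb)
  cen <- is_centric(rs$sym, hkl_matrix(rs))
  no <- normalize_amplitudes(rs$refl$fobs, bins)
  nc <- normalize_amplitudes(Mod(fc$f), bins)
  sam <- estimate_sigma_a(no$e, nc$e, rs$refl$free, bins, centric = cen)
  fom <- figures_of_merit(sam, no$e, nc$e, no$mean_f2, nc$mean_f2, centric = cen)
  dco <- difference_coefficients(rs, fc, fom$m, fom$d_lk,
                                 exclude_free = o$exclude_free)
  grid <- choose_grid(model$cell, d_cycle, o$oversample)
  dmap <- synthesize_map(dco, grid, cell = model$cell)
  grads <- gradient_maps(fc, grid, mode = o$mode)
  kern <- suppressWarnings(build_kernel(grid, model$cell, r0))
  fields <- build_regression_fields(dmap, grads, o$include_const, kern)
  sf <- solve_shift_field(fields, o$ridge_fraction, o$floor_fraction)
  ctr <- if (isTRUE(o$fix_origin)) polar_axes(model$sym) else c(FALSE, FALSE, FALSE)
  appl <- apply_shifts(model, sf, scale = o$shift_scale, b_min = o$b_min,
                       center_axes = ctr)
  smag <- sqrt(rowSums(appl$shift_orth^2))
  stats <- data.frame(d = d_cycle, r0 = r0, n_refl = nrow(rs$refl),
                      r_work = rf$r_work, r_free = rf$r_free,
                      mean_shift = if (length(smag)) mean(smag) else 0,
                      max_shift = if (length(smag)) max(smag) else 0)
  list(model = appl$model, stats = stats, shift_field = sf,
       sigma_a = sam$sigma_a)
}
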