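#' Calculated structure factors
#'
#' Computes complex F_calc(h) for every reflection in `refl` from the model,
#' F(h) = sum_atoms f(s) occ exp(-B s^2/4) exp(2 pi i h.x), summed over
#' symmetry copies. Two paths exist: direct summation (the reference path,
#' used up to `direct_limit` atom-symmetry copies) and density sampling on a
#' fine grid followed by a forward FFT. The FFT path adds an anti-aliasing
#' B to every atom before sampling and removes it again in reciprocal space,
#' so sharp atoms do not alias at the sampling rate.
#'
#' @param model An `atomic_model`.
#' @param refl A `reflection_set` sharing the model's cell.
#' @param method "auto" (direct below `direct_limit`, FFT above), "direct" or
#'   "fft".
#' @param hydrogens Include hydrogen atoms (default FALSE).
#' @param direct_limit Atom-copy count above which "auto" switches to FFT.
#' @return Object of class `structure_factors`: list with `hkl`, complex `f`,
#'   `d`, the cell, and the applied overall `scale` (k, b).
#' @export
calc_structure_factors <- function(model, refl, method = c("auto", "direct", "fft"),
                                   hydrogens = FALSE, direct_limit = 2000L) {
  method <- match.arg(method)
  stopifnot(inherits(model, "atomic_model"), inherits(refl, "reflection_set"))
  at <- model$atoms
  if (!hydrogens) at <- at[at$element != "H", , drop = FALSE]
  at <- at[at$occ > 0, , drop = FALSE]
  if (!nrow(at)) stop("no scattering atoms in model")
  hkl <- hkl_matrix(refl)
  s2 <- inv_d2(model$cell, hkl)
  frac <- expand_sym_frac(model$sym, as.matrix(at[, c("u", "v", "w")]))
  nops <- n_sym_ops(model$sym)
  occ <- rep(at$occ, nops)
  b <- rep(at$b_iso, nops)
  elem <- rep(at$element, nops)
  if (method == "auto")
    method <- if (length(occ) <= direct_limit) "direct" else "fft"
  f <- if (method == "direct") {
    sf_direct(hkl, s2, frac, elem, occ, b)
  } else {
    sf_fft(model$cell, hkl, s2, frac, elem, occ, b, d = min(refl$refl$d))
  }
  structure(list(hkl = hkl, f = f, d = refl$refl$d, s2 = s2,
                 cell = model$cell, scale = list(k = 1, b = 0)),
            class = "structure_factors")
}

sf_direct <- function(hkl, s2, frac, elem, occ, b, chunk = 512L) {
  n_h <- nrow(hkl)
  wt <- matrix(0, n_h, length(occ))         # f(s) occ exp(-B s^2/4)
  for (el in unique(elem)) {
    sel <- elem == el
    wt[, sel] <- scatter_factor(el, s2) * exp(outer(-s2 / 4, b[sel])) *
      matrix(occ[sel], n_h, sum(sel), byrow = TRUE)
  }
  f <- complex(n_h)
  for (a0 in seq(1, length(occ), by = chunk)) {
    a1 <- min(a0 + chunk - 1L, length(occ))
    ph <- exp(2i * pi * tcrossprod(hkl, frac[a0:a1, , drop = FALSE]))
    f <- f + rowSums(wt[, a0:a1, drop = FALSE] * ph)
  }
  f
}

sf_fft <- function(cell, hkl, s2, frac, elem, occ, b, d, tol = 1e-8) {
  # anti-alias sharpening: ensure every Gaussian term is wide enough for the
  # sampling rate (spacing ~ d/6), then deconvolve the extra B afterwards
  b_extra <- max(0, 0.5 * d^2 + 2 - min(b))
  spacing <- d / 6
  dims <- vapply(c(cell$a, cell$b, cell$c),
                 function(e) fft_friendly(e / spacing), integer(1))
  rho <- array(0, dims)
  fracsamp <- list(seq_len(dims[1]) - 1, seq_len(dims[2]) - 1, seq_len(dims[3]) - 1)
  for (a in seq_along(occ)) {
    ff <- FORM_FACTORS[[elem[a]]]
    bt <- c(ff$b, 0) + b[a] + b_extra
    at_ <- c(ff$a, ff$c)
    rmax <- sqrt(max(bt * log(pmax(abs(at_), 1e-6) / tol)) / (4 * pi^2))
    # local box of grid points within rmax of the atom
    ext <- ceiling(rmax / c(cell$a, cell$b, cell$c) * dims) + 1L
    ctr <- frac[a, ] * dims
    iu <- (round(ctr[1]) - ext[1]):(round(ctr[1]) + ext[1])
    iv <- (round(ctr[2]) - ext[2]):(round(ctr[2]) + ext[2])
    iw <- (round(ctr[3]) - ext[3]):(round(ctr[3]) + ext[3])
    dd <- expand.grid(u = iu, v = iv, w = iw)
    df <- cbind(dd$u / dims[1] - frac[a, 1],
                dd$v / dims[2] - frac[a, 2],
                dd$w / dims[3] - frac[a, 3])
    r2 <- rowSums((df %*% t(cell$orth))^2)
    val <- numeric(nrow(df))
    for (g in seq_along(at_)) {
      val <- val + at_[g] * (4 * pi / bt[g])^1.5 * exp(-4 * pi^2 * r2 / bt[g])
    }
    idx <- 1L + (dd$u %% dims[1]) + dims[1] * ((dd$v %% dims[2]) +
                                                 dims[2] * (dd$w %% dims[3]))
    add <- occ[a] * val
    # accumulate (indices may repeat when the box wraps)
    tt <- rowsum(add, idx)
    rho[as.integer(rownames(tt))] <- rho[as.integer(rownames(tt))] + tt[, 1]
  }
  g <- density_grid(cell, dims, rho)
  sf_from_grid(g, hkl) * exp(b_extra * s2 / 4)
}

#' Babinet-style bulk-solvent correction
#'
#' Attenuates low-resolution structure factors per the Babinet principle:
#' F <- F (1 - k_sol exp(-b_sol s^2/4)). With k_sol = 0 this is the identity.
#'
#' @param fc A `structure_factors` object.
#' @param k_sol Solvent scale (>= 0; default 0.35 when enabled).
#' @param b_sol Solvent smearing B (Angstrom^2, >= 0; default 46).
#' @return The corrected `structure_factors`.
#' @export
apply_bulk_solvent <- function(fc, k_sol = 0.35, b_sol = 46) {
  stopifnot(k_sol >= 0, b_sol >= 0)
  fc$f <- fc$f * (1 - k_sol * exp(-b_sol * fc$s2 / 4))
  fc
}

#' Overall scaling of calculated to observed amplitudes
#'
#' Least-squares fit of log(|Fo|/|Fc|) against s^2/4 over the work set gives
#' the overall scale k and overall B; the scaled amplitudes are
#' |Fc| <- k exp(-B s^2/4) |Fc|. The fit puts observed and calculated
#' amplitudes on one scale so that difference coefficients are meaningful;
#' atomic B values are untouched.
#'
#' @param refl A `reflection_set` (work reflections are used for the fit).
#' @param fc The matching `structure_factors`.
#' @return List with `k`, `b_overall` and `fc` (the scaled structure factors,
#'   with the applied scale recorded in `fc$scale`).
#' @export
scale_fobs_fcalc <- function(refl, fc) {
  fo <- refl$refl$fobs
  fca <- Mod(fc$f)
  if (all(fca == 0)) stop("all calculated amplitudes are zero; cannot scale")
  use <- !refl$refl$free & is.finite(fo) & fo > 0 & fca > 0
  if (sum(use) < 6) use <- is.finite(fo) & fo > 0 & fca > 0
  if (sum(use) < 6) stop("too few usable reflections for scaling")
  x <- fc$s2[use] / 4
  y <- log(fo[use] / fca[use])
  fit <- stats::lm.fit(cbind(1, x), y)
  k <- exp(fit$coefficients[[1]])
  b_overall <- -fit$coefficients[[2]]
  fc$f <- fc$f * k * exp(-b_overall * fc$s2 / 4)
  fc$scale <- list(k = k, b = b_overall)
  list(k = k, b_overall = b_overall, fc = fc)
}

#' Electron-density synthesis from structure factors
#'
#' Real inverse Fourier synthesis with Friedel completion:
#' rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x).
#'
#' @param fc A `structure_factors` object (or list with `hkl`, complex `f`).
#' @param grid A `grid_spec` or integer dimensions; must be Nyquist-adequate
#'   for the reflections present (error otherwise).
#' @param cell Cell override (default the cell stored in `fc`).
#' @return A `density_grid`.
#' @export
synthesize_map <- function(fc, grid, cell = fc$cell) {
  dim <- if (inherits(grid, "grid_spec")) grid$dim else as.integer(grid)
  synth_real(cell, fc$hkl, fc$f, dim)
}

#' Gradient maps of the calculated density (Lifchitz formulation)
#'
#' For `mode = "coords"`, returns three maps g_u, g_v, g_w: the density
#' change per unit positive shift of the model along each fractional axis,
#' synthesized from coefficients (2 pi i h_k) F(h). (Equivalently
#' g_k = -d(rho)/d(u_k) of the static map: translating the model by +delta
#' changes rho by ~ sum_k g_k delta_k.) For `mode = "biso"`, one map from
#' coefficients (-s^2/4) F(h), the density change per unit B increase.
#'
#' @param fc A `structure_factors` object.
#' @param grid A `grid_spec` or integer dimensions.
#' @param mode "coords" or "biso".
#' @return List of `density_grid`s (named u, v, w or biso).
#' @export
gradient_maps <- function(fc, grid, mode = c("coords", "biso")) {
  mode <- match.arg(mode)
  dim <- if (inherits(grid, "grid_spec")) grid$dim else as.integer(grid)
  if (mode == "coords") {
    out <- lapply(1:3, function(k)
      synth_real(fc$cell, fc$hkl, 2i * pi * fc$hkl[, k] * fc$f, dim))
    names(out) <- c("u", "v", "w")
  } else {
    out <- list(biso = synth_real(fc$cell, fc$hkl, -fc$s2 / 4 * fc$f, dim))
  }
  out
}
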