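#' Equal-population resolution binning
#'
#' Partitions reflections into bins of (near-)equal population ordered by
#' 1/d^2, the standard binning for sigma-A estimation and scaling.
#'
#' @param d Numeric vector of d-spacings (Angstroms).
#' @param nbins Number of bins (default 12; reduced only by the caller).
#' @return Object of class `resolution_bins`: list with `nbins`, integer
#'   `bin` per reflection, per-bin `mean_invd2` and `counts`.
#' @export
resolution_bins <- function(d, nbins = 12) {
  n <- length(d)
  stopifnot(n > 0, nbins >= 1)
  invd2 <- 1 / d^2
  r <- rank(invd2, ties.method = "first")
  bin <- as.integer(ceiling(r / n * nbins))
  structure(list(nbins = nbins, bin = bin,
                 mean_invd2 = as.numeric(tapply(invd2, bin, mean)),
                 counts = as.integer(table(factor(bin, levels = 1:nbins)))),
            class = "resolution_bins")
}

#' Normalized structure-factor amplitudes E
#'
#' E^2 = F^2 / <F^2>_bin computed per resolution bin, separately for any
#' amplitude set, so that <E^2> = 1 in every bin.
#'
#' @param f Numeric vector of amplitudes (NA allowed, propagated).
#' @param bins A `resolution_bins` object over the same reflections.
#' @return List with `e` (normalized amplitudes) and `mean_f2` per bin.
#' @export
normalize_amplitudes <- function(f, bins) {
  stopifnot(length(f) == length(bins$bin))
  if (any(bins$counts < 3))
    stop("resolution bin with fewer than 3 reflections; use fewer bins")
  mean_f2 <- as.numeric(tapply(f^2, bins$bin, mean, na.rm = TRUE))
  if (any(!is.finite(mean_f2)) || any(mean_f2 <= 0))
    stop("empty or zero-power resolution bin; use fewer bins")
  list(e = f / sqrt(mean_f2[bins$bin]), mean_f2 = mean_f2)
}

# per-reflection log-likelihood of Eo given sigma_a * Ec:
# acentric Rice; centric folded-normal (cosh) variant
loglik_sigma_a <- function(sa, eo, ec, centric) {
  v <- 1 - sa^2
  x <- 2 * sa * eo * ec / v
  ll <- numeric(length(eo))
  a <- !centric
  if (any(a)) {
    xa <- x[a]
    ll[a] <- log(2 * eo[a] / v) - (eo[a]^2 + sa^2 * ec[a]^2) / v +
      log(besselI(xa, 0, expon.scaled = TRUE)) + xa
  }
  if (any(centric)) {
    xc <- x[centric] / 2
    ll[centric] <- 0.5 * log(2 / (pi * v)) -
      (eo[centric]^2 + sa^2 * ec[centric]^2) / (2 * v) +
      log(cosh(xc) * exp(-abs(xc))) + abs(xc)
  }
  sum(ll)
}

#' Estimate sigma-A per resolution bin
#'
#' Maximizes the Rice log-likelihood of the observed normalized amplitudes
#' given sigma_A times the calculated ones, by 1-D numeric search on
#' \[0.01, 0.99\] per bin. By default only free reflections enter the
#' estimate (so the weights are not biased by the refinement target); bins
#' with too few free reflections fall back to all reflections with a
#' warning.
#'
#' @param eo,ec Normalized observed/calculated amplitudes (same length).
#' @param free Logical vector marking free reflections.
#' @param bins A `resolution_bins` object.
#' @param centric Logical vector (default all acentric).
#' @param min_free Minimum free count per bin below which the estimate falls back to all reflections in that bin (default 20: a handful of free amplitudes gives clamp-to-clamp noise in sigma-A, which is worse than the small bias of using the work set).
#' @return Object of class `sigmaa_model`: list with `bins`, `sigma_a` per
#'   bin, per-bin `sum_eo2`/`sum_ec2` normalizers, and the used selection.
#' @export
estimate_sigma_a <- function(eo, ec, free, bins, centric = NULL, min_free = 20L) {
  n <- length(eo)
  stopifnot(length(ec) == n, length(bins$bin) == n)
  if (bins$nbins < 2) stop("sigma-A estimation needs at least 2 resolution bins")
  if (is.null(centric)) centric <- rep(FALSE, n)
  free <- as.logical(free)
  ok <- is.finite(eo) & is.finite(ec)
  sigma_a <- numeric(bins$nbins)
  fellback <- FALSE
  for (bnum in seq_len(bins$nbins)) {
    inb <- bins$bin == bnum & ok
    sel <- inb & free
    if (sum(sel) < min_free) {
      sel <- inb
      fellback <- TRUE
    }
    if (sum(sel) < 2) stop("resolution bin ", bnum, " has fewer than 2 usable reflections")
    opt <- stats::optimize(loglik_sigma_a, c(0.01, 0.99), maximum = TRUE,
                           eo = eo[sel], ec = ec[sel], centric = centric[sel])
    sigma_a[bnum] <- opt$maximum
  }
  if (fellback)
    warning("bin(s) with fewer than ", min_free,
            " free reflections: sigma-A estimated from all reflections there")
  # optimize() never quite reaches the interval ends; snap to the clamps
  sigma_a <- pmin(pmax(sigma_a, 0.01), 0.99)
  sigma_a[sigma_a > 0.9897] <- 0.99
  sigma_a[sigma_a < 0.0103] <- 0.01
  structure(list(bins = bins, sigma_a = sigma_a,
                 sum_eo2 = as.numeric(tapply(eo^2, bins$bin, sum, na.rm = TRUE)),
                 sum_ec2 = as.numeric(tapply(ec^2, bins$bin, sum, na.rm = TRUE))),
            class = "sigmaa_model")
}

#' Figures of merit m and amplitude scale D
#'
#' For acentric reflections X = 2 sigma_A Eo Ec / (1 - sigma_A^2) and
#' m = I1(X)/I0(X); centric reflections use m = tanh(X/2). The amplitude
#' scale D_lk = sigma_A sqrt(<Fo^2>_bin / <Fc^2>_bin) converts the weighted
#' calculated amplitude to the observed scale.
#'
#' @param sam A `sigmaa_model`.
#' @param eo,ec Normalized amplitudes (as used for the estimate).
#' @param mean_fo2,mean_fc2 Per-bin mean squared raw amplitudes (from
#'   [normalize_amplitudes()]).
#' @param centric Logical vector (default all acentric).
#' @return List with per-reflection `m` (in \[0,1\]), `d_lk` (>= 0) and `x`.
#' @export
figures_of_merit <- function(sam, eo, ec, mean_fo2, mean_fc2, centric = NULL) {
  bin <- sam$bins$bin
  if (is.null(centric)) centric <- rep(FALSE, length(eo))
  sa <- sam$sigma_a[bin]
  x <- 2 * sa * eo * ec / (1 - sa^2)
  m <- ifelse(centric, tanh(x / 2),
              besselI(x, 1, expon.scaled = TRUE) /
                besselI(x, 0, expon.scaled = TRUE))
  m[!is.finite(m)] <- 0
  d_lk <- sa * sqrt(mean_fo2[bin] / mean_fc2[bin])
  list(m = m, d_lk = d_lk, x = x)
}

#' Likelihood-weighted difference-map coefficients
#'
#' coefficient = (m |Fo| - D |Fc|) exp(i phi_calc); reflections with missing
#' |Fo| get coefficient zero, and free reflections are excluded (zeroed) by
#' default so the difference map never sees the cross-validation set.
#'
#' @param refl A `reflection_set`.
#' @param fc The matching (scaled) `structure_factors`.
#' @param m,d_lk Per-reflection figure of merit and amplitude scale.
#' @param exclude_free Zero the coefficients of free reflections (default
#'   TRUE).
#' @return List with `hkl` and complex `coeff`, synthesizable by
#'   [synthesize_map()].
#' @export
difference_coefficients <- function(refl, fc, m, d_lk, exclude_free = TRUE) {
  fo <- refl$refl$fobs
  amp <- m * fo - d_lk * Mod(fc$f)
  amp[!is.finite(fo)] <- 0
  if (exclude_free) amp[refl$refl$free] <- 0
  phase <- Arg(fc$f)
  phase[Mod(fc$f) == 0] <- 0
  list(hkl = fc$hkl, f = amp * exp(1i * phase), cell = fc$cell)
}

#' Crystallographic R factors
#'
#' R = sum | |Fo| - |Fc| | / sum |Fo| over the work and free partitions
#' separately, on the amplitudes as given (scale first).
#'
#' @param refl A `reflection_set`.
#' @param fc The matching scaled `structure_factors`.
#' @return List with `r_work` and `r_free` (NA when the free set is empty —
#'   undefined, never reported as 0).
#' @export
r_factors <- function(refl, fc) {
  fo <- refl$refl$fobs
  fca <- Mod(fc$f)
  ok <- is.finite(fo)
  free <- refl$refl$free & ok
  work <- !refl$refl$free & ok
  rpart <- function(sel) {
    if (!any(sel) || sum(fo[sel]) == 0) return(NA_real_)
    sum(abs(fo[sel] - fca[sel])) / sum(fo[sel])
  }
  list(r_work = rpart(work), r_free = rpart(free))
}
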