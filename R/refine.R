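#' Cycle schedule: resolution ramp and regression radius
#'
#' The working resolution decreases linearly in d with cycle number from
#' `d_start` to `d_end` inclusive (single-cycle schedules run at `d_end`),
#' and the regression-sphere radius is `radius_factor` times the current
#' resolution. Defaults: 12 cycles, 6 to 3 Angstroms, radius factor 4 —
#' so the first cycle runs at d = 6 with r0 = 24 and the last at d = 3
#' with r0 = 12.
#'
#' @param n_cycles Number of cycles (>= 1, default 12).
#' @param d_start,d_end Starting/final resolution in Angstroms
#'   (d_start >= d_end > 0).
#' @param radius_factor Ratio r0 / d (default 4).
#' @return data.frame of class `cycle_schedule` with columns `cycle`, `d`,
#'   `r0`.
#' @export
make_schedule <- function(n_cycles = 12, d_start = 6, d_end = 3,
                          radius_factor = 4) {
  stopifnot(n_cycles >= 1, d_end > 0)
  if (d_end > d_start) stop("d_end must not exceed d_start")
  d <- if (n_cycles == 1) d_end else
    d_start + (d_end - d_start) * (seq_len(n_cycles) - 1) / (n_cycles - 1)
  out <- data.frame(cycle = seq_len(n_cycles), d = d, r0 = radius_factor * d)
  class(out) <- c("cycle_schedule", "data.frame")
  out
}

#' Refinement configuration
#'
#' Collects every tunable of the refinement with its default. Any subset may
#' be overridden; [run_refinement()] and [shift_field_cycle()] merge the
#' given values over these defaults.
#'
#' @param n_cycles,d_start,d_end,radius_factor Schedule parameters, see
#'   [make_schedule()].
#' @param mode "coords" (refine fractional coordinates) or "biso" (refine
#'   isotropic B factors).
#' @param include_const Include the constant regression term (default FALSE:
#'   it offers no significant benefit and costs extra transforms).
#' @param ridge_fraction,floor_fraction Regularization of the per-voxel
#'   solve, see [solve_shift_field()].
#' @param shift_scale Multiplier on applied shifts (default 1: full shifts).
#' @param solvent,k_sol,b_sol Babinet bulk-solvent correction (default off;
#'   k_sol 0.35, b_sol 46 when on).
#' @param hydrogens Include hydrogens in the structure-factor sums.
#' @param oversample Map oversampling rate (default 1.5, i.e. ~d/3 spacing).
#' @param nbins Resolution bins for sigma-A (default 12, reduced for small
#'   sets).
#' @param exclude_free Exclude free reflections from the difference map
#'   (default TRUE).
#' @param fix_origin Subtract the mean coordinate shift along polar axes
#'   each cycle (default TRUE): amplitudes carry no origin information
#'   along those axes, so without this the model drifts on a flat
#'   likelihood direction.
#' @param b_min B-factor floor in biso mode (Angstrom^2).
#' @param early_stop_shift Stop when the max shift falls below this value in
#'   Angstroms (default 0: disabled; convergence is cycle-count based).
#' @return A named list of class `refinement_config`.
#' @export
refinement_config <- function(n_cycles = 12, d_start = 6, d_end = 3,
                              radius_factor = 4,
                              mode = "coords", include_const = FALSE,
                              ridge_fraction = 1e-6, floor_fraction = 1e-12,
                              shift_scale = 1,
                              solvent = FALSE, k_sol = 0.35, b_sol = 46,
                              hydrogens = FALSE, oversample = 1.5,
                              nbins = 12, exclude_free = TRUE, b_min = 1,
                              fix_origin = TRUE, early_stop_shift = 0) {
  structure(list(n_cycles = n_cycles, d_start = d_start, d_end = d_end,
                 radius_factor = radius_factor, mode = mode,
                 include_const = include_const,
                 ridge_fraction = ridge_fraction,
                 floor_fraction = floor_fraction, shift_scale = shift_scale,
                 solvent = solvent, k_sol = k_sol, b_sol = b_sol,
                 hydrogens = hydrogens, oversample = oversample,
                 nbins = nbins, exclude_free = exclude_free, b_min = b_min,
                 fix_origin = fix_origin, early_stop_shift = early_stop_shift),
            class = "refinement_config")
}

#' Multi-cycle shift-field refinement
#'
#' Runs [shift_field_cycle()] over the resolution ramp of the schedule,
#' collecting per-cycle statistics. The run is deterministic: identical
#' inputs and configuration give identical results. R factors in each row
#' describe the model *entering* that cycle at that cycle's resolution;
#' `final_r` holds the R factors of the final model at `d_end`. A
#' bond-length r.m.s.d. reporter tracks the geometry distortion that
#' restraint-free refinement allows (the method relies on downstream
#' conventional refinement to restore geometry).
#'
#' @param model An `atomic_model`.
#' @param refl A `reflection_set` extending to at least `d_end` resolution.
#' @param config A [refinement_config()] (or list of overrides).
#' @param verbose Print one key=value line per cycle.
#' @return List with `model` (final), `stats` (per-cycle data.frame with
#'   cycle, d, r0, n_refl, r_work, r_free, mean/max shift, bond r.m.s.d.)
#'   and `final_r` (list r_work/r_free at d_end).
#' @export
run_refinement <- function(model, refl, config = refinement_config(),
                           verbose = FALSE) {
  o <- utils::modifyList(refinement_config(), config)
  if (!nrow(refl$refl)) stop("empty reflection set")
  if (refl$d_min > o$d_end + 0.01)
    stop(sprintf("data extend only to %.2f A but the schedule ends at %.2f A",
                 refl$d_min, o$d_end))
  sched <- make_schedule(o$n_cycles, o$d_start, o$d_end, o$radius_factor)
  rows <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    cyc <- shift_field_cycle(model, refl, sched$d[i], sched$r0[i], o)
    model <- cyc$model
    row <- cbind(cycle = sched$cycle[i], cyc$stats,
                 bond_rmsd = bond_length_rmsd(model))
    rows[[i]] <- row
    if (verbose)
      cat(sprintf("cycle=%d d=%.2f r0=%.1f nrefl=%d r_work=%.4f r_free=%s mean_shift=%.4f max_shift=%.4f\n",
                  row$cycle, row$d, row$r0, row$n_refl, row$r_work,
                  formatC(row$r_free, format = "f", digits = 4),
                  row$mean_shift, row$max_shift))
    if (o$early_stop_shift > 0 && row$max_shift < o$early_stop_shift) {
      rows <- rows[seq_len(i)]
      break
    }
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  fin <- suppressWarnings(truncate_resolution(refl, o$d_end))
  fc <- calc_structure_factors(model, fin, hydrogens = o$hydrogens)
  if (o$solvent) fc <- apply_bulk_solvent(fc, o$k_sol, o$b_sol)
  fc <- scale_fobs_fcalc(fin, fc)$fc
  list(model = model, stats = stats, final_r = r_factors(fin, fc))
}

IDEAL_BONDS <- data.frame(
  from = c("N", "CA", "C", "C"),
  to = c("CA", "C", "O", "N+"),          # N+ = N of the next residue
  length = c(1.458, 1.525, 1.231, 1.329))

#' Backbone bond-length r.m.s.d. from ideal values
#'
#' Reports the r.m.s. deviation of the N-CA, CA-C, C-O and peptide C-N bond
#' lengths from their ideal values, over residues where both partner atoms
#' are present. A cheap reporter of the geometric distortion accumulated by
#' restraint-free refinement; returns NA when no such bonds exist.
#'
#' @param model An `atomic_model`.
#' @return r.m.s.d. in Angstroms, or NA.
#' @export
bond_length_rmsd <- function(model) {
  at <- model$atoms
  if (!nrow(at)) return(NA_real_)
  xyz <- model_orth(model)
  key <- paste(at$chain, at$resno, at$atom_name)
  lookup <- stats::setNames(seq_len(nrow(at)), key)
  devs <- numeric(0)
  mic_dist <- function(i, j) {
    df <- wrap_frac(model_frac(model)[j, , drop = FALSE] -
                      model_frac(model)[i, , drop = FALSE] + 0.5) - 0.5
    sqrt(rowSums(frac_to_orth(model$cell, df)^2))
  }
  for (b in seq_len(nrow(IDEAL_BONDS))) {
    to <- IDEAL_BONDS$to[b]
    dres <- if (to == "N+") 1L else 0L
    toname <- sub("\\+$", "", to)
    i <- lookup[paste(at$chain, at$resno, IDEAL_BONDS$from[b])]
    j <- lookup[paste(at$chain, at$resno + dres, toname)]
    ok <- !is.na(i) & !is.na(j)
    if (any(ok))
      devs <- c(devs, mic_dist(i[ok], j[ok]) - IDEAL_BONDS$length[b])
  }
  if (!length(devs)) return(NA_real_)
  sqrt(mean(devs^2))
}
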