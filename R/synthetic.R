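# -- internal: NeRF atom placement and backbone construction ------------------

# place atom D given positions A, B, C, bond |CD|, angle B-C-D (deg) and
# torsion A-B-C-D (deg)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# ideal-geometry backbone (N, CA, C, O per residue) from phi/psi torsions
build_backbone <- function(phi, psi, omega = 180) {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res)
  xyz <- matrix(NA_real_, 4 * n_res, 3)
  nm <- character(4 * n_res)
  idx <- function(i, what) (i - 1) * 4 + match(what, c("N", "CA", "C", "O"))
  # residue 1 seed frame
  xyz[idx(1, "N"), ] <- c(0, 0, 0)
  xyz[idx(1, "CA"), ] <- c(1.458, 0, 0)
  xyz[idx(1, "C"), ] <- place_atom(c(0, 1, 0), xyz[idx(1, "N"), ],
                                   xyz[idx(1, "CA"), ], 1.525, 111.2, 60)
  for (i in seq_len(n_res)) {
    Ni <- xyz[idx(i, "N"), ]; CAi <- xyz[idx(i, "CA"), ]; Ci <- xyz[idx(i, "C"), ]
    if (i < n_res) {
      Nn <- place_atom(Ni, CAi, Ci, 1.329, 116.2, psi[i])
      CAn <- place_atom(CAi, Ci, Nn, 1.458, 121.7, omega)
      Cn <- place_atom(Ci, Nn, CAn, 1.525, 111.2, phi[i + 1])
      xyz[idx(i + 1, "N"), ] <- Nn
      xyz[idx(i + 1, "CA"), ] <- CAn
      xyz[idx(i + 1, "C"), ] <- Cn
    }
    xyz[idx(i, "O"), ] <- place_atom(Ni, CAi, Ci, 1.231, 120.8, psi[i] + 180)
  }
  nm <- rep(c("N", "CA", "C", "O"), n_res)
  list(xyz = xyz, atom_name = nm, resno = rep(seq_len(n_res), each = 4),
       element = rep(c("N", "C", "C", "O"), n_res))
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Ground-truth toy structures
#'
#' Generates small protein-like backbone models (N, CA, C, O per residue,
#' ideal bond lengths and angles) placed in a P 1 cell with the requested
#' padding around the molecule. Styles: `poly_ala_helix` (one alpha helix,
#' phi = -57, psi = -47), `two_domain_helix_pair` (two parallel helices,
#' centroids ~16 Angstroms apart, residues numbered consecutively so the
#' second helix is a selectable "domain"), `random_coil` (seeded random
#' torsions). All atoms are ALA with B_iso as given.
#'
#' @param style One of "poly_ala_helix", "two_domain_helix_pair",
#'   "random_coil".
#' @param n_residues Residues per chain segment (>= 3); the two-domain style
#'   contains 2 * n_residues in total.
#' @param cell_padding Minimum model-to-cell-edge distance in Angstroms.
#' @param angles Cell angles in degrees (default orthogonal; any triclinic
#'   angles are accepted).
#' @param b_iso Uniform isotropic B (Angstrom^2).
#' @param spacegroup "P 1" (default) or "P -1". A pure translation of the
#'   whole model is a gauge mode in P 1 — the amplitudes are exactly
#'   invariant, so nothing pins the origin. The centrosymmetric "P -1"
#'   fixture adds an inversion image that pins the origin, making rigid
#'   offsets observable; the molecule is then centred at fractional
#'   (1/4, 1/4, 1/4) so the image stays spatially separated.
#' @param seed RNG seed (used only by random_coil; the generator is
#'   deterministic given style, size and seed).
#' @return An `atomic_model`.
#' @export
make_toy_structure <- function(style = c("poly_ala_helix",
                                         "two_domain_helix_pair",
                                         "random_coil"),
                               n_residues = 10, cell_padding = 8,
                               angles = c(90, 90, 90), b_iso = 20,
                               spacegroup = "P 1",
                               seed = 1) {
  style <- match.arg(style)
  stopifnot(n_residues >= 3, cell_padding > 0)
  helix <- function(n) build_backbone(rep(-57, n), rep(-47, n))
  bb <- switch(style,
    poly_ala_helix = helix(n_residues),
    two_domain_helix_pair = {
      b1 <- helix(n_residues)
      b2 <- helix(n_residues)
      b2$xyz <- b2$xyz + matrix(c(0, 16, 0), nrow(b2$xyz), 3, byrow = TRUE)
      b2$resno <- b2$resno + n_residues
      list(xyz = rbind(b1$xyz, b2$xyz),
           atom_name = c(b1$atom_name, b2$atom_name),
           resno = c(b1$resno, b2$resno),
           element = c(b1$element, b2$element))
    },
    random_coil = with_seed(seed, build_backbone(stats::runif(n_residues, -180, 180),
                                                 stats::runif(n_residues, -180, 180))))
  xyz <- bb$xyz
  ext <- apply(xyz, 2, function(v) diff(range(v)))
  span <- ext + 2 * cell_padding
  # for oblique cells pad a little extra so images cannot approach closer
  # than the padding through the cell obliquity
  obl <- max(abs(cos(angles * pi / 180)))
  span <- span * (1 + obl)
  sym <- symmetry_ops(spacegroup)
  if (n_sym_ops(sym) > 1) span <- span * 4 / 3  # room for the inversion image
  if (cell_padding < 2)
    stop("cell too small to keep periodic images apart; increase cell_padding")
  cell <- unit_cell(span[1], span[2], span[3], angles[1], angles[2], angles[3])
  # P -1: a generic centre keeps the image separated AND avoids the
  # pseudo-translation that arises at (1/4,1/4,1/4), where the image sits
  # exactly half a lattice vector away and the amplitudes become blind to
  # some rigid motions
  ctr_frac <- if (n_sym_ops(sym) > 1) c(0.21, 0.29, 0.27) else c(0.5, 0.5, 0.5)
  xyz <- xyz - matrix(colMeans(apply(xyz, 2, range)), nrow(xyz), 3, byrow = TRUE)
  frac <- orth_to_frac(cell, xyz) +
    matrix(ctr_frac, nrow(xyz), 3, byrow = TRUE)
  atoms <- data.frame(element = bb$element,
                      u = frac[, 1], v = frac[, 2], w = frac[, 3],
                      occ = 1, b_iso = b_iso,
                      chain = "A", resno = bb$resno, resname = "ALA",
                      atom_name = bb$atom_name, stringsAsFactors = FALSE)
  atomic_model(cell, sym, atoms)
}

#' Perturb a model with a known error mode
#'
#' Applies one of the error modes used to validate refinement by parameter
#' recovery: a rigid translation of the selected atoms, a hinge rotation of
#' a domain about an axis through a pivot (emulating the domain-rotation
#' errors of molecular-replacement models), or random coordinate jitter.
#'
#' @param model An `atomic_model`.
#' @param kind "rigid_translation", "hinge_rotation" or "random_jitter".
#' @param magnitude Angstroms (translation / r.m.s. jitter) or degrees
#'   (rotation); >= 0.
#' @param selection Integer vector of residue numbers to perturb (default:
#'   all residues).
#' @param direction Unit-vector direction for translations (orthogonal
#'   frame; normalized internally).
#' @param axis,pivot Rotation axis (normalized) and pivot point in
#'   orthogonal Angstroms (pivot default: selection centroid).
#' @param seed Seed for random_jitter.
#' @return The perturbed `atomic_model`.
#' @export
perturb_model <- function(model, kind = c("rigid_translation", "hinge_rotation",
                                          "random_jitter"),
                          magnitude, selection = NULL,
                          direction = c(1, 0, 0), axis = c(0, 0, 1),
                          pivot = NULL, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(magnitude >= 0)
  at <- model$atoms
  sel <- if (is.null(selection)) rep(TRUE, nrow(at)) else at$resno %in% selection
  if (!any(sel)) stop("empty atom selection")
  xyz <- model_orth(model)
  if (kind == "rigid_translation") {
    u <- direction / sqrt(sum(direction^2))
    xyz[sel, ] <- xyz[sel, , drop = FALSE] +
      matrix(magnitude * u, sum(sel), 3, byrow = TRUE)
  } else if (kind == "hinge_rotation") {
    u <- axis / sqrt(sum(axis^2))
    if (is.null(pivot)) pivot <- colMeans(xyz[sel, , drop = FALSE])
    th <- magnitude * pi / 180
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    cen <- sweep(xyz[sel, , drop = FALSE], 2, pivot)
    xyz[sel, ] <- cen %*% t(R) + matrix(pivot, sum(sel), 3, byrow = TRUE)
  } else {
    xyz[sel, ] <- xyz[sel, , drop = FALSE] + with_seed(seed,
      matrix(stats::rnorm(3 * sum(sel), sd = magnitude / sqrt(3)), ncol = 3))
  }
  frac <- wrap_frac(orth_to_frac(model$cell, xyz))
  at[, c("u", "v", "w")] <- frac
  atomic_model(model$cell, model$sym, at)
}

#' Simulate observed amplitudes from a ground-truth model
#'
#' Enumerates the unique reflections to `d_min`, computes |F_calc| of the
#' truth model, applies multiplicative Gaussian amplitude noise
#' |Fo| = |Fc| (1 + eps), eps ~ N(0, noise_fraction) clipped at -0.9, sets
#' sigma(F) = noise_fraction |Fo|, and assigns free flags by a seeded
#' uniform draw at the requested fraction.
#'
#' @param truth An `atomic_model`.
#' @param d_min Resolution limit in Angstroms.
#' @param noise_fraction Relative amplitude noise (>= 0; 0 = error-free).
#' @param free_fraction Fraction of reflections flagged free (default 0.05).
#' @param seed RNG seed; identical seeds give identical sets.
#' @return A `reflection_set`.
#' @export
simulate_observations <- function(truth, d_min, noise_fraction = 0,
                                  free_fraction = 0.05, seed = 1) {
  stopifnot(noise_fraction >= 0, free_fraction >= 0, free_fraction <= 0.5)
  cell <- truth$cell
  hmax <- ceiling(c(cell$a, cell$b, cell$c) / d_min) + 1L
  g <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2], l = 0:hmax[3])
  keep <- g$l > 0 | (g$l == 0 & g$k > 0) | (g$l == 0 & g$k == 0 & g$h > 0)
  g <- g[keep, ]
  d <- d_spacing(cell, as.matrix(g))
  g <- g[d >= d_min, ]
  if (nrow(g) < 10) stop("d_min too large: fewer than 10 reflections")
  rs <- reflection_set(cell, truth$sym,
                       data.frame(g, fobs = 0, sigf = 0, free = FALSE))
  fc <- calc_structure_factors(truth, rs)
  fmag <- Mod(fc$f)
  with_seed(seed, {
    eps <- if (noise_fraction > 0)
      pmax(-0.9, stats::rnorm(length(fmag), sd = noise_fraction)) else 0
    fobs <- fmag * (1 + eps)
    free <- stats::runif(length(fmag)) < free_fraction
    reflection_set(cell, truth$sym,
                   data.frame(h = rs$refl$h, k = rs$refl$k, l = rs$refl$l,
                              fobs = fobs, sigf = noise_fraction * fobs,
                              free = free))
  })
}

#' Matched coordinate r.m.s.d. between two models
#'
#' Atoms are matched by (chain, residue number, atom name); distances use
#' the minimum-image convention in the (shared) periodic cell. Selection
#' rules: `all_atoms`, `ca_only`, or `ca_within_3A` — C-alpha pairs farther
#' than 3 Angstroms apart are excluded, the standard rule for excluding
#' outlier residues that would otherwise dominate the r.m.s.d.
#'
#' @param model_a,model_b `atomic_model`s with shared labelling.
#' @param selection_rule One of "all_atoms", "ca_only", "ca_within_3A".
#' @return r.m.s.d. in Angstroms (error, not 0, when no atoms match).
#' @export
matched_rmsd <- function(model_a, model_b,
                         selection_rule = c("all_atoms", "ca_only",
                                            "ca_within_3A")) {
  selection_rule <- match.arg(selection_rule)
  a <- model_a$atoms; b <- model_b$atoms
  if (selection_rule != "all_atoms") {
    a <- a[a$atom_name == "CA", ]; b <- b[b$atom_name == "CA", ]
  }
  key_a <- paste(a$chain, a$resno, a$atom_name)
  key_b <- paste(b$chain, b$resno, b$atom_name)
  common <- intersect(key_a, key_b)
  if (!length(common)) stop("no matched atoms between the two models")
  ia <- match(common, key_a); ib <- match(common, key_b)
  df <- as.matrix(b[ib, c("u", "v", "w")]) - as.matrix(a[ia, c("u", "v", "w")])
  df <- wrap_frac(df + 0.5) - 0.5           # minimum image
  dist <- sqrt(rowSums(frac_to_orth(model_a$cell, df)^2))
  if (selection_rule == "ca_within_3A") {
    dist <- dist[dist <= 3]
    if (!length(dist)) stop("no matched C-alpha pairs within 3 Angstroms")
  }
  sqrt(mean(dist^2))
}

THREE_TO_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

model_sequence <- function(model, chain) {
  at <- model$atoms[model$atoms$chain == chain & model$atoms$atom_name == "CA", ]
  at <- at[order(at$resno), ]
  letters <- THREE_TO_ONE[at$resname]
  letters[is.na(letters)] <- "X"
  list(seq = paste(letters, collapse = ""), resno = at$resno)
}

#' Align residues of two models by sequence
#'
#' Global alignment (match +1, mismatch -1, gap -2 per position) of the
#' one-letter sequences of each chain the models share, returning the
#' aligned residue-number pairs (gaps excluded). The alignment itself is
#' delegated to Biostrings.
#'
#' @param model_a,model_b `atomic_model`s carrying residue names.
#' @return data.frame with columns `chain`, `resno_a`, `resno_b`; the total
#'   alignment score is in attribute `"score"`.
#' @export
align_residue_pairs <- function(model_a, model_b) {
  chains <- intersect(unique(model_a$atoms$chain), unique(model_b$atoms$chain))
  if (!length(chains)) stop("models share no chains")
  alpha <- unique(c(unname(THREE_TO_ONE), "X"))
  submat <- matrix(-1, length(alpha), length(alpha),
                   dimnames = list(alpha, alpha))
  diag(submat) <- 1
  out <- list(); total <- 0
  for (ch in chains) {
    sa <- model_sequence(model_a, ch); sb <- model_sequence(model_b, ch)
    if (!nzchar(sa$seq) || !nzchar(sb$seq)) next
    aln <- Biostrings::pairwiseAlignment(sa$seq, sb$seq, type = "global",
                                         substitutionMatrix = submat,
                                         gapOpening = 0, gapExtension = 2)
    total <- total + Biostrings::score(aln)
    ga <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    gb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    pa <- cumsum(ga != "-"); pb <- cumsum(gb != "-")
    both <- ga != "-" & gb != "-"
    if (any(both))
      out[[ch]] <- data.frame(chain = ch,
                              resno_a = sa$resno[pa[both]],
                              resno_b = sb$resno[pb[both]])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chain = character(), resno_a = integer(), resno_b = integer())
  rownames(res) <- NULL
  attr(res, "score") <- total
  res
}
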