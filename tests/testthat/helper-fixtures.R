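# shared fixtures, built once per test file and memoised
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 10-residue helix in a centrosymmetric cell with error-free 3 A data:
# the workhorse recovery fixture (P -1 pins the origin so rigid offsets
# are observable in the amplitudes)
helix_p1bar <- function() fixture("helix_p1bar", function() {
  truth <- make_toy_structure("poly_ala_helix", 10, cell_padding = 12,
                              spacegroup = "P -1")
  list(truth = truth,
       refl = simulate_observations(truth, 3.0, 0, 0.05, seed = 7))
})

# small pure-P1 helix + data, for map/gradient machinery tests
helix_p1 <- function() fixture("helix_p1", function() {
  truth <- make_toy_structure("poly_ala_helix", 10)
  list(truth = truth,
       refl = simulate_observations(truth, 3.0, 0, 0.05, seed = 7))
})

# hinge fixture: two 20-residue helices, P -1; domain 2 rotated 8 degrees
# about an axis perpendicular to its helix axis through the boundary CA,
# giving ~4.5 A maximum main-chain displacement
hinge_p1bar <- function() fixture("hinge_p1bar", function() {
  truth <- make_toy_structure("two_domain_helix_pair", 20, cell_padding = 10,
                              spacegroup = "P -1")
  at <- truth$atoms
  ca <- function(r) model_orth(truth)[which(at$resno == r &
                                              at$atom_name == "CA")[1], ]
  ax <- ca(40) - ca(21); ax <- ax / sqrt(sum(ax^2))
  perp <- c(ax[2], -ax[1], 0); perp <- perp / sqrt(sum(perp^2))
  pert <- perturb_model(truth, "hinge_rotation", 8, selection = 21:40,
                        axis = perp, pivot = ca(21))
  list(truth = truth, pert = pert,
       refl = simulate_observations(truth, 3.0, 0, 0.05, seed = 11))
})
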