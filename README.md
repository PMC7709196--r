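# shiftfield

Restraint-free refinement of macromolecular atomic models against
structure-factor amplitudes, for crystallographers working with poor
starting models — typically molecular-replacement solutions whose chains or
domains are mispositioned by more than the convergence radius of
conventional restrained refinement.

## The method

Instead of refining per-atom parameters, the package computes a **shift
field**: one parameter-update vector per grid point of the map, obtained by
locally regressing a likelihood-weighted difference map *D* onto the
gradient maps of the calculated density. With gradient maps
*g<sub>k</sub>* = ∂ρ/∂ξ<sub>k</sub> (ξ = fractional coordinates *u, v, w*,
or the local isotropic *B*), the field at grid point **x**<sub>i</sub>
solves the weighted normal equations

&nbsp;&nbsp;&nbsp;&nbsp;
[ Σ<sub>j</sub> w<sub>ij</sub> g<sub>k</sub>(**x**<sub>j</sub>) g<sub>l</sub>(**x**<sub>j</sub>) ] Δξ<sub>l</sub>(**x**<sub>i</sub>)
= Σ<sub>j</sub> w<sub>ij</sub> D(**x**<sub>j</sub>) g<sub>k</sub>(**x**<sub>j</sub>),
&nbsp;&nbsp; w<sub>ij</sub> = 1 − (r<sub>ij</sub>/r<sub>0</sub>)² for r < r<sub>0</sub>,

where every sum over the spherical region is a periodic convolution with
the kernel *w*, evaluated by FFT. Atoms read their update by trilinear
interpolation of the field. Difference coefficients are the standard
(m|F<sub>o</sub>| − D|F<sub>c</sub>|)e<sup>iφ<sub>c</sub></sup> with σ<sub>A</sub>
estimated per resolution bin from the free reflections (Rice likelihood).
The driver runs 12 cycles with the resolution ramped linearly from 6 Å to
3 Å and the sphere radius fixed at four times the current resolution, so
early cycles move whole domains and later cycles sharpen detail. There are
no stereochemical restraints; the method is designed to precede, not
replace, conventional refinement.

The package includes a first-class synthetic-data harness — ideal-geometry
toy structures, rigid/hinge/jitter perturbations, simulated amplitudes with
seeded noise and free flags, matched (Cα) r.m.s.d. metrics with the 3 Å
outlier rule, and sequence alignment of residue pairs — so every claim is
validated by parameter recovery with no external data.

## Worked example: recovering a mispositioned model

```r
library(shiftfield)

truth <- make_toy_structure("poly_ala_helix", n_residues = 10,
                            cell_padding = 12, spacegroup = "P -1")
refl  <- simulate_observations(truth, d_min = 3.0, noise_fraction = 0.05,
                               free_fraction = 0.05, seed = 7)
start <- perturb_model(truth, "rigid_translation", magnitude = 1.5,
                       direction = c(1, 1, 0))
matched_rmsd(truth, start)      # 1.5 A off

res <- run_refinement(start, refl, refinement_config(), verbose = TRUE)
matched_rmsd(truth, res$model)
```

Output (abridged):

```
cycle=1  d=6.00 r0=24.0 nrefl=923  r_work=0.4275 r_free=0.5425 mean_shift=0.5793 max_shift=0.5834
cycle=2  d=5.73 r0=22.9 nrefl=1043 r_work=0.3054 r_free=0.4341 mean_shift=0.5323 max_shift=0.5346
cycle=3  d=5.45 r0=21.8 nrefl=1234 r_work=0.1532 r_free=0.1963 mean_shift=0.3015 max_shift=0.3025
cycle=4  d=5.18 r0=20.7 nrefl=1434 r_work=0.0568 r_free=0.0579 mean_shift=0.0791 max_shift=0.0803
...
cycle=12 d=3.00 r0=12.0 nrefl=7343 r_work=0.0407 r_free=0.0378 mean_shift=0.0012 max_shift=0.0030
r.m.s.d. after: 0.009 A        final R_work 0.040, R_free 0.037
```

Each row reports the model *entering* that cycle at the cycle's resolution:
the starting offset gives R_work 0.43 at 6 Å; the first three 24–22 Å
regression spheres walk the whole molecule back (mean shifts of 0.5–0.3 Å
per cycle); by cycle 5 the shifts are sub-0.01 Å and the R factors sit at
the 5% noise floor of the simulated data. The final matched r.m.s.d. of
0.009 Å means the 1.5 Å placement error is fully recovered. The fixture
uses a centrosymmetric (P -1) cell because in P 1 a rigid translation of
the whole model leaves the amplitudes unchanged — there would be nothing
to recover.

A shell interface wraps the same driver:

```sh
Rscript inst/scripts/shiftfield-simulate.R --residues 10 --d-min 3 --translate 1.5 --prefix toy
Rscript inst/scripts/shiftfield-refine.R --model toy_start.pdb --hklin toy_data.csv \
        --output refined.pdb --cycles 12 --res-start 6 --res-end 3
```

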