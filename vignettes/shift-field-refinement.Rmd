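---
title: "Shift-field refinement: model, implementation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-field refinement: model, implementation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftfield)
```

## The problem

Conventional crystallographic refinement optimizes the parameters of every
atom against the observed structure-factor amplitudes, stabilized by
stereochemical restraints. Restraints couple neighbouring atoms and make the
refinement landscape rugged, so convergence from a poor starting model — a
molecular-replacement solution with a mispositioned chain or a rotated
domain — is slow and often fails. When the fine structure of the model
(bond lengths, rotamers) is already acceptable and only coarse-scale errors
remain, a much simpler parameterization is available: a smooth spatial
field of shifts applied to the model.

## The shift-field model

Let $\rho$ be the density calculated from the current model and $D$ a
likelihood-weighted difference map between the observations and the model.
Around any map position, a small change of the model parameters changes
the calculated density by a linear combination of *gradient maps*

$$ g_k(\mathbf{x}) = \frac{\partial \rho(\mathbf{x})}{\partial \xi_k}, $$

where $\xi_k$ are the refined parameters: the three fractional coordinates
$u, v, w$ of a rigid shift of the local density (coordinate mode), or the
local isotropic $B$ value ($B$ mode). At every grid point $i$ of the map we
solve a small weighted linear regression of $D$ on the $g_k$, accumulated
over a surrounding spherical region,

$$ \Big(\sum_j w_{ij}\, g_k(\mathbf{x}_j)\, g_l(\mathbf{x}_j)\Big)\,
   \Delta\xi_l(\mathbf{x}_i)
 = \sum_j w_{ij}\, D(\mathbf{x}_j)\, g_k(\mathbf{x}_j), $$

with weights $w_{ij} = f(|\mathbf{x}_j - \mathbf{x}_i|)$,
$f(r) = 1 - (r/r_0)^2$ for $r < r_0$ and $0$ beyond. Both sides are maps:
the right-hand side is the *residual vector field* (difference map times
gradient maps, smoothed), the matrix is the *normal matrix field* (pairwise
gradient products, smoothed). Because the weight depends only on the
separation, every sum is a periodic convolution with the kernel $f$ and is
computed by FFT. Solving the $n \times n$ system per voxel
($n \in \{1, 3\}$, $+1$ with the constant term) yields the **shift field**:
one parameter-shift vector per grid point. Each atom then reads its update
by trilinear interpolation of the field at its own position.

The regression weights *are* the convolution kernel — there is no second
weighting scheme. The kernel is normalized to unit sum; normalization
cancels between the two sides of the normal equations and only improves the
conditioning of logged fields.

### Likelihood weighting

The difference map uses the standard amplitude-likelihood machinery.
Normalized amplitudes $E_o, E_c$ are formed in equal-population resolution
bins; $\sigma_A$ per bin maximizes the Rice likelihood of $E_o$ given
$\sigma_A E_c$ (1-D search on $[0.01, 0.99]$), evaluated over free
reflections so the weights are not biased by the refinement target. Bins
with fewer than 20 free reflections fall back to all reflections in the
bin, with a warning: a handful of free amplitudes produces clamp-to-clamp
noise in $\sigma_A$, which harms the difference map far more than the mild
model bias of the work set. From $\sigma_A$ follow the figure of merit
$m = I_1(X)/I_0(X)$ with $X = 2\sigma_A E_o E_c / (1 - \sigma_A^2)$
(centric reflections: $m = \tanh(X/2)$, detected from the symmetry
operators) and the amplitude scale
$D = \sigma_A (\langle F_o^2\rangle / \langle F_c^2\rangle)^{1/2}$. The
difference coefficients are $(m|F_o| - D|F_c|)\,e^{i\varphi_c}$; missing
amplitudes contribute zero, and free reflections are excluded from the map
by default so the free $R$ stays honest.

### The cycle and the ramp

One cycle at resolution $d$: truncate the data; compute $F_c$ by direct
summation (with an optional Babinet bulk-solvent factor
$1 - k_s e^{-B_s s^2/4}$); fit the overall scale
$\log(|F_o|/|F_c|) \sim s^2/4$ on work reflections; estimate $\sigma_A$,
$m$, $D$; synthesize $\rho$, $D$-map and gradient maps on a grid with
spacing $\le d/3$; build and smooth the regression fields; solve; apply
interpolated shifts. The driver repeats this for 12 cycles with the working
resolution decreasing linearly in $d$ from 6 to 3 Å and the kernel radius
fixed at $r_0 = 4d$. Early cycles (low resolution, 24 Å spheres) capture
whole-domain motions; later cycles sharpen detail. Convergence is
cycle-count based; an optional early stop on maximum shift exists but is
off by default.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_cycles`, `d_start`, `d_end` | 12, 6 Å, 3 Å | linear-in-$d$ resolution ramp |
| `radius_factor` | 4 | $r_0 = 4 d$, regression-sphere radius |
| `oversample` | 1.5 | grid spacing $= d / (2 \cdot 1.5) \approx d/3$ (1 Å grid at 3 Å) |
| `mode` | `"coords"` | `"biso"` refines isotropic $B$ instead |
| `include_const` | `FALSE` | constant regression term; absorbs a uniform map offset but measurably helps nothing, so off |
| `ridge_fraction` | `1e-6` | $\lambda = 10^{-6}\max(\mathrm{diag}\,N)$ per voxel; bias negligible, solve total |
| `floor_fraction` | `1e-12` | voxels with no gradient power (flat solvent) get zero shift |
| `shift_scale` | 1 | shifts applied in full |
| `solvent`, `k_sol`, `b_sol` | off, 0.35, 46 Å² | Babinet correction; off for synthetic data, which contain no solvent |
| `nbins` | 12 | $\sigma_A$/scaling bins, reduced automatically for small sets |
| `fix_origin` | `TRUE` | subtract the mean shift along polar axes each cycle |
| `b_min` | 1 Å² | floor for refined $B$ values |

## Numerical choices

**Gradient sign convention.** $g_k$ is the density change per unit positive
shift of the model along fractional axis $k$, synthesized from coefficients
$(2\pi i h_k) F(h)$ under the $\rho = V^{-1}\sum F e^{-2\pi i h\cdot x}$
convention — equivalently $-\partial\rho/\partial u_k$ of the static map.
The convention is pinned by a finite-difference test (agreement to $10^{-3}$
relative) and end-to-end by translation recovery; with the opposite sign
every recovery test diverges.

**Structure factors.** Direct summation over atoms (and symmetry copies) is
the production path up to 2000 atom copies and the oracle beyond; the FFT
path samples Gaussian atoms on a $\sim d/6$ grid with an anti-aliasing $B$
added before sampling and removed in reciprocal space, and agrees with the
direct sum to $10^{-4}$ relative at 3 Å. Form factors are the standard
four-Gaussian-plus-constant coefficients; hydrogens are skipped by default.

**Per-voxel solve.** The $3\times 3$ systems are solved in closed form
(adjugate), vectorized over the grid; the $n = 4$ case (constant term) falls
back to a per-voxel dense solve. Voxels whose ridge-regularized determinant
is nonpositive, or whose diagonal falls under the absolute floor, return a
zero shift, so the field is finite everywhere by construction.

**Origin fixing.** Along polar axes of the spacegroup (all three in P 1)
the amplitudes carry no information about the global origin, so the
refinement would drift on a flat likelihood direction; the mean coordinate
shift along polar axes is subtracted each cycle, the standard remedy in
polar-spacegroup refinement. In P -1 no axis is polar and the correction is
inert.

**Kernel distances** are orthogonal Ångströms even in oblique cells,
computed per grid point under the minimum-image convention (27-image
search); when $2 r_0$ exceeds the shortest cell edge the kernel wraps onto
itself and a warning is issued — refinement still works, with reduced
spatial selectivity.

## The synthetic harness, and what it does (not) show

All validation runs on synthetic structures built from ideal-geometry
backbone fragments (N, CA, C, O; NeRF construction from ideal bond lengths,
angles and torsions): a 10-residue poly-alanine α-helix, a two-domain pair
of 20-residue helices, and a random coil. Simulated amplitudes are
$|F_{\rm calc}|$ of the ground truth, optionally with multiplicative
Gaussian noise, plus a seeded 5% free-flag partition.

One physical subtlety dictates the fixtures' spacegroup. A rigid
translation of the *entire* model in P 1 is a gauge mode: the amplitudes
are exactly invariant, so "recovering" it is meaningless. Translation- and
hinge-recovery fixtures therefore use P -1, where the inversion image pins
the origin (and exercises the centric likelihood path throughout). Two
placement rules matter: the molecule is centred away from special
positions, because a centre at $(1/4,1/4,1/4)$ puts the image exactly half
a lattice vector away and the resulting pseudo-translation makes the
amplitudes nearly blind to rigid motion along some axes; and the cell is
enlarged so the image clears the largest regression sphere.

Under these conditions the package recovers a 1.5 Å rigid offset to below
0.01 Å (noise-free, and below 0.01 Å with 5% amplitude noise) and reduces
an 8° domain rotation (4.5 Å maximum displacement) by ~80% in matched
Cα r.m.s.d.; refining an already-correct model moves no atom by more than
~0.01 Å. Matched r.m.s.d. uses minimum-image distances, and the
`ca_within_3A` rule excludes residue pairs farther than 3 Å, the standard
guard against outliers dominating the statistic.

What the tests do *not* show: synthetic data contain no bulk solvent, no
measurement-error model beyond multiplicative noise, no missing
reflections, no model incompleteness, and only two spacegroups. Real
deposited data add all of these, and behaviour there is outside what this
test suite can certify. Problem sizes were chosen so the full suite and the
validation script each run in well under a minute of FFT work: 40–160-atom
models, cells of 40–60 Å, 1000–16000 reflections to 3 Å.

## Known limitations

* No stereochemical restraints: geometry drifts slowly with cycle count
  (the `bond_rmsd` column of the stats table tracks it); the method is
  meant to be followed by conventional restrained refinement, which this
  package deliberately does not wrap.
* The regression sphere cannot represent discontinuous shift fields, e.g.
  opposite motions of close-packed neighbouring molecules — behaviour
  across a molecular boundary is averaged, a documented failure mode of
  the approach.
* Spacegroup support is P 1 and P -1; other groups should be expanded to
  P 1 upstream. Anisotropic $B$, occupancy refinement and mask-based
  solvent are out of scope.
* Amplitude-only input: experimental $\sigma(F)$ is stored but not folded
  into the likelihood.
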