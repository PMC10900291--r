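---
title: "Cross-link restraints for coarse-grained protein modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-link restraints for coarse-grained protein modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinkforge)
```

## The problem

Chemical cross-linking coupled with mass spectrometry (XL-MS) identifies
pairs of residues bridged by a reagent of known maximum dimension. Each
identified pair is an upper bound on a distance in the folded protein, and a
set of such bounds can be fed into structure modeling as restraints. This
package implements the restraint machinery for a coarse-grained (CG)
two-center representation: each residue is reduced to its alpha carbon
(C&alpha;) and a side-chain center (SC, the centroid of the side-chain heavy
atoms). Glycine, which has no side-chain heavy atoms, takes SC = C&alpha;;
alanine's SC is its C&beta;.

A cross-link is not attached at the SC itself but at an *anchor point* X on
the C&alpha;&rarr;SC axis, at a reagent- and residue-specific offset
$d_X$ from the alpha carbon. The cross-link geometry between residues $i$
and $j$ is then described by five internal coordinates: the anchor–anchor
distance $d_{X_iX_j}$, the two planar angles
$\theta_{X_i} = \angle(\mathrm{C}^\alpha_i, X_i, X_j)$ and
$\theta_{X_j} = \angle(\mathrm{C}^\alpha_j, X_j, X_i)$, and the virtual-bond
dihedral $\gamma_{X_iX_j}$ defined by
C&alpha;$_i$&ndash;$X_i$&ndash;$X_j$&ndash;C&alpha;$_j$ (right-handed IUPAC
convention, reported in $(-\pi, \pi]$). Anchor offsets beyond the SC center
are permitted; the geometry does not care.

## Restraint potential families

Three families of cross-link penalties are implemented, with analytic first
derivatives throughout, plus a backbone dihedral restraint. In full-scale
refinement these terms extend a physical coarse-grained force field; the
force field itself is outside this package's scope, and the bundled toy
minimizer substitutes a harmonic tether for it (see below).

### Bounded Lorentz-like flat-bottom wall

Acting on the SC–SC distance $d$, with lower and upper contact boundaries
$d_l < d_u$, wall thickness $\sigma$ and well depth $A$:

$$
V^{\mathrm{Lor}}(d) = A\,\frac{x^2}{x^2 + \sigma^2},
\qquad
x = \max(d - d_u, 0) + \max(d_l - d, 0).
$$

The potential is identically zero on $[d_l, d_u]$, rises monotonically
outside, and saturates at the plateau $A$, so a grossly violated restraint
exerts essentially no force. That bounded character is the family's point:
false restraints — links that could only have been captured through large
fluctuations or distortion — stop fighting the fold once they are far past
their bound. The sub-$d_l$ branch mirrors the upper wall; the lower-side
behavior is not pinned down by the flat-bottom contract alone, and the
symmetric choice keeps side chains from fusing while preserving the zero
bottom. Defaults: $d_l = 2.5$ Å; $d_u$ from the reagent (TATA 4, SDA 5,
ABAS/DSG 6, DSA 7, BS3 12, disulfide 4.5 Å); four named wall presets
`LR(5,8)`, `LR(15,8)`, `LR(5,20)`, `LR(15,20)` combine $\sigma \in \{5,
15\}$ Å with $A \in \{8, 20\}$ kcal/mol. Disulfide bridges use $\sigma = 5$,
$A = 10$.

### Statistical potential on the C&alpha; distance

Statistical cross-link potentials derive from Boltzmann inversion of
empirical cross-linked-pair distance distributions. The family implemented
here inverts a generalized distance distribution
$p(d) \propto d^{a} \exp\!\big(-c\,d - (d-b)^2/2\sigma^2\big)$:

$$
V^{\mathrm{stat}}(d) = A\,RT \left[ \frac{(d-b)^2}{2\sigma^2} + c\,d
  - a \ln d \right],
$$

finite, continuous and once-differentiable for $d > 0$ and linear in the
confidence weight $A$ (default 15), with $RT = 0.591$ kcal/mol ($T = 298$
K). The shape parameters $a$, $b$, $c$, $\sigma$ are cross-link-specific
and load from JSON parameter files; nothing beyond the documented defaults
is hard-coded. The potential is evaluated without large-$d$ truncation;
whether published implementations truncate is not documented, and the
untruncated form keeps the gradient contract exact.

### MD-derived potential on the anchor geometry

The MD-based penalty is a sum of four components in the cross-link internal
coordinates,

$$
V^{\mathrm{MD}} = V_d(d_{X_iX_j}) + V_\theta(\theta_{X_i})
  + V_\theta(\theta_{X_j}) + V_\gamma(\gamma_{X_iX_j}),
$$

where the distance and angle components are Gaussian-term sums
$\sum_k a_k \exp\!\big(-(x-\mu_k)^2/2w_k^2\big)$ and the dihedral component
is a cosine series $\sum_k a_k \cos(n_k\gamma - \phi_k)$ with integer
orders, hence exactly $2\pi$-periodic. An optional additive constant
absorbs the arbitrary zero of a fitted free-energy profile (it carries no
force). The number of terms per component is free; coefficient sets load
from JSON.

### Backbone dihedral restraints

Secondary-structure knowledge enters as flat-bottom quartic restraints on
the C&alpha; virtual-bond dihedrals: zero inside a window $[\gamma_l,
\gamma_u]$ (modulo 360°) and $w_{\mathrm{dih}}\,\Delta^4$ outside, where
$\Delta$ is the angular excess measured in **radians** along the shorter
path to the window — the weight's units, kcal/(mol rad$^4$), settle which
unit the quartic acts on. Canonical windows: (30°, 70°) helical,
(120°, 240°) extended; default $w_{\mathrm{dih}} = 50$ kcal/(mol rad$^4$).

## Deriving MD-based parameters: Boltzmann inversion and fitting

Given an ensemble of cross-link geometries (in production work, snapshots
of an all-atom simulation of the cross-linked model compound; here, any
source of the four internal coordinates), `derive_mdbased_params()` runs,
per coordinate:

1. **Histogram** (`xl_histogram`): 50 bins for distances, 36 for angles and
   72 for dihedrals (5° bins) by default; published bin widths are not
   documented, so these are exposed as options. Dihedrals are binned
   periodically on $(-\pi, \pi]$.
2. **Boltzmann inversion** (`pmf_from_histogram`):
   $W_i = -RT \ln h_i$ with $R = 1.9872\times10^{-3}$ kcal/(mol K) and
   $T = 300$ K by default, shifted so the minimum over populated bins is
   zero. Empty bins are *masked*, not pseudo-counted: the inversion is
   undefined at $h = 0$ and invented counts would pollute the fit.
3. **Least-squares fit** (`fit_potential`): Levenberg–Marquardt
   (via \pkg{minpack.lm}) of the matching basis, from five deterministic
   initializations (centers seeded from detected PMF wells, quantiles and
   the data range; dihedral phases spread over $[0, 2\pi)$), keeping the
   best residual. An additive constant is always fitted. Convergence is
   declared on the optimizer's own criteria or an objective-gradient norm
   below $10^{-8}$; an unconverged fit is returned with `converged =
   FALSE`, never silently retried. Weights default to uniform;
   `weights = "counts"` selects Boltzmann weighting by bin population,
   which downweights the noisy, sparsely sampled tail bins and is the
   sensible choice when fitting sampled (rather than noiseless) profiles.

The suite checks this pipeline three ways: noiseless profiles built from
known parameters are recovered to residual $<10^{-6}$ (and random draws to
residual $<10^{-4}$ in at least 95 of 100 seeded trials); the inverted PMF
reproduces the empirical bin frequencies exactly; and a full sampled round
trip (5000 Metropolis samples per coordinate, matching the snapshot count
of a short production simulation) recovers the generating energy surfaces
to better than 0.3 kcal/mol RMS over the central 90% of the sampled region,
up to the free-energy zero, which is not an observable.

## Planning and auditing cross-link sets

`find_crosslinkable_pairs()` enumerates residue pairs that (a) match the
reagent's residue-type specificity, (b) have SC–SC distance within the
reagent's $d_u$, and (c) are both surface-exposed. Exposure is computed
directly on the CG sphere model (Shrake–Rupley-style test points on the
probe-inflated SC sphere, probe 1.4 Å, occluded by all other site spheres)
relative to the isolated residue — no published surface criterion exists
for this representation, so the package defines one and exposes its
threshold (default 0.2).

The *topological length* of a link is the residue index difference
$L = |j - i|$; $\Sigma L$ sums it over a set. A set with $\Sigma L > 150$
(strictly) is classified high-capacity: sets that long, in aggregate, pin
down enough long-range contacts to improve coarse-grained models
consistently. The threshold derives from benchmarks of small single-chain
proteins and is exposed as an argument. The alternative loop-size
convention $|j - i| + 1$ (counting both residues closing the loop) is
available because published per-protein "loop of $N$ residues" figures may
use either; the default is the index difference.

`violation_report()` audits a set against a (reference) structure: a link's
*excess* is its C&alpha; distance minus the reagent's maximum C&alpha;
span, taken as $d_u + 2 \times$ (side-chain reach; 6.4 Å for lysine, 2.8 Å
for cysteine). Counts over 5 and 10 Å margins are reported by default.
Violated links are counted, never deleted: with the structure unknown there
is no way to tell false restraints from true ones, so the toolkit never
curates — robustness to false restraints is the wall potential's job.

## Scoring

`kabsch_superpose()` is the standard SVD least-squares rigid superposition
with the proper-rotation branch enforced; `ca_rmsd()` applies it over the
author-index intersection of two chains (models of the same sequence, no
alignment). `gdt_ts()` implements the Global Distance Test Total Score:
for each cutoff (1, 2, 4, 8 Å) the maximal fraction of C&alpha; pairs
superposable within the cutoff, averaged and scaled to 0–100. The per-cutoff
search is the standard fragment-seeded heuristic — superpositions seeded
from every contiguous fragment of lengths 3, 5 and 7 plus the global fit,
each refined by iterating superpose-on-inliers to a fixed point. The
heuristic can only improve on the single global fit (the global fit is one
of its seeds, an invariant the suite asserts on hundreds of random decoys),
but it may differ from an exhaustive search by up to about 2 GDT_TS units
on hard decoys; tests therefore pin scores only on constructed fixtures
with unambiguous values (rigid transforms score 100; a half-displaced rigid
block scores exactly 50).

## The toy minimizer

`restrained_minimize()` exists to demonstrate and test the restraint
gradients end to end, not to fold anything. The objective is a per-site
harmonic tether to the starting coordinates (the stand-in for a physical
force field, chosen to isolate restraint behavior) plus the cross-link and
dihedral penalties, minimized by gradient descent with backtracking — the
energy trace is monotone non-increasing by construction. Cartesian
gradients are analytic for the wall (SC–SC), statistical (C&alpha;–C&alpha;)
and backbone-dihedral terms (Blondel–Karplus torsion derivatives); for
MD-based links the internal-coordinate gradient is analytic and the chain
rule to the twelve Cartesian coordinates involved is applied by central
differences, which is entirely adequate for a demonstrator. Expected
behaviors covered by tests: a violated wall link is pulled back to its flat
bottom against a weak tether; a grossly violated link on the plateau moves
nothing; satisfied restraints exert zero force; stronger tethers keep the
output monotonically closer to the input.

## Synthetic data: what it does and does not emulate

The fixture generators supply every input the tests need, in code:

- `ideal_helix()` — C&alpha; positions on a regular helical lattice (rise
  1.5 Å/residue, twist 100°/residue, radius 2.3 Å — the textbook
  alpha-helical geometry) with SC centers offset 2 Å radially outward. Its
  interior virtual-bond dihedrals fall inside the (30°, 70°) helical
  window, consistent with the dihedral-restraint convention.
- `perturb_chain()` — hinge rotations plus Gaussian coordinate noise,
  deterministic per seed: cheap decoys with controllable error.
- `boltzmann_sample()` — 1-D Metropolis with a uniform $\pm$step proposal
  and 10% burn-in. Coordinates with hard physical bounds (angles in
  $[0, \pi]$, distances above contact) should be sampled with a `domain`,
  since a localized model potential is flat far away and an unbounded
  walker would simply diffuse; rejecting out-of-domain proposals preserves
  detailed balance for the symmetric proposal.
- `make_xlink_fixture()` — cross-link sets with exact counts of satisfied
  and false (excess > 5 Å) links, emulating the observation that
  substantial false-restraint fractions occur in real data and must be
  tolerated.
- `write_toy_pdb()` — genuine ATOM records (CA plus one side-chain heavy
  atom placed at the SC position) so `read_structure()` can ingest its own
  fixtures, closing the I/O loop.

What passing tests on these fixtures shows: the geometry, potentials,
gradients, inversion/fitting pipeline, descriptors and scoring behave
exactly as specified on inputs with known ground truth. What it does not
show: performance on real proteins — real side-chain centroids are not
radial offsets, real decoys are not hinge perturbations, real PMFs come
from solvated all-atom dynamics rather than the model potentials sampled
here, and the $\Sigma L > 150$ rule's predictive value rests on the
original simulation benchmarks, which require a full conformational-search
engine and are deliberately out of scope.

## Numerical choices and degenerate inputs

- Collinearity: a cross-product norm below $10^{-8}$ Å² makes the dihedral
  undefined; it is reported as `NA` and MD-based evaluation refuses the
  geometry ("degenerate geometry") rather than guessing. Anchors with zero
  offset sit on the alpha carbon, making the planar angles undefined
  (`NA`) while the anchor distance remains valid.
- Glycine's zero-length C&alpha;&rarr;SC axis is a hard error for
  `anchor_point()` unless a fallback axis is supplied.
- Author (PDB) numbering is preserved everywhere user-facing; internal
  storage is positional. Unresolvable residue numbers are collected and
  reported together ("mapping error"), not dropped silently.
- The structure reader keeps the first alternate location (the underlying
  \pkg{bio3d} convention), skips residues lacking a C&alpha; with a
  warning, and applies the glycine fallback (with a warning) to residues
  whose side-chain atoms are all missing.
- Test problem sizes — helices of 10–30 residues, 40–60-residue stretched
  chains, 100-trial fit batteries, 5000-sample ensembles, 50000-sample
  harmonic checks, 40–300 decoys for scoring invariants — were chosen as
  the smallest sizes at which the statistical assertions are stable; the
  whole suite is a desk-scale computation.

## Known limitations

Single chain per analysis (no inter-protein links), no nucleic acids or
ligands, no mmCIF. No second derivatives. The GDT_TS search is a heuristic
(see above). TATA's third reactive arm is not modeled; links are pairwise.
Published fitted coefficient tables for specific reagents are not bundled;
they load from JSON parameter files when available, and the reproduction
checks that depend on published experimental link tables look for them
under `inst/extdata/experimental/` (see the README there).
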