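---
title: "Voronoi structural neighboring properties: model and methods"
author: "vorbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voronoi structural neighboring properties: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vorbind)
```

# The model

Binding sites on protein surfaces are not random: the residues that end up
buried in an interface tend to carry correlated physicochemical signatures
on both sides. `vorbind` turns this into a predictor in four stages.

## Geometry: the power diagram

Every heavy atom is a weighted site of a 3D power (Laguerre) diagram, with
weight equal to the squared van der Waals radius (C 1.70, N 1.55, O 1.52,
S 1.80, P 1.80 Å, default 1.70; editable via `structure_sites(radii = )`).
The bisector of two weighted sites is a plane — the *radical plane*, at
distance $(d^2 + w_1 - w_2)/2d$ from the first center — so every cell is an
intersection of half-spaces and hence a convex polyhedron. Cells are
clipped to the sites' bounding box expanded by `padding` (default 5 Å).

Faces are annotated with their neighboring site, and their polygon areas
aggregate per residue into `total` (all faces against other residues or the
boundary; faces between atoms of the *same* residue are internal and
excluded), `surface` (faces against the box boundary, read as solvent
exposure), and `contact(x, y)` per partner residue. The identity
`surface + Σ contact = total` is structural, and face areas are symmetric:
the face between cells *i* and *j* is computed independently from both
sides and agrees to well below $10^{-6}$ Å².

**Construction route.** Cells are built by direct half-space clipping
(Sutherland–Hodgman on each face plus a reconstructed cap polygon), nearest
sites first, at $O(n^2)$ overall. For the problem sizes this package
targets — single subunits of up to a few thousand heavy atoms — this is
fast (a 50-atom fixture tessellates in ~20 ms), exact, and avoids the
numerically delicate 4D-hull dualization that a regular-triangulation route
would need. Degenerate (cospherical) configurations such as perfect
lattices are handled by the clipping tolerance ($10^{-10}$ of the box
diagonal) and still tile the box to machine precision.

**Solvent model.** Instead of surrounding the protein with explicit water
sites, cells are clipped to the padded box and box-facing area counts as
solvent-exposed. This is deterministic and dependency-free, and it
preserves the semantics that matter downstream — the `surface/total` ratio
is 1 for an isolated residue, 0 for a fully buried one. It does
overestimate absolute exposed areas of convex surface patches relative to a
rolling-probe definition; only the *ratio* enters the statistics.

## The structural neighboring property

For residue features $p(x)$ — Kyte–Doolittle hydrophobicity, net formal
charge, and hydrogen-bond capacity, tabulated for the 20 standard amino
acids in `feature_table()` — the property of a surface residue blends its
own exposure-weighted feature with its Voronoi neighborhood:

$$p'(x) = \frac{surface(x)}{total(x)}\,p(x) +
  \sum_{y:\,contact(x,y)>0} \frac{surface(y)}{total(y)}\,p(y).$$

A *surface residue* is one with nonzero solvent-exposed face area; only
surface residues receive profiles. Neighbors are taken from the same
protein, since the property describes an isolated subunit before pairing.
Faces below $10^{-9}$ Å² are treated as zero contact.

## Pair statistics and the energy

Across training interfaces (heavy-atom contact, strictly below 6 Å), each
feature gets a univariate normal $F(x)$ fitted on the pooled $p'$ of
interface residues, and a bivariate normal $F(x_1, x_2)$ fitted on property
pairs. Fits are maximum-likelihood moments. Training pairs enter in both
orders (interfaces carry no canonical side ordering), which forces
$\mu_1 = \mu_2$, $\sigma_1 = \sigma_2$; `fit_bivariate_normal(symmetrize =
FALSE)` exposes the raw asymmetric fit. The per-pair energy is

$$s_f(x_1, x_2) = -k_BT\,\ln\frac{F(x_1, x_2)}{F(x_1)F(x_2)}, \qquad
  S = \sum_f w_f\, s_f,$$

with $k_BT = 1$ (the threshold `s_th` is then on the same dimensionless
scale), equal feature weights $w_f = 1/3$ by default, and all densities
floored at $\varepsilon = 10^{-12}$ so tail evaluations stay finite. When
the fitted joint factorizes ($\rho = 0$ with matched marginals) the energy
is identically zero; positive association makes matched pairs score
negative. Models serialize to JSON at 17 significant digits, which
round-trips IEEE doubles exactly.

The printed pair energy can be read per pair or summed over all interface
pairs; `pair_energy()`/`score_all_pairs()` implement the per-pair reading
used for extraction, and `neighborhood_energy()` the interface-summed
reading used for docking.

## Extraction

All surface-residue cross pairs are scored; pairs with $S \le s_{th}$ are
harvested (the harvested set is monotone non-decreasing in $s_{th}$, which
is why recall and false-positive rates rise together as the threshold is
relaxed). The neighborhood update

$$S'(x_1,x_2) = S(x_1,x_2)
 + \sum_{dis(x_1,r_i)\le 10} \frac{S(r_i,x_2)}{dis(x_1,r_i)}
 + \sum_{dis(x_2,r_j)\le 10} \frac{S(x_1,r_j)}{dis(x_2,r_j)}$$

(Cα distances, inclusive bound, self-terms excluded, $r_i$ over all scored
residues of the same protein) reinforces spatially coherent signals.
Residues are then ranked by their *minimum* $S'$ over their pairs — the
most favorable pair a residue participates in is what marks it as
interface-like — with ties broken lexicographically, and the `top_k`
(default 100) carried into clustering. Within each protein separately,
residues within 10 Å Cα distance are connected and the connected components
form patches; components smaller than `min_patch_size` (default 3) are
discarded as weak signals. "Strongly connected components" on this
undirected graph are ordinary connected components.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| contact cutoff | 6 (strict <) | Å | heavy-atom interface definition (training) |
| evaluation cutoff | 6 (inclusive ≤, any atom) | Å | CAPRI contact rule |
| `padding` | 5 | Å | tessellation box margin |
| `s_th` | 0 | kBT | harvest threshold; larger = more permissive |
| `update_radius` | 10 | Å | neighborhood-update sphere |
| `edge_radius` | 10 | Å | patch-graph edges |
| `min_patch_size` | 3 | residues | weak-patch discard |
| `top_k` | 100 | residues | ranked residues kept for clustering |
| `kBT` | 1 | — | energy scale |
| `epsilon` | 1e-12 | — | density floor |

The two contact rules deliberately differ: training interfaces use heavy
atoms and strict inequality, evaluation contacts use any atom and an
inclusive bound. Both knobs are exposed on `heavy_atom_contacts()` and
`eval_contacts()`.

# Synthetic data: what it emulates, what it does not

`make_toy_complex()` builds two pseudo-residue chains (idealized 5-atom
residues: N, CA, C, O, CB) with a *planted* interface: a contiguous block
of residue pairs brought within heavy-atom contact (< 6 Å) while all other
cross pairs stay beyond 8 Å, verified against `heavy_atom_contacts()` at
construction. Residue spacing is 9.5 Å so each chain is a single connected
component under the 10 Å patch graph, mirroring the spatial contiguity of
real interfaces. By default both members of a planted pair draw the *same*
residue type from a spread composition, planting the positive cross-
interface association the statistics are designed to detect;
`sample_property_pairs()` plants the same structure directly at the
distribution level (correlated pairs vs product-of-marginal decoys).

What the toys do **not** emulate: real packing density (residues are
isolated pseudo-clusters, so surface ratios are high), side-chain
chemistry, backbone connectivity constraints, or the composition biases of
real interfaces. Passing tests therefore demonstrate the *mechanics* of
the pipeline — geometry exactness, statistical recovery, monotonicity,
ranking behavior — not predictive performance on real complexes, which
depends on training on large structure sets outside this package's test
scope. Problem sizes in the test suite and acceptance script (10–20
residues per chain, 100 tessellation fixtures of 5–50 atoms, $10^4$
property samples, $10^6$–$10^7$ Monte-Carlo points, 8-pose sets) were
chosen as the smallest sizes at which each property is statistically
unambiguous.

# Numerical choices

- **Clipping tolerance** $10^{-10}\times$ box diagonal; cap-face vertices
  deduplicated at $10\times$ that. Faces under $10^{-14}$ Å² are dropped
  as noise; contact gating uses $10^{-9}$ Å².
- **Cell volumes** via the divergence theorem over outward-oriented faces;
  conservation ($\sum$ cells = box) holds to ~$10^{-14}$ relative.
- **Kabsch superposition** via SVD with determinant sign correction;
  collinear references are rejected. Ties in pose ranking keep input
  order; residue-rank ties break lexicographically by (side, chain, id).
- **P-value** computed as a log-space binomial upper tail
  (log-sum-exp over `lchoose` terms), exact against enumeration for
  $N \le 12$ and against `pbinom`.
- **Self-distance guard**: the neighborhood update zeroes the Cα
  self-distance diagonal explicitly before inverting distances, since
  floating-point cancellation can make $|x-x|$ of order $10^{-6}$ rather
  than 0.
- **Degenerate inputs**: duplicate tessellation sites, zero-variance
  features, rank-deficient coefficient designs, empty contact sets and
  missing Cα/backbone atoms all produce typed errors or explicit warnings
  rather than silent results.

# Design choices on genuinely open points

- **Marginals** are fitted on interface residues only (the distribution the
  energy compares against), not all surface residues.
- **One energy from three features**: per-feature log-odds are combined
  with configurable weights (default equal) rather than thresholding each
  feature separately; both per-feature and combined values are available
  from `pair_energy(per_feature = TRUE)`.
- **Neighborhood update range**: $r_i$ ranges over all residues with
  computed scores against the partner, not only previously harvested ones.
- **Docking term** uses $S$ per pair by default (`use_update = TRUE`
  switches to $S'$).
- **Amino-acid energy** reads "constructed by probabilities" as a negative
  log-likelihood of interface residue types, with add-one smoothing in
  `fit_aa_probs()` so every type stays scoreable.
- **Coefficient fitting** is ordinary least squares on pose labels;
  π–π stacking, dihedral-angle and side-chain packing terms are plugin
  slots (`energy_model()` accepts any `function(pose)`), since their
  parameterizations live in external force fields and tools.
- **Altlocs** resolve to highest occupancy (ties → 'A'); insertion codes
  are part of the residue key; MSE-type modified residues map to parents.

# Known limitations

- The box-clip solvent model is not a probe-based accessible surface;
  absolute surface areas are geometry-of-the-box dependent (ratios are
  what the method uses). An explicit solvent-shell mode would be the
  natural extension for sensitivity analysis.
- Gaussian marginals/joints are a modeling assumption; heavy-tailed or
  multimodal property distributions would call for mixtures, which are out
  of scope.
- The predictor is partner-specific by construction (it scores pairs of
  proteins); it does not predict binding sites for a protein in isolation.
- Pose generation, side-chain repacking and SVM-based final selection are
  outside the package: `rank_poses()` re-scores externally supplied poses.
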