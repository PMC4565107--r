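# vorbind

Prediction of protein–protein binding sites from the **structural
neighboring property** of surface residues, computed on a weighted Voronoi
(power/Laguerre) tessellation of heavy atoms, plus a docking-pose re-scorer
and a CAPRI-style evaluation suite. The package is aimed at structural
bioinformaticians who want a transparent, statistics-based interface
predictor and a fully synthetic, deterministic test bed for it.

## The method

**Geometry.** All heavy atoms of a protein are treated as weighted sites of
a 3D power diagram: atom *i* with center *c_i* and weight *w_i = r_i²*
(squared van der Waals radius) owns the cell
`{ p : |p − c_i|² − w_i ≤ |p − c_j|² − w_j  ∀j }`,
clipped to a padded bounding box. Summing polyhedral face areas per residue
gives `contact(x, y)` (area shared by residues *x* and *y*), `surface(x)`
(area facing the solvent boundary) and `total(x)`, with
`surface + Σ contact = total` holding exactly.

**Structural neighboring property.** For each of three physicochemical
features *p(x)* (Kyte–Doolittle hydrophobicity, net formal charge,
hydrogen-bond capacity), the property of a surface residue *x* blends its
own exposure-weighted feature with those of its Voronoi contact neighbors:

```
p′(x) = surface(x)/total(x) · p(x) + Σ_{y : contact(x,y) > 0} surface(y)/total(y) · p(y)
```

**Pair statistics.** Over training interfaces, a univariate normal *F(x)*
models p′ on one side and a bivariate normal *F(x₁, x₂)* models p′ pairs
across the interface. The effective free energy of a residue pair is the
log-odds

```
S(x₁, x₂) = −k_B T · ln [ F(x₁, x₂) / (F(x₁) · F(x₂)) ]
```

combined over the three features with configurable weights; negative values
mean the pair's properties co-occur across interfaces more than chance.

**Extraction.** Pairs with `S ≤ s_th` are harvested as interacting
residues; each pair energy is reinforced by spatial neighbors within a
10 Å Cα sphere (`S′ = S + Σ S(r_i, x₂)/dis(x₁, r_i) + Σ S(x₁, r_j)/dis(x₂, r_j)`);
residues are ranked by their best S′, clustered into connected components
under a 10 Å Cα graph, and weak patches discarded. The predicted patches are
the binding sites.

**Docking & evaluation.** The same statistics yield an interface-summed
neighborhood energy and an amino-acid composition energy, combined linearly
(least-squares coefficient fitting, plugin slots for further terms) to rank
candidate poses. Predictions are assessed with F_nat, F_non-nat, interface
RMSD (Kabsch superposition of interface backbones) and a binomial-tail
binding-site P-value.

## Worked example

Everything below is synthetic and deterministic — no external data needed.

```r
library(vorbind)

# four training complexes with planted interfaces; fit the statistics
train <- lapply(1:4, function(s)
  make_toy_complex(n_res_a = 12, n_res_b = 12, n_contact_pairs = 5,
                   seed = 500 + s)$complex)
model <- fit_model(train, min_pairs = 10)
model
#> vb_model (kBT = 1 )
#>   hydrophobicity w=0.333 marginal N(2.242, 3.175) joint mu=(2.242, 2.242) sd=(3.175, 3.175) rho=0.756
#>   electrostatic  w=0.333 marginal N(-0.321, 0.401) joint mu=(-0.321, -0.321) sd=(0.401, 0.401) rho=0.662
#>   hbonds         w=0.333 marginal N(5.302, 1.365) joint mu=(5.302, 5.302) sd=(1.365, 1.365) rho=0.310

# predict the interface of a held-out complex
toy <- make_toy_complex(n_res_a = 12, n_res_b = 12, n_contact_pairs = 4, seed = 601)
res <- predict_interface(toy$complex$subunits$A, toy$complex$subunits$B,
                         model, vb_config(s_th = 5, top_k = "all"))
res$patches
#> vb_patchset: 22 residues in 3 patch(es)
#>   A1: 12 residues, best S' -0.520
#>   B1: 6 residues, best S' -0.520
#>   B2: 4 residues, best S' -0.492

planted <- unique(c(toy$planted$res_a, toy$planted$res_b))
length(intersect(res$patches$patches$reskey, planted)) / length(planted)
#> [1] 1
```

The positive correlations (rho 0.31–0.76) are the planted association the
training toys carry: residues facing each other across an interface have
matched properties, so their joint density exceeds the product of marginals
and their pair energy S is negative. At the permissive threshold the
predictor recovers the entire planted interface (recall 1), in three
patches whose best members score lowest.

A shell interface wraps the same pipeline
(`inst/scripts/vorbind predict --receptor A.pdb --ligand B.pdb --model model.json ...`);
`vorbind pvalue --n 10 --N 10 --m 50 --M 100` prints the binomial-tail
P-value (here 2⁻¹⁰ ≈ 0.0009765625).

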