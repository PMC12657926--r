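# braintopo

Graph-theoretic staging features from grayscale images. braintopo converts
an image into a *pixel graph* — vertices are pixels, edges join pixels of
similar brightness — summarizes the graph with six distance-based
topological indices, normalizes them against matched Watts–Strogatz (WS)
small-world ensembles, and classifies multi-stage labels (e.g. dementia
stages 0–3 from structural MRI) from the resulting six-feature vectors.
It is aimed at researchers studying brain-network organization who want
interpretable, graph-invariant features rather than black-box image models.

## The model in brief

**Image → graph.** With `Lum(p)` the luminance of pixel `p`, the brightness
distance matrix is `L(p,q) = |Lum(p) − Lum(q)|`, min–max normalized to
`L_n ∈ [0,1]`; pixels are adjacent iff `1 − L_n(p,q) ≥ τ` (default
`τ = 0.95`). Analysis runs on the largest connected component.

**Graph → features.** For each edge `rs`, `α_r` and `α_s` count the
vertices strictly closer to each endpoint. The six indices are

| index | formula |
|---|---|
| Szeged | `Sz = Σ_e α_r·α_s` |
| Graovac–Ghorbani | `ABC = Σ_e √((α_r+α_s−2)/(α_r·α_s))` |
| Padmakar–Ivan | `PI = Σ_e (α_r+α_s)` |
| Mostar | `MO = Σ_e |α_r−α_s|` |
| normalized Graovac–Ghorbani | `NGG = Σ_e 1/√(α_r·α_s)` |
| Wiener | `W = Σ_{pairs} ρ(r,s)` |

`MO = 0` exactly characterizes distance-balanced graphs (the unrewired WS
ring lattice is one, and the package proves it to itself by BFS).

**Features → scale.** Each graph's index vector is divided by the mean
vector of a matched WS ensemble (same `v`, `δ` ≈ mean degree, rewiring
probability 0.25), the analogue of `C/C_rand` small-world normalization.

**Scale → stages.** SMOTE-balanced, stratified K-fold cross-validation over
four classifier families (decision tree, multinomial logistic regression,
RBF-kernel SVM with σ = 1, and 2- or 4-hidden-layer neural networks trained
with categorical cross-entropy).

The package also ships the WS machinery on its own: sequential-rewiring
graph generation, replicate ensemble scans over the rewiring probability,
and a closed-form lattice partition count audited against a BFS oracle
(`theorem1_validate()` — the `γ < u` branch of the printed formula is known
to disagree with BFS at e.g. `(v, δ, u) = (10, 4, 2)`, and the package
reports rather than hides this).

## Worked example

```r
library(braintopo)

# six indices of the 3-vertex path a-b-c
p3 <- make_graph("path", size = 3)
compute_index_vector(p3)
#>       Sz      ABC       PI       MO      NGG        W
#> 4.000000 1.414214 6.000000 2.000000 1.414214 4.000000

# the unrewired WS lattice is distance-balanced, with a known Szeged value
set.seed(1)
ensemble_indices(50, 10, p = 0, reps = 1)$mean[c("Sz", "MO")]
#>    Sz    MO
#> 50250     0

# ensemble scan over the rewiring probability: where is each index extreme?
sc <- extremum_scan(50, 10, p_grid = seq(0, 1, 0.05), reps = 200, seed = 1)
sc$argext[sc$argext$index %in% c("MO", "NGG"), ]
#>   index p_max p_min
#> 4    MO  0.05  0.00
#> 5   NGG  0.05  0.30

# end-to-end on synthetic 4-class images (50 per class, 32x32)
ds  <- make_dataset(n_per_class = 50, seed = 101)
rep <- run_full(run_config(seed = 101), dataset = ds)
rep$mean_metrics
```

Reading the output: the path's Mostar index 2 comes from its two edges,
each splitting the three vertices (1, 2) with no ties; the lattice's
`MO = 0` certifies distance balance, and `Sz = 50250` matches the
closed-form partition counts; the scan shows the mean Mostar curve peaking
at the first nonzero rewiring probability (0.05) while NGG attains an
interior minimum at 0.30. The final run prints five-fold cross-validated
metrics of the 4-hidden-layer network on the synthetic fixture; accuracies
far above the 0.25 chance rate confirm that class-dependent graph structure
survives the whole pipeline (mean accuracy 0.945 under this seed).

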