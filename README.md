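# scPanelDesign

Targeted single-cell spatial transcriptomics assays (MERFISH, seqFISH+ and
related FISH-based technologies) measure a fixed panel of *d* genes, so the
panel must be designed before the experiment — typically from an annotated
scRNA-seq reference. scPanelDesign selects that panel by *embedded feature
selection*: a small neural classifier learns to predict cell types through a
one-to-one selection layer, and a custom regularizer simultaneously pushes
the selection weights to 0/1, pins the effective panel size at *d*, rewards
inclusion of user-prioritized genes (e.g. easy-to-probe genes, pathway
genes), and keeps receptor–ligand complex members together. It is aimed at
groups designing probe panels who have a labelled scRNA-seq reference of the
tissue.

## Model

Given log-normalized expression **x** ∈ ℝⁿ and cell labels *y* ∈ {1,…,c},
the network computes **w** ∘ **x** (a one-to-one selection layer), feeds it
through dense ReLU layers of 32 and 16 units, and predicts classes with a
softmax. Training minimizes

    J(θ) = l(θ) + λ₀ R(w) + λ₁ Σₖ ‖W⁽ᵏ⁾‖²

where l(θ) is the mean cross-entropy, the last term is dense-layer weight
decay, and the regularizer is

    R(w) = Σᵢ |wᵢ||wᵢ − 1|                    (push weights to 0 or 1)
         + α · | ‖w‖₁ − d |                   (effective panel size = d)
         + β · Σ_{i∈G} pᵢ (1 − min(|wᵢ|, 1))  (include prioritized genes)
         + γ · Σ_{(i,j)∈C} | |wᵢ| − |wⱼ| |    (keep complex pairs together)

with defaults α = 1.5, β = 0.2, γ = 0.5, λ₀ = 1, λ₁ = 0.01. Priorities pᵢ ∈
[0, 1] are user-supplied; complexes are expanded to all gene pairs, one
member of each otherwise-unprioritized pair receiving priority 1. After
training (Adam, 100 epochs by default), the *d* genes with the largest |wᵢ|
form the panel. The size penalty can optionally fire only when the weight
sum *exceeds* d (`exceed_only = TRUE`), allowing panels smaller than the
budget.

The package also provides the standard scRNA-seq preprocessing the model
consumes (filter → total-count normalize + log1p → highly-variable-gene
selection → covariate regression → unit-variance scaling with clipping →
per-type cell cap), the panel evaluation protocol (75:25 split, k-NN
classifier, accuracy / macro F1 / confusion matrix), and a
negative-binomial simulator with planted markers, co-expression modules and
complex pairs for testing the whole pipeline offline.

## Worked example

Design a 15-gene panel on simulated data with 5 cell types, 3 exclusive
markers each and 200 noise genes:

```r
library(scPanelDesign)

sim <- simulate_panel_data(synthetic_spec(seed = 1))
pp  <- preprocess_pipeline(sim$counts, sim$labels,
         preprocess_config(min_genes_per_cell = 50, hvg = FALSE,
                           regress = FALSE, seed = 1))

model <- train_model(pp$x, pp$labels, panel_config(d = 15), seed = 0)
model
#> Panel-design model: 215 genes, 5 cell types
#>   target panel size d = 15  |w|_1 = 14.9
#>   final loss: 13.144 after 100 epochs

panel <- select_panel(model)
head(panel, 5)
#>   rank gene_id    weight prioritized complex_id
#> 1    1   MK5_1 0.4448840       FALSE         NA
#> 2    2   MK4_3 0.4332621       FALSE         NA
#> 3    3   MK4_2 0.4324947       FALSE         NA
#> 4    4   MK3_3 0.4321358       FALSE         NA
#> 5    5   MK1_1 0.4232850       FALSE         NA

truth_recovery_score(panel, sim$truth)
#> [1] 1

knn_evaluate(panel, pp$x, pp$labels, k = 5, seed = 1)
#> k-NN evaluation (k = 5, panel size = 15, 250 test cells)
#>   accuracy: 0.9880   macro F1: 0.9880
```

The trained ‖w‖₁ sits at 14.9 ≈ d, the panel contains all 15 planted
markers (recovery 1.0), and a k-NN classifier restricted to those 15 genes
classifies held-out cells with 98.8% accuracy and macro F1. To prioritize
genes, pass `priorities = c(GENE1 = 1, GENE2 = 0.5, ...)` to
`panel_config()`; to request complexes, run their gene lists through
`encode_complexes()` and pass the resulting `pairs` and `priorities`.

The same pipeline is scriptable from a shell via `inst/cli/scpaneldesign.R`
with subcommands `simulate`, `preprocess`, `design`, `evaluate` and
`run-all` (see the flag reference at the top of that file).

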