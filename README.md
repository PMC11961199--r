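# catsite

Catalytic residue prediction from enzyme structure graphs, with
contrastive enzyme-class pre-training and downstream mutation-tolerance
triage.

## What it does and for whom

Catalytic residues — the few amino acids that perform the chemical step
in an enzyme's active site — are expensive to annotate experimentally.
`catsite` is for structural bioinformaticians who have an enzyme
structure (PDB/mmCIF), evolutionary profiles (PSI-BLAST PSSM, HMMER3
profile) and optionally per-residue language-model embeddings, and want:

* per-residue **catalytic propensities** from a graph neural network over
  the structure's Cα contact graph;
* residue-level **evaluation metrics** (precision/recall/F1, Best-F1,
  AUC, AUPR) and the **spatial-cohesion analysis** of catalytic sites;
* **MAVE variant triage**: binarize deep-mutational-scanning scores at a
  three-Gaussian mixture intersection and classify residues as wild
  type-like (WTL) or functional-loss (FL) from distance-to-predicted-
  catalytic-site and solvent accessibility.

A fully synthetic data generator plants spatially clustered catalytic
residues with realistic feature signals, so the entire pipeline trains,
predicts and evaluates offline with no external databases.

## The model

A chain of *n* residues is an attributed graph *G = (V, A, X)* with
binary Cα–Cα contact adjacency *A* (default cutoff 10 Å) and features
*X = (X_L, X_G, X_A)*: a 50-column evolutionary block (sigmoid-normalized
PSSM ‖ profile-HMM), a 1024-column embedding block, and a 14-column
averaged atomic block. Three graph-convolution layers propagate
*H⁽ⁱ⁾ = ReLU(D̃^(−1/2)(A + Iₙ)D̃^(−1/2) H⁽ⁱ⁻¹⁾ W⁽ⁱ⁾)* from
*H⁽⁰⁾ = [X_L, X_A]* (width θ = 64); the concatenation [H₁, H₂, H₃] is
fused with the embedding branch by an MLP into *X_E ∈ R^(n×d)* and
reduced to a two-channel softmax propensity per residue.

Training mixes a contrastive objective with supervised learning under a
dynamic schedule λ(epoch): pooled enzyme representations *z* are pulled
toward their enzyme-class cluster center and pushed from a sampled
other-class center by the hinged triplet margin loss
*max(0, ‖z_a − z_p‖₂ − ‖z_a − z_n‖₂ + α)* with α = 1, while a
class-weighted cross-entropy drives the residue head; λ decays linearly
to 0 over the first 30% of epochs. Forward pass, backpropagation and
Adam are implemented directly on base-R matrices and verified against
numerical gradients and brute-force oracles in the test suite.

## Worked example

```r
library(catsite)

cfg <- synth_config(n_enzymes = 40, n_test = 10, seed = 1)
run <- end_to_end(cfg, out_dir = tempfile(),
                  train_config = catsite_train_config(epochs = 20, seed = 1))
unlist(run$metrics[c("aupr", "auc", "best_f1", "prevalence")])
#>      aupr       auc   best_f1 prevalence
#> 0.4058372 0.9357263 0.5309735 0.0500000
```

With only 40 training enzymes the model already ranks held-out catalytic
residues far above the 5% prevalence baseline (AUPR 0.41 ≈ 8× chance;
AUC 0.94); at the full benchmark size (200 enzymes) AUPR exceeds 0.6.
The planted active sites are spatially cohesive, as in real enzymes:

```r
b <- synth_dataset(cfg, n = 10)
d <- distance_to_nearest_catalytic(b[[1]]$record$ca_coords,
                                   b[[1]]$record$catalytic_mask)
summarize_distances(d, by = "is_catalytic")
#>   is_catalytic     n    q1 median    q3
#> 1 FALSE           95  7.79  12.8  17.1
#> 2 TRUE             5  3.78   3.84  4.73
```

Catalytic residues sit ~4 Å from their nearest fellow catalytic residue;
non-catalytic residues sit ~13 Å from the site. Variant triage on the
same enzyme:

```r
vt <- synth_variants(b[[1]]$record, cfg)
cut <- gaussian_cutoff(vt$score)     # mixture intersection: 0.02
calls <- classify_variants(vt, as.numeric(cut))
head(calls$residues, 2)
#>   residue_number n_wtl  n_fl call
#> 1 1                  5     0 WTL
#> 2 10                 4     1 WTL
```

A command-line wrapper with `synth` / `features` / `train` / `predict` /
`evaluate` / `triage` / `end-to-end` subcommands is installed at
`inst/cli/catsite`.

## Package layout

* `R/structure_io.R` — PDB/mmCIF parsing, contact maps, Shrake–Rupley
  SASA, the 14-channel atomic descriptor, graph assembly
* `R/profile_features.R` — PSSM/HMMER3 parsers, sigmoid normalization,
  embedding loader
* `R/network.R` — model, normalized adjacency, GCN forward, fusion head,
  checkpoints
* `R/training.R` — triplet loss, cluster centers, schedule, backprop,
  Adam
* `R/evaluation.R` — metrics and distance analyses
* `R/triage.R` — mixture cutoff, WTL/FL calls, triage tree
* `R/synthetic_data.R` — generator and fixture emitter
* `vignettes/catalytic-residue-prediction.Rmd` — methods and design
  rationale
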