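# dtifuse

Tri-modal drug–target interaction (DTI) prediction in R: each drug and each
protein is described by three complementary views — **structure** (a graph
isomorphism network over the molecular graph for drugs; a multi-scale CNN
over the amino-acid sequence for proteins), **sequence** (frozen
language-model-style embeddings, with a deterministic k-mer provider for
fully offline use), and **relation** (a GATv2 encoder over 2-hop subgraphs
of a drug–drug similarity network and a protein–protein interaction
network). The three views are projected into a shared space, aligned with a
bidirectional cross-modal contrastive objective, fused with soft attention
plus bidirectional cross-attention, and classified into an interaction
probability.

## Who this is for

Computational drug-discovery researchers who want a tested, self-contained
reference implementation of attention-fused tri-modal DTI prediction —
including dataset loaders (interaction tables, STRING-style PPI edge lists),
cold-start evaluation splits, ranking metrics, and a synthetic benchmark
generator with planted ground truth, so the entire pipeline runs and is
testable without downloading any external dataset or pretrained model.

## The model

For a drug *d* and protein *t* with modality embeddings
`Z_struct, Z_seq, Z_rel`:

1. **Structure.** Drugs: atoms carry 79-dimensional feature vectors (atom
   type, degree, hydrogen count, implicit valence, aromaticity); two GIN
   layers `h_i ← MLP((1+ε)·h_i + Σ_{j∈N(i)} h_j)` followed by a mean over
   atoms. Proteins: learnable token embeddings through three parallel
   convolution branches (kernel sizes 1, 3, 5; three layers each), global
   max-pooling per branch, concatenation, and a linear map.
2. **Sequence.** Frozen per-entity embeddings (mean-pooled token embeddings
   from a pretrained provider, a precomputed matrix, or the package's
   deterministic k-mer provider).
3. **Relation.** A per-node top-k sparsified network (cosine similarity for
   drugs, PPI confidence for proteins), 2-hop subgraph extraction around
   each entity, two GATv2 layers
   `α_ij = softmax_j a'·LeakyReLU(W_l h_i + W_r h_j)`,
   `h_i ← ELU(Σ_j α_ij W_r h_j)`, and a mean over subgraph members.
4. **Alignment.** Each modality is projected with
   `GELU(Z W₁ + B₁) W₂ + B₂`; a bidirectional contrastive loss (temperature
   τ = 0.1) pulls each entity's structure and relation projections toward
   its sequence projection, with other entities *within the same modality*
   as negatives.
5. **Fusion + classification.** Soft attention computes a convex combination
   of the three projections per entity; bidirectional cross-attention with
   residuals exchanges information between the pair
   (`z_D ← z_D + Attn(D→T)`), and an MLP with a sigmoid head yields the
   interaction probability. Training minimizes
   `BCE + λ·L_contrast` (λ = 1e-4) with AdamW (lr 5e-4, batch 16,
   dropout 0.1), selecting the checkpoint with the best validation AUROC.

Because no deep-learning framework is available in this R stack, the
trainable pipeline runs on a compact reverse-mode automatic-differentiation
engine inside the package (`R/autodiff.R`, with compiled gather/scatter
kernels in `src/ops.cpp`); gradients are verified against finite differences
in the test suite.

## Worked example

```r
library(dtifuse)

# a self-contained synthetic benchmark: molecules, proteins, embeddings,
# a PPI network, and planted labels with a known signal structure
bench <- synthetic_benchmark(synthetic_spec(n_drugs = 30, n_proteins = 40,
                                            n_pairs = 1200,
                                            protein_length_range = c(48, 96),
                                            seed = 1))
mean(bench$dataset$records$label)                      # 0.5 positive rate
auroc(bench$truth$logit_true, bench$dataset$records$label)  # oracle ceiling

split <- random_split(bench$dataset, seed = 1)         # 7:1:2
cfg <- dti_config(gin_dim = 16, cnn_dim = 16, gat_dim = 16, proj_dim = 16,
                  soft_hidden = 16, max_epochs = 30, seed = 1)
fit <- train_dti(bench$dataset, bench$drug_embeddings,
                 bench$protein_embeddings, split, cfg,
                 ppi_edges = bench$ppi_edges)
fit$test_metrics$auroc
```

On this benchmark (seed 1) the positive rate is 0.50 and the planted-signal
oracle reaches AUROC 0.962; the tri-modal model reaches test AUROC 0.651
after 30 epochs at this small scale, and averaged over five seeds the
tri-modal model scores 0.727 against 0.690 / 0.666 / 0.533 for the
structure-only / sequence-only / relation-only ablations
(`ablate_dti(..., variant = "sequence_only")` etc.) — the tri-modal
advantage reflects the complementary signal planted across the three views.
At the larger 60 × 80 reference size (2000 pairs) the tri-modal model
reaches test AUROC 0.76 within the 30-epoch budget against an oracle
ceiling of 0.96, still improving when the epoch cap is reached.

Real data enter through `load_interaction_table()` (TSV/CSV with labels or
Kd affinities — Kd < 30 nM is a positive), `load_ppi_edges()` (STRING-style
edge lists, subset to the dataset's proteins), and
`load_precomputed_embeddings()` for language-model embeddings computed
elsewhere.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/dtifuse.R simulate --out data/ --n-drugs 60 --n-proteins 80 --seed 1
Rscript inst/cli/dtifuse.R train --data data/ --out run/ --max_epochs 30 --seed 1
Rscript inst/cli/dtifuse.R coldsplit --data data/ --mode unseen_drug --out split.jsonl
Rscript inst/cli/dtifuse.R ablate --data data/ --variant sequence_only
Rscript inst/cli/dtifuse.R sweep --data data/ --param tau --values 0.05,0.1,0.5
```

## Package layout

- `R/featurize.R` — SMILES → molecular graphs (via OpenBabel/ChemmineOB),
  interaction-table and PPI loaders, tokenization
- `R/seq_providers.R` — frozen sequence-embedding providers
- `R/relational.R` — similarity/PPI networks, top-k sparsification, 2-hop
  subgraphs, GATv2
- `R/struct_encoders.R` — GIN and the multi-scale protein CNN
- `R/alignment.R` — projection and the contrastive objective
- `R/fusion.R` — soft attention, cross-attention, classifier
- `R/metrics.R`, `R/splits.R` — AUROC/AUPRC/F1/accuracy, random / five-fold
  / cold-start splits
- `R/synthetic.R` — the synthetic benchmark generator
- `R/autodiff.R`, `src/ops.cpp`, `R/model.R`, `R/train.R` — the autodiff
  engine, the batched model graph, and the AdamW training loop
- `vignettes/dtifuse-methods.Rmd` — the methods vignette
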