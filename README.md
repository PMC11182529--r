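# ddigcl — dual-view graph contrastive learning for drug–drug interaction prediction

`ddigcl` predicts drug–drug interactions (DDIs) by fusing two views of a
drug pair and training them to agree:

* a **molecular-structure view**: each drug's SMILES becomes an atom-level
  graph (78-dim atom features via RDKit) encoded by a GCN whose weights
  are *shared* between the two drugs, pooled by max readout and
  concatenated into `Z_C`;
* a **network-topology view**: the pair's H-hop common-neighbor subgraph
  (nodes carry 166-bit MACCS fingerprints, plus a virtual node connected
  to everything whose feature is the mean of the rest) encoded by a GCN;
  the virtual node's final-layer feature is `Z_T`.

A projection aligns the widths, a batch contrastive loss pulls each
sample's two views together (temperature-scaled cosine softmax), and a
fusion MLP scores `[Z_C + Z_T, Z_C ⊙ Z_T, Z_C, Z_T]`. The training
objective is

```
l_total = α·l_contr + β·l_const + λ·l_sub + η·l_joint      (α=0.1, β=λ=η=1)
```

where `l_sub`, `l_const`, `l_joint` are cross-entropies of the topology,
structure and fusion heads. The package ships the full experimental
harness: 8:1:1 random splits at 1:1 negative sampling, ablation variants,
edge-removal robustness sweeps, drug-wise/pairwise cold-start CV, AUC /
AUPR / F1 and MAP / MRR / HIT@K metrics, and a synthetic-data generator
that plants learnable signal in both views so everything runs end-to-end
with no downloads. Intended users: computational drug-discovery /
cheminformatics researchers who want a transparent, fully testable
reference implementation of this class of model in R.

## Requirements and installation

Pre-installed R packages: `Matrix`, `Rcpp` (+ `RcppArmadillo` to build),
`glmnet`, `jsonlite`. Molecular parsing needs a `python` on the PATH with
RDKit (`inst/python/mol_features.py` is invoked in batch; set
`options(ddigcl.python=...)` or `DDIGCL_PYTHON` to point elsewhere).

```sh
R CMD INSTALL .                       # compiles the float32 training kernel
Rscript -e 'testthat::test_dir("tests/testthat", package = "ddigcl", load_package = "installed")'
```

## Worked example

```r
library(ddigcl)

fx   <- make_fixture_data("small")          # 100 drugs, 4 scaffold classes
mols <- featurize_drugs(fx$library)         # RDKit: graphs + MACCS bits
#> <ddi_mols> 100 drugs featurized (maccs fingerprints), 0 dropped

samples <- make_pair_dataset(fx$network, seed = 1)   # positives + 1:1 negatives
split   <- random_split(samples, seed = 1)           # 8:1:1
model   <- ddi_train(split, mols,
                     default_config(epochs = 10, hop_count = 1),
                     seed = 1, verbose = TRUE)
#> epoch   1 | total 2.6533 contr 5.4861 const 0.7007 sub 0.6936 joint 0.7105 | val auc 0.6960 aupr 0.7143 f1 0.6742
#> ...
#> epoch   6 | total 2.3198 contr 5.4727 const 0.6150 sub 0.6078 joint 0.5497 | val auc 0.8313 aupr 0.8417 f1 0.7826
#> ...
#> epoch  10 | total 2.0806 contr 5.4551 const 0.5522 sub 0.5112 joint 0.4718 | val auc 0.8186 aupr 0.8158 f1 0.8000

pred <- predict(model, split$test, mols)   # uses the best-val-AUC checkpoint
unlist(binary_metrics(pred$score, pred$label))
#>       auc      aupr        f1 n_samples
#> 0.7922144 0.8412215 0.7912088        89
```

Reading the output: the four loss components all fall (the contrastive
term starts near `log(2·batch_size) ≈ 5.55` by construction); validation
AUC is logged per epoch and the best-AUC checkpoint is what `predict()`
uses. On the `default` 400-drug fixture a 30-epoch run reaches test AUC
≈ 0.87 in about two minutes on one CPU (the acceptance bar is 0.85); the
AUC above is lower simply because the `small` fixture and 10 epochs are
used to keep the example quick.

Protocol tools:

```r
run_ablation("no_contrastive", split, mols, default_config(epochs = 10), seed = 1)
net_attacked <- edge_attack(fx$network, 0.3, seed = 1)     # drop 30% of edges
part <- cold_start_partition(fx$network, mols$ids, cold_fraction = 0.2, seed = 1)
cold_start_eval(model, part, mols)    # frozen encoders + logistic probe
```

There is also a CLI (`inst/cli/ddigcl`): `fixture`, `train`, `evaluate`,
`ablate`, `attack`, `coldstart`, all emitting JSON.

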