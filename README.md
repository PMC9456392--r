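# strucsynergy

Predicting anticancer **drug-combination synergy** from the topology of a
protein–protein interaction (PPI) network — and nothing else.

Given (a) a PPI network, (b) drug→target-protein associations, (c) cell
line→protein associations and (d) a table of drug–drug–cell-line synergy
scores (Loewe/ZIP; only the sign is used), the package:

1. embeds every protein by **structural identity**: per-hop degree-ring
   fingerprints $s(R_k(u))$ compared with dynamic time warping under the
   ratio cost $\max/\min - 1$, accumulated into distances
   $f_k(u,v) = f_{k-1}(u,v) + \mathrm{DTW}(s(R_k(u)), s(R_k(v)))$,
   turned into a multilayer graph with weights $e^{-f_k(u,v)}$, explored by
   biased random walks (20 per node, length 80, stay-probability $q = 0.3$)
   and trained with Skip-Gram + negative sampling (window 5, $d = 64$);
2. pools protein vectors into entity features by the arithmetic mean
   $D_i = (P_1 + \dots + P_n)/n$;
3. concatenates `[drug A | drug B | cell line]` into $3d$-wide rows
   (192 columns at $d = 64$); and
4. classifies synergistic vs antagonistic with gradient-boosted trees
   (depth 7, η = 0.1, subsample/colsample 0.9, γ = 0.1) under repeated
   stratified five-fold cross-validation, reporting ACC, recall, precision,
   F1, AUC-ROC and AUC-PR, plus per-cell-line and per-tissue AUC.

It is aimed at computational biologists studying combination therapy who
want a network-only baseline: no chemical fingerprints, no expression
profiles. A seeded synthetic-study generator with planted structural roles
makes every stage testable offline.

## Worked example

```r
library(strucsynergy)

study <- make_synergy_study(seed = 1)   # synthetic: 48-protein network,
print(study)                            # 20 drugs, 8 cell lines
#> Synthetic synergy study (seed 1):
#>   network: 48 proteins, 57 interactions
#>   entities: 20 drugs, 8 cell lines
#>   records: 2000 ( 946 synergistic / 1054 antagonistic )

emb <- embed_network(study$network, dim = 64,
                     walk = walk_config(seed = 11), seed = 7)
ft  <- assemble_pairs(study$records, emb, study$drug_map, study$cell_map)
cv  <- cross_validate(ft, folds = 5, repeats = 1, seed = 5)
print(cv)
#> Cross-validation: 5 folds x 1 repeat(s), 2000 records
#>   acc       0.971 +/- 0.005
#>   recall    0.964 +/- 0.015
#>   precision 0.973 +/- 0.006
#>   f1        0.969 +/- 0.006
#>   auc_roc   0.981 +/- 0.007
#>   auc_pr    0.976 +/- 0.010
```

Held-out AUC-ROC of 0.98 means the planted, role-borne synergy signal is
almost fully recovered from network structure alone; with permuted labels
the same pipeline sits at chance (≈ 0.5). `stratified_performance(cv,
"cell")` breaks the AUC down by cell line, `stratified_performance(cv,
"tissue")` by tissue.

The one-call model interface wraps the same pipeline:

```r
fit <- synergy_fit(study$records, study$network,
                   study$drug_map, study$cell_map, seed = 1)
predict(fit, data.frame(drug_a = "D01", drug_b = "D02", cell = "C01"))
```

A thin CLI over the same functions lives at
`inst/cli/synergy_pipeline.R` (subcommands `simulate`, `embed`,
`featurize`, `train`, `evaluate`, `run-all`; YAML/JSON config).

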