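# entiresist

Identifying genomic drivers of HDAC-inhibitor resistance from expression,
copy number, networks and survival — as a tested, reusable R pipeline.

Luminal breast cancers respond to HDAC inhibition, but tumors that progress
on therapy often carry focal DNA copy-number changes whose downstream
transcriptional footprint betrays the causal gene. This package implements
the full analysis chain used to find such drivers and validates every step
on synthetic cohorts with planted ground truth:

1. **Differential expression** (`sam_permute`): SAM-style two-class
   statistic `d = (x̄_b − x̄_a)/(s + s0)` with permutation-derived expected
   order statistics, delta-band calling and FDR estimation ("FDR 0%" =
   zero median permuted exceedances).
2. **Signatures** (`cluster_genes`, `extract_signatures`,
   `score_signatures`): median-centered genes, centroid linkage on
   `1 − Pearson r`; a signature is a maximal dendrogram node with ≥ 10
   genes and node correlation > 0.5; samples are scored by the median
   expression of signature genes. Ortholog mapping and hypergeometric
   overlap tests (`map_orthologs`, `overlap_test`) support cross-species
   and gene-set interpretation.
3. **Copy number** (`segment_track`, `project_to_genes`,
   `call_gains_losses`): recursive F-statistic breakpoint detection on
   probe-level log2 ratios with a 250 kb flank rule, |z| ≥ 3 and
   |mean| ≥ 0.09 significance filters, length-weighted projection onto
   genes, and gain/loss calls at +0.25 / −0.32 (GISTIC-style −1/−2 codes
   via `categorical_loss_filter`).
4. **Driver ranking** (`propagate`, `rank_drivers`): personalized network
   propagation `r = (1−d)·g + d·T·r` where each sample's absolute
   expression shift from the reference arm personalizes the walk and mass
   flows from perturbed targets back to their regulators; percent ranks
   (top gene = 1.0) are averaged per group and reported for
   copy-number-altered genes.
5. **Survival** (`stratify_tertiles`, `logrank_test`, `cox_univariate`):
   score tertiles or deletion status, Kaplan-Meier curves, two-sided
   log-rank tests and univariate Cox regression (Breslow ties), with
   > 20-year survivors excluded by convention.

The synthetic-cohort generator (`sim_config`, `simulate_cohort`) plants a
deleted driver whose network out-neighborhood forms a coherent
up-regulated module in resistant samples and whose module score drives the
hazard — the causal chain the pipeline is meant to recover. See
`vignettes/entiresist-methods.Rmd` for models, parameters and limitations.

## Worked example

The `analysis/` scripts run the whole workflow on one simulated cohort and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1
Rscript analysis/02_differential_expression.R 1
Rscript analysis/03_signatures.R
Rscript analysis/04_copy_number.R
Rscript analysis/05_driver_ranking.R
Rscript analysis/06_survival.R
```

With seed 1 this prints:

```
cohort (seed 1): 1000 genes x 40 samples (resistant=20, treated=10, untreated=10);
  planted driver DRV1 inside chr4:[400000,600000)
SAM (s0 = 0.309, pi0 = 0.90, 200 permutations): delta 1.003 calls 70 up / 1 down
up_sig_1: 20 genes (up), node correlation 0.903
up_sig_2: 31 genes (up), node correlation 0.507
20 significant segments across 20 samples; 200 gene-level loss calls
peak loss frequency 100% in group 'resistant' at chr4:[0,590000)
group resistant  top drivers: DRV1 (1.000, chr4), G0002 (0.997, chr4), G0003 (0.992, chr4)
signature up_sig_1 tertiles: log-rank chi2 13.40 (p = 0.000251); Cox log HR per SD 1.17 (p = 7.86e-05)
DRV1 deletion (20/40 samples): log-rank chi2 11.69 (p = 0.000629); Cox log HR 1.53
```

Reading it: the one down-called gene is the planted driver itself; the
20-gene `up_sig_1` (node correlation 0.90) is exactly the planted
downstream module; every resistant sample's track yields the planted
chr4 deletion, so the driver is called lost in 20/40 samples; propagation
ranks the driver at percent rank 1.000 among altered genes in the
resistant arm; and both the signature tertiles and the deletion status
stratify survival as planted (higher score / deletion → higher hazard).

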