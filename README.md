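# neutraldiv

Neutral community assembly and phylogenetic diversification of
host-associated microbiota.

`neutraldiv` is for microbial ecologists asking two linked questions about a
host-associated community surveyed by 16S amplicon sequencing across many
hosts:

1. **How neutral is assembly?** Fit the Sloan occupancy–abundance neutral
   model, `F_i = 1 − I_d(mN·p_i, mN·(1−p_i))`, where `p_i` is a taxon's
   metacommunity relative abundance, `d` the detection limit (default
   1/rarefaction depth) and `mN` the single dispersal parameter
   (metacommunity size × immigration rate). Classify each taxon's deviation
   with exact two-tailed binomial tests on its presence/absence profile:
   *ecologically selected* (over-occurring), *neutral*, or *not ecologically
   selected* (under-occurring).
2. **Are host-restricted lineages under purifying selection?** On a
   reference phylogeny containing the study sequences as *focal* tips,
   compute each focal tip's distance to its nearest reference tip
   (`d_ref`), its observed count of closer focal neighbors (`n_obs`), a
   resampled power-law null for the expected count at that radius
   (`n_exp(r) = a·r^b`), and the diversification index
   `ADI = n_obs − n_exp`. Negative ADI flags a sparser neighborhood than
   expected — missing intermediate variants, the signature of purifying
   selection — and the package tests whether ecologically selected taxa
   have lower ADI than non-selected ones.

Supporting modules provide table conditioning (rarefaction, strict
prevalence filtering, CLR, accumulation curves), self-contained diversity
statistics (Bray–Curtis, Aitchison, unweighted/weighted UniFrac, Faith's
PD, PCoA, ANOSIM, dispersion homogeneity, rank tests), TSV/newick/FASTA
readers and writers, a synthetic-data generator with known ground truth,
and a pipeline orchestrator with a JSON manifest.

## Worked example

Simulate a study-scale world (176 taxa × 111 hosts at depth 5300,
mN = 132.49; a ~3000-tip reference tree with 16 focal clades, half of them
pruned of 60% of their tips and injected as over-occupying taxa):

```r
library(neutraldiv)

bundle <- suppressWarnings(simulate_study(seed = 42, scale = "paper"))

fit <- fit_ncm(bundle$table)
fit
#> <ncm_fit> mN = 116.6, R^2 = 0.829, d = 0.000189, N = 111 hosts, 176 taxa

cls <- classify_selection(fit, alpha = 0.05)
table(cls$category)
#>     ecologically_selected                   neutral not_ecologically_selected
#>                        35                       102                        39

recs <- adi_records(bundle$tree, n_iter = 1000, seed = 7)
cmp <- compare_adi_by_selection(recs, cls)
cmp$summary
#>                    category  n mean_adi median_adi
#> 1     ecologically_selected 29     2.59       2.41
#> 2 not_ecologically_selected 38     8.38       8.67
cmp$p_value
#> 1.14e-10

anosim(bray_curtis(bundle$table), bundle$metadata, n_perm = 999, seed = 3)
#> <perm_test> R = -0.02752, p = 0.868 (999 permutations)
```

Reading the output: the fitted dispersal parameter (116.6) recovers the
generator's 132.49 within the expected ~±20%, and the occupancy–abundance
relationship is strong (R² = 0.83). The injected over-occupying taxa are
flagged as ecologically selected; because they sit in pruned clades, their
mean diversification index (2.59) is far below the non-selected group's
(8.38), rank-sum p ≈ 1e-10 — the purifying-selection signal. ANOSIM on
Bray–Curtis shows no geographic clustering, as expected under neutral
dispersal across colonies.

On-disk pipeline, from a single config:

```r
paths <- make_fixtures(seed = 1, scale = "small", dir = "fixtures")
cfg <- pipeline_config(paths$table, paths$metadata, paths$tree, paths$focal,
                       output_dir = "out", rarefaction_depth = NULL,
                       n_perm = 999, k = 10, n_iter = 1000, seed = 1)
run_pipeline(cfg)   # writes TSV/JSON artifacts and out/manifest.json
```

A command-line wrapper lives at `inst/cli/neutraldiv.R`
(`simulate`, `run-all` subcommands).

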