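# ontokine

Plasma cytokine and chemokine ontogeny analysis by trajectory clustering.

Newborns undergo rapid immune development: across the first week of life,
plasma concentrations of cytokines and chemokines shift in coordinated
ways — interferon-axis mediators rise while birth-associated inflammatory
mediators resolve. Quantifying that ontogeny from bead-based multiplex
immunoassay (Luminex-style) plates requires a chain of careful steps, each
of which ontokine implements as a tested, pipe-friendly function:

1. **Quantification** — per-(plate, analyte) standard curves fitted by
   least squares on log10(MFI), with model selection among the
   four-parameter logistic `mfi(x) = d + (a−d)/(1 + (x/c)^−b)`, its
   five-parameter asymmetric extension, and a power-law fallback;
   detection limits from blanks (mean + 3 SD), quantification limits from
   70–130% back-calculated recovery; bead-count filtering (< 30 beads
   discarded) and censoring imputation at the limits of quantification.
2. **Normalization** — log10 transform; near-zero-variance analyte
   exclusion (frequency ratio > 95/5 and unique values < 10%); parametric
   empirical-Bayes plate (batch) correction with bridge-sample QC.
3. **Ontogeny statistics** — per-participant fold changes indexed to day
   of life (DOL) 0; exact paired Wilcoxon signed-rank tests; Holm
   step-down adjustment at a fixed family size; PCA; covariate
   association models (`value ~ covariate * visit`); volcano filtering
   (p < 0.01, |log2 FC| > 0.2).
4. **Trajectory clustering** — the core analysis: per-analyte mean
   standardized 4-point series over DOL {0, 1, 3, 7}; dynamic time
   warping (DTW) distances; complete-linkage clustering with the number
   of clusters chosen by average silhouette width; stability by bootstrap
   co-clustering consensus over resamples of 90% of participants; and an
   individual-level (no averaging) consensus as a validation methodology,
   compared by adjusted Rand index.
5. **Synthetic cohort generator** — a fully synthetic study (608
   participants sampled at DOL0 plus one follow-up at DOL 1/3/7, 41
   analytes on 7 plates with batch effects, bridge aliquots, standards
   ladders, bead counts, three floor-censored analytes, five planted
   kinetic trajectory classes) so the whole pipeline is verifiable end to
   end with ground truth.

Results come back as tibbles; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_volcano()` graphics. The methods vignette
(`vignettes/ontokine-methods.Rmd`) documents every model, default and
design decision.

## Worked example

```r
library(ontokine)

cohort <- generate_cohort(sim_config(seed = 42))
cohort
#> <ontokine_cohort> 608 participants, 41 analytes, 7 plates, 50717 plate-table rows

curves <- fit_standard_curves(cohort$standards, seed = 1)
glance(curves)
#> # A tibble: 1 × 6
#>   n_curves n_failed n_logistic4 n_logistic5 n_exponential median_sse
#>      <int>    <int>       <int>       <int>         <int>      <dbl>
#> 1      287        0         165         122             0   0.000198

conc <- assemble_table(quantify_wells(cohort$plates, curves))
norm <- normalize_table(conc)
norm
#> <ontokine_norm> 38 retained analytes (3 excluded), 1237 samples

si <- sample_table(read_metadata(cohort$metadata))
#> Metadata: 608 participants; follow-ups DOL1 n=202, DOL3 n=206, DOL7 n=200.

consensus <- bootstrap_consensus(norm, si, B = 200, seed = 2)
consensus
#> <ontokine_consensus: trajectory> k=5, B=200, average consensus=100.0%

validation <- individual_consensus(norm, si, B = 200, k = consensus$k,
                                   seed = 3, reference = consensus)
validation
#> <ontokine_consensus: individual> k=5, B=200, average consensus=79.5%, ARI vs reference=0.795
```

What the numbers mean: every standard curve converged (mostly as 4PL; the
5PL wins where noise favors the asymmetry term). The near-zero-variance
filter removed exactly the three floor-censored analytes, keeping 38. The
silhouette criterion selected **five** trajectory clusters (average
silhouette width 0.69), and across 200 bootstrap resamples of 90% of the
participants, analytes co-clustered with an average within-cluster
consensus of 100% — the planted kinetic classes are rock-stable at this
cohort size. The individual-level validation, which clusters on two-point
per-participant series without averaging, finds largely the same
partition (ARI 0.80) at a markedly lower consensus (79.5%), as expected
when per-participant noise is retained.

Per-analyte contrasts come from the same objects:

```r
contrasts <- ontogeny_contrasts(norm, si, conc)
head(volcano_filter(contrasts) |> dplyr::filter(hit), 3)
#>   analyte   dol n_pairs median_log10_fc median_log2_fc statistic    p_raw
#> 1 CCL11       1     200          0.117           0.388     15000 1.55e- 9
#> 2 CCL2        1     201          0.0929          0.309     15106 1.96e- 9
#> 3 CCL3        1     202         -0.151          -0.501      3589 1.16e-15
```

and plots via `autoplot(build_trajectories(norm, si), labels = tidy(consensus))`,
`autoplot(consensus)`, `autoplot(pca_summary(norm, si))` and
`plot_volcano(contrasts)`.

The whole chain, including a run manifest with per-stage accounting and
file checksums, is also available as one call:

```r
run <- run_pipeline(pipeline_config(seed = 1, B = 1000, outdir = "out"))
```

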