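# methcluster

Methylation-based tumor subgrouping by consensus hierarchical clustering
with feature selection (CHC-FS), for paired tumor / adjacent-tissue
cohorts profiled on promoter-centric CpG arrays (27K-style β-values).

Hepatocellular carcinoma tumors are far more heterogeneous in their DNA
methylation than the matched non-tumorous liver tissue around them. This
package asks, and answers on simulated cohorts with known truth, whether
that heterogeneity contains stable molecular subgroups and whether those
subgroups predict survival. It is written for statistical genomicists who
want the full chain — simulation, preprocessing, differential calling,
class discovery, cross-platform integration, outcome association — as
composable, pipe-friendly functions returning tibbles.

## The statistics at the core

* **Differential methylation.** Per probe, a two-group ANOVA on the
  tissue factor (equivalently the squared pooled-variance t) with
  Benjamini–Hochberg control; a CpG is called when q < 0.05 and
  |Δβ| > 0.1 (both strict), where Δβ = mean β(tumor) − mean β(adjacent).
  CpG-island localization of the hyper- and hypomethylated sets is tested
  with Fisher's exact test against the array background.
* **CHC-FS.** On the top 5% most variable probes among tumors, the
  consensus index of a sample pair is
  C<sub>ij</sub> = n<sub>together</sub>(i,j) / n<sub>co-sampled</sub>(i,j),
  accumulated over (default) 1000 average-linkage clusterings on
  1 − Pearson distance of 80% subsamples. k is chosen by the Δ-area
  criterion on the consensus CDFs (PAC reported alongside); features are
  then iteratively reduced to the probes whose empirical-Bayes moderated
  F across the current subgroups passes FDR 0.05, reclustering until the
  set is a fixed point. A consensus k-means run validates the labels.
* **Moderated statistics.** t̃ = effect / (s̃ · u) with
  s̃² = (d₀s₀² + d_g s_g²)/(d₀ + d_g); the prior (d₀, s₀²) is fitted by
  moment matching on log variances (digamma/trigamma identities).
* **Batch correction.** Parametric empirical-Bayes location/scale
  adjustment of per-gene platform effects (normal prior on locations,
  inverse-gamma on scales, moment-matched, iterated), preserving the
  tissue-role contrast; verified numerically identical to the reference
  implementation of the method.
* **Outcome.** Kaplan–Meier curves, the generalized (Gehan–Breslow)
  Wilcoxon test (weight = number at risk), and univariate Cox fits with
  Breslow ties and Wald 95% CIs. The most aberrant subgroup ("B") is
  contrasted against the merged remainder ("A").

A fully parameterized synthetic-cohort generator (`cohort_config()`,
`simulate_cohort()`) provides paired methylation, two-platform
expression and survival data with ground-truth labels, so every claim
above is testable end to end.

## Worked example

```r
library(methcluster)
library(dplyr)

cfg    <- cohort_config(seed = 42)     # 59 patients, 3 latent subgroups
cohort <- simulate_cohort(cfg)
beta   <- preprocess_beta(cohort$beta, cohort$detp, cohort$annotation)

diff <- differential_methylation(beta)
glance(diff)
#>   n_probes n_significant n_hyper n_hypo frac_hypo
#> 1     4850          1010     577    433     0.429

cgi_enrichment(diff, cohort$annotation)
#>   direction     n n_cgi prop_cgi background_prop_cgi odds_ratio        p
#> 1 hyper       577   492    0.853               0.677      2.76  1.01e-19
#> 2 hypo        433   132    0.305               0.737      0.157 1.78e-70

res <- chcfs(beta, n_iter = 200, seed = 42)
res
#> <chcfs_result> k = 3 (stable), 161 features, 59 tumors
#>   k-means validation ARI: 1.000
```

The discovered subgroups split survival: group B (the subgroup whose
methylation deviates most from adjacent tissue across the 161
subgroup-defining probes) carries the planted 4-fold hazard.

```r
surv <- filter(cohort$survival, endpoint == "OS")
surv$group <- tidy(res)$group[match(paste0(surv$patient, "T"), tidy(res)$sample)]
b <- identify_group_b(beta, res$labels, res$features)
surv$ab <- merge_groups(surv$group, list(A = setdiff(unique(surv$group), b), B = b))

cox_univariate(surv, "ab")
#>   term  estimate std_error    hr conf_low conf_high          p flagged
#> 1 ab        2.17     0.487  8.79     3.38      22.8 0.00000808 FALSE

gehan_wilcoxon(mutate(surv, group = ab))
#>    chi2    df          p observed_1 expected_1
#> 1  19.7     1 0.00000918          7       17.6
```

Reading the numbers: 1010 of 4850 probes are differentially methylated;
the hypermethylated set concentrates in CpG islands (85% vs 68%
background) and the hypomethylated set avoids them (31%), the canonical
island pattern. CHC-FS finds exactly the three planted subgroups
(k-means agreement ARI = 1), and the group-B hazard ratio (8.8, 95% CI
3.4–22.8) brackets the simulated truth of 4 within one cohort's sampling
spread.

Plots: `plot_volcano(diff)`, `autoplot(res)` (consensus heat map),
`plot_starburst(...)`, `plot_km(surv)`. The whole chain, with artifacts
written per stage, is `run_all(pipeline_config(out_dir = "run1"))`.

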