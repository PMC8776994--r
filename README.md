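# m6aTME

Tumor transcriptomes differ systematically in the expression of
N6-methyladenosine (m6A) regulators — the *writer* methyltransferases,
*eraser* demethylases and *reader* binding proteins that control the most
prevalent reversible mRNA modification — and those differences track the
immune composition of the tumor microenvironment (TME) and patient
prognosis. `m6aTME` is an R package for analysts who want to run the full
m6A-regulator TME workflow on an expression cohort with survival
follow-up:

1. **m6A subtypes** — consensus NMF clustering of a packaged 26-gene
   regulator registry (10 writers / 14 readers / 2 erasers), with the
   number of clusters chosen by average silhouette width among candidates
   whose groups separate progression-free survival (log-rank p < 0.05);
2. **phenotype signature** — empirical-Bayes moderated t differential
   expression between subtypes (|log2FC| > 1, adjusted p < 0.05),
   intersected across subtype contrasts;
3. **prognostic screen** — univariate Cox per signature gene, keeping
   Wald p < 0.01;
4. **m6A score** — per sample, the sum of the first two
   principal-component scores over the prognostic genes,
   `score_i = PC1_i + PC2_i` (genes z-scored; sign oriented so high score
   = risk), dichotomized at the maximally selected rank-statistic
   cutpoint into high/low groups;
5. **ssGSEA** — single-sample rank-based running-sum enrichment
   (exponent α = 0.25) for immune-infiltration, pathway, stromal/immune
   and correlation-proxy (e.g. EBV) scores;
6. **mRNAsi** — the Spearman-correlation stemness index rescaled to
   [0, 1].

A synthetic-cohort generator (`simulate_cohort()`) reproduces the
statistical structure the chain assumes — two regulator-driven expression
subtypes, immune programs co-expressed with one of them, and an
exponential hazard tied to a latent regulator score — so the whole
pipeline is testable end to end without any external download. Standard
formats are used throughout: expression and clinical tables as TSV/CSV,
gene sets as GMT, stemness weights as a two-column TSV.

## Worked example

```r
library(m6aTME)

cohort <- simulate_cohort(sim_config(seed = 1))   # 88 samples, 2,146 genes
reg    <- load_regulator_registry()

# subtype discovery on the regulator panel
X        <- nmf_input(cohort$expr[reg$symbol, ])
subtypes <- select_k(X, cohort$clinical, k_range = 2:3, n_runs = 50, seed = 1)
subtypes$selection
#>   k silhouette    logrank_p
#> 1 2  1.0000000 3.301079e-07
#> 2 3  0.7776813 1.966528e-06

# differential expression -> signature -> Cox screen -> PCA score -> groups
scores <- run_score_pipeline(cohort$expr, cohort$clinical, subtypes$labels)
#> phenotype signature: 146 genes
#> prognostic genes (p < 0.01): 94
head(scores, 4)
#>   sample_id m6a_score score_group subtype
#> 1      S001  4.723208        high       1
#> 2      S002 -8.118027         low       2
#> 3      S003 -1.383870         low       2
#> 4      S004  4.263172        high       1

logrank_test(cohort$clinical$time, cohort$clinical$event, scores$score_group)
#> log-rank chi2 = 31.84, p = 1.68e-08
```

The selection table shows k = 2 winning on silhouette width with a
survival split at log-rank p ≈ 3e-07; the score pipeline reduces 146
subtype-associated genes to 94 prognostic ones, and the resulting
high-score group has significantly worse progression-free survival
(p ≈ 2e-08) — the planted hazard structure, recovered from expression
alone.

Immune infiltration behaves as planted (programs up in the
immune-activated subtype, which falls in the low-score group):

```r
infil <- immune_infiltration(cohort$expr, cohort$gene_sets)
round(infil[1:3, 1:4], 3)
#>                    S001  S002  S003   S004
#> immune_program_01 0.032 0.629 0.615 -0.032
#> immune_program_02 0.128 0.453 0.579  0.151
#> immune_program_03 0.019 0.619 0.579  0.161
compare_groups_report(as.list(as.data.frame(t(infil))), scores$score_group)
#>            variable     test            p         adjP
#> 1 immune_program_01 wilcoxon 4.821209e-14 5.785451e-14
#> 2 immune_program_02 wilcoxon 4.289424e-15 8.578847e-15
#> ...
```

`run_full_pipeline(pipeline_config(simulation = sim_config(seed = 1)))`
chains all stages and writes stage-numbered TSV/JSON artifacts plus a
reproducibility manifest; configs can also be given as YAML via
`read_pipeline_config()`.

The methods vignette (`vignettes/m6a-tme-methods.Rmd`) documents the
models, parameter defaults, numerical choices and known limitations.

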