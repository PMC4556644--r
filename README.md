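# codis — cooperativity disorientation analysis of gene expression

`codis` is an R package for finding prognostic gene signatures by asking a
different question than a differential-expression screen: not *which genes
change level* between tissue states, but *which genes abandon the
correlation structure they maintained during development*. It targets
transcriptomic studies that span a developmental axis (embryonic and normal
tissue), a precancerous stage (adenoma) and cancer (adenocarcinoma), with an
optional paired miRNA layer and survival follow-up — the setting of
colorectal-carcinogenesis cohorts.

## The model at the core

For each macro-stage *s* ∈ {development, progression, cancer} the package
computes the gene–gene Pearson correlation matrix over that stage's samples,
bias-adjusted for the stage's sample count via
r′ = r (1 + (1 − r²) / (2(n − 3))). Row *g* of a stage matrix is gene *g*'s
**intra-immune vector** — its correlation with every other gene in the set.
The **Spearman transition** of gene *g* between consecutive stages is the
rank correlation of its intra-immune vectors (self excluded):

* ST<sub>D-P</sub> — development → progression,
* ST<sub>P-C</sub> — progression → cancer.

Each gene becomes a point (ST<sub>D-P</sub>, ST<sub>P-C</sub>). The point
(1, 1) is the **theoretically stable point (TSP)**: perfect preservation of
the gene's association rank order through carcinogenesis. Genes within one
Euclidean distance of the TSP are **obedient**; genes beyond it are
**diversion** genes — the carriers of cooperativity disorientation, and the
candidate pool for everything downstream:

* an ANOVA screen (one-way F across the four developmental sample types,
  BH-adjusted) restricts the analysis to development-varying members of a
  gene set of interest;
* a miRNA–mRNA network keeps diversion genes with at least one regulator:
  an edge needs ≥ 2 prediction sources and significantly negative expression
  correlation (one-sided, BH q < 0.01) on paired samples;
* AUC-RF selection ranks candidates once by random-forest mean decrease
  Gini, then removes genes from the bottom while scoring every prefix by the
  AUC of leave-one-out "Poor-vote" proportions against 5-year survival
  classes, returning the smallest subset with maximal AUC;
* validation splits patients into two equal groups by the rank of PC1 over
  the panel and compares them by log-rank test and Cox regression, with a
  random-panel permutation null quantifying how special the selected panel
  is relative to its pool.

All of it runs on synthetic data with planted ground truth (`sim_config()`,
`simulate_stage_expression()`, `simulate_mirna_layer()`,
`simulate_survival_cohort()`), so every claim about sensitivity and
specificity of the pipeline is measurable.

## Worked example

```r
library(codis)

cfg <- sim_config(n_genes = 120, seed = 42)   # 15% planted diversion genes
sim <- simulate_stage_expression(cfg)
fit <- transition_model(sim$expr)
summary(fit)
#> Transition-model summary
#>   obedient 104 / diversion 16 (radius 1)
#>   median ST_D-P 0.699, median ST_P-C 0.775
#>   genes farthest from the stable point:
#>  gene_id       st_dp       st_pc tsp_distance     label
#>    g0020 -0.71209229 -0.17998148     2.079331 diversion
#>    g0049 -0.07429853 -0.55653753     1.891276 diversion
#>    g0047 -0.54868965  0.05095428     1.816350 diversion
#>    g0018  0.20670132 -0.62076627     1.804496 diversion
#>    g0041 -0.71389403  0.63047999     1.753276 diversion
#>    g0074 -0.12575132 -0.03411195     1.528628 diversion
```

Obedient genes sit near the TSP (median transitions ≈ 0.7–0.8 at these
sample sizes); the listed genes lost their developmental correlation rank
order in at least one transition. Against the generator's ground truth this
fit recovers 16 of the 18 planted diversion genes with no false positives.

Survival validation of a planted 12-gene signature on a simulated cohort of
200 patients:

```r
co <- simulate_survival_cohort(cfg)            # log HR = ln 2 per PC1 SD
split <- pc1_group_split(co$dataset$expression[co$truth$prognostic_genes, ])
km_logrank(data.frame(time = co$dataset$endpoints$os_time,
                      event = co$dataset$endpoints$os_event), split$groups)
#> Kaplan-Meier / log-rank: low=100, high=100 ; chisq = 20.584, p = 5.706e-06
```

The two PC1-assigned halves of the cohort differ strongly in overall
survival, as they should when the hazard is driven by the panel's first
principal component.

A command-line wrapper over the same functions ships in `inst/cli/codis.R`
with subcommands `simulate`, `dvig`, `transition`, `network`, `signature`,
`survival` and `panel-null`; see `?codis_main`.

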