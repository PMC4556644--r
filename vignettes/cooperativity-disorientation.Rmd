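---
title: "Quantifying cooperativity disorientation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cooperativity disorientation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codis)
```

## The problem

During colonic development, the expression of functionally related genes —
immune-response genes in particular — is tightly co-regulated: pairwise
expression correlations within the set form a compact, reproducible pattern.
The working hypothesis behind this package is that carcinogenesis disrupts
that pattern, and that the genes whose *correlation structure* (not
necessarily their expression level) is most disoriented on the way from
normal tissue through precancerous lesions to carcinoma are enriched for
prognostic information. `codis` implements the full discovery pipeline:

1. screen a gene set for members that vary across developmental sample types
   (whole embryo, early/middle embryonic colon, normal mucosa);
2. quantify each gene's *cooperativity disorientation* across the three
   macro-stages — development, progression (adenoma), cancer
   (adenocarcinoma) — with a Spearman correlation-transition statistic;
3. keep the "diversion" genes and intersect them with a miRNA–mRNA
   inverse-correlation regulatory network;
4. reduce the surviving candidates to a compact signature by AUC-optimised
   random-forest backward elimination;
5. validate any panel by PC1-stratified Kaplan–Meier/Cox analysis and a
   random-panel permutation null.

Every stage can be exercised against synthetic data with planted ground
truth, which is how the package's tests quantify sensitivity and specificity
of the whole chain.

## The transition model

For one macro-stage with $n$ samples, the stage correlation matrix holds the
pairwise Pearson correlations of all genes over that stage's samples. Row
$g$ is gene $g$'s *intra-immune vector*: its correlation with every other
gene in the set. Because the three stages have unequal sample counts, each
off-diagonal entry $r$ is bias-adjusted by the Olkin–Pratt-style correction

$$ r' \;=\; r\!\left(1 + \frac{1 - r^2}{2(n-3)}\right), $$

clipped to $[-1, 1]$. The sample correlation underestimates $|\rho|$ at
small $n$; the correction removes the leading-order bias so matrices
estimated from 30 and from 60 samples are comparable. The exact form of the
adjustment is a package choice (`adjustment = "small_sample_bias"`), and
`"none"` is available for raw correlations.

The transition statistic of gene $g$ between consecutive stages $a$ and $b$
is the Spearman rank correlation between its intra-immune vectors in the two
stages, with the self-entry excluded (it is identically 1 in both stages and
would only inflate agreement). Values near 1 mean the rank order of $g$'s
associations survived the transition; near 0, that it was reshuffled; near
$-1$, inverted. Ties receive average ranks; a constant vector has no defined
rank correlation and yields 0 with the gene flagged.

Each gene is then projected onto the plane
$(\mathrm{ST}_{D\text{-}P}, \mathrm{ST}_{P\text{-}C})$. The point $(1, 1)$
— the theoretically stable point (TSP) — represents perfect preservation
through both transitions. Genes within one Euclidean distance of the TSP
(boundary inclusive; the tie has measure zero on continuous data but the
rule must be deterministic) are *obedient*; the rest are *diversion* genes
and proceed to the next stage of the pipeline. The statistic is invariant
under any common permutation of the gene universe, which the test-suite
asserts directly; heatmap reordering is a visualization concern only.

```{r transition-example}
sim <- simulate_stage_expression(sim_config(n_genes = 80, seed = 7))
fit <- transition_model(sim$expr)
fit
```

## The screens around it

**Development ANOVA screen.** Development-varying genes are found by an
equal-variance one-way F-test across the four developmental sample types,
with Benjamini–Hochberg adjustment over the tested genes and a default
threshold of q < 1e-4. The four-type grouping (rather than the three
macro-stages) is used because the screen asks which genes *vary during
development*. BH is used because no specific FDR procedure is prescribed by
the phrasing "FDR < 1e-4" and BH is the field default; on two groups the F
statistic equals the squared pooled-variance t statistic, which the tests
use as an oracle.

**miRNA–mRNA network.** A predicted miRNA→gene pair (from sequence-based
target-prediction sources supplied as input files) becomes a regulatory edge
when (i) at least two sources list it, (ii) the expression correlation on
paired samples is negative, and (iii) the one-sided BH q-value is below
0.01. The test is one-sided because the repression hypothesis is
directional; Pearson on log2 values is the default estimator with Spearman
and two-sided alternatives available. The BH universe is the set of
prediction-supported pairs actually tested in the run, matching the
pair-level phrasing of the selection rule.

**AUC-RF.** Patients are dichotomised at five years: death within the
cutoff is "Poor", observation beyond it is "Good", censoring at or before
the cutoff yields no usable label. Genes are ranked once by mean decrease
Gini from a single forest on all candidates; subsets are prefixes of that
ranking (the elimination schedule removes low-ranked genes and never
re-ranks, the literal reading of recursive elimination "based on the
initial ranking"). Each subset is scored by the AUC of its leave-one-out
Poor-vote proportions — the fraction of trees voting the held-out sample
into the Poor class, a continuous ROC predictor. The best subset is the
smallest attaining the maximal AUC (parsimony breaks ties
deterministically). Forest defaults are 1000 trees and
mtry = floor(sqrt(p)); the vote is a fraction of trees rather than an
averaged 0/1 prediction because the ROC construction requires a continuous
score. The default operating threshold maximises Youden's J on the best
subset's votes; a fixed threshold can be supplied instead when reproducing
an external operating point.

**Survival validation.** A panel is evaluated by computing the first
principal component of its per-gene-centred submatrix (centering only, no
unit scaling, since log-scale expression is already comparable; scaling is
available via a flag), orienting PC1 so the sum of gene loadings is
positive, and splitting samples at the median PC1 rank into two equal
groups (odd cohorts put the extra sample in the lower-PC1 group). Groups
are compared by Kaplan–Meier/log-rank; Cox proportional-hazards analysis
reports univariate hazard ratios and a single multivariate model over the
covariates passing the univariate screen at p < 0.05 — the simplest
procedure consistent with a univariate-then-multivariate table. The
loading-sum convention makes the *orientation* deterministic across
linear-algebra backends; the split partition itself is invariant to a
global sign flip of the data.

**Random-panel null.** Drawing `n_draws` random panels of the signature's
size from a gene pool and counting the draws that are simultaneously
significant (log-rank p < 0.05 on every requested dataset/endpoint)
measures how much of a pool's prognostic content is generic rather than
specific. The joint-significance criterion at α = 0.05 is the package's
reading of "simultaneously discriminate", matching the log-rank usage
elsewhere in the pipeline.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline's operating characteristics are measured.

**Stage expression.** Each gene has a loading vector over
`n_latent_factors` latent factors; factors are drawn independently per
sample, and expression is loadings · factors + Gaussian noise. Obedient
genes reuse their loadings in all three stages, so their population
correlation pattern is preserved; diversion genes draw fresh loadings in
progression and again in cancer, so their correlation rank order is
re-randomised at each transition. Defaults: 200 genes, 40 samples per
stage, 15% diversion, noise SD 0.5 on the log2 scale.

The factor count defaults to **5**. In a low-dimensional loading space,
two independently drawn loading vectors are too often nearly collinear —
for unit vectors in $\mathbb{R}^3$ the cosine is uniform on $[-1,1]$, so
roughly 15% of "re-randomised" diversion genes land within 45° of their
developmental direction and keep much of their correlation rank order by
chance. At five factors the collision probability is small enough that
planted diversion is recoverable at ≥ 0.9 sensitivity and specificity,
which is the regime the recovery benchmarks are defined in.

**miRNA layer.** Each regulating miRNA represses a disjoint module of
co-expressed genes (a random seed gene plus its most-correlated pool
mates); its profile is `regulation_strength` × the module's mean expression
plus noise. Regulating a co-expressed module — rather than an arbitrary
gene set — reflects how miRNA repression targets functionally coherent
groups, and it keeps every planted pair strongly anti-correlated instead of
diluting the signal across mutually cancelling targets. Decoy prediction
edges pair *null* miRNAs (pure-noise profiles) with random genes: decoys
must carry prediction support but no expression coupling, and in a
factor-structured transcriptome a random pair involving a regulating miRNA
would be genuinely coupled. Planted edges appear in two prediction sources;
decoys in two or one.

**Survival cohort.** The planted signature genes share a latent-factor
block; all other genes are independent noise with matched marginal
variance. The per-patient risk score is `log_hazard_coef` × the unit-scaled
PC1 of the signature submatrix; event times are exponential with rate
(1/60 months⁻¹) × exp(risk) — a plausible colorectal time scale — with
independent exponential censoring calibrated to the requested censoring
fraction (default 0.3). Restricting the factor structure to the signature
genes is deliberate: panels of non-signature genes must carry *no* survival
information for null calibration (uniform log-rank p-values) to be
testable. DFS is OS scaled by Uniform(0.5, 1) with the same event flags —
only relative discrimination is exercised, not joint endpoint modelling.

**What the generator does not emulate:** probe-level microarray noise,
batch effects, pooled biopsies, non-proportional hazards, miRNAs with
overlapping target modules, and any real gene annotation. Passing the
recovery benchmarks therefore demonstrates the pipeline's correctness and
calibration under its stated model, not its power on any particular real
cohort.

## Numerical choices and degenerate inputs

* Zero-variance genes: correlations set to 0 and the gene flagged (stage
  matrices); screen p-value 1 and flagged (ANOVA); pairs skipped and
  counted (network).
* Spearman ties: average ranks. Constant transition vectors: statistic 0,
  flagged.
* Boundary: TSP distance equal to the radius is obedient (inclusive).
* AUC: Mann–Whitney rank statistic, ties counted one half.
* Max-AUC ties across subset sizes: smallest subset.
* MDG ties in the ranking: broken alphabetically for determinism.
* Log-rank with zero events: chi-square 0, p 1 rather than an error.
* All randomness flows from explicit integer seeds; every simulation,
  forest fit and panel draw is bitwise reproducible.

## Problem sizes used by the checks

The recovery benchmarks run at the generator defaults above (10 seeds for
the transition benchmark, 20 for the network and AUC-RF benchmarks with
forests reduced to 200 trees, 100–500 replicates for the survival
calibration checks, 200 draws per pool for the panel null). These sizes
give stable estimates of the operating characteristics while keeping a full
run of the suite on the order of minutes.

## Known limitations

* The bias adjustment is one defensible choice among several; raw
  correlations are available, and conclusions should be insensitive to the
  switch at the benchmark sample sizes.
* The ANOVA screen assumes equal within-type variances; a Welch variant
  would be a straightforward extension.
* The AUC-RF loop inherits the optimism of selecting and evaluating on the
  same cross-validated votes; the selected subset's AUC is an in-sample
  optimum, which is why external survival validation is part of the
  pipeline rather than an afterthought.
* The random-panel null treats datasets as independent; shared platform or
  cohort effects in real data would make the joint-significance null less
  conservative.
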