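---
title: "Methods: context-specific QTL and allele-specific co-expression"
author: "stimqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-specific QTL and allele-specific co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the design
choices made where the design was genuinely open, and the limits of what
the synthetic validation shows.

## The measurement model

All mapping stages share one regression backbone. For phenotype $y$
(a gene count, transcript abundance or CpG beta after normalisation) and
variant dosage $g \in \{0,1,2\}$ (minor-allele counts; R = reference,
M = minor allele), the cis model is

$$ y = \mu + b\,g + C\gamma + \varepsilon, $$

with $C$ the covariate matrix (expression PCs) and a two-sided t-test on
$b$. Dosage is treated additively throughout. Variants enter a
phenotype's test set when they lie within a closed window around the
strand-aware TSS (CpG coordinate for methylation): ±1 Mb for genes and
CpGs, ±100 kb for transcripts. Both window sizes are `pipeline_config()`
parameters. The tested subset drops variants below the MAF floor
(default 0.04) and variants with zero dosage variance (skipped with a
log entry, never fatal). Missing genotypes are mean-imputed per variant
at read time.

**Normalisation.** Conditional quantile normalisation and
variance-stabilising transforms are out of scope here; the package
substitutes a log2(x+1) transform followed by a per-phenotype
rank-inverse-normal transform, after the expression filters (genes with
fewer than 50 total reads removed; transcripts kept when abundance
≥ 0.5 in every individual of at least one condition, via
`fpkm_keep_set()`). The rank-INT makes the per-variant t-test robust to
the raw scale, at the price of losing mean–variance information — a
deliberate simplification, documented as such.

**PC selection.** Zero to `max(k_grid)` expression PCs are tried as
covariates; the yield is the number of phenotypes whose best nominal cis
p falls below a fixed threshold (default 1e-3). The selection heuristic
is named loosely in the field ("inflection points and local maxima"); we
operationalise it as the *first local maximum* of the yield curve, ties
to the smallest k, with a warning and the grid maximum when the curve is
still rising at the edge. The full curve is returned for audit
(`autoplot()` shows it).

**Permutation pass.** Phenotype labels are permuted (n_perm ≥ 100,
default 1000); the best cis statistic per permutation forms the null.
The empirical p uses the (1+k)/(1+N) estimator so it is never zero. For
transcripts grouped under a gene the best statistic is taken across the
group within each permutation (group-best), which is the two-level
multiplicity correction for multiple transcripts per gene. A beta
distribution fitted to the permutation null by maximum likelihood
refines small p-values; the raw empirical p is always reported
alongside, because the beta refinement is an approximation whose fit is
not guaranteed in the tail. A fully exhaustive mode (all n!
permutations) exists for tiny cohorts and is what the enumeration tests
compare against.

**Conditional pass.** Forward selection adds the best remaining variant
while its conditional p stays below the threshold; the backward step
re-tests each selected variant given the others and drops failures; each
surviving signal is assigned its best hit by rescanning the window
conditional on the other signals, and signals are ranked by conditional
significance. Collinear selections are dropped with a log entry.

**Power.** `eqtl_power_slr()` gives the analytic power of the slope
t-test with genotype variance $2\,\mathrm{MAF}(1-\mathrm{MAF})$ under
HWE and non-centrality $b\sqrt{n\,\mathrm{var}(g)}/\sigma_e$, where
$\sigma_e$ derives from the marginal outcome SD $\sigma_y$ (default
$b/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})}$). The function errors when
$\sigma_y$ is inconsistent with the slope (non-positive residual
variance). It is checked against a 20 000-replicate Monte-Carlo
rejection rate to ±0.01.

## Context specificity

With per-condition records (b, fdr, nominal p) at a variant–phenotype
pair, labels are assigned in this precedence order: `differential`
(significant in ≥ 2 conditions with discordant slope signs), `shared`
(significant in all), `condition-specific:<c>` (significant in exactly
one and nominal p above `nonsig_floor` elsewhere), `stimulated-only`
(significant in ≥ 1 stimulated condition, naive clean), then
`none`/`ambiguous`. The specificity definition in the field rests on
significance alone; the floor (default nominal p > 0.05, configurable)
guards against calling a pair "specific" when a second condition sits
just under the significance line. The floor has a measurable cost: a
truly condition-specific pair lands above the floor in both other
conditions only ~90% of the time at the default, so a small fraction of
genuinely specific pairs fall through to `stimulated-only`/`ambiguous`.
This is by design — those calls are honest "can't rule out a second
condition" outcomes.

## Colocalization, MR, directionality

Per-variant Wakefield approximate Bayes factors are computed from
(beta, se) with prior effect variance W (default 0.15², the conventional
quantitative-trait default; configurable). Hypothesis posteriors PPH0–4
come from the standard single-causal-variant enumeration with priors
p1 = p2 = 1e-4, p12 = 1e-5. Note the ABF is a function of z = beta/se
and W/se²: rescaling the effect axis requires rescaling √W with it,
which the tests assert. Multi-trait (three-way) colocalization is
replaced by all pairwise runs — a documented caveat, since pairwise
posteriors do not compose into a three-way statement. Harmonisation
aligns on variant id and alleles; strand-ambiguous A/T and C/G variants
are dropped because their orientation cannot be resolved from alleles
alone.

MR combines per-instrument Wald ratios β_outcome/β_exposure by simple
mean, inverse-variance weighting, or the penalised weighted median
(weights 1/se², penalty min(1, 20·p) on each instrument's heterogeneity
Q contribution, bootstrap se). Median-type combined estimates always lie
within the range of the per-instrument ratios.

The Steiger test compares |r(SNP, methylation)| with
|r(SNP, expression)| via the Fisher-z difference; `M->E` requires the
SNP to explain methylation significantly better (p < 0.05 by default).
`undetermined` is an explicit output, never silently dropped, and the
call flips exactly under argument swap. Methylation–expression coupling
itself is a Pearson correlation with BH across tested pairs and a sign
class at FDR < 1e-4; an optional genotype-adjusted partial correlation
is reported alongside to separate coupling from the shared genetic
driver.

## Feature enrichment

Foreground = window SNPs at FDR < 0.001 (optionally expanded by LD
proxies, default off); background = the remaining window SNPs; overlap
against 0-based half-open BED intervals (a 1-based SNP at p overlaps
[start, end) iff start < p ≤ end). The z-score is
(f/F − b/B)/SE. The printed form of the statistic names the SE of a
difference of proportions without a formula; the *unpooled*
two-proportion SE is the default because it transcribes that expression
most directly, with the pooled variant behind a flag. Degenerate
zero-SE cases return Z = 0 with a warning so downstream ranking stays
total. Counts are aggregated across phenotypes by default; a
per-phenotype mode exists. Under the null the Z distribution is
confirmed to have mean ≈ 0, SD ≈ 1 over 2000 simulated feature classes.

## Allele-specific co-expression

Individuals are stratified at a variant into RR/RM/MM; analysis
requires a homozygous-minor count strictly greater than 5. Stratum
correlations (Spearman by default — rank correlation is the stated
preference in this literature and is robust to outliers and monotone
distortions; Pearson by flag) are Fisher-z transformed and compared by

$$ dz = \frac{z_1 - z_2}{\sqrt{1/(n_1-3) + 1/(n_2-3)}}. $$

The denominator deserves a note: the source formula is sometimes typeset
as $\sqrt{|\mathrm{var}(z_1) - \mathrm{var}(z_2)|}$, which is singular
whenever the two strata have equal size. The standard sum-of-variances
form is therefore the default; the literal form is preserved behind
`mode = "literal"` and errors explicitly at equal group sizes
rather than silently correcting anything.

The primary interaction p comes from the linear model
`partner ~ anchor + g + anchor:g` with additive genotype — the source
literature reports an interaction p without defining the model, so this
choice is made explicitly here; the dz-based normal p is always computed
alongside, and the two agree in rank order (Spearman ρ > 0.9 in the test
batch). Each stratum's correlation is labelled significant-positive /
non-significant / significant-negative at α = 0.05, and the ordered
label pair over the compared strata gives one of 9
differential-correlation classes. The three pairwise comparisons are
checked for consistency: when the MM-vs-RM pair is differentially
correlated, the RM-vs-RR call is expected to match the MM-vs-RR call;
violations are flagged, never corrected. Replication between datasets
requires the identical (anchor, partner, variant) triple and the same
direction of correlation change. Methylation links reuse the same
machinery with CpG vectors as anchors.

## Pathway differential connectivity

ORA is a one-sided hypergeometric tail on the query/set overlap within
the background universe, BH across sets. The module statistic is

$$ \mathrm{MDC} = \mathrm{median}_{i \ne j}\, |dz_{ij}| $$

over all unordered gene pairs of the filter-passing members, between two
genotype strata (MM vs RR by default). The typeset source expression
wraps this median in an outer sum over a permutation index divided by
the gene count, which is not a well-formed statistic; the prose —
median pairwise z-score difference with a 1000-resampling permutation
test — is implemented instead. Genes enter MDC only if their own
connectivity change (median |dz| over their pairs) is significant at
0.05 by genotype-label permutation; at least 3 passing genes are
required. The MDC p is two-sided by default, measured as distance from
the permutation-null median, with the (1+k)/(1+N) estimator. The null
calibration is run with the gene filter off: the filter is a selection
step, and calibrating through it would measure the selection, not the
test.

## The synthetic cohort

The generator's defaults define the validation conditions: 280
individuals paired across three conditions (naive UT plus LPS and IFN
stimulation — a size at the scale of the monocyte stimulation cohorts
this design emulates, and large enough to fill the homozygous-minor
stratum at a MAF-0.5 variant with ~70 individuals); 300 variants on a
20-Mb toy chromosome with MAF uniform on [0.04, 0.5]; planted cis
slopes of 0.8 SD per minor allele with unit residual noise (12
condition-specific, 8 shared, 8 sign-discordant QTL); two global latent
confounders so PC correction is genuinely needed; co-expression targets
r = (0.6, 0.1, −0.4) across RR/RM/MM (an extreme-stratum difference of
1.0); mediation chains with a strong SNP→methylation edge (1.2) and a
moderate methylation→expression edge (0.6), which keeps the
directionality signal detectable while leaving realistic
methylation–expression coupling; and annotation intervals at fold-4
enrichment over a 10% background coverage.

Choices worth flagging:

* **No LD.** Variants are drawn independently, so the panel has no
  linkage structure. Clumping, proxy handling and the distinct-variant
  colocalization case are exercised with explicitly constructed proxies
  (a dosage column copied with controlled flips). Conclusions about
  LD-driven behaviour on real data do not follow from these tests.
* **Exact-HWE co-expression variants.** The fixture fixes the designated
  co-expression variants at MAF 0.5 with exact HWE genotype counts so
  the extreme strata hold ≥ 60 individuals by construction; ordinary
  variants are binomial draws.
* **Methylation scale.** CpG betas are a logistic transform of a latent
  Gaussian, which respects the (0,1) range while keeping linear mQTL
  mapping well behaved; Pearson correlations on the beta scale are
  mildly attenuated relative to the latent scale.
* **Confounder structure.** The latent-factor model (global factors,
  random loadings) is an emulation choice — the real study's confounder
  structure is unknown — so the PC-selection results show that the
  heuristic works under factor-type confounding, nothing more.
* **What passing tests do not show.** The generator has Gaussian noise,
  no population structure or relatedness, no read-level sampling, no
  mean–variance coupling and no batch structure. Calibration and
  recovery results certify the statistics under their own assumptions,
  not performance on any particular cohort.

## Numerical choices and degenerate inputs

* Empirical permutation p is never 0 ((1+k)/(1+N)); exhaustive mode
  reports the exact enumeration fraction instead.
* Correlations are clipped away from ±1 before Fisher z inside MDC;
  `fisher_z()` itself errors at |r| ≥ 1.
* LD-clump ties in p break to the smaller genomic position, making the
  output deterministic.
* Zero-variance phenotypes/variants/partners are dropped or skipped with
  warnings or log messages, never silently and never fatally, except
  where the result would be meaningless (all-zero matrix, constant
  vector in a correlation test) — those error.
* Beta-null fitting failures degrade to the raw empirical p (`p_beta =
  NA`), never to a crash.
* Sizes used by the validation runs: 2000 replicates for each null
  calibration, 100 replicate fixtures for context recovery, 100 for
  coExQTL power, 200 mediation chains, 30 colocalization simulations per
  scenario, and `n_perm = 199` inside permutation-test calibration —
  chosen so each study gives stable estimates at comfortable desk-scale
  runtimes.

## Known limitations

Trans-QTL, mixed models, genotype phasing/imputation, isoform-switch
analysis, three-way colocalization and LD-proxy lookup against external
reference panels are out of scope. The pipeline assumes paired
individuals across conditions; unpaired designs would need the context
classification rethought. The penalised-weighted-median bootstrap se is
parametric and assumes independent instruments.
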