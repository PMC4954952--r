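---
title: "Models and methods behind ricemqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ricemqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ricemqtl implements the quantitative-genetic workflow used to dissect
replicated multi-trait (typically metabolomic) variation in a biparental
recombinant inbred line (RIL) population: heritability and
genotype-by-experiment (G×E) decomposition, Haley–Knott interval mapping
with permutation thresholds, stepwise multi-QTL models, sliding-window QTL
hotspots, hotspot-marker additive and epistasis ANOVAs, and mapping of
per-line CV as a stochastic-variation phenotype. The design it emulates is
a *japonica* × *indica* rice cross (Lemont × Teqing): 280 lines genotyped
at 175 RFLP markers on 12 chromosomes, phenotyped in two independent
experiments with two complete blocks each (four replicates per line).

This vignette explains each model, its assumptions, the tunable parameters,
and the numerical and design choices that were genuinely open.

## Genetic map arithmetic and genotype probabilities

Distances are genetic (cM) throughout. The map function converts distance
to a meiotic recombination fraction; the default is Haldane
(`r = (1 - e^{-2d/100})/2`, no crossover interference), matching the common
default of RIL mapping software, with Kosambi available as a switch. On a
selfed RIL, accumulated meioses expand the observed recombination fraction
to `R = 2r/(1+2r)` (so `R(0) = 0`, `R(0.5) = 0.5`); the genotype process
along a chromosome is treated as a two-state Markov chain with this
transition probability.

Conditional QTL-genotype probabilities `P(A | flanking markers)` are
computed from the nearest non-missing flanking markers only — a two-point
conditioning rather than a full multipoint HMM. At the study's marker
density (median spacing ≈ 8 cM) the two approaches are practically
indistinguishable, and the two-point form can be verified by enumerating
the two flanking-transition paths by hand, which the test suite does. With
no informative marker on a chromosome the probability falls back to the
unconditional 1/2 with a warning. There is no genotyping-error model and no
map re-estimation. Scan grids insert pseudomarkers so that no gap exceeds
the step (default 1 cM); the wide gaps the template map carries on
chromosomes 3 and 9 are traversed by the same interval rules.

## Haley–Knott scans and permutation thresholds

At every grid position the per-line trait means are regressed on `P(A)` and
the fit is scored as `LOD = (n/2) log10(RSS0/RSS1)` against the
intercept-only null. With complete genotypes this reduces exactly to
two-group marker regression at marker positions — an identity the tests
exploit as an oracle (tolerance 1e-8). LOD values are capped at 300 so that
noise-free fits stay finite while preserving order; zero-variance traits
return an all-zero profile with a warning.

Genome-wide significance uses the permutation test (default 1000
repetitions, α = 0.05): trait values are permuted across lines, the genome
rescanned, and the threshold taken as the `ceil((1-α)·n_perm)`-th order
statistic of the null genome-wide maximum LOD. `scan_trait_panel()` shares
one threshold (and one interaction penalty) per panel by default: the
genotypes are common to all traits, so the null max-LOD distribution is
too; per-trait thresholds (`share_threshold = FALSE`) reproduce the
single-trait protocol at proportional cost.

## Stepwise multi-QTL models

Model search maximizes a penalized LOD: model LOD minus a main-effect
penalty per QTL (the permutation threshold) and an interaction penalty per
product term. The interaction penalty is itself estimated from a
permutation null: the maximum two-locus interaction LOD (full vs additive
two-locus model) over all marker pairs, under trait permutation. Forward
steps add the best single locus or the best interaction among selected
loci; when neither passes its penalty, a marker-level two-locus scan may
propose a locus pair plus its interaction, charged two main penalties plus
one interaction penalty — this is what lets purely epistatic architectures
(no marginal effects) enter, and it is disabled by default at panel scale
(`pair_search = FALSE` in `scan_trait_panel()`) because it triggers on
every trait whose forward search stalls and costs ~0.3 s per trait on the
full map. Backward elimination then removes any term whose deletion
improves the penalized score, and drop-one refinement assigns each QTL a
LOD (the loss in model LOD when it is removed, its interactions with it)
and prunes below-threshold terms until stable. Ties at equal LOD break
toward the lower cM position, for determinism. The per-trait QTL cap
defaults to 10.

Support intervals are 1.5-LOD: the contiguous region around the peak
within 1.5 LOD of it, extended one grid position outward and clipped at
chromosome ends, reported with flanking marker names. In multi-QTL models
the interval for each QTL comes from a covariate-adjusted profile (the
other terms residualized out). Effects are reported on the study's
dimensionless scale: (mean of Lemont-class lines − mean of Teqing-class
lines) / grand mean, positive when the Lemont allele raises the trait, with
a pooled two-sample standard error.

## Heritability and G×E

The replicated design is a balanced randomized complete block design, so
variance components use expected mean squares rather than REML — every
quantity is hand-checkable, which the tests use. Within one experiment,
`Vg = (MS_line − MS_error)/r`; across combined experiments the interaction
mean square replaces the error in the numerator
(`Vg = (MS_line − MS_int)/(rE)`), so combined-scope Vg is the strict
among-line variance with experiment and G×E variance removed — they remain
in Vp, and `H² = Vg/Vp`. Harmonic-mean replicate counts tolerate mild
imbalance; negative estimates truncate to zero; a constant trait has
`H² = 0` by convention, and a single replicate per line is an error.
Counting G×E variance as genetic is available as an option
(`include_gxe_in_vg`). The block term is omitted from the default model.

One subtlety: with only two experiments, any G×E structure is
sum-to-zero within line, which makes the interaction mean square carry
`E/(E−1) = 2×` the naive per-cell G×E variance; the EMS subtraction is
therefore conservative for combined-scope Vg. This is exactly the behaviour
that reproduces the study pattern — within-experiment H² medians near 0.5
collapsing to ~0.25 in the combined scope once substantial G×E is present —
and the generator's default variance split (additive 0.75, G×E 0.25,
residual 1) is calibrated to that regime.

The replicate-level ANOVA (`fit_gxe_anova`) fits
`trait ~ line + experiment + line:experiment` with sum-to-zero contrasts
and Type III sums of squares (via car); with a fully confounded design the
interaction is dropped with a warning.

## Hotspots

QTL peaks from all traits are counted in a 10 cM sliding window (full
width, i.e. ±5 cM) at every grid position; the window width and the merge
radius (default 10 cM, one window) are the resolution-defining parameters.
The count threshold comes from a placement permutation: each permutation
re-places every QTL peak uniformly at random and records the genome-wide
maximum window count. Peaks are re-placed over *marker* positions by
default, not uniformly in cM: interval mapping localizes peaks at or near
markers, so on an unevenly spaced map a uniform-in-cM null systematically
under-counts chance clustering in marker-dense regions (and over-counts it
inside map gaps), which manifests as spurious hotspot calls on panels of
randomly placed QTLs. Uniform-grid placement remains available
(`placement = "grid"`). Runs of above-threshold positions collapse to one
peak each; peaks from the three datasets merge by single linkage within the
merge radius, represented by the marker nearest the highest-count peak.

Validation refits every trait against
`trait ~ Σ hotspot markers + experiment` on line × experiment means,
counts per marker the traits significant after Benjamini–Hochberg FDR
within each trait's model (q < 0.05), and compares that count with a null
built by permuting the line-to-genotype assignment (the same permutation in
both experiments, preserving the trait panel's correlation structure). A
hotspot is validated when its count exceeds the (1−α) null quantile. Adding
marker × experiment terms partitions each hotspot's traits into
main-effect-driven versus G×E-driven counts; a hotspot is called
main-dominant when the former exceeds the latter. The per-trait effect
table at a hotspot marker (standardized effects with BH q-values across
traits and a Lemont-up/Teqing-up direction label) is the export behind
network views.

## Epistasis

All hotspot-marker pairs are tested jointly in one model per trait:
`trait ~ Σ M_m + Σ M_m×M_n + experiment + Σ M_m×M_n×experiment`, with ±1
sum-to-zero coding. Every term is a single-degree-of-freedom contrast, so
its Type III sum of squares equals `t² σ̂²` for its coefficient — computed
in-package and vectorized across traits (car::Anova serves as the
independent oracle in the tests). Missing genotype calls are imputed from
conditional genotype probabilities (`2P(A) − 1`) so the joint design stays
complete; aliased terms are dropped with a warning, and a pair-at-a-time
mode exists for degenerate-rank cases. FDR is BH within each model.

Enrichment asks, per pair, whether more traits show a significant
interaction than expected: the null permutes line labels of the genotypes
against the intact trait matrix (preserving trait–trait correlations, which
a QTL-count null would destroy) and retains pairs whose observed count
exceeds the per-pair (1−α) null quantile; a pooled null is available. The
three-way term counts get the same treatment and define the
experiment-dependence flag (the dashed-edge convention in the SIF export).
The epistatic share of a trait's model variance is the pairwise-interaction
Type III SS over the summed model-term SS, in percent; group comparisons
use Welch's t-test.

## The synthetic-data generator

The generator is the package's study stand-in, and its defaults are the
study conditions: a deterministic 175-marker, 12-chromosome template map on
a rice-like scale (~1500 cM, uneven golden-ratio spacings, deliberate wide
gaps on chromosomes 3 and 9); RIL genotypes as independent two-state Markov
chains with the selfed-RIL transition probability; and replicated traits
`y = μ + Σaᵢxᵢ + Σwᵢⱼxᵢxⱼ + e·1[exp 2] + s·Σhᵢxᵢ + ε` with x = ±1
(A/Lemont = +1), `s = +1/−1` in experiments 1/2 (so G×E cancels in combined
means but contributes within-experiment variance), and
`ε ~ N(0, σ²k^{2·1[B at variance QTL]})`. Product-coded epistasis matches
the interaction term fitted downstream; the ±1 coding makes an additive
effect half the class difference, and the reporting layer converts to the
allelic-substitution scale. Baselines are log-normal-like and positive
(default μ ≈ 10, σ = 1) so CV is well defined; abundances of real
metabolomes are emulated only at the normalized-abundance level — no
spectra, retention times or instrument drift.

What passing tests on this generator do *not* show about real data:
real metabolite panels have correlated traits (shared pathways), heavier
tails, occasional missing replicates, and marker maps with genotyping
error; none of these are generated by default (trait correlation enters
only through shared loci, and missingness only via `missing_rate`).

A consequence worth knowing: per-line CV computed across all four
replicates absorbs between-experiment spread, so a locus with a G×E effect
on a trait that also has an experiment main effect is a genuine
variance-QTL for that CV trait (the within-line spread contains
`(e − 2hx)²`). The per-experiment CV option removes this channel. The
default follows the all-replicate convention.

## Numerical choices and degenerate inputs

* Thresholds are order statistics (`ceil((1−α)n)`), not interpolated
  quantiles; seeded and reproducible bit-for-bit.
* LOD cap 300; RSS floors at `RSS0·10^{−2·cap/n}` prevent log-of-zero.
* Monomorphic scan positions (zero predictor variance) score LOD 0.
* Pair-scan linear algebra uses closed-form 3×3 projections with
  determinant guards falling back to the additive 2-column or single-column
  reduction when a pair is collinear.
* Co-located markers collapse to one grid point; duplicated QTLs at one
  position are pruned by drop-one refinement.
* The sample (n−1) standard deviation is used in CV (four replicates,
  unbiased-variance convention).
* Median normalization is per sample (per-metabolite available); zero- or
  NA-median samples are flagged and left unscaled.
* All pipeline randomness derives from one master seed through fixed
  per-stage substreams, so changing one stage's draws cannot perturb
  another's.

## Problem sizes used by the tests and scripts

The test suite exercises the operating characteristics at sizes chosen to
make the Monte-Carlo answers sharp while keeping a full run in minutes on
one core: the oracle identities on 50 lines × 40 markers; scan type-I
error on 200 null traits at 1000 permutations each; single-QTL recovery
(20% PVE, 250 lines) over 50 replicates; heritability recovery over 100
replicates per target; hotspot and epistasis operating characteristics on
200-trait panels over 20 replicates; grid steps of 2–2.5 cM for the
replicated simulations and 1 cM elsewhere. The analysis drivers and the
acceptance script run the full pipeline at the study's population scale
(280 lines, 175 markers, 1 cM grid) with a 150-trait panel; the trait count
is the one dimension scaled below the study's ~500, which narrows the
panel-level summaries (medians, counts) without changing any per-trait
computation.

## Known limitations

* Two-point conditioning, not multipoint: with dense missingness the
  probabilities are coarser than an HMM's.
* EMS heritability assumes near-balance; heavily unbalanced designs should
  use a mixed model instead.
* The stepwise search is greedy; strongly correlated linked architectures
  can settle in local optima that exhaustive multi-QTL searches would not.
* The hotspot placement null conditions on the estimated QTL count and the
  map, not on the traits' correlation structure; the validation stage's
  line-permutation null is the complementary check, and a hotspot is only
  reported as such when it passes both.
* No X-chromosome handling, no composite interval mapping with cofactors,
  no three-locus epistasis search.
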