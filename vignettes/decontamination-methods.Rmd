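---
title: "Control-informed decontamination of low-biomass ASV tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-informed decontamination of low-biomass ASV tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asvdecon)
```

## The problem

Amplicon sequencing does not measure absolute abundance: a library is
made from whatever 16S copies are in the extraction, whether they came
from the sample or from the extraction kit, the sampling instrument, or
the air. For a high-biomass sample (adult feces, ~10⁹–10¹¹ copies) the
reagent background — on the order of 10³–10⁴ copies per extraction — is
invisible. For a newborn's meconium swab carrying 10³–10⁵ copies, that
same background can be most of the library. Any comparison of neonatal
and adult communities that ignores this will "discover" reagent organisms
(classically *Ralstonia*) as members of the newborn microbiota.

`asvdecon` removes contaminant-compatible ASVs by comparing each ASV's
behaviour in a sample group against its behaviour in two kinds of
negative controls:

* **instrument controls** — unopened sterile swabs taken through
  extraction and sequencing; they capture the kit/reagent background;
* **field controls** — swabs exposed to the sampling-environment air;
  they additionally capture airborne environmental input.

PCR no-template controls are reported but do not enter the rule: they
see only amplification-stage contamination, a subset of what the
instrument controls already capture.

## The removal rule

For sample group $g$ and ASV $a$, let $P_g(a)$ be the prevalence (the
proportion of $g$'s samples with ≥ 1 read of $a$) and $A_g(a)$ the mean
relative abundance (mean over $g$'s samples of $a$'s within-sample read
proportion). With control profiles $P_I, A_I$ (instrument) and
$P_F, A_F$ (field), the ASV is removed from group $g$ iff

$$
P_g(a) \le k_P \max\{P_I(a), P_F(a)\}
\quad\text{and}\quad
A_g(a) \le k_A \max\{A_I(a), A_F(a)\},
$$

with default factors $k_P = 2$ and $k_A = 10$. Design points worth
making explicit:

* **Inclusive comparisons.** Ties remove: an ASV at exactly twice the
  control prevalence and exactly ten times the control abundance is
  treated as contaminant-compatible. This is what "≤" means and the
  package implements it literally.
* **Multiplicative form.** The rule is evaluated as a product, never a
  ratio, so control entries of zero are unproblematic — and imply the
  important safety property that an ASV absent from *all* controls can
  never satisfy the prevalence criterion and is always kept wherever it
  occurs.
* **OR over control types.** "≤ 2× instrument controls or field
  controls" is read as an OR, equivalent to comparing against the
  maximum over the two control types. It is the natural reading and the
  more aggressive (contaminant-removing) one. The stricter AND parse
  (comparison against the minimum) is available via
  `control_combine = "and"` for sensitivity analysis.
* **Per-group filtering with group-local removal.** Each non-control
  group is filtered independently, and removal zeroes the ASV's counts
  only in that group's samples. The retained universe is the union of
  per-group retained sets, and control samples are re-tabulated over
  that universe rather than filtered themselves — which is why
  decontaminated controls keep small nonzero read totals, a useful
  quality readout. Group-locality matters: prevalences are only
  comparable within a batch of similar biomass, and an ASV can be a
  contaminant signature in one stratum and a genuine community member in
  another.
* **Prevalence as a proportion.** Groups and control sets differ in
  size (6 controls versus 11–18 samples), so prevalence is a proportion
  of samples, not a count; the detection threshold is ≥ 1 read because
  no per-sample minimum is otherwise defined. Zero-depth samples carry
  no compositional information and are excluded from both prevalence
  denominators and abundance means.

One subtlety follows directly from the rule: an ASV that is ubiquitous
in a group *and* in the controls (both prevalences 1.0) satisfies the
prevalence criterion, and will be removed whenever its group abundance is
within $10\times$ of the controls. Retention of genuine community
members relies on their prevalence or abundance genuinely exceeding the
control multiples — in real data, gut taxa are (near-)absent from
controls, which is what makes the rule safe in practice.

## Pre- and post-filters

Before decontamination, ASVs that no 16S analysis can use are dropped,
in a fixed first-match-wins order so every removal has one reason:
(1) no domain assignment; (2) domain-assigned but phylum-unassigned or
carrying a mitochondrial lineage token — these are mostly host
mitochondrial reads, whose 16S-like sequence classifies weakly;
(3) chloroplast lineages. A dataset-wide minimum-count filter then drops
ASVs seen fewer than 10 times in the entire dataset, controls included
("fewer than" is strict: a total of exactly 10 survives). The
minimum-count filter runs *before* decontamination so that control
profiles are built on the same feature set as the groups.

After decontamination, samples with fewer than 1500 accepted reads are
excluded from composition analyses; negative controls are exempt because
their post-filter totals are a reported metric, not analysed
communities. The threshold is configurable; the package encodes only the
numeric rule and surfaces per-sample totals so an analyst can apply
judgment to borderline cases.

## Sharing analyses

`dyad_shared_fraction()` asks, per mare–foal dyad, what percentage of
the foal's ASVs its own dam's compartment contains. The denominator is
deliberately the foal's set — the scientific question is how much of the
newborn community the maternal source can account for, not the reverse.
"Detected" means ≥ 1 read after decontamination. `reads_explained()`
complements the ASV count with an abundance-weighted view (the share of
each foal's reads carried by source-shared ASVs), since a few shared
ASVs can dominate a newborn community. Group-level Venn partitions
default to requiring detection in ≥ 2 animals per group
(`min_animals = 2`), which suppresses singleton noise in cross-group
comparisons; per-dyad analyses use `min_animals = 1` because each animal
contributes one sample. All-ASV Venns (`min_animals = 1`) remain
available.

## The statistical battery

All rank procedures use mid-ranks for ties and are implemented from
their explicit formulas; tests cross-validate them against base R's
`kruskal.test`, `friedman.test`, `cor.test` and `wilcox.test`, and the
post-hoc procedures against independent in-test recomputations.

* **Shannon diversity** uses the natural logarithm (the convention of
  the dominant microbiome packages); the base is configurable. No
  rarefaction is applied before diversity — deliberately, since the
  upstream design sequences groups to comparable depth — and because the
  index is depth-dependent this is stated prominently rather than
  hidden.
* **Kruskal–Wallis** with the standard ties correction
  $C = 1 - \sum(t^3 - t)/(N^3 - N)$; all-identical input returns
  statistic 0, p 1, rather than an error.
* **Nemenyi all-pairs (χ² form)** after Kruskal–Wallis: pairwise
  squared mean-rank differences scaled by $(N(N+1)/12)(1/n_i + 1/n_j)$,
  divided by the same ties correction, referred to χ² with $k-1$ df.
  For $k = 2$ this collapses exactly onto the Kruskal–Wallis p-value,
  which the tests assert.
* **Friedman** for unreplicated blocks with the within-block ties
  correction, mirroring the reference implementation; fully tied input
  returns statistic 0, p 1.
* **Nemenyi for blocked data** on the studentized range:
  $q = |\bar R_i - \bar R_j| / \sqrt{k(k+1)/(6n)}$, with
  $p = P(Q_{k,\infty} > q\sqrt 2)$. For $k = 2$ this reproduces the
  Friedman p-value.
* **Mann–Whitney U** enumerates the exact null distribution over all
  rank assignments when both arms have ≤ 8 observations and no ties
  (cheap: at most $\binom{16}{8}$ subsets), and otherwise uses the
  tie-corrected normal approximation with continuity correction. The
  study's own comparisons (e.g. 11 newborns vs 6 field controls) sit in
  the asymptotic regime.
* **Spearman** on mid-ranks with the t-approximation and optional
  Bonferroni correction over an explicit family size. The profile
  representation for dyad correlations (taxonomic level, union versus
  intersection support) is a parameter; the default is ASV-level over
  the union, with zeros for absences.
* **Mock-community check**: per-taxon absolute deviation and total
  variation distance between an observed and an expected composition;
  labels present on only one side are pooled into side-specific "other"
  masses so that disjoint compositions are at distance 1.

## The synthetic-data generator

`simulate_dataset()` emulates the study design so every stage is
testable without any sequence data: 14 mare–foal dyads; foal rectal
samples at 0 h, 24 h and 7 d; mare feces, vagina and mouth; 3 PCR, 6
instrument and 6 field controls. Its model:

* **Biomass** is log-uniform per group: 10³–10⁵ copies at 0 h,
  10⁸–10¹⁰ at 24 h, 10⁹–10¹¹ at 7 d, 10⁸–10¹¹ for mare compartments.
* **Contamination is a fixed additive copy load** (default 4×10³
  copies per extraction, the field-control level; 10³ in PCR controls;
  field controls add a 700-copy environmental trace). A fixed load —
  not a proportional one — is what makes low-biomass samples
  contaminant-dominated and is the standard view of reagent
  contamination kinetics. Expected composition is
  `biomass × true profile + load × contaminant profile`, and reads are
  drawn multinomially at a depth ~ Normal(6×10⁴, 10⁴) truncated at
  2×10³, matching typical MiSeq per-sample yields.
* **True communities** are log-normal abundance profiles with
  group-specific richness (0 h 80, 24 h 30, 7 d 90, mare feces 350,
  vagina 90, mouth 25) and dispersion chosen to reproduce the familiar
  diversity ordering (adult feces ≫ 0 h > 7 d > 24 h ≫ mouth). Foal
  profiles are seeded from the *paired* dam's compartments at
  configured transmission fractions (0 h: 9% feces / 4% vagina / 0.3%
  mouth of the foal's richness; 24 h: vagina-dominant; 7 d:
  feces-leaning) plus an age-specific novel pool; the assignment is
  recorded as ground truth.
* **Taxonomy** draws from a small bundled lexicon — *Ralstonia*-heavy
  contaminant genera, typical intestinal and mucosal genera — so
  taxon-level rollups are exercisable.

Everything is deterministic given `(config, seed)`. What the generator
does *not* model: sequence-level error, chimeras, PCR preamplification
bias, batch effects, or cross-contamination between samples. Passing
tests on synthetic data therefore demonstrate that the filter removes
additive reagent-style contamination and spares control-absent
community members under realistic biomass gradients — not that it
corrects batch effects or index hopping in real runs.

Because true ASVs never appear in the simulated controls, the filter's
specificity on synthetic data is essentially perfect; the demanding part
of the recovery criterion is sensitivity in the lowest-biomass group,
where rare contaminant ASVs may evade the controls by sampling chance.

## Numerical and degenerate-input choices

* Counts are validated as non-negative integers (tolerance 1e-8 on
  integrality) with offending cells named.
* Zero-depth samples: excluded from prevalence/abundance denominators;
  all-zero rows in relative-abundance output are flagged, not NaN.
* Degenerate statistics (all-identical values, fully tied blocks,
  zero-variance profiles) return the conventional boundary results
  (statistic 0 / p 1) or an explicit NA-with-warning for undefined ρ,
  never silent NaNs.
* `taxon_removal_rollup()` on a taxon with zero reads in scope signals
  an undefined result (NA with warning) rather than returning a number.
* Venn regions are computed exactly from membership signatures;
  region counts always sum to the union cardinality.

## Problem sizes used in the test-suite and acceptance runs

The bundled checks run the brute-force decision oracle on 1000 random
tables of up to 10 samples × 50 ASVs, score parameter recovery on 20
generator seeds at the default design (99 samples, ~900 ASVs), and
cross-validate every statistical procedure on ≥ 10 seeded fixtures.
These sizes give stable Monte-Carlo summaries while keeping a full run
in the minutes range on a single core; the generator scales linearly in
samples × ASVs if larger experiments are wanted.

## Known limitations

* The rule compares marginal summaries (prevalence, mean relative
  abundance); it does not model the frequency–biomass relationship that
  dedicated contaminant classifiers exploit when qPCR concentrations
  are available for every sample.
* An ASV ubiquitous in both a group and the controls is removed (see
  above); with heavily contaminated *controls* this can discard genuine
  organisms. The factors and the OR/AND switch are the available
  levers.
* Shannon values are depth-dependent and no rarefaction is performed.
* 16S resolution cannot support strain-level transmission claims; the
  sharing analyses count identical ASVs, nothing more.
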