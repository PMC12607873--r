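---
title: "Quantifying the ecological fidelity of human microbiota-associated mice"
author: "hmaFidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the ecological fidelity of human microbiota-associated mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmaFidelity)
```

## The scientific problem

Human microbiota-associated (HMA) mice are germ-free or antibiotic-treated
mice colonized by gavage with human stool, widely used as "avatars" of a
donor's gut ecosystem. Their value rests on an assumption this package is
built to interrogate: that the recipient community faithfully reflects the
donor community, and that ecological responses to an intervention in the
donor (for example a therapeutic bacterial consortium) are recapitulated in
the mice. In practice only a subset of donor taxa establishes in the mouse
gut, and the taxa that do engraft tend to be the same mouse-adapted genera
regardless of donor, so HMA mice from unrelated donors can end up more
similar to each other than to the people they were derived from.

`hmaFidelity` packages the statistics needed to quantify this: per-taxon
engraftment rates with a high/medium/low stratification, beta-diversity
permutation tests comparing donors against recipients, and donor-recipient
concordance of abundance changes and abundance profiles. A parametric
cohort simulator with a truth sidecar makes every stage testable without
sequencing data, and provides parameter-recovery checks for the estimators.

## Data model

Relative abundances live in a `TaxonTable`, a `SummarizedExperiment` with
one assay `"ra"` on the **percent** scale (columns sum to 100 after
`renormalize()`). Percent, not proportion, is the canonical unit
throughout; Bray-Curtis is scale-invariant after renormalization, so no
conversions are needed. Sample annotations (host species, donor, timepoint,
study, exposure route, replicate group) are a validated `DataFrame`;
`buildPairing()` derives the donor-to-recipient-group `PairingMap` from
them by matching donor identity and timepoint.

Two input dialects are read: a plain `taxon` x samples TSV, and merged
profiler output whose first column holds rank-prefixed taxonomy strings
(`k__...|g__...|s__...`); in the latter case only rows terminating at the
requested rank are kept and unclassified terminal clades are dropped with a
message. Whether unclassified fractions should instead be retained before
renormalization is not settled usage; dropping and logging keeps the
retained composition interpretable, and the renormalization flag makes the
lost mass visible.

## Pseudo-replication control

Cage mates seeded from a single donor stool are technical replicates, not
independent samples. `averageReplicates()` therefore collapses every
replicate group to its arithmetic mean profile before any between-group
statistic (dissimilarity categories, correlation categories, ordination
group tests). Averaging of 100-sum columns already yields a 100-sum column,
so the renormalization that follows is a guard, not a transformation. The
mean is arithmetic: the profiles are compositions on a linear scale and the
collapsed profile should be the expected composition of the cage, not a
geometric compromise. Averaging is idempotent, which the test suite checks.

Downstream, "mouse" units are these replicate-group profiles. The same rule
shapes engraftment: a recipient group counts as carrying a taxon if any
member mouse does, since averaging preserves any positive value.

## Abundance filtering and display

`filterLowAbundance()` retains a taxon iff its maximum percent RA across
samples reaches the threshold (default 0.1%). The convention is that
"contributing less than 0.1% in one sample" is removed, so a taxon at
exactly 0.1% survives. The filter feeds association and correlation stages
and deliberately does not renormalize. For display, `logDisplay()` maps
positive values to log10 and pins zeros to a floor (default -3, i.e.
0.001%), below any plausible detection limit.

## Beta diversity

`brayCurtis()` implements d(i,j) = sum|x-y| / sum(x+y) over taxa and is
checked against a naive double-loop evaluation and against `vegan::vegdist`
to 1e-12. `pcoa()` is classical metric scaling (Gower double-centering of
-d^2/2); axes with eigenvalues at or below 1e-12 contribute zero
coordinates, and `proportionExplained` is normalized over the positive
eigenvalue sum. Negative eigenvalues - expected for a semi-metric like
Bray-Curtis - are kept.

`permanova()` computes the one-way pseudo-F from total and within-group
sums of squared dissimilarities and permutes group labels;
`R^2 = SS_between/SS_total`. `permdisp()` tests homogeneity of dispersion:
each sample's distance to its group centroid is computed in the corrected
principal-coordinate embedding, where squared real-axis contributions are
reduced by imaginary-axis contributions and floored at zero, and a one-way
ANOVA F compares groups. Group centroids rather than spatial medians are
used - centroids are the variant with the clean eigenspace correction and
the common default. Permutations relabel samples and recompute the full
statistic (centroids included) within the fixed embedding, which does not
depend on labels; in simulations this variant held the 5% level within
[0.035, 0.065] at two groups of six, whereas permuting the fixed centroid
distances alone was mildly liberal at that sample size.

Both tests report the bias-avoiding permutation p-value (1+b)/(1+m), so p
is never 0 and never below 1/(m+1). The permutation count defaults to 999
and a seed is mandatory: there is no hidden global RNG state, and repeated
calls are reproducible by construction.

`extractGroupDissimilarities()` partitions every unordered off-diagonal
pair of the (replicate-averaged) dissimilarity matrix into donor-donor,
mouse-mouse, donor-paired-recipient and donor-other-recipient, which feeds
`compareGroups()`: Kruskal-Wallis with midranks and tie correction followed
by Dunn's z-tests (Bonferroni-adjusted by default - the adjustment is a
free parameter since conventions differ), or one-way ANOVA with Tukey HSD.
The omnibus statistics delegate to `stats::kruskal.test` and `stats::aov`;
Dunn's pairwise z is implemented here. A fully degenerate input (all values
identical) reports H = 0, p = 1 with a warning rather than NaN.

## Engraftment statistics

For each taxon, percent engraftment is 100 x (donors whose paired
recipient group also carries the taxon) / (donors carrying the taxon),
with presence meaning RA strictly above a detection threshold (default 0;
configurable because profiler floors differ). Counting donors rather than
raw pairs keeps the numerator bounded by the denominator if one donor
sample ever maps to several recipient groups; in the one-group-per-donor
designs analyzed here the two counts coincide. Taxa never seen in a donor
have an undefined denominator and are excluded.

Engraftment displays conventionally restrict to taxa engrafting in more
than four mice: `filterEngrafters()` keeps `n_pairs_engrafted >= 5`.
`stratifyEngrafters()` averages percent engraftment across studies and
labels taxa high (mean > 80), medium (60 <= mean <= 80) or low
(mean < 60) - the only reading of exclusive "high > 80" / "low < 60"
bounds that partitions the scale. `donorEngraftmentFraction()` reports the
per-donor breadth of transfer (share of donor taxa recovered in the paired
group), and `engraftmentAbundanceCorrelation()` the Pearson association
between a taxon's engraftment rate and its mean abundance in recipients.

## Concordance

`deltaRA()` computes per-taxon changes in percent RA between two
timepoints for each donor entity (human samples, or the mean over a
donor's mouse profiles), treating absence as zero. `deltaConcordance()`
restricts to taxa observed in both hosts (any timepoint - a taxon present
in mice only at baseline still overlaps), correlates the paired deltas,
and reports sign-quadrant percentages. Taxa with a zero delta on either
axis lie on a quadrant boundary; they are excluded from the quadrant
denominator but retained in the correlation, so the quadrant fractions
always sum to 100 over off-axis taxa.

`sampleCorrelationMatrix()` pools tables by taxon union with zero fill
(absence is a true zero on the percent scale; taxa absent from every
sample are dropped, making the result invariant to padding), correlates
sample profiles on the linear percent scale, and stores both r and the
Fisher transform z = atanh(r) with |r| clamped to 1 - 1e-15. Clamping
rather than dropping perfect correlations preserves pair counts in small
designs. `groupCorrelationSummary()` classifies pairs as human-human,
human-mouse or mouse-mouse (within and across studies), reports category
means of the untransformed r - the display convention - while running the
ANOVA/Tukey comparison on z, the variance-stabilized scale appropriate for
testing.

## The synthetic cohort generator

The generator is a mechanistic host-filter model, not a fit to any
dataset. Its components:

* **Donor communities.** Each taxon has a log-normal abundance law
  exp(N(mu, sigma)); carriage is Bernoulli with probability derived from
  mu by a saturating abundance-occupancy rule, `min(1, plogis(mu) * 1.15)`,
  so consistently abundant taxa are core to every donor while low-mu taxa
  are patchy.
* **Host filtering.** For every donor-taxon with positive abundance, one
  Bernoulli draw with the taxon's engraftment probability decides whether
  it colonizes that donor's mouse lineage. The draw is shared by all
  replicate mice: engraftment is modelled as a colonization event of the
  cage, which is what makes cage mates technical replicates. Engrafted
  abundance is donor RA x mouse fitness x exp(N(0, noiseSd)) per mouse,
  renormalized.
* **Consortium exposure.** `spikeConsortium()` scales resident taxa to
  (100 - dose)% and distributes the dose equally over consortium members,
  so a consortium-free community carries exactly the dose after spiking.
  `generateCohort()` wires the two exposure routes: HTR seeds separate
  mouse lineages from pre- and post-treatment donor stool (post = drifted
  and spiked); MTR seeds mice from pre-treatment stool and spikes them
  directly, gating newly introduced consortium taxa by their engraftment
  probability.

The default truth (`defaultTruth()`) encodes the study conditions the
analyses assume: 120 taxa of which 20 form a core of mouse-adapted,
high-prevalence taxa (mu ~ N(2.3, 0.7), sigma in [0.25, 0.5], engraftment
probability 0.95, fitness ~ lognormal(log 2, 0.1)) and 100 are variable,
human-specific taxa (mu ~ N(-0.3, 0.15), sigma in [1.5, 2.2], probability
0.03, fitness 0.6); replicate noise sd 0.3; a 30-member consortium of 10
core and 20 variable taxa, mirroring a therapeutic consortium whose
members span the engraftment spectrum. Two features of this regime carry
the qualitative behaviour and were chosen for mechanistic reasons, checked
for robustness across independent truth draws rather than tuned to any
single seed:

* the variable block is *patchy and heavy-tailed* (prevalence around 0.5,
  large sigma), so each human is dominated by donor-specific taxa that two
  humans rarely share - this keeps human-human profile correlations
  moderate, as observed in real cohorts;
* the core block has *small donor-to-donor scatter and near-uniform
  fitness*, so every mouse community converges toward a consensus
  fitness-weighted core profile. Correlation with a consensus exceeds
  correlation between two noisy realizations, which is exactly why
  mouse-mouse agreement is highest and human-mouse agreement exceeds
  human-human agreement in this model, the ordering reported for real HMA
  cohorts.

What the generator does **not** emulate: ecological interactions
(competition, cross-feeding), strain-level dynamics, sequencing noise and
compositional detection limits, diet or housing covariates, and any
taxonomy-specific biology - taxa are exchangeable labels. Passing the
qualitative checks on these cohorts therefore shows that the estimators
detect the modelled mechanism correctly, not that any particular real
cohort satisfies the model.

## Problem sizes and numerical conventions

The simulation-backed checks run at sizes chosen to make their Monte-Carlo
error small relative to the margins being tested: type-I error of the
permutation tests over 2,000 null datasets (two groups of six, 999
permutations each, iid log-normal compositions); engraftment recovery over
500 cohorts of 50 carrying donors, pooled over true probabilities 0.9,
0.7, 0.3 against a two-standard-error binomial band; qualitative
orderings over 200 cohorts (6 donors for the dissimilarity pattern,
matching a single-trial cohort; 12 donors for the correlation pattern,
matching a pooled multi-study analysis). Sampler p-values are compared to
full enumeration on designs of up to 8 samples, where all label
assignments can be listed.

Degenerate inputs fail loudly rather than silently: all-zero sample
columns cannot be renormalized, singleton groups have no dispersion,
single groups no between-group variance, donors with no detected taxa no
engraftment breadth. Ties in rank tests use midranks with the standard
correction factor. Permutation ties (|F_perm - F_obs| below 1e-12) count
as exceedances, keeping p conservative.

## Pipeline

`runPipeline()` chains simulate, preprocess, beta diversity, engraftment
and concordance with a validated configuration (list or YAML), writing
each stage's TSVs before the next stage runs, a `summary.json` with every
statistic, and a run log. All randomness flows from the single configured
seed, so identical configurations produce byte-identical summaries -
checked in the test suite. Figures are deliberately out of scope: the tidy
TSVs are the canonical outputs and can be plotted with any tool.

## Known limitations

* The engraftment estimator treats recipient groups as units; studies that
  track individual mice longitudinally need a different variance model.
* PERMANOVA is one-way only; stratified or multi-factor designs are out of
  scope.
* Correlation categories weight every sample pair equally; unbalanced
  cohorts give abundant-study pairs more influence on category means.
* The simulator's independence assumptions (no taxon interactions) make
  its dissimilarity distributions smoother than real data; effect sizes
  estimated on it transfer to real cohorts only qualitatively.
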