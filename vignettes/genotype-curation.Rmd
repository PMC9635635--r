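---
title: "Curating two-generation cross genotypes: models and design choices"
author: "crossqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating two-generation cross genotypes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossqc)
```

This vignette documents the statistical model behind `crossqc`, the
rationale for every tunable parameter, what the simulator does and does not
emulate, and the numerical choices made where the design was genuinely open.
The README shows the user-facing workflow; here we explain *why* the
pipeline is built the way it is.

## The genetic model

A two-generation cross between two inbred strains has a deliberately simple
genetic structure. Every second-generation individual is a mosaic of the two
parental genomes. At any marker, an F2 intercross segregates
1:2:1 (P1 homozygote : heterozygote : P2 homozygote) on autosomes, and an N2
backcross segregates 1:1 (recurrent homozygote : heterozygote), with no
other genotype possible. Between two markers at genetic distance $d$ cM, the
per-gamete recombination probability under the Haldane (no-interference)
model is

$$ r = \frac{1 - e^{-d/50}}{2}, \qquad d = -50\,\ln(1 - 2r). $$

Each of these structural facts is a filter: a genotype that violates them is
more plausibly an assay artifact than biology. The pipeline turns them into
a cascade over a per-marker ledger; a marker is retained only if no filter
flags it. Flags are tristate (`untested`/`pass`/`fail`), so the provenance
of every exclusion is preserved and the cascade can be re-run or re-ordered:
the missingness, polymorphism and proportion filters read only the genotype
counts and are therefore order-invariant and idempotent by construction.

## Allele handling

Raw service files carry two allele columns per call. These are collapsed at
read time to a six-letter alphabet (`A/C/G/T/H/N`) and the two-column form
never propagates further: one normalization point, one invariant alphabet.
A `-` in either allele column makes the call `N`; the file format does not
distinguish a half-missing call from a fully missing one, and treating any
`-` as missing is the conservative reading.

Parental alleles come from a consensus over replicate samples per strain:
unanimity among non-missing calls wins, any disagreement yields `N`. We
deliberately do not majority-vote — replicate disagreement in an inbred
parent is itself a red flag, and a missing consensus simply routes the
marker through the imputation or exclusion logic of the allele filter.

When exactly one parental allele is missing (and strict mode is off), the
other is imputed as the unique additional base observed among homozygous
offspring. Two design points here:

* only homozygous offspring calls drive imputation. A heterozygous call at
  such a marker is consistent with *any* second allele and identifies none.
* two or more candidate bases make the imputation ambiguous and fail the
  marker outright, rather than guessing.

Imputation provenance is recorded (`p1_source`/`p2_source` = `"imputed"`),
so running the allele filter in strict `parNH` mode afterwards
retro-excludes previously imputed markers — strict mode means "parental
alleles must be directly observed and homozygous", not merely "currently
known". A heterozygous parental call is treated as unknown in non-strict
mode: parents are expected inbred, and an `H` signals residual
heterozygosity that strict mode exists to catch.

One subtlety in the parent-monomorphic rule (parents share one allele,
offspring polymorphic): a heterozygous offspring call counts as evidence of
a second allele even if only one homozygous base is seen, because the
Illumina pair behind an `H` contains two distinct bases by definition.

## Filter thresholds

| parameter | default | reading |
|---|---|---|
| `na_max` | 0.5 | fail when missing fraction is strictly **>** 50% |
| `prop_min_homo`, `prop_min_het` | 0.10 | fail when a class proportion is strictly **<** 10% |
| `chi2_alpha` | 0.05 | chi-square mode significance level |
| `x_prop_min` | 0.10 | X chromosome, homozygote classes only |
| `bypass_chromosomes` | Y, M | exempt from the proportion filter |
| `wrong_homo_tol` | 0 | tolerated wrong-allele homozygotes in an N2 |
| `estmap_threshold` | 100 cM | map-sanity distance threshold |

The strict/non-strict inequalities are deliberate: a marker with exactly 50%
missing passes, a class at exactly 10% passes. The X chromosome is tested on
its two homozygote classes only: hemizygous males are read by the assay as
homozygotes, so without sex metadata the heterozygote proportion mixes male
hemizygotes and female heterozygotes unpredictably; the homozygote-deficit
check remains meaningful. Y and mitochondrial markers have no diploid
segregation to test and pass untested. The backcross wrong-homozygote rule
fires on a single wrong homozygote by default — one impossible genotype is
already evidence of an assay problem — but the count is configurable for
users who prefer to tolerate isolated miscalls.

## Recombination fractions and the map-sanity filter

The map filter needs only *adjacent-pair* recombination fractions, so we
estimate them pairwise rather than re-fitting a multipoint map. This is a
deliberate deviation from multipoint EM (as in R/qtl's `est.map()`): it is
self-contained, fast, and exact for the quantity the filter consumes, at the
cost of slightly different estimates next to markers with heavy missingness
— which can shift borderline exclusions relative to a multipoint fit.

For a backcross the estimate is the direct recombinant proportion (each
individual carries one informative gamete). For an intercross the two-locus
class table is incomplete data: every class except the double heterozygote
determines its recombinant-gamete count exactly (concordant corners 0,
discordant corners 2, homozygote × heterozygote 1), while the double
heterozygote mixes coupling (0) and repulsion (2) with conditional
expectation $2r^2 / (r^2 + (1-r)^2)$. The EM update divides expected
recombinant gametes by twice the informative count. Numerical choices:

* start at $r_0 = 0.25$, an interior point that avoids the boundary fixed
  points at 0 and 1; tolerance $10^{-6}$ on successive iterates, at most
  1000 iterations (convergence is typically ~20 iterations);
* the iteration runs over $r \in [0, 1]$ and the result is folded to
  $\min(\hat r, 1 - \hat r)$. An allele-origin mislabeling at one marker
  maps the table to its row-swap, whose likelihood peaks at $1 - r$; folding
  makes the estimate invariant to the swap instead of saturating at 0.5;
* a table containing only double heterozygotes has a likelihood flat in the
  phase direction; it is reported unconverged with `r_hat = NA` rather than
  returning an arbitrary point;
* $\hat r$ is capped at 0.499 before the Haldane transform so that
  independent markers produce a large-but-finite distance (≈310 cM) instead
  of infinity. The cap is far above any plausible adjacent distance and far
  below nothing — it only needs to land on the "absurd" side of the
  map-sanity threshold.

The map-sanity filter fails a marker only when its estimated distance to
**every** adjacent retained marker exceeds the threshold (chromosome ends
are judged on their single neighbor). The threshold defaults to 100 cM:
genuine adjacent intervals in a dense array are a few cM, while a defective
assay is essentially independent of both neighbors and lands near the
310 cM cap — the regimes are separated by an order of magnitude on either
side of 100. The filter is single-pass; after removal the caller may
re-estimate and re-run, and `run_pipeline()` runs exactly one pass, which
suffices because a defective marker's exclusion does not create new
long distances between its (formerly) flanking markers beyond their true
spacing.

The EM implementation is validated against an independent brute-force
oracle: the two-locus multinomial log-likelihood maximized over a grid of
step $10^{-4}$, with agreement required within $10^{-3}$ (tests), and
observed agreement around $5\times10^{-5}$.

## The simulator

`simulate_cross()` generates gametes as Markov chains along each
chromosome: crossover between adjacent markers with the inverse-Haldane
probability of their known spacing, no interference (matching the map
function used everywhere else), two independent gametes per F2 individual,
one plus a constant recurrent gamete per N2 individual. Parental strains are
fully inbred unless a residual heterozygosity rate is configured. Phenotypes
are standard normal noise, optionally with one additive marker effect for
end-to-end demonstrations. Error classes are injected by transforming clean
markers: assay noise (`random_call`), parent/reference mismatches
(`parent_mismatch`), the parent-monomorphic/offspring-polymorphic pattern
(`parent_monomorphic_sgipoly`), monomorphic markers (`nonpolymorphic`) and
high missingness (`high_missing`).

Defaults mirror a realistic MiniMUGA mouse intercross: 176 individuals,
~93% call rate, evenly spaced autosomal markers. What the simulator does
**not** emulate: clustered or intensity-dependent missingness, linkage
disequilibrium between error markers, annotation misplacement (wrong
chromosome/position), sex chromosomes with proper male hemizygosity (X is
simulated autosome-like when present in the map), and crossover
interference. Passing tests therefore demonstrate that each filter detects
the error pattern it targets under clean Mendelian sampling — not that the
thresholds are optimal for any particular real array.

## Validation problem sizes

The checked properties and the sizes chosen for them: EM-vs-grid agreement
on 100 random tables (n = 50–500); estimator bias at true r = 0.1 over 200
replicates of n = 176; chi-square type-I rate on 1000 unlinked clean markers
(expected 5% at α = 0.05); cascade sensitivity/specificity on ~2000 markers
with 10 injected markers per error class (observed: 100% of injected
excluded, ≥95% required; ~3–4% of clean markers lost, almost entirely the
chi-square construction rate); genome-wide estimated/known map-length ratio
on a curated clean cross (observed ≈1.02, required within [0.85, 1.30]) and
on an uncurated cross with random-call markers (observed ≈2.6, required
>2). These are also the quantities `scripts/acceptance.R` recomputes.

## Known limitations

* No per-individual QC (sample call rate, sex checks, duplicate detection)
  — the unit of curation is the marker.
* No multipoint map re-estimation or marker re-ordering; the map filter
  assumes the annotation order is correct.
* X-chromosome filtering without sex metadata is necessarily conservative;
  users with sex information can tighten `x_prop_min` or filter X markers
  with their own rule.
* The proportion-mode retained set depends on thresholds that published
  analyses do not always report; when reproducing a published count, the
  chi-square mode with its explicit α is the better-specified choice.
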