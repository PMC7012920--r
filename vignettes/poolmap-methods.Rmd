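---
title: "Methods: pooled-segregant mapping statistics and the F2 simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-segregant mapping statistics and the F2 simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolmap)
```

## The mapping problem

An F2 population segregating for a quantitative trait is phenotyped, and two
bulks of extreme individuals (a *high* pool and a *low* pool) are sequenced
as pools. At a marker linked to a causal locus the two pools carry skewed
parental allele frequencies; away from causal loci both pools sit near the
F2 expectation of 0.5. `poolmap` implements the pooled statistics
(SNP-index, windowed Δ, confidence envelopes, candidate-interval
extraction), a conventional single-marker LOD scan for the full population,
a pool-contrast read-depth scan for large insertions, and — because every
stage needs to be testable without sequencing data — a simulator that
generates the whole study in silico.

## SNP-index and the combined Δ statistic

For pool $p$ and marker $m$, with $a$ reads carrying parent A's allele and
$b$ reads carrying parent B's,

$$\mathrm{SI}_P(p, m) = \frac{\#\{\text{reads carrying } P\text{'s allele}\}}{a + b}, \qquad P \in \{A, B\},$$

computed by `compute_snp_index()`. Markers with fewer than `min_depth`
(default 5) reads in a pool are set missing and never enter window
averages; the default echoes the conventional per-sample DP < 5 variant
filter, since no separate pool-level floor is established practice.

Windows of `window` bp advancing by `step` bp (defaults 200 kb / 20 kb)
average the per-marker indices per pool (`window_deltas()`), and each
reference parent contributes a windowed difference

$$\Delta_P = \overline{\mathrm{SI}}_P(\mathrm{high}) - \overline{\mathrm{SI}}_P(\mathrm{low}) \in [-1, 1].$$

The two-reference statistic is reported as
$\Delta_{\mathrm{comb}} = \Delta_A - \Delta_B \in [-2, 2]$. The subtraction
is deliberate: on shared biallelic markers $\mathrm{SI}_B = 1 -
\mathrm{SI}_A$ identically, so $\Delta_B = -\Delta_A$ and a literal sum of
the two orientations would cancel to zero. Subtracting (equivalently,
summing after orienting both terms so that high-pool enrichment for parent
A's alleles is positive) yields a non-degenerate statistic with the
familiar −2..+2 range, and reduces to $2\Delta_A$ when both reference sets
contain the same markers — an identity the test suite asserts. In a
real-data setting the two reference sets are instead the two
variant-calling passes (sites where parent A differs from the assembly
used for alignment, and sites where parent B does), which is why the
statistic is parameterized by two index tables rather than one. The sign
convention is a package convention; flip `reference_parent` to invert it.

### The 0.3/0.7 co-segregation filter

`filter_cosegregating()` removes markers whose index is below `low` (0.3)
in **both** pools or above `high` (0.7) in **both** pools: same-side
extremes in both pools mean the pools co-segregate one genotype (typically
a mis-genotyped parental site) and carry no contrast. The direction of
this rule is genuinely ambiguous in common usage, so two alternatives are
selectable: `"either-pool"` (drop anything extreme anywhere — note this
deletes true causal signal, where the high pool is legitimately extreme)
and `"keep-extreme"` (retain only extreme markers). The both-pools rule is
the default because it is the only one of the three that removes
uninformative markers without touching causal ones.

### Confidence envelopes

No closed-form null for the windowed statistic is attempted. Instead
`confidence_envelope()` simulates, per window, `n_sims` replicates of the
null in which pooling is independent of genotype: each replicate draws
`pool_size` F2 genotypes per pool from the 1:2:1 distribution, then
binomial read counts at the window's mean depth for each of its markers,
and recomputes $\Delta_{\mathrm{comb}}$. The `(1 \pm \gamma)/2` percentiles
give the envelope at confidence $\gamma$. Windows with identical marker
count and (rounded) mean depth share one simulation, which keeps the cost
at a few seconds for thousands of windows. Two conventions matter:

* pool genotypes are redrawn per replicate, matching the marginal
  distribution of a random F2 pool (the genome-wide correlation induced by
  using *one* pool for all windows is a property of a single run, not of
  the null distribution of a window);
* with `shared_markers = TRUE` (the synthetic layout) the null combined
  delta is exactly $2\Delta_A$; with disjoint reference sets the two terms
  are simulated independently, which narrows the envelope by $\sqrt{2}$.

### Candidate intervals

`find_candidate_interval()` selects the run of `k` consecutive windows
maximizing the minimum $\Delta_{\mathrm{comb}}$ (ties by summed delta,
then leftmost) and intersects them: `[start of last window, end of first
window]`. With 200-kb windows, 20-kb steps and `k = 5` the raw
intersection is exactly `200 - 4 × 20 = 120` kb. Bounds are then refined
outward to the nearest retained SNP at or beyond each raw bound, because
the true interval boundary is only resolved to the nearest observed
marker. `genes_in_interval()` and `report_candidates()` map the refined
interval onto a GFF3 annotation (via `rtracklayer`/`GenomicRanges`) and
rank genes: pathway-annotated genes containing a depth dip first, then
pathway-only, then dip-only, then the rest, by position within rank.

## The LOD linkage scan

`lod_scan()` replaces composite interval mapping with a single-marker
regression scan: phenotype on additive dosage plus a dominance indicator,

$$\mathrm{LOD}(m) = \frac{n}{2}\,\log_{10}\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1},$$

where the three-genotype model's $\mathrm{RSS}_1$ equals the
within-genotype-class sum of squares (the design is saturated), which the
implementation exploits to vectorize the scan. The simulated contrast this
package studies — extreme-pool statistics versus full-population
association — depends on the two sampling designs, not on cofactor
machinery, so interval mapping between markers and cofactor selection are
out of scope. Scans are indexed by physical position; the simulated map
has no separate genetic-distance coordinate. Numerical conventions:
$\mathrm{RSS}_1$ is floored at $10^{-12}\,\mathrm{RSS}_0$ so perfect fits
stay finite; a constant phenotype returns an all-zero profile with a
warning; `bin_size > 1` merges consecutive markers by per-individual
majority genotype (ties to the smaller code). Genome-wide significance
uses `lod_permutation_threshold()`, the standard permutation null of the
maximum LOD.

## The depth-contrast insertion scan

A large insertion present in one parent but absent from the alignment
reference leaves a local collapse of mapped depth in the pool enriched for
that parent: reads spanning the insertion fail to map over a halo around
the insertion point. `detect_depth_dips()` smooths each pool's per-base
depth with a centered moving average (truncated at region edges), forms
the ratio `(smoothed affected + pseudocount) / (smoothed other +
pseudocount)`, and emits maximal runs below `ratio_threshold` of length at
least `min_length`, testing each pool as the affected one (so relabeling
pools swaps the attribution, never the interval). Defaults — 50-bp
smoothing, threshold 0.5, 50-bp minimum, pseudocount 1 — are set to detect
a ~100-bp-halo collapse at 20–30× depth with wide margin while keeping
the false-call rate on dip-free Poisson profiles below one call per
megabase (asserted in the tests). Between-pool yield normalization is not
applied by default; the ratio is invariant to it only when both pools have
comparable totals, so unequal libraries should be depth-normalized
upstream.

## What the simulator emulates

`simulate_gametes()` draws, per gamete, a genome-wide crossover count
uniformly from the closed integer range `[round(25 × 0.8), round(25 ×
1.2)] = [20, 30]` — the "about 25, within 20%" convention; a zero bias
degenerates to a constant count. Counts are apportioned to chromosomes by
a multinomial on chromosome length (10 equal chromosomes thus average 2.5
crossovers each), positions are uniform, and each chromosome's starting
phase is a fair coin. `make_f2_population()` pairs egg and pollen
haplotypes (a permutation pairing when the counts match the population
size, so every simulated haplotype is used exactly once) and codes
genotypes 0/1/2 as parent-B allele counts.

The default trait architecture (`default_trait_architecture()`) has six
loci: a dominant suppressor on chromosome 2 whose suppressor allele comes
from the *non-trait* parent (so the trait parent scores 1.0, the other
parent and the F1 score 0.0), and five recessive direct loci — 60% on
chromosome 4 and four 10% effects on chromosomes 1, 6, 8, 10 — each
contributing only when homozygous for the trait parent's allele. Loci sit
on the marker nearest each chromosome midpoint.

`select_pools()` samples `pool_size` individuals uniformly from
phenotype > 0.7 (high) and phenotype = 0 (low). `simulate_pool_reads()`
draws exactly `depth` reads per marker (a Poisson depth is available as
`depth_model = "poisson"`; the fixed default makes unit tests exact); each
read picks a pool member uniformly, one of its two allele copies
uniformly, and flips with probability `error_rate` — equivalent to one
binomial draw per marker at the error-adjusted pool allele frequency,
which is the implementation. The default `error_rate` of 0.01 is a
typical short-read substitution scale; the read model otherwise has no
error process.

Default genome: 10 chromosomes × 30 Mb with 5000 uniformly spaced markers
each — a desk-scale stand-in for a million-SNP parental map that keeps
every windowed computation realistic (about 33 markers per 200-kb window)
while the full synthetic study runs in seconds.

### What it does not emulate

Crossover interference (counts are multinomial, not interfering), genetic
vs physical distance, marker ascertainment bias, depth heterogeneity along
the genome, mapping artifacts, indels, and linkage disequilibrium with
unmodeled loci. Tests passing on this generator therefore demonstrate the
statistics' correctness and calibration under clean sampling assumptions,
not robustness to alignment or calling artifacts in real pools.

## Feasibility of strict extreme pools at n = 200

One property of the default architecture deserves emphasis. An individual
exceeds phenotype 0.7 only if it carries no suppressor allele (probability
1/4), is homozygous at the 60% locus (1/4), and is homozygous at two or
more of the four 10% loci ($P[\mathrm{Bin}(4, 1/4) \ge 2] \approx 0.26$):
overall $p \approx 0.016$, i.e. an expected **3.3 of 200** F2 individuals.
A strict high pool of 25 at threshold 0.7 is therefore essentially never
available from a 200-individual population, and `select_pools()` raises
its contractual error. For this reason the umbrella `run_all()` defaults
to `pool_strategy = "rank"` (take the 25 most extreme individuals per
side), while `select_pools()` itself keeps the strict threshold semantics.

A second consequence follows from the same arithmetic. Any individual
with a nonzero phenotype is homozygous non-suppressor, so a high pool —
however selected — is *fixed* at the suppressor locus, while the
phenotype-0 low pool is depleted of the non-suppressor allele there
(expected low-pool frequency $\approx 0.38$, versus $\approx 0.49$ at the
60% locus). The expected windowed contrast at the suppressor
($\approx 0.62$ per reference) therefore *exceeds* the contrast at the
major direct locus ($\approx 0.51$), and under these defaults both the
pooled scan and the LOD scan tend to peak on the suppressor chromosome;
runs in which the pooled scan instead peaks on the 60%-locus chromosome
are a minority outcome driven by pool-sampling noise. The acceptance
suite states the divergence claim under the strict study conditions and
reports it as observed.

## Problem sizes used by the test suite

Unit tests use 1–10 chromosomes of 0.1–3 Mb with 10–300 markers each and
populations of 6–200; the envelope-calibration test aggregates 15
replicate 50-individual null populations over a 10 × 3-Mb genome (about
22,000 windows); the divergence experiment uses 20 seeds of the full
200-individual study at 200 markers per chromosome. These sizes are the
package's chosen desk scale: large enough for every asymptotic claim
tested (envelope coverage to ±2 percentage points, crossover rate to
±0.2), small enough that the whole suite runs in well under a minute per
file.

## Known limitations

* The combined Δ orientation is a convention; cross-package comparisons
  should check the sign definition first.
* The envelope conditions on the realized mean window depth rather than
  the full per-marker depth profile; with `depth_model = "fixed"` these
  coincide.
* `bin_size` binning assumes dense, evenly informative markers; with
  sparse maps prefer `bin_size = 1`.
* The depth-dip scan reports collapse regions, not breakpoints; resolving
  the inserted sequence is out of scope.
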