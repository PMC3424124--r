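---
title: "metashot: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metashot: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metashot)
```

## The problem and the method

Shotgun metagenomic sequencing yields millions of short reads drawn from
every genome in a microbial community. `metashot` attributes those reads to
bacterial and archaeal **species** — not strains, and not high taxonomic
ranks such as phyla — by aligning them against a *representative
reference*: a concatenated collection of genomes containing exactly one
strain per species. Each mapped read's primary alignment is rolled up
through a record-to-species metadata table, producing a per-species read
count table; a species is reported present when its count reaches a
detection threshold (100 reads by default).

The approach is deliberately closed-reference: it is highly accurate when
the sampled organisms have a sequenced relative of the same species in the
reference, and it cannot find species that are absent from it. This
trade-off buys species-level resolution and speed (ungapped short-read
alignment instead of BLAST-style search) and avoids the
lowest-common-ancestor behaviour of pushing ambiguous reads to
uninformative high ranks.

## Reference construction

`parse_organism_name()` normalises free-text organism descriptions to a
species key: the binomial, keeping the token after a placeholder epithet
(`"Marinomonas sp. MWYL1"` is its own species-level entity) and keeping a
leading `Candidatus`. `select_representatives()` keeps, per species, all
chromosomes of the strain with the **earliest release date**. "Earliest
sequenced" is not operationally defined anywhere we could anchor it
(publication date? accession order?); release date from a side metadata
table was chosen because FASTA headers rarely carry dates and release date
is the one field public genome collections consistently provide. Missing
dates sort last; full-tie cases fall back to lexicographic strain order
with a warning, so selection is always deterministic and idempotent.

"Concatenation" is realised as a multi-record FASTA (one record per
chromosome), not one spliced sequence: reads can then never span an
artificial junction, and the species rollup happens entirely in metadata.

## The read simulator as a stated world

`simulate_reads()` draws reads with uniform start positions over the valid
starts of each source record, uniform strand, and an i.i.d. per-base
substitution error model (each base flipped to a uniformly chosen
different base with probability `sub_rate`, default 0.01). Defaults are
50 bp reads — the short-read regime the method targets — and the
ten-strain ocean community design (`ocean_design()`, 100,000 reads with
fixed per-strain counts) as the benchmark composition.

What the generator does *not* emulate: platform-specific error profiles
(454/Sanger homopolymer errors, quality ramps), indels, paired ends,
chimeras, GC bias, or circular-genome wraparound (reads never cross record
ends). The built-in aligner is ungapped, so indel realism could not be
rewarded anyway; the original benchmark's simulator profile was not
recorded, so uniform substitution at 1% is an explicit assumption. A green
test on this world therefore establishes correctness of counting,
thresholding and bookkeeping under clean uniform placement — it does not
establish robustness to real platform artefacts or to conserved inter-
species homology, which the synthetic random genomes (effectively
orthogonal sequences) cannot produce.

Truth labels ride in the read id (`record|start|strand|serial`) and in a
sidecar table, so any SAM produced downstream retains ground truth.

## Alignment semantics

The built-in aligner reports **one best placement per read** (fewest
mismatches across both strands, at most `k`), with ties broken by record
order, then leftmost position, then forward strand. Counting only the
primary alignment matches the default behaviour of the short-read aligners
the method was designed around, and it is the attribution semantics
throughout: a read contributes exactly one count. Candidates are
enumerated by the pigeonhole principle — a read with at most k mismatches
contains at least one of k+1 disjoint exact seeds — and verified by direct
mismatch counting, so the result is provably identical to an exhaustive
scan; the test suite asserts that equivalence against an independent
brute-force oracle. Internal coordinates are 0-based half-open; conversion
happens only at SAM boundaries. External aligners are supported through a
command-template adapter that passes extra parameters through verbatim and
never falls back silently.

## Coverage statistics

Under the null of uniform placement, the probability that `n` reads of
length `l` on a sequence of length `L` are pairwise non-overlapping has
the closed form

$$p = \frac{n!\binom{L - nl + n}{n}}{(L-l+1)^n},$$

derived by the standard gap transformation (subtracting `l - 1` from each
successive ordered start turns "pairwise at least `l` apart" into "all
distinct"). It is evaluated as a product of per-factor ratios in log
space, exact to machine precision; the tests anchor it to exhaustive pair
enumeration (n = 2) and Monte-Carlo simulation, and verify monotonicity
in n, l and L. Because roughly 100 reads pin down the length and
abundance of a feature to ~20% (relative error ≈ 2/√n), 100 reads is the
default detection threshold, applied inclusively (a count of exactly 100
is detected; the threshold's strictness was otherwise unspecified).

Feature metrics invert the expectation that a feature of length $L_f$ is
overlapped by $d(L_f + l - 1)$ reads at genome-wide density $d$ (reads per
valid start): $\hat L_f = n/d - l + 1$, floored at zero. The abundance
estimate is defined as reads per available start position of the feature,
$n/(L_f + l - 1)$, using the known feature length when supplied and
$\hat L_f$ otherwise — with the caveat that in the latter case it
degenerates to $d$ by construction, so supplying the annotated feature
length is what makes it informative (it is then proportional to the
feature's copy number in the community).

The localized-hits flag targets the known failure mode of closed-reference
attribution: reads from a shared genomic island or low-complexity locus
mapping onto an otherwise absent genome. Two criteria, both configurable:
bin-occupancy deficit (observed occupied bins below
`min_occupied_fraction` = 0.2 of the Poisson expectation
$B(1-e^{-n/B})$) and overlap excess (observed overlapping pairs tested
against their null expectation $\binom{n}{2}(1-p_2)$ with a Poisson upper
tail at `overlap_alpha` = 0.01). The thresholds have no published values;
the defaults were set so that 10⁴ uniform reads on 5 Mb false-flag at most
5% of the time (verified by simulation in the tests) while single-locus
pileups flag with margin. Overlap is strand-ignorant: an overlap on the
reference interval is an overlap.

## Evaluation

`evaluate_detection()` is exact set arithmetic over species keys, with
false negatives whose species is missing from the reference reported
separately — a closed-reference method could never have found them. Note
one bookkeeping subtlety inherited from the benchmark literature: a
detected-count arithmetic of "106 of 113" implies 7 false negatives by
set arithmetic even where 9 are narrated; all raw sets are exposed so any
convention can be audited. `assignment_accuracy()` scores each species by
the fraction of its inserted reads assigned back to it (unassigned reads
count as incorrect) and averages **unweighted** over species, so rare
community members count as much as dominant ones. Strains are always
rolled up to species keys before scoring; the per-record table preserves
the strain-level view for diagnostics.

## Numerical and degenerate-input choices

* Detection threshold comparison is `>=`; threshold 0 returns every
  species with at least one read.
* `no_overlap_pvalue`: 1 for n ≤ 1 (no pair exists), exactly 0 when
  n·l > L (pigeonhole), error when l > L.
* `estimate_feature_metrics` with zero feature reads reports abundance 0
  and an absent (NA) length; density must be positive.
* Empty alignment streams yield an empty count table with zeroed totals;
  an empty reference selection is an error.
* All simulation entry points require an explicit seed and are
  byte-deterministic given one.

## Known limitations

* Ungapped alignment only; reads spanning indels relative to the
  reference lose a placement they might deserve.
* Random synthetic genomes contain essentially no shared homology, so the
  desk-scale benchmarks exercise the machinery, not the hard biology of
  near-identical strains; the near-identical-strain case is covered only
  by targeted unit tests of the rollup semantics.
* Multi-mapping reads are counted once at their primary placement;
  per-hit counting is deliberately out of contract.
* The simulator's error model is substitution-only and
  platform-agnostic.
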