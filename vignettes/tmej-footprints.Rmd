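---
title: "Detecting TMEJ footprints of APOBEC3 mutagenesis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting TMEJ footprints of APOBEC3 mutagenesis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tmejscan` quantifies two somatic footprints and their spatial coupling:
APOBEC3-driven TCW substitutions (including kataegis clusters) and the
microhomology-mediated deletions (MMDs) that theta-mediated end joining
(TMEJ) leaves at repaired double-strand breaks. This vignette documents
the underlying models, every tunable parameter, the numerical choices
made where a convention was genuinely open, and what the synthetic
cohorts used for verification do and do not establish about real data.

## Coordinates and variant normalization

Interchange formats (VCF, TSV `pos` columns) are 1-based; every internal
type is 0-based half-open. All variants are normalized before
classification: the shared suffix and then the shared prefix of REF/ALT
are trimmed, and pure insertions/deletions are shifted left while the
reference base 5' of the event equals the last payload base. This yields
the unique smallest-start (left-aligned, parsimonious) representation,
so equivalent indel representations from different callers collapse to
one key, and repeat/microhomology context is measured from a canonical
anchor. Normalization is idempotent and is verified against exhaustive
enumeration of equivalent representations in the test suite.

Records that cannot be normalized are dropped with a logged count rather
than aborting a cohort run: REF/genome mismatches, multi-nucleotide
(complex) substitutions, and payloads containing N (their contexts are
undefined). Whether upstream pipelines left-align before channel
assignment varies in practice; `tmejscan` always normalizes, and this is
the package's fixed convention.

## SBS-96 classification and the TCW rule

Each SNV is assigned one of 96 pyrimidine-centered trinucleotide
channels; when the reference base is a purine, the substitution and its
context are reverse-complemented first. A substitution is called
APOBEC3-type iff its channel is `T[C>T]W` or `T[C>G]W` with W ∈ {A, T} —
evaluated on the pyrimidine-normalized representation, so G>A/G>C events
at 5'-WGA-3' on the given strand count via their reverse complement.
This strand symmetry is fuzz-tested over all 96 channels. Dinucleotide
and complex substitutions are excluded (counted) before matrix
generation.

## ID83 classification and the MMD definition

Indels are annotated with:

* `repeat_count` — the number of additional exact adjacent copies of the
  payload immediately 3' of the left-aligned event;
* `mh_length` — for deletions, the longest proper prefix of the deleted
  segment matching the 3' flank, or the longest proper suffix matching
  the 5' flank, whichever is larger (both junction sides are scored
  because either end of the break can anneal), bounded by length − 1.

Channel assignment is total and exclusive over 83 channels in the
standard hierarchy: 1-bp events map to homopolymer channels keyed by the
pyrimidine-normalized base; events of ≥ 2 bp with `repeat_count ≥ 1` map
to repeat channels (repeat context takes precedence, so a deletion
inside a tandem repeat is never an MMD — this prevents double counting,
since a repeat-unit deletion always shows trivial "microhomology");
deletions of ≥ 2 bp with no adjacent copy and `mh_length ≥ 1` map to
microhomology channels. An **MMD** is such a microhomology-channel
deletion. The minimum microhomology for the flag defaults to
`min_mh = 1` — the footprint definition is "deletions containing
microhomology sequences", with no stated lower bound — and is
configurable for sensitivity analyses. `repeat_unit_count` and
`microhomology_length` are checked against independent brute-force
string matching on 10,000 random instances in the acceptance suite.

## Cluster detection and categorization

Clusters are maximal runs of substitutions (per sample and contig) in
which every consecutive intermutation distance is ≤ a threshold, with
`min_size = 2` by default (doublets count, matching standard clustered-
mutation callers). The reference tools calibrate per-sample thresholds
by genome simulation; `tmejscan` substitutes a closed-form
uniform-placement null — spacings are approximately exponential with
rate n/L, so the threshold is `d = floor(-(L/n) · ln(1 − q))` with
`q = 0.01` — which preserves the per-sample adaptive character without a
heavyweight dependency. A fixed threshold (e.g. the classic 1-kb
kataegis rule) can be supplied instead.

A cluster is APOBEC3-induced when *coordinated* TCW C>T/G members make
up at least two-thirds of its mutations, inclusive at the boundary; the
comparison uses integer arithmetic (`3·n_q ≥ 2·n`) so exact-2/3 cases
never depend on floating-point rounding. "Coordinated" is interpreted as
shared strand orientation of the mutated pyrimidine (processive
deamination of one ssDNA strand): qualifying members are the APOBEC
members on the plurality strand. This is the default and can be switched
off (`require_strand_coordination = FALSE`), since the term admits a
laxer reading. The cluster *center* — the anchor for distance
measurements — is the floor midpoint of the outermost member positions,
the simplest reproducible choice.

## Proximity statistics

Every (cluster, indel) pair on the same contig of the same sample with
`|center − anchor| < 100,000` bp (strict, i.e. < 0.1 Mb) is kept. The
indel anchor defaults to the left breakpoint (0-based start), which is
deterministic and strand-free; a midpoint option exists. An indel within
the window of several clusters contributes one pair per cluster by
default (`dedupe = TRUE` keeps only the nearest). Summaries are computed
on pairs pooled across samples (a per-sample aggregation would weight
sparse samples heavily at these pair counts). The test of the planted
hypothesis — MMDs lie closer to APOBEC3 clusters than to other
clusters — is a one-sided Welch t-test; Welch is the safer default when
only "one-sided t-test" is specified, and the choice is recorded in the
output metadata. Distances are reported in integer bp and in Mb at 3
decimals.

## Cohort statistics

Samples with an HRDetect probability strictly above 0.70 are excluded
before burden correlations: HR-deficient genomes rely more on TMEJ and
would confound the APOBEC3-driven signal. "Over 70%" is read literally
as a strict inequality (0.70 exactly is retained); the cutoff is a
parameter. Correlations are plain product-moment or mid-rank Spearman
with two-sided p-values, unadjusted (a BH option exists for cohort
scans). Treated-vs-control replicate MMD counts are compared with a
one-sided Welch test of H1: treated > control. When two external screens
provide a per-sample score, their mean is used.

## Consensus filtering

Per-caller calls are merged on normalized position + alleles. Where
callers disagree on depth/alt counts, the maximum is taken — the most
permissive choice for the evidence rule, recorded here because the
convention is otherwise unstated. Retention rules, in order: depth > 10
(strict), alt reads > 2 (strict), ≥ 2 distinct caller names, key absent
from the supplied common-site list, key absent from the control set.
Records missing depth/alt evidence are dropped under a distinct
`missing_evidence` fate. The retained set is order-independent (verified
against an order-free predicate); only the recorded first-failing rule
depends on rule order. Site lists are matched by exact normalized
(contig, pos, ref, alt) key; build-specific annotation logic stays
outside the core.

## The synthetic-cohort generator

`sim_config()` defaults describe an episodic deaminase-exposure
experiment: 5 treated and 3 control replicates; 13 DSB loci per treated
sample with one expected MMD each (Poisson-distributed per locus, so
replicates vary as count data do); control samples carry 9/13 of the
treated MMD expectation at unanchored positions; MMD deletion lengths
2–20 bp with microhomology 1–5 bp; MMD offsets from their parent DSB are
Gaussian with sigma 20 kb (APOBEC3-type loci) vs 40 kb (other loci),
which places the two categories' mean distances on either side of
~0.02–0.03 Mb inside the 0.1 Mb pairing window; kataegis tracts span
~1 kb with a mean of 6 members, 90% of them TCW C>T/G on one strand per
cluster (typical kataegis purity). Background SNVs (10⁻⁶/bp) and indels
(3×10⁻⁷/bp) are placed uniformly; background indels mix 1-bp events,
natural tandem-repeat deletions, and multi-bp deletions
rejection-sampled to carry no microhomology, so planted MMDs are the
only MMD source and truth labels stay exact.

Two constructions make truth exact rather than probabilistic. First,
MMDs are planted by *locally editing the reference*: the mh-prefix of
the deleted segment is copied immediately 3' of it, capped by a
mismatching base (no full adjacent copy, microhomology exactly as
requested), and the 5' base is forced to differ from the deletion's last
base (left-aligned as emitted, no 5'-side microhomology). Second,
cluster members are placed only at genuine TCW sites of the simulated
sequence (scanning both strands), so the substitution classifier is
exercised honestly rather than fed labels. Planted events reserve
intervals in an occupancy map; later draws that would collide are
resampled, and genome edits happen before any read-only event is placed.

For cluster-recovery experiments at whole-genome mutation densities,
`simulate_cluster_positions()` works at the coordinate level only (no
sequence), so callable lengths of hundreds of Mb — where the derived IMD
threshold sits in the kb range, well above planted spans — are cheap to
simulate. The sequence-based and position-level generators together
cover the regimes the sequence generator alone cannot reach at desk
scale.

What passing on these cohorts shows: the classifiers, cluster logic,
pairing, and statistics recover exactly what was planted, at the planted
operating conditions. What it does not show: performance on real tumor
genomes with non-uniform base composition, replication-timing and
chromatin covariates, copy-number structure, caller-specific artifacts,
or mapping noise — none of which the generator emulates.

## Problem sizes and numerical choices

The test suite runs the oracle-equivalence check on 10,000 random
(sequence ≤ 300 bp, deletion ≤ 30 bp) instances; strand-symmetry fuzz on
5,000 substitutions; MMD round-trip on 500 planted MMDs on a 2-Mb
genome; cluster recovery on 200 planted clusters over a 500-Mb virtual
callable genome; the proximity contrast on ~500 pairs from a 24-Mb
six-contig cohort; and the type-I check of the one-sided test over 200
seeded null repetitions. These sizes were chosen so each property is
measured with comfortable statistical margin while the whole suite stays
quick to run routinely. All randomness is seed-governed; identical seeds
give byte-identical generator output and pipeline reports (numeric
formatting in reports is fixed: bp as integers, Mb at 3 decimals, full
precision in machine-readable tables).

## Known limitations

* Cluster thresholds assume a homogeneous callable genome; regional
  mutation-rate covariates would need a stratified null.
* Doublet/multi-nucleotide substitutions are excluded rather than
  classified; omikli-style subclassification is out of scope.
* The proximity analysis pairs within samples only and offers no
  permutation null of indel placement; the planted-contrast test is a
  two-group comparison of pair distances.
* Structural variants, CRAM/BAM input, liftover, and signature
  extraction (NMF) are out of scope; channel matrices are written in
  standard orders for downstream signature tools.
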