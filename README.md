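# tmejscan

Tools for detecting the genomic footprints that **theta-mediated end
joining (TMEJ)** leaves behind when it repairs **APOBEC3-induced
double-strand breaks**.

APOBEC3 cytidine deaminases attack single-stranded DNA and mutate
cytosines in the TCW motif (5'-T, mutated C, W = A/T), producing the
characteristic C>T and C>G substitutions and, in episodic bursts,
kataegis — tight clusters of strand-coordinated TCW mutations near break
sites. When the resulting double-strand breaks are repaired by
Polθ-dependent TMEJ, the junctions retain short stretches of flanking
sequence identity, leaving **microhomology-mediated deletions (MMDs)**:
deletions of ≥ 2 bp, not part of a tandem repeat, with ≥ 1 bp of junction
microhomology. `tmejscan` quantifies both footprints and their spatial
coupling in somatic variant catalogs:

* **SBS-96 classification** of substitutions into pyrimidine-normalized
  trinucleotide channels (`X[C>T]Y` labels, COSMIC order) with APOBEC3 TCW
  calls: a substitution is APOBEC3-type iff its channel is `T[C>T]W` or
  `T[C>G]W`, W ∈ {A, T}.
* **ID83 indel classification** with repeat-unit counts and two-sided
  junction microhomology lengths; MMD flagging with repeat precedence
  (a deletion inside a tandem repeat is never an MMD).
* **Kataegis-like cluster detection** by intermutation distance (IMD).
  The threshold is either fixed or derived per sample from a
  uniform-placement null: `d = floor(-(L/n) · ln(1 - q))` for `n`
  mutations on a callable length `L` (default `q = 0.01`). A cluster is
  categorized **APOBEC3-induced** when coordinated TCW C>T/G members make
  up ≥ 2/3 (inclusive) of its mutations; otherwise it is attributed to
  other mutagenic factors.
* **Cluster–indel proximity**: (cluster center, indel) pairs at distance
  < 0.1 Mb (strict), per-category mean/median distances, the ratio of
  medians, and a one-sided Welch t-test of whether MMDs sit closer to
  APOBEC3 clusters than to other clusters.
* **Cohort statistics**: exclusion of homologous-recombination-deficient
  samples (HRDetect probability strictly > 0.70), Pearson/Spearman burden
  correlations, and a one-sided Welch comparison of replicate MMD counts
  between treated and control groups.
* **Multi-caller consensus filtering**: calls merged on left-aligned
  position + alleles; retained when depth > 10 (strict), alt reads > 2
  (strict), called by ≥ 2 callers, absent from a common-variant site list
  and from the matched control set.
* A fully **seeded synthetic-cohort generator** that plants clusters,
  MMDs of exact microhomology length (by local reference editing), and
  background noise, with a ground-truth table for every emitted variant —
  so every stage of the analysis is verifiable without external data.

## Worked example

Simulate a doxycycline-style exposure cohort (5 treated, 3 control
replicates) and run the full pipeline:

```r
library(tmejscan)

cfg <- sim_config(seed = 7)                 # study-design defaults
run <- simulate_cohort(cfg, dir = "sim_run")  # FASTA + VCFs + truth tables
res <- run_pipeline(list(reference = run$paths$reference,
                         vcf_dir = "sim_run",
                         sample_table = run$paths$sample_table,
                         out_dir = "reports"))

res$indel$summary
#>   sample_id total mmd_count
#> 1 control_1    16        10
#> 2 control_2    11         4
#> 3 control_3     8         5
#> 4 treated_1    25        15
#> 5 treated_2    25        13
#> 6 treated_3    18        11
#> 7 treated_4    24        18
#> 8 treated_5    18        11
```

Treated replicates carry more MMDs than controls (one-sided Welch test):

```r
res$mmd_comparison
#> $mean_treated  13.6
#> $mean_control  6.33
#> $t_statistic   3.19
#> $p_one_sided   0.0165
```

and MMDs lie closer to APOBEC3-categorized substitution clusters than to
clusters from other mutagenic factors, within the 0.1 Mb pairing window:

```r
res$proximity$per_category
#>   category n_pairs mean_distance median_distance
#> 1  APOBEC3      19      17030.21           17384
#> 2    other      34      36572.15           31957
res$proximity$ratio_of_medians   # 0.544
res$proximity$p_one_sided        # 0.00011
```

Both effects are planted by the generator (MMD offsets of sigma 20 kb
around APOBEC3 cluster loci vs 40 kb around other clusters; ~13 vs ~9
expected MMDs per replicate) and recovered by the pipeline from the VCFs
alone. `reports/` contains the SBS-96 and ID83 channel matrices, the
cluster and pair tables, the proximity and cohort summaries, and a
`manifest.json` with the package version, the echoed config, and input
checksums.

A thin command-line wrapper ships in `inst/cli/tmejscan.R`
(`simulate`, `validate`, `run-all`, `consensus-filter`).

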