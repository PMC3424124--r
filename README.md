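# metashot

Species-level taxonomic attribution of short metagenomic shotgun reads.

## What it does, and for whom

Shotgun metagenomics sequences all DNA in a community sample; the analysis
question is *which bacterial and archaeal species are present, and in what
proportions*. `metashot` answers it by the representative-reference
strategy: align short reads (~50 bp) against a concatenated reference
containing **one strain per species**, count each read's primary alignment
under its species via a record→species metadata table, and report the
species whose counts reach a detection threshold (default 100 reads —
roughly the number of mapped reads needed to estimate a taxon's sequence
length and abundance to ~20%, since the relative error scales as 2/√n).
It is aimed at microbiome researchers who want species-level calls — not
strain calls, and not lowest-common-ancestor assignments to phyla — from
habitats whose members are represented by sequenced genomes.

The package implements the full surrounding workflow:

* **Reference construction** — organism-name parsing to species keys,
  earliest-released-strain selection, include/exclude filtering
  (`parse_organism_name`, `select_representatives`, `build_reference`).
* **Mock-community simulation** — seeded read simulator with uniform
  placement and a per-base substitution error model, plus short-read
  trimming (`simulate_genomes`, `simulate_reads`, `trim_reads`,
  `ocean_design`).
* **Alignment** — a built-in ungapped ≤k-mismatch best-hit aligner
  (pigeonhole seed index, provably equivalent to exhaustive scan), SAM/BAM
  import of primary alignments, and an external-aligner adapter with
  verbatim parameter pass-through (`builtin_align`, `read_alignments`,
  `invoke_external_aligner`).
* **Attribution** — species count tables, the inclusive detection
  threshold, and decoy-based contaminant read removal
  (`count_by_species`, `detect_species`, `filter_reads_by_reference`).
* **Read-placement statistics** — coverage profiles; the exact no-overlap
  probability for n uniformly placed reads of length l on a sequence of
  length L,

  ```
  p = n! * choose(L - n*l + n, n) / (L - l + 1)^n ,
  ```

  feature length/abundance estimation by inverting
  E[n] = d·(L_f + l − 1); and a localized-hits flag that catches reads
  piling onto a shared genomic island of an absent genome
  (`coverage_profile`, `no_overlap_pvalue`, `estimate_feature_metrics`,
  `flag_localized`).
* **Evaluation** — detection recall/precision with reference-awareness and
  unweighted per-species read-assignment accuracy (`evaluate_detection`,
  `assignment_accuracy`).
* **Pipeline** — `run_pipeline()` orchestrates the whole run from a flat
  config file with a JSON manifest and deterministic outputs; a
  `metashot` CLI (in `inst/scripts/`) exposes every step as a subcommand.

## Worked example

```r
library(metashot)

catalog <- simulate_genomes(3, 100000, seed = 42,
  species_names = c("Alcanivorax borkumensis", "Shewanella loihica",
                    "Prochlorococcus marinus"))
design <- data.frame(id = catalog$records$species_key,
                     read_count = c(2000L, 1200L, 90L))
reads <- simulate_reads(catalog, design, read_length = 50,
                        sub_rate = 0.01, seed = 43)
aln <- builtin_align(reads, catalog, max_mismatches = 3)
tab <- count_by_species(aln, catalog$records)
tab
#> species_count_table: 3 species; 3285/3290 reads mapped (99.8%)
#>               species_key read_count fraction_of_total
#> 1 Alcanivorax borkumensis       1998        0.60729483
#> 2      Shewanella loihica       1197        0.36382979
#> 3 Prochlorococcus marinus         90        0.02735562

detect_species(tab, min_reads = 100)
#> [1] "Alcanivorax borkumensis" "Shewanella loihica"
```

All 3290 simulated reads are accounted for: 3285 map (five carried more
than three substitution errors), counts track the inserted proportions,
and the 90-read species correctly falls below the 100-read detection
threshold. Truth-based scoring puts per-species assignment accuracy at
0.999/0.998/1.000 (mean 0.9988), and the coverage report leaves all three
genomes unflagged (reads spread over all bins; the 90-read genome's
no-overlap probability of 0.017 simply says some read overlap is expected
by chance at that depth).

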