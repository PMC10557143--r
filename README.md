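# peakcoloc

Genome-wide co-localization screening of ChIP-seq peak sets against R-loop
and DNA G-quadruplex (G4) structure loci, in tidyverse-style R.

R-loops (RNA:DNA hybrids with a displaced single strand) and G4s
(four-stranded structures in G-rich DNA) co-occur preferentially in the
promoters of active human genes. A productive way to discover proteins that
engage these structures in chromatin is a peak co-occupancy screen: for each
of many transcription-factor ChIP-seq peak sets, compute what percentage of
its peaks overlaps an R-loop map (R-ChIP-seq) and a G4 map (BG4 ChIP-seq),

```
pct = 100 * (# peaks overlapping >= 1 structure peak) / (# peaks),
```

with record-level `bedtools intersect -wa -u` overlap semantics (>= 1 shared
base, half-open BED coordinates), then examine the scatter of the two
percentage vectors across proteins and their Pearson correlation *r*.
Proteins high on both axes are candidate structure-binding proteins.

The package is written for regulatory-genomics analysts: every user-facing
function takes a data frame first and returns a tibble, results have
`tidy()` / `glance()` / `autoplot()` methods, and a seeded synthetic-data
generator with exact planted ground truth makes the entire pipeline testable
end-to-end without downloading anything.

## What's inside

| area | functions |
|---|---|
| I/O (BED3/6, narrowPeak, bedGraph, chrom.sizes; gzip-transparent) | `read_peaks()`, `read_bedgraph()`, `read_chrom_sizes()`, `read_gene_models()` + writers |
| overlap engine (`-wa -u` semantics) | `intersect_report_a()`, `overlap_membership()`, `three_way_cooccupancy()` |
| the screen | `run_screen()`, `overlap_percentage()`, `pearson_r()`, `rank_candidates()` |
| promoter annotation | `promoter_regions()`, `classify_peaks()`, `promoter_fraction()` |
| signal profiles | `aggregate_profile()`, `metagene_profile()`, `region_density()`, `rpkm_normalize()` |
| splicing metric | `exclusion_ratio()`, `ratio_table()` |
| synthetic data | `simulate_scenario()`, `make_genome()`, `make_genes()`, `make_structure_peaks()`, `make_tf_sets()`, `make_coverage()` |
| pipeline | `run_end_to_end()`, `validate_inputs()`, CLI at `inst/scripts/peakcoloc` |

## Worked example

Simulate a small scenario (one 10-Mb chromosome, 8 proteins x 200 peaks,
400 structure peaks per set with 70% planted promoter localization), then
screen it:

```r
library(peakcoloc)

scen <- simulate_scenario("demo", seed = 42, n_proteins = 8, n_peaks = 200,
                          n_genes = 200, n_structure = 400,
                          n_chroms = 1, chrom_length = 1e7)

rloop <- read_peaks(scen$paths$rloop, "narrowPeak")
g4    <- read_peaks(scen$paths$g4, "narrowPeak")
tfs   <- sapply(list.files(scen$paths$tf_dir, full.names = TRUE),
                read_peaks, dialect = "narrowPeak", simplify = FALSE)
names(tfs) <- sub(".narrowPeak", "", basename(names(tfs)), fixed = TRUE)

tab <- run_screen(tfs, rloop, g4)
tab
#> # Co-localization screen: 8 protein(s); Pearson r = 0.9585
#> # A tibble: 8 × 7
#>   protein n_peaks n_rloop pct_rloop  n_g4 pct_g4 n_both
#> * <chr>     <int>   <int>     <dbl> <int>  <dbl>  <int>
#> 1 TF001       200     108      54      97   48.5     50
#> 2 TF002       200      83      41.5    64   32       27
#> 3 TF003       200      20      10      42   21        3
#> # ℹ 5 more rows
```

One row per protein: peak count, overlap counts/percentages against each
structure set, and the three-way count. The header's *r* is the
cross-protein Pearson correlation of `pct_g4` vs `pct_rloop` — here 0.9585,
recovering the planted linear relation between the two overlap fractions.
Rank the candidates that clear 40% on **both** axes (ordered by the weaker
percentage):

```r
rank_candidates(tab, min_pct = 40)
#> # A tibble: 3 × 4
#>   protein pct_rloop pct_g4 pct_min
#> 1 TF005        74     66      66
#> 2 TF001        54     48.5    48.5
#> 3 TF004        42.5   45      42.5
```

Promoter localization and the aggregation profile around R-loop peak
centers:

```r
sizes <- read_chrom_sizes(scen$paths$chrom_sizes)
genes <- read_gene_models(scen$paths$genes)
prom  <- promoter_regions(genes, upstream = 1000, downstream = 500, sizes)
promoter_fraction(rloop, prom)
#> [1] 70        # exactly the planted fraction

cov  <- read_bedgraph(scen$paths$coverage, sizes)
prof <- aggregate_profile(cov, rloop, sizes, window = 2000, bin_size = 50)
prof
#> # Aggregation profile: 400 anchors (0 dropped), 80 bins of 50 bp over +/- 2000 bp
#> # peak mean signal 17.43 at offset +25 bp
autoplot(prof)   # mean-signal curve, peaked at the anchor
```

The signal maximum sits in the central bin (+25 bp is the midpoint of the
first bin right of the anchor), as planted. `run_end_to_end()` chains all
stages — simulate, screen, annotate, profile, metagene, density — and writes
a `report.tsv` comparing every result to the generator's ground-truth
ledger.

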