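# bindscape

Where does a transcription factor bind relative to genes — and does the
chromatin context split its binding sites into functionally distinct groups?
`bindscape` is an R package for answering these questions from ChIP-Seq peak
calls, a genome annotation, and a chromatin-state segmentation.  It was built
around the analysis of EIN3, the master transcriptional regulator of ethylene
signaling in *Arabidopsis thaliana*, whose binding regions (EBRs) show a
bimodal promoter distribution — a sharp peak just upstream of the TSS and a
broad distal peak associated with a specific repressive-leaning chromatin
state — but every component is generic.

## What it computes

* **Peak ingest and filtering** — BED-like or MACS-style peak tables; peaks
  with height ≥ 7 (configurable) are kept as binding regions
  (`read_peaks()`, `peak_filter()`).
* **Location classification** — each region is `TSS` (overlaps a
  transcription start), `GENE` (otherwise overlaps a gene body) or
  `INTERGENIC`, with a Monte-Carlo permutation test of per-class counts
  (`classify_locations()`, `location_class_test()`).
* **Track permutation tests** — the *fraction of overlap* statistic
  (shared bases / permuted-track length) against a null that re-places each
  interval uniformly on its own chromosome (`permute_track()`,
  `track_overlap_test()`).
* **TSS-relative occurrence profile and bimodal model** — for each offset
  `x`, the fraction of genes whose position `TSS + x` is covered; modelled as

  ```
  f(x) = C + A_p * Norm(x; m_p, s_p) + A_d * Norm(x; m_d, s_d)
  ```

  where `C` captures non-specific binding and the two Gaussian components
  describe the proximal and distal binding modes; fitted by multi-start
  nonlinear least squares with a nested one-vs-two-component comparison
  (`occurrence_profile()`, `fit_bimodal()`).
* **Chromatin-state stratification** — per-state profiles that sum
  position-wise to the total exactly (`stratified_profile()`), plus
  state-exclusive gene lists (`compile_state_gene_lists()`).
* **Upstream-region datasets** — seven 500-bp bins spanning `[-3500; +1]`
  and the 5'UTR `[+1; AUG]`, strand-aware, with overlap-based filtering
  rules (`build_upstream_datasets()`).
* **Motif scanning** — PWM from a position-frequency matrix with min-max
  normalised scores (threshold 0.91 by default), both-strand scanning, and
  per-interval Fisher tests of site density at Bonferroni 0.05/8
  (`teil_pfm()`, `pwm_from_pfm()`, `scan_pwm()`, `density_compare()`).
* **GO-term comparison** — local EASE-score enrichment (the one-gene
  jackknife of the one-sided Fisher test), robust-term selection (>3% of the
  list, BH FDR < 0.05), and a two-list Fisher/BH comparison
  (`ease_score()`, `go_compare()`).
* **Synthetic data** — seeded generators for a genome + annotation, a
  nine-state chromatin map, bimodally placed peaks, motif-planted sequences
  and GO tables, each recording its ground truth (`make_genome()`,
  `make_state_map()`, `make_peaks()`, `plant_motifs()`,
  `make_go_annotations()`), so the full pipeline runs with no downloads.

## Worked example

```r
library(bindscape)

genome <- make_genome(n_genes = 1000, mean_intergenic = 8000, seed = 1)
smap   <- make_state_map(genome, seed = 2)
peaks  <- make_peaks(genome, n_peaks = 2000, seed = 3)
ebrs   <- peak_filter(peaks, min_height = 7)

classify_locations(ebrs, genome$transcripts)
#> location classes over 1677 regions
#>   TSS           305  (18.19%)
#>   GENE          103  (6.14%)
#>   INTERGENIC   1269  (75.67%)

location_class_test(ebrs, genome$transcripts,
                    chrom_lengths = genome$chrom_lengths,
                    n_perm = 1000, seed = 4)$TSS
#> permutation test [count[TSS]]: observed = 305, null = 35.53 +/- 5.67 (n = 1000)
#>   enriched, p_empirical = 0.000999, p_normal = 0
```

Binding regions pile up on TSSs (~9x the null mean, empirical p at its
resolution floor of 1/1001) and are depleted from gene bodies.  The
TSS-relative profile and its bimodal fit:

```r
tx5  <- genome$transcripts[genome$transcripts$has_5utr, ]
prof <- occurrence_profile(ebrs, tx5, window = c(-2500, 100))
fit_bimodal(prof)
#> bimodal model: C = 0.011936
#>   proximal: A = 136.57, m = -152.0, sigma = 149.7
#>   distal:   A = 106.37, m = -856.2, sigma = 490.0
#>   fit RSS = 0.0723772
```

The fitted means sit ~150 bp and ~860 bp upstream of the TSS — the
generator planted the two modes at -150 and -900.  Site-density comparison
between chromatin states, with motifs planted 3x denser in state 4:

```r
pwm     <- pwm_from_pfm(teil_pfm())         # consensus AYGWAYCT, threshold 0.91
planted <- plant_motifs(genome$sequences, rates = c("1" = 1, "2" = 1, "4" = 3),
                        states_map = smap, seed = 5)
# scan state-4 vs state-1/2 domain sequences, Fisher at Bonferroni 0.05/8
#>   interval hits_a positions_a hits_b positions_b  density_a  density_b     p         significant
#> 1      all   3994     1195317    954      687000  0.0033414  0.0013886  3.2e-154    TRUE
```

End-to-end with one call (writes TSV/JSON artifacts with provenance):

```r
res <- run_all(pipeline_config(seed = 1), outdir = "out")
```

A command-line front end with `synth` and `run-all` subcommands is installed
at `inst/cli/pipeline.R`.

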