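# semotif

Region-wise RBP motif enrichment and positional RNA maps for skipped-exon
splicing programs.

## What this package is for

Tissue-specific splicing regulators such as the epithelial splicing
regulatory proteins (Esrp1/Esrp2) control programs of cassette-exon
("skipped exon", SE) splicing.  A standard way to characterise such a
program from a knockout-versus-wildtype RNA-seq screen is:

1. classify differentially spliced SE events into **enhanced** exons
   (inclusion promoted by the regulator: high PSI in wild type,
   ΔΨ = Ψ(WT) − Ψ(KO) ≥ +0.05 at FDR < 0.05) and **silenced** exons
   (ΔΨ ≤ −0.05), against **control** exons that splice but do not change
   (FDR > 0.5, every group-mean PSI in (0.15, 0.85), gene average
   FPKM > 5 in at least one group);
2. scan the exon body and the 250-nt flanking intronic windows (excluding
   20 nt inside each 3′ splice site and 6 nt inside each 5′ splice site)
   for RBP binding motifs, and test region-wise enrichment in regulated
   versus control exons with a right-sided Fisher exact test.  Occurrences
   are counted in two modes — **by-NT** (every matching position, possibly
   overlapping) and **by-Sequence** (at most once per sequence) — with
   Benjamini–Hochberg correction applied to the by-NT p-values per region;
   a motif is *enriched* when FDR(by-NT) < 5% and p(by-Sequence) < 0.01;
3. draw a positional **RNA map**: the fraction of nucleotides covered by
   any motif of a GU-rich panel inside a 50-nt window slid 1 nt at a time
   across five segments (upstream exon, 250-nt upstream intron, cassette
   exon, 250-nt downstream intron, downstream exon), averaged per event
   set.  For Esrp-like regulators, silenced exons peak in the upstream
   intron/exon body and enhanced exons in the downstream intron.

`semotif` implements this workflow over rMATS-style SE tables, a genome
FASTA and Cuffdiff-style expression tables, together with the small
quantitative statistics that accompany such studies (PSI from RT-PCR band
intensities normalised by product length, mutually-exclusive-exon
inclusion ratios, percent change and pooled-variance t-tests from summary
statistics, Pearson concordance of predicted versus validated ΔΨ) and a
fully seeded synthetic-data generator with planted motif occurrences that
provides ground truth for every stage.

## Worked example

```r
library(semotif)

sim <- simulate_dataset(sim_config(n_enhanced = 30, n_silenced = 30,
                                   n_control = 80, seed = 1))
cl <- classify_events(sim$events, sim$expression)
attr(cl, "counts")
#>     enhanced     silenced      control unclassified
#>           28           29           46           37

sets <- split(as.character(cl$event_id), cl$label)
regions <- extract_regions(sim$events, sim$genome)
res <- enrich(list(silenced = regions[regions$event_id %in% sets$silenced, ],
                   enhanced = regions[regions$event_id %in% sets$enhanced, ]),
              regions[regions$event_id %in% sets$control, ], esrp_motifs())
subset(res, enriched, c(motif, region, direction, a, c, fdr_by_nt, p_by_seq))
#>     motif            region direction  a  c fdr_by_nt p_by_seq
#> 13 UGGUGG   upstream_intron  silenced 69 11  1.81e-17 4.69e-09
#> 61 UGGUGG downstream_intron  enhanced 63 14  3.34e-14 2.95e-09
#> ...
```

The generator planted `UGGUGG` in the upstream introns (and, at a lower
rate, exon bodies) of silenced events and the downstream introns of
enhanced events; the enrichment scan recovers exactly that architecture:
`a` and `c` are by-NT occurrence counts in regulated and control regions.
The few misclassified counts (28/30, 29/30 recovered) reflect the
simulated replicate noise passing through a real t-test + BH screen, not
labelling errors.

The positional map makes the same architecture visible by location:

```r
segments <- extract_map_segments(sim$events, sim$genome)
profile <- build_map(sets[c("silenced", "enhanced", "control")],
                     segments, esrp_motifs())
plot_rna_map(profile)   # silenced peaks upstream, enhanced downstream
```

Summary statistics reproduce printed group comparisons from their means,
SDs and sizes, e.g. hair-follicle counts 16.00 ± 2.37 (n = 8) versus
12.25 ± 1.24 (n = 6):

```r
tt <- t_test_two_tailed(16.00, 2.37, 8, 12.25, 1.24, 6)
#> t = 3.508, df = 12, p = 0.0043
percent_change(25.79, 16.68)
#> 35.3
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The script simulates a full default-scale dataset from the given seed,
runs every pipeline stage against the installed package (classification,
region extraction, enrichment, RNA map, expression filters, summary
statistics) and writes the acceptance report to `--out`.

## Layout

- `R/` — implementation: event I/O, region extraction, motif enrichment,
  RNA map, expression filters, quantitative statistics, synthetic data,
  pipeline orchestration (`run_pipeline()`).
- `tests/testthat/` — unit, property and acceptance suites with
  brute-force oracles.
- `vignettes/skipped-exon-motif-maps.Rmd` — the methods vignette: model,
  parameter choices, what the synthetic generator does and does not
  emulate, numerical conventions and limitations.
- `inst/extdata/` — small plain-text fixtures (synthetic stand-ins,
  labelled as such).
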