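---
title: "Skipped-exon motif enrichment and positional RNA maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skipped-exon motif enrichment and positional RNA maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semotif)
```

# The model

A cassette (skipped) exon is quantified by its percent spliced in,
$\Psi \in [0,1]$: the fraction of a gene's transcripts that include the
exon.  Comparing a wild-type (reference) group against a knockout group,
$\Delta\Psi = \bar\Psi_{\mathrm{ref}} - \bar\Psi_{\mathrm{cmp}}$, with
group means taken over the available biological replicates.  Under this
sign convention an exon whose inclusion the regulator promotes is
*enhanced* ($\Delta\Psi > 0$: high inclusion where the regulator is
present) and a repressed exon is *silenced* ($\Delta\Psi < 0$).

`classify_events()` partitions events:

* **enhanced** — FDR $< 0.05$ and $\Delta\Psi \ge +0.05$ (inclusive);
* **silenced** — FDR $< 0.05$ and $\Delta\Psi \le -0.05$;
* **control** — FDR $> 0.5$, every group-mean $\Psi$ strictly inside
  $(0.15, 0.85)$, and the event's gene has average FPKM $> 5$ in at
  least one group;
* **unclassified** — everything else.

The boundary conventions follow the published wording exactly: the
$\ge 5\%$ $\Delta\Psi$ cutoff is inclusive, the twofold expression rule
used elsewhere is strict.  The control PSI bound is stated in the
literature in two superficially swapped forms ("min PSI > 0.15, max PSI
< 0.85" and "maxPSI > 15%, minPSI < 85%"); both are read here as
$0.15 < \Psi < 0.85$, applied to the *group means* (the per-replicate
alternative is not identifiable from the published wording; group means
are what the control definition's other clauses operate on).  Events
whose gene has no expression record can never become controls (controls
are the enrichment background, so under-filling that set is the
conservative failure mode); they fall into `unclassified` with a
warning rather than an error.

# Region extraction

For each event `extract_regions()` returns the exon body and the
intronic windows scanned for motifs: up to 250 nt of intron immediately
adjacent to the cassette exon on either side, with splice-site
nucleotides *masked out* of the scanned window — 20 nt inside every 3′
splice site and 6 nt inside every 5′ splice site, wherever the window
covers them.  The effective scanned lengths on long introns are
therefore 230 nt (upstream) and 244 nt (downstream).  Two readings of
"excluding the splice sites" are possible: masking the excluded
nucleotides out of the fixed exon-adjacent window, or shifting the
window outward so that 250 scannable nucleotides remain.  Masking is
the default (the exclusion is described as *within* the splice site,
i.e. a property of the sequence, not of the window); shifting is
available via `region_config(shift_exclusions = TRUE)`.

Introns shorter than the window truncate it; an intron shorter than the
combined exclusions yields an empty region with a truncation flag, not
an error.  All sequences are returned as RNA, 5′→3′ in transcript
orientation: minus-strand events are reverse-complemented, and
"upstream"/"downstream" always refer to transcription direction (the
upstream flanking exon of a minus-strand event has the larger genomic
coordinates, as in rMATS output).  Soft-masked genome bases are
uppercased and scanned; ambiguity codes such as `N` are retained and
never match any motif position.

`extract_map_segments()` returns the five RNA-map segments (upstream
exon, 250-nt upstream intron, cassette exon, 250-nt downstream intron,
downstream exon) *without* splice-site exclusions — the positional map
is described without them, and masking would carve artificial notches
into the profile at fixed offsets.

# Motif enrichment

Occurrences are counted in two modes.  **by-NT** counts every matching
start position, including overlapping matches ("GUGGUG" occurs twice in
"GUGGUGGUG").  **by-Sequence** records presence/absence.  Motif
patterns may use IUPAC degeneracy; `N` in a *scanned sequence* matches
nothing.

For each motif × region × direction, `enrich()` builds a 2×2 table
against the control set and computes the right-sided Fisher exact
p-value, $P(X \ge a)$ under the fixed-margin hypergeometric null
(`fisher_right()`, verified against exhaustive enumeration in the test
suite).  The exact construction of the published by-NT table is not
recoverable from the text, so two constructions are provided and the
active one is recorded in the result's `counting` attribute:

* `"positions"` (default): occurrences versus remaining scannable start
  positions, $\sum_s \max(0, |s| - k + 1)$ per set.  This treats each
  possible motif start as a Bernoulli trial and is the construction
  under which the null calibration suite runs.
* `"coverage"`: motif-covered nucleotides versus uncovered nucleotides.

Benjamini–Hochberg correction is applied to the by-NT p-values across
motifs *within each region family separately* (exon body, upstream
intron, downstream intron), and additionally per direction, since the
enhanced and silenced sets are tested independently (the published
threshold names region families only; the direction split is this
package's choice and makes the two directions' FDRs non-competing).
By-Sequence p-values are reported raw: the published enrichment rule
names an FDR only for by-NT ("FDR(by-NT) < 5% and p-value(by-Sequence)
< 0.01"), and that dual rule is what the `enriched` flag implements.

# The RNA map

`coverage_track()` marks each nucleotide lying under at least one
occurrence of any panel motif; `window_scores()` averages that binary
track over a 50-nt window slid 1 nt at a time.  `build_map()` aligns
windows across events:

* intron segments anchor at the exon-proximal boundary (upstream-intron
  position $-50$ is the window flush against the 3′ splice site;
  downstream-intron position $0$ is flush against the 5′ splice site);
* exon segments anchor from *both* edges, up to 100 windows per edge by
  default (positions $\ge 0$ count from the segment 5′ end, positions
  $< 0$ from its 3′ end).  Exons are not rescaled to percent length:
  positions beyond a short exon simply receive no contribution, and the
  number of contributing events is reported per position.

Windows are emitted only when fully inside one segment — cross-boundary
windows would make segment attribution ambiguous — and no smoothing is
applied beyond the 50-nt window itself.  The published panel of "top 12
GU-rich binding sites" is only partially printed (UGGUGG, GGUGGU,
GUGGUG); `esrp_motifs()` ships those three plus nine documented
UGG-containing stand-ins, flagged as such in their `source` column, and
any analysis where the exact panel matters should supply its own
`motif_set()`.

# Quantitative statistics

* `psi_from_bands()` converts RT-PCR band intensities to PSI after
  dividing each intensity by its product length, making the ratio molar
  (a longer product incorporates proportionally more label).
* `t_test_two_tailed()` works from summary statistics.  The default is
  the pooled-variance Student's t with $n_1+n_2-2$ degrees of freedom;
  "±" values accompanying published group summaries are interpreted as
  sample standard deviations.  This interpretation is testable: with
  means/SDs 16.00 ± 2.37 ($n=8$) versus 12.25 ± 1.24 ($n=6$) the pooled
  test gives $p = 0.0043$ to two significant figures, matching the
  printed value, whereas an SEM reading does not.  Welch's
  approximation is available by flag.
* `concordance()` is the sample Pearson correlation with the two-tailed
  p-value from the $t = r\sqrt{(n-2)/(1-r^2)}$ transform.
* Degenerate-input conventions: two zero-SD groups with equal means give
  $p = 1$; zero-variance vectors make the correlation an error rather
  than `NA`; a PSI from two zero intensities is an error.

# The synthetic world

`simulate_dataset()` emits a genome FASTA, an rMATS-style SE table, a
Cuffdiff-style expression table and a truth bundle.  Its defaults *are*
the stated conditions of the motivating screen's largest comparison and
are not tuned per test:

* 119 enhanced, 95 silenced, 500 control events; 3 replicates per group
  (the study used 2–3).
* Replicate PSIs are beta-distributed with within-group SD 0.05;
  regulated events have group means 0.7/0.3 ($|\Delta\Psi| = 0.4$), and
  control events share a per-event mean drawn uniformly from
  $(0.30, 0.70)$ — chosen comfortably inside the $(0.15, 0.85)$ control
  bound so that replicate noise does not leak control events across it.
* Event p-values come from an actual two-sample t-test on the simulated
  replicates, FDRs from BH across events, so the FDR column behaves
  like a real screen (a handful of null events near the threshold is
  expected behaviour, not a bug).  A `fdr_model = "fixed"` mode places
  FDRs deterministically beyond the thresholds for exact truth-recovery
  checks.
* The GU-rich motif `UGGUGG` is planted at Poisson-distributed,
  non-overlapping positions uniformly within the *scannable* part of
  each region: rate 2 in silenced upstream introns (plus rate 1 in
  silenced exon bodies, following the positional architecture in which
  upstream/exonic binding silences and downstream binding enhances),
  rate 2 in enhanced downstream introns, and a uniform background rate
  of 0.2 everywhere else — roughly a tenfold excess where planted.
* Exons are 80–200 nt (flanks 100–250 nt), introns 300–800 nt, on
  random strands across synthetic chromosomes separated by `N` spacers;
  control-event genes get FPKM above the control floor, and the
  expression table carries planted DEGs (fold 2.5–8, $q \le 0.01$)
  against nulls (fold $\le 1.25$, $q \ge 0.2$).

What the generator deliberately does **not** emulate: read-level noise
(PSI is drawn, not estimated from simulated reads), realistic base
composition and splice-site signals (background is i.i.d. uniform by
default, with a configurable composition for stress tests — real
introns are not i.i.d., and GU-rich backgrounds inflate GU-motif
counts), transcript structure beyond a single exon trio per gene, and
correlated motif co-occurrence.  A green end-to-end test therefore
establishes that the statistical machinery recovers a planted signal of
the stated size under the stated noise — not that the thresholds would
perform identically on biological data.

# Numerical and degenerate-input conventions

* All intervals are 0-based half-open internally; the rMATS dialect
  (0-based start, 1-based end) is numerically identical and read
  unshifted, while fully 1-based tables are converted on read.
* Fold changes with one zero mean are $\infty$ (they pass a strict fold
  floor iff the q-value and expression floor pass); two zero means
  never yield a DEG.  A pseudocount option exists for users who prefer
  shrunk ratios.
* BH ties need no special handling (the step-up adjustment is
  tie-stable); permutation equivariance and monotonicity are asserted
  in the property suite.
* `fisher_right()` is computed from the hypergeometric tail rather than
  by table enumeration; the two agree to $10^{-12}$ over all tables
  with total $\le 60$ (acceptance suite).

# Known limitations

* Only skipped-exon trios are modelled; mutually exclusive exons are
  supported at the quantification level (`psi_iiib()`) but not
  re-detected.
* The enrichment background inherits whatever ascertainment the control
  definition imposes (well-expressed genes, mid-range PSI); no
  composition matching (GC/length correction) beyond the control-set
  design is applied, mirroring the original procedure.
* Profiles carry no uncertainty bands; the per-position
  contributing-event counts are reported so users can judge support at
  long offsets.
* The shipped 12-motif panel is a documented stand-in for an only
  partially published list and should be replaced for any scientific
  use against real data.
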