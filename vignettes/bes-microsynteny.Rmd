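---
title: "Methods: BAC-end-sequence comparative mapping with besmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BAC-end-sequence comparative mapping with besmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A BAC (bacterial artificial chromosome) library carries a genome in
~30–300 kb cloned inserts. Sequencing one read from each end of a clone
(a BES pair) gives two anchors whose relative placement on a *related*
reference genome is informative twice over: it validates the library
(insert integrity, contamination, coverage) and it measures how the two
genomes have diverged structurally (local expansion and contraction,
inversions, translocations). besmap implements that analysis for the
setting of the SS_SBa sugarcane (SP80-3280) library surveyed against the
ten sorghum chromosomes: a monoploid genome of 760–930 Mb sampled by
36,864 clones with a 125 kb mean insert, of which 192 clones / 384 end
reads were end-sequenced.

The package has three entry points:

* `run_simulate()` — generate a synthetic clone library with full planted
  truth (see below);
* `run_analyze()` — QC, repeat annotation, mapping, paired-end synteny
  classification, expansion statistics, repeat ledger;
* `run_tables()` — recompute every derived statistic from transcriptions
  of the survey's published summary tables (worked-example mode).

A thin command-line wrapper with the same three verbs is installed at
`system.file("cli", "besmap", package = "besmap")`.

## Synteny classification model

Each clone's two end reads are placed on the reference with the built-in
mapper (or imported BLAST-tabular alignments). For a pair mapped to one
chromosome, let U be the hit with the smaller start and D the other; the
**orientation pattern** is *opposite-in* (`> <`, U on `+`, D on `-`),
*opposite-out* (`< >`), or *same* (`<<`/`>>`). The **outer span** is
max(end) − min(start), i.e. the projected insert size. The class grid is:

| class | chromosome | orientation | outer span | reading |
|------|------------|-------------|-----------|---------|
| C1 | same | opposite-in | 20–300 kb | concordant (microsyntenic) |
| C2 | same | same | 20–300 kb | discordant (local inversion) |
| C3 | same | opposite-in | > 300 kb | discordant (expansion beyond window) |
| C4 | same | same | > 300 kb | discordant |
| C5 | same | opposite-out | > 300 kb | discordant |
| C6 | different | — | — | discordant (translocation) |
| C7 | one end aligned, single hit | | | |
| C8 | one end aligned, multiple hits | | | |
| C9 | no end aligned | | | |

Three conventions deserve explanation because the grid alone does not fix
them:

* **Outer vs inner span.** The 20–300 kb window brackets the observed
  insert sizes (29–293 kb), so the span compared against it must be the
  projected insert size — the outer span. The window is closed:
  20,000 ≤ span ≤ 300,000 counts as "in range".
* **Extension labels.** The grid leaves out spans below 20 kb and
  opposite-out spans up to 300 kb. Such pairs get labels X1–X4 (X1/X2/X3 =
  opposite-in/same/opposite-out below 20 kb, X4 = opposite-out in range),
  reported distinctly and counted as discordant; silently folding them
  into C1–C6 would corrupt the class accounting.
* **Same-chromosome priority.** When several hits per end exist, the
  placement maximising the score sum over same-chromosome pairings wins
  (ties: concordant first, then smaller span, then chromosome name). C6 is
  assigned only when *no* same-chromosome pairing exists; a config switch
  (`require_same_chrom = FALSE`) lets a higher-scoring cross-chromosome
  combination force C6 instead.

The published survey's class table itself contains a numbering
discrepancy against its running text for the single-end classes (the text
swaps the single-hit and multi-hit labels); the table's convention
(C7 = single hit, C8 = multiple, C9 = none) is implemented.

## Expansion and contraction statistics

Every concordant (C1) clone contributes a syntenic region with
`query_bp` = its insert size and `ref_bp` = its placement's outer span;
`delta_bp = ref_bp − query_bp` with ties counted as contracted (so
"expanded" strictly means larger — the surveyed data have no ties, so the
convention is documented rather than consequential). Regions aggregate by
chromosome and direction, and the headline statistic is the grand-total
ratio

$$\text{expansion %} = 100\,\frac{\sum \text{ref\_bp} - \sum \text{query\_bp}}
{\sum \text{query\_bp}},$$

which on the published table rows gives 29.97% (printed as "29%"). The
report carries both the raw two-decimal value and the integer-rounded
one. Whether the survey used this total-ratio convention, a per-region
mean, or the reference-side denominator is not derivable from the text;
total-ratio is the default (it reproduces the printed headline) and the
alternatives are available via `expansion_method` — they are genuinely
different statistics, which is why the choice is surfaced rather than
hidden.

Coverage is total cloned bases over the monoploid genome size
(36,864 × 125 kb / 760–930 Mb = 6.06–4.95×, and 7.94× at the revised
580 Mb estimate); contamination is reported per clone to one decimal.

## The built-in mapper and its oracle

The mapper is a seed-and-extend aligner sufficient for the synthetic
data this package validates itself on, not a general-purpose competitor:
exact k-mer seeds (default k = 16, stride 16) from the read and its
reverse complement, grouped per (chromosome, strand, diagonal); ungapped
extension scored +1/−3 taking the best-scoring segment on the diagonal
(optimal for a substitution-only error model, which is also why exact
diagonal grouping suffices — there are no indels to shift the diagonal);
a Karlin–Altschul E-value analogue `E = K·m·n·exp(−λS)` with fixed
λ = 1.28, K = 0.46 (configurable); an E ≤ 1e-20 cutoff; and one-HSP-
per-locus reporting (best hit per chromosome/strand/10 kb window).
Annotated repeat intervals contribute no seeds, emulating masked search.

`brute_force_map()` is the independent oracle: an exhaustive sliding-
window scan of both strands (delegated to `Biostrings::matchPattern`,
which implements exactly that, in C) that must equal the mapper's hit set
on error-free reads — the equality is asserted over 500 reads against a
5 Mb genome in the acceptance suite.

Reads more than half covered by repeat annotations are excluded from
synteny mapping (the survey excluded "repetitive" end reads without
stating a threshold; 0.5 is the package default,
`repeat_exclusion_fraction`). A clone with an excluded end is classified
as if that end were unaligned.

## Quality control

* **Vector trimming** removes the longest read prefix/suffix matching a
  vector terminus with ≥ 16 matching bases (configurable, floor 12) and
  ≤ 2 mismatches; an interior vector hit keeps the longer flank.
* **Quality trimming** keeps the largest contiguous segment whose every
  20-base window has mean phred quality ≥ 20, then clips terminal bases
  below the threshold (window means alone would drag in a few low-quality
  bases at the boundaries); reads shorter than 100 bases after trimming
  are rejected. The surveyed pipeline used an EST-era trimming procedure
  whose exact parameters are unpublished; this sliding-window scheme with
  those defaults is the package's interpretation, fully configurable.
  The survey's observed 312 bp minimum read length is treated as an
  observation, not a trimming threshold.
* **Organelle screening** flags a read if any hit against the organelle
  genome has E ≤ 1e-20 and covers ≥ 80% of the read; a clone is
  contaminated if either end is flagged (per-clone reporting, matching
  the survey's "1 BAC out of 192 = 0.5%"). Contaminated clones keep
  their place in the class table (their reads are excluded from mapping,
  so they classify as C9), which is what keeps the class counts a
  partition of all clones.

Every stage logs records in/out; the run manifest asserts the
identities (input = passed + rejected; class counts sum to clones;
aligned + no-hit ends = 2 × clones).

## The synthetic-data generator

The generator is first-class, tested code: it emulates the statistical
structure the analysis assumes, with full ground truth, so that every
downstream stage can be validated by parameter recovery.

* **Query genome**: 10 chromosomes of 3 Mb (the smallest round length
  at least 10× the maximum insert), i.i.d. background at GC 0.44
  (grass-like), optionally with repeat copies placed by a renewal
  process at target density 0.45 of bases — the surveyed repeat share of
  read bases. Copies diverge from their family consensus by uniform
  substitutions at 2–12%; the ceiling keeps copies recognisable by
  library similarity, because the emulation target (45% of read bases)
  is *detected* repeat content and a similarity masker fragments copies
  much beyond that divergence. The library itself is synthetic
  consensus sequences for the surveyed families (Copia, Gypsy, L1, RTE,
  SINE, SINE2/tRNA, EnSpm, Harbinger, Helitron, MuDr, hAT,
  Caulimoviridae, Satellite) with weights matching the published
  base-share ledger.
* **Rearrangement plan**: each chromosome tiles into 6 equal blocks.
  Block scale factors are a mixture — contracted with probability 0.3,
  uniform on (0.85, 1.05), else uniform on (1.30, 1.60) — whose mean is
  exactly 1.30, so contracted regions exist (the survey found 20 of 42)
  while the mean matches the ~1.3× reference expansion. Blocks invert
  with probability 0.15 and translocate with probability 0.1.
  Expansion/contraction is realised by inserting/deleting random-sequence
  chunks at uniform positions (≤ 50 chunks per block), recorded exactly,
  so query→reference projection is available at base resolution outside
  edited positions. Random-sequence insertion (rather than repeat-copy
  insertion) keeps the expansion and repeat-content tests orthogonal;
  repeat-mediated expansion is not simulated.
* **Clones and reads**: insert sizes are truncated-normal, mean 125 kb,
  sd 30 kb, truncated to 29–293 kb. The sd is the one free parameter and
  is set so that P(insert > 90 kb) ≈ 0.88, the survey's observed
  fraction (sd 40 kb would give ≈ 0.82). Read lengths are truncated-
  normal mean 944 bp, sd 150, floor 312, capped at half the insert; the
  forward read is the 5′ end of the insert, the reverse read the
  reverse complement of the 3′ end. Reads get a vector flank of 20–60 bp
  from the simulated cloning-vector terminus, a 3′-decaying quality
  profile, and uniform substitution errors at 0.5%/base (no indels —
  adequate to exercise mismatch tolerance while keeping the brute-force
  oracle exact). Partial-digest chemistry is not simulated: the analysis
  consumes insert sizes, not restriction sites.
* **Planted classes**: the default class mix is the survey's observed
  table (42 C1, 1 C2, 16 C3, 12 C4, 15 C5, 9 C6, 10 C7, 65 C8, 22 C9 per
  192 clones). C1/C2 clones sit inside ordinary blocks; C2/C4 flip one
  end and C5 both ends (small terminal inversions of the query relative
  to the reference); C3–C5 need spans above 300 kb, which the standard
  insert model cannot reach at scale ≤ 1.6, so they are planted in a few
  strongly expanded "jumbo" blocks (scale uniform on 2.5–4) that are
  excluded from the concordant pool; C6 clones straddle a block boundary
  whose blocks map to different reference chromosomes; C7/C9 replace one
  or both end reads with fresh random sequence (genome-specific DNA with
  no counterpart in the reference); C8 additionally writes two extra
  copies of the intact end's footprint into unoccupied reference
  positions, ≥ 12 kb from any other footprint so one-HSP-per-locus
  reporting keeps three distinct hits. Placements are resampled until
  both end-read footprints avoid block boundaries and edit points —
  planted truth requires each read to be contiguous in the reference —
  and until the realised geometry (via exact projection) matches the
  intended class. Organelle contamination then replaces clones at rate
  0.005 with inserts drawn from a circular 150 kb chloroplast-like
  genome.
* **Determinism**: all randomness flows from one seed through named
  substreams, so identical (config, seed) give byte-identical datasets
  and stages can be re-run in isolation.

What the generator does *not* emulate — and hence what passing recovery
tests do and do not show — includes polyploidy and homeologous
chromosomes (every clone has a single true origin), indel and chimeric-
read artefacts, biased clone distributions (real libraries under-sample
centromeric repeats), diverged-ortholog alignment (reads either match
nearly exactly or not at all, unlike cross-species BlastN at ~8 Myr
divergence), and gene content. Recovery at 100% on clean synthetic data
validates the *logic* of the pipeline, not its sensitivity on real
cross-species alignments.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; BLAST-tabular
  files (1-based inclusive, strand by coordinate inversion) are
  normalised at import so nothing downstream ever sees an inverted
  interval.
* FASTA input gets an implicit uniform quality of 40 so the trimming
  operators are total.
* Repeat-ledger roll-up never forces children to sum to their parent:
  internal nodes may carry bases classified only at family level (the
  published ledger itself has such rows, e.g. LTR retrotransposons
  exceeding Copia + Gypsy); a parent holding *fewer* bases than its
  children is rejected as inconsistent. In the published ledger the
  SINE2/tRNA row duplicates the SINE row's elements, so the taxonomy
  nests SINE2/tRNA under SINE rather than beside it — the only reading
  under which the non-LTR totals are consistent.
* The abstract-level "83% LTR" and text-level "85.2% LTR" use different
  denominators (total repeat bases vs transposable-element bases); both
  fractions are emitted, neither is "corrected".
* Tie-breaks in placement selection end with leftmost position, making
  reports reproducible to the byte.

## Problem sizes and validation design

The acceptance suite runs at the study's scale: 192 clones / 384 reads
on a 10 × 3 Mb query genome, mapper-oracle agreement on 500 reads over
a 5 Mb genome, and expansion recovery aggregated over three replicate
all-concordant libraries with 8 blocks per chromosome. The replicate
aggregation is a variance design decided a priori: a single library's
total-expansion estimate inherits block-sampling noise of about 3
percentage points (mixture sd 0.24 over ~80 blocks), so three pooled
replicates bring the standard error to ~1.8 points against the ±5-point
recovery band. Unit tests use a scaled-down library (4 × 0.4 Mb genome,
12–40 kb inserts, a 5–60 kb concordance window) so the default test run
stays fast.

## Known limitations

* The mapper is ungapped; data with indels need external alignments
  (`alignments_path`, outfmt-6 or the native dialect).
* Repeat annotation reports the best segment per diagonal; heavily
  diverged copies (> ~15%) are fragmented or shortened, as with any
  similarity masker.
* Classes are assigned per clone in isolation; no multi-clone
  scaffolding or cross-clone consistency is attempted.
* The expansion statistic treats insert sizes as exact; in the surveyed
  data they are gel estimates, so the real-data statistic inherits gel
  sizing error that the simulation does not model.
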