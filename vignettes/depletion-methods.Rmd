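---
title: "Probe-panel design and depletion QC: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-panel design and depletion QC: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrna)
```

## The problem

Ribosomal RNA can account for the large majority of a total-RNA sequencing
library — in an untreated fresh-frozen library well over 90% of uniquely
mapped reads, and around 60% in libraries made from formalin-fixed,
paraffin-embedded (FFPE) tissue. PolyA+ selection, the usual remedy, fails
on FFPE RNA because archival RNA is fragmented into pieces too short to
carry a poly-A tail with their body sequence. An alternative is enzymatic
depletion: tile short antisense DNA oligos across the abundant species,
digest the resulting RNA:DNA hybrids with RNase H, and remove the probes
with DNase I. Because every fragment of the target hybridizes to some probe,
the approach works on fragmented input.

This package implements the computational side of that workflow: panel
design, off-target screening, read trimming, read-class QC, depletion
efficiency, and cross-library correlation — plus a simulator that makes the
whole pipeline testable end to end with known truth.

## Probe tiling

A target of length $L$ is partitioned into adjacent, non-overlapping windows
of at most `max_len` (default 80 nt) and at least `min_len` (default 39 nt)
bases; each window's reverse complement is one probe. Two policies are
provided:

* **greedy** (default): consecutive 80-nt windows from position 0 plus one
  remainder window of $L \bmod 80$ nt when that remainder is at least
  `min_len`. This reproduces the published panel layouts for the 18S
  (24 × 80 + 56), 28S (62 × 80 + 65), 12S (11 × 80 + 74) and 16S
  (19 × 80 + 39) subunits.
* **balanced**: $\lceil L/80 \rceil$ windows whose lengths differ by at most
  one base. Greedy falls back to balanced when its remainder would be
  shorter than `min_len`, so no target ever loses terminal coverage. The
  5.8S reference design (two 78-mers against a 157-nt record) is closer to
  the balanced layout (79 + 78) than to greedy (80 + 77); neither matches it
  exactly and the probe count (2) is the same either way, so greedy remains
  the single default rather than special-casing one target.

Under both policies the probe count is exactly $\lceil L/80 \rceil$.
`min_len = 39` is the length of the shortest probe actually synthesized in
the reference panels (the 16S remainder), which we take as more
authoritative than the nominal 50–80 nt range.

Concentration groups are a pooling convention: group A targets (18S, 28S)
contribute 0.5 µM per probe to the pool, group B targets (5.8S, 12S, 16S)
0.05 µM. The 88-probe two-target panel therefore totals 44 µM.

## Off-target screening

Probes are screened against a transcriptome by exact local alignment
(Smith–Waterman with affine gaps, implemented in C++) under blastn-style
low-stringency scoring: match +2, mismatch −3, gap of length $k$ costing
$5 + 2k$. Both subject strands are searched; ties between strands are broken
toward the longer alignment, then the smaller subject start, then the plus
strand. A word-seeded fast path (11-mers, the blastn default word size)
restricts the dynamic programming to windows of ±2× query length around
exact word hits and falls back to the exhaustive search when no seed exists;
the test suite verifies seeded/exhaustive score equality on randomized
instances.

Two deliberate interpretations:

* **Identity denominator.** A probe–gene pair is flagged as homologous when
  the number of aligned identities is at least 50% *of the probe length*,
  not of the alignment length. The alignment-length denominator can call a
  12-base perfect hit "100% identity"; the probe-length denominator is the
  probe-centric risk measure the flag is meant to be.
* **No E-values.** Low stringency is realized as a raw-score floor
  (default 20) before identity filtering, rather than a Karlin–Altschul
  E-value: the downstream rule (identity ≥ 50%) never consults the E-value,
  so computing one would add calibration machinery without changing any
  result. A DUST-style low-complexity mask is available but off by default
  so that toy tests are exactly reproducible.

Flagged genes are classified by which probes hit them: any hit from a
core-panel probe (18S/28S, present in both panel versions) marks the gene
`SDRNA`; hits only from the added targets mark it `SDRNA2-only` — the two
sub-populations highlighted in depleted-vs-undepleted scatterplots.

## Adapter and fixed-end trimming

The 3′-adapter trimmer tests adapter prefixes longest-first against the read
suffix of equal length (Hamming comparison, no gaps) and trims the first
prefix within the mismatch allowance. The allowance is a user function of
match length; the default `floor(k/10)` (~10% tolerance, `k_min = 5`) is the
convention common to 3′-adapter trimmers, since the source procedure states
only that tolerance "varied". Fixed-end trimming (defaults 6 nt from the 5′
end, 8 nt from the 3′ end, both exposed as policy parameters because they
are dataset-specific constants, not method constants) follows adapter
trimming; that composition order is fixed. Reads left shorter than one base
are dropped and counted.

## Read classification and the efficiency statistic

Uniquely mapped reads (SAM rule: `NH` absent or 1 and MAPQ ≥ 10 by default —
the upstream definition of "unique" varies by mapper, so both knobs are
configurable) are classified by ≥1-base overlap with labeled regions under a
fixed priority ladder: targeted rRNA > non-targeted rRNA spacer >
mitochondrial 12S/16S > other mitochondrial > exon > intron > intergenic. A
read straddling a boundary takes the higher class. The two-way rollup counts
all nuclear rRNA labels plus the mitochondrial rRNAs as "rRNA".

Depletion efficiency is estimated from the targeted-class fractions of an
untreated library ($f_u$) and a depleted library ($f_d$) as

$$E = 1 - \frac{f_d/(1-f_d)}{f_u/(1-f_u)}.$$

Read proportions are compositional: removing targeted molecules inflates the
apparent proportion of everything else, so the naive $1 - f_d/f_u$
underestimates removal. The odds form cancels the renormalization exactly —
if a fraction $e$ of targeted fragments is removed before sequencing, the
odds ratio recovers $E = e$ in expectation, which the simulation tests
confirm to ±0.01 at 2×10⁵ reads. Both estimators are exposed.

Cross-library correlation is the Pearson R of log10 counts over genes with
nonzero counts in *both* libraries. The pairwise exclusion rule is the only
one compatible with log10 on both axes. Per-stratum R values are reported
for small-RNA biotypes (sno/sn/sc/mir) and probe-homolog flags, with
identity-line residuals for outlier listing.

## The simulator

`make_reference()` builds a random-sequence genome with the structural
features the pipeline cares about: a 13 kb ribosomal repeating-unit contig
with embedded 18S/5.8S/28S regions (defaults 1976/157/5025 nt, the lengths
implied by the published probe arithmetic) separated by non-targeted
spacers; a mitochondrial contig with 12S/16S regions (954/1559 nt); and
mRNA genes with alternating exon/intron blocks. `simulate_library()` draws
fragments by class fraction (gene-derived fragments weighted by log-normal
abundances and split between exons and introns by `intron_retention`),
removes fragments overlapping targeted regions with probability $e$, and
emits one read per survivor together with a truth alignment table — the
upstream mapper is out of scope, so simulated alignments *are* truth and all
reads are unique by construction.

Default fractions emulate an untreated FFPE library: 60.5% combined rRNA
(decomposed as 54% targeted nuclear rRNA + 1.5% spacer + 5% mitochondrial
rRNA, a split the headline composition does not constrain), intergenic 4%,
and `intron_retention = 0.7`, reflecting the intron-heavy gene-derived read
population of fixed tissue. Fragment lengths are discretized gamma with mean
60 nt (FFPE-like; use ~200 for fresh-frozen-like input) and shape 4. Reads
are 51 nt. Fragments are placed entirely within their region of origin, so
truth recovery by the classifier is exact rather than merely ≥ 99.9%;
boundary-straddling is exercised separately with constructed fixtures.

What the simulator does **not** model: sequencing error, mapper artifacts,
multimapping, splice-junction reads, positional coverage bias, or any
mechanistic explanation of FFPE intron retention (the retention fraction is
a free parameter). Passing tests on simulated data therefore demonstrate
correctness of the analytics under the stated sampling model, not
performance on real libraries.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the simulator at 2×10⁵ reads
(binomial 3σ for a 94.4% fraction is ±0.15 percentage points, comfortably
inside the ±0.3 reporting tolerance), replicate correlation at 10⁶ reads
over 5000 genes, and alignment equivalence on queries ≤ 80 nt against
subjects ≤ 500 nt. Proportions are kept at full precision internally and
rounded half-up to 0.1% only for display, so displayed two-way splits can
sum to 100.1%. All randomness flows from explicit integer seeds; identical
inputs produce byte-identical panel reports.
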