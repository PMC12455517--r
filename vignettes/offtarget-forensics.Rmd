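---
title: "Host off-target forensics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host off-target forensics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplihijack)
```

## The problem

16S rRNA amplicon surveys of host-rich material (intestinal biopsies
and other tissues) routinely use the V3–V4 primer pair 341F/805R. PCR
specificity is probabilistic: when host template vastly outnumbers
microbial template, primers anneal to host regions that are imperfect
copies of themselves, provided the 3′ terminus — where the polymerase
extends — matches perfectly. Where two such landings sit convergently
a few hundred bases apart, an exponential off-target product forms.
The result is a reproducible contamination mode: recurrent host loci
emitting amplicons that can consume from under 0.1 % to tens of
percent of a run's reads.

`amplihijack` turns that mechanism into an analysis pipeline: find the
landings, predict the products, classify and localize observed
off-targets, summarize their shared sequence as an IUPAC consensus,
design a blocking oligo against it, and measure the community-analysis
bias of leaving off-targets in.

## The mis-priming model

A priming site is an ungapped alignment of the (degenerate) primer at
a genomic position and strand such that

* the `anchor_len` 3′-terminal bases match perfectly under IUPAC set
  intersection, and
* at most `max_mismatches` positions mismatch elsewhere.

Defaults are `anchor_len = 5` and `max_mismatches = 4`. The anchor
expresses the biochemical requirement that extension needs a paired 3′
end; five bases is the shortest anchor that still makes accidental
anchor matches rare (4^-5 with one degenerate position ≈ 1/512 per
position and strand). Four mismatches covers the 2–4 internal/5′
mismatches observed at the recurrent human landings while keeping the
site count interpretable. Both are user-settable; indel (gapped)
priming is deliberately unsupported — mis-primed extension products
with indels would not produce the exact recurrent 5′ ends observed.

An unknown genome base (`N`) never matches any primer base: a
conservative rule, since calling a site through an unsequenced base
would be evidence-free.

Convergent site pairs on one chromosome whose primer-spanning product
lies within `[min_len, max_len]` (default 100–600 bp, covering both
the ~300 bp off-target including primers and the ~460 bp legitimate
V3–V4 product) become predicted amplicons. Coordinates are 0-based
half-open internally and in BED output; human-facing tables add
1-based positions.

The scanner is exact by construction and is additionally pinned, in
the test suite, to an independent matcher (Biostrings
`matchPattern(fixed = FALSE)` plus per-window verification) on 100
seeded random genomes.

## Classification and localization

ASVs are aligned to the host genome by a k-mer–seeded (k = 16),
ungapped, both-strand aligner intended for desk-scale references; an
external aligner's SAM can be ingested instead (mapped primary records
become off-targets; secondary/supplementary records are ignored). A
feature is a host off-target iff its best hit reaches identity ≥ 0.95
and query coverage ≥ 0.90 — chosen so that sequencing-error-bearing
reads from a true host locus (≤ 1–2 % substitutions) classify
positively while half-host chimeras fail on coverage. Only the single
best hit is kept (ties break by reference name, then position, then
plus strand), matching the one-locus-per-ASV reporting convention.

Off-target 5′ mapping positions are clustered per (chromosome, strand)
by single linkage with a 5 bp gap tolerance; the biological 5′ end of
a minus-strand hit is its rightmost genomic coordinate. Clusters are
ranked by read weight, reproducing the "recurrent position" summaries
that expose the dominant source loci.

## Consensus calling

Off-target reads share an exact, primer-defined start, so a gapless
end-anchored alignment replaces general multiple sequence alignment:
reads are truncated to a window from the chosen end (default 32 nt at
the 5′ end, 29 nt at the 3′ end, the lengths of the recurrent motifs);
for 3′ windows the reads are reverse-complemented first so columns
read 5′→3′ of the motif. No gaps can arise between reads born from the
same priming event, so nothing is lost relative to a general aligner.

Counts (ambiguous input residues distributed fractionally over their
expansion sets) form a position frequency matrix, from which two
consensus strings are called:

* **full** — per column, every base with frequency ≥ `include_freq`
  (default 0.25) joins the IUPAC code;
* **reduced** — columns whose minor included bases all stay below
  `drop_freq` (default 0.10) collapse to the majority base, and
  trailing columns observed in fewer than `min_coverage` (default
  0.50) of the reads are trimmed.

The thresholds operationalize "exclude degenerations with extremely
low frequency": a balanced two-base column (e.g. the C/G S column of
the off-target motif) survives reduction, while rare-variant
degeneracies collapse. One documented discrepancy: the published full
form of the 5′ motif is a 33-character degenerate string labelled as
32 nucleotides; this package treats 32 nt as the *reduced*-consensus
length, which is internally consistent, and makes no use of the
33-character form.

`locate_motif()` searches a motif IUPAC-aware, ungapped, on both
strands with a mismatch allowance — the role a BLASTn search of a
short near-exact query plays — and reports 1-based positions.

## Thermodynamics and the blocking oligo

Melting temperatures use SantaLucia (1998) unified nearest-neighbor
parameters with the 0.368·(N−1)·ln[Na⁺] entropy salt correction, at
50 mM monovalent salt and 0.25 µM total oligo (CT/4 term,
non-self-complementary duplex). These conditions are a fixed,
published operating point chosen so that "Tm comparable to the
primers" becomes an assertable ±5 °C window; the degenerate-oligo Tm
is the arithmetic mean over all concrete expansions (min and max are
reported as attributes). Under these settings the 24-mer blocker sits
3.9 °C below the 341F/805R mean.

The hairpin scan enumerates every antiparallel self-complementary
window pair with loop ≥ `min_loop` (default 3). A stem qualifies only
if it contains at least `min_gc = 1` G:C pairs: a short stem held
exclusively by A:T pairs has no stability at PCR annealing
temperatures, and counting it would flag oligos that thermodynamic
tools (and the wet-lab behaviour of the 24-mer blocker) show to be
hairpin-free. Degenerate positions count optimistically toward both
pairing and G:C content, so the check errs toward caution for real
hairpins.

The blocker itself is a 5′ prefix of the reduced consensus — by
construction it anneals immediately downstream of the primer-like
region, exactly where extension would begin — annotated with a 3′ C3
spacer and never treated as an extensible primer anywhere in the
package. With `explicit_length = 24` the published 24-mer (degenerate
S retained) is reproduced; without it, the shortest length in
`length_range = [20, 26]` whose Tm enters the ±5 °C window is chosen,
and the Tm-selected and 24-mer designs can be compared. A design is
`accepted` iff it passes the Tm window, the hairpin check and (when
references are supplied) a cross-reactivity screen that reuses the
mis-priming scanner with the oligo as the query (anchor 5, ≤ 3
mismatches): an empty hit list on microbial references is the
in-silico analogue of producing no "off–off-target" products on a
bacteria-rich matrix.

## Community-bias assessment

Filtering follows the standard contaminant/noise rules at genus level:
a genus is kept iff its maximum per-sample relative abundance reaches
0.01 % **and** it occurs in at least 1 % of samples; organelle reads
and reads unassigned at phylum level are dropped when taxonomy is
available. Genus aggregation precedes filtering; unlabelled features
aggregate as their own singleton groups. Every removal is logged with
its reason, and the operation is idempotent (removals only shrink
denominators, which cannot push a surviving genus below the abundance
cut-off).

`compare_with_without()` recomputes per-taxon mean relative abundances
with host features included in vs excluded from the per-sample
denominators. Since removal only shrinks denominators, microbial
abundances in removed mode are ≥ retained mode, strictly greater
wherever host reads exist — the systematic deflation retained
off-targets cause.

Rarefaction uses the analytic hypergeometric expectation
E[S(n)] = Σ_g (1 − C(N−N_g, n)/C(N, n)) (computed via `vegan::rarefy`)
rather than a single random subsample, making the saturation rule
deterministic. The "final slope" is the one-step increment
(E[S(N)] − E[S(N−step)])/step with step = 100 reads; a sample is
saturated when the slope drops below 1e−4 genera per read. The window
of the final slope (one step vs a fitted tail) is not canonical;
one step is the simplest choice and both step and threshold are
configurable. Samples with fewer than 2·step reads are reported as
unevaluable rather than silently dropped.

Ordination is classical metric scaling of Euclidean distances on
Hellinger-transformed (square-root relative abundance) genus tables.
Hellinger distances are Euclidean-embeddable, so negative eigenvalues
should not exceed numerical noise; if they do, a warning is raised and
those axes are excluded from coordinates. Proportions explained are
relative to the sum of positive eigenvalues. The maximum Hellinger
distance, √2, is attained by samples with disjoint taxa and is used as
a closed-form test anchor.

## What the synthetic generator emulates

The generator is first-class, tested code whose defaults *are* the
study conditions:

* **Host genome** — three 50-kb chromosomes, each carrying one planted
  convergent locus patterned on the recurrent chr5/chr11/chr17 human
  loci: a 341F-like landing with two mismatches outside the 3′ anchor
  (3′-relative offsets 13 and 15), the shared 32-nt 5′ consensus
  immediately downstream (S realized as C, G, C across the three
  loci), a 149-bp spacer, the chromosome-specific 29-nt 3′ consensus
  and an 805R-like landing with two non-anchor mismatches (offsets 8
  and 12) — a 248-bp product spanning both landings, matching the
  outer-end span the printed chr17 consensus coordinates imply, with
  ~300 bp including primers. The chr5/chr11 analogues are planted in
  reverse orientation and chr17 forward, as the motif strands recur.
  The printed chr11 coordinates place the two motifs ~1.8 kb apart,
  inconsistent with a ~250 bp product; the generator does not encode
  printed coordinates as constraints, only the geometry.
  The random background is *screened with the scanner itself*: any
  accidental anchor-perfect landing of 341F, 805R or the blocker
  outside the planted loci is ablated by a single-base anchor patch
  (a spacer spawning a site is redrawn), so planted truth is
  exhaustive and classifier sensitivity/specificity are well-defined.
* **Mock community** — 20 templates of a concrete 341F expansion, a
  420–435 bp random insert (total ≈ 460 bp) and a reverse-complemented
  805R expansion; Dirichlet(1) abundances; templates screened at
  generation time against the consensus motif and blocker-primable
  sites. Kitome contaminants are identical in structure but at trace
  copy number (1 pool copy over 3 taxa), so they surface only when
  host amplification is suppressed or cycles are extended.
* **PCR** — deterministic exponential weights
  `W_t = T_t (1 + e_t)^cycles` with
  `e_t = e0 · rho^(m_t) · (1 − b · I_t)`, followed by one multinomial
  read draw and per-base substitution errors. Defaults: e0 = 0.95,
  rho = 0.6, 25 cycles (35 for the contaminant-enhancing preset),
  error rate 0.005, depth 50,000 reads. Host pool 2e8 copies vs
  microbial 1e3 — an extreme host:bacteria template ratio of the kind
  a biopsy presents; copy numbers are relative template availabilities,
  not absolute molecule counts. With the planted 4 landing mismatches
  this yields an expected off-target fraction of ~17 %, inside the
  observed < 0.1 %–30 % range, and sweeping host copies spans that
  range. The model has no per-cycle stochastic branching: early-cycle
  stochasticity (visible in real qPCR as variable fluorescence onset
  between technical replicates) is deliberately not captured, which is
  the main reason passing tests do not certify behaviour on real data.
  Likewise absent: paired-end structure, chimeras, indels, quality
  variation (constant Phred 35) — the simulation emulates template
  competition and mismatch-penalized efficiency, not a sequencer.

Fixed seeds drive every draw; identical seeds give byte-identical
outputs.

## Numerical and interface choices

* All randomized functions take explicit seeds and restore the
  caller's RNG state.
* Tie-breaks are total and documented: best alignment by (identity,
  length, name, position, strand); cluster modes at the weight-maximal
  position, lowest position on ties; duplicate priming sites
  deduplicated on (chrom, start, strand, primer).
* Degenerate expansion refuses inputs above a 64-expansion limit,
  naming the count; empty inputs round-trip as empty objects, not
  errors, except where a contract requires content (e.g. an empty
  reference set for cross-screening).
* Differential abundance testing is intentionally out of scope; the
  bias stage emits filtered with/without tables ready for external
  tools.
* The command-line interface (`inst/cli/amplihijack.R`) is a thin
  Rscript over the exported functions; `run_pipeline()` is the
  in-R entry point and writes a JSON manifest (seed, effective
  parameters, per-stage record counts) sufficient to reproduce a run.

## Problem sizes in the test suite

The suite favours many small seeded instances over few large ones:
scanner-vs-oracle equivalence on 100 random genomes of 2–10 kb;
consensus recovery over 100 seeds at 50 reads / 2 % noise (and the
120-read / 1 % headline configuration); the full default fixture
(3 × 50 kb, depth 50,000) exercised once end to end; rarefaction
validated against 10,000 subsampling replicates on a 20-genus sample.
These sizes were chosen as the smallest at which every property is
sharply testable.

## Known limitations

* The aligner and scanner are exact but desk-scale; whole-human-genome
  scans work and are linear in genome size, but are not performance
  tuned.
* Priming probability is a threshold model, not a ΔG calculation;
  borderline sites near the anchor/mismatch limits are in or out with
  no grading.
* The blocker design space is prefixes of the 5′ consensus only —
  multi-locus inhibitor panels are out of scope by design.
* Taxonomy in the synthetic world is nominal (labels, not sequence
  phylogeny); bias summaries exercise the arithmetic, not classifier
  behaviour.
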