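---
title: "Mapping intron gain and loss across a whole-genome duplication"
author: "IntronDollo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping intron gain and loss across a whole-genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Saccharomycetaceae yeasts are extremely intron poor: a typical genome keeps
a few hundred spliceosomal introns, most of them ancestral. Comparing the
same intron position across twenty species tells us, for every *ancestral
intron site*, where the intron survives, where it was removed, and by what
mechanism. Two features make this comparison unusual. First, the ancestor
of the *Saccharomyces* clade underwent a whole-genome duplication (WGD), so
twelve of the twenty species carry every ancestral gene at up to two loci
(A and B); an intron character must therefore be followed along a *locus*
tree, not the species tree. Second, yeast splice signals follow a strict
consensus — GTATGT at the 5' splice site, TACTAAC at the branch point (BP),
a terminal AG — which makes intron presence decidable from sequence alone
and makes the BP-to-3'ss spacing (the S2 distance) a measurable,
species-characteristic quantity.

IntronDollo implements this analysis as a reusable pipeline: classify the
fate of every ancestral intron site from annotated orthologous gene
alignments, map gains and losses onto a WGD-expanded tree by Dollo
parsimony, and produce the downstream summaries (state tallies, per-branch
event counts, S2 summaries, post-WGD snoRNA fates, ribosomal-protein-gene
statistics). A synthetic-data module simulates the whole generative process
and emits every input file, so each stage is verifiable end to end without
external data.

## Site classification

Each cell of the site-by-locus grid is classified from the alignment:

* **present** — the row's intron span contains sequence passing the splice
  grammar. Full validation requires the 5'ss at offset 0 (within a
  configurable mismatch budget, default 0), an exact terminal AG, length in
  [49, 1050] nt, and a qualifying BP. A row passing at least two of the
  three signals is still called present with a "degenerate" note; with
  fewer, the cell is an unknown-state loss. The 49–1050 nt bounds are the
  extremes of annotated *S. cerevisiae* introns.
* **lost_perfect** — the span is empty and the net indel at the junction is
  at most two codons: the signature of cDNA-mediated gene replacement.
* **lost_imperfect(k)** — net indel of 3–40 whole codons.
* **lost_unknown** — frameshifting indel, indel beyond 40 codons, a
  degenerate-signal span, or an unresolvable 5'-UTR site (the `utrPolicy`
  default; UTR introns have no codon frame, so their indels are measured in
  nucleotides and need not be multiples of three).
* **no_data** — the gene is absent from the pillar at that locus, or its
  sequence was excluded from the alignment.

The net indel is measured against the **modal** ungapped exon length among
present rows — not a single reference row — over an adaptive column window:
walking away from the junction, the window grows until the focal row *and*
every present row have accumulated `flankCodons` (default 10) codons of
exon, so insertion and deletion blocks of any size up to the 40-codon
imperfect limit are covered however the alignment places them. Window
growth stops at another annotated intron span, which keeps multi-intron
genes independent. Indels not divisible by three are never rounded into a
codon count; they are recorded as frameshifts with the residual noted and
classified unknown, since silently rounding would fabricate perfect losses.

Intron sliding — relocation of an intron within the gene, known from
*RPS22B* — is detected separately: rows not present at the annotated span
are scanned for a fully valid intron elsewhere, and the report gives the
offset in exon-frame alignment columns (columns of the annotated intron
block do not count, so a +3-codon slide reads as +9) and whether the move
crosses the annotated start codon.

## Dollo parsimony on the WGD-expanded tree

The species tree (the 20-taxon YGOB-style topology ships as a fixture)
carries one tagged WGD node. `expandWgdTree` duplicates the subtended clade
into isomorphic A and B copies attached at that node, and keeps a total map
from every expanded branch back to its simplified-tree branch; the two
copy-root branches fold onto the branch subtending the WGD node. Branches
are identified by the label of their child node, so pruning never
renumbers them.

For each site the expanded tree is pruned to the loci with data; sites with
no present tip cannot anchor a Dollo character and are skipped (logged).
Under Dollo parsimony (at most one gain, irreversible loss) the gain node
is the MRCA of the present tips, and the minimal loss set for that gain is
unique: one loss per maximal all-absent clade strictly inside the gain
clade; under a multifurcation, one loss per absent child subtree. Placing
the gain at the MRCA is always globally minimal — moving it higher adds at
least one absent clade per step — so no tie-breaking is needed for the
fixed-gain assignment. A gain is an *event* only when the gain node is not
the pruned-tree root; otherwise the site was ancestrally present.

`dolloOracle` is a deliberately brute-force reference: it enumerates every
admissible gain placement on trees of up to 14 tips and takes the global
minimum. The test suite sweeps a thousand random trees and presence
patterns against it.

Manual gain curation in the original analysis (a few apparent gains were
re-read as repeated losses) is reproduced by an explicit, configurable
mechanism rather than judgment: an override list of site ids, plus an
optional automatic rule rejecting gains whose clade spans more than a
configurable number of species (off by default). An overridden site is
recomputed with ancestral presence assumed, turning the gain into losses on
the alternative branches. If the automatic rule ever produced equal-cost
alternatives, the assignment with fewer gains and then the
lexicographically smallest branch set would be kept, for determinism.

Event totals are re-projected through the branch map onto the simplified
tree, so each post-WGD branch reports the sum over its A and B locus
branches, alongside per-species terminal totals and the count of sites
lost more than once.

## The synthetic-data generator

The simulator draws, per gene: an RPG flag, the intron count, and post-WGD
locus retention (independent per locus, with one locus forced to survive so
every pillar row has an ancestral survivor). Intron history is then
simulated on the *observable* locus tree — the expanded tree pruned to
retained loci — because losses at loci whose gene never survived are
invisible to any downstream analysis. Each site is present at the root with
probability 0.97 or gained on a uniformly random branch with probability
0.01 (gains never arise inside an already-present lineage, keeping
single-gain Dollo semantics testable); present lineages then lose the
intron per branch with probability 0.05 (multiplied by 0.35 at RPG sites,
reflecting the reduced loss rate of ribosomal protein introns). Each
realized loss event draws a type from the (perfect, imperfect, unknown) =
(0.71, 0.03, 0.26) mixture — the proportions observed among the ~1,200
absences in the real data — with perfect indels uniform on −2..2 codons,
imperfect uniform on 3..40 codons with random sign, and unknown realized
as a frameshifting 4–20 nt insertion. All tips under one loss event share
its indel signature, as a single deletion event would.

Branch-level events of a Dollo process are identifiable only up to Dollo
equivalence: two sibling losses cannot be distinguished from one loss on
the parent branch, and a gain followed by a sister-lineage loss collapses
to a deeper gain. The truth table therefore records both the **raw**
generative events (used for rate-recovery tests) and the **canonical**
minimal representation (sibling losses merged upward, the gain slid to the
MRCA of surviving tips), computed by an event-rewriting routine
independent of the reconstruction code. End-to-end recovery is asserted
against the canonical events; on noise-free emission the pipeline
reproduces them, and the truth states, exactly.

Emission builds alignments that are correct by construction: exon blocks
are shared random codon sequence (5% per-site substitution noise by
default, zero in recovery tests), introns are placed so that 5'ss, BP and
3'ss are column-aligned (spacers left-aligned after the 5'ss, the S2
region right-aligned into the terminal AG), and every loss signature is an
explicit indel block at the junction. Intron lengths are log-normal
(median 120 nt; a longer 420 nt component for RPGs, which reproduces the
bimodal length distribution used downstream); S2 distances are normal per
species (mean 30, sd 6, matching the scale of reported medians) and spacer
sequence is regenerated until the rightmost-BP rule recovers the intended
branch point. Tips outside a gain clade never carried the intron, so their
exon junction is uninterrupted; the truth table records them as perfect
losses with k = 0, which is exactly what any classifier must read off such
an alignment. snoRNA-carrying introns (8 by default, matching the
*S. cerevisiae* intronic snoRNA count) get a fixed 120-nt spacer so the
90-nt snoRNA span fits upstream of the BP; where the host gene was lost
after WGD a snoRNA copy survives intergenically with probability 0.4,
encoding the deintronization fate. Junction read counts are negative
binomial (dispersion 0.3) around a shared log-normal per-site mean scaled
by library size, which induces the positive cross-species correlation the
correlation machinery is tested against; dispersion 0 gives deterministic
counts for the noise-free limit.

What the generator does **not** emulate: realistic substitution models or
codon usage, alignment-construction error (alignments are correct by
construction, so recovery tests validate the classification and mapping
logic, not robustness to misalignment), species-specific gene loss in
pre-WGD lineages, genome-scale sequence context, or the RNAseq reads
themselves. Passing tests therefore demonstrate correctness of the
inference chain under the stated generative model, not performance on
noisy real alignments.

## Numerical and design choices

* **S2 convention.** The operational definition of S2 is the number of
  nucleotides from the end of the BP heptamer to the final intron base,
  terminal AG included: `s2 = length − bpPos − 7`. Published values are
  not tied to an explicit formula (branch adenosine vs. motif end,
  AG inclusive or not are all defensible), so comparisons to reported
  per-species means are qualitative; the convention is monotone in the
  BP→3'ss gap and reproduces the ">30 nt median" scale. The BP search
  takes the **rightmost** qualifying motif, since the yeast BP is
  3'-proximal — this makes S2 well defined when TACTAAC occurs twice.
* **Motif strictness.** Default mismatch budgets are 0 (the signals are a
  strict consensus in these species); both are configurable for divergent
  taxa.
* **Bimodality.** "Some degree of bimodality" in intron length is
  operationalized as a 1- vs 2-component Gaussian mixture comparison on
  log2 length (unequal variances), calling bimodal when the 2-component
  BIC wins by ≥ 10 — a conventional "decisive" BIC margin. The mixture fit
  uses deterministic hierarchical initialization, so verdicts are
  reproducible.
* **Per-locus RPG loss rate.** The rate is defined as loss events divided
  by defined RPG loci (alongside the cell-level absence rate). Published
  per-locus figures are not exactly derivable from printed counts
  (105/(59×20) ≈ 0.089, printed as 0.07), so the definition here is
  documented rather than reconciled.
* **snoRNA fates.** The five post-duplication categories are decided from
  locus-level flags (gene present, intron present, snoRNA copy present)
  with a fixed precedence — deintronized first (any snoRNA surviving
  outside an intact host intron), then both-retained, one-copy-retained,
  snoRNA-in-paralog-intron, removed — which is exhaustive and mutually
  exclusive over all 64 flag combinations (enumerated in the tests).
  snoRNA presence in a paralogous region is taken from annotation flags,
  not sequence search.
* **Coordinates.** Internally 0-based half-open everywhere; GFF3 (1-based
  inclusive) and BED (0-based half-open) are converted only in the io
  functions.
* **Problem sizes.** The verification suite runs 1,000 random Dollo
  instances against the exhaustive oracle, a 300-gene noise-free recovery
  on the 20-taxon tree, a ~2,000-loss mixture recovery on a two-taxon
  tree (terminal losses are independent draws, so the multinomial check is
  exact), and full splice-grammar round trips over every emitted junction
  in four species. These sizes give tight statistical checks (3-SD bands)
  at desk scale.

## Limitations

Reproducing the published headline counts (5,553 sites, 630 losses, eight
gains, ...) requires the original supplementary alignment set; the package
verifies the method, not the data release. Gain curation beyond the
override mechanism, maximum-likelihood rate models, branch-length-aware
reconstruction, GC–AG or U12-type introns, and alignment construction
itself are out of scope.
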