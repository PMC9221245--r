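---
title: "From minigene splicing readouts to point-based clinical classifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From minigene splicing readouts to point-based clinical classifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minigeneACMG)
```

## The problem

Splice-site variants of cancer-susceptibility genes are abundant in clinical
databases, and most of them sit in ClinVar as variants of uncertain
significance. A minigene splicing reporter — gene exons cloned between two
vector exons, transfected into cultured cells — reveals what a variant does
to splicing without patient RNA: every transcript observed comes from the
variant allele. Semi-quantitative fluorescent RT-PCR then resolves the
transcript mixture into peaks whose areas are proportional to transcript
abundance.

Turning such a readout into a clinical call requires a chain of inferences:
name each transcript, work out what it encodes, decide what evidence each
transcript carries, aggregate transcripts weighted by their expression
share, add rarity evidence, and sum everything on the point scale of the
Bayesian ACMG/AMP framework. `minigeneACMG` implements that chain as
testable, reusable parts, with a RAD51C exon 2–8 minigene cohort shipped as
a worked fixture.

## Transcript nomenclature

Aberrant transcripts are written in a compact grammar: `Δ` for skipped
exonic sequence, `▼` for included intronic sequence, `E` plus the exon
number, `p`/`q` for acceptor/donor shifts followed by the shift size in
nucleotides. `Δ(E2p3)` is the use of an alternative acceptor 3 nt into
exon 2; `▼(E6q4)-a` is a 4-nt donor-side intronic inclusion after exon 6,
the `-a` tag distinguishing transcripts with the same splice event but a
different underlying variant base. `parse_label()` and `format_label()`
convert between text and structured events, are inverses on the full
grammar (property-tested), and accept ASCII aliases (`D`, `v`) for shells
where the glyphs are awkward. Donor-shift deletion sizes (`Δ(E2q175)`) are
counted in exonic (spliced) nucleotides; this is the reading consistent
with `Δ(E3q1)` removing exactly one exonic base.

## Consequence model

`apply_isoform()` reconstructs the mature mRNA. Two conventions matter:

* **The variant is applied to the pre-mRNA first.** Bases in excised
  introns vanish; an exonic variant base survives in the full-length
  transcript (the `FL` transcript of an exon-terminal substitution is a
  missense transcript); a variant base inside an included intronic segment
  appears in the inclusion. This is what makes `▼(E6q4)-a` and `-b`
  one-base-different molecules.
* **Native versus minigene context.** Protein-level consequences are
  evaluated on the native full transcript; amplicon sizes add the
  vector-exon/primer flank (181 nt for the shipped layout, giving the
  1062-nt full-length amplicon).

`analyze_consequence()` translates the edited CDS, finds the first in-frame
stop, and calls a premature termination codon whenever that stop precedes
the (event-shifted) native terminator. Frame status is pure mod-3
arithmetic on the net length change and is available without sequences. An
in-frame-by-length inclusion can still be PTC when the included segment
carries a stop codon — the 27-nt donor-side inclusion of exon 2 in the
fixture is the regression case.

**NMD rule.** A PTC ending more than 50 nt upstream of the transcript's own
last exon–exon junction is predicted to trigger nonsense-mediated decay
(the 50-nt boundary rule). The source data cite NMD predictions without
stating a rule; the 50-nt rule is fixed here and validated against the
published 10 NMD / 4 escape split. The junction set is the transcript's
own: skipping the last internal exon moves the last junction, which is
exactly why the late frameshifts escape.

**Domain loss.** An in-frame deletion loses only domains fully contained in
the deleted residue range; a truncating change (frameshift or PTC) loses
every domain whose end lies at or after the first altered residue. The
asymmetry is deliberate: a frameshift garbles everything downstream,
including the rest of a domain it enters, while an in-frame deletion splices
the flanks back together. It is also the only reading consistent with the
fixture's evidence table: the exon-8 frameshift (first altered residue 322)
must count the beta strand that starts at 319 as lost, while the one-residue
delins of the same Arg322 must not count as a domain loss.

## The synthetic reference sequence

The shipped RAD51C fixture reconstructs exon boundaries (exons 2–8:
c.146–404, 405–571, 572–705, 706–837, 838–904, 905–965, 966–1026) from the
assayed variant coordinates. The actual mRNA sequence is not redistributed;
instead `rad51c_synthetic_reference()` builds a deterministic **stand-in**
from T-free filler (no stop codon can arise by accident in any frame) plus
engineered positions encoding every documented sequence-level fact the
pipeline depends on: the 376-codon CDS; the codon identities of Glu49,
Val236/Arg237, Val280, Gly302, Glu303 and Arg322; canonical GT/AG splice
dinucleotides, the cryptic acceptor AG 3 nt inside exon 2, the consensus
GTAAGT donor of intron 6, the TAG acceptor tail of intron 7; and stop
codons placed in the two shifted reading frames exactly where the published
frameshift products end (`p.Gly302Ser/ValFs*47`, `p.Glu303TrpFs*41`,
`p.Arg322SerFs*22`), with additional shifted-frame stops in exons 3–7 so
that early frameshifts terminate long before the last junction. The
constructor asserts these constraints at build time.

A green test on this stand-in therefore establishes that the *engine*
reproduces the published consequence set given a sequence with the
documented properties — not that the stand-in is the real NM_058216.3
sequence. Users with the real reference can attach it via
`transcript_model()`'s `exon_sequences`/`intron_flanks` and rerun
everything unchanged. Exon 1 start, exon 9 end and the CDS end are fixture
parameters flagged `unverified` in the model's provenance attribute, since
they are externally sourced rather than derivable from the assay tables.

## Fragment quantification

`quantify()` mirrors the semi-quantitative fluorescent RT-PCR protocol:
peaks below 200 RFU are discarded — from the denominator as well as the
report, a choice the protocol leaves open and which is flagged here;
surviving peaks are matched to expected amplicon sizes within ±2 nt
(nearest match, ties toward the larger product so that 1-nt-apart species
resolve deterministically); unmatched peaks become `"<size>nt"`
uncharacterized entries; percentages are per-replicate area shares,
averaged across replicates with n−1 SDs (single replicates report SD 0
with a warning). Missing peaks in a replicate count as 0% for that
transcript.

## Evidence and classification

Per-transcript evidence follows the loss-of-function decision-tree
rationale: PTC-NMD transcripts are very strong pathogenic evidence
(`P_VS`); PTC transcripts escaping NMD are strong, upgraded to very strong
when they truncate a critical domain (a rule-table entry, not a gene-specific
hard-code); in-frame transcripts are very strong when they delete a critical
domain, supporting (`P_P`) when an in silico score supports deleteriousness
(PROVEAN ≤ −2.5 or REVEL ≥ 0.7 by default), otherwise no evidence; a
wild-type-identical full-length transcript is strong benign evidence
(`B_S`); a full-length missense transcript is judged by its in silico
score.

`aggregate_readout()` then applies the deconvolution algorithm: if
pathogenic-evidence transcripts contribute ≥ 90% of overall expression the
assay yields a `PVS1_O` code whose strength is the weakest strength among
pathogenic transcripts individually contributing > 10%; `BP7_O` is derived
symmetrically; otherwise the assay is uninformative (0 points).
Thresholds use raw, unrounded fractions (published percentages are rounded
for display only); the share test is `≥ 90`, the contributor test strictly
`> 10`. Uncharacterized transcripts count in the denominator but carry no
evidence. One case the algorithm leaves open — share ≥ 90% with no single
qualifying transcript above 10% — falls back to the weakest strength
present and is flagged `extrapolated`.

`pm2_evidence()` adds supporting-strength rarity evidence at allele
frequency ≤ 0.01% (gnomAD global counts are inputs; proxy-SNP allele-number
substitution for absent variants is the data preparer's responsibility).
`classify_variant()` sums points (supporting/moderate/strong/very strong =
±1/±2/±4/±8) into P ≥ +10, LP +6..+9, VUS 0..+5, LB −6..−1, B ≤ −7,
excluding predictive codes (PVS1/PP3/BP4) whenever an assay code is
present: functional splicing evidence replaces predictions.

```{r verdicts}
verdicts <- rad51c_verdicts()
table(verdicts$category)
head(verdicts[, c("variant_id", "assay_code", "pm2", "total_points", "category")])
```

## Candidate pre-filter

`select_candidates()` reproduces the cohort selection: positions within
±10 intronic or the first 2 / last 3 exonic nucleotides; MaxEntScan score
reduction ≥ 40% (scores are inputs; negative post-variant scores are
allowed and give reductions above 100%); one variant per splice-site
position unless a de novo/cryptic site is predicted (dedup keeps the
most-recorded variant, ties broken by reduction then HGVS order — an
invented, documented tie-break); at least two ClinVar records; no prior
published splicing assay. Every rejection is audited with its first failed
criterion. A note on the source's own inconsistency: its discussion once
says "≤ 40%" where the methods say "at least 40%"; the methods reading is
implemented.

## Synthetic data generator

`simulate_gene()` draws exon lengths from the configured range (defaults
bracket the fixture's 61–259 nt), fills codons from a stop-free pool so the
full-length ORF is clean by construction, and attaches GT/AG flanks.
`simulate_readout()` emulates the triplicate fluorescent assay: true
fractions default to a published-style readout (73.8 / 25.1 / 1.1), peak
areas get multiplicative lognormal noise with CV 0.02 (published SDs are
mostly under 2 percentage points), heights scale with abundance so that
lowering `rfu_baseline` pushes trace transcripts below the 200-RFU cutoff,
and sizes get a ±0.3 nt calling jitter. Ground truth accompanies every
simulated artifact; all randomness flows through the configuration seed and
global RNG state is restored afterwards. The generator does not emulate
electropherogram traces, stutter peaks, heteroduplexes, or size-calling
bias — a green recovery test establishes statistical correctness of the
quantification chain, not instrument realism.

## Numerical choices and limitations

* Readout entry sums are validated to 100 ± 0.2; aggregation tolerates
  fraction sums up to 100.5 before erroring.
* The HGVS `p.` annotator covers substitutions, deletions (3′-shifted),
  delins, insertions and frameshifts (`Fs*N`); without sequences it
  degrades to `p.fs?` rather than guessing.
* Supported DNA variant syntax is the splice-variant subset:
  substitutions, deletions, delins. Duplications/insertions and
  multi-isoform gene models are out of scope, as are genome-to-transcript
  liftover, computation of MES/SpliceAI/PROVEAN/REVEL scores, and
  ribosome-profiling-grade NMD modelling.
* Domain spans in the shipped table are approximate synthetic placements
  consistent with the documented containment statements, not curated
  coordinates; per-variant ClinVar record counts in the fixture are
  synthetic plausible values (each ≥ 2, summing to the published total
  of 65).
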