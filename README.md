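# minigeneACMG

Turn minigene splicing-assay readouts of candidate spliceogenic variants
into ACMG/AMP point-based clinical classifications.

Splice-site variants are a major source of variants of uncertain
significance in cancer-susceptibility genes such as *RAD51C*. A minigene
reporter (gene exons cloned between vector exons, expressed in cultured
cells) reveals each variant's transcript profile without patient RNA, and
semi-quantitative fluorescent RT-PCR resolves the profile into transcript
fractions. This package implements the full downstream analysis:

* **Gene model** — exon architecture in HGVS c. coordinates with intronic
  offsets (`c.404+2`, `c.146-3`), optional sequences, coordinate
  arithmetic (`c_to_exon()`, `exon_to_c()`), JSON serialization, and a
  *RAD51C* NM_058216.3 exon 2–8 fixture whose internal boundaries are
  reconstructed from the assayed variant coordinates.
* **Splice-transcript nomenclature** — parser/serializer for the compact
  grammar `Δ` (exonic deletion), `▼` (intronic inclusion), `E` (exon),
  `p`/`q` (acceptor/donor shift + size in nt): `Δ(E2p3)`, `▼(E6q4)-a`,
  `Δ(E4_5)`, `FL`.
* **Consequence engine** — applies a DNA variant (to the pre-mRNA) plus a
  splice-event set, reconstructs the mature mRNA, and derives frame status,
  premature termination codons, NMD susceptibility (50-nt boundary rule
  against the transcript's own last junction), HGVS p. annotations and
  lost protein domains.
* **Fragment quantification** — capillary-electrophoresis peak tables →
  transcript fractions: ≥ 200 RFU height cutoff, ±2 nt size matching,
  uncharacterized-by-size minor species, replicate mean ± SD.
* **ACMG/AMP engine** — per-transcript evidence (P_VS/P_S/P_P/B_S/N/A)
  following the loss-of-function decision-tree rationale with a
  critical-domain upgrade; readout aggregation into `PVS1_O`/`BP7_O` codes
  (≥ 90% expression-share rule, weakest strength contributing > 10%); PM2
  rarity evidence (allele frequency ≤ 0.01%, supporting); point-sum
  classifier (P ≥ +10, LP +6..+9, VUS 0..+5, LB −6..−1, B ≤ −7) in which
  assay codes replace predictive codes (PVS1/PP3/BP4).
* **Candidate filter** — splice-site windows (±10 intronic, first 2 / last
  3 exonic nt), MaxEntScan reduction ≥ 40% (scores are inputs), per-site
  deduplication with de novo/cryptic-site exemption, ClinVar record and
  prior-report filters, with a full rejection audit.
* **Synthetic data** — seeded generators for gene models (clean ORF,
  GT/AG flanks) and triplicate peak tables with lognormal noise and ground
  truth, so every stage is testable offline.

The shipped reference sequence is a **synthetic stand-in** (the real mRNA
is not redistributed) engineered to satisfy every documented sequence-level
property the pipeline depends on; see the methods vignette
(`vignettes/minigene-classification.Rmd`) for the construction and what a
green test does and does not establish.

## Worked example

Classify the shipped 20-variant *RAD51C* cohort end to end:

```r
library(minigeneACMG)
verdicts <- rad51c_verdicts()
table(verdicts$category)
#>  LP VUS
#>  16   4
subset(verdicts, category == "VUS",
       c(variant_id, assay_code, pm2, total_points))
#>          variant_id       assay_code        pm2 total_points
#> 1  c.146-4_146-2del    PVS1_O_P (+1) PM2_P (+1)            2
#> 4        c.404+3A>G PVS1_O/BP7_O_N/A PM2_P (+1)            1
#> 10       c.705+3A>G PVS1_O/BP7_O_N/A PM2_P (+1)            1
#> 20       c.966-1G>C    PVS1_O_P (+1) PM2_P (+1)            2
```

Sixteen variants reach likely pathogenic (+9: a very-strong assay code +8
plus supporting rarity +1). The four VUS show why deconvolution matters:
`c.146-4_146-2del` and `c.966-1G>C` express > 10% of an in-frame transcript
whose evidence is only supporting, so the aggregated assay code drops to
supporting (+1); `c.404+3A>G` and `c.705+3A>G` retain ~21–26% full-length
transcript, leaving neither the pathogenic nor the benign side at ≥ 90% —
the assay is uninformative (0 points).

One transcript, step by step:

```r
model <- build_rad51c_fixture(sequences = "synthetic")
cons <- analyze_consequence(model, "Δ(E7)", variant = "c.905-2del",
                            domains = rad51c_domains())
cons
#> <consequence> Δ(E7): -61 nt, PTC_escape, p.Glu303TrpFs*41, loses beta6+beta7+beta8+beta9+NLS
```

Skipping the 61-nt exon 7 shifts the frame; the new stop lands in the last
exon, so the transcript escapes NMD (`PTC_escape`), but the frameshift
truncates β-strands 6–9 and the nuclear localization signal — critical
domains — so its evidence is upgraded to very strong.

Quantify a raw peak table:

```r
cfg <- simulation_config(seed = 1)           # triplicates, 2% CV noise
gene <- simulate_gene(cfg)
sim <- simulate_readout(gene, cfg)
quantify(sim$peaks, sim$expected)[["sim"]]
#> <readout> sim (3 replicates)
#>   FL              73.7% ± 0.4%
#>   Δ(E2)          25.2% ± 0.4%
#>   Δ(E3)           1.1% ± 0.0%
```

## Command line

An installed script exposes the pipeline as subcommands:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "minigene_acmg", package = "minigeneACMG"))')
$CLI simulate --seed 4 --out-dir sim/
$CLI peaks --peaks sim/peaks.csv --model sim/model.json --isoforms "FL,D(E2),D(E3)" --out readout.tsv
$CLI annotate --isoform "D(E5)" --variant c.837+1G>T
$CLI classify --model model.json --readouts readouts.tsv --variants variants.tsv --out-dir out/
$CLI filter --variants variants.tsv --out-dir out/
```

Exit codes: 0 success, 1 validation error, 2 internal error. ASCII aliases
(`D`, `v`) are accepted everywhere; `--ascii` writes them on output.

## Data notes

Fixture tables under `inst/extdata/` carry the published readout fractions
and allele counts; per-variant ClinVar record counts and protein-domain
spans are synthetic plausible values (documented in the vignette). gnomAD
proxy-SNP allele-number substitution for absent variants is expected to be
done upstream by the data preparer.
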