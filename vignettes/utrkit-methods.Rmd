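---
title: "utrkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{utrkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrkit)
```

## The problem

Genome-scale 3'UTR clone collections are built by amplifying each gene's
3'UTR from genomic DNA with gene-specific primers carrying Gateway
recombination tails, shuttling the amplicons into entry vectors, screening
colonies by amplicon size, confirming clone identity by Sanger sequencing,
and finally using the clones in dual-luciferase reporter screens to detect
miRNA-mediated repression. utrkit implements the computational side of
that pipeline end to end: locus resolution and primer panel design,
in-silico PCR, clone verification, screen statistics, and library QC.

## Locus anatomy and the anchoring rules

For each gene the cloned insert is the region from the STOP codon of its
longest transcript through the annotated 3' end plus 150 nt of downstream
genomic sequence:

* The forward primer anneals inside the last exon and ends exactly on the
  last base of the STOP codon. Anchoring in coding sequence keeps the
  primer G/C-rich (G/C content drops sharply after the STOP), and the
  cloned insert then starts with the gene's own in-frame termination
  codon, which makes the clones composable with STOP-less ORF
  collections.
* The reverse primer defines the downstream boundary 150 nt beyond the
  annotated transcript end, so 3'-end formation elements downstream of
  the cleavage site are retained, and minor annotation errors or
  alternative cleavage sites near the 3' end are still covered.

"Longest transcript" is interpreted as the transcript whose 3' end is most
distal in the direction of transcription — the rule exists to pick the
downstream boundary, so total exonic length is irrelevant; ties break on
the lexicographically smallest transcript ID for determinism. The STOP
codon must lie entirely within the last exon (genomic PCR needs a
contiguous template through the anchor); genes violating this, or whose
insert would run off the contig, are emitted as design-failure records
with a reason code, never silently dropped.

Coordinates are handled internally as 0-based half-open intervals; GTF and
GFF3 input (1-based closed) is converted on read and BED output is 0-based
half-open. When the annotation has no explicit `stop_codon` feature the
stop is derived from the CDS extent and checked against the genome — the
last three CDS bases (stop-inclusive CDS, the GFF3 convention) or the
three bases immediately downstream (stop-exclusive CDS, the GTF
convention), whichever spells TAA/TAG/TGA on the coding strand.

## Primer design

Primer cores grow 5'-ward from their fixed 3' termini one base at a time,
starting at 18 nt, until the melting temperature reaches the 60 °C target
or the 35 nt cap. A fixed 3' terminus with Tm-driven length is a
deterministic rule that reproduces the same panel on every run; the
historical collections report only the resulting Tm spread (roughly 50-76
°C), which this rule reproduces on synthetic loci. Cores whose Tm falls
outside [50, 76] °C are flagged (`low-Tm`, `high-Tm`, `tm-below-target`)
but kept, because touchdown cycling tolerates a wide Tm range; cores that
would span an ambiguous base (N) are rejected — ambiguity only matters
where the oligo anneals, so N inside the rest of the insert is allowed.

Tm uses nearest-neighbor duplex thermodynamics with the unified
(SantaLucia 1998) parameter set, an entropic monovalent-salt correction
(0.368·(N−1)·ln[Na+]) and a two-state transition at the oligo
concentration, defaulting to 50 mM Na+ and 500 nM oligo — standard PCR
primer conditions. Below 14 nt the Wallace rule 2(A+T) + 4(G+C) is used
instead, where the nearest-neighbor model is unreliable. The test suite
cross-checks the implementation against a second, independently written
parameter summation to ±0.1 °C.

Every forward primer is fused to the 28-nt attB2 tail and every reverse
primer to the 26-nt attB3 tail; the tails are fixed properties of the
Gateway cloning chemistry and take no part in genomic annealing.

The finished panel excludes inserts outside 200-2,500 nt (the published
range of such collections; BP recombination efficiency drops sharply for
longer amplicons), recording them as `length filter` failures. The filter
is applied to the insert length (STOP + 3'UTR + 150) and is configurable
via `design_config()`.

## In-silico PCR

The touchdown schedule enumerates annealing temperatures floor-exclusively:
start 66 °C, −1 °C per cycle, down to but not including the 50 °C floor —
16 touchdown cycles — followed by 15 cycles at 55 °C. The floor-exclusive
convention is deliberate: an inclusive enumeration of 66..50 gives 17
values, which contradicts the protocol's printed 16-cycle count, so the
builder drops the floor value and documents that as the package
convention (`build_touchdown_schedule()` exposes all parameters).

`predict_amplicons()` finds core binding sites on both strands (exact
match by default), pairs convergent sites within a product cap, and
reports each product's first productive cycle — the first cycle whose
annealing temperature both core Tms reach. When mismatches are allowed,
the five bases at a core's 3' terminus must still match exactly:
polymerase extension requires a paired 3' end. The reported product is
the *cloned-insert region* — from the STOP codon (the forward core's
3'-terminal trinucleotide) through the reverse-core boundary — flanked by
the two Gateway tails, so a uniquely binding designed pair always yields
`product_length = insert_length + 54`. The forward core's anchor upstream
of the STOP codon is genomic context that is reported via the binding-site
fields, not counted in the product: it is the insert, not the raw
amplicon, that defines the clone downstream.

Size screening mimics the gel step: relative error |observed −
expected|/expected with a 15% default tolerance, approximating agarose
resolution; the definition is deliberately asymmetric in
expected/observed, as the tests document.

## Clone verification

Sanger-like reads are trimmed of the 5' vector flank (located with up to 2
mismatches; reads starting inside the flank are anchored on its 3'-terminal
20-mer), then aligned against the expected insert panel by a seeded
strategy: an 11-mer index nominates candidate references ranked by shared
seeds on their best diagonal, and the top candidates are re-scored with a
banded affine local alignment (match +1, mismatch −1, gap open −2, gap
extend −1; band half-width 24) implemented in C++. Seed length 11 follows
common tiling-index practice; the band is generous for Sanger error
profiles, where substitutions dominate and indels rarely shift the
diagonal by more than a few bases. On fixture panels the seeded aligner's
best target agrees with exhaustive unbanded local alignment on every
read-reference pair (a test-only oracle).

A clone is `verified` when its best hit is the claimed gene with identity
≥ 0.95, read coverage ≥ 0.90 and a ≥ 10% score margin over the runner-up;
the same thresholds with a different best target mean `misassigned`
(a re-array mix-up), thresholds unmet mean `sequence_fail`, and no
alignment at all means `no_hit`. The thresholds are package conventions
chosen for Sanger error rates (well below 5% per base) and are
configurable. One verified well suffices per gene; all remaining panel
genes go onto the second-pass list with their original primer pairs,
mirroring the two-pass cloning flow.

## Screen statistics

Each well yields a normalized ratio r = firefly/renilla (the test 3'UTR
rides the firefly reporter; renilla is the co-transfection control). The
repression index of a 3'UTR is computed replicate-paired:
RI_i = r(query miRNA, replicate i) / r(control miRNA, replicate i), so
plate-level batch effects shared by a replicate cancel; a pooled-control
mode (`paired = FALSE`) is available. Wells with non-positive renilla are
dropped and the dropped replicates recorded.

Significance uses a two-sided one-sample t-test of log2(RI) against 0 —
the log transform symmetrizes ratio noise, which is multiplicative — with
a Welch two-sample alternative on raw ratios behind a flag. A 3'UTR is a
`repressed_hit` when mean RI < 0.8 and p < 0.05, and `enhanced` when mean
RI > 1.25 (the reciprocal of 0.8, making enhancement symmetric and
testable) with the same alpha. No multiple-testing correction is applied
by default, matching the raw p < 0.05 convention of such screens;
Benjamini-Hochberg is available via `adjust = "BH"`. Positive/negative
miRNA controls are built by inserting the reverse complement of the first
22 nt of the mature 3p arm (respectively 5p arm) into a host SV40-derived
3'UTR.

## Synthetic fixtures: what they emulate and what they do not

All tests run on generated data with known truth:

* `simulate_genome()` packs two-exon genes on both strands of one contig,
  each with a CDS ending in a genuine STOP codon inside the last exon, a
  3'UTR of sampled length and ≥ 150 nt of intergenic runway. Defaults: 3'UTR
  lengths spanning 40-2,900 nt so the 200-2,500 panel filter sees both
  passing and failing inserts; 60-150 nt of coding runway in the last exon
  so primer growth is never artificially truncated. Base composition is
  uniform random.
* `simulate_sanger_reads()` starts each read inside the fixed vector
  flank, plants independent per-base substitutions (default 1%, a
  generous Sanger error rate) and can relabel a fraction of reads to wrong
  wells to emulate re-array mix-ups. The error model is substitution-only
  so the alignment truth stays simple.
* `simulate_screen()` draws multiplicative lognormal noise (CV 10%,
  standard for automated reporter assays) around planted repression
  ratios, with 5 replicates — the screening depth the assay is run at —
  in a replicate-paired layout.

Every generator is a pure function of its parameters and seed and
restores the caller's RNG state. What passing these tests shows is that
the pipeline's logic is correct under its stated error models; real data
adds non-uniform base composition, repeats and paralogy (which can make
primers non-unique and reads ambiguous), chromatogram-quality artifacts,
and biological noise structure that a lognormal CV does not capture. The
fixtures make no attempt to mimic human sequence composition.

## Problem sizes and numerical choices

The shipped test matrix uses 8-100 genes per fixture genome, a
50-reference × 200-read alignment oracle comparison, and 1,000 simulated
3'UTRs for each of the null (type-I) and planted-effect (power) screen
checks; these sizes give stable Monte-Carlo estimates (binomial s.e.
≈ 0.7% at n = 1,000) while keeping the whole suite desk-scale. Acceptance
quantities are recomputed from scratch by `scripts/acceptance.R` at the
same sizes. Ties and degenerate inputs are resolved deterministically
throughout: transcript ties by ID, alignment ties by score then target
ID, the lower-middle median convention, and empty QC bins reported as
undefined (NA) rather than 0%.

## Known limitations

* No off-target/specificity screen of primers against a background
  genome, and no hairpin/dimer thermodynamics beyond Tm.
* No polymerase kinetics: in-silico PCR predicts products and the first
  productive cycle, not yields.
* Reads enter as base sequences; chromatogram (AB1) base-calling and
  quality modelling are out of scope.
* No seed-site prediction for miRNA targets; the screen module measures
  repression, it does not explain it.
* The full published human panel is reproducible only with an external
  human genome and annotation; all shipped checks run on synthetic
  fixtures.
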