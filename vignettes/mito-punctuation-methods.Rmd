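---
title: "Methods: mitogenome annotation and tRNA-punctuation transcript analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome annotation and tRNA-punctuation transcript analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopunct)
```

## The biological model

Animal mitochondrial genomes are transcribed end-to-end from both strands
(heavy, H, and light, L), each strand producing one long polycistronic
primary transcript. The tRNA genes interspersed between the protein-coding
genes (PCGs) and rRNAs fold into cloverleaf structures inside that
transcript and are recognised and excised by the processing machinery, so
cleavage happens essentially *only* at tRNA loci ("tRNA punctuation"). The
mature products therefore carry one gene where tRNAs flank it directly, and
two or three genes where no tRNA intervenes — in the lepidopteran gene
order, the bicistrons nd4/nd4L and nd6/cytb and the tricistron
atp8/atp6/cox3.

Two further quirks of insect mitogenomes matter throughout the package:

* **Non-standard initiators.** Under the invertebrate mitochondrial code
  (AGA/AGG = Ser, AUA = Met, UGA = Trp), genes start not only at ATG but at
  ATT, ATA, TTG, GTG, TTA and — for cox1 — the arginine codon CGA.
  `translate_cds()` renders an annotated initiator as `M` and keeps the raw
  codon in the annotation.
* **Truncated stop codons.** A genomic CDS may end at a bare `T` or `TA` at
  the cleavage boundary; polyadenylation of the mature mRNA completes the
  `TAA` stop. `complete_truncated_stop()` implements the completion, and
  `verify_stop_completion()` tests it against read evidence: reads whose
  alignment *ends* at the truncated terminus and whose 3' soft clip begins
  with the required adenines.

## The punctuation rule

The packaged gene table has several tRNAs that overlap coding sequence by a
few bases (trnL-UUR overlaps cox1 by 5 bp, trnK overlaps cox2 by 3 bp) and
one tRNA, trnT, that lies 27 bp inside the antisense gene nd4L. A naive
"every tRNA cuts everything" rule would sever nd4 from nd4L inside their
1 bp overlap, destroying one of the two reading frames. The default rule in
`punctuate()` is therefore:

* a **same-strand** tRNA always punctuates — it is physically excised from
  that very transcript, so cleavage is obligatory, and a few base pairs of
  terminal overlap with a CDS are treated as annotation slop (cistron spans
  are extended afterwards to cover their member genes, so an overlapped CDS
  terminus stays inside its mature transcript);
* an **antisense** tRNA locus also punctuates, *unless* it overlaps a PCG on
  the strand being processed, where cutting would truncate the coding
  sequence.

Both alternatives (`"sense_only"`, `"all"`) are available for comparison.
On the packaged table the default rule yields eleven sense cistrons: the
ten gene combinations observed as EST contigs, row for row, plus an nd3
monocistron. An nd3 transcript is a structural necessity of the punctuation
model — nd3 sits alone between trnG and trnA, neither of which overlaps
anything — and its absence from the EST contig set is an observation about
transcript abundance or library sampling, not about processing. The package
therefore reports 11 predicted cistrons while the observed contig census is
10; `match_cistrons()` makes the comparison explicit.

Fragments are the maximal intervals not covered by any punctuating tRNA;
fragments containing no same-strand PCG or rRNA (antisense-only regions)
are discarded. Each same-strand gene is assigned to the fragment it
overlaps most (ties to the earlier fragment), which guarantees every gene
lands in exactly one cistron even under adversarial annotations. For this
partial, linear assembly the transcript ends also terminate fragments; a
circular genome would instead be linearised at an arbitrary punctuating
tRNA.

## Codon analytics

`codon_usage()` tallies all codons (stops included) and computes relative
synonymous codon usage, RSCU — a codon's count over its synonymous-family
mean, 1 meaning no bias — under the invertebrate-mitochondrial families
(six leucine codons, eight serine codons including AGA/AGG; TAA/TAG form
their own two-codon family). `at_composition()` reports overall and
per-codon-position A+T fractions with ambiguity codes excluded from both
numerator and denominator, and `position_bias_chi2()` runs the standard
2×2 Pearson test (no continuity correction) for a positional AT-bias
difference.

Two numbers printed alongside the source tables are knowingly not
reproducible and are surfaced rather than patched: the published positional
chi-square values (4.69 and 6.23) cannot be obtained from the printed
proportions by any standard 2×2 construction (the same counts give ≈550),
and the printed UCA count (12) is inconsistent with its own printed RSCU
(2.06) and its family's other values, all of which fit a count of ≈75. The
packaged codon table carries the printed values verbatim plus a
`count_corrected` column; the package's own chi-square is the standard
test.

Similarly, the gene table's printed "length" column disagrees with its own
coordinates on every L-strand row written in transcription orientation (all
short by exactly 2 — the table evidently computed end − start − 1).
`validate_annotation()` reports these as warnings, never errors:
coordinates are authoritative everywhere in the package.

## Read processing and quantification

`filter_reads()` applies the 454-era QC rules: discard reads under 50 nt
and reads in which one nucleotide makes up ≥ 60% of the read.
`map_reads()` is a seed-and-extend mapper: exact 11-mer seeds (non-
overlapping, both strands) vote for a diagonal; the winning diagonal,
widened by 15% of the read length on each side, bounds a local alignment
(match +1, mismatch −1, gap open 2 / extend 1) that plays the role of a
banded extension. A placement is reported only with ≥ 8 matching bases and
a matching fraction ≥ 0.70 (matches over alignment columns, gaps included)
— the scaffolding thresholds for EST-to-mitogenome mapping. The seed
length, window and scoring are this package's choices; they are exposed as
arguments, and the test suite holds the mapper to an exhaustive-placement
oracle on toy genomes. The unaligned 3' read suffix is kept as a soft clip;
`detect_polyA()` calls a tail when the clip's leading run is ≥ 5 bases with
at most one non-A per ten.

Reads are assigned to the same-strand cistron with maximal span overlap;
`expression_table()` then reports, per cistron, the read count, total
aligned nucleotides, mean depth (aligned nt / cistron length — the relative
expression measure appropriate for variable-length transcripts) and the
library proportion. The proportion denominator is an explicit input because
an EST library's total size is a property of the library, not of the
mitochondrial subset; when it is not supplied, proportions are computed
over the mitochondrially assigned reads and the table is flagged
accordingly. Fold differences between cistrons (`fold_differences()`) use
mean depth for pairwise ratios and the proportion column for the global
dynamic range.

## The synthetic study

The simulators exist so every pipeline stage can be scored against known
truth without any external data.

* `generate_genome()` reproduces the real gene geometry exactly (34
  features, 19 tRNAs, the 7 bp and 1 bp overlaps, genes whose coordinate
  length leaves a 1- or 2-base terminal stop). Non-coding regions draw
  bases i.i.d. at the 0.80 A+T target; coding interiors draw codons with
  per-position A+T probabilities proportional to the observed positional
  fractions (0.73 / 0.698 / 0.94) rescaled to preserve the overall target.
  Would-be stop codons are re-coded by swapping the third base within its
  AT/GC class, which removes in-frame stops without touching the positional
  composition. Where a declared stop conflicts with coordinate arithmetic
  (nd5 is annotated TAA but its coordinate length is ≡ 1 mod 3) the
  generator writes the in-frame truncated stop and records the realised
  codon in the truth manifest.
* `generate_transcripts()` emits each predicted cistron span in
  strand-correct orientation, weighting species by the observed contig
  proportions (so the unobserved nd3 cistron has weight 0 and the
  transcriptome has the ten observed species), with poly(A) tails (~20 nt)
  on the two species observed to carry them: the cox2 and atp8/atp6/cox3
  transcripts.
* `simulate_reads()` draws 7,608 reads (the published mitochondrial read
  total) with lengths from a truncated Normal(350, 50) on [50, 600] — an
  invented stand-in, as no read-length distribution was published — and a
  454-like error model: substitution 0.5%, indel 0.5%, homopolymer
  extension 2% per run of three or more. All simulators are deterministic
  given their seed.

What the synthetic study does *not* emulate: flowgram-level 454 error
structure, 3'-end coverage bias, chimeric reads, nuclear mitochondrial
insertions, or contamination by non-mitochondrial cDNA. Passing the
recovery tests therefore demonstrates the pipeline's internal correctness
under a realistic error model, not robustness to every artefact of a real
EST library.

At the default scale the end-to-end experiment (simulate → QC → map →
assign → quantify) recovers the true cistron proportions within three
binomial standard deviations each and with Spearman ρ ≈ 1, verifies the
cox2 truncated stop from tail-bearing reads, and finishes in a few minutes
on one CPU; the per-module tests use smaller problem sizes (toy genomes of
≤ 2 kb, read sets of 50–300) chosen to keep the whole suite quick while
still exercising every code path.

## Numerical and edge-case choices

* Intervals are 1-based inclusive on the forward axis with an explicit
  strand flag; table dialects written in transcription orientation are
  normalised on read.
* Mapper ties are broken by more matching bases, then lower genome
  coordinate, then H before L; gene-to-fragment ties go to the earlier
  fragment; consensus ties fall back to the genome base.
* `rscu()` returns `NA` for families with zero total count; codons
  containing ambiguity characters are excluded from usage counts and
  reported.
* Stop-completion verification tolerates 5 bp between the alignment end and
  the CDS terminus, because an AT-rich genome can absorb the first tail
  adenines into the alignment.
* A zero-length fragment (between adjacent overlapping tRNAs) is dropped
  silently; an annotation with no tRNAs returns the whole strand as one
  cistron with a warning rather than failing.

## Known limitations

* The punctuation rule is a hypothesis that reproduces the observed contig
  set; the mechanism behind the nd1 cistron's 3' boundary (the nearest
  downstream tRNA is antisense) is not independently established, and the
  rRNA termini are taken to be the fragment boundaries rather than
  experimentally mapped ends.
* The mapper is designed for one small circular-or-partial genome (tens of
  kb); the k-mer index and windowed extension would need chunking for
  chromosome-scale references.
* Expression proportions over mitochondrial reads only are not comparable
  across libraries with different non-mitochondrial content; supply the
  library total for cross-library work.
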