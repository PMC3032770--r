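Package: mitopunct
Title: Mitochondrial Genome Annotation and tRNA-Punctuation Transcript Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating AT-rich insect mitochondrial genomes and for
    analysing their transcription under the tRNA punctuation model. Reads and
    validates gene feature tables (lepidopteran gene order, overlapping genes,
    truncated stop codons), computes codon usage and relative synonymous codon
    usage (RSCU) under the invertebrate mitochondrial genetic code, predicts
    mature (poly)cistronic transcripts by cleaving each strand's primary
    transcript at tRNA loci, maps EST-style reads to the genome with a
    seed-and-extend aligner, detects poly(A) tails in soft-clipped read ends,
    verifies polyadenylation-completed TAA stop codons, and quantifies
    per-cistron expression (read counts, aligned nucleotides, mean depth,
    proportions). Includes simulators for genomes, mature transcripts and
    454-style reads with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    rtracklayer,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
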