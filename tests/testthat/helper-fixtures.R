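# Shared helpers: tiny genomes and annotations built in code.

random_dna <- function(n, at = 0.8, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# a single PCG flanked by two tRNAs, with configurable geometry
toy_flanked_annotation <- function(gene_strand = "H") {
  mito_annotation(data.frame(
    name = c("trnX", "gene1", "trnZ"),
    ftype = c("tRNA", "PCG", "tRNA"),
    strand = c("H", gene_strand, "H"),
    start = c(11L, 101L, 501L),
    end = c(75L, 480L, 565L),
    stringsAsFactors = FALSE), genome_id = "toy")
}

maruca_ann <- function() read_gene_table_fixture()

# H-strand gene lists the punctuation model predicts for the packaged table
expected_h_cistrons <- list(
  "nd2", "cox1", "cox2", c("atp8", "atp6", "cox3"), "nd3", c("nd6", "cytb"))
expected_l_cistrons <- list(
  "nd5", c("nd4l", "nd4"), "nd1", "rrnl", "rrns")

# build a toy coxII-like locus: PCG ending in a bare T, abutting (not
# overlapping) a downstream tRNA, for stop-completion experiments.
# Returns genome, annotation and the polyadenylated transcript.
toy_truncated_stop_world <- function(seed = 11L, tail_len = 20L) {
  withr::local_seed(seed)
  lead_trna <- random_dna(65)
  # CDS: ATG + 120 non-stop codons + bare T  (length 364, mod 3 == 1)
  interior <- replicate(120, {
    repeat {
      c3 <- paste(sample(c("A", "T", "C", "G"), 3, replace = TRUE,
                         prob = c(.4, .4, .1, .1)), collapse = "")
      if (!c3 %in% c("TAA", "TAG")) break
    }
    c3
  })
  cds <- paste0("ATG", paste(interior, collapse = ""), "T")
  trail_trna <- random_dna(68)
  pad <- random_dna(30)
  genome <- mito_genome("toy_cox2", paste0(pad, lead_trna, cds, trail_trna, pad))
  cds_start <- nchar(pad) + 65L + 1L
  cds_end <- cds_start + nchar(cds) - 1L
  ann <- mito_annotation(data.frame(
    name = c("trnU", "cox2like", "trnV2"),
    ftype = c("tRNA", "PCG", "tRNA"),
    strand = "H",
    start = c(nchar(pad) + 1L, cds_start, cds_end + 1L),
    end = c(nchar(pad) + 65L, cds_end, cds_end + 68L),
    stop_codon = c(NA, "T", NA),
    stringsAsFactors = FALSE), genome_id = "toy_cox2")
  transcript <- paste0(substring(genome$seq, cds_start, cds_end),
                       strrep("A", tail_len))
  list(genome = genome, annotation = ann, cds = cds,
       cds_start = cds_start, cds_end = cds_end, transcript = transcript)
}
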