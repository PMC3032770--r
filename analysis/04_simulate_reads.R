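#!/usr/bin/env Rscript
# Generate the synthetic study: a mitogenome with the real gene geometry and
# AT-rich composition, the ten mature transcript species at the observed
# contig proportions, and a 7,608-read 454-style library with known truth.

suppressMessages(library(mitopunct))
dir.create("results", showWarnings = FALSE)

seed <- 1L
gs <- genome_spec_maruca(seed = seed)
gen <- generate_genome(gs)
cis <- predict_cistrons(gen$annotation)
tsp <- transcriptome_spec(seed = seed)   # n_reads = 7608, default error model
tx <- generate_transcripts(gen$genome, gen$annotation, tsp, cistrons = cis)
sim <- simulate_reads(tx, tsp)

write_genome_fasta(gen$genome, "results/synthetic_genome.fa")
write_feature_table(gen$annotation, "results/synthetic_annotation.tsv")
write_reads_fastq(sim$reads, "results/synthetic_reads.fastq")
write.table(tx$truth, "results/transcript_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth, "results/read_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("genome: ", gen$genome$length, " bp, A+T = ",
        round(at_composition(gen$genome$seq)$at_fraction, 3))
message(length(tx$transcripts), " transcript species; poly(A) on: ",
        paste(tx$truth$cistron_id[tx$truth$polyA_len > 0], collapse = ", "))
message(length(sim$reads), " reads simulated (", sim$n_resampled,
        " length resamples); wrote results/synthetic_* and *_truth.tsv")
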