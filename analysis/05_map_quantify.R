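#!/usr/bin/env Rscript
# QC-filter, map and quantify the simulated read library against the
# synthetic genome, then score recovery against the simulation truth.

suppressMessages(library(mitopunct))
stopifnot(file.exists("results/synthetic_reads.fastq"))  # run 04 first

genome <- read_genome_fasta("results/synthetic_genome.fa")
ann <- read_annotation_table("results/synthetic_annotation.tsv", "gene_table_tsv")
cis <- predict_cistrons(ann)
reads <- read_reads_fastq("results/synthetic_reads.fastq")
truth <- read.delim("results/transcript_truth.tsv")

qc <- filter_reads(reads)
message(length(qc$kept), " reads kept, ", nrow(qc$rejected), " rejected (",
        paste(names(table(qc$rejected$reason)),
              table(qc$rejected$reason), collapse = ", "), ")")

mp <- map_reads(qc$kept, genome)
message(nrow(mp$alignments), " mapped, ", nrow(mp$unmapped), " unmapped")

asg <- assign_to_cistron(detect_polyA(mp$alignments), cis)
expr <- expression_table(asg, cis)
write_expression_tsv(expr, "results/expression.tsv")
write_sam(mp$alignments, qc$kept, genome, "results/alignments.sam")

w <- stats::setNames(truth$weight, truth$cistron_id)
w <- w / sum(w)
est <- stats::setNames(expr$proportion, expr$cistron_id)[names(w)]
message(sprintf("proportion recovery: Spearman rho = %.3f, max |err| = %.4f",
                cor(est, w, method = "spearman"), max(abs(est - w))))

v <- verify_stop_completion(ann, asg, genome, cis)
message("stop-codon verification:")
print(v)
write.table(v, "results/stop_verification.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/expression.tsv, alignments.sam, stop_verification.tsv")
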