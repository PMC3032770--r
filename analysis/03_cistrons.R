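#!/usr/bin/env Rscript
# Predict mature transcripts by tRNA-punctuation cleavage of both strand
# transcripts, and compare them with the observed EST contigs.

suppressMessages(library(mitopunct))
dir.create("results", showWarnings = FALSE)

ann <- read_gene_table_fixture()
cis <- predict_cistrons(ann)
mg <- multigene_cistrons(cis)
prof <- read_expression_fixture()
m <- match_cistrons(cis, prof)

message(nrow(cis), " predicted sense cistrons (", nrow(mg), " multi-gene: ",
        paste(mg$genes, collapse = "; "), ")")
message(sum(!is.na(m$cistron_id)),
        " of them match an observed EST contig row-for-row")
unmatched <- cis$genes[is.na(m$cistron_id)]
if (length(unmatched))
  message("predicted but not observed in the EST library: ",
          paste(unmatched, collapse = ", "))

chk <- overlap_implies_cocistronic_check(ann, cis)
message("overlapping same-strand gene pairs co-cistronic: ",
        all(chk$cocistronic))

write_cistron_tsv(cbind(as.data.frame(cis), observed = m$cistron_id),
                  "results/cistrons.tsv")
write_cistron_bed(cis, "results/cistrons.bed")
message("wrote results/cistrons.{tsv,bed}")
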