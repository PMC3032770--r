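#!/usr/bin/env Rscript
# Headline report: the published expression profile's summary numbers
# (recomputed from the packaged contig table) next to the synthetic run's,
# plus a machine-readable JSON summary.

suppressMessages(library(mitopunct))
dir.create("results", showWarnings = FALSE)

prof <- read_expression_fixture()
pub <- expression_report(prof)
message(sprintf("published profile: %d cistrons, %d multi-gene", pub$n_cistrons,
                pub$n_multigene))
message(sprintf("  total reads %d; nd1/nd2 depth fold %.2f; cox2/cox3 %.2f; ",
                sum(prof$read_no), pub$fold_nd1_nd2, pub$fold_cox2_cox3),
        sprintf("proportion range %.0f-fold", pub$proportion_range))
message(sprintf("  contig length %.1f +/- %.1f bp", mean(prof$contig_length),
                sd(prof$contig_length)))

summary <- list(
  published = list(
    n_cistrons = pub$n_cistrons, n_multigene = pub$n_multigene,
    total_reads = sum(prof$read_no),
    fold_nd1_nd2 = round(pub$fold_nd1_nd2, 2),
    fold_cox2_cox3 = round(pub$fold_cox2_cox3, 2),
    proportion_range = round(pub$proportion_range, 1),
    contig_length_mean = round(mean(prof$contig_length), 1),
    contig_length_sd = round(sd(prof$contig_length), 1)))

if (file.exists("results/expression.tsv")) {
  expr <- read.delim("results/expression.tsv")
  syn <- expression_report(expr)
  message(sprintf("synthetic run: nd1/nd2 fold %.2f; cox2/cox3 fold %.2f; %d poly(A) reads",
                  syn$fold_nd1_nd2, syn$fold_cox2_cox3,
                  sum(expr$polyA_read_count)))
  summary$synthetic <- list(
    fold_nd1_nd2 = round(syn$fold_nd1_nd2, 2),
    fold_cox2_cox3 = round(syn$fold_cox2_cox3, 2),
    proportion_range = round(syn$proportion_range, 1),
    polyA_reads = sum(expr$polyA_read_count))
}

jsonlite::write_json(summary, "results/report.json", auto_unbox = TRUE,
                     digits = NA)
message("wrote results/report.json")
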