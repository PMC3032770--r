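#' Annotation census and QC report
#'
#' Feature counts by class, coordinate-derived length table, all pairwise
#' gene overlaps, intergenic gaps between consecutive features, start/stop
#' codon classification of the protein-coding genes (flagging truncated
#' stops and non-ATG initiators), and the [validate_annotation()] report.
#'
#' @param a A `mito_annotation`.
#' @param genome Optional `mito_genome` for bound checks.
#' @return A list of class `annotation_qc` with components `counts`,
#'   `lengths`, `overlaps`, `gaps`, `codons`, `validation`.
#' @export
annotate_qc <- function(a, genome = NULL) {
  f <- a$features
  counts <- table(factor(f$ftype, ftype_levels))
  lens <- data.frame(name = f$name, ftype = f$ftype, strand = f$strand,
                     length = feature_length(f), stringsAsFactors = FALSE)
  ov <- annotation_overlaps(a, ftypes = c("PCG", "tRNA", "rRNA"))
  fs <- f[order(f$start), ]
  gaps <- data.frame(
    upstream = head(fs$name, -1L), downstream = tail(fs$name, -1L),
    gap_bp = tail(fs$start, -1L) - head(fs$end, -1L) - 1L,
    stringsAsFactors = FALSE)
  pcg <- f[f$ftype == "PCG", , drop = FALSE]
  code <- invertebrate_mito_code()
  codons <- data.frame(
    name = pcg$name,
    start_codon = pcg$start_codon,
    stop_codon = pcg$stop_codon,
    atypical_start = !is.na(pcg$start_codon) & pcg$start_codon != "ATG",
    truncated_stop = !is.na(pcg$stop_codon) & pcg$stop_codon %in% c("T", "TA"),
    valid_start = is.na(pcg$start_codon) |
      pcg$start_codon %in% code$start_codons,
    stringsAsFactors = FALSE)
  structure(list(counts = counts, lengths = lens, overlaps = ov, gaps = gaps,
                 codons = codons, validation = validate_annotation(a, genome)),
            class = "annotation_qc")
}

#' @export
print.annotation_qc <- function(x, ...) {
  cat("<annotation_qc>\n")
  print(x$counts)
  cat("overlapping features:\n"); print(x$overlaps)
  cat(sprintf("validation: %d violation(s), %d warning(s)\n",
              sum(x$validation$level == "violation"),
              sum(x$validation$level == "warning")))
  invisible(x)
}

#' Run the full synthetic pipeline end to end
#'
#' Generates the default synthetic mitogenome (real lepidopteran gene
#' geometry, AT-rich composition), predicts cistrons, simulates the mature
#' transcriptome and a 454-style read library at the packaged expression
#' profile's abundances, QC-filters and maps the reads, assigns them to
#' cistrons and quantifies expression. This is the package's ground-truth
#' recovery experiment: every downstream number can be compared against the
#' simulation truth.
#'
#' @param seed Integer seed driving genome generation and read simulation.
#' @param n_reads Library size (default 7608).
#' @param error_rates Passed to [transcriptome_spec()].
#' @param min_match_bases,min_match_pct Mapping thresholds (defaults 8 and
#'   0.70).
#' @return List with `genome`, `annotation`, `cistrons`, `transcripts`,
#'   `sim` (reads + truth), `qc`, `alignments`, `unmapped`, `assigned`,
#'   `expression`, `truth_proportions` (named numeric, normalised simulation
#'   weights).
#' @export
run_synthetic_pipeline <- function(seed = 1L, n_reads = 7608L,
                                   error_rates = c(substitution = 0.005,
                                                   insertion = 0.0025,
                                                   deletion = 0.0025,
                                                   homopolymer_extension = 0.02),
                                   min_match_bases = 8L, min_match_pct = 0.70) {
  gs <- genome_spec_maruca(seed = seed)
  gen <- generate_genome(gs)
  cis <- predict_cistrons(gen$annotation)
  tspec <- transcriptome_spec(n_reads = n_reads, error_rates = error_rates,
                              seed = seed)
  tx <- generate_transcripts(gen$genome, gen$annotation, tspec,
                             cistrons = cis)
  sim <- simulate_reads(tx, tspec)
  qc <- filter_reads(sim$reads)
  mp <- map_reads(qc$kept, gen$genome,
                  min_match_bases = min_match_bases,
                  min_match_pct = min_match_pct)
  aln <- detect_polyA(mp$alignments)
  asg <- assign_to_cistron(aln, cis)
  expr <- expression_table(asg, cis)
  w <- stats::setNames(tx$truth$weight, tx$truth$cistron_id)
  list(genome = gen$genome, annotation = gen$annotation, cistrons = cis,
       transcripts = tx, sim = sim, qc = qc, alignments = aln,
       unmapped = mp$unmapped, assigned = asg, expression = expr,
       truth_proportions = w / sum(w))
}

#' Summary report of a pipeline run or of the packaged expression profile
#'
#' Collects the headline numbers: cistron census (total, multi-gene), the
#' expression table, intra-complex mean-depth fold differences (NADH
#' dehydrogenase: nd1-vs-nd2 cistrons; cytochrome c oxidase: cox2-vs-cox3
#' carriers) and the overall proportion dynamic range, and the poly(A)
#' summary when alignments are available.
#'
#' @param expr An expression table with `cistron_id`, `genes`, `mean_depth`
#'   and a proportion column ([expression_table()] output or
#'   [read_expression_fixture()]).
#' @param cistrons Optional `cistron_set` for the census (defaults to the
#'   rows of `expr`).
#' @return List of class `mito_report`: `n_cistrons`, `n_multigene`,
#'   `expression`, `fold_nd1_nd2`, `fold_cox2_cox3`, `proportion_range`.
#' @export
expression_report <- function(expr, cistrons = NULL) {
  find_carrier <- function(gene) {
    hit <- vapply(strsplit(expr$genes, ","), function(g)
      gene %in% normalize_gene_name(g), logical(1))
    if (!any(hit)) return(NA_character_)
    expr$cistron_id[which(hit)[1]]
  }
  fd <- function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    fold_differences(expr, list(c(a, b)))$pair_ratios$fold
  }
  n_multi <- sum(vapply(strsplit(expr$genes, ","), length, integer(1)) >= 2L)
  if (!is.null(cistrons)) {
    n_cis <- nrow(cistrons); n_multi <- nrow(multigene_cistrons(cistrons))
  } else n_cis <- nrow(expr)
  structure(list(
    n_cistrons = n_cis, n_multigene = n_multi, expression = expr,
    fold_nd1_nd2 = fd(find_carrier("nd1"), find_carrier("nd2")),
    fold_cox2_cox3 = fd(find_carrier("cox2"), find_carrier("cox3")),
    proportion_range = fold_differences(expr)$proportion_range),
    class = "mito_report")
}

#' @export
print.mito_report <- function(x, ...) {
  cat(sprintf(paste0("<mito_report> %d cistrons (%d multi-gene); ",
                     "nd1/nd2 depth fold %.2f; cox2/cox3 depth fold %.2f; ",
                     "proportion range %.0f-fold\n"),
              x$n_cistrons, x$n_multigene, x$fold_nd1_nd2, x$fold_cox2_cox3,
              x$proportion_range))
  invisible(x)
}
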