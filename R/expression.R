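#' Per-cistron expression quantification
#'
#' Tallies, for every cistron, the number of assigned reads, the total
#' aligned nucleotides, the mean depth (total aligned nt divided by cistron
#' length -- the relative expression measure used for EST scaffold data) and
#' the proportion of the library the cistron's reads represent. When the
#' library total is unknown the proportion is computed over the
#' mitochondrially assigned reads only, and the table is flagged accordingly.
#'
#' @param assignments A `read_alignments` table with a `cistron_id` column
#'   ([assign_to_cistron()]); a `polyA_len` column, if present, feeds
#'   `polyA_read_count`.
#' @param cistrons The `cistron_set` quantified against.
#' @param library_total_reads Optional library size for the proportion
#'   denominator.
#' @return A `cistron_expression` data.frame: `cistron_id`, `genes`,
#'   `length`, `read_count`, `total_nt`, `mean_depth`, `proportion`,
#'   `polyA_read_count`; attribute `proportion_denominator` records the
#'   denominator used.
#' @export
expression_table <- function(assignments, cistrons,
                             library_total_reads = NULL) {
  len <- cistrons$end - cistrons$start + 1L
  if (any(len <= 0L)) stop("zero-length cistron in cistron set")
  assigned <- assignments[!is.na(assignments$cistron_id), , drop = FALSE]
  denom <- library_total_reads %||% nrow(assigned)
  rows <- lapply(seq_len(nrow(cistrons)), function(i) {
    sub <- assigned[assigned$cistron_id == cistrons$id[i], , drop = FALSE]
    total_nt <- sum(sub$aligned_bases)
    data.frame(
      cistron_id = cistrons$id[i], genes = cistrons$genes[i],
      length = len[i], read_count = nrow(sub), total_nt = total_nt,
      mean_depth = total_nt / len[i],
      proportion = if (denom > 0) nrow(sub) / denom else 0,
      polyA_read_count = if ("polyA_len" %in% names(sub))
        sum(sub$polyA_len > 0L) else NA_integer_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out,
            proportion_denominator = if (is.null(library_total_reads))
              "mitochondrial_assigned_reads" else "library_total",
            n_assigned = nrow(assigned),
            class = c("cistron_expression", "data.frame"))
}

#' Fold differences between cistron expression levels
#'
#' For each requested cistron pair, the ratio of the larger to the smaller
#' mean depth; plus the global max/min ratio of the proportion column (the
#' overall dynamic range of cistron levels).
#'
#' @param expr A `cistron_expression` table, or any data.frame with
#'   `cistron_id`, `mean_depth` and a proportion column (`proportion` or
#'   `proportion_pct`), e.g. [read_expression_fixture()].
#' @param pairs List of length-2 character vectors of cistron ids.
#' @return List with `pair_ratios` (data.frame `a`, `b`, `fold`) and
#'   `proportion_range` (max/min proportion ratio).
#' @export
fold_differences <- function(expr, pairs = list()) {
  prop <- expr[["proportion"]] %||% expr[["proportion_pct"]]
  ratio <- function(a, b) {
    da <- expr$mean_depth[expr$cistron_id == a]
    db <- expr$mean_depth[expr$cistron_id == b]
    if (!length(da) || !length(db)) stop("unknown cistron id in pair ", a, "/", b)
    if (da == 0 || db == 0) stop("undefined ratio: zero mean depth for ",
                                 if (da == 0) a else b)
    max(da, db) / min(da, db)
  }
  pr <- if (length(pairs)) data.frame(
    a = vapply(pairs, `[`, character(1), 1L),
    b = vapply(pairs, `[`, character(1), 2L),
    fold = vapply(pairs, function(p) ratio(p[1], p[2]), numeric(1)),
    stringsAsFactors = FALSE)
  else data.frame(a = character(), b = character(), fold = numeric(),
                  stringsAsFactors = FALSE)
  pos <- prop[prop > 0]
  list(pair_ratios = pr,
       proportion_range = if (length(pos)) max(pos) / min(pos) else NA_real_)
}

#' Verify polyadenylation-completed stop codons from mapped reads
#'
#' For every protein-coding gene annotated with a truncated genomic stop
#' (`T` or `TA`), looks for assigned reads whose alignment covers the CDS 3'
#' terminus and carries a poly(A) soft clip, and checks that the genomic CDS
#' plus the observed tail completes a TAA stop in frame. Genes whose genomic
#' copy already ends in a full stop are confirmed without tail evidence.
#'
#' @param annotation A `mito_annotation`.
#' @param assignments A `read_alignments` table (clips are consulted
#'   directly; reads whose 3' soft clip covers the truncated terminus act as
#'   the tail evidence).
#' @param genome The `mito_genome`.
#' @param cistrons The `cistron_set` (restricts which genes are examined to
#'   those on retained cistrons; pass `NULL` to examine all PCGs).
#' @param min_tail Minimum poly(A) clip length counted as a tail (default 5).
#' @param end_slack Tolerance (bp) between the alignment 3' end and the CDS
#'   terminus (default 5; AT-rich genomic context can absorb the first tail
#'   bases into the alignment).
#' @return data.frame per examined PCG: `gene`, `stop_codon`, `status`
#'   (`"confirmed"`, `"unconfirmed"`, `"inconclusive"`), `n_support`
#'   (reads covering the terminus with a poly(A) clip).
#' @export
verify_stop_completion <- function(annotation, assignments, genome,
                                   cistrons = NULL, min_tail = 5L,
                                   end_slack = 5L) {
  f <- annotation$features[annotation$features$ftype == "PCG", , drop = FALSE]
  if (!is.null(cistrons)) {
    on_cistron <- unique(unlist(cistron_genes(cistrons)))
    f <- f[f$name %in% on_cistron, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(f)), function(i) {
    gene <- f[i, ]
    cds <- gene_sequence(genome, gene)
    n <- nchar(cds); r <- n %% 3L
    genomic_stop <- if (r == 0L) substring(cds, n - 2L, n) else
      substring(cds, n - r + 1L, n)
    if (r == 0L && genomic_stop %in% c("TAA", "TAG"))
      return(data.frame(gene = gene$name, stop_codon = genomic_stop,
                        status = "confirmed", n_support = NA_integer_,
                        stringsAsFactors = FALSE))
    # tail evidence: reads whose alignment covers the terminus AND ends at it
    # (within `end_slack` bp -- a poly(A) tail may be partially absorbed by an
    # AT-rich genome); a read aligning straight through the terminus shows the
    # transcript was not 3'-cleaved there
    terminus <- if (gene$strand == "H") gene$end else gene$start
    aln_3p_end <- ifelse(assignments$strand == "H",
                         assignments$g_end, assignments$g_start)
    ends_at <- if (gene$strand == "H")
      aln_3p_end >= terminus & aln_3p_end - terminus <= end_slack
    else aln_3p_end <= terminus & terminus - aln_3p_end <= end_slack
    cover <- assignments$strand == gene$strand & ends_at &
      assignments$g_start <= terminus & assignments$g_end >= terminus &
      nchar(assignments$clip3) >= min_tail
    sup <- assignments[cover, , drop = FALSE]
    if (!nrow(sup))
      return(data.frame(gene = gene$name, stop_codon = genomic_stop,
                        status = "inconclusive", n_support = 0L,
                        stringsAsFactors = FALSE))
    # a read's 3' clip is the observed transcript tail: completion holds if
    # its leading bases supply the A's the truncated stop needs
    ok <- vapply(seq_len(nrow(sup)), function(j) {
      complete_truncated_stop(cds, sup$clip3[j])$status %in%
        c("complete", "completed")
    }, logical(1))
    data.frame(gene = gene$name, stop_codon = genomic_stop,
               status = if (any(ok)) "confirmed" else "unconfirmed",
               n_support = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract a gene's coding-strand sequence from the genome
#'
#' @param genome A `mito_genome`.
#' @param feature One feature row (`start`, `end`, `strand`).
#' @return DNA string in transcription orientation (reverse complement for
#'   L-strand features).
#' @export
gene_sequence <- function(genome, feature) {
  s <- substring(genome$seq, feature$start, min(feature$end, genome$length))
  if (feature$strand == "L") revcomp_chr(s) else s
}

#' Majority-vote consensus over a cistron span
#'
#' Per-position majority vote over the aligned read bases of a cistron's
#' assigned reads (alignment columns where the genome base is a gap, i.e.
#' read insertions, do not vote). Positions with zero coverage are emitted as
#' the genome base in lowercase; voting ties fall back to the genome base.
#'
#' @param assignments `read_alignments` with `cistron_id`.
#' @param genome The `mito_genome`.
#' @param cistron One row of a `cistron_set`.
#' @return Consensus sequence (forward-genome orientation) over
#'   `[cistron$start, cistron$end]`.
#' @export
build_consensus <- function(assignments, genome, cistron) {
  span <- cistron$start:cistron$end
  n <- length(span)
  votes <- matrix(0L, nrow = 4L, ncol = n,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  sub <- assignments[!is.na(assignments$cistron_id) &
                       assignments$cistron_id == cistron$id, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    p <- strsplit(sub$pattern_aln[i], "")[[1]]
    s <- strsplit(sub$subject_aln[i], "")[[1]]
    gpos <- sub$g_start[i] + cumsum(s != "-") - 1L
    keep <- s != "-" & p %in% c("A", "C", "G", "T") &
      gpos >= cistron$start & gpos <= cistron$end
    if (!any(keep)) next
    col <- gpos[keep] - cistron$start + 1L
    base <- p[keep]
    for (b in c("A", "C", "G", "T")) {
      hit <- col[base == b]
      if (length(hit)) {
        tab <- tabulate(hit, nbins = n)
        votes[b, ] <- votes[b, ] + tab
      }
    }
  }
  gbase <- strsplit(substring(genome$seq, cistron$start, cistron$end),
                    "")[[1]]
  cov <- colSums(votes)
  out <- tolower(gbase)
  has <- which(cov > 0L)
  if (length(has)) {
    top <- apply(votes[, has, drop = FALSE], 2L, function(v) {
      w <- which(v == max(v))
      if (length(w) == 1L) rownames(votes)[w] else NA_character_
    })
    gb <- gbase[has]
    out[has] <- ifelse(is.na(top), gb, top)
    # ties fall back to the genome base when it is among the leaders
    tie <- is.na(top)
    if (any(tie)) {
      for (k in which(tie)) {
        v <- votes[, has[k]]
        leaders <- rownames(votes)[v == max(v)]
        out[has[k]] <- if (gb[k] %in% leaders) gb[k] else leaders[1]
      }
    }
  }
  paste(out, collapse = "")
}

#' Write a cistron expression table as TSV
#'
#' @param expr A `cistron_expression` table.
#' @param path Output file.
#' @export
write_expression_tsv <- function(expr, path) {
  write.table(as.data.frame(expr), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
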