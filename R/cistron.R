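#' Predict mature cistrons by tRNA-punctuation cleavage
#'
#' Both strands of a mitochondrial genome are transcribed end-to-end; the
#' primary polycistronic transcript is then cleaved at the cloverleaf-folding
#' tRNA sequences that intersperse the genes, releasing mature transcripts
#' that carry one or more protein-coding genes or rRNAs (mono-, bi-,
#' tricistronic). `punctuate()` applies that model to one strand of an
#' annotation: the strand's transcript (the whole genome in that strand's
#' transcription orientation) is cut at every punctuating tRNA locus, and the
#' fragments between punctuating loci are emitted. Fragments containing no
#' same-strand PCG or rRNA (antisense-only regions) are discarded.
#'
#' Which tRNA loci punctuate is controlled by `rule`:
#' \describe{
#'   \item{`"antisense_overlap_exempt"` (default)}{A same-strand tRNA always
#'     punctuates -- its excision from that very transcript necessarily cleaves
#'     it. An antisense tRNA locus is assumed cleavable too, *unless* it
#'     overlaps a PCG on the strand being processed: cutting there would
#'     destroy the coding sequence (the trnT locus sits 27 bp inside nd4L on
#'     the opposite strand, and the nd4/nd4L bicistron shows the L transcript
#'     is not cut there). This is the rule that reproduces the observed
#'     lepidopteran cistron set, including the atp8/atp6/cox3 tricistron and
#'     the nd6/cytb and nd4/nd4L bicistrons.}
#'   \item{`"sense_only"`}{Only same-strand tRNAs punctuate.}
#'   \item{`"all"`}{Every tRNA locus punctuates both strands.}
#' }
#'
#' Small terminal overlaps between a tRNA and an adjacent same-strand CDS
#' (annotation slop of a few bp) do not protect the CDS: cistron spans are
#' extended to cover their genes, so an overlapped CDS end stays inside its
#' cistron even when the cleavage fragment stops short of it.
#'
#' @param a A [mito_annotation()]; must contain at least one tRNA (if none, the
#'   whole strand is returned as a single cistron with a warning).
#' @param strand `"H"` or `"L"`.
#' @param rule Punctuation rule, see Details.
#' @param genome_length Length of the primary transcript; defaults to the
#'   maximum annotated end coordinate.
#' @return A `cistron_set`: data.frame with columns `id` (`Mt<strand>_<nn>`,
#'   numbered in ascending genome coordinate), `strand`, `start`, `end`
#'   (genomic span, covering all member genes), `genes` (comma-separated, in
#'   transcription order: descending coordinate for L), `arity` (number of
#'   PCGs + rRNAs). Attributes `fragments` (the exact cleavage partition,
#'   including discarded fragments), `punctuators` (the tRNA loci used) and
#'   `rule` document the cleavage.
#' @examples
#' ann <- read_gene_table_fixture()
#' punctuate(ann, "H")$genes
#' @export
punctuate <- function(a, strand = c("H", "L"),
                      rule = c("antisense_overlap_exempt", "sense_only", "all"),
                      genome_length = NULL) {
  strand <- match.arg(strand)
  rule <- match.arg(rule)
  f <- a$features[order(a$features$start, a$features$end), , drop = FALSE]
  L <- as.integer(genome_length %||% max(f$end))
  trna <- f[f$ftype == "tRNA", , drop = FALSE]
  genes <- f[f$ftype %in% c("PCG", "rRNA") & f$strand == strand, , drop = FALSE]

  empty_set <- function(df, punct, frags) {
    structure(df, fragments = frags, punctuators = punct, rule = rule,
              strand = strand, genome_length = L,
              class = c("cistron_set", "data.frame"))
  }

  if (nrow(trna) == 0L) {
    warning("annotation contains no tRNA: returning the whole ", strand,
            "-strand transcript as one cistron")
    if (nrow(genes) == 0L)
      return(empty_set(cistron_df(NULL), trna,
                       data.frame(start = 1L, end = L, retained = FALSE)))
    df <- cistron_row(strand, 1L, L, genes, 1L)
    return(empty_set(df, trna, data.frame(start = 1L, end = L, retained = TRUE)))
  }

  punct <- switch(rule,
    all = trna,
    sense_only = trna[trna$strand == strand, , drop = FALSE],
    antisense_overlap_exempt = {
      pcg_sense <- f[f$ftype == "PCG" & f$strand == strand, , drop = FALSE]
      overlaps_sense_pcg <- vapply(seq_len(nrow(trna)), function(i) {
        any(trna$start[i] <= pcg_sense$end & trna$end[i] >= pcg_sense$start)
      }, logical(1))
      keep <- trna$strand == strand | !overlaps_sense_pcg
      trna[keep, , drop = FALSE]
    })

  pr <- IRanges::reduce(IRanges::IRanges(punct$start, pmin(punct$end, L)))
  frag_ir <- IRanges::gaps(pr, start = 1L, end = L)
  frags <- data.frame(start = BiocGenerics::start(frag_ir),
                      end = BiocGenerics::end(frag_ir))

  # assign every same-strand PCG/rRNA to the fragment it overlaps most
  # (ties -> the earlier fragment), so each gene lands in exactly one cistron
  assign_frag <- rep(NA_integer_, nrow(genes))
  if (nrow(genes) && nrow(frags)) {
    for (i in seq_len(nrow(genes))) {
      ov <- pmin(genes$end[i], frags$end) - pmax(genes$start[i], frags$start) + 1L
      ov[ov < 0L] <- 0L
      if (any(ov > 0L)) assign_frag[i] <- which.max(ov)
    }
  }

  rows <- list()
  retained <- logical(nrow(frags))
  for (j in seq_len(nrow(frags))) {
    members <- genes[which(assign_frag == j), , drop = FALSE]
    if (nrow(members) == 0L) next
    retained[j] <- TRUE
    span_start <- min(frags$start[j], members$start)
    span_end <- max(frags$end[j], members$end)
    rows[[length(rows) + 1L]] <- cistron_row(strand, span_start, span_end,
                                             members, length(rows) + 1L)
  }
  df <- if (length(rows)) do.call(rbind, rows) else cistron_df(NULL)
  if (nrow(df)) df$id <- sprintf("Mt%s_%02d", strand, seq_len(nrow(df)))
  frags$retained <- retained
  empty_set(df, punct, frags)
}

cistron_row <- function(strand, start, end, members, ordinal) {
  ord <- order(if (strand == "H") members$start else -members$start)
  data.frame(id = sprintf("Mt%s_%02d", strand, ordinal), strand = strand,
             start = as.integer(start), end = as.integer(end),
             genes = paste(members$name[ord], collapse = ","),
             arity = nrow(members), stringsAsFactors = FALSE)
}

cistron_df <- function(x) {
  data.frame(id = character(), strand = character(), start = integer(),
             end = integer(), genes = character(), arity = integer(),
             stringsAsFactors = FALSE)
}

#' Predict cistrons on both strands
#'
#' Convenience wrapper running [punctuate()] on H then L and row-binding the
#' results (ids stay strand-scoped).
#'
#' @inheritParams punctuate
#' @return A `cistron_set` covering both strands.
#' @export
predict_cistrons <- function(a, rule = c("antisense_overlap_exempt",
                                         "sense_only", "all"),
                             genome_length = NULL) {
  rule <- match.arg(rule)
  h <- punctuate(a, "H", rule, genome_length)
  l <- punctuate(a, "L", rule, genome_length)
  out <- rbind(as.data.frame(h), as.data.frame(l))
  structure(out, rule = rule, genome_length = attr(h, "genome_length"),
            fragments = list(H = attr(h, "fragments"), L = attr(l, "fragments")),
            punctuators = list(H = attr(h, "punctuators"),
                               L = attr(l, "punctuators")),
            class = c("cistron_set", "data.frame"))
}

#' Split the comma-joined gene list of a cistron set
#'
#' @param cistrons A `cistron_set`.
#' @return Named list (by cistron id) of gene name character vectors, in
#'   transcription order.
#' @export
cistron_genes <- function(cistrons) {
  stats::setNames(strsplit(cistrons$genes, ","), cistrons$id)
}

#' Multi-gene cistrons
#'
#' @param cistrons A `cistron_set`.
#' @return The subset with `arity >= 2`, with a `label` column
#'   (`bicistronic`/`tricistronic`/`polycistronic`).
#' @export
multigene_cistrons <- function(cistrons) {
  out <- cistrons[cistrons$arity >= 2L, , drop = FALSE]
  out$label <- ifelse(out$arity == 2L, "bicistronic",
                      ifelse(out$arity == 3L, "tricistronic", "polycistronic"))
  out
}

#' Check that overlapping same-strand genes share a cistron
#'
#' Overlapping coding sequences on the same strand must remain on the same
#' mature transcript, or cleavage would truncate one of them. This check
#' asserts that property for a predicted cistron set and lists violations.
#'
#' @param a The annotation the cistrons were predicted from.
#' @param cistrons A `cistron_set` (both strands or one).
#' @return data.frame with one row per same-strand overlapping PCG pair:
#'   `name1`, `name2`, `overlap_bp`, `cocistronic` (logical).
#' @export
overlap_implies_cocistronic_check <- function(a, cistrons) {
  f <- a$features[a$features$ftype == "PCG", , drop = FALSE]
  gl <- cistron_genes(cistrons)
  rows <- list()
  if (nrow(f) >= 2L) {
    for (i in seq_len(nrow(f) - 1L)) for (j in (i + 1L):nrow(f)) {
      if (f$strand[i] != f$strand[j]) next
      ov <- gene_overlap(f[i, ], f[j, ])
      if (ov == 0L) next
      together <- any(vapply(gl, function(g)
        all(c(f$name[i], f$name[j]) %in% g), logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        name1 = f$name[i], name2 = f$name[j], overlap_bp = ov,
        cocistronic = together, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(name1 = character(), name2 = character(),
               overlap_bp = integer(), cocistronic = logical(),
               stringsAsFactors = FALSE)
}

#' Write cistron spans as BED / TSV
#'
#' BED is 0-based half-open with the cistron id in column 4 and strand
#' (`+` = H, `-` = L) in column 6; the TSV carries the full cistron table.
#'
#' @param cistrons A `cistron_set`.
#' @param path Output file.
#' @export
write_cistron_bed <- function(cistrons, path) {
  bed <- data.frame(chrom = "genome",
                    start = cistrons$start - 1L, end = cistrons$end,
                    name = cistrons$id, score = 0L,
                    strand = ifelse(cistrons$strand == "H", "+", "-"))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_cistron_bed
#' @export
write_cistron_tsv <- function(cistrons, path) {
  write.table(as.data.frame(cistrons), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Match predicted cistrons to a reference expression table by gene content
#'
#' @param cistrons A `cistron_set`.
#' @param reference A data.frame with `cistron_id` and comma-separated
#'   `genes` columns (e.g. [read_expression_fixture()]).
#' @return data.frame mapping `id` (predicted) to `cistron_id` (reference;
#'   `NA` where the predicted cistron has no reference row) by identical gene
#'   sets.
#' @export
match_cistrons <- function(cistrons, reference) {
  pred <- lapply(cistron_genes(cistrons), sort)
  ref <- lapply(stats::setNames(strsplit(reference$genes, ","),
                                reference$cistron_id),
                function(g) sort(normalize_gene_name(g)))
  hit <- vapply(pred, function(g) {
    m <- which(vapply(ref, identical, logical(1), y = g))
    if (length(m)) names(ref)[m[1]] else NA_character_
  }, character(1))
  data.frame(id = cistrons$id, cistron_id = unname(hit),
             stringsAsFactors = FALSE)
}
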