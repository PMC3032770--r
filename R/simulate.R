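#' Specification for a synthetic mitogenome
#'
#' Either supply `gene_order` (name, ftype, strand, length) together with
#' intergenic gaps and overlaps, from which coordinates are laid out left to
#' right, or supply a ready `annotation` whose coordinates are used verbatim.
#' The default, [genome_spec_maruca()], embeds the packaged lepidopteran gene
#' table so the synthetic genome reproduces the real gene order, strand
#' layout, 7 bp and 1 bp gene overlaps, and truncated-stop geometry exactly.
#'
#' The base composition model is AT-rich with a positional codon bias:
#' non-coding and structural-RNA regions draw bases i.i.d. at `at_target`;
#' protein-coding interiors draw codons with per-position A+T probabilities
#' proportional to `pos_at_profile` and rescaled so the expected overall
#' composition stays `at_target` (third positions most AT-rich, as in insect
#' mitogenomes). Codons that would spell a stop are re-coded by swapping the
#' third base within its AT/GC class, which leaves the positional
#' composition untouched.
#'
#' @param gene_order data.frame with `name`, `ftype`, `strand`, `length`.
#' @param intergenic_gaps Integer vector (length `nrow(gene_order) - 1`) of
#'   gaps between consecutive features; negative values create overlaps.
#' @param annotation Alternatively, a `mito_annotation` used verbatim.
#' @param at_target Target overall A+T fraction (default 0.80).
#' @param pos_at_profile Relative A+T weights for codon positions 1--3
#'   (default `c(0.73, 0.698, 0.94)`, the observed positional fractions).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(gene_order = NULL, intergenic_gaps = NULL,
                        annotation = NULL, at_target = 0.80,
                        pos_at_profile = c(0.73, 0.698, 0.94),
                        seed = 1L) {
  stopifnot(at_target > 0, at_target < 1, length(pos_at_profile) == 3L)
  if (is.null(annotation)) {
    stopifnot(is.data.frame(gene_order),
              all(c("name", "ftype", "strand", "length") %in% names(gene_order)))
    if (any(gene_order$length <= 0L)) stop("gene lengths must be positive")
    n <- nrow(gene_order)
    gaps <- intergenic_gaps %||% rep(0L, n - 1L)
    if (length(gaps) != n - 1L)
      stop("intergenic_gaps must have length nrow(gene_order) - 1")
    start <- integer(n); end <- integer(n)
    start[1] <- 1L; end[1] <- gene_order$length[1]
    for (i in seq_len(n - 1L)) {
      start[i + 1L] <- end[i] + gaps[i] + 1L
      end[i + 1L] <- start[i + 1L] + gene_order$length[i + 1L] - 1L
      if (-gaps[i] >= min(gene_order$length[i], gene_order$length[i + 1L]))
        stop("infeasible overlap between ", gene_order$name[i], " and ",
             gene_order$name[i + 1L])
      if (start[i + 1L] < 1L) stop("infeasible geometry: negative coordinate")
    }
    ft <- data.frame(name = gene_order$name, ftype = gene_order$ftype,
                     strand = gene_order$strand, start = start, end = end,
                     stringsAsFactors = FALSE)
    if (!is.null(gene_order$start_codon)) ft$start_codon <- gene_order$start_codon
    if (!is.null(gene_order$stop_codon)) ft$stop_codon <- gene_order$stop_codon
    annotation <- mito_annotation(ft, genome_id = "synthetic_mtDNA")
  }
  pos_at <- pos_at_profile / mean(pos_at_profile) * at_target
  if (any(pos_at >= 1)) pos_at <- pmin(pos_at, 0.995)
  structure(list(annotation = annotation, at_target = at_target,
                 pos_at = pos_at, seed = as.integer(seed)),
            class = "genome_spec")
}

#' @rdname genome_spec
#' @export
genome_spec_maruca <- function(at_target = 0.80,
                               pos_at_profile = c(0.73, 0.698, 0.94),
                               seed = 1L) {
  ann <- read_gene_table_fixture()
  ann$genome_id <- "synthetic_mtDNA"
  genome_spec(annotation = ann, at_target = at_target,
              pos_at_profile = pos_at_profile, seed = seed)
}

sample_bases <- function(n, at) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
}

# interior codons under the positional model; stop spellings (TA[AG]) are
# re-coded by swapping the third base within its AT/GC class (A->T, G->C),
# which preserves each position's A+T probability exactly
sample_codons <- function(m, pos_at) {
  if (m <= 0L) return(character(0))
  b <- vapply(1:3, function(p) sample_bases(m, pos_at[p]), character(m))
  b <- matrix(b, nrow = m)
  ta <- b[, 1] == "T" & b[, 2] == "A"
  b[ta & b[, 3] == "A", 3] <- "T"
  b[ta & b[, 3] == "G", 3] <- "C"
  paste0(b[, 1], b[, 2], b[, 3])
}

#' Generate a synthetic mitogenome with known truth
#'
#' Lays down an AT-rich background, writes every protein-coding gene in its
#' annotated interval (valid initiator, stop-free interior codons under the
#' positional composition model, and an in-frame terminator at the 3' end:
#' the annotated TAA/TAG where the coordinate length permits a full stop,
#' otherwise the truncated `T`/`TA` completed later by polyadenylation),
#' honouring strand (L-strand genes are written in reverse complement) and
#' positional gene overlaps. Start and stop codons are re-stamped last so
#' overlapping genes keep theirs (the canonical 7 bp and 1 bp overlap
#' geometries are mutually compatible).
#'
#' @param spec A [genome_spec()].
#' @return List with `genome` (a `mito_genome`), `annotation` (input
#'   coordinates with *realized* start/stop codons) and `truth` (per-PCG
#'   data.frame of realized codons and frame remainders).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  seed_locally(spec$seed)
  f <- spec$annotation$features
  L <- max(f$end)
  g <- sample_bases(L, spec$at_target)

  pcg <- f[f$ftype == "PCG", , drop = FALSE]
  place <- function(chars, start, end, strand) {
    if (strand == "L")
      chars <- rev(chartr("ACGT", "TGCA", chars))
    g[start:end] <<- chars
  }
  realized_start <- character(nrow(pcg))
  realized_stop <- character(nrow(pcg))
  for (i in seq_len(nrow(pcg))) {
    len <- pcg$end[i] - pcg$start[i] + 1L
    if (len < 6L) stop("PCG ", pcg$name[i], " too short to generate")
    r <- len %% 3L
    start_codon <- pcg$start_codon[i]
    if (is.na(start_codon)) start_codon <- "ATG"
    stop_codon <- if (r == 1L) "T" else if (r == 2L) "TA" else {
      sc <- pcg$stop_codon[i]
      if (!is.na(sc) && sc %in% c("TAA", "TAG")) sc else "TAA"
    }
    m <- (len - 3L - nchar(stop_codon)) %/% 3L
    cds <- paste0(start_codon, paste(sample_codons(m, spec$pos_at),
                                     collapse = ""), stop_codon)
    stopifnot(nchar(cds) == len)
    place(strsplit(cds, "")[[1]], pcg$start[i], pcg$end[i], pcg$strand[i])
    realized_start[i] <- start_codon
    realized_stop[i] <- stop_codon
  }
  # re-stamp terminal codons so overlapping neighbours keep theirs
  for (i in seq_len(nrow(pcg))) {
    sc <- strsplit(realized_stop[i], "")[[1]]
    st <- strsplit(realized_start[i], "")[[1]]
    if (pcg$strand[i] == "H") {
      place(sc, pcg$end[i] - length(sc) + 1L, pcg$end[i], "H")
      place(st, pcg$start[i], pcg$start[i] + 2L, "H")
    } else {
      place(sc, pcg$start[i], pcg$start[i] + length(sc) - 1L, "L")
      place(st, pcg$end[i] - 2L, pcg$end[i], "L")
    }
  }
  genome <- mito_genome(spec$annotation$genome_id %||% "synthetic_mtDNA",
                        paste(g, collapse = ""))
  ann <- spec$annotation
  idx <- match(pcg$name, ann$features$name)
  ann$features$start_codon[idx] <- realized_start
  ann$features$stop_codon[idx] <- realized_stop
  ann$genome_id <- genome$id
  truth <- data.frame(name = pcg$name, strand = pcg$strand,
                      start = pcg$start, end = pcg$end,
                      start_codon = realized_start, stop_codon = realized_stop,
                      frame_remainder = (pcg$end - pcg$start + 1L) %% 3L,
                      stringsAsFactors = FALSE)
  list(genome = genome, annotation = ann, truth = truth)
}

#' Specification for a synthetic mature transcriptome and read library
#'
#' Defaults reproduce the packaged cistron expression profile: relative
#' abundances from the EST contig proportions (cistrons absent from that
#' table -- in practice the predicted nd3 monocistron, which the EST library
#' did not detect -- get weight 0), poly(A) tails on the cox2 and
#' atp8/atp6/cox3 transcripts ("two of the eight" mRNA species), 7,608
#' reads, 454-like lengths (Normal(350, 50) truncated to [50, 600]) and
#' error rates (substitution 0.5%, indel 0.5%, homopolymer extension 2% per
#' run of 3+).
#'
#' @param abundances Named numeric weights. Names are reference cistron ids
#'   (`MvMtD_*`, matched to predictions by gene content) or predicted ids.
#'   `NULL` = the packaged profile.
#' @param polyA Named numeric vector of poly(A) probabilities (same naming);
#'   `NULL` = 1 for the cox2 and atp8/atp6/cox3 cistrons, 0 otherwise.
#' @param polyA_tail Function(n) returning n sampled tail lengths (default
#'   ~20 nt: `5 + rpois(n, 15)`).
#' @param n_reads Number of reads (default 7608).
#' @param read_length Function(n) returning n sampled lengths (default
#'   truncated Normal(350, 50)).
#' @param error_rates Numeric: `substitution`, `insertion`, `deletion` (per
#'   base), `homopolymer_extension` (per run of length >= 3).
#' @param seed Integer seed.
#' @return A `transcriptome_spec` list.
#' @export
transcriptome_spec <- function(abundances = NULL, polyA = NULL,
                               polyA_tail = function(n) 5L + rpois(n, 15),
                               n_reads = 7608L,
                               read_length = function(n)
                                 pmin(pmax(round(rnorm(n, 350, 50)), 50L), 600L),
                               error_rates = c(substitution = 0.005,
                                               insertion = 0.0025,
                                               deletion = 0.0025,
                                               homopolymer_extension = 0.02),
                               seed = 1L) {
  structure(list(abundances = abundances, polyA = polyA,
                 polyA_tail = polyA_tail, n_reads = as.integer(n_reads),
                 read_length = read_length, error_rates = error_rates,
                 seed = as.integer(seed)),
            class = "transcriptome_spec")
}

resolve_per_cistron <- function(x, cistrons, default = 0) {
  out <- stats::setNames(rep(default, nrow(cistrons)), cistrons$id)
  if (is.null(x)) return(out)
  direct <- intersect(names(x), cistrons$id)
  out[direct] <- x[direct]
  rest <- setdiff(names(x), cistrons$id)
  if (length(rest)) {
    map <- match_cistrons(cistrons, read_expression_fixture())
    for (nm in rest) {
      hit <- map$id[!is.na(map$cistron_id) & map$cistron_id == nm]
      if (length(hit)) out[hit] <- x[[nm]]
    }
  }
  out
}

#' Generate mature transcripts from a punctuation-cleaved annotation
#'
#' Predicts cistrons (default punctuation rule), keeps those with positive
#' abundance weight, and emits each as the exact cistron span in
#' strand-correct orientation, with a sampled poly(A) tail appended where the
#' spec says the species is polyadenylated.
#'
#' @param genome A `mito_genome`.
#' @param annotation A `mito_annotation`.
#' @param spec A [transcriptome_spec()].
#' @param cistrons Optionally, a precomputed `cistron_set`.
#' @return List with `transcripts` (named character vector, span + tail),
#'   `truth` (data.frame `cistron_id`, `strand`, `start`, `end`,
#'   `span_length`, `weight`, `polyA_len`), and `cistrons`.
#' @export
generate_transcripts <- function(genome, annotation, spec = transcriptome_spec(),
                                 cistrons = NULL) {
  seed_locally(spec$seed)
  if (is.null(cistrons)) cistrons <- predict_cistrons(annotation)
  w <- resolve_per_cistron(
    spec$abundances %||% default_expression_weights(), cistrons)
  pA <- resolve_per_cistron(spec$polyA %||% default_polyA_species(), cistrons)
  keep <- which(w > 0)
  tr <- character(0); truth <- list()
  for (i in keep) {
    cs <- cistrons[i, ]
    s <- substring(genome$seq, cs$start, min(cs$end, genome$length))
    if (cs$strand == "L") s <- revcomp_chr(s)
    tail_len <- if (runif(1) < pA[[cs$id]]) spec$polyA_tail(1L) else 0L
    tr[[cs$id]] <- paste0(s, strrep("A", tail_len))
    truth[[length(truth) + 1L]] <- data.frame(
      cistron_id = cs$id, strand = cs$strand, start = cs$start, end = cs$end,
      span_length = nchar(s), weight = w[[cs$id]], polyA_len = tail_len,
      stringsAsFactors = FALSE)
  }
  list(transcripts = tr, truth = do.call(rbind, truth), cistrons = cistrons)
}

default_expression_weights <- function() {
  prof <- read_expression_fixture()
  stats::setNames(prof$proportion_pct, prof$cistron_id)
}

default_polyA_species <- function() {
  c(MvMtD_03 = 1, MvMtD_04 = 1)  # the cox2 and atp8/atp6/cox3 transcripts
}

apply_read_errors <- function(chars, rates) {
  n <- length(chars)
  bases <- c("A", "C", "G", "T")
  # substitutions
  ns <- rbinom(1L, n, rates[["substitution"]])
  if (ns > 0L) {
    at <- sample.int(n, ns)
    for (p in at) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  # homopolymer extensions on runs of 3+ (one extra copy of the run base)
  hp <- rates[["homopolymer_extension"]]
  if (hp > 0) {
    r <- rle(chars)
    runs <- which(r$lengths >= 3L)
    if (length(runs)) {
      ext <- runs[runif(length(runs)) < hp]
      if (length(ext)) r$lengths[ext] <- r$lengths[ext] + 1L
      chars <- inverse.rle(r)
      n <- length(chars)
    }
  }
  # point insertions / deletions
  ni <- rbinom(1L, n, rates[["insertion"]])
  nd <- rbinom(1L, n, rates[["deletion"]])
  if (nd > 0L && nd < n) chars <- chars[-sample.int(length(chars), nd)]
  if (ni > 0L) {
    at <- sort(sample.int(length(chars), min(ni, length(chars))))
    out <- character(0); prev <- 0L
    for (p in at) {
      out <- c(out, chars[(prev + 1L):p], sample(bases, 1L))
      prev <- p
    }
    if (prev < length(chars)) out <- c(out, chars[(prev + 1L):length(chars)])
    chars <- out
  }
  chars
}

#' Simulate 454-style reads from mature transcripts
#'
#' Reads are sampled from transcript species proportionally to their
#' abundance weights, start positions uniform, lengths from the spec's
#' distribution (a sampled length longer than its transcript is resampled
#' and the event counted), then corrupted by substitution, point indel and
#' homopolymer-extension errors. Deterministic given the spec seed.
#'
#' @param transcripts Output of [generate_transcripts()] (or a named
#'   character vector plus a `weights` argument).
#' @param spec A [transcriptome_spec()].
#' @param weights Optional named abundance weights (defaults to the truth
#'   table's weights).
#' @return List with `reads` (named character vector), `truth` (data.frame
#'   `read_id`, `cistron_id`, `tr_start`, `tr_end`, `covers_tail`) and
#'   `n_resampled`.
#' @export
simulate_reads <- function(transcripts, spec = transcriptome_spec(),
                           weights = NULL) {
  seed_locally(spec$seed + 1L)
  if (is.list(transcripts) && !is.null(transcripts$transcripts)) {
    weights <- weights %||% stats::setNames(transcripts$truth$weight,
                                            transcripts$truth$cistron_id)
    polyA_len <- stats::setNames(transcripts$truth$polyA_len,
                                 transcripts$truth$cistron_id)
    transcripts <- transcripts$transcripts
  } else {
    if (is.null(weights)) stop("supply abundance weights")
    polyA_len <- stats::setNames(rep(0L, length(transcripts)),
                                 names(transcripts))
  }
  stopifnot(spec$n_reads > 0L, all(weights >= 0), any(weights > 0))
  w <- weights[names(transcripts)]
  species <- sample(names(transcripts), spec$n_reads, replace = TRUE,
                    prob = w / sum(w))
  tlen <- nchar(transcripts)
  reads <- character(spec$n_reads)
  truth <- vector("list", spec$n_reads)
  n_resampled <- 0L
  for (i in seq_len(spec$n_reads)) {
    sp <- species[i]
    len <- spec$read_length(1L)
    if (tlen[[sp]] <= 60L) {
      if (len > tlen[[sp]]) { n_resampled <- n_resampled + 1L; len <- tlen[[sp]] }
    } else while (len > tlen[[sp]]) {
      n_resampled <- n_resampled + 1L
      len <- spec$read_length(1L)
    }
    pos <- sample.int(tlen[[sp]] - len + 1L, 1L)
    raw <- substring(transcripts[[sp]], pos, pos + len - 1L)
    chars <- apply_read_errors(strsplit(raw, "")[[1]], spec$error_rates)
    id <- sprintf("read_%06d", i)
    reads[i] <- paste(chars, collapse = "")
    tail_start <- tlen[[sp]] - polyA_len[[sp]] + 1L
    truth[[i]] <- data.frame(
      read_id = id, cistron_id = sp, tr_start = pos, tr_end = pos + len - 1L,
      covers_tail = polyA_len[[sp]] > 0L && (pos + len - 1L) >= tail_start,
      stringsAsFactors = FALSE)
  }
  names(reads) <- sprintf("read_%06d", seq_len(spec$n_reads))
  list(reads = reads, truth = do.call(rbind, truth),
       n_resampled = n_resampled)
}

#' Write / read a simple FASTQ
#'
#' Flat `I` quality; wrappers over [Biostrings::writeXStringSet()] /
#' [Biostrings::readDNAStringSet()].
#'
#' @param reads Named character vector.
#' @param path FASTQ path.
#' @export
write_reads_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(
    ss, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}
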