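#' Filter EST reads before mapping
#'
#' Applies the two 454-era QC rules used for EST assembly: reads shorter than
#' `min_len` nucleotides are rejected, as are reads in which any single
#' nucleotide makes up at least `homopolymer_frac` of the entire read (a
#' homopolymer-dominated read).
#'
#' @param reads Named character vector or [Biostrings::DNAStringSet] of read
#'   sequences.
#' @param min_len Minimum read length (default 50 nt).
#' @param homopolymer_frac Single-nucleotide fraction at or above which a read
#'   is rejected (default 0.60).
#' @return List with `kept` (named character vector) and `rejected`
#'   (data.frame `read_id`, `reason` in `"too_short"`/`"homopolymer"`).
#' @export
filter_reads <- function(reads, min_len = 50L, homopolymer_frac = 0.60) {
  if (is(reads, "DNAStringSet")) {
    ids <- names(reads) %||% as.character(seq_along(reads))
    reads <- stats::setNames(as.character(reads), ids)
  }
  if (is.null(names(reads))) names(reads) <- as.character(seq_along(reads))
  seqs <- toupper(reads)
  len <- nchar(seqs)
  ss <- Biostrings::DNAStringSet(seqs)
  freq <- Biostrings::letterFrequency(ss, c("A", "C", "G", "T"))
  max_frac <- apply(freq, 1L, max) / pmax(len, 1L)
  too_short <- len < min_len
  homo <- !too_short & max_frac >= homopolymer_frac
  rejected <- data.frame(
    read_id = c(names(seqs)[too_short], names(seqs)[homo]),
    reason = c(rep("too_short", sum(too_short)),
               rep("homopolymer", sum(homo))),
    stringsAsFactors = FALSE)
  list(kept = seqs[!(too_short | homo)], rejected = rejected)
}

#' Build an exact k-mer index of a genome
#'
#' Hash of every forward-strand k-mer to its start positions; reads are
#' seeded against it on both strands (the reverse complement of the read is
#' looked up for L-strand placements).
#'
#' @param genome A `mito_genome` or DNA string.
#' @param k Seed length (default 11).
#' @return A `genome_index` (environment-backed) used by [map_reads()].
#' @export
genome_index <- function(genome, k = 11L) {
  seq <- if (inherits(genome, "mito_genome")) genome$seq else
    toupper(as.character(genome))
  L <- nchar(seq)
  if (L < k) stop("genome shorter than seed length k = ", k)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  env <- list2env(split(starts, kmers), hash = TRUE)
  structure(list(env = env, k = as.integer(k), seq = seq, length = L,
                 dna = Biostrings::DNAString(seq)),
            class = "genome_index")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

submat_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE)
    cache
  }
})

# Rebuild the two gapped alignment strings from the aligned (ungapped)
# pattern/subject regions plus the indel ranges reported by
# pairwiseAlignment(): insertions (extra pattern bases = subject gaps) in
# pattern-local coordinates, deletions (extra subject bases = pattern gaps)
# in subject-local coordinates. Two-pointer merge over the few indel events.
build_gapped <- function(p0, s0, ins, del) {
  pi_ <- BiocGenerics::start(ins); pw <- BiocGenerics::width(ins)
  si_ <- BiocGenerics::start(del); sw <- BiocGenerics::width(del)
  if (!length(pi_) && !length(si_)) return(c(p0, s0))
  pc <- strsplit(p0, "")[[1]]; sc <- strsplit(s0, "")[[1]]
  np <- length(pc); ns <- length(sc)
  outp <- list(); outs <- list()
  p <- 1L; s <- 1L; i <- 1L; d <- 1L
  while (p <= np || s <= ns) {
    # an insertion range starts at the subject position following the subject
    # gap; a deletion range starts at the pattern position following the
    # pattern gap (widths = gap lengths)
    nis <- if (i <= length(pi_)) pi_[i] else .Machine$integer.max
    ndp <- if (d <= length(si_)) si_[d] else .Machine$integer.max
    if (nis == s) {
      outp[[length(outp) + 1L]] <- pc[p:(p + pw[i] - 1L)]
      outs[[length(outs) + 1L]] <- rep("-", pw[i])
      p <- p + pw[i]; i <- i + 1L
    } else if (ndp == p) {
      outs[[length(outs) + 1L]] <- sc[s:(s + sw[d] - 1L)]
      outp[[length(outp) + 1L]] <- rep("-", sw[d])
      s <- s + sw[d]; d <- d + 1L
    } else {
      run <- min(nis - s, ndp - p, np - p + 1L, ns - s + 1L)
      if (run <= 0L) stop("inconsistent indel ranges")  # should not happen
      outp[[length(outp) + 1L]] <- pc[p:(p + run - 1L)]
      outs[[length(outs) + 1L]] <- sc[s:(s + run - 1L)]
      p <- p + run; s <- s + run
    }
  }
  c(paste(unlist(outp), collapse = ""), paste(unlist(outs), collapse = ""))
}

# Best-supported diagonal for an oriented read: non-overlapping k-mer seeds
# looked up in the genome hash; the diagonal with the most seed hits wins,
# ties going to the lowest genome coordinate. NA when no seed hits.
seed_diagonal <- function(oriented, idx) {
  k <- idx$k
  rl <- nchar(oriented)
  offs <- seq.int(1L, rl - k + 1L, by = k)
  kmers <- substring(oriented, offs, offs + k - 1L)
  hits_diag <- integer(0)
  for (j in seq_along(offs)) {
    pos <- idx$env[[kmers[j]]]
    if (!is.null(pos)) hits_diag <- c(hits_diag, pos - offs[j] + 1L)
  }
  if (!length(hits_diag)) return(NA_integer_)
  tab <- table(hits_diag)
  min(as.integer(names(tab)[tab == max(tab)]))
}

#' Map reads to the genome by seed-and-extend
#'
#' Exact k-mer seeds on both strands, the best-supported diagonal extended by
#' a windowed local alignment (window = the diagonal widened by `band_frac`
#' of the read length on both sides, playing the role of an alignment band),
#' and a placement reported only if it has at least `min_match_bases`
#' matching bases and a matching fraction (matches over alignment columns,
#' gaps included) of at least `min_match_pct` -- the scaffolding thresholds
#' used for EST-to-mitogenome transcript mapping. Ties between candidate
#' placements are broken by more matching bases, then the lower genome
#' coordinate, then H before L. The unaligned read suffix on the read's 3'
#' side is reported as `clip3` (in read orientation) for poly(A) detection.
#'
#' Alignment extension for all seeded candidates is performed in a single
#' vectorised [Biostrings::pairwiseAlignment()] call (local, match +1,
#' mismatch -1, gap open 2 / extend 1).
#'
#' @param reads Named character vector (e.g. the `kept` component of
#'   [filter_reads()]) or `DNAStringSet`.
#' @param genome A `mito_genome`, DNA string, or prebuilt [genome_index()].
#' @param k Seed length (default 11).
#' @param min_match_bases Minimum matching bases (default 8).
#' @param min_match_pct Minimum matching fraction (default 0.70).
#' @param band_frac Window margin as a fraction of read length (default 0.15).
#' @return List with `alignments` (a `read_alignments` data.frame, one row
#'   per mapped read: `read_id`, `strand`, `g_start`, `g_end`,
#'   `aligned_bases`, `nmatch`, `matching_fraction`, `clip5`, `clip3`,
#'   `pattern_aln`, `subject_aln`) and `unmapped` (data.frame `read_id`,
#'   `reason`).
#' @export
map_reads <- function(reads, genome, k = 11L, min_match_bases = 8L,
                      min_match_pct = 0.70, band_frac = 0.15) {
  idx <- if (inherits(genome, "genome_index")) genome else
    genome_index(genome, k = k)
  if (is(reads, "DNAStringSet")) {
    ids <- names(reads) %||% as.character(seq_along(reads))
    reads <- stats::setNames(as.character(reads), ids)
  }
  if (is.null(names(reads))) names(reads) <- as.character(seq_along(reads))
  reads <- toupper(reads)
  n <- length(reads)
  rl <- nchar(reads)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads)))

  too_short <- rl < idx$k
  # collect seeded candidates (up to one per strand per read)
  c_read <- integer(0); c_strand <- character(0); c_diag <- integer(0)
  for (i in which(!too_short)) {
    d <- seed_diagonal(reads[[i]], idx)
    if (!is.na(d)) {
      c_read <- c(c_read, i); c_strand <- c(c_strand, "H"); c_diag <- c(c_diag, d)
    }
    d <- seed_diagonal(rc[[i]], idx)
    if (!is.na(d)) {
      c_read <- c(c_read, i); c_strand <- c(c_strand, "L"); c_diag <- c(c_diag, d)
    }
  }

  aln_rows <- NULL
  if (length(c_read)) {
    crl <- rl[c_read]
    margin <- pmax(10L, ceiling(band_frac * crl))
    ws <- pmax(1L, c_diag - margin)
    we <- pmin(idx$length, c_diag + crl - 1L + margin)
    oriented <- ifelse(c_strand == "H", reads[c_read], rc[c_read])
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(unname(oriented)),
      subject = Biostrings::DNAStringSet(substring(idx$seq, ws, we)),
      type = "local", substitutionMatrix = submat_default(),
      gapOpening = 2, gapExtension = 1)
    nm <- Biostrings::nmatch(aln)
    ps <- BiocGenerics::start(Biostrings::pattern(aln))
    pe <- BiocGenerics::end(Biostrings::pattern(aln))
    g_start <- ws + BiocGenerics::start(Biostrings::subject(aln)) - 1L
    g_end <- ws + BiocGenerics::end(Biostrings::subject(aln)) - 1L
    # gapped alignment strings rebuilt from the compact indel ranges;
    # far cheaper than alignedPattern()/alignedSubject() per element
    ins <- Biostrings::insertion(aln)
    del <- Biostrings::deletion(aln)
    pattern_aln <- character(length(ps))
    subject_aln <- character(length(ps))
    for (j in seq_along(ps)) {
      gp <- build_gapped(substring(oriented[j], ps[j], pe[j]),
                         substring(idx$seq, g_start[j], g_end[j]),
                         ins[[j]], del[[j]])
      pattern_aln[j] <- gp[1]
      subject_aln[j] <- gp[2]
    }
    cols <- nchar(pattern_aln)
    ok <- cols > 0L & nm >= min_match_bases & (nm / pmax(cols, 1L)) >= min_match_pct
    if (any(ok)) {
      w <- which(ok)
      # best candidate per read: most matching bases, then lowest genome
      # coordinate, then H before L
      o <- w[order(c_read[w], -nm[w], g_start[w], c_strand[w] == "L")]
      o <- o[!duplicated(c_read[o])]
      ri <- c_read[o]
      clip3 <- ifelse(c_strand[o] == "H",
                      substring(reads[ri], pe[o] + 1L, rl[ri]),
                      substring(reads[ri], rl[ri] - ps[o] + 2L, rl[ri]))
      clip5 <- ifelse(c_strand[o] == "H",
                      substring(reads[ri], 1L, ps[o] - 1L),
                      substring(reads[ri], 1L, rl[ri] - pe[o]))
      aln_rows <- data.frame(
        read_id = names(reads)[ri], strand = c_strand[o],
        g_start = g_start[o], g_end = g_end[o],
        aligned_bases = pe[o] - ps[o] + 1L, nmatch = nm[o],
        matching_fraction = nm[o] / cols[o],
        clip5 = clip5, clip3 = clip3,
        pattern_aln = pattern_aln[o], subject_aln = subject_aln[o],
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(aln_rows))
    aln_rows <- data.frame(read_id = character(), strand = character(),
                           g_start = integer(), g_end = integer(),
                           aligned_bases = integer(), nmatch = integer(),
                           matching_fraction = numeric(), clip5 = character(),
                           clip3 = character(), pattern_aln = character(),
                           subject_aln = character(), stringsAsFactors = FALSE)
  mapped_idx <- match(aln_rows$read_id, names(reads))
  reason <- rep(NA_character_, n)
  reason[too_short] <- "shorter_than_seed"
  seeded <- unique(c_read)
  reason[setdiff(which(!too_short), seeded)] <- "no_seed_hit"
  reason[setdiff(seeded, mapped_idx)] <- "below_threshold"
  unmapped <- data.frame(read_id = names(reads)[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  class(aln_rows) <- c("read_alignments", class(aln_rows))
  list(alignments = aln_rows, unmapped = unmapped)
}

#' Map a single read
#'
#' Convenience wrapper over [map_reads()]; returns the one-row alignment
#' data.frame, or `NULL` when the read is unmapped (too short for a seed, no
#' seed hit, or below the matching thresholds).
#'
#' @param read Read sequence (character scalar).
#' @param idx A [genome_index()], `mito_genome` or DNA string.
#' @param read_id Identifier carried into the result.
#' @inheritParams map_reads
#' @export
map_read <- function(read, idx, read_id = "read",
                     min_match_bases = 8L, min_match_pct = 0.70,
                     band_frac = 0.15) {
  res <- map_reads(stats::setNames(read, read_id), idx,
                   min_match_bases = min_match_bases,
                   min_match_pct = min_match_pct, band_frac = band_frac)
  if (nrow(res$alignments) == 0L) NULL else res$alignments
}

#' Detect a poly(A) tail in a 3' soft clip
#'
#' Length of the leading run of the clip that is at least `1 - tolerance`
#' adenine (at most one non-A per ten bases by default), reported only if it
#' reaches `min_len`; otherwise 0. Works on a clip string, a vector of clips,
#' or a `read_alignments` table (adds a `polyA_len` column).
#'
#' @param x Clip string(s) or a `read_alignments` data.frame (its `clip3`).
#' @param min_len Minimum tail length to call (default 5).
#' @param tolerance Maximum non-A fraction within the tail (default 0.1).
#' @return Integer vector of tail lengths (0 = none), or the alignment table
#'   with a `polyA_len` column.
#' @examples
#' detect_polyA("AAAAAAAA")  # 8
#' detect_polyA("")          # 0
#' @export
detect_polyA <- function(x, min_len = 5L, tolerance = 0.1) {
  if (is.data.frame(x)) {
    x$polyA_len <- detect_polyA(x$clip3, min_len, tolerance)
    return(x)
  }
  vapply(as.character(x), function(clip) {
    clip <- toupper(clip)
    n <- nchar(clip)
    if (is.na(clip) || n == 0L) return(0L)
    chars <- strsplit(clip, "")[[1]]
    non_a <- cumsum(chars != "A")
    ok <- which(non_a <= floor(seq_len(n) * tolerance) & chars == "A")
    len <- if (length(ok)) max(ok) else 0L
    if (len >= min_len) as.integer(len) else 0L
  }, integer(1), USE.NAMES = FALSE)
}

#' Assign mapped reads to cistrons
#'
#' Each alignment is assigned to the same-strand cistron whose span it
#' overlaps most (ties -> the earlier cistron ordinal); reads overlapping no
#' same-strand cistron are left unassigned.
#'
#' @param alignments A `read_alignments` data.frame.
#' @param cistrons A `cistron_set`.
#' @return The alignment table with a `cistron_id` column (`NA` =
#'   unassigned).
#' @export
assign_to_cistron <- function(alignments, cistrons) {
  alignments$cistron_id <- NA_character_
  for (i in seq_len(nrow(alignments))) {
    cs <- cistrons[cistrons$strand == alignments$strand[i], , drop = FALSE]
    if (!nrow(cs)) next
    ov <- pmin(alignments$g_end[i], cs$end) -
      pmax(alignments$g_start[i], cs$start) + 1L
    ov[ov < 0L] <- 0L
    if (any(ov > 0L))
      alignments$cistron_id[i] <- cs$id[which.max(ov)]
  }
  alignments
}

#' Write alignments as SAM
#'
#' Minimal single-reference SAM: header (`@HD`, `@SQ`) plus one line per
#' mapped read, with soft clips as `S` CIGAR operations and the L strand as
#' FLAG 16 (sequence stored reverse-complemented, per SAM convention).
#'
#' @param alignments A `read_alignments` data.frame.
#' @param reads The read sequences (named character vector).
#' @param genome The `mito_genome` used as reference.
#' @param path Output SAM path.
#' @export
write_sam <- function(alignments, reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$id, genome$length)), con)
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    read <- toupper(reads[[a$read_id]])
    rl <- nchar(read)
    flag <- if (a$strand == "H") 0L else 16L
    seq_out <- if (a$strand == "H") read else revcomp_chr(read)
    # CIGAR from the aligned strings (genome orientation)
    p <- strsplit(a$pattern_aln, "")[[1]]
    s <- strsplit(a$subject_aln, "")[[1]]
    ops <- ifelse(p == "-", "D", ifelse(s == "-", "I", "M"))
    r <- rle(ops)
    core <- paste0(r$lengths, r$values, collapse = "")
    left_clip <- if (a$strand == "H") nchar(a$clip5) else nchar(a$clip3)
    right_clip <- if (a$strand == "H") nchar(a$clip3) else nchar(a$clip5)
    cigar <- paste0(if (left_clip) paste0(left_clip, "S") else "", core,
                    if (right_clip) paste0(right_clip, "S") else "")
    writeLines(paste(a$read_id, flag, genome$id, a$g_start, 60L, cigar,
                     "*", 0L, 0L, seq_out, strrep("I", rl),
                     sep = "\t"), con)
  }
  invisible(path)
}
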