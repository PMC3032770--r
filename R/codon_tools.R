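#' The invertebrate mitochondrial genetic code
#'
#' Translation table 5 (AGA/AGG = Ser, AUA = Met, UGA = Trp) via
#' [Biostrings::getGeneticCode()], together with the initiator and terminator
#' sets seen in insect mitogenomes. Besides the canonical NCBI initiators
#' (ATG/ATA/ATT/ATC/TTG/GTG), insect mitochondrial annotations use TTA
#' (nd2-type starts) and the arginine codon CGA (the cox1 initiator), so both
#' are in the default start set. Stops are TAA/TAG; truncated genomic stops
#' (T, TA) are handled by [complete_truncated_stop()], not by the code table.
#'
#' @return An object of class `genetic_code`: list with `table` (named
#'   character vector, 64 DNA codons -> amino-acid letters, `*` = stop),
#'   `start_codons`, `stop_codons`, `name`.
#' @examples
#' invertebrate_mito_code()$table[["AGA"]]  # "S"
#' @export
invertebrate_mito_code <- function() {
  tab <- Biostrings::getGeneticCode("5")
  structure(list(
    table = tab,
    start_codons = c("ATG", "ATA", "ATT", "ATC", "TTA", "TTG", "GTG", "CGA"),
    stop_codons = c("TAA", "TAG"),
    name = "invertebrate mitochondrial (table 5)"),
    class = "genetic_code")
}

dna_codon <- function(x) chartr("Uu", "Tt", toupper(x))
rna_codon <- function(x) chartr("T", "U", toupper(x))

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Complete a truncated stop codon by polyadenylation
#'
#' Genomic copies of mitochondrial genes may end at a bare `T` or `TA`; the
#' mature mRNA acquires a complete `TAA` stop when the poly(A) tail is added.
#' Given a CDS and the observed 3' tail, this either returns the CDS unchanged
#' (already ends in a frame-aligned TAA/TAG), appends the required number of
#' `A`s from the tail, or signals that completion is not possible (no
#' exception is thrown: a non-completable stop is a result, not an error).
#'
#' @param cds DNA string (coding strand).
#' @param tail DNA string observed 3' of the CDS (e.g. a soft-clipped read
#'   tail); only its leading bases are consumed.
#' @return List of class `stop_completion`: `cds` (possibly extended),
#'   `status` (`"complete"`, `"completed"`, `"not_completable"`),
#'   `n_added` (0, 1 or 2).
#' @examples
#' complete_truncated_stop("ATGTTTT", "AAAAA")$status   # "completed"
#' @export
complete_truncated_stop <- function(cds, tail = "") {
  cds <- dna_codon(cds); tail <- dna_codon(tail)
  if (nchar(cds) == 0L) stop("cds must be non-empty")
  n <- nchar(cds); r <- n %% 3L
  done <- function(cds, status, n_added)
    structure(list(cds = cds, status = status, n_added = n_added),
              class = "stop_completion")
  if (r == 0L && substring(cds, n - 2L, n) %in% c("TAA", "TAG"))
    return(done(cds, "complete", 0L))
  if (r == 1L && substring(cds, n, n) == "T" &&
      substring(tail, 1L, 2L) == "AA")
    return(done(paste0(cds, "AA"), "completed", 2L))
  if (r == 2L && substring(cds, n - 1L, n) == "TA" &&
      substring(tail, 1L, 1L) == "A")
    return(done(paste0(cds, "A"), "completed", 1L))
  done(cds, "not_completable", 0L)
}

#' Translate a mitochondrial CDS
#'
#' Codon-by-codon translation under a [genetic code][invertebrate_mito_code].
#' Annotated initiator codons are rendered as `M` (the reporting convention
#' for non-ATG mitochondrial starts such as ATT, TTG or the cox1 CGA); the
#' same codon translated mid-gene keeps its table value. A trailing truncated
#' stop (`T`/`TA`) can first be extended to `TAA`, modelling the
#' polyadenylation completion of the mature mRNA.
#'
#' @param seq DNA (or RNA) string; length must be a multiple of 3 after
#'   optional stop completion.
#' @param code A `genetic_code` (default invertebrate mitochondrial).
#' @param is_annotated_start If `TRUE`, the first codon is reported as `M`.
#' @param polyA_completed If `TRUE`, a trailing `T`/`TA` is extended to `TAA`
#'   before translation.
#' @return Protein string; a frame-aligned terminal stop is dropped. Internal
#'   stops raise an error naming the codon position. Codons containing
#'   non-ACGT characters translate to `X`.
#' @examples
#' translate_cds("ATGTTTTAA")                             # "MF"
#' translate_cds("CGATTTTAA", is_annotated_start = TRUE)  # "MF"
#' @export
translate_cds <- function(seq, code = invertebrate_mito_code(),
                          is_annotated_start = FALSE, polyA_completed = FALSE) {
  seq <- dna_codon(seq)
  if (polyA_completed) {
    n <- nchar(seq); r <- n %% 3L
    if (r == 1L && substring(seq, n, n) == "T") seq <- paste0(seq, "AA")
    else if (r == 2L && substring(seq, n - 1L, n) == "TA")
      seq <- paste0(seq, "A")
  }
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  if (nchar(seq) %% 3L != 0L)
    stop("frame error: length ", nchar(seq), " is not a multiple of 3")
  codons <- split_codons(seq)
  aa <- unname(code$table[codons])
  aa[is.na(aa)] <- "X"
  stops <- which(aa == "*")
  if (length(stops) && any(stops < length(aa)))
    stop("premature stop codon at codon position ", min(stops[stops < length(aa)]))
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (is_annotated_start && length(aa)) aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Synonymous codon families under a genetic code
#'
#' Amino-acid letter -> codon set; stop codons form their own family (`*`),
#' so that their relative usage is defined the same way as for sense codons.
#' Under the invertebrate mitochondrial code the Leu family has 6 codons and
#' the Ser family 8 (including AGA/AGG).
#'
#' @param code A `genetic_code`.
#' @return Named list of DNA codon character vectors.
#' @export
codon_families <- function(code = invertebrate_mito_code()) {
  split(names(code$table), unname(code$table))
}

#' Relative synonymous codon usage from codon counts
#'
#' RSCU of a codon is its count divided by the mean count of its synonymous
#' family; a value of 1 means no bias within the family. Families with zero
#' total count get `NA`.
#'
#' @param counts Named numeric vector of codon counts (DNA or RNA alphabet).
#' @param code A `genetic_code`.
#' @return Named numeric vector (DNA codon names) of RSCU values.
#' @examples
#' leu <- c(TTA = 426, TTG = 9, CTT = 26, CTC = 2, CTA = 23, CTG = 0)
#' round(rscu(leu)[["TTA"]], 2)  # 5.26
#' @export
rscu <- function(counts, code = invertebrate_mito_code()) {
  names(counts) <- dna_codon(names(counts))
  full <- stats::setNames(numeric(length(code$table)), names(code$table))
  full[names(counts)] <- counts
  out <- full
  for (fam in codon_families(code)) {
    m <- mean(full[fam])
    out[fam] <- if (m > 0) full[fam] / m else NA_real_
  }
  out[names(counts)]
}

#' Codon usage table for a set of coding sequences
#'
#' Tallies all codons (stop codons included) across the supplied CDSs and
#' computes RSCU per synonymous family. Codons containing non-ACGT characters
#' are excluded from the tally and reported.
#'
#' @param cds_list Character vector (or list) of DNA/RNA coding sequences,
#'   each a multiple of 3 long (complete truncated stops first, e.g. via
#'   [complete_truncated_stop()]).
#' @param code A `genetic_code`.
#' @return A `codon_usage_table`: data.frame with columns `codon` (RNA
#'   alphabet, for display), `aa`, `count`, `rscu`; attributes `n_codons`
#'   (total tallied) and `n_excluded` (ambiguous codons dropped).
#' @export
codon_usage <- function(cds_list, code = invertebrate_mito_code()) {
  cds_list <- vapply(cds_list, dna_codon, character(1))
  bad <- which(nchar(cds_list) %% 3L != 0L | nchar(cds_list) == 0L)
  if (length(bad))
    stop("frame error: cds ", bad[1], " has length ", nchar(cds_list[bad[1]]))
  codons <- unlist(lapply(cds_list, split_codons), use.names = FALSE)
  clean <- grepl("^[ACGT]{3}$", codons)
  counts <- table(factor(codons[clean], levels = names(code$table)))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  out <- data.frame(
    codon = rna_codon(names(counts)),
    aa = unname(code$table),
    count = unname(counts),
    rscu = unname(rscu(counts, code)),
    stringsAsFactors = FALSE)
  structure(out, n_codons = sum(counts), n_excluded = sum(!clean),
            class = c("codon_usage_table", "data.frame"))
}

#' Write a codon usage table as TSV
#'
#' Columns `codon`, `aa`, `count`, `rscu`, in the shape of printed codon-usage
#' tables.
#'
#' @param x A `codon_usage_table` (or compatible data.frame).
#' @param path Output file.
#' @param alphabet `"RNA"` (default, display convention) or `"DNA"`.
#' @export
write_codon_usage <- function(x, path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  out <- as.data.frame(x)[, c("codon", "aa", "count", "rscu")]
  out$codon <- if (alphabet == "RNA") rna_codon(out$codon) else
    dna_codon(out$codon)
  out$rscu <- round(out$rscu, 2)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Nucleotide composition and per-codon-position AT fractions
#'
#' For a plain sequence, the overall A+T fraction; for a list of coding
#' sequences, additionally the A+T fraction at each of the three codon
#' positions. `N`/ambiguity characters are excluded from both numerator and
#' denominator.
#'
#' @param x A DNA string (genome) or a character vector/list of CDSs (each a
#'   multiple of 3 long).
#' @return A `composition_stats` list: `at_fraction`, `at_by_codon_position`
#'   (length-3 numeric, `NA` for plain sequences), `n_codons`, `n_bases`.
#' @examples
#' at_composition("ATAT")$at_fraction  # 1
#' @export
at_composition <- function(x) {
  frac_at <- function(chars) {
    acgt <- chars %in% c("A", "C", "G", "T")
    if (!any(acgt)) return(NA_real_)
    sum(chars[acgt] %in% c("A", "T")) / sum(acgt)
  }
  if (is.character(x) && length(x) == 1L && !is.list(x)) {
    seq <- dna_codon(x)
    if (nchar(seq) == 0L) stop("empty input")
    chars <- strsplit(seq, "")[[1]]
    res <- list(at_fraction = frac_at(chars),
                at_by_codon_position = rep(NA_real_, 3L),
                n_codons = NA_integer_, n_bases = sum(chars %in% c("A", "C", "G", "T")))
  } else {
    seqs <- vapply(x, dna_codon, character(1))
    if (length(seqs) == 0L || all(nchar(seqs) == 0L)) stop("empty input")
    if (any(nchar(seqs) %% 3L != 0L))
      stop("frame error: cds lengths must be multiples of 3")
    chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
    pos <- rep_len(1:3, length(chars))
    res <- list(
      at_fraction = frac_at(chars),
      at_by_codon_position = vapply(1:3, function(p) frac_at(chars[pos == p]),
                                    numeric(1)),
      n_codons = length(chars) %/% 3L,
      n_bases = sum(chars %in% c("A", "C", "G", "T")))
  }
  structure(res, class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("<composition_stats> A+T = %.3f", x$at_fraction))
  if (!anyNA(x$at_by_codon_position))
    cat(sprintf(" (codon positions: %.3f / %.3f / %.3f over %d codons)",
                x$at_by_codon_position[1], x$at_by_codon_position[2],
                x$at_by_codon_position[3], x$n_codons))
  cat("\n")
  invisible(x)
}

#' Pearson chi-square for an AT-proportion difference between codon positions
#'
#' Standard 2x2 Pearson test (no continuity correction) on the
#' `[AT, GC] x [position i, position j]` contingency table, with the p-value
#' from the chi-square distribution with 1 df.
#'
#' @param n_at_i,n_i AT count and total at position i.
#' @param n_at_j,n_j AT count and total at position j.
#' @return List with `chi2`, `p_value`, `df` and the contingency `table`.
#' @examples
#' position_bias_chi2(50, 100, 50, 100)$chi2  # 0
#' @export
position_bias_chi2 <- function(n_at_i, n_i, n_at_j, n_j) {
  stopifnot(n_at_i >= 0, n_at_j >= 0, n_i > 0, n_j > 0,
            n_at_i <= n_i, n_at_j <= n_j)
  m <- matrix(c(n_at_i, n_i - n_at_i, n_at_j, n_j - n_at_j), nrow = 2,
              dimnames = list(c("AT", "GC"), c("pos_i", "pos_j")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("undefined statistic: zero marginal in the 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), p_value = unname(ht$p.value), df = 1L,
       table = m)
}
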