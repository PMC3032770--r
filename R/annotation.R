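#' @title Genome sequence container
#'
#' @description A minimal container for a (near-complete) mitochondrial genome
#' sequence: an identifier, the residues as an uppercase IUPAC DNA string, and
#' the topology. Partial assemblies that lack the control region (as is common
#' for PCR-walked insect mitogenomes) are `"linear"`; complete mitogenomes may
#' be declared `"circular"`.
#'
#' @param id Sequence identifier.
#' @param residues DNA string (character scalar); converted to uppercase.
#' @param topology `"linear"` (default) or `"circular"`.
#' @return An object of class `mito_genome` with fields `id`, `seq`,
#'   `topology`, `length`.
#' @examples
#' g <- mito_genome("toy", "ACGTACGT")
#' g$length
#' @export
mito_genome <- function(id, residues, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("genome sequence must be non-empty")
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", residues)
  if (nchar(bad) > 0L)
    stop("non-IUPAC characters in genome sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  structure(list(id = as.character(id), seq = residues, topology = topology,
                 length = nchar(residues)),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %d bp, %s\n", x$id, x$length, x$topology))
  invisible(x)
}

#' Read / write a genome FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] (70-column wrapping on output). A
#' multi-record FASTA is rejected: the unit of analysis is one mitogenome.
#'
#' @param path FASTA file path.
#' @param topology Passed to [mito_genome()].
#' @return `read_genome_fasta`: a `mito_genome`.
#' @export
read_genome_fasta <- function(path, topology = c("linear", "circular")) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected exactly one sequence in ", path, ", found ", length(ss))
  mito_genome(sub("\\s.*$", "", names(ss)[1]), as.character(ss[[1]]),
              match.arg(topology))
}

#' @rdname read_genome_fasta
#' @param genome A `mito_genome`.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(stats::setNames(genome$seq, genome$id))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

ftype_levels <- c("PCG", "tRNA", "rRNA")

#' Normalise a gene name for lookup
#'
#' Lowercases and canonicalises separators so that display-style names
#' (`trnL-UUR`, `Nd 4L`, `cytB`) all key the same feature. Display names are
#' kept alongside in the annotation table.
#' @param x Character vector of names.
#' @return Character vector of normalised tokens (e.g. `"trnl-uur"`).
#' @export
normalize_gene_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:space:]_]+", "", x)
  x
}

#' Construct an annotation
#'
#' @param features A data.frame with columns `name`, `ftype` (PCG/tRNA/rRNA),
#'   `strand` (H/L), `start`, `end` (1-based inclusive, start <= end on the
#'   forward axis) and optionally `declared_length`, `start_codon`,
#'   `stop_codon`, `anticodon`.
#' @param genome_id Identifier of the genome the features annotate.
#' @return An object of class `mito_annotation`: a list with `genome_id` and
#'   the feature data.frame (sorted by `start`), with normalised `name` and
#'   the original spelling kept as `display_name`.
#' @export
mito_annotation <- function(features, genome_id = NA_character_) {
  stopifnot(is.data.frame(features))
  req <- c("name", "ftype", "strand", "start", "end")
  miss <- setdiff(req, names(features))
  if (length(miss))
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(features) == 0L) stop("annotation contains no features")
  opt <- c("declared_length", "start_codon", "stop_codon", "anticodon")
  for (col in opt) {
    if (!col %in% names(features))
      features[[col]] <- if (col == "declared_length") NA_integer_ else NA_character_
  }
  features$display_name <- as.character(features$name)
  features$name <- normalize_gene_name(features$name)
  features$ftype <- as.character(features$ftype)
  features$strand <- as.character(features$strand)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$declared_length <- as.integer(features$declared_length)
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    v <- toupper(as.character(features[[col]]))
    v[!nzchar(v) | v == "NA"] <- NA_character_
    features[[col]] <- v
  }
  if (!all(features$ftype %in% ftype_levels))
    stop("ftype must be one of ", paste(ftype_levels, collapse = "/"))
  if (!all(features$strand %in% c("H", "L")))
    stop("strand must be 'H' or 'L'")
  if (any(features$start < 1L) || any(features$end < features$start))
    stop("feature coordinates must satisfy 1 <= start <= end")
  if (anyDuplicated(features$name))
    stop("duplicate feature name(s): ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "))
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  cols <- c("name", "display_name", "ftype", "strand", "start", "end",
            "declared_length", "start_codon", "stop_codon", "anticodon")
  structure(list(genome_id = genome_id, features = features[, cols]),
            class = "mito_annotation")
}

#' @export
print.mito_annotation <- function(x, ...) {
  tab <- table(factor(x$features$ftype, ftype_levels))
  cat(sprintf("<mito_annotation> %s: %d features (%s)\n",
              x$genome_id, nrow(x$features),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  invisible(x)
}

#' Read a feature annotation
#'
#' Two dialects are supported. `"gene_table_tsv"` is the gene-table dialect used
#' for AT-rich insect mitogenomes: tab-separated columns `name`, `ftype`,
#' `strand`, `start5`, `stop3` and optionally `declared_length`,
#' `start_codon`, `stop_codon`, `anticodon`, with coordinates written in
#' transcription orientation, i.e. L-strand rows may have `start5 > stop3`.
#' Coordinates are normalised at read time to forward-axis `start`/`end`
#' (minimum/maximum). `"gff3"` is standard GFF3 (1-based inclusive, `+` = H,
#' `-` = L) as written by [write_gff3()].
#'
#' @param path Input file.
#' @param dialect `"gene_table_tsv"` or `"gff3"`.
#' @param genome Optional `mito_genome`; when supplied, features beyond the
#'   genome bounds raise an error.
#' @return A `mito_annotation`.
#' @export
read_annotation_table <- function(path, dialect = c("gene_table_tsv", "gff3"),
                                  genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  ann <- switch(dialect,
                gene_table_tsv = read_gene_table_tsv(path),
                gff3 = read_gff3(path))
  if (!is.null(genome)) {
    bad <- ann$features$end > genome$length
    if (any(bad))
      stop("feature(s) beyond genome length (", genome$length, " bp): ",
           paste(ann$features$display_name[bad], collapse = ", "))
    ann$genome_id <- genome$id
  }
  ann
}

read_gene_table_tsv <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no feature rows in ", path)
  df <- tryCatch(
    read.delim(text = lines[keep], header = TRUE, sep = "\t", fill = TRUE,
               colClasses = "character", strip.white = TRUE),
    error = function(e) stop("malformed feature table ", path, ": ",
                             conditionMessage(e)))
  req <- c("name", "ftype", "strand", "start5", "stop3")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("gene_table_tsv dialect requires column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("no feature rows in ", path)
  line_no <- which(keep)[-1]  # data lines (header is the first kept line)
  s5 <- suppressWarnings(as.integer(df$start5))
  s3 <- suppressWarnings(as.integer(df$stop3))
  bad <- which(is.na(s5) | is.na(s3) | !nzchar(df$name))
  if (length(bad))
    stop("malformed row at line ", line_no[bad[1]], " of ", path,
         " (name/start5/stop3)")
  features <- data.frame(
    name = df$name, ftype = df$ftype, strand = df$strand,
    start = pmin(s5, s3), end = pmax(s5, s3),
    stringsAsFactors = FALSE)
  if ("declared_length" %in% names(df))
    features$declared_length <- suppressWarnings(as.integer(df$declared_length))
  for (col in c("start_codon", "stop_codon", "anticodon"))
    if (col %in% names(df)) features[[col]] <- df[[col]]
  mito_annotation(features)
}

read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) stop("no features in ", path)
  mc <- S4Vectors::mcols(gr)
  get1 <- function(col, default) {
    if (col %in% names(mc)) as.character(mc[[col]]) else
      rep(default, length(gr))
  }
  strand_chr <- as.character(BiocGenerics::strand(gr))
  if (any(strand_chr == "*"))
    stop("GFF3 features must be stranded (+/-)")
  features <- data.frame(
    name = get1("ID", NA_character_),
    ftype = as.character(mc$type),
    strand = ifelse(strand_chr == "+", "H", "L"),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    start_codon = get1("start_codon", NA_character_),
    stop_codon = get1("stop_codon", NA_character_),
    anticodon = get1("anticodon", NA_character_),
    stringsAsFactors = FALSE)
  dl <- get1("declared_length", NA_character_)
  features$declared_length <- suppressWarnings(as.integer(dl))
  nm <- get1("Name", NA_character_)
  has_nm <- !is.na(nm) & nzchar(nm)
  features$name[has_nm] <- nm[has_nm]
  ann <- mito_annotation(features,
                         genome_id = as.character(GenomeInfoDb::seqnames(gr)[1]))
  ann
}

#' Write an annotation as GFF3
#'
#' GFF3 version 3, 1-based inclusive coordinates; strand H is written `+`,
#' L is written `-`; the feature type column carries the feature class
#' (PCG/tRNA/rRNA) and codon metadata travel as attributes, so that
#' `read_annotation_table(dialect = "gff3")` round-trips every field.
#'
#' @param a A `mito_annotation`.
#' @param path Output file.
#' @export
write_gff3 <- function(a, path) {
  f <- a$features
  gr <- GenomicRanges::GRanges(
    seqnames = ifelse(is.na(a$genome_id), "genome", a$genome_id),
    ranges = IRanges::IRanges(f$start, f$end),
    strand = ifelse(f$strand == "H", "+", "-"))
  S4Vectors::mcols(gr)$type <- f$ftype
  S4Vectors::mcols(gr)$ID <- f$name
  S4Vectors::mcols(gr)$Name <- f$display_name
  S4Vectors::mcols(gr)$declared_length <- f$declared_length
  S4Vectors::mcols(gr)$start_codon <- f$start_codon
  S4Vectors::mcols(gr)$stop_codon <- f$stop_codon
  S4Vectors::mcols(gr)$anticodon <- f$anticodon
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write an annotation in the gene-table (gene_table_tsv) dialect
#'
#' L-strand rows are written in transcription orientation (`start5 > stop3`),
#' mirroring how such tables are printed; reading the file back yields an
#' identical annotation.
#'
#' @param a A `mito_annotation`.
#' @param path Output file.
#' @export
write_feature_table <- function(a, path) {
  f <- a$features
  out <- data.frame(
    name = f$display_name, ftype = f$ftype, strand = f$strand,
    start5 = ifelse(f$strand == "H", f$start, f$end),
    stop3 = ifelse(f$strand == "H", f$end, f$start),
    declared_length = f$declared_length,
    start_codon = f$start_codon, stop_codon = f$stop_codon,
    anticodon = f$anticodon, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Feature length from coordinates
#'
#' `end - start + 1` (1-based inclusive). Printed "length" columns of gene
#' tables are not consulted: coordinates are authoritative (see
#' [validate_annotation()] for the discrepancy report).
#'
#' @param f One or more feature rows (a data.frame with `start`/`end`), or a
#'   `mito_annotation`.
#' @return Integer vector of lengths, named by feature name when available.
#' @examples
#' feature_length(data.frame(start = 4461, end = 5249))  # 789
#' @export
feature_length <- function(f) {
  if (inherits(f, "mito_annotation")) f <- f$features
  len <- f$end - f$start + 1L
  if (!is.null(f$name)) names(len) <- f$name
  len
}

#' Overlap between two features
#'
#' Size of the intersection of the two genomic intervals in bp, 0 if disjoint.
#' Strand-agnostic: the canonical insect-mitogenome overlaps (atp8/atp6 7 bp,
#' nd4/nd4L 1 bp) are same-strand and opposite-strand overlaps also count.
#'
#' @param f1,f2 Single feature rows (data.frames with `start`/`end`).
#' @return Integer overlap in bp.
#' @export
gene_overlap <- function(f1, f2) {
  if (inherits(f1, "mito_annotation") || inherits(f2, "mito_annotation"))
    stop("gene_overlap expects single feature rows; see annotation_overlaps()")
  max(0L, min(f1$end, f2$end) - max(f1$start, f2$start) + 1L)
}

#' All pairwise feature overlaps in an annotation
#'
#' @param a A `mito_annotation`.
#' @param ftypes Feature classes to consider (default protein-coding genes).
#' @return data.frame with columns `name1`, `name2`, `overlap_bp` for all
#'   pairs with positive overlap, ordered by genome position.
#' @export
annotation_overlaps <- function(a, ftypes = "PCG") {
  f <- a$features[a$features$ftype %in% ftypes, , drop = FALSE]
  out <- list()
  if (nrow(f) >= 2L) {
    for (i in seq_len(nrow(f) - 1L)) for (j in (i + 1L):nrow(f)) {
      ov <- gene_overlap(f[i, ], f[j, ])
      if (ov > 0L)
        out[[length(out) + 1L]] <- data.frame(
          name1 = f$name[i], name2 = f$name[j], overlap_bp = ov,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(name1 = character(), name2 = character(),
               overlap_bp = integer(), stringsAsFactors = FALSE)
}

#' Validate an annotation
#'
#' Always returns a report (never throws). Violations: empty feature list,
#' coordinates beyond genome bounds, duplicate names, tRNA lengths outside
#' 40--100 bp. Warnings: declared-length columns that disagree with coordinate
#' arithmetic -- printed gene tables do contain such internal inconsistencies
#' (systematically on L-strand rows written in transcription orientation),
#' and coordinates are treated as authoritative.
#'
#' @param a A `mito_annotation` (or a raw feature data.frame).
#' @param genome Optional `mito_genome` for bound checks.
#' @return An `annotation_report`: data.frame with columns `level`
#'   (`"violation"`/`"warning"`), `check`, `feature`, `message`.
#' @export
validate_annotation <- function(a, genome = NULL) {
  rows <- list()
  add <- function(level, check, feature, message)
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, check = check, feature = feature, message = message,
      stringsAsFactors = FALSE)
  f <- if (inherits(a, "mito_annotation")) a$features else a
  if (is.null(f) || nrow(f) == 0L) {
    add("violation", "no_features", NA_character_, "annotation has no features")
  } else {
    if (anyDuplicated(f$name))
      for (nm in unique(f$name[duplicated(f$name)]))
        add("violation", "duplicate_name", nm, "feature name not unique")
    if (!is.null(genome)) {
      for (i in which(f$end > genome$length | f$start < 1L))
        add("violation", "out_of_bounds", f$name[i],
            sprintf("feature [%d, %d] outside genome [1, %d]",
                    f$start[i], f$end[i], genome$length))
    }
    is_trna <- f$ftype == "tRNA"
    len <- f$end - f$start + 1L
    for (i in which(is_trna & (len < 40L | len > 100L)))
      add("violation", "trna_length", f$name[i],
          sprintf("tRNA length %d bp outside [40, 100]", len[i]))
    has_dl <- !is.na(f$declared_length)
    for (i in which(has_dl & f$declared_length != len))
      add("warning", "declared_length_mismatch", f$name[i],
          sprintf("declared length %d != end - start + 1 = %d (diff %+d)",
                  f$declared_length[i], len[i], f$declared_length[i] - len[i]))
  }
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = character(), check = character(), feature = character(),
               message = character(), stringsAsFactors = FALSE)
  class(rep) <- c("annotation_report", class(rep))
  rep
}

#' @export
print.annotation_report <- function(x, ...) {
  nv <- sum(x$level == "violation"); nw <- sum(x$level == "warning")
  cat(sprintf("<annotation_report> %d violation(s), %d warning(s)\n", nv, nw))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Packaged Maruca vitrata fixtures
#'
#' Accessors for the tables shipped with the package: the gene feature table
#' (34 features of the near-complete *M. vitrata* mitogenome, coordinates in
#' transcription orientation, printed lengths verbatim), the codon usage
#' table (counts and printed RSCU for all 64 codons, plus a corrected count
#' for the internally inconsistent UCA row), and the cistron expression
#' profile (10 EST contigs with lengths, aligned nucleotides, mean depth,
#' read counts and library proportions).
#'
#' @return `read_gene_table_fixture()`: a `mito_annotation`;
#'   `read_codon_usage_fixture()` and `read_expression_fixture()`: data.frames.
#' @export
read_gene_table_fixture <- function() {
  read_annotation_table(
    system.file("extdata", "maruca_gene_table.tsv", package = "mitopunct",
                mustWork = TRUE),
    dialect = "gene_table_tsv")
}

#' @rdname read_gene_table_fixture
#' @export
read_codon_usage_fixture <- function() {
  read.delim(system.file("extdata", "maruca_codon_usage.tsv", package = "mitopunct",
                         mustWork = TRUE),
             comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname read_gene_table_fixture
#' @export
read_expression_fixture <- function() {
  df <- read.delim(system.file("extdata", "maruca_cistron_expression.tsv",
                               package = "mitopunct", mustWork = TRUE),
                   comment.char = "#", stringsAsFactors = FALSE)
  df
}
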