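test_that("gene-table dialect parsing normalises transcription-orientation rows", {
  ann <- maruca_ann()
  f <- ann$features
  expect_s3_class(ann, "mito_annotation")
  expect_equal(nrow(f), 34L)
  expect_equal(as.vector(table(factor(f$ftype, c("PCG", "tRNA", "rRNA")))),
               c(13L, 19L, 2L))
  # H-strand row kept as printed
  cox2 <- f[f$name == "cox2", ]
  expect_equal(c(cox2$start, cox2$end), c(2802L, 3486L))
  expect_equal(cox2$strand, "H")
  expect_equal(cox2$stop_codon, "T")
  # L-strand row printed 5'start > 3'stop is normalised to min/max
  trny <- f[f$name == "trny", ]
  expect_equal(c(trny$start, trny$end), c(1137L, 1199L))
  expect_equal(trny$strand, "L")
  # features come back sorted by start
  expect_true(!is.unsorted(f$start))
})

test_that("malformed and empty feature tables raise parse errors", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("name\tftype\tstrand\tstart5\tstop3", empty)
  expect_error(read_annotation_table(empty, "gene_table_tsv"), "no feature rows")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tftype\tstrand\tstart5\tstop3",
               "nd2\tPCG\tH\t1\t999",
               "cox1\tPCG\tH\toops\t2739"), bad)
  expect_error(read_annotation_table(bad, "gene_table_tsv"), "line 3")
})

test_that("feature lengths follow coordinate arithmetic", {
  ann <- maruca_ann()
  len <- feature_length(ann)
  expect_equal(unname(len[c("cox3", "nd2")]), c(789L, 999L))
  expect_equal(feature_length(data.frame(start = 42, end = 42)), 1L)
  # every H-strand PCG's printed length agrees with its coordinates
  printed <- c(cox1 = 1533, cox2 = 685, atp8 = 162, atp6 = 675, cox3 = 789,
               nd3 = 354, nd6 = 430, cytb = 988, nd2 = 999)
  expect_equal(len[names(printed)], printed,
               ignore_attr = FALSE, tolerance = 0)
})

test_that("gene overlaps match the canonical 7 bp and 1 bp cases", {
  f <- maruca_ann()$features
  g <- function(nm) f[f$name == nm, ]
  expect_equal(gene_overlap(g("atp8"), g("atp6")), 7L)
  expect_equal(gene_overlap(g("nd4l"), g("nd4")), 1L)
  expect_equal(gene_overlap(g("nd3"), g("nd5")), 0L)
  # symmetry and the min-length bound, over every feature pair
  idx <- utils::combn(nrow(f), 2L)
  for (k in sample(ncol(idx), 60L)) {
    a <- f[idx[1, k], ]; b <- f[idx[2, k], ]
    ov <- gene_overlap(a, b)
    expect_identical(ov, gene_overlap(b, a))
    expect_lte(ov, min(feature_length(a), feature_length(b)))
  }
  ovs <- annotation_overlaps(maruca_ann())
  expect_true(all(c(7L, 1L) %in% ovs$overlap_bp))
})

test_that("validation reports length mismatches as warnings, never errors", {
  rep <- validate_annotation(maruca_ann())
  expect_s3_class(rep, "annotation_report")
  expect_equal(sum(rep$level == "violation"), 0L)
  mm <- rep[rep$check == "declared_length_mismatch", ]
  # the four protein/rRNA-adjacent genes known to disagree are all flagged
  expect_true(all(c("nd5", "nd4", "nd4l", "nd1") %in% mm$feature))
  # every mismatch is an L-strand row short by exactly 2 (the table computed
  # end - start - 1 for rows printed in transcription orientation)
  f <- maruca_ann()$features
  expect_true(all(f$strand[match(mm$feature, f$name)] == "L"))
  expect_true(all(grepl("diff -2", mm$message)))
})

test_that("validation flags empty annotations and out-of-bounds features", {
  rep <- validate_annotation(data.frame())
  expect_equal(rep$check, "no_features")
  g <- mito_genome("short", random_dna(500, seed = 1))
  ann <- mito_annotation(data.frame(
    name = "x", ftype = "PCG", strand = "H", start = 400L, end = 700L))
  rep <- validate_annotation(ann, g)
  expect_true("out_of_bounds" %in% rep$check)
  expect_error(read_annotation_table(
    system.file("extdata", "maruca_gene_table.tsv", package = "mitopunct"),
    "gene_table_tsv", genome = g), "beyond genome length")
  # tRNA length bounds
  ann2 <- mito_annotation(data.frame(
    name = "trnq", ftype = "tRNA", strand = "H", start = 1L, end = 200L))
  expect_true("trna_length" %in% validate_annotation(ann2)$check)
})

test_that("feature-table and GFF3 writers round-trip every field", {
  ann <- maruca_ann()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ann, tsv)
  back <- read_annotation_table(tsv, "gene_table_tsv")
  expect_equal(back$features, ann$features)

  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, gff)
  lines <- readLines(gff)
  data_lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  expect_equal(length(data_lines), 34L)
  # L-strand features carry '-' in GFF3 column 7
  trny_line <- data_lines[grepl("ID=trny", data_lines)]
  expect_equal(strsplit(trny_line, "\t")[[1]][7], "-")
  back2 <- read_annotation_table(gff, "gff3")
  expect_equal(back2$features[, c("name", "ftype", "strand", "start", "end",
                                  "declared_length", "start_codon",
                                  "stop_codon")],
               ann$features[, c("name", "ftype", "strand", "start", "end",
                                "declared_length", "start_codon",
                                "stop_codon")])
})

test_that("genome FASTA round-trips through Biostrings", {
  g <- mito_genome("toy", random_dna(333, seed = 5))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, fa)
  back <- read_genome_fasta(fa)
  expect_equal(back$seq, g$seq)
  expect_equal(back$id, "toy")
  expect_equal(back$length, 333L)
})
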