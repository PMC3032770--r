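test_that("read QC applies the length and homopolymer rules", {
  reads <- c(short = random_dna(49, seed = 1),
             homoA = paste0(strrep("A", 61), random_dna(39, at = 0)),
             edge60 = paste0(strrep("T", 30), random_dna(20, at = 0)),
             balanced = strrep("ACGT", 15))
  res <- filter_reads(reads)
  expect_setequal(names(res$kept), "balanced")
  expect_equal(res$rejected$reason[res$rejected$read_id == "short"],
               "too_short")
  expect_equal(res$rejected$reason[res$rejected$read_id == "homoA"],
               "homopolymer")
  # exactly 60% of one base is already rejected
  expect_equal(res$rejected$reason[res$rejected$read_id == "edge60"],
               "homopolymer")
})

test_that("error-free reads map back to their exact source interval", {
  g <- mito_genome("toy", random_dna(2000, seed = 2))
  p <- 511L
  read <- substring(g$seq, p, p + 119L)
  r <- map_read(read, g)
  expect_equal(c(r$g_start, r$g_end), c(p, p + 119L))
  expect_equal(r$strand, "H")
  expect_equal(r$matching_fraction, 1)
  expect_equal(r$aligned_bases, 120L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  r2 <- map_read(rc, g)
  expect_equal(c(r2$g_start, r2$g_end), c(p, p + 119L))
  expect_equal(r2$strand, "L")
})

test_that("seed-and-extend placements equal exhaustive placements on a toy genome", {
  # oracle: exact substring search over both strands (independent of the
  # seeded path); every error-free read must be placed at an oracle position,
  # at the lowest coordinate when several exist
  g <- mito_genome("toy", random_dna(2000, at = 0.8, seed = 3))
  dna <- Biostrings::DNAString(g$seq)
  withr::local_seed(13)
  for (i in 1:50) {
    len <- sample(40:300, 1)
    p <- sample(2000 - len + 1L, 1)
    read <- substring(g$seq, p, p + len - 1L)
    strand <- sample(c("H", "L"), 1)
    if (strand == "L")
      read <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(read)))
    oracle_fwd <- BiocGenerics::start(Biostrings::matchPattern(
      if (strand == "H") read else as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(read))), dna))
    r <- map_read(read, g)
    expect_false(is.null(r))
    expect_equal(r$strand, strand)
    expect_equal(r$matching_fraction, 1)
    expect_equal(r$g_start, min(oracle_fwd))
    expect_equal(r$g_end, min(oracle_fwd) + len - 1L)
  }
})

test_that("reads below the matching thresholds are rejected", {
  g <- mito_genome("toy", random_dna(2000, seed = 4))
  read <- substring(g$seq, 301, 700)
  ch <- strsplit(read, "")[[1]]
  withr::local_seed(5)
  flip <- sample(400, 140)  # 35% substitutions: ~65% identity < 70% threshold
  for (q in flip) ch[q] <- sample(setdiff(c("A", "C", "G", "T"), ch[q]), 1)
  res <- map_reads(stats::setNames(paste(ch, collapse = ""), "noisy"), g)
  expect_equal(nrow(res$alignments), 0L)
  expect_equal(nrow(res$unmapped), 1L)
  # shorter than the seed is reported as such
  res2 <- map_reads(c(tiny = "ACGTACGT"), g)
  expect_equal(res2$unmapped$reason, "shorter_than_seed")
})

test_that("poly(A) detection measures the leading adenine run of the clip", {
  expect_equal(detect_polyA("AAAAAAAA"), 8L)
  expect_equal(detect_polyA(""), 0L)
  expect_equal(detect_polyA("AAAA"), 0L)            # below min_len
  expect_equal(detect_polyA("AAAAAAAAAACAAAAAAAAA"), 20L)  # 1 non-A per 10 ok
  expect_equal(detect_polyA("CCCCCCCC"), 0L)
  expect_equal(detect_polyA("AAAAACCCCCCCCCC"), 5L)
  df <- data.frame(clip3 = c("AAAAAA", ""), stringsAsFactors = FALSE)
  expect_equal(detect_polyA(df)$polyA_len, c(6L, 0L))
})

test_that("reads are assigned to the same-strand cistron they overlap most", {
  cis <- predict_cistrons(maruca_ann())
  aln <- data.frame(
    read_id = c("in_nd3", "junction", "wrong_strand"),
    strand = c("H", "H", "H"),
    g_start = c(5400L, 3700L, 6500L),
    g_end = c(5600L, 3900L, 6800L),
    stringsAsFactors = FALSE)
  got <- assign_to_cistron(aln, cis)
  gl <- cistron_genes(cis)
  expect_equal(gl[[got$cistron_id[1]]], "nd3")
  expect_equal(gl[[got$cistron_id[2]]], c("atp8", "atp6", "cox3"))
  # an H-strand read inside the L-strand nd5 span stays unassigned
  expect_true(is.na(got$cistron_id[3]))
})

test_that("expression arithmetic matches the published depth calculations", {
  prof <- read_expression_fixture()
  expect_equal(round(prof$total_nt[prof$cistron_id == "MvMtD_01"] /
                       prof$contig_length[prof$cistron_id == "MvMtD_01"], 2), 7.58)
  expect_equal(round(prof$total_nt[prof$cistron_id == "MvMtD_04"] /
                       prof$contig_length[prof$cistron_id == "MvMtD_04"], 2), 83.69)
  # expression_table: exact identity mean_depth * length == total_nt
  cis <- predict_cistrons(maruca_ann())
  aln <- data.frame(read_id = c("a", "b", "c"), strand = c("H", "H", "L"),
                    g_start = c(5400L, 5350L, 6500L),
                    g_end = c(5600L, 5470L, 6800L),
                    aligned_bases = c(201L, 121L, 301L),
                    stringsAsFactors = FALSE)
  expr <- expression_table(assign_to_cistron(aln, cis), cis)
  expect_equal(expr$mean_depth * expr$length, expr$total_nt)
  expect_equal(sum(expr$read_count), 3L)
  expect_equal(sum(expr$proportion), 1)
  nd3_row <- expr[grepl("^nd3$", expr$genes), ]
  expect_equal(nd3_row$read_count, 2L)
  expect_equal(nd3_row$total_nt, 322L)
  # a cistron with no assigned reads reports an all-zero row
  expect_true(any(expr$read_count == 0L & expr$total_nt == 0L &
                    expr$mean_depth == 0))
})

test_that("fold differences reproduce the published expression ratios", {
  prof <- read_expression_fixture()
  fd <- fold_differences(prof, list(c("MvMtD_08", "MvMtD_01"),
                                  c("MvMtD_03", "MvMtD_04")))
  expect_equal(round(fd$pair_ratios$fold[1], 2), 11.15)  # nd1 vs nd2
  expect_equal(round(fd$pair_ratios$fold[2], 2), 3.59)   # cox2 vs cox3
  expect_equal(fd$proportion_range, 321, tolerance = 0.01)
  same <- data.frame(cistron_id = c("a", "b"), mean_depth = c(2, 2),
                     proportion = c(0.5, 0.5))
  expect_equal(fold_differences(same, list(c("a", "b")))$pair_ratios$fold, 1)
  zero <- data.frame(cistron_id = c("a", "b"), mean_depth = c(0, 2),
                     proportion = c(0, 1))
  expect_error(fold_differences(zero, list(c("a", "b"))), "zero mean depth")
  rep <- expression_report(prof)
  expect_equal(round(rep$fold_nd1_nd2, 2), 11.15)
  expect_equal(round(rep$fold_cox2_cox3, 2), 3.59)
  expect_equal(rep$n_multigene, 3L)
})

test_that("poly(A)-completed stop codons are verified from mapped reads", {
  world <- toy_truncated_stop_world()
  tspec <- transcriptome_spec(
    abundances = NULL, n_reads = 150L, seed = 3L,
    read_length = function(n) pmin(pmax(round(rnorm(n, 150, 30)), 60L), 250L),
    error_rates = c(substitution = 0.01, insertion = 0.002,
                    deletion = 0.002, homopolymer_extension = 0.01))
  sim <- simulate_reads(c(toy_tx = world$transcript),
                        tspec, weights = c(toy_tx = 1))
  mp <- map_reads(sim$reads, world$genome)
  cis <- punctuate(world$annotation, "H")
  asg <- assign_to_cistron(detect_polyA(mp$alignments), cis)
  v <- verify_stop_completion(world$annotation, asg, world$genome, cis)
  expect_equal(v$status[v$gene == "cox2like"], "confirmed")
  expect_gt(v$n_support[v$gene == "cox2like"], 0L)
  # >95% of 3'-terminal reads (reaching the last 5 nt) carry a poly(A) clip
  tail_reads <- sim$truth$read_id[sim$truth$tr_end >=
                                    nchar(world$transcript) - 5L]
  aln_t <- detect_polyA(mp$alignments)
  covered <- aln_t[aln_t$read_id %in% tail_reads, ]
  expect_gt(nrow(covered), 0L)
  expect_gt(mean(covered$polyA_len > 0L), 0.95)
})

test_that("a genomic full stop confirms without tails; non-A tails never do", {
  world <- toy_truncated_stop_world()
  # same locus but with the PCG re-annotated to a frame-aligned genomic TAA
  f <- world$annotation$features
  f$end[f$name == "cox2like"] <- f$end[f$name == "cox2like"] - 1L
  g2 <- world$genome
  # splice a TAA onto the (now length-divisible-by-3) CDS end
  chars <- strsplit(g2$seq, "")[[1]]
  e <- f$end[f$name == "cox2like"]
  chars[(e - 2):e] <- c("T", "A", "A")
  g2 <- mito_genome(g2$id, paste(chars, collapse = ""))
  ann2 <- mito_annotation(f)
  v <- verify_stop_completion(ann2, data.frame(
    read_id = character(), strand = character(), g_start = integer(),
    g_end = integer(), clip3 = character(), stringsAsFactors = FALSE),
    g2, cistrons = NULL)
  expect_equal(v$status[v$gene == "cox2like"], "confirmed")
  # C-tails covering the truncated terminus: unconfirmed, not inconclusive
  aln <- data.frame(read_id = "ctail", strand = "H",
                    g_start = world$cds_end - 100L, g_end = world$cds_end,
                    clip3 = strrep("C", 15L), stringsAsFactors = FALSE)
  v2 <- verify_stop_completion(world$annotation, aln, world$genome, NULL)
  expect_equal(v2$status[v2$gene == "cox2like"], "unconfirmed")
})

test_that("majority-vote consensus recovers the genomic span", {
  g <- mito_genome("toy", random_dna(1200, seed = 6))
  ann <- toy_flanked_annotation()
  cis <- punctuate(ann, "H")
  # error-free tiling reads
  starts <- seq(80L, 450L, by = 30L)
  reads <- stats::setNames(substring(g$seq, starts, starts + 120L),
                           paste0("r", seq_along(starts)))
  asg <- assign_to_cistron(map_reads(reads, g)$alignments, cis)
  cons <- build_consensus(asg, g, cis[1, ])
  span <- substring(g$seq, cis$start[1], cis$end[1])
  expect_equal(toupper(cons), span)
  # covered positions uppercase, uncovered lowercase genome base
  expect_true(any(grepl("[acgt]", strsplit(cons, "")[[1]])))
  expect_equal(nchar(cons), cis$end[1] - cis$start[1] + 1L)
  # a single read: consensus equals that read over its span
  one <- asg[1, , drop = FALSE]
  cons1 <- build_consensus(one, g, cis[1, ])
  seg <- substring(cons1, one$g_start - cis$start[1] + 1L,
                   one$g_end - cis$start[1] + 1L)
  expect_equal(seg, substring(g$seq, one$g_start, one$g_end))
  # 1% substitution errors at depth >= 10 still vote the genome base
  withr::local_seed(17)
  noisy <- character(0)
  for (j in 1:60) {
    p <- 101L + ((j - 1L) %% 12L) * 30L
    seg <- strsplit(substring(g$seq, p, p + 99L), "")[[1]]
    flips <- which(runif(100) < 0.01)
    for (q in flips) seg[q] <- sample(setdiff(c("A", "C", "G", "T"), seg[q]), 1)
    noisy[paste0("n", j)] <- paste(seg, collapse = "")
  }
  asg2 <- assign_to_cistron(map_reads(noisy, g)$alignments, cis)
  cons2 <- build_consensus(asg2, g, cis[1, ])
  hi <- min(cis$end[1], 431L + 99L)   # last covered position inside the span
  covered <- substring(cons2, 101L - cis$start[1] + 1L,
                       hi - cis$start[1] + 1L)
  expect_equal(covered, substring(g$seq, 101L, hi))
})

test_that("SAM output carries clips as S operations and valid layout", {
  g <- mito_genome("toy", random_dna(800, seed = 7))
  read <- paste0(substring(g$seq, 101, 250), strrep("A", 12))
  mp <- map_reads(c(r1 = read), g)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(mp$alignments, c(r1 = read), g, sam)
  lines <- readLines(sam)
  expect_true(startsWith(lines[1], "@HD"))
  expect_true(grepl("LN:800", lines[2]))
  fields <- strsplit(lines[3], "\t")[[1]]
  expect_equal(fields[1], "r1")
  expect_equal(as.integer(fields[4]), 101L)
  expect_match(fields[6], "S")           # the poly(A) clip is soft-clipped
  expect_equal(nchar(fields[10]), 162L)
})
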