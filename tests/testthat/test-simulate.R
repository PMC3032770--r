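test_that("the default genome spec reproduces the packaged gene geometry", {
  gs <- genome_spec_maruca(seed = 2)
  gen <- generate_genome(gs)
  ref <- maruca_ann()$features
  f <- gen$annotation$features
  expect_equal(nrow(f), 34L)
  expect_equal(sum(f$ftype == "tRNA"), 19L)
  expect_equal(f$name, ref$name)
  expect_equal(f$start, ref$start)
  expect_equal(f$end, ref$end)
  expect_equal(f$strand, ref$strand)
  expect_equal(gen$genome$length, max(ref$end))
  # realized PCG codons: valid initiators, frame-consistent terminators
  code <- invertebrate_mito_code()
  expect_true(all(gen$truth$start_codon %in% code$start_codons))
  expect_true(all(ifelse(gen$truth$frame_remainder == 1L,
                         gen$truth$stop_codon == "T",
                         ifelse(gen$truth$frame_remainder == 2L,
                                gen$truth$stop_codon == "TA",
                                gen$truth$stop_codon %in% c("TAA", "TAG")))))
})

test_that("generated genomes hit the AT target within binomial noise", {
  gen <- generate_genome(genome_spec_maruca(seed = 3))
  at <- at_composition(gen$genome$seq)$at_fraction
  sd3 <- 3 * sqrt(0.8 * 0.2 / gen$genome$length)
  expect_lt(abs(at - 0.8), sd3)
  # third codon positions are more AT-rich than first/second
  pcg <- gen$annotation$features[gen$annotation$features$ftype == "PCG", ]
  cds <- vapply(seq_len(nrow(pcg)), function(i)
    gene_sequence(gen$genome, pcg[i, ]), character(1))
  cds3 <- substring(cds, 1L, (nchar(cds) %/% 3L) * 3L)
  cs <- at_composition(cds3)
  expect_gt(cs$at_by_codon_position[3], cs$at_by_codon_position[1] + 0.1)
  expect_gt(cs$at_by_codon_position[3], 0.9)
})

test_that("generated coding interiors are free of in-frame stop codons", {
  gen <- generate_genome(genome_spec_maruca(seed = 4))
  pcg <- gen$annotation$features[gen$annotation$features$ftype == "PCG", ]
  for (i in seq_len(nrow(pcg))) {
    cds <- gene_sequence(gen$genome, pcg[i, ])
    r <- nchar(cds) %% 3L
    interior <- substring(cds, 4L, nchar(cds) - (if (r == 0L) 3L else r))
    codons <- substring(interior, seq(1, nchar(interior) - 2, 3),
                        seq(3, nchar(interior), 3))
    expect_false(any(codons %in% c("TAA", "TAG")),
                 label = paste("stop inside", pcg$name[i]))
  }
})

test_that("genome generation is deterministic under its seed", {
  g1 <- generate_genome(genome_spec_maruca(seed = 5))
  g2 <- generate_genome(genome_spec_maruca(seed = 5))
  g3 <- generate_genome(genome_spec_maruca(seed = 6))
  expect_identical(g1$genome$seq, g2$genome$seq)
  expect_false(identical(g1$genome$seq, g3$genome$seq))
})

test_that("coordinates can be laid out from gene order, gaps and overlaps", {
  go <- data.frame(name = c("trnA1", "g1", "g2", "trnB1"),
                   ftype = c("tRNA", "PCG", "PCG", "tRNA"),
                   strand = "H", length = c(65L, 300L, 210L, 68L),
                   stringsAsFactors = FALSE)
  spec <- genome_spec(go, intergenic_gaps = c(2L, -7L, 0L), seed = 1)
  f <- spec$annotation$features
  expect_equal(f$start, c(1L, 68L, 361L, 571L))
  expect_equal(f$end, c(65L, 367L, 570L, 638L))
  expect_equal(gene_overlap(f[2, ], f[3, ]), 7L)
  gen <- generate_genome(spec)
  expect_equal(gen$genome$length, 638L)
  expect_error(genome_spec(go, intergenic_gaps = c(2L, -250L, 0L)),
               "infeasible overlap")
})

test_that("the default transcriptome has the ten observed species", {
  gen <- generate_genome(genome_spec_maruca(seed = 7))
  tx <- generate_transcripts(gen$genome, gen$annotation,
                             transcriptome_spec(seed = 7))
  expect_equal(length(tx$transcripts), 10L)
  expect_equal(nrow(tx$truth), 10L)
  # the nd3 monocistron is predicted but carries zero weight, hence absent
  gl <- cistron_genes(tx$cistrons)
  nd3_id <- names(gl)[vapply(gl, identical, logical(1), y = "nd3")]
  expect_false(nd3_id %in% tx$truth$cistron_id)
  # poly(A) only on the cox2 and atp8/atp6/cox3 transcripts
  tailed <- tx$truth$cistron_id[tx$truth$polyA_len > 0L]
  carriers <- vapply(tailed, function(id) paste(gl[[id]], collapse = ","),
                     character(1))
  expect_setequal(unname(carriers), c("cox2", "atp8,atp6,cox3"))
  # a tricistronic transcript contains its three genes in order
  tri_id <- names(gl)[vapply(gl, function(g)
    identical(g, c("atp8", "atp6", "cox3")), logical(1))]
  tri <- tx$transcripts[[tri_id]]
  f <- gen$annotation$features
  pos <- vapply(c("atp8", "atp6", "cox3"), function(nm)
    regexpr(gene_sequence(gen$genome, f[f$name == nm, ]), tri,
            fixed = TRUE)[[1]], numeric(1))
  expect_true(all(pos > 0))
  expect_true(all(diff(pos) > 0))
})

test_that("poly(A) probability zero appends no tails", {
  gen <- generate_genome(genome_spec_maruca(seed = 8))
  tx <- generate_transcripts(gen$genome, gen$annotation,
                             transcriptome_spec(polyA = c(none = 0), seed = 8))
  expect_true(all(tx$truth$polyA_len == 0L))
  expect_equal(nchar(tx$transcripts), stats::setNames(tx$truth$span_length,
                                                      tx$truth$cistron_id))
})

test_that("error-free reads are exact transcript substrings", {
  gen <- generate_genome(genome_spec_maruca(seed = 9))
  tsp <- transcriptome_spec(n_reads = 300L, seed = 9,
                            error_rates = c(substitution = 0, insertion = 0,
                                            deletion = 0,
                                            homopolymer_extension = 0))
  tx <- generate_transcripts(gen$genome, gen$annotation, tsp)
  sim <- simulate_reads(tx, tsp)
  expect_equal(length(sim$reads), 300L)
  for (i in seq_len(50)) {
    tr <- tx$transcripts[[sim$truth$cistron_id[i]]]
    expect_equal(sim$reads[[i]],
                 substring(tr, sim$truth$tr_start[i], sim$truth$tr_end[i]))
  }
})

test_that("per-species read counts follow the multinomial weights", {
  gen <- generate_genome(genome_spec_maruca(seed = 10))
  tsp <- transcriptome_spec(n_reads = 7608L, seed = 10)
  tx <- generate_transcripts(gen$genome, gen$annotation, tsp)
  sim <- simulate_reads(tx, tsp)
  w <- tx$truth$weight / sum(tx$truth$weight)
  names(w) <- tx$truth$cistron_id
  counts <- table(factor(sim$truth$cistron_id, names(w)))
  for (id in names(w)) {
    expe <- 7608 * w[[id]]
    sd3 <- 3 * sqrt(7608 * w[[id]] * (1 - w[[id]]))
    expect_lt(abs(counts[[id]] - expe), max(sd3, 1))
  }
})

test_that("read simulation and FASTQ output are seed-deterministic", {
  gen <- generate_genome(genome_spec_maruca(seed = 11))
  tsp <- transcriptome_spec(n_reads = 50L, seed = 11)
  tx <- generate_transcripts(gen$genome, gen$annotation, tsp)
  s1 <- simulate_reads(tx, tsp)
  s2 <- simulate_reads(tx, tsp)
  expect_identical(s1$reads, s2$reads)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(s1$reads, f1)
  write_reads_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(read_reads_fastq(f1), s1$reads)
})
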