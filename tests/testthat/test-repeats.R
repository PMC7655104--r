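test_that("pseudo-chromosome length follows the flank/spacer arithmetic", {
  # 1000 bp contig; interior instances of 100 bp and 200 bp
  set.seed(1)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                 collapse = "")))
  ann <- data.frame(repeat_type = "R1", chrom = "chr1",
                    start = c(100, 500), end = c(200, 700), strand = "+")
  asm <- build_repeat_assembly(genome, ann)
  # (100+150) + 150 + (200+150) = 750
  expect_equal(nchar(as.character(asm$sequences[["R1"]])), 750L)
  expect_equal(asm$index$offset_start, c(0L, 400L))
  # the spacer is all N
  spacer <- substr(as.character(asm$sequences[["R1"]]), 251, 400)
  expect_equal(spacer, strrep("N", 150))
})

test_that("flanks are clipped at contig boundaries and logged", {
  set.seed(2)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")))
  ann <- data.frame(repeat_type = "edge", chrom = "chr1",
                    start = 0, end = 100, strand = "+")
  asm <- build_repeat_assembly(genome, ann)
  expect_equal(nchar(as.character(asm$sequences[["edge"]])), 175L)
  expect_equal(asm$index$clip_left, 75L)
  expect_equal(asm$index$clip_right, 0L)

  expect_error(build_repeat_assembly(genome,
    data.frame(repeat_type = "x", chrom = "nope", start = 0, end = 10,
               strand = "+")), "unknown contig")
  expect_error(build_repeat_assembly(genome,
    data.frame(repeat_type = "x", chrom = "chr1", start = 250, end = 400,
               strand = "+")), "outside contig")
})

test_that("indexed slices minus flanks round-trip to the planted genome sequence", {
  catalog <- data.frame(repeat_type = c("roo", "(AC)n"),
                        length = c(120, 60), n_instances = c(3, 2))
  sim <- simulate_repeat_genome(catalog, n_contigs = 2, contig_length = 3000,
                                seed = 4)
  asm <- build_repeat_assembly(sim$genome, sim$annotations)
  for (r in seq_len(nrow(asm$index))) {
    ix <- asm$index[r, ]
    pseudo <- as.character(asm$sequences[[ix$repeat_type]])
    slice <- substr(pseudo, ix$offset_start + 1L, ix$offset_end)
    core <- substr(slice, 75 - ix$clip_left + 1L,
                   nchar(slice) - (75 - ix$clip_right))
    planted <- sim$ledger$sequence[sim$ledger$start == ix$start &
                                   sim$ledger$chrom == ix$chrom]
    expect_equal(core, planted)
  }
  # length-formula invariant across all pseudo-chromosomes
  for (rt in unique(asm$index$repeat_type)) {
    ix <- asm$index[asm$index$repeat_type == rt, ]
    expected <- sum(ix$end - ix$start + 2L * 75L - ix$clip_left - ix$clip_right) +
      (nrow(ix) - 1L) * 150L
    expect_equal(nchar(as.character(asm$sequences[[rt]])), expected)
  }
})

test_that("annotation dialects (.out and TSV) parse to identical coordinates", {
  catalog <- data.frame(repeat_type = c("jockey", "(GT)n"),
                        length = c(90, 40), n_instances = c(2, 2))
  sim <- simulate_repeat_genome(catalog, seed = 9, contig_length = 2000)
  dir <- tempfile()
  paths <- write_repeat_genome(sim, dir)
  tsv <- read_repeat_annotations(paths[["tsv"]], format = "tsv")
  rmout <- read_repeat_annotations(paths[["rmout"]], format = "rmout")
  expect_equal(tsv, rmout, ignore_attr = TRUE)
  expect_equal(tsv$start, sim$ledger$start)
  expect_equal(tsv$end, sim$ledger$end)
})

test_that("reverse-complement simple repeats merge to a canonical motif", {
  expect_equal(merge_revcomp_simple_repeats(c("(AC)n" = 10, "(GT)n" = 5)),
               c("(AC)n" = 15))
  # rotation + reverse complement: (AAT)n and (ATT)n are one array
  m <- merge_revcomp_simple_repeats(c("(AAT)n" = 4, "(ATT)n" = 6))
  expect_equal(length(m), 1L)
  expect_equal(unname(m), 10)
  expect_equal(merge_revcomp_simple_repeats(c(roo = 7)), c(roo = 7))
  # idempotent and order-insensitive totals
  x <- c("(AC)n" = 10, "(GT)n" = 5, roo = 7, "(AAT)n" = 1)
  once <- merge_revcomp_simple_repeats(x)
  expect_equal(merge_revcomp_simple_repeats(once), once)
  expect_equal(sum(merge_revcomp_simple_repeats(rev(x))), sum(once))
})

test_that("counts normalize to counts-per-million and preserve shape", {
  expect_equal(normalize_counts(500, 2.5e6), 200)
  expect_equal(normalize_counts(0, 1e6), 0)
  v <- c(a = 10, b = 0, c = 55)
  out <- normalize_counts(v, 1e7)
  expect_equal(names(out), names(v))
  expect_equal(unname(out), c(1, 0, 5.5))
  expect_error(normalize_counts(5, 0), "positive")
})
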