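test_that("FASTA round-trip preserves sequences, roles and ingroup order", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1|ingroup", "ATGAAA", ">s2|ingroup", "ATGAAA",
               ">s3|ingroup", "ATGAAA", ">sim|sister", "ATGAAA"), fa)
  aln <- read_alignment(fa)
  expect_s3_class(aln, "PopulationAlignment")
  expect_equal(aln$length, 6L)
  expect_equal(length(aln$ingroup), 3L)
  expect_equal(names(aln$ingroup), c("s1", "s2", "s3"))
  expect_null(aln$outgroup)

  out <- tempfile(fileext = ".fa")
  write_alignment(aln, out)
  back <- read_alignment(out)
  expect_equal(unname(back$ingroup), unname(aln$ingroup))
  expect_equal(back$sister, aln$sister)
})

test_that("malformed alignments are rejected with informative errors", {
  expect_error(make_aln(c("ATGAAA", "ATG"), "ATGAAA"), "ragged")
  expect_error(make_aln(c("ATGA", "ATGA"), "ATGA"), "divisible by 3")
  expect_error(make_aln(c("ATGXAA", "ATGXAA"), "ATGAAA"), "illegal")
  # internal stop in the major-allele sequence, named by codon index
  expect_error(make_aln(c("ATGTAAAAA", "ATGTAAAAA", "ATGCAAAAA"), "ATGCAAAAA"),
               "codon 2")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a|ingroup", "ATGAAA", ">b|ingroup", "ATGAAA"), fa)
  expect_error(read_alignment(fa), "sister")
})

test_that("low-frequency masking is strict-below-threshold and reports sites", {
  # 40 haplotypes, one singleton (freq 0.025 < 0.05): masked
  ing <- rep("AAA", 40); ing[1] <- "AAG"
  aln <- make_aln(ing, "AAA")
  f <- filter_low_frequency_variants(aln, 0.05)
  expect_true(all(f$ingroup == "AAA"))
  rep_tab <- attr(f, "masked_sites")
  expect_equal(rep_tab$site, 3L)
  expect_equal(rep_tab$allele, "G")
  expect_equal(rep_tab$freq, 0.025)

  # 20 haplotypes, count 1 = freq 0.05: retained (strict "<")
  ing20 <- rep("AAA", 20); ing20[1] <- "AAG"
  f20 <- filter_low_frequency_variants(make_aln(ing20, "AAA"), 0.05)
  expect_equal(sum(f20$ingroup == "AAG"), 1L)
  expect_equal(nrow(attr(f20, "masked_sites")), 0L)

  # threshold 0 is the identity
  f0 <- filter_low_frequency_variants(make_aln(ing, "AAA"), 0)
  expect_equal(f0$ingroup, aln$ingroup)
})

test_that("masking never increases the number of segregating sites", {
  set.seed(42)
  n_seg <- function(a) {
    m <- do.call(rbind, strsplit(a$ingroup, ""))
    sum(apply(m, 2L, function(col) length(unique(col[col %in% c("A","C","G","T")])) > 1L))
  }
  for (rep in 1:10) {
    sim <- simulate_gene_history(simulation_config(
      seed = rep, n_codons = 50, n_ingroup = 25,
      poly = c(nonsyn = 5, syn = 5), poly_low = c(nonsyn = 2, syn = 2),
      d_focal = c(nonsyn = 2, syn = 2), d_sister = c(nonsyn = 2, syn = 2),
      d_outgroup = c(nonsyn = 1, syn = 1)))
    aln <- sim$alignment
    filt <- filter_low_frequency_variants(aln, 0.05)
    expect_lte(n_seg(filt), n_seg(aln))
  }
})

test_that("major-allele profile follows majority, alphabetical ties and missing data", {
  aln <- make_aln(c("AAA", "AAA", "AAG"), "AAA")
  cons <- major_allele_profile(aln)
  expect_equal(cons$sequence, "AAA")
  expect_equal(cons$frequency, c(1, 1, 2 / 3))

  tie <- make_aln(c("AAA", "GAA"), "AAA")
  expect_equal(substr(major_allele_profile(tie)$sequence, 1, 1), "A")

  gap <- make_aln(c("AA-", "AA-"), "AAA", validate = FALSE)
  cons_gap <- major_allele_profile(gap)
  expect_equal(substr(cons_gap$sequence, 3, 3), "N")
  expect_equal(cons_gap$frequency[3], 0)
})

test_that("domain extraction slices all roles and partitions reconstruct the gene", {
  aln <- make_aln(c("ATGAAACCCGGG", "ATGAAACCCGGG"), "ATGAAACCAGGG",
                  outgroup = "ATGAAACCCGGG")
  full <- extract_domain(aln, domain_span("all", 1, 4))
  expect_equal(unname(full$ingroup), unname(aln$ingroup))
  expect_equal(full$sister, aln$sister)

  mid <- extract_domain(aln, domain_span("mid", 2, 3))
  expect_equal(unname(mid$ingroup[1]), "AAACCC")
  expect_equal(mid$sister, "AAACCA")
  expect_equal(mid$outgroup, "AAACCC")
  expect_error(extract_domain(aln, domain_span("oops", 3, 5)), "out of range")

  # concatenating a complete partition reproduces the alignment
  parts <- list(domain_span("a", 1, 1), domain_span("b", 2, 3),
                domain_span("c", 4, 4))
  glued <- sapply(seq_along(aln$ingroup), function(i)
    paste(vapply(parts, function(p) extract_domain(aln, p)$ingroup[[i]],
                 character(1)), collapse = ""))
  expect_equal(unname(glued), unname(aln$ingroup))
})

test_that("domain spans at study-table scale carry the expected codon counts", {
  # a 448-codon gene partitioned into ZAD (71), linker (216), C2H2 (136)
  spans <- list(domain_span("ZAD", 1, 71), domain_span("linker", 72, 287),
                domain_span("C2H2", 288, 423))
  widths <- vapply(spans, function(s) s$end_codon - s$start_codon + 1L, integer(1))
  expect_equal(widths, c(71L, 216L, 136L))
  sim <- simulate_gene_history(simulation_config(seed = 7, n_codons = 448,
                                                 n_ingroup = 10))
  for (k in seq_along(spans))
    expect_equal(extract_domain(sim$alignment, spans[[k]])$length / 3, widths[k])
})

test_that("overlapping domain spans in a TSV are rejected", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tdomain\tstart_codon\tend_codon",
               "g\tZAD\t1\t70", "g\tlinker\t60\t200"), tsv)
  expect_error(read_domain_spans(tsv), "overlap")
  writeLines(c("gene\tdomain\tstart_codon\tend_codon",
               "g\tZAD\t1\t70", "g\tlinker\t71\t200"), tsv)
  spans <- read_domain_spans(tsv)
  expect_equal(vapply(spans, `[[`, character(1), "name"), c("ZAD", "linker"))
})
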