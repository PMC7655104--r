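test_that("polymorphisms are classified against the major-allele codon", {
  # AAA x3 + AAG: Lys -> Lys, synonymous
  p <- count_polymorphisms(make_aln(c("AAA", "AAA", "AAA", "AAG"), "AAA"))
  expect_equal(c(p$Pn, p$Ps), c(0L, 1L))

  # GAT x2 / GCT x2: Asp -> Ala (major allele GAT by A<C tie at site 2)
  p <- count_polymorphisms(make_aln(c("GAT", "GAT", "GCT", "GCT"), "GAT"))
  expect_equal(c(p$Pn, p$Ps), c(1L, 0L))

  # two segregating sites in one codon, classified one change at a time
  p <- count_polymorphisms(make_aln(c("AAA", "AAA", "AAG", "CAA"), "AAA"))
  expect_equal(c(p$Pn, p$Ps), c(1L, 1L))
  expect_setequal(p$ledger$class, c("nonsyn", "syn"))

  # a triallelic site yields two polymorphisms
  p <- count_polymorphisms(make_aln(c("AAA", "AAA", "AAT", "AAG"), "AAA"))
  expect_equal(p$Pn + p$Ps, 2L)
})

test_that("fixed differences require ingroup monomorphism and differ from sister", {
  # simple synonymous fixed difference
  d <- count_divergence(make_aln(c("TTA", "TTA"), "TTG"))
  expect_equal(c(d$Dn, d$Ds), c(0, 1))

  # two differences in one codon: fractional pathway average
  d <- count_divergence(make_aln(c("CCT", "CCT"), "CAA"))
  expect_equal(c(d$Dn, d$Ds), c(1.5, 0.5))

  # shared polymorphism: sister carries one of the segregating alleles
  d <- count_divergence(make_aln(c("AAA", "GAA"), "GAA"))
  expect_equal(c(d$Dn, d$Ds), c(0, 0))

  # sister third allele at a polymorphic site still contributes nothing
  d <- count_divergence(make_aln(c("AAA", "GAA"), "CAA"))
  expect_equal(c(d$Dn, d$Ds), c(0, 0))

  # missing data in the sister skips the codon and logs it
  d <- count_divergence(make_aln(c("TTAAAA", "TTAAAA"), "TTGAN-", validate = FALSE))
  expect_equal(c(d$Dn, d$Ds), c(0, 1))
  expect_equal(d$skipped_codons, 2L)
})

test_that("polarization assigns fixed differences by outgroup parsimony", {
  # focal A, sister G, outgroup G: change on the focal lineage
  pol <- polarize(make_aln(c("AAA", "AAA"), "GAA", outgroup = "GAA"))
  expect_equal(pol$focal$Dn + pol$focal$Ds, 1)
  expect_equal(pol$sister$Dn + pol$sister$Ds, 0)
  expect_equal(pol$ledger$lineage, "focal")

  # focal A, sister G, outgroup A: change on the sister lineage
  pol <- polarize(make_aln(c("AAA", "AAA"), "GAA", outgroup = "AAA"))
  expect_equal(pol$sister$Dn + pol$sister$Ds, 1)
  expect_equal(pol$ledger$lineage, "sister")

  # three distinct alleles: ambiguous, excluded from both lineages
  pol <- polarize(make_aln(c("AAA", "AAA"), "GAA", outgroup = "CAA"))
  expect_equal(pol$focal$Dn + pol$focal$Ds + pol$sister$Dn + pol$sister$Ds, 0)
  expect_equal(pol$ambiguous_dn + pol$ambiguous_ds, 1)

  # outgroup missing at the site: ambiguous
  pol <- polarize(make_aln(c("AAA", "AAA"), "GAA", outgroup = "NAA"))
  expect_equal(pol$ledger$lineage, "ambiguous")

  expect_error(polarize(make_aln(c("AAA", "AAA"), "GAA")), "outgroup")
})

test_that("polarized counts plus ambiguous equal unpolarized on simulated genes", {
  for (seed in 1:5) {
    sim <- simulate_gene_history(simulation_config(
      seed = seed, n_codons = 80, n_ingroup = 20,
      d_focal = c(nonsyn = 6, syn = 4), d_sister = c(nonsyn = 5, syn = 5),
      d_outgroup = c(nonsyn = 8, syn = 8), poly = c(nonsyn = 4, syn = 4),
      multi_hit = TRUE))   # multi-hit codons stress the additivity bookkeeping
    pol <- polarize(sim$alignment)
    expect_equal(pol$focal$Dn + pol$sister$Dn + pol$ambiguous_dn,
                 pol$unpolarized$Dn)
    expect_equal(pol$focal$Ds + pol$sister$Ds + pol$ambiguous_ds,
                 pol$unpolarized$Ds)
  }
})

test_that("run_mk ties the components together deterministically", {
  # planted history mirroring a strongly selected full-length gene:
  # focal 17/8 and sister 26/16 fixed differences, 14/20 polymorphisms
  sim <- simulate_gene_history(simulation_config(seed = 11))
  res <- run_mk(sim$alignment)
  r <- res[[1]]
  expect_equal(unname(r$counts), c(43, 24, 14, 20), ignore_attr = TRUE)
  expect_equal(unlist(r$polarized$focal), c(Dn = 17, Ds = 8))
  expect_equal(unlist(r$polarized$sister), c(Dn = 26, Ds = 16))
  # the polarized NI matches the published convention: Pn/Ps over focal Dn/Ds
  expect_equal(round(r$polarized$NI, 3), 0.329)
  # identical rerun: determinism
  res2 <- run_mk(simulate_gene_history(simulation_config(seed = 11))$alignment)
  expect_identical(as.data.frame(res), as.data.frame(res2))

  # no variation anywhere: zero counts, undefined NI, uninformative p
  null_aln <- make_aln(c("ATGAAA", "ATGAAA"), "ATGAAA", outgroup = "ATGAAA")
  rn <- run_mk(null_aln)[[1]]
  expect_equal(unname(rn$counts), c(0, 0, 0, 0), ignore_attr = TRUE)
  expect_true(is.na(rn$NI) || rn$NI == 0)
  expect_equal(rn$p_fisher, 1, ignore_attr = TRUE)
})

test_that("per-domain counts sum to the full-length counts over a complete partition", {
  sim <- simulate_gene_history(simulation_config(
    seed = 5, n_codons = 120, n_ingroup = 30,
    d_focal = c(nonsyn = 8, syn = 6), d_sister = c(nonsyn = 8, syn = 6),
    d_outgroup = c(nonsyn = 6, syn = 6), poly = c(nonsyn = 8, syn = 10)))
  spans <- list(domain_span("d1", 1, 40), domain_span("d2", 41, 90),
                domain_span("d3", 91, 120))
  res <- run_mk(sim$alignment, domains = spans)
  full <- res[[1]]$counts_fractional
  parts <- Reduce(`+`, lapply(res[-1], `[[`, "counts_fractional"))
  expect_equal(parts, full)
})
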