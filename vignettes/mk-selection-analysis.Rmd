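---
title: "Methods: codon-aware MK tests, gene turnover and repeat references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-aware MK tests, gene turnover and repeat references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynasel)
```

This vignette documents the statistical model behind `dynasel`, the
conventions and tunable parameters that affect its numbers, the design
choices we made where the methodology is genuinely underdetermined, and
what the simulation-based tests do and do not demonstrate about real data.

## The McDonald–Kreitman framework

The MK test contrasts two ratios estimated from a codon alignment of many
haplotypes of a focal species (here modelled on population resequencing of
hundreds of *D. melanogaster* strains), one sister-species reference
(*D. simulans*-like) and optionally one outgroup (*D. yakuba*-like):

* **Polymorphism** (Pn : Ps): non-synonymous vs synonymous variants
  segregating within the focal sample.
* **Divergence** (Dn : Ds): non-synonymous vs synonymous differences fixed
  between the focal sample and the sister reference.

Under strict neutrality, both ratios estimate the same underlying ratio of
mutational target sizes, so the 2×2 table (Dn, Ds / Pn, Ps) is homogeneous.
An excess of Dn signals adaptive fixation; the neutrality index
NI = (Pn/Ps)/(Dn/Ds) summarizes the direction, with NI < 1 indicating
positive selection. The test assumes sites are independent, that
polymorphism and divergence were accumulated under comparable mutation
processes, and that segregating slightly-deleterious variants have been
dealt with — which is what the frequency filter below is for.

## Conventions that determine the counts

**Minor-allele filter.** `filter_low_frequency_variants()` masks, at every
site, any allele whose frequency among *non-missing* ingroup alleles is
strictly below the threshold (default 0.05), replacing it with the site's
major allele. We mask rather than delete columns so coordinates are
preserved and a masked site can still yield a fixed difference; this
matches common MK-server preprocessing, but since upstream descriptions of
such filters rarely say whether sites were removed or alleles masked (nor
the denominator under missing data), absolute Pn/Ps counts from raw
population data can differ slightly between implementations. The boundary
is strict: a variant at exactly the threshold frequency is retained.

**Major-allele background.** The consensus used as the polymorphism
background and as the ingroup sequence for divergence is the per-site major
allele among non-missing ingroup bases, with ties broken alphabetically
(A < C < G < T) — deterministic and documented rather than random.
All-missing sites become `N` and their codons are skipped and logged.

**Polymorphism counting.** Within a codon, each segregating allele is
classified as a single nucleotide step from the major-allele codon; a
triallelic site therefore contributes two polymorphisms. This single-step
convention is standard but approximate when two minor alleles co-occur on
one haplotype; at realistic polymorphism densities the approximation is
negligible.

**Fixed differences and pathway averaging.** A site is a fixed difference
only if the (filtered) ingroup is monomorphic there and differs from the
sister base; a sister allele that matches one segregating ingroup allele,
or a third allele at a polymorphic site, contributes nothing. Codons with
several fixed differences are scored by `codon_change_paths()`: all
orderings of the differing positions are enumerated, orderings passing
through a stop codon are discarded, each step is classified against the
genetic code, and Dn/Ds are averaged over the admissible orderings
(Nei–Gojobori convention). Fractional counts are kept internally; reported
tables round half away from zero, which is how published MK tables print
integer counts.

**Polarization.** With an outgroup, each fixed-difference site is assigned
by parsimony: to the focal lineage if sister = outgroup ≠ focal, to the
sister lineage if focal = outgroup ≠ sister, otherwise ambiguous (three
alleles, or missing outgroup data). Codon context for classification is the
inferred ancestral codon (sister alleles substituted at focal-lineage
sites). The ambiguous synonymous/non-synonymous remainder is defined by
subtraction from the unpolarized counts, which makes the additivity
invariant — focal + sister + ambiguous = unpolarized, separately for Dn and
Ds — hold identically, including on multi-difference codons where pathway
fractions would not otherwise decompose cleanly. Within a codon that mixes
focal- and sister-lineage changes, this bookkeeping can allocate small
negative fractional remainders to the ambiguous class; site totals always
balance, and such codons do not arise when divergence is sparse.

**Neutrality index conventions.** Degenerate tables follow reporting
conventions chosen to match how published MK tables render them: Pn = 0
gives NI = 0; Ds = 0 with Dn > 0 gives 0; any remaining division by zero
(Ps = 0 or Dn = 0) is undefined and rendered blank (`NA`). NI is reported
to three decimals, rounded half away from zero.

**Which p-value.** MK-server output rarely states its test statistic, and
Fisher, Pearson X² and the G-test disagree at MK-table count sizes. We
verified that published table p-values of the motivating analysis reproduce
under Pearson X² *without* continuity correction (e.g. (52, 24 / 14, 20) →
0.007; (18, 15 / 5, 25) → 0.002) and not under Fisher; `run_mk()` therefore
reports `p_chisq` in table position, with the exact two-tailed Fisher
p-value always computed alongside, and a G-test available. The in-package
Fisher test uses the "sum of all tables with point probability not
exceeding the observed" definition — the same as `stats::fisher.test` but
distinct from tail-doubling, which can give roughly twice the p-value on
asymmetric margins. Tables with a zero margin return p = 1 (no information
about association), flagged with an attribute.

**Polarized NI.** The polarized NI reuses the unpolarized Pn/Ps with the
focal-lineage Dn/Ds, which is the convention the published tables imply
(polymorphism is a property of the focal population regardless of how
divergence is split).

## Gene-set association

`build_contingency()` cross-tabulates two categorical gene attributes over
genes informative for both, dropping and counting rows with missing
phenotype data or untestable selection status (e.g. no sister-species
ortholog). `association_test()` applies the two-tailed Fisher test.
Essentiality is coded broadly: any reported lethal *or* sterile outcome
counts as essential, treating viability and fertility jointly.
`example_gene_table()` provides an entirely synthetic 91-gene table whose
margins match the study-scale family (its per-gene labels are
placeholders); published exclusion counts for such tables are sometimes
internally inconsistent with the printed cells, so we always reproduce
printed 2×2 cells and report our own exclusion count.

## Gene age and loss

`infer_gene_age()` dates a gene by the age of the MRCA of the species
carrying an ortholog — equivalently the divergence time of the two most
distant carriers — on an ultrametric species tree with ages in Ma. A gene
found in one species gets age 0 and a species-specific flag.
`infer_losses()` assumes a single origin on the branch above that MRCA and
no regain (Dollo parsimony): every maximal subtree of the origin clade
containing no carrier is one loss. This greedy count is provably minimal;
the tests confirm it against exhaustive search over loss placements on
trees of up to 8 leaves. Multifurcations are supported, a lost clade under
a multifurcation counting once. Ortholog detection itself (BLAST/OrthoDB
style searches) is out of scope: presence/absence matrices are inputs, and
published presence calls are treated as fixtures, not re-derived truths.

## Repeat expression references

`build_repeat_assembly()` concatenates, per repeat type, all annotated
genomic instances into one pseudo-chromosome: each instance is extended by
`flank_bp` (default 75, half a typical 150 bp read, so a read overlapping a
repeat edge can still map) and instances are separated by `spacer_bp`
(default 150) `N` bases so no read can span two instances. Instances are
taken in annotation order and extracted as plus-strand genome sequence
regardless of annotated orientation — downstream aligners handle read
orientation, so this does not affect counting. Flanks are clipped at contig
boundaries and the clipping is recorded in the offset index. Both the UCSC
RepeatMasker `.out` dialect (1-based inclusive, strand `C`) and a
simplified 0-based half-open TSV are accepted. Read mapping and count
testing are delegated to external tools; `merge_revcomp_simple_repeats()`
canonicalizes simple-repeat motifs to the lexicographically smallest
rotation of the motif or its reverse complement before summing, and
`normalize_counts()` converts raw counts to counts per million reads.

## The simulator: what it emulates, and what it does not

`simulate_gene_history()` plants events rather than running a
continuous-time model: substitutions are placed by count on three branches
(focal, sister, outgroup stem) of the implied ((focal, sister), outgroup)
topology, choosing single-nucleotide changes of the requested
synonymous/non-synonymous class and rejecting stop-creating changes
(bounded at 1000 retries per event); polymorphisms are placed on the focal
population at derived-allele frequencies drawn uniformly from a
configurable range, with an optional class of planted singletons sitting
below the frequency filter. The analysis consumes counts, so planting by
count makes *exact* recovery the test currency; a Poisson mode draws counts
from the requested means instead, for null-distribution work. All
randomness flows from one integer seed.

Defaults mirror the data shape of the motivating study: 448 codons
(a full-length ZAD-ZNF gene), 200 ingroup haplotypes (a "hundreds of
strains" population panel), planted counts equal to the strongest
selection signal in the published table (focal 17/8, sister 26/16,
polymorphism 14/20), and polymorphism frequencies in (0.1, 0.9), safely
above the 5% filter.

The simulator deliberately omits linkage, demography, selection
coefficients, alignment error and missing data patterns of real
resequencing panels. Passing its tests therefore demonstrates that the
*counting and testing machinery* is correct — that planted (Pn, Ps, Dn, Ds)
are recovered exactly when codons carry at most one event, that
polarization splits match planted branches, and that neutral Poisson
configurations give nominal type-I error — not that the pipeline would
reproduce any particular published count from raw population genomes, which
additionally depends on unrecoverable manual alignment trimming.

One structural consequence is worth noting: with a clean two-branch
planting, every fixed difference polarizes, so planted unpolarized
divergence always equals focal + sister. Published tables routinely show
unpolarized Dn exceeding the polarized total (ambiguous sites from
alignment gaps, outgroup homoplasy or triple alleles); the simulator
produces such ambiguity only in multi-hit mode, where the outgroup stem can
overwrite a site independently.

## Numerical and scale choices

* Pathway enumeration is exact (at most 3! orderings); no approximation.
* Fractional counts are rounded half away from zero only at the reporting
  boundary; statistics in table position use the rounded integers so that
  printed tables and printed p-values stay mutually consistent.
* The test suite sizes its Monte-Carlo studies to run comfortably on one
  CPU: exact recovery over 100 seeds uses 150-codon genes with 25
  haplotypes; the neutral type-I study uses 500 replicates of 200-codon
  genes with 30 haplotypes and Poisson means of 15 per class (counts
  comparable to the published tables), with the rejection rate checked
  against the binomial 95% band around 0.05.
* Monotonicity, additivity and filter-bookkeeping invariants are asserted
  on every simulated case rather than on single examples.

## Known limitations

* Polymorphism classification is single-step against the major-allele
  codon; haplotype-phase information within a codon is not used.
* The ambiguous-class Dn/Ds split is defined by subtraction (see above);
  its per-codon values are bookkeeping quantities, not per-site calls.
* `chi_square_test()` is asymptotic; for sparse domain tables prefer the
  Fisher column, which is always reported.
* Gene ages inherit the tree's node ages; no uncertainty is propagated.
* The simulator's rejection sampling slightly biases which codons can host
  synonymous changes (e.g. ATG/TGG cannot); with events placed uniformly
  over hundreds of codons this has no measurable effect on recovered
  counts.
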