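.codon_at <- function(seq, i) substr(seq, 3L * i - 2L, 3L * i)

.codon_chars <- function(seq, i) strsplit(.codon_at(seq, i), "")[[1]]

.clean <- function(codon_chars) !any(!codon_chars %in% c("A", "C", "G", "T"))

# amino-acid change classification for a single-nucleotide step; a change
# to or from a stop is amino-acid altering, hence non-synonymous
.classify_step <- function(codon_from, codon_to, code) {
  if (.translate1(codon_from, code) == .translate1(codon_to, code)) "syn" else "nonsyn"
}

#' Count synonymous and non-synonymous polymorphisms
#'
#' Walks the alignment codon by codon. Within a codon, every segregating
#' allele (a non-missing ingroup allele differing from the site's major
#' allele) is classified as one single-nucleotide change against the
#' major-allele codon background. A triallelic site therefore contributes
#' two polymorphisms. Haplotypes carrying a gap or \code{N} at a site are
#' excluded from that site; codons whose major-allele background contains a
#' missing site are skipped and logged.
#'
#' @param aln A \code{PopulationAlignment}, normally already passed through
#'   \code{\link{filter_low_frequency_variants}}.
#' @param code Genetic code (codon -> amino acid).
#' @return List with \code{Pn}, \code{Ps} and a per-change \code{ledger}
#'   data frame (codon, site, background codon, variant codon, class).
#' @export
count_polymorphisms <- function(aln, code = standard_genetic_code()) {
  cons <- major_allele_profile(aln)
  counts <- .allele_counts(.seq_matrix(aln$ingroup))
  cons_chars <- strsplit(cons$sequence, "")[[1]]
  seg <- which(colSums(counts > 0L) > 1L)
  bad_codons <- unique((which(!cons_chars %in% rownames(counts)) - 1L) %/% 3L + 1L)
  ledger <- list()
  skipped <- sort(bad_codons)
  pn <- 0L; ps <- 0L
  for (i in setdiff(unique((seg - 1L) %/% 3L + 1L), bad_codons)) {
    bg <- cons_chars[(3L * i - 2L):(3L * i)]
    bg_codon <- paste(bg, collapse = "")
    for (j in seg[(seg - 1L) %/% 3L + 1L == i]) {
      k <- j - 3L * (i - 1L)
      alleles <- setdiff(rownames(counts)[counts[, j] > 0L], bg[k])
      for (al in alleles) {
        var_chars <- bg
        var_chars[k] <- al
        var_codon <- paste(var_chars, collapse = "")
        cls <- .classify_step(bg_codon, var_codon, code)
        if (cls == "syn") ps <- ps + 1L else pn <- pn + 1L
        ledger[[length(ledger) + 1L]] <-
          list(codon = i, site = j, background = bg_codon,
               variant = var_codon, class = cls)
      }
    }
  }
  empty <- data.frame(codon = integer(), site = integer(),
                      background = character(), variant = character(),
                      class = character())
  list(Pn = pn, Ps = ps, ledger = .bind_records(ledger, empty),
       skipped_codons = skipped)
}

# per-site fixed differences between the (filtered) ingroup and the sister:
# site monomorphic among non-missing ingroup alleles, sister unambiguous,
# and the two alleles differ. Returns site indices.
.fixed_diff_sites <- function(aln, cons = major_allele_profile(aln)) {
  bases <- c("A", "C", "G", "T")
  cons_chars <- strsplit(cons$sequence, "")[[1]]
  sis_chars <- strsplit(aln$sister, "")[[1]]
  mono <- cons$frequency == 1          # monomorphic among observed alleles
  ok <- cons_chars %in% bases & sis_chars %in% bases
  which(mono & ok & cons_chars != sis_chars)
}

#' Count synonymous and non-synonymous fixed differences
#'
#' A fixed difference is a site monomorphic in the (filtered) ingroup whose
#' allele differs from the sister allele; polymorphic sites contribute no
#' divergence even when the sister carries a third allele. Differences are
#' accumulated codon-wise through \code{\link{codon_change_paths}}, so
#' multi-difference codons yield fractional counts averaged over admissible
#' mutational orderings. Codons with a gap or \code{N} in either the ingroup
#' consensus or the sister are skipped and logged.
#'
#' @inheritParams count_polymorphisms
#' @return List with fractional \code{Dn}, \code{Ds}, a per-codon
#'   \code{ledger} (codon, ingroup codon, sister-substituted codon, n_diff,
#'   dn, ds) and \code{skipped_codons}.
#' @export
count_divergence <- function(aln, code = standard_genetic_code()) {
  cons <- major_allele_profile(aln)
  fixed <- .fixed_diff_sites(aln, cons)
  dn <- 0; ds <- 0
  ledger <- list()
  bases <- c("A", "C", "G", "T")
  bad_sites <- which(!strsplit(cons$sequence, "")[[1]] %in% bases |
                     !strsplit(aln$sister, "")[[1]] %in% bases)
  skipped <- sort(unique((bad_sites - 1L) %/% 3L + 1L))
  for (i in setdiff(sort(unique((fixed - 1L) %/% 3L + 1L)), skipped)) {
    bg <- .codon_chars(cons$sequence, i)
    sis <- .codon_chars(aln$sister, i)
    in_codon <- fixed[(fixed - 1L) %/% 3L + 1L == i]
    derived <- bg
    derived[in_codon - 3L * (i - 1L)] <- sis[in_codon - 3L * (i - 1L)]
    a <- paste(bg, collapse = ""); b <- paste(derived, collapse = "")
    p <- tryCatch(codon_change_paths(a, b, code), error = function(e) NULL)
    if (is.null(p)) { skipped <- c(skipped, i); next }  # stop-codon endpoint
    dn <- dn + p$dn; ds <- ds + p$ds
    ledger[[length(ledger) + 1L]] <-
      list(codon = i, ingroup = a, sister = b, n_diff = p$n_diff,
           dn = p$dn, ds = p$ds)
  }
  empty <- data.frame(codon = integer(), ingroup = character(),
                      sister = character(), n_diff = integer(),
                      dn = numeric(), ds = numeric())
  list(Dn = dn, Ds = ds, ledger = .bind_records(ledger, empty),
       skipped_codons = skipped)
}

#' Polarize fixed differences with an outgroup
#'
#' Assigns each fixed difference between the ingroup and the sister to the
#' branch on which it occurred, by parsimony against the outgroup allele: the
#' change lies on the focal (ingroup) lineage when sister and outgroup share
#' an allele the ingroup lacks, on the sister lineage when ingroup and
#' outgroup agree, and is ambiguous otherwise (three distinct alleles, or a
#' missing outgroup base). Codon classification reuses
#' \code{\link{codon_change_paths}} on the inferred ancestral codon, and the
#' ambiguous synonymous/non-synonymous remainder is obtained by subtracting
#' both lineage counts from the unpolarized counts, so the additivity
#' focal + sister + ambiguous = unpolarized holds by construction.
#'
#' @inheritParams count_polymorphisms
#' @return List of class \code{"polarized_counts"}: \code{focal} and
#'   \code{sister} (each with fractional \code{Dn}, \code{Ds}),
#'   \code{ambiguous_dn}, \code{ambiguous_ds}, \code{n_ambiguous_sites} and a
#'   per-site \code{ledger} (site, focal/sister/outgroup alleles, assignment).
#' @export
polarize <- function(aln, code = standard_genetic_code()) {
  if (is.null(aln$outgroup)) stop("polarization requires outgroup")
  bases <- c("A", "C", "G", "T")
  cons <- major_allele_profile(aln)
  unpol <- count_divergence(aln, code)
  fixed <- .fixed_diff_sites(aln, cons)
  cons_chars <- strsplit(cons$sequence, "")[[1]]
  sis_chars <- strsplit(aln$sister, "")[[1]]
  out_chars <- strsplit(aln$outgroup, "")[[1]]
  assign_site <- function(j) {
    f <- cons_chars[j]; s <- sis_chars[j]; o <- out_chars[j]
    if (!o %in% bases) "ambiguous"
    else if (o == s && o != f) "focal"
    else if (o == f && o != s) "sister"
    else "ambiguous"
  }
  focal_dn <- 0; focal_ds <- 0; sister_dn <- 0; sister_ds <- 0
  ledger <- list()
  codons <- sort(unique((fixed - 1L) %/% 3L + 1L))
  codons <- setdiff(codons, unpol$skipped_codons)
  for (i in codons) {
    in_codon <- fixed[(fixed - 1L) %/% 3L + 1L == i]
    pos <- in_codon - 3L * (i - 1L)
    cls <- vapply(in_codon, assign_site, character(1))
    for (k in seq_along(in_codon))
      ledger[[length(ledger) + 1L]] <-
        list(site = in_codon[k], codon = i, focal = cons_chars[in_codon[k]],
             sister = sis_chars[in_codon[k]], outgroup = out_chars[in_codon[k]],
             lineage = cls[k])
    bg <- .codon_chars(cons$sequence, i)
    # inferred ancestral codon: sister (= outgroup) allele at focal-lineage
    # sites, focal allele elsewhere
    anc <- bg
    anc[pos[cls == "focal"]] <- sis_chars[in_codon[cls == "focal"]]
    der_sister <- anc
    der_sister[pos[cls == "sister"]] <- sis_chars[in_codon[cls == "sister"]]
    anc_s <- paste(anc, collapse = "")
    pf <- tryCatch(codon_change_paths(anc_s, paste(bg, collapse = ""), code),
                   error = function(e) NULL)
    ps_ <- tryCatch(codon_change_paths(anc_s, paste(der_sister, collapse = ""), code),
                    error = function(e) NULL)
    if (!is.null(pf)) { focal_dn <- focal_dn + pf$dn; focal_ds <- focal_ds + pf$ds }
    if (!is.null(ps_)) { sister_dn <- sister_dn + ps_$dn; sister_ds <- sister_ds + ps_$ds }
  }
  structure(list(
    focal = list(Dn = focal_dn, Ds = focal_ds),
    sister = list(Dn = sister_dn, Ds = sister_ds),
    ambiguous_dn = unpol$Dn - focal_dn - sister_dn,
    ambiguous_ds = unpol$Ds - focal_ds - sister_ds,
    unpolarized = list(Dn = unpol$Dn, Ds = unpol$Ds),
    ledger = .bind_records(ledger, data.frame(
      site = integer(), codon = integer(), focal = character(),
      sister = character(), outgroup = character(), lineage = character()))
  ), class = "polarized_counts")
}

#' Neutrality index
#'
#' NI = (Pn/Ps) / (Dn/Ds). Values below 1 indicate an excess of fixed
#' non-synonymous differences (positive selection). Degenerate counts follow
#' reporting conventions: \code{Pn = 0} gives 0; \code{Ds = 0} with
#' \code{Dn > 0} gives 0; any other division by zero (\code{Ps = 0} or
#' \code{Dn = 0}) is undefined and returned as \code{NA} (rendered blank in
#' tables).
#'
#' @param Pn,Ps Non-synonymous and synonymous polymorphism counts.
#' @param Dn,Ds Non-synonymous and synonymous fixed-difference counts.
#' @return A single number, or \code{NA} when undefined.
#' @examples
#' neutrality_index(Pn = 14, Ps = 20, Dn = 52, Ds = 24)  # 0.323 (3 dp)
#' @export
neutrality_index <- function(Pn, Ps, Dn, Ds) {
  stopifnot(Pn >= 0, Ps >= 0, Dn >= 0, Ds >= 0)
  if (Pn == 0) return(0)
  if (Ds == 0 && Dn > 0) return(0)
  if (Ps == 0 || Dn == 0) return(NA_real_)
  (Pn / Ps) / (Dn / Ds)
}

#' Round half away from zero
#'
#' The convention used for table-style reporting of fractional pathway
#' counts and neutrality indices (base \code{round()} rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Run the McDonald-Kreitman analysis for a gene and its domains
#'
#' Applies the minor-allele-frequency filter once to the full alignment, then
#' computes polymorphism and divergence counts, the neutrality index, and
#' Fisher / Pearson chi-square p-values for the full-length gene and for each
#' supplied domain span, optionally polarizing fixed differences with the
#' outgroup. Fractional pathway counts are kept internally and rounded half
#' away from zero for the reported tables and tests.
#'
#' @param aln A \code{PopulationAlignment}.
#' @param domains List of \code{\link{domain_span}} objects (may be empty).
#' @param threshold Minor-allele-frequency mask threshold (see
#'   \code{\link{filter_low_frequency_variants}}). Default 0.05.
#' @param polarized Polarize fixed differences (requires an outgroup).
#'   Defaults to TRUE when the alignment carries an outgroup.
#' @param code Genetic code.
#' @return An object of class \code{"mk_result_set"}: a list with one element
#'   per region (full-length first), each holding the region label, length in
#'   codons, integer-reported and fractional counts, NI, \code{p_fisher},
#'   \code{p_chisq}, and (when polarized) the per-lineage counts with their
#'   own NI and p-values. \code{as.data.frame()} renders the familiar
#'   MK-table layout.
#' @export
run_mk <- function(aln, domains = list(), threshold = 0.05,
                   polarized = !is.null(aln$outgroup),
                   code = standard_genetic_code()) {
  if (polarized && is.null(aln$outgroup))
    stop("polarization requires outgroup")
  faln <- filter_low_frequency_variants(aln, threshold)
  regions <- c(list(domain_span("full-length", 1L, faln$length %/% 3L)), domains)
  res <- lapply(regions, function(span) {
    sub <- if (span$name == "full-length" &&
               span$start_codon == 1L && span$end_codon == faln$length %/% 3L)
      faln else extract_domain(faln, span)
    poly <- count_polymorphisms(sub, code)
    div <- count_divergence(sub, code)
    counts <- c(Dn = div$Dn, Ds = div$Ds, Pn = poly$Pn, Ps = poly$Ps)
    rep_counts <- round_half_up(counts)
    tab <- matrix(rep_counts, 2L, 2L, byrow = TRUE,
                  dimnames = list(c("fixed", "polymorphic"), c("nonsyn", "syn")))
    out <- list(
      gene = aln$name, region = span$name,
      length_codons = span$end_codon - span$start_codon + 1L,
      counts = rep_counts, counts_fractional = counts,
      NI = neutrality_index(rep_counts[["Pn"]], rep_counts[["Ps"]],
                            rep_counts[["Dn"]], rep_counts[["Ds"]]),
      p_fisher = fisher_exact_two_tailed(tab),
      p_chisq = tryCatch(chi_square_test(tab), error = function(e) NA_real_),
      ledger = list(polymorphism = poly$ledger, divergence = div$ledger)
    )
    if (polarized) {
      pol <- polarize(sub, code)
      fDn <- round_half_up(pol$focal$Dn); fDs <- round_half_up(pol$focal$Ds)
      sDn <- round_half_up(pol$sister$Dn); sDs <- round_half_up(pol$sister$Ds)
      ptab <- matrix(c(fDn, fDs, rep_counts[["Pn"]], rep_counts[["Ps"]]),
                     2L, 2L, byrow = TRUE)
      out$polarized <- list(
        focal = list(Dn = fDn, Ds = fDs),
        sister = list(Dn = sDn, Ds = sDs),
        ambiguous_dn = pol$ambiguous_dn, ambiguous_ds = pol$ambiguous_ds,
        total_Dn = fDn + sDn, total_Ds = sDs + fDs,
        NI = neutrality_index(rep_counts[["Pn"]], rep_counts[["Ps"]], fDn, fDs),
        p_fisher = fisher_exact_two_tailed(ptab),
        p_chisq = tryCatch(chi_square_test(ptab), error = function(e) NA_real_),
        ledger = pol$ledger
      )
    }
    structure(out, class = "mk_result")
  })
  structure(res, class = "mk_result_set",
            masked_sites = attr(faln, "masked_sites"))
}

#' @export
as.data.frame.mk_result_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    d <- data.frame(
      gene = r$gene, region = r$region, length_codons = r$length_codons,
      p_chisq = r$p_chisq, Dn = r$counts[["Dn"]], Ds = r$counts[["Ds"]],
      Pn = r$counts[["Pn"]], Ps = r$counts[["Ps"]], NI = r$NI,
      p_fisher = r$p_fisher, stringsAsFactors = FALSE
    )
    if (!is.null(r$polarized)) {
      p <- r$polarized
      d$pol_p_chisq <- p$p_chisq
      d$pol_Dn <- p$focal$Dn; d$pol_Ds <- p$focal$Ds; d$pol_NI <- p$NI
      d$sister_Dn <- p$sister$Dn; d$sister_Ds <- p$sister$Ds
      d$total_pol_Dn <- p$total_Dn; d$total_pol_Ds <- p$total_Ds
    }
    d
  }))
}

#' @export
print.mk_result_set <- function(x, digits = 3, ...) {
  d <- as.data.frame(x)
  d$NI <- round_half_up(d$NI, 3)
  for (cl in grep("^p_|_p_", names(d), value = TRUE)) d[[cl]] <- signif(d[[cl]], 2)
  if ("pol_NI" %in% names(d)) d$pol_NI <- round_half_up(d$pol_NI, 3)
  print(d, row.names = FALSE)
  invisible(x)
}
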