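#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

.seq_matrix <- function(seqs) {
  # haplotypes x sites character matrix
  do.call(rbind, strsplit(toupper(seqs), ""))
}

#' Construct a codon-aligned population alignment
#'
#' Bundles an in-frame codon alignment of ingroup haplotypes with a single
#' sister-species reference and an optional outgroup reference. All
#' downstream polymorphism/divergence counting operates on this container.
#'
#' @param ingroup Character vector (>= 2) of aligned nucleotide haplotypes.
#' @param sister Single aligned sister-species sequence.
#' @param outgroup Optional single aligned outgroup sequence.
#' @param name Gene identifier.
#' @param validate Check invariants (equal lengths, frame, alphabet, and that
#'   the ingroup major-allele sequence is free of in-frame stop codons).
#' @return An object of class \code{"PopulationAlignment"}: a list with
#'   \code{ingroup} (named character vector), \code{sister}, \code{outgroup}
#'   (or NULL), \code{length} (nucleotides) and \code{name}.
#' @export
population_alignment <- function(ingroup, sister, outgroup = NULL, name = "gene",
                                 validate = TRUE) {
  ingroup <- toupper(unlist(ingroup))
  if (is.null(names(ingroup)) || any(names(ingroup) == ""))
    names(ingroup) <- paste0("hap", seq_along(ingroup))
  sister <- toupper(sister[[1]])
  if (!is.null(outgroup)) outgroup <- toupper(outgroup[[1]])
  aln <- structure(list(ingroup = ingroup, sister = sister, outgroup = outgroup,
                        length = nchar(sister), name = name),
                   class = "PopulationAlignment")
  if (validate) validate_alignment(aln)
  aln
}

#' @rdname population_alignment
#' @param aln A \code{PopulationAlignment}.
#' @export
validate_alignment <- function(aln) {
  all_seq <- c(aln$ingroup, sister = aln$sister,
               if (!is.null(aln$outgroup)) c(outgroup = aln$outgroup))
  lens <- nchar(all_seq)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  if (length(aln$ingroup) < 2L)
    stop("need at least 2 ingroup haplotypes, got ", length(aln$ingroup))
  if (aln$length %% 3L != 0L)
    stop("alignment length ", aln$length, " is not divisible by 3")
  bad <- grepl(sprintf("[^%s]", paste(ALN_ALPHABET, collapse = "")), all_seq)
  if (any(bad))
    stop("illegal characters in sequence(s): ",
         paste(names(all_seq)[bad], collapse = ", "))
  # the ingroup major-allele sequence must be an open reading frame
  cons <- major_allele_profile(aln)
  code <- standard_genetic_code()
  for (i in seq_len(aln$length %/% 3L)) {
    cd <- substr(cons$sequence, 3L * i - 2L, 3L * i)
    if (!grepl("[^ACGT]", cd) && .is_stop(cd, code))
      stop("in-frame stop codon ", cd, " in ingroup major-allele sequence at codon ", i)
  }
  invisible(aln)
}

#' @export
print.PopulationAlignment <- function(x, ...) {
  cat(sprintf("PopulationAlignment '%s': %d ingroup haplotype(s), %d nt (%d codons), sister%s\n",
              x$name, length(x$ingroup), x$length, x$length %/% 3L,
              if (is.null(x$outgroup)) "" else " + outgroup"))
  invisible(x)
}

#' Read a population alignment from FASTA
#'
#' Sequence roles are taken from a \code{"|role"} suffix on each FASTA header
#' (\code{|ingroup}, \code{|sister}, \code{|outgroup}) or, if \code{roles} is
#' supplied, from a name-to-role map (a named character vector or a two-column
#' data frame / TSV file with columns \code{name} and \code{role}). Exactly
#' one sister and at most one outgroup are required.
#'
#' @param fasta Path to a FASTA file.
#' @param roles Optional role map overriding header suffixes.
#' @param name Gene identifier; defaults to the file name without extension.
#' @return A validated \code{PopulationAlignment}; ingroup order follows file
#'   order.
#' @export
read_alignment <- function(fasta, roles = NULL, name = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  headers <- names(seqs)
  seqs <- as.character(seqs)
  if (is.null(roles)) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    ids <- vapply(parts, `[`, character(1), 1L)
    role <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_,
                   character(1))
  } else {
    if (is.character(roles) && length(roles) == 1L && file.exists(roles))
      roles <- utils::read.delim(roles, stringsAsFactors = FALSE)
    if (is.data.frame(roles)) roles <- stats::setNames(roles$role, roles$name)
    ids <- headers
    role <- unname(roles[headers])
  }
  if (anyNA(role))
    stop("no role for sequence(s): ", paste(ids[is.na(role)], collapse = ", "))
  bad <- setdiff(unique(role), c("ingroup", "sister", "outgroup"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (sum(role == "sister") != 1L)
    stop("exactly one sister sequence required, found ", sum(role == "sister"))
  if (sum(role == "outgroup") > 1L)
    stop("at most one outgroup sequence allowed, found ", sum(role == "outgroup"))
  og <- if (any(role == "outgroup")) seqs[[which(role == "outgroup")]] else NULL
  population_alignment(
    ingroup = stats::setNames(seqs[role == "ingroup"], ids[role == "ingroup"]),
    sister = seqs[[which(role == "sister")]],
    outgroup = og,
    name = if (is.null(name)) sub("\\.(fa|fasta|fna)$", "", basename(fasta)) else name
  )
}

#' Write a population alignment to FASTA
#'
#' Headers carry the \code{"|role"} suffix understood by
#' \code{\link{read_alignment}}, so write/read round-trips.
#'
#' @param aln A \code{PopulationAlignment}.
#' @param path Output FASTA path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- c(aln$ingroup, aln$sister, aln$outgroup)
  nms <- c(paste0(names(aln$ingroup), "|ingroup"), "sister|sister",
           if (!is.null(aln$outgroup)) "outgroup|outgroup")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- nms
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Per-site major-allele consensus of the ingroup
#'
#' @param aln A \code{PopulationAlignment}.
#' @return A list of class \code{"consensus_sequence"}: \code{sequence} (the
#'   per-site most frequent non-missing ingroup allele; ties broken
#'   alphabetically A<C<G<T; all-missing sites become \code{N}) and
#'   \code{frequency} (the major allele's fraction among non-missing ingroup
#'   alleles at each site; 0 where all are missing).
#' @export
major_allele_profile <- function(aln) {
  counts <- .allele_counts(.seq_matrix(aln$ingroup))
  n_obs <- colSums(counts)
  # max.col("first") on A,C,G,T rows implements the alphabetical tie-break
  major <- max.col(t(counts), ties.method = "first")
  allele <- rownames(counts)[major]
  freq <- counts[cbind(major, seq_along(allele))] / pmax(n_obs, 1L)
  allele[n_obs == 0L] <- "N"
  freq[n_obs == 0L] <- 0
  structure(list(sequence = paste(allele, collapse = ""), frequency = freq),
            class = "consensus_sequence")
}

# 4 x n_sites matrix of non-missing allele counts (rows A, C, G, T)
.allele_counts <- function(m) {
  bases <- c("A", "C", "G", "T")
  t(vapply(bases, function(b) colSums(m == b), numeric(ncol(m))))
}

#' Mask minor alleles below a frequency threshold
#'
#' At every ingroup site where a minor allele's frequency among non-missing
#' alleles is strictly below \code{threshold}, the minor allele is replaced
#' by the site's major allele in all carriers. Sites, coordinates, sister and
#' outgroup are untouched, so masked sites can still contribute fixed
#' differences downstream. Mirrors the standard pre-filtering of
#' low-frequency variants before a McDonald-Kreitman test.
#'
#' @param aln A \code{PopulationAlignment}.
#' @param threshold Minor-allele-frequency cutoff in \[0, 0.5\]; alleles with
#'   frequency \code{< threshold} (strict) are masked. Default 0.05.
#' @return The filtered \code{PopulationAlignment}, with a
#'   \code{"masked_sites"} attribute: a data frame (site, allele, count,
#'   freq, replacement) listing every masked allele.
#' @export
filter_low_frequency_variants <- function(aln, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  m <- .seq_matrix(aln$ingroup)
  counts <- .allele_counts(m)
  masked <- list()
  for (j in which(colSums(counts > 0L) > 1L)) {   # segregating sites only
    tab <- counts[counts[, j] > 0L, j]
    major <- names(tab)[order(-tab, names(tab))][1L]  # alphabetical tie-break
    for (al in setdiff(names(tab), major)) {
      fr <- tab[[al]] / sum(tab)
      if (fr < threshold) {
        m[m[, j] == al, j] <- major
        masked[[length(masked) + 1L]] <-
          list(site = j, allele = al, count = unname(tab[[al]]), freq = fr,
               replacement = major)
      }
    }
  }
  out <- aln
  out$ingroup <- stats::setNames(apply(m, 1L, paste, collapse = ""),
                                 names(aln$ingroup))
  attr(out, "masked_sites") <- .bind_records(masked, data.frame(
    site = integer(), allele = character(), count = integer(),
    freq = numeric(), replacement = character()))
  out
}

#' Define a protein-domain span in codon coordinates
#'
#' @param name Domain label (e.g. \code{"ZAD"}, \code{"linker"}, \code{"C2H2"}).
#' @param start_codon,end_codon 1-based inclusive codon indices.
#' @return A \code{"domain_span"} list.
#' @export
domain_span <- function(name, start_codon, end_codon) {
  start_codon <- as.integer(start_codon); end_codon <- as.integer(end_codon)
  if (start_codon < 1L || start_codon > end_codon)
    stop("invalid span [", start_codon, ", ", end_codon, "]")
  structure(list(name = name, start_codon = start_codon, end_codon = end_codon),
            class = "domain_span")
}

#' Read domain spans from a TSV (gene, domain, start_codon, end_codon)
#'
#' @param path TSV path with columns \code{gene}, \code{domain},
#'   \code{start_codon}, \code{end_codon}.
#' @param gene Optional gene to restrict to.
#' @return A list of \code{domain_span} objects.
#' @export
read_domain_spans <- function(path, gene = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "domain", "start_codon", "end_codon")
  if (!all(need %in% names(d)))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  if (!is.null(gene)) d <- d[d$gene == gene, , drop = FALSE]
  spans <- Map(domain_span, d$domain, d$start_codon, d$end_codon)
  .check_span_overlap(spans)
  unname(spans)
}

.check_span_overlap <- function(spans) {
  if (length(spans) < 2L) return(invisible())
  iv <- cbind(vapply(spans, `[[`, integer(1), "start_codon"),
              vapply(spans, `[[`, integer(1), "end_codon"))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  if (any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
    stop("domain spans overlap")
  invisible()
}

#' Extract a codon-range sub-alignment
#'
#' All roles (ingroup, sister, outgroup) are sliced identically.
#'
#' @param aln A \code{PopulationAlignment}.
#' @param span A \code{domain_span} (1-based inclusive codon coordinates).
#' @return A \code{PopulationAlignment} covering the span's codons.
#' @export
extract_domain <- function(aln, span) {
  n_codons <- aln$length %/% 3L
  if (span$end_codon > n_codons)
    stop("span [", span$start_codon, ", ", span$end_codon,
         "] out of range for ", n_codons, " codons")
  from <- 3L * (span$start_codon - 1L) + 1L
  to <- 3L * span$end_codon
  slice <- function(s) substr(s, from, to)
  population_alignment(
    ingroup = stats::setNames(vapply(aln$ingroup, slice, character(1)),
                              names(aln$ingroup)),
    sister = slice(aln$sister),
    outgroup = if (is.null(aln$outgroup)) NULL else slice(aln$outgroup),
    name = paste0(aln$name, ":", span$name),
    validate = FALSE
  )
}
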