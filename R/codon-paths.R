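#' @importFrom Biostrings GENETIC_CODE
NULL

# The standard genetic code as a named character vector (codon -> amino acid,
# "*" for stop), taken from Biostrings at load time.
standard_genetic_code <- function() Biostrings::GENETIC_CODE

.translate1 <- function(codon, code) {
  aa <- code[[codon]]
  if (is.null(aa)) stop("not a codon: ", codon)
  aa
}

.is_stop <- function(codon, code) identical(.translate1(codon, code), "*")

.permutations <- function(x) {
  # all orderings of an integer vector (n <= 3 in practice)
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

#' Count synonymous and non-synonymous steps between two codons
#'
#' Enumerates every ordering of the nucleotide positions at which two codons
#' differ, walks each ordering one substitution at a time, classifies each
#' step as synonymous or non-synonymous under the genetic code, and averages
#' the two step counts over all admissible orderings (the Nei-Gojobori
#' pathway convention). Orderings that pass through a stop codon are
#' discarded; if every ordering does, the average is taken over all orderings
#' and the result is flagged.
#'
#' @param codon_a,codon_b Three-letter nucleotide strings over \{A,C,G,T\}.
#'   Both must translate to an amino acid (no stop codons, no ambiguity
#'   codes, no gaps).
#' @param code Named character vector mapping codons to amino acids
#'   (\code{"*"} for stop); defaults to the standard genetic code.
#' @return A list of class \code{"pathway_summary"} with elements
#'   \code{n_diff} (nucleotide differences), \code{dn} and \code{ds}
#'   (fractional non-synonymous and synonymous counts; their sum equals
#'   \code{n_diff} whenever a path was admissible), \code{n_paths_used}
#'   (number of stop-free orderings averaged over) and
#'   \code{all_paths_blocked} (TRUE when no stop-free ordering existed).
#' @examples
#' codon_change_paths("TTA", "TTG")  # Leu -> Leu: one synonymous step
#' codon_change_paths("CCT", "CAA")  # averages the two orderings: dn 1.5, ds 0.5
#' @export
codon_change_paths <- function(codon_a, codon_b, code = standard_genetic_code()) {
  for (cd in c(codon_a, codon_b)) {
    if (nchar(cd) != 3L || grepl("[^ACGT]", cd))
      stop("codon contains a non-ACGT character: ", cd)
    if (.is_stop(cd, code))
      stop("stop codon endpoint: ", cd)
  }
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(a != b)
  n_diff <- length(diff_pos)
  if (n_diff == 0L) {
    return(structure(list(n_diff = 0L, dn = 0, ds = 0, n_paths_used = 0L,
                          all_paths_blocked = FALSE),
                     class = "pathway_summary"))
  }
  orderings <- .permutations(diff_pos)
  step_counts <- lapply(orderings, function(ord) {
    cur <- a
    dn <- 0L; ds <- 0L; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa_cur <- .translate1(paste(cur, collapse = ""), code)
      aa_nxt <- .translate1(paste(nxt, collapse = ""), code)
      if (aa_nxt == "*") blocked <- TRUE
      if (aa_cur == aa_nxt) ds <- ds + 1L else dn <- dn + 1L
      cur <- nxt
    }
    list(dn = dn, ds = ds, blocked = blocked)
  })
  ok <- !vapply(step_counts, `[[`, logical(1), "blocked")
  use <- if (any(ok)) step_counts[ok] else step_counts
  structure(list(
    n_diff = n_diff,
    dn = mean(vapply(use, `[[`, integer(1), "dn")),
    ds = mean(vapply(use, `[[`, integer(1), "ds")),
    n_paths_used = length(use),
    all_paths_blocked = !any(ok)
  ), class = "pathway_summary")
}

#' @export
print.pathway_summary <- function(x, ...) {
  cat(sprintf("codon pathway: %d difference(s), dn = %.3g, ds = %.3g over %d path(s)%s\n",
              x$n_diff, x$dn, x$ds, x$n_paths_used,
              if (x$all_paths_blocked) " [all paths pass through a stop]" else ""))
  invisible(x)
}

# All 61 sense codons of a code
sense_codons <- function(code = standard_genetic_code()) {
  names(code)[code != "*"]
}
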