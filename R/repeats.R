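#' Read repeat annotations
#'
#' Accepts either the RepeatMasker \code{.out} whitespace format (three
#' header lines, 1-based inclusive query coordinates, strand \code{+}/\code{C})
#' or a simplified TSV with columns \code{repeat_type}, \code{chrom},
#' \code{start}, \code{end}, \code{strand} already in 0-based half-open
#' coordinates. Both are normalized to 0-based half-open.
#'
#' @param path Annotation file.
#' @param format \code{"auto"} (sniff), \code{"rmout"} or \code{"tsv"}.
#' @return Data frame: repeat_type, chrom, start, end (0-based half-open),
#'   strand, in file order.
#' @export
read_repeat_annotations <- function(path, format = c("auto", "rmout", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("\\bSW\\b|score.*div", first) ||
                  grepl("^\\s", first)) "rmout" else "tsv"
  }
  if (format == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("repeat_type", "chrom", "start", "end", "strand")
    if (!all(need %in% names(d)))
      stop("TSV needs columns: ", paste(need, collapse = ", "))
    return(d[, need])
  }
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]     # banner + blank line
  lines <- trimws(lines[nzchar(trimws(lines))])
  fields <- strsplit(lines, "\\s+")
  d <- data.frame(
    repeat_type = vapply(fields, `[`, character(1), 10L),
    chrom = vapply(fields, `[`, character(1), 5L),
    start = as.integer(vapply(fields, `[`, character(1), 6L)) - 1L,  # to 0-based
    end = as.integer(vapply(fields, `[`, character(1), 7L)),
    strand = ifelse(vapply(fields, `[`, character(1), 9L) == "C", "-", "+"),
    stringsAsFactors = FALSE
  )
  d
}

#' Build a concatenated per-repeat-type expression reference
#'
#' For each repeat type, every annotated genomic instance is extracted
#' (plus-strand genome sequence regardless of annotated orientation, since a
#' downstream aligner handles read orientation), extended by \code{flank_bp}
#' of flanking genome sequence on each side (clipped at contig boundaries),
#' and the extended instances are concatenated in annotation order with
#' \code{spacer_bp} \code{N} bases between consecutive instances. The result
#' is one pseudo-chromosome per repeat type, suitable as an alignment
#' reference for quantifying repeat-derived expression.
#'
#' @param genome A \code{Biostrings::DNAStringSet}, or path to a genome FASTA.
#' @param annotations Data frame as returned by
#'   \code{\link{read_repeat_annotations}}, or a path to an annotation file.
#' @param flank_bp Flanking bases added to each side of an instance (default
#'   75, half a typical 150 bp read).
#' @param spacer_bp \code{N} bases inserted between instances (default 150).
#' @return List of class \code{"repeat_assembly"}: \code{sequences} (a
#'   \code{DNAStringSet}, one entry per repeat type) and \code{index} (data
#'   frame: repeat_type, chrom, start, end, strand, offset_start, offset_end
#'   (the 0-based half-open span of the extended instance within its
#'   pseudo-chromosome), clip_left, clip_right).
#' @export
build_repeat_assembly <- function(genome, annotations, flank_bp = 75L,
                                  spacer_bp = 150L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.character(annotations)) annotations <- read_repeat_annotations(annotations)
  bad <- setdiff(annotations$chrom, names(genome))
  if (length(bad)) stop("unknown contig(s): ", paste(bad, collapse = ", "))
  contig_len <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(annotations$start < 0 | annotations$end > contig_len[annotations$chrom] |
          annotations$start >= annotations$end))
    stop("annotation coordinates outside contig bounds")
  spacer <- strrep("N", spacer_bp)
  seqs <- character(); index <- list()
  for (rt in unique(annotations$repeat_type)) {
    inst <- annotations[annotations$repeat_type == rt, , drop = FALSE]
    offset <- 0L; pieces <- character(nrow(inst))
    for (k in seq_len(nrow(inst))) {
      len <- contig_len[[inst$chrom[k]]]
      from <- max(0L, inst$start[k] - flank_bp)
      to <- min(len, inst$end[k] + flank_bp)
      piece <- as.character(Biostrings::subseq(genome[[inst$chrom[k]]],
                                               from + 1L, to))
      pieces[k] <- piece
      index[[length(index) + 1L]] <- data.frame(
        repeat_type = rt, chrom = inst$chrom[k], start = inst$start[k],
        end = inst$end[k], strand = inst$strand[k],
        offset_start = offset, offset_end = offset + nchar(piece),
        clip_left = flank_bp - (inst$start[k] - from),
        clip_right = flank_bp - (to - inst$end[k])
      )
      offset <- offset + nchar(piece) + if (k < nrow(inst)) spacer_bp else 0L
    }
    seqs[[rt]] <- paste(pieces, collapse = spacer)
  }
  structure(list(sequences = Biostrings::DNAStringSet(seqs),
                 index = do.call(rbind, index),
                 flank_bp = flank_bp, spacer_bp = spacer_bp),
            class = "repeat_assembly")
}

#' @export
print.repeat_assembly <- function(x, ...) {
  cat(sprintf("repeat assembly: %d pseudo-chromosome(s), %d instance(s), flank %d bp, spacer %d bp\n",
              length(x$sequences), nrow(x$index), x$flank_bp, x$spacer_bp))
  invisible(x)
}

#' Write a repeat assembly to FASTA plus an offset-index TSV
#'
#' @param assembly A \code{repeat_assembly}.
#' @param fasta,index Output paths (index omitted if NULL).
#' @export
write_repeat_assembly <- function(assembly, fasta, index = NULL) {
  Biostrings::writeXStringSet(assembly$sequences, fasta)
  if (!is.null(index))
    utils::write.table(assembly$index, index, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fasta)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.rotations <- function(x) {
  n <- nchar(x)
  vapply(seq_len(n), function(i) paste0(substr(x, i, n), substr(x, 1L, i - 1L)),
         character(1))
}

# canonical motif: lexicographically smallest rotation of the motif or of
# its reverse complement, so "(AC)n" and "(GT)n" share a canonical form
canonical_simple_repeat <- function(name) {
  m <- regmatches(name, regexec("^\\(([ACGT]+)\\)n$", name))[[1]]
  if (length(m) < 2L) return(name)
  motif <- m[[2L]]
  sprintf("(%s)n", min(c(.rotations(motif), .rotations(.revcomp(motif)))))
}

#' Merge counts of reverse-complementary simple repeats
#'
#' Simple-repeat annotations name the two strands of one tandem array as two
#' repeat types (e.g. \code{(AC)n} and \code{(GT)n}). Each motif is
#' canonicalized to the lexicographically smallest rotation of itself or of
#' its reverse complement and counts sharing a canonical form are summed.
#' Non-simple repeat names (anything not of the form \code{(MOTIF)n}) pass
#' through unchanged. The operation is idempotent.
#'
#' @param counts Named numeric vector, repeat type -> count.
#' @return Named numeric vector with merged names; first-seen name order.
#' @examples
#' merge_revcomp_simple_repeats(c("(AC)n" = 10, "(GT)n" = 5, roo = 7))
#' @export
merge_revcomp_simple_repeats <- function(counts) {
  stopifnot(!is.null(names(counts)))
  canon <- vapply(names(counts), canonical_simple_repeat, character(1))
  out <- tapply(unname(counts), factor(canon, levels = unique(canon)), sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Normalize read counts to counts per million
#'
#' Divides each count by the library size expressed in millions of reads.
#'
#' @param counts Numeric vector (optionally named) of per-repeat-type raw
#'   read counts.
#' @param total_fragments Total reads sequenced for the sample.
#' @return Counts per million, same shape and names as \code{counts}.
#' @export
normalize_counts <- function(counts, total_fragments) {
  stopifnot(all(counts >= 0))
  if (total_fragments <= 0) stop("total_fragments must be positive")
  counts / (total_fragments / 1e6)
}
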