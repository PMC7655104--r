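#' Configuration for a simulated gene history
#'
#' Defines the shape of a simulated population-genomic input: one focal
#' population (emulating hundreds of sequenced strains), one sister-species
#' reference diverged from the common ancestor, and one outgroup reference
#' diverged earlier. Substitutions are planted by count on each branch,
#' split into synonymous and non-synonymous classes, and polymorphisms are
#' planted on the focal population at drawn derived-allele frequencies, so
#' downstream counting can be checked against an exact ground-truth ledger.
#'
#' @param seed Integer seed; all randomness flows through it.
#' @param n_codons Gene length in codons (default 448, a typical
#'   full-length zinc-finger gene).
#' @param n_ingroup Number of ingroup haplotypes (default 200).
#' @param d_focal,d_sister,d_outgroup Named vectors \code{c(nonsyn =, syn =)}
#'   of fixed differences to plant on the focal branch, the sister branch
#'   and the outgroup stem.
#' @param poly Named vector \code{c(nonsyn =, syn =)} of polymorphisms to
#'   plant on the focal population at frequencies in \code{freq_range}.
#' @param poly_low Like \code{poly}, but planted as singletons (frequency
#'   \code{1/n_ingroup}), i.e. below a 5\% minor-allele-frequency filter for
#'   the default population size; used to exercise the filter.
#' @param freq_range Range from which derived-allele frequencies of
#'   \code{poly} variants are drawn uniformly (default \code{c(0.1, 0.9)}).
#' @param multi_hit Allow several events in one codon. Default FALSE: every
#'   event gets its own codon, so pathway counting recovers planted counts
#'   exactly.
#' @param count_mode \code{"fixed"} plants exactly the requested counts;
#'   \code{"poisson"} treats each requested count as a Poisson mean (useful
#'   for null-distribution studies).
#' @param max_retries Rejection-sampling bound when a codon cannot host a
#'   requested change class (default 1000).
#' @return A \code{"simulation_config"} list.
#' @export
simulation_config <- function(seed = 1L, n_codons = 448L, n_ingroup = 200L,
                              d_focal = c(nonsyn = 17, syn = 8),
                              d_sister = c(nonsyn = 26, syn = 16),
                              d_outgroup = c(nonsyn = 20, syn = 20),
                              poly = c(nonsyn = 14, syn = 20),
                              poly_low = c(nonsyn = 0, syn = 0),
                              freq_range = c(0.1, 0.9),
                              multi_hit = FALSE,
                              count_mode = c("fixed", "poisson"),
                              max_retries = 1000L) {
  count_mode <- match.arg(count_mode)
  stopifnot(n_ingroup >= 2L, n_codons >= 1L,
            all(c(d_focal, d_sister, d_outgroup, poly, poly_low) >= 0),
            freq_range[1L] > 0, freq_range[2L] < 1,
            freq_range[1L] <= freq_range[2L])
  structure(as.list(environment()), class = "simulation_config")
}

# single-nucleotide changes of a given class available from a codon,
# excluding changes that create a stop
.candidate_changes <- function(codon, class, code) {
  chars <- strsplit(codon, "")[[1]]
  out <- list()
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      nxt <- chars; nxt[pos] <- alt
      nxt_codon <- paste(nxt, collapse = "")
      if (.is_stop(nxt_codon, code)) next
      cls <- .classify_step(codon, nxt_codon, code)
      if (cls == class)
        out[[length(out) + 1L]] <- list(pos = pos, alt = alt, codon = nxt_codon)
    }
  }
  out
}

.draw_count <- function(x, mode) {
  if (mode == "poisson") stats::setNames(stats::rpois(length(x), x), names(x))
  else round(x)
}

#' Simulate a gene history with a ground-truth ledger
#'
#' Draws a stop-free ancestral codon sequence, plants the configured
#' synonymous/non-synonymous substitutions on the focal, sister and
#' outgroup-stem branches and the configured polymorphisms on the focal
#' population, and returns the resulting \code{PopulationAlignment} together
#' with a \code{TruthLedger} recording every planted event and the planted
#' count totals. With \code{multi_hit = FALSE} all events occupy distinct
#' codons, so \code{\link{run_mk}} recovers the planted quadruple exactly.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{alignment} (a \code{PopulationAlignment} with
#'   outgroup) and \code{ledger}: \code{events} data frame (branch, codon,
#'   site, ancestral and derived codon/allele, class, frequency,
#'   below_threshold) and \code{totals} (planted Pn, Ps, per-branch Dn/Ds,
#'   and unpolarized Dn/Ds over focal + sister).
#' @export
simulate_gene_history <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  code <- standard_genetic_code()
  sense <- sense_codons(code)
  n <- config$n_codons
  anc <- sample(sense, n, replace = TRUE)

  counts <- list(
    focal = .draw_count(config$d_focal, config$count_mode),
    sister = .draw_count(config$d_sister, config$count_mode),
    outgroup = .draw_count(config$d_outgroup, config$count_mode)
  )
  poly_counts <- .draw_count(config$poly, config$count_mode)
  poly_low_counts <- .draw_count(config$poly_low, config$count_mode)

  wanted <- c(sum(unlist(counts)), sum(poly_counts), sum(poly_low_counts))
  if (!config$multi_hit && sum(wanted) > n)
    stop("more events requested (", sum(wanted), ") than codons (", n,
         ") with multi_hit disallowed")

  used <- logical(n)
  seqs <- list(focal = anc, sister = anc, outgroup = anc)
  events <- list()

  plant_substitution <- function(branch, class) {
    for (try in seq_len(config$max_retries)) {
      i <- sample.int(n, 1L)
      if (!config$multi_hit && used[i]) next
      cand <- .candidate_changes(seqs[[branch]][i], class, code)
      if (!length(cand)) next
      ch <- cand[[sample.int(length(cand), 1L)]]
      old <- seqs[[branch]][i]
      seqs[[branch]][i] <<- ch$codon
      used[i] <<- TRUE
      events[[length(events) + 1L]] <<- list(
        type = "divergence", branch = branch, codon = i,
        site = 3L * (i - 1L) + ch$pos,
        ancestral_codon = old, derived_codon = ch$codon,
        ancestral = substr(old, ch$pos, ch$pos), derived = ch$alt,
        class = class, frequency = 1, below_threshold = FALSE)
      return(invisible(TRUE))
    }
    stop("could not place a ", class, " substitution on branch ", branch,
         " after ", config$max_retries, " retries")
  }
  for (branch in names(counts))
    for (class in c("nonsyn", "syn"))
      for (k in seq_len(counts[[branch]][[class]]))
        plant_substitution(branch, class)

  # polymorphisms on the focal population
  n_hap <- config$n_ingroup
  hap <- matrix(rep(seqs$focal, each = n_hap), nrow = n_hap)
  plant_polymorphism <- function(class, low) {
    for (try in seq_len(config$max_retries)) {
      i <- sample.int(n, 1L)
      if (!config$multi_hit && used[i]) next
      cand <- .candidate_changes(seqs$focal[i], class, code)
      if (!length(cand)) next
      ch <- cand[[sample.int(length(cand), 1L)]]
      count <- if (low) 1L else {
        f <- stats::runif(1L, config$freq_range[1L], config$freq_range[2L])
        max(1L, min(n_hap - 1L, as.integer(round(f * n_hap))))
      }
      carriers <- sample.int(n_hap, count)
      hap[carriers, i] <<- ch$codon
      used[i] <<- TRUE
      events[[length(events) + 1L]] <<- list(
        type = "polymorphism", branch = "focal", codon = i,
        site = 3L * (i - 1L) + ch$pos,
        ancestral_codon = seqs$focal[i], derived_codon = ch$codon,
        ancestral = substr(seqs$focal[i], ch$pos, ch$pos), derived = ch$alt,
        class = class, frequency = count / n_hap, below_threshold = low)
      return(invisible(TRUE))
    }
    stop("could not place a ", class, " polymorphism after ",
         config$max_retries, " retries")
  }
  for (class in c("nonsyn", "syn")) {
    for (k in seq_len(poly_counts[[class]])) plant_polymorphism(class, low = FALSE)
    for (k in seq_len(poly_low_counts[[class]])) plant_polymorphism(class, low = TRUE)
  }

  events <- .bind_records(events, data.frame(
    type = character(), branch = character(), codon = integer(),
    site = integer(), ancestral_codon = character(),
    derived_codon = character(), ancestral = character(),
    derived = character(), class = character(),
    frequency = numeric(), below_threshold = logical()))
  totals <- list(
    Pn = poly_counts[["nonsyn"]], Ps = poly_counts[["syn"]],
    Pn_low = poly_low_counts[["nonsyn"]], Ps_low = poly_low_counts[["syn"]],
    Dn_focal = counts$focal[["nonsyn"]], Ds_focal = counts$focal[["syn"]],
    Dn_sister = counts$sister[["nonsyn"]], Ds_sister = counts$sister[["syn"]],
    Dn_outgroup = counts$outgroup[["nonsyn"]], Ds_outgroup = counts$outgroup[["syn"]],
    Dn = counts$focal[["nonsyn"]] + counts$sister[["nonsyn"]],
    Ds = counts$focal[["syn"]] + counts$sister[["syn"]]
  )
  aln <- population_alignment(
    ingroup = apply(hap, 1L, paste, collapse = ""),
    sister = paste(seqs$sister, collapse = ""),
    outgroup = paste(seqs$outgroup, collapse = ""),
    name = paste0("sim_seed", config$seed)
  )
  list(alignment = aln, ledger = list(events = events, totals = totals))
}

#' Simulate a gene attribute table with a planted odds ratio
#'
#' Draws independent per-gene attributes: selection status, essentiality
#' conditional on selection status (so the planted selection-essentiality
#' odds ratio is known), conservation, and a missing-phenotype mask.
#'
#' @param n_genes Number of genes (default 91, the study-scale family size).
#' @param p_selected Probability a gene is positively selected.
#' @param p_essential_given_selected,p_essential_given_not Conditional
#'   essentiality probabilities.
#' @param p_missing Probability the essentiality call is missing.
#' @param p_conserved Probability a gene is conserved across all species.
#' @param seed Integer seed.
#' @return List with \code{table} (a \code{gene_attribute_table}) and
#'   \code{ledger} holding the parameters and the planted odds ratio.
#' @export
simulate_gene_table <- function(n_genes = 91L, p_selected = 12 / 91,
                                p_essential_given_selected = 8 / 12,
                                p_essential_given_not = 14 / 73,
                                p_missing = 6 / 91, p_conserved = 61 / 91,
                                seed = 1L) {
  stopifnot(all(c(p_selected, p_essential_given_selected,
                  p_essential_given_not, p_missing, p_conserved) >= 0),
            all(c(p_selected, p_essential_given_selected,
                  p_essential_given_not, p_missing, p_conserved) <= 1))
  set.seed(seed)
  selected <- stats::rbinom(n_genes, 1L, p_selected) == 1L
  p_ess <- ifelse(selected, p_essential_given_selected, p_essential_given_not)
  essential <- ifelse(stats::rbinom(n_genes, 1L, p_ess) == 1L, "yes", "no")
  essential[stats::rbinom(n_genes, 1L, p_missing) == 1L] <- "missing"
  conserved <- ifelse(stats::rbinom(n_genes, 1L, p_conserved) == 1L, "yes", "no")
  tab <- load_gene_table(data.frame(
    gene = sprintf("simgene%03d", seq_len(n_genes)),
    essential = essential,
    conserved_all_species = conserved,
    positively_selected = ifelse(selected, "yes", "no"),
    stringsAsFactors = FALSE
  ))
  or <- (p_essential_given_selected / (1 - p_essential_given_selected)) /
    (p_essential_given_not / (1 - p_essential_given_not))
  list(table = tab,
       ledger = list(odds_ratio = or, p_selected = p_selected,
                     p_essential_given_selected = p_essential_given_selected,
                     p_essential_given_not = p_essential_given_not,
                     p_missing = p_missing, seed = seed))
}

#' Simulate a genome with planted repeat instances
#'
#' Generates random-background contigs and plants non-overlapping instances
#' of the catalogued repeat types at recorded coordinates. Simple-repeat
#' types (names of the form \code{(MOTIF)n}) are filled with tandem copies
#' of their motif; other types get an independent random sequence per
#' instance. The ledger records every planted coordinate and sequence.
#'
#' @param repeat_catalog Data frame with columns \code{repeat_type},
#'   \code{length} (instance length, bp) and \code{n_instances}.
#' @param n_contigs Number of contigs (default 2).
#' @param contig_length Length of each contig in bp (default 10000).
#' @param seed Integer seed.
#' @return List: \code{genome} (a \code{DNAStringSet}), \code{annotations}
#'   (data frame as from \code{\link{read_repeat_annotations}}, 0-based
#'   half-open, in planting order) and \code{ledger} (annotations plus the
#'   planted sequence of every instance).
#' @export
simulate_repeat_genome <- function(repeat_catalog, n_contigs = 2L,
                                   contig_length = 10000L, seed = 1L) {
  stopifnot(nrow(repeat_catalog) >= 1L,
            all(c("repeat_type", "length", "n_instances") %in% names(repeat_catalog)))
  if (any(repeat_catalog$length > contig_length))
    stop("repeat instance longer than contig")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  contigs <- vapply(seq_len(n_contigs), function(i)
    paste(sample(bases, contig_length, replace = TRUE), collapse = ""),
    character(1))
  names(contigs) <- paste0("contig", seq_len(n_contigs))
  free_from <- stats::setNames(rep(1L, n_contigs), names(contigs))  # 1-based cursor
  ledger <- list()
  for (r in seq_len(nrow(repeat_catalog))) {
    rt <- repeat_catalog$repeat_type[r]
    len <- repeat_catalog$length[r]
    motif <- regmatches(rt, regexec("^\\(([ACGT]+)\\)n$", rt))[[1]]
    for (k in seq_len(repeat_catalog$n_instances[r])) {
      # place sequentially with a random gap, cycling over contigs
      chrom <- names(contigs)[(length(ledger) %% n_contigs) + 1L]
      gap <- sample(50:200, 1L)
      start1 <- free_from[[chrom]] + gap
      if (start1 + len - 1L > contig_length)
        stop("contig ", chrom, " too short for requested instances")
      seq_inst <- if (length(motif) >= 2L)
        substr(strrep(motif[[2L]], ceiling(len / nchar(motif[[2L]]))), 1L, len)
      else paste(sample(bases, len, replace = TRUE), collapse = "")
      substr(contigs[[chrom]], start1, start1 + len - 1L) <- seq_inst
      free_from[[chrom]] <- start1 + len
      ledger[[length(ledger) + 1L]] <- data.frame(
        repeat_type = rt, chrom = chrom, start = start1 - 1L,
        end = start1 - 1L + len, strand = sample(c("+", "-"), 1L),
        sequence = seq_inst, stringsAsFactors = FALSE)
    }
  }
  ledger <- do.call(rbind, ledger)
  list(genome = Biostrings::DNAStringSet(contigs),
       annotations = ledger[, c("repeat_type", "chrom", "start", "end", "strand")],
       ledger = ledger)
}

#' Write simulated repeat-genome outputs in standard dialects
#'
#' Emits the genome FASTA, the simplified annotation TSV, and a minimal
#' RepeatMasker-style \code{.out} file (1-based inclusive coordinates,
#' strand \code{C} for minus) for dialect round-trip checks.
#'
#' @param sim Result of \code{\link{simulate_repeat_genome}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_repeat_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  tsv <- file.path(dir, "repeats.tsv")
  out <- file.path(dir, "repeats.out")
  Biostrings::writeXStringSet(sim$genome, fa)
  utils::write.table(sim$annotations, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  a <- sim$annotations
  lines <- c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat   class/family",
    "",
    sprintf("  100    0.0  0.0  0.0  %s  %d  %d  (0)  %s  %s  Unknown  1  %d  (0)  %d",
            a$chrom, a$start + 1L, a$end, ifelse(a$strand == "-", "C", "+"),
            a$repeat_type, a$end - a$start, seq_len(nrow(a)))
  )
  writeLines(lines, out)
  c(genome = fa, tsv = tsv, rmout = out)
}
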