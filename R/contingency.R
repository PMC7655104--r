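#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric two-tailed p-value: with both margins fixed, the
#' probabilities of all tables whose point probability does not exceed that
#' of the observed table are summed. This is the "sum of less-probable
#' tables" convention (as in \code{stats::fisher.test}), not the doubling of
#' the smaller one-sided tail; the two definitions differ for asymmetric
#' margins.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return The p-value. A table with a zero row or column margin carries no
#'   information about association and returns 1 by convention, with a
#'   \code{"degenerate"} attribute set.
#' @examples
#' fisher_exact_two_tailed(matrix(c(8, 4, 14, 59), 2, byrow = TRUE))
#' @export
fisher_exact_two_tailed <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  r <- rowSums(table); cl <- colSums(table); n <- sum(table)
  if (any(r == 0) || any(cl == 0))
    return(structure(1, degenerate = TRUE))
  # support of cell (1,1) given the margins
  support <- max(0L, r[1L] - cl[2L]):min(r[1L], cl[1L])
  probs <- stats::dhyper(support, cl[1L], cl[2L], r[1L])
  p_obs <- stats::dhyper(table[1L, 1L], cl[1L], cl[2L], r[1L])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Pearson chi-square test of homogeneity for a 2x2 table
#'
#' One-degree-of-freedom Pearson X-squared, by default without the Yates
#' continuity correction (the form under which published MK-table p-values
#' reproduce from their printed counts).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param correct Apply the Yates continuity correction. Default FALSE.
#' @return The p-value.
#' @examples
#' chi_square_test(matrix(c(52, 24, 14, 20), 2, byrow = TRUE))  # ~0.007
#' @export
chi_square_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(!is.finite(expected)) || any(expected == 0))
    stop("chi-square undefined: zero expected cell count")
  # small-expected-count warnings are routine for domain-level tables and
  # the exact Fisher alternative is always reported alongside
  suppressWarnings(stats::chisq.test(table, correct = correct)$p.value)
}

#' Likelihood-ratio (G) test for a 2x2 table
#'
#' G = 2 * sum(O * log(O/E)) on one degree of freedom; zero observed cells
#' contribute nothing to the sum.
#'
#' @inheritParams chi_square_test
#' @param williams Apply Williams' correction for small samples.
#' @return The p-value.
#' @export
g_test <- function(table, williams = FALSE) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(!is.finite(expected)) || any(expected == 0))
    stop("G-test undefined: zero expected cell count")
  o <- table[table > 0]
  e <- expected[table > 0]
  g <- 2 * sum(o * log(o / e))
  if (williams) {
    q <- 1 + ((n / rowSums(table)[1L] + n / rowSums(table)[2L] - 1) *
              (n / colSums(table)[1L] + n / colSums(table)[2L] - 1)) / (6 * n)
    g <- g / q
  }
  stats::pchisq(g, df = 1, lower.tail = FALSE)
}
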