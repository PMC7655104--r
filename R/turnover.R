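#' @importFrom ape read.tree getMRCA node.depth.edgelength Ntip
NULL

#' Node ages of a dated tree
#'
#' Ages in the tree's time unit (conventionally million years), measured from
#' the leaves; assumes an ultrametric tree, which is checked to a small
#' tolerance.
#'
#' @param tree An \code{ape::phylo} with branch lengths in time units.
#' @return Numeric vector of ages indexed by ape node number (tips first,
#'   then internal nodes).
#' @export
node_ages <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(ape::Ntip(tree))]) - depth
  tip_age <- age[seq_len(ape::Ntip(tree))]
  if (any(abs(tip_age) > 1e-6 * max(age)))
    warning("tree is not ultrametric; leaf ages differ from 0")
  age
}

#' Infer the minimum age of a gene from its ortholog presence pattern
#'
#' The minimum gene age is the age of the most recent common ancestor of all
#' species carrying an ortholog - equivalently the divergence time of the
#' two most distantly related species that still encode the gene.
#'
#' @param present Character vector of species (tree leaf labels) in which an
#'   ortholog was found.
#' @param tree A dated \code{ape::phylo}.
#' @return List: \code{age} (time units, 0 for a species-specific gene),
#'   \code{origin_node} (ape node number of the origin clade) and
#'   \code{species_specific} flag.
#' @export
infer_gene_age <- function(present, tree) {
  present <- unique(present)
  if (!length(present)) stop("gene must be present in at least one species")
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  if (length(present) == 1L) {
    node <- match(present, tree$tip.label)
    return(list(age = 0, origin_node = node, species_specific = TRUE))
  }
  node <- ape::getMRCA(tree, present)
  list(age = unname(node_ages(tree)[node]), origin_node = node,
       species_specific = FALSE)
}

# children of a node (works for multifurcations)
.children <- function(tree, node) tree$edge[tree$edge[, 1L] == node, 2L]

# leaf labels under a node
.leaves_under <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  if (node <= n_tip) return(tree$tip.label[node])
  unlist(lapply(.children(tree, node), .leaves_under, tree = tree))
}

#' Infer gene-loss events under single-origin (Dollo) parsimony
#'
#' Assumes the gene arose once, on the branch above the most recent common
#' ancestor of all species that carry it, and was never regained. Each
#' maximal subtree within the origin clade containing no carrier species is
#' then one loss event; this assignment is the minimum number of losses
#' consistent with a single origin.
#'
#' @inheritParams infer_gene_age
#' @return List: \code{n_losses}, \code{loss_nodes} (ape node numbers of the
#'   roots of lost clades), \code{lost_clades} (list of leaf-label vectors),
#'   \code{origin_node} and \code{age}.
#' @export
infer_losses <- function(present, tree) {
  origin <- infer_gene_age(present, tree)
  loss_nodes <- integer()
  if (!origin$species_specific) {
    recurse <- function(node) {
      leaves <- .leaves_under(tree, node)
      if (!any(leaves %in% present)) {
        loss_nodes <<- c(loss_nodes, node)   # maximal absent subtree: one loss
        return(invisible())
      }
      if (node > ape::Ntip(tree))
        for (ch in .children(tree, node)) recurse(ch)
    }
    for (ch in .children(tree, origin$origin_node)) recurse(ch)
  }
  list(n_losses = length(loss_nodes), loss_nodes = loss_nodes,
       lost_clades = lapply(loss_nodes, .leaves_under, tree = tree),
       origin_node = origin$origin_node, age = origin$age)
}

#' Gene age and loss summary for a presence/absence matrix
#'
#' @param presence Genes x species matrix (0/1 or logical) or a data frame /
#'   TSV path in that shape with gene identifiers as row names or a
#'   \code{gene} first column; column names must be tree leaf labels.
#' @param tree A dated \code{ape::phylo}.
#' @return Data frame: gene, age, n_losses, lost_clades (comma-separated
#'   clade descriptions), species_specific.
#' @export
turnover_summary <- function(presence, tree) {
  if (is.character(presence) && length(presence) == 1L) {
    presence <- utils::read.delim(presence, stringsAsFactors = FALSE,
                                  check.names = FALSE)
  }
  if (is.data.frame(presence)) {
    if ("gene" %in% names(presence)) {
      rownames(presence) <- presence$gene
      presence$gene <- NULL
    }
    presence <- as.matrix(presence)
  }
  mode(presence) <- "logical"
  if (any(rowSums(presence) == 0))
    stop("gene(s) present in no species: ",
         paste(rownames(presence)[rowSums(presence) == 0], collapse = ", "))
  rows <- lapply(rownames(presence), function(g) {
    sp <- colnames(presence)[presence[g, ]]
    loss <- infer_losses(sp, tree)
    data.frame(gene = g, age = loss$age, n_losses = loss$n_losses,
               lost_clades = paste(vapply(loss$lost_clades, paste,
                                          character(1), collapse = "+"),
                                   collapse = ","),
               species_specific = length(sp) == 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
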