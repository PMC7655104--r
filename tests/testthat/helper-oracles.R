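# Independent oracles used by the property tests. These deliberately share no
# code with the package internals.

oracle_code <- Biostrings::GENETIC_CODE

# all orderings of a site vector, built by filtering the k-fold cartesian
# product down to permutations (independent of the package's recursion)
oracle_orderings <- function(pos) {
  k <- length(pos)
  grid <- as.matrix(expand.grid(rep(list(pos), k)))
  grid[apply(grid, 1L, function(r) length(unique(r)) == k), , drop = FALSE]
}

# brute-force pathway averaging between two codons
oracle_pathway <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  pos <- which(av != bv)
  if (!length(pos)) return(list(n_diff = 0L, dn = 0, ds = 0, n_paths_used = 0L))
  ords <- oracle_orderings(pos)
  res <- apply(ords, 1L, function(ord) {
    cur <- av; dn <- 0; ds <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- bv[p]
      if (oracle_code[[paste(nxt, collapse = "")]] == "*") blocked <- TRUE
      if (oracle_code[[paste(cur, collapse = "")]] ==
          oracle_code[[paste(nxt, collapse = "")]]) ds <- ds + 1 else dn <- dn + 1
      cur <- nxt
    }
    c(dn = dn, ds = ds, blocked = blocked)
  })
  ok <- res["blocked", ] == 0
  use <- if (any(ok)) res[, ok, drop = FALSE] else res
  list(n_diff = length(pos), dn = mean(use["dn", ]), ds = mean(use["ds", ]),
       n_paths_used = ncol(use))
}

# minimum number of losses explaining a presence pattern under a single
# origin at the MRCA of the present leaves, by exhaustive search over loss
# placements on the edges of the origin subtree
oracle_min_losses <- function(tree, present) {
  origin <- if (length(present) == 1L) match(present, tree$tip.label)
            else ape::getMRCA(tree, present)
  # edges within the origin clade
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    c(node, unlist(lapply(kids, desc)))
  }
  clade_nodes <- desc(origin)
  edge_idx <- which(tree$edge[, 1L] %in% clade_nodes)
  n_tip <- ape::Ntip(tree)
  tips <- clade_nodes[clade_nodes <= n_tip]
  # path edges from origin to each tip
  path_edges <- lapply(tips, function(t) {
    path <- integer(); node <- t
    while (node != origin) {
      e <- which(tree$edge[, 2L] == node)
      path <- c(path, e)
      node <- tree$edge[e, 1L]
    }
    path
  })
  is_present <- tree$tip.label[tips] %in% present
  best <- Inf
  for (mask in 0:(2^length(edge_idx) - 1L)) {
    losses <- edge_idx[bitwAnd(mask, 2^(seq_along(edge_idx) - 1L)) > 0]
    if (length(losses) >= best) next
    absent <- vapply(path_edges, function(pe) any(pe %in% losses), logical(1))
    if (all(absent == !is_present)) best <- length(losses)
  }
  best
}

# small helper for hand-built alignments
make_aln <- function(ingroup, sister, outgroup = NULL, name = "toy",
                     validate = TRUE) {
  population_alignment(ingroup, sister, outgroup, name = name,
                       validate = validate)
}
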