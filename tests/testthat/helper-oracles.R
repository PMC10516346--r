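# Independent brute-force patristic oracle: for each tip, walk the edge list
# up to the root accumulating branch lengths, then sum the unshared parts of
# the two root paths. Shares no code with patristic_distances().
oracle_patristic <- function(tree, labels = tree$tip.label) {
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_to_root <- function(node) {
    nodes <- node
    lens <- numeric(0)
    while (node != root) {
      row <- which(tree$edge[, 2] == node)
      lens <- c(lens, tree$edge.length[row])
      node <- tree$edge[row, 1]
      nodes <- c(nodes, node)
    }
    list(nodes = nodes, lens = lens)
  }
  tipno <- match(labels, tree$tip.label)
  paths <- lapply(tipno, path_to_root)
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      pi <- paths[[i]]; pj <- paths[[j]]
      shared <- intersect(pi$nodes, pj$nodes)
      # depth of the most recent common ancestor along each path
      ki <- min(match(shared, pi$nodes))
      kj <- min(match(shared, pj$nodes))
      m[i, j] <- sum(pi$lens[seq_len(ki - 1)]) +
        sum(pj$lens[seq_len(kj - 1)])
    }
  }
  m
}

# small noiseless configuration used across tests; any argument can be
# overridden
noiseless_config <- function(...) {
  args <- list(sigma_species = 0, sigma_plate = 0, sigma_resid = 0,
               sigma_obs = 0, dropout_prob = 0)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}
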