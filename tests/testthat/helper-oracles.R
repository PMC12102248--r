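# Independent oracles used across the suite.

# Exhaustive small-parsimony oracle: minimum number of state changes over
# all assignments of APO/DPO to the internal nodes of a rooted tree.
# The constrained variant scores the pseudo-tip-augmented tree: a
# zero-length leaf carrying `root_state` hangs off the root, so histories
# whose root is not in that state pay one extra change (this is the
# statistic fitch_min_changes() documents).  Exponential in the number of
# internal nodes; intended for trees of <= 12 tips.
brute_force_parsimony <- function(phy, states, root_state = NULL) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  stopifnot(nnode <= 16)
  tip_code <- ifelse(states[phy$tip.label] == "DPO", 1L, 0L)
  best <- Inf
  for (mask in 0:(2^nnode - 1L)) {
    internal <- as.integer(intToBits(mask))[seq_len(nnode)]
    node_state <- c(tip_code, internal)
    chg <- sum(node_state[phy$edge[, 1L]] != node_state[phy$edge[, 2L]])
    if (!is.null(root_state))        # node ntip+1 is the root
      chg <- chg + (internal[1L] != (root_state == "DPO"))
    best <- min(best, chg)
  }
  best
}

# Grid + 1-D optimisation oracle for MAD rooting: for every branch,
# numerically minimise the RMS root-spanning deviation over the root
# position, independent of the closed form used by mad_root().
mad_oracle <- function(phy) {
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  D <- ape::dist.nodes(phy)
  post <- stats::reorder(phy, "postorder")$edge
  below <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (e in seq_len(nrow(post)))
    below[[post[e, 1]]] <- c(below[[post[e, 1]]], below[[post[e, 2]]])

  score_at <- function(e, rho) {
    u <- phy$edge[e, 1]; v <- phy$edge[e, 2]; L <- phy$edge.length[e]
    tv <- below[[v]]; tu <- setdiff(seq_len(ntip), tv)
    dev <- c(outer(D[u, tu] + rho, D[v, tv] + (L - rho),
                   function(db, dc) abs(2 * db / (db + dc) - 1)))
    sqrt(mean(dev^2))
  }
  res <- lapply(seq_len(nrow(phy$edge)), function(e) {
    L <- phy$edge.length[e]
    grid <- seq(0, L, length.out = 101)
    g <- vapply(grid, function(r) score_at(e, r), numeric(1))
    i <- which.min(g)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    o <- stats::optimize(function(r) score_at(e, r), c(lo, hi),
                         tol = 1e-10)
    ends <- c(score_at(e, 0), score_at(e, L))
    if (min(ends) < o$objective) {
      pos <- c(0, L)[which.min(ends)]
      list(score = min(ends), rho = pos)
    } else list(score = o$objective, rho = o$minimum)
  })
  scores <- vapply(res, `[[`, numeric(1), "score")
  e <- which.min(scores)
  list(edge = e, rho = res[[e]]$rho, score = scores[e],
       split = sort(phy$tip.label[below[[phy$edge[e, 2]]]]))
}

# tip labels below a node, tolerating tip nodes
tips_under <- function(phy, node) {
  if (node <= length(phy$tip.label)) return(phy$tip.label[node])
  ape::extract.clade(phy, node)$tip.label
}

# The bipartition a rooted tree's root implies: sorted tip labels of each
# of the root's child clades.
root_split_of <- function(rooted) {
  root <- length(rooted$tip.label) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  lapply(kids, function(k) sort(tips_under(rooted, k)))
}
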