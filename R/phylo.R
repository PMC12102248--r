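#' A gene tree with APO/DPO tip states
#'
#' Couples an `ape` phylo object with a binary character marking, for each
#' tip genome, whether its phosphite-dehydrogenase gene co-occurs with
#' dissimilatory-pathway genes (state `DPO`) or not (state `APO`).  States
#' are supplied as a side table rather than parsed from tip labels, keeping
#' the Newick file standard-clean.
#'
#' @param tree an `ape::phylo` tree.
#' @param states named character vector (or two-column data.frame with
#'   columns `tip` and `state`) mapping every tip label to `"APO"` or
#'   `"DPO"`.
#' @return object of class `labeled_tree`.
#' @export
labeled_tree <- function(tree, states) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object",
                                     call. = FALSE)
  if (is.data.frame(states)) {
    .assert_cols(states, c("tip", "state"), "states")
    states <- stats::setNames(as.character(states$state),
                              as.character(states$tip))
  }
  if (is.null(names(states)))
    stop("'states' must be named by tip label", call. = FALSE)
  unknown <- setdiff(names(states), tree$tip.label)
  if (length(unknown))
    stop("state table names tip(s) absent from the tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop("tip(s) without a state: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(states), c("APO", "DPO"))
  if (length(bad))
    stop("states must be 'APO' or 'DPO' (got: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("branch lengths must be >= 0", call. = FALSE)
  structure(list(tree = tree,
                 states = states[tree$tip.label]),
            class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat(sprintf("Labeled gene tree: %d tips (%d APO, %d DPO), %s\n",
              length(x$tree$tip.label), sum(x$states == "APO"),
              sum(x$states == "DPO"),
              if (ape::is.rooted(x$tree)) "rooted" else "unrooted"))
  invisible(x)
}

#' Parse a Newick string or file into a labeled tree
#'
#' @param text Newick string (use either `text` or `file`).
#' @param file path to a Newick file.
#' @param states tip-state table as in [labeled_tree()].
#' @return a `labeled_tree`.
#' @export
parse_newick <- function(text = NULL, file = NULL, states) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'", call. = FALSE)
  tree <- tryCatch(
    withCallingHandlers(
      if (is.null(text)) ape::read.tree(file = file)
      else ape::read.tree(text = text),
      warning = function(w) stop(conditionMessage(w), call. = FALSE)),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error: input is not a single well-formed tree",
         call. = FALSE)
  labeled_tree(tree, states)
}

#' Write a labeled tree to Newick
#'
#' @param x a `labeled_tree` or `phylo`.
#' @param file optional path; when missing the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(x, file = NULL) {
  tree <- if (inherits(x, "labeled_tree")) x$tree else x
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Test whether the tips carrying a state form one clade
#'
#' True when the tips in the given state are exactly the leaf set of a
#' single clade of the rooted tree.  A single tip is a (degenerate) clade,
#' as is the full tip set.
#'
#' @param x a `labeled_tree`; must be rooted.
#' @param state `"APO"` or `"DPO"`.
#' @return logical flag.
#' @export
is_monophyletic <- function(x, state) {
  stopifnot(inherits(x, "labeled_tree"))
  if (!ape::is.rooted(x$tree))
    stop("monophyly requires a rooted tree", call. = FALSE)
  tips <- names(x$states)[x$states == state]
  if (length(tips) == 0L)
    stop(sprintf("state '%s' is absent from the tree", state), call. = FALSE)
  if (length(tips) %in% c(1L, length(x$tree$tip.label))) return(TRUE)
  ape::is.monophyletic(x$tree, tips)
}

# Fitch state sets, postorder.  Returns list(changes, root_set) where
# root_set is a logical pair (APO, DPO).  Sequential pairwise combination;
# exact for binary trees (multifurcations are resolved by the caller).
.fitch_pass <- function(phy, states) {
  phy <- stats::reorder(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  sets <- matrix(FALSE, nnode, 2L)
  sets[cbind(seq_len(ntip), match(states[phy$tip.label], c("APO", "DPO")))] <-
    TRUE
  seen <- logical(nnode)
  seen[seq_len(ntip)] <- TRUE
  changes <- 0L
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    if (!seen[p]) {                # first child initialises the parent set
      sets[p, ] <- sets[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- sets[p, ] & sets[ch, ]
      if (any(inter)) sets[p, ] <- inter
      else {
        sets[p, ] <- sets[p, ] | sets[ch, ]
        changes <- changes + 1L
      }
    }
  }
  root <- ntip + 1L
  list(changes = changes, root_set = sets[root, ])
}

#' Minimum number of APO/DPO switches on a rooted gene tree
#'
#' Fitch small parsimony: the minimum number of state changes needed to
#' explain the tip states on the rooted tree.  With
#' `root_state = "free"` the root's ancestral state is unconstrained; fixing
#' it asks how many switches the history needs if the earliest gene was
#' associated with that pathway.  The constrained count is obtained by
#' attaching a zero-length pseudo-tip carrying the constrained state at the
#' root, which reduces the problem to standard Fitch: the count grows by
#' one exactly when the constrained state is not among the optimal free
#' root states.
#'
#' Multifurcating nodes are resolved arbitrarily into zero-length binary
#' splits (with a message), as consensus trees may contain polytomies.
#'
#' @param x a `labeled_tree`; must be rooted with every tip labeled.
#' @param root_state `"free"`, `"APO"` or `"DPO"`.
#' @return object of class `parsimony_result`: list with `min_changes`,
#'   `root_state_constraint` and `optimal_root_states` (the free-root
#'   optimal state set).
#' @examples
#' tr <- parse_newick("(((d1:1,d2:1):1,a1:1):1,a2:1);",
#'                    states = c(d1 = "DPO", d2 = "DPO",
#'                               a1 = "APO", a2 = "APO"))
#' fitch_min_changes(tr)$min_changes                       # 1
#' fitch_min_changes(tr, root_state = "DPO")$min_changes   # 2
#' @export
fitch_min_changes <- function(x, root_state = c("free", "APO", "DPO")) {
  stopifnot(inherits(x, "labeled_tree"))
  root_state <- match.arg(root_state)
  phy <- x$tree
  if (!ape::is.rooted(phy))
    stop("Fitch parsimony requires a rooted tree", call. = FALSE)
  if (anyNA(x$states)) stop("unlabeled tip(s)", call. = FALSE)
  if (!ape::is.binary(phy)) {
    message("multifurcating nodes resolved arbitrarily (zero-length splits)")
    phy <- ape::multi2di(phy)
  }
  pass <- .fitch_pass(phy, x$states)
  changes <- pass$changes
  root_set <- pass$root_set
  if (root_state != "free") {
    # pseudo-tip of the constrained state combined into the root set
    pseudo <- c(APO = root_state == "APO", DPO = root_state == "DPO")
    if (!any(root_set & pseudo)) changes <- changes + 1L
    root_set <- pseudo
  }
  structure(list(min_changes = changes,
                 root_state_constraint = root_state,
                 optimal_root_states = c("APO", "DPO")[pass$root_set]),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf("Fitch parsimony: %d change(s), root %s (free-root optima: %s)\n",
              x$min_changes, x$root_state_constraint,
              paste(x$optimal_root_states, collapse = "/")))
  invisible(x)
}

# tips below every node, as a list indexed by node id
.tips_below <- function(phy) {
  ntip <- length(phy$tip.label)
  out <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  edges <- stats::reorder(phy, "postorder")$edge
  for (e in seq_len(nrow(edges)))
    out[[edges[e, 1L]]] <- c(out[[edges[e, 1L]]], out[[edges[e, 2L]]])
  out
}

#' Root an unrooted gene tree by minimal ancestor deviation
#'
#' Considers every branch and every continuous root position along it.  For
#' a candidate root, each tip pair (b, c) separated by the root deviates
#' from clocklike behaviour by `|2 * d(root, b) / d(b, c) - 1|`; the root
#' minimising the root-mean-square of these deviations over all
#' root-spanning pairs is returned.  On a perfectly clocklike tree the
#' optimum deviation is zero at the midpoint of the basal branch.  The
#' optimal position on each branch has a closed form (the deviations are
#' affine in the position); ties between branches are broken by the first
#' branch in the tree's edge-matrix traversal, with a message.
#'
#' @param x a `labeled_tree` or `phylo` with >= 3 tips and positive total
#'   branch length.  A rooted input is unrooted first.
#' @return rooted tree of the same class as the input, with attributes
#'   `mad_score` (the minimised RMS deviation), `root_position` and
#'   `root_split` (tip labels on one side of the root).
#' @export
mad_root <- function(x) {
  states <- NULL
  phy <- if (inherits(x, "labeled_tree")) { states <- x$states; x$tree }
         else x
  if (!inherits(phy, "phylo")) stop("'x' must be a tree", call. = FALSE)
  if (length(phy$tip.label) < 3L)
    stop("MAD rooting needs >= 3 tips", call. = FALSE)
  if (is.null(phy$edge.length))
    stop("MAD rooting needs branch lengths", call. = FALSE)
  if (all(phy$edge.length == 0))
    stop("all branch lengths are zero: deviations undefined", call. = FALSE)
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)

  ntip <- length(phy$tip.label)
  D <- ape::dist.nodes(phy)
  below <- .tips_below(phy)
  all_tips <- seq_len(ntip)

  n_edges <- nrow(phy$edge)
  scores <- rep(Inf, n_edges)
  rhos <- rep(NA_real_, n_edges)
  for (e in seq_len(n_edges)) {
    u <- phy$edge[e, 1L]; v <- phy$edge[e, 2L]
    L <- phy$edge.length[e]
    tips_v <- below[[v]]
    tips_u <- setdiff(all_tips, tips_v)
    if (!length(tips_v) || !length(tips_u)) next
    # spanning pairs: b on the u side, c on the v side
    dub <- D[u, tips_u]                       # d(u, b)
    dbc <- outer(dub + L, D[v, tips_v], "+")  # d(b, c)
    if (any(dbc == 0))
      stop("tip pair at zero distance: deviations undefined", call. = FALSE)
    a  <- 2 / dbc
    b0 <- 2 * dub / dbc - 1                   # recycles down columns
    rhos[e] <- min(max(-sum(a * b0) / sum(a * a), 0), L)
    scores[e] <- sqrt(mean((a * rhos[e] + b0)^2))
  }
  e <- which.min(scores)
  tied <- which(scores <= scores[e] + 1e-12)
  if (length(tied) > 1L)
    message(sprintf("MAD tie between branches %s; keeping branch %d",
                    paste(tied, collapse = ", "), e))
  best <- list(score = scores[e], edge = e, rho = rhos[e])
  v <- phy$edge[e, 2L]; L <- phy$edge.length[e]
  # root at distance rho from the rootward end of the branch, i.e. L - rho
  # above node v on its parent edge
  rooted <- phytools::reroot(phy, node.number = v, position = L - best$rho)
  out <- if (!is.null(states)) labeled_tree(rooted, states) else rooted
  attr(out, "mad_score") <- best$score
  attr(out, "root_position") <- best$rho
  attr(out, "root_split") <- sort(phy$tip.label[below[[v]]])
  out
}
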