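## Internal helpers around ape "phylo" objects. All modules address tree
## branches by the id of the node the branch leads INTO ("branch_id"):
## tip label for leaves, node label (assigned "n<k>" in preorder when the
## Newick carries none) for internal nodes. The root has no incoming branch.

.tree_index <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' tree")
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  root <- n_tip + 1L
  kids <- split(phy$edge[, 2], factor(phy$edge[, 1], levels = seq_len(n_node)))
  children <- lapply(kids, as.integer)
  parent <- integer(n_node)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  parent[root] <- 0L
  if (length(children[[root]]) != 2L) {
    stop("tree is unrooted (basal multifurcation with ",
         length(children[[root]]),
         " children); supply a rooted tree with a basal bifurcation")
  }
  brlen <- rep(NA_real_, n_node)
  if (!is.null(phy$edge.length)) brlen[phy$edge[, 2]] <- phy$edge.length
  ## preorder over nodes, root first
  preorder <- integer(n_node)
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- k + 1L
    preorder[k] <- v
    ch <- children[[v]]
    if (length(ch)) stack <- c(stack, rev(ch))
  }
  ## branch ids
  id <- character(n_node)
  id[seq_len(n_tip)] <- phy$tip.label
  lab <- phy$node.label
  internal_pre <- preorder[preorder > n_tip]
  auto <- sprintf("n%d", seq_along(internal_pre))
  for (i in seq_along(internal_pre)) {
    v <- internal_pre[i]
    l <- if (!is.null(lab)) lab[v - n_tip] else ""
    id[v] <- if (!is.na(l) && nzchar(l)) l else auto[i]
  }
  if (anyDuplicated(id)) {
    stop("duplicated node/tip labels in tree: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  list(phy = phy, n_tip = n_tip, n_node = n_node, root = root,
       parent = parent, children = children, preorder = preorder,
       postorder = rev(preorder), branch_id = id, brlen = brlen)
}

## indices of all nodes in the subtree rooted at v (v included)
.subtree_nodes <- function(ti, v) {
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    u <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, u)
    stack <- c(stack, ti$children[[u]])
  }
  out
}

## sum of branch lengths on the path root -> v (v's incoming branch included)
.depth_ks <- function(ti, v) {
  d <- 0
  while (v != ti$root) {
    d <- d + ti$brlen[v]
    v <- ti$parent[v]
  }
  d
}

## leaf labels under node v, sorted
.subtree_leaves <- function(ti, v) {
  nodes <- .subtree_nodes(ti, v)
  sort(ti$branch_id[nodes[nodes <= ti$n_tip]])
}
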