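#' LCA reconciliation of a gene tree against a species tree
#'
#' Maps every gene-tree node to the species-tree LCA of the species under it
#' and labels each internal node a `duplication` when its mapping coincides
#' with that of at least one child, otherwise a `speciation`. Paralogs are
#' thereby identified as homologs co-occurring in one genome. Alternatively,
#' a pre-reconciled gene tree can carry duplication tags in its internal
#' node labels (suffix `"D"` after an optional `*`), in which case the tags
#' are taken as-is via `use_labels = TRUE`.
#'
#' @param gtree [gene_tree].
#' @param stree [species_tree]; every species in the gene tree must occur.
#' @param use_labels If TRUE, trust `D`-suffixed internal node labels instead
#'   of LCA mapping (NOTUNG-style annotated input).
#' @return A `reconciled_tree`: the gene tree plus a `nodes` data.frame with
#'   columns `node`, `branch_id`, `parent_branch_id`, `length`, `is_leaf`,
#'   `species` (species-tree mapping), `event` (leaf/speciation/duplication),
#'   `gene_id`.
#' @export
lca_reconcile <- function(gtree, stree, use_labels = FALSE) {
  stopifnot(inherits(gtree, "gene_tree"), inherits(stree, "species_tree"))
  ti <- gtree$index
  si <- stree$index
  sp_of_tip <- gtree$species
  unknown <- setdiff(unique(sp_of_tip), stree$phy$tip.label)
  if (length(unknown)) {
    stop("species not present in the species tree: ",
         paste(unknown, collapse = ", "))
  }
  ## species-tree depth for LCA walking
  sdepth <- integer(si$n_node)
  for (v in si$preorder) {
    sdepth[v] <- if (v == si$root) 0L else sdepth[si$parent[v]] + 1L
  }
  slca <- function(a, b) {
    while (a != b) {
      if (sdepth[a] >= sdepth[b]) a <- si$parent[a] else b <- si$parent[b]
    }
    a
  }
  sp_node <- match(stree$phy$tip.label, stree$phy$tip.label) # tip index = node index
  M <- integer(ti$n_node)
  event <- character(ti$n_node)
  for (v in ti$postorder) {
    if (v <= ti$n_tip) {
      M[v] <- match(sp_of_tip[[ti$branch_id[v]]], stree$phy$tip.label)
      event[v] <- "leaf"
    } else {
      ch <- ti$children[[v]]
      m <- M[ch[1]]
      for (c2 in ch[-1]) m <- slca(m, M[c2])
      M[v] <- m
      event[v] <- if (any(M[ch] == m)) "duplication" else "speciation"
    }
  }
  if (use_labels) {
    for (v in ti$preorder) {
      if (v > ti$n_tip) {
        event[v] <- if (grepl("\\*?D$", ti$branch_id[v])) "duplication" else "speciation"
      }
    }
  }
  nodes <- data.frame(
    node = seq_len(ti$n_node),
    branch_id = ti$branch_id,
    parent_branch_id = ifelse(ti$parent == 0L, NA_character_,
                              ti$branch_id[pmax(ti$parent, 1L)]),
    length = ti$brlen,
    is_leaf = seq_len(ti$n_node) <= ti$n_tip,
    species = si$branch_id[M],
    event = event,
    gene_id = ifelse(seq_len(ti$n_node) <= ti$n_tip, ti$branch_id, NA_character_),
    stringsAsFactors = FALSE
  )
  structure(list(family_id = gtree$family_id, tree = gtree, stree = stree,
                 nodes = nodes, index = ti),
            class = "reconciled_tree")
}

#' Extract duplication records from a reconciled tree
#'
#' One record per duplication node. Its two clades are the branch sets of the
#' two child subtrees (each child's own incoming branch included); `clade1`
#' is the clade containing the lexicographically smallest leaf label.
#' `depth_ks` is the branch-length sum from the root down to (and including)
#' the duplication node's incoming branch — an age proxy in Ks units.
#' A duplication is flagged `terminal` when both clades are single terminal
#' branches.
#'
#' @param rtree `reconciled_tree` from [lca_reconcile()].
#' @return List with `duplications` (data.frame: `family_id`, `dup_id`,
#'   `clade1_ks`, `clade2_ks`, `clade1_n_branches`, `clade2_n_branches`,
#'   `depth_ks`, `terminal`) and `clade_branches` (long data.frame:
#'   `family_id`, `dup_id`, `clade`, `branch_id`).
#' @export
extract_duplications <- function(rtree) {
  stopifnot(inherits(rtree, "reconciled_tree"))
  ti <- rtree$index
  dups <- which(rtree$nodes$event == "duplication")
  recs <- list(); membs <- list()
  for (v in dups) {
    ch <- ti$children[[v]]
    sub <- lapply(ch, function(c) .subtree_nodes(ti, c))
    first_leaf <- vapply(sub, function(s) min(ti$branch_id[s[s <= ti$n_tip]]), "")
    ord <- order(first_leaf)
    sub <- sub[ord]
    ks <- vapply(sub, function(s) sum(ti$brlen[s]), 0)
    dup_id <- ti$branch_id[v]
    recs[[length(recs) + 1L]] <- data.frame(
      family_id = rtree$family_id, dup_id = dup_id,
      clade1_ks = ks[1], clade2_ks = ks[2],
      clade1_n_branches = length(sub[[1]]), clade2_n_branches = length(sub[[2]]),
      depth_ks = .depth_ks(ti, v),
      terminal = all(lengths(sub) == 1L),
      stringsAsFactors = FALSE
    )
    for (k in 1:2) {
      membs[[length(membs) + 1L]] <- data.frame(
        family_id = rtree$family_id, dup_id = dup_id, clade = k,
        branch_id = ti$branch_id[sub[[k]]], stringsAsFactors = FALSE
      )
    }
  }
  empty_d <- data.frame(family_id = character(), dup_id = character(),
                        clade1_ks = numeric(), clade2_ks = numeric(),
                        clade1_n_branches = integer(), clade2_n_branches = integer(),
                        depth_ks = numeric(), terminal = logical(),
                        stringsAsFactors = FALSE)
  empty_m <- data.frame(family_id = character(), dup_id = character(),
                        clade = integer(), branch_id = character(),
                        stringsAsFactors = FALSE)
  list(
    duplications = if (length(recs)) do.call(rbind, recs) else empty_d,
    clade_branches = if (length(membs)) do.call(rbind, membs) else empty_m
  )
}

#' Partition branches by duplication context
#'
#' A branch strictly below a duplication node belongs to the duplicated part
#' of the family (its substitutions are more terminal than the duplication);
#' the duplication node's own incoming branch does not. All other branches
#' are single-copy, qualified by whether the family harbours any duplication
#' at all.
#'
#' @param rtree `reconciled_tree`.
#' @return Named character vector branch_id -> context, one entry for every
#'   non-root branch; values in `c("duplicated", "single_copy_in_dup_family",
#'   "single_copy_no_dup_family")`.
#' @export
partition_branches <- function(rtree) {
  stopifnot(inherits(rtree, "reconciled_tree"))
  ti <- rtree$index
  is_dup <- rtree$nodes$event == "duplication"
  below_dup <- logical(ti$n_node)
  for (v in ti$preorder) {
    if (v == ti$root) next
    p <- ti$parent[v]
    below_dup[v] <- below_dup[p] || is_dup[p]
  }
  has_dup <- any(is_dup)
  single <- if (has_dup) "single_copy_in_dup_family" else "single_copy_no_dup_family"
  nodes <- setdiff(seq_len(ti$n_node), ti$root)
  stats::setNames(ifelse(below_dup[nodes], "duplicated", single),
                  ti$branch_id[nodes])
}
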