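## Shared fixtures: tiny trees, random instances and independent oracles.

## brute-force minimum-change count: exhaustive enumeration over all
## labelings of internal nodes (and of leaves carrying missing data) from a
## restricted alphabet; independent of the package's DP.
bf_fitch <- function(phy, column, alphabet) {
  n_tip <- length(phy$tip.label)
  leaf_state <- column[phy$tip.label]
  free_leaves <- which(leaf_state %in% c("-", "X"))
  internals <- sort(unique(phy$edge[, 1]))
  free <- c(free_leaves, internals)
  grid <- as.matrix(do.call(expand.grid,
                            c(rep(list(alphabet), length(free)),
                              list(stringsAsFactors = FALSE))))
  M <- matrix(NA_character_, nrow(grid), n_tip + phy$Nnode)
  M[, seq_len(n_tip)] <- rep(leaf_state, each = nrow(grid))
  M[, free] <- grid
  cost <- 0
  for (e in seq_len(nrow(phy$edge))) {
    cost <- cost + (M[, phy$edge[e, 1]] != M[, phy$edge[e, 2]])
  }
  min(cost)
}

## random rooted binary tree with unit branch lengths and a random column
random_instance <- function(n_tip, n_states, p_missing = 0.1) {
  phy <- ape::rtree(n_tip, rooted = TRUE)
  phy$node.label <- NULL
  alphabet <- aa_alphabet()[seq_len(n_states)]
  col <- sample(alphabet, n_tip, replace = TRUE)
  miss <- stats::runif(n_tip) < p_missing
  col[miss] <- "-"
  list(phy = phy, column = stats::setNames(col, phy$tip.label),
       alphabet = alphabet)
}

## the spec-style worked 5-leaf tree: (((A,A),(C,C)),A)
five_leaf_tree <- function() {
  ape::read.tree(text = "(((t1:1,t2:1)n2:1,(t3:1,t4:1)n3:1)n1:1,t5:1)root;")
}
five_leaf_column <- function() c(t1 = "A", t2 = "A", t3 = "C", t4 = "C", t5 = "A")

## small two-species fixture used across reconcile tests
two_species_tree <- function() species_tree(ape::read.tree(text = "(A:1,B:1);"))

## events implied by the full labeling set of an MPR enumeration:
## (intersection, union) over per-labeling event sets
mpr_event_sets <- function(mp, phy) {
  per <- lapply(mp$labelings, function(l) {
    e <- mpr_events(l, phy)
    paste(e$branch_id, e$source_aa, e$dest_aa)
  })
  list(intersection = Reduce(intersect, per), union = Reduce(union, per))
}

## brute-force BH step-up used as an oracle for bh_fdr
bf_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ks)) reject[o[seq_len(max(ks))]] <- TRUE
  reject
}

## one simulated family plus its reconciliation, shared by several tests
sim_family_fixture <- function(seed, n_species = 8, seq_length = 150,
                               dup_rate = 0.15, subst_rate = 0.05,
                               model = "symmetric", bias_strength = 0) {
  cfg <- simulation_config(n_species = n_species, seq_length = seq_length,
                           dup_rate = dup_rate, subst_rate = subst_rate,
                           model = model, bias_strength = bias_strength,
                           seed = seed)
  sim <- simulate_family(cfg, family_id = sprintf("fam%d", seed))
  sim$rtree <- lca_reconcile(sim$tree, sim$species_tree)
  sim
}

## minimal hand-made substitution record table
make_records <- function(src, dst, branch = NULL, family_id = "fam") {
  n <- length(src)
  if (is.null(branch)) branch <- sprintf("b%d", seq_len(n))
  if (n == 0L) return(make_records("A", "C")[0, ])
  data.frame(record_id = sprintf("%s:%d:1", family_id, seq_len(n)),
             family_id = family_id, site = seq_len(n), branch_id = branch,
             source_aa = src, dest_aa = dst, ambiguous = FALSE,
             n_alternatives = 0L, context = NA_character_,
             clade_ids = NA_character_, stringsAsFactors = FALSE)
}
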