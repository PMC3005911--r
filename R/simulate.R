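#' Simulation configuration
#'
#' Conditions of the synthetic gene families. Defaults emulate a
#' 12-genome-scale study: 12 species, root-to-tip depth 1.5 Ks, duplication
#' births at 0.08 per lineage per Ks, and an amino-acid substitution
#' intensity of 0.08 expected changes per site per Ks (so that whole-tree
#' substitutions per site land near the empirical ~0.4 and whole-tree
#' Ka/Ks near 0.08).
#'
#' @param species_tree Optional [species_tree]; when NULL a random rooted
#'   coalescent tree with `n_species` tips is drawn and scaled to
#'   `tree_depth`.
#' @param n_species Number of species when generating the species tree.
#' @param tree_depth Root-to-tip depth of the generated species tree (Ks).
#' @param dup_rate Duplication birth rate per gene lineage per unit branch
#'   length (Ks).
#' @param seq_length Number of alignment columns.
#' @param subst_rate Expected amino-acid changes per site per unit branch
#'   length.
#' @param model `"symmetric"` (uniform exchange) or `"biased"`
#'   (polarity-biased, see [biased_rate_matrix()]).
#' @param bias_strength Bias strength for `model = "biased"`.
#' @param seed Mandatory integer seed.
#' @return Validated `sim_config` list.
#' @export
simulation_config <- function(species_tree = NULL, n_species = 12L,
                              tree_depth = 1.5, dup_rate = 0.08,
                              seq_length = 500L, subst_rate = 0.08,
                              model = c("symmetric", "biased"),
                              bias_strength = 0, seed) {
  model <- match.arg(model)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(dup_rate >= 0, subst_rate >= 0, seq_length >= 1,
            tree_depth > 0, n_species >= 2, bias_strength >= 0)
  if (!is.null(species_tree)) stopifnot(inherits(species_tree, "species_tree"))
  structure(list(species_tree = species_tree, n_species = as.integer(n_species),
                 tree_depth = tree_depth, dup_rate = dup_rate,
                 seq_length = as.integer(seq_length), subst_rate = subst_rate,
                 model = model, bias_strength = bias_strength,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Polarity-biased 20-state exchange rate matrix
#'
#' Off-diagonal rates `rate(x -> y) = exp(-strength * (pol(y) - pol(x)))`,
#' so that replacements lowering polarity run faster; `strength = 0` gives
#' the symmetric-uniform model. The diagonal closes each row to zero and the
#' matrix is scaled so the mean exit rate under uniform state frequencies
#' is 1 (branch lengths then read as expected changes per unit intensity).
#'
#' @param polarity Named polarity vector (default the bundled scale).
#' @param strength Non-negative bias strength.
#' @return 20 x 20 rate matrix, rows summing to zero.
#' @export
biased_rate_matrix <- function(polarity = aa_scales()$polarity, strength = 0) {
  stopifnot(strength >= 0, all(AA_ALPHABET %in% names(polarity)))
  pol <- polarity[AA_ALPHABET]
  Q <- exp(-strength * outer(pol, pol, function(x, y) y - x))
  dimnames(Q) <- list(AA_ALPHABET, AA_ALPHABET)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / mean(-diag(Q))
}

## random rooted ultrametric species tree, tips sp01..spNN, depth scaled
.random_species_tree <- function(n_species, depth) {
  phy <- ape::rcoal(n_species, tip.label = sprintf("sp%02d", seq_len(n_species)))
  d <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / d * depth
  phy$node.label <- NULL
  species_tree(phy)
}

#' Simulate one gene family with a known history
#'
#' Grows a gene tree on the species tree by a Poisson duplication birth
#' process (a duplication copies the whole sequence; both copies evolve
#' independently; no gene loss), evolves sequences site-independently under
#' the chosen 20-state Markov model with expected changes per branch equal
#' to `subst_rate` x branch length, and logs every substitution event and
#' every duplication node. The alignment is the gap-free leaf matrix.
#'
#' @param cfg [simulation_config()].
#' @param family_id Family id for the outputs.
#' @return List: `alignment` ([family_alignment]), `tree` ([gene_tree],
#'   branch lengths in Ks units, internal nodes labelled), `species_tree`,
#'   and `truth` (list with `events` data.frame `site`, `branch_id`,
#'   `source_aa`, `dest_aa`, `time_ks`, and `duplications`, the branch ids
#'   of the true duplication nodes).
#' @export
simulate_family <- function(cfg, family_id = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  stree <- if (is.null(cfg$species_tree)) {
    .random_species_tree(cfg$n_species, cfg$tree_depth)
  } else cfg$species_tree
  si <- stree$index

  env <- new.env()
  env$parent <- integer(0); env$brlen <- numeric(0); env$label <- character(0)
  env$kind <- character(0); env$species <- character(0)
  env$children <- list()
  env$leaf_count <- stats::setNames(integer(si$n_tip), stree$phy$tip.label)
  new_node <- function(parent, brlen, kind, label = NA_character_,
                       species = NA_character_) {
    id <- length(env$parent) + 1L
    env$parent[id] <- parent; env$brlen[id] <- brlen
    env$kind[id] <- kind; env$species[id] <- species
    env$label[id] <- if (!is.na(label)) label else sprintf("i%d", id)
    env$children[[id]] <- integer(0)
    if (parent > 0L) env$children[[parent]] <- c(env$children[[parent]], id)
    id
  }
  dup_nodes <- integer(0)
  sim_lineage <- function(sp_child, gene_parent, t0) {
    L <- si$brlen[sp_child]
    t <- t0
    parent <- gene_parent
    repeat {
      w <- if (cfg$dup_rate > 0) stats::rexp(1, cfg$dup_rate) else Inf
      if (t + w < L) {
        t <- t + w
        d <- new_node(parent, w, "duplication")
        dup_nodes <<- c(dup_nodes, d)
        sim_lineage(sp_child, d, t)   # one copy
        parent <- d                    # the other continues below
      } else {
        if (sp_child <= si$n_tip) {
          sp <- stree$phy$tip.label[sp_child]
          env$leaf_count[sp] <- env$leaf_count[sp] + 1L
          new_node(parent, L - t, "leaf",
                   label = sprintf("%s_g%d", sp, env$leaf_count[sp]),
                   species = sp)
        } else {
          s <- new_node(parent, L - t, "speciation")
          for (c2 in si$children[[sp_child]]) sim_lineage(c2, s, 0)
        }
        break
      }
    }
  }
  root <- new_node(0L, NA_real_, "speciation")
  for (c2 in si$children[[si$root]]) sim_lineage(c2, root, 0)

  ## sequence evolution with event logging
  Q <- if (cfg$model == "biased") {
    biased_rate_matrix(strength = cfg$bias_strength)
  } else biased_rate_matrix(strength = 0)
  exit <- -diag(Q)
  jump_prob <- Q; diag(jump_prob) <- 0
  jump_prob <- jump_prob / rowSums(jump_prob)
  L <- cfg$seq_length
  seqs <- vector("list", length(env$parent))
  events <- list()
  seqs[[root]] <- sample.int(20L, L, replace = TRUE)
  order_nodes <- order(seq_along(env$parent)) # ids are created parent-first
  for (v in order_nodes) {
    if (v == root) next
    s <- seqs[[env$parent[v]]]
    dur <- cfg$subst_rate * env$brlen[v]
    if (dur > 0) {
      w <- stats::rexp(L, exit[s])
      hot <- which(w < dur)
      for (i in hot) {
        t <- w[i]
        st <- s[i]
        while (t < dur) {
          dest <- sample.int(20L, 1L, prob = jump_prob[st, ])
          events[[length(events) + 1L]] <- data.frame(
            site = i, branch_id = env$label[v],
            source_aa = AA_ALPHABET[st], dest_aa = AA_ALPHABET[dest],
            time_ks = t / cfg$subst_rate, stringsAsFactors = FALSE)
          st <- dest
          t <- t + stats::rexp(1, exit[st])
        }
        s[i] <- st
      }
    }
    seqs[[v]] <- s
  }

  ## assemble Newick (internal labels preserved as stable branch ids)
  nwk <- function(v) {
    ch <- env$children[[v]]
    if (!length(ch)) {
      sprintf("%s:%.10g", env$label[v], env$brlen[v])
    } else {
      inner <- paste(vapply(ch, nwk, ""), collapse = ",")
      if (v == root) sprintf("(%s)%s;", inner, env$label[v])
      else sprintf("(%s)%s:%.10g", inner, env$label[v], env$brlen[v])
    }
  }
  phy <- ape::read.tree(text = nwk(root))
  leaves <- which(env$kind == "leaf")
  species_map <- stats::setNames(env$species[leaves], env$label[leaves])
  gtree <- gene_tree(phy, species = species_map, family_id = family_id)
  aln_m <- do.call(rbind, lapply(leaves, function(v) AA_ALPHABET[seqs[[v]]]))
  rownames(aln_m) <- env$label[leaves]
  aln <- family_alignment(aln_m, family_id = family_id)
  ev_df <- if (length(events)) do.call(rbind, events) else
    data.frame(site = integer(), branch_id = character(),
               source_aa = character(), dest_aa = character(),
               time_ks = numeric(), stringsAsFactors = FALSE)
  ev_df <- ev_df[order(ev_df$site, ev_df$time_ks), , drop = FALSE]
  rownames(ev_df) <- NULL
  list(alignment = aln, tree = gtree, species_tree = stree,
       truth = list(events = ev_df, duplications = env$label[dup_nodes]))
}

#' Inject gap blocks into an alignment
#'
#' Overwrites random stretches of random sequences with gap characters, to
#' exercise the indel-region mask. Returns the modified alignment together
#' with the set of columns the mask is expected to exclude (those covered by
#' an injected run of length >= 2; length-1 gaps must be retained).
#'
#' @param aln [family_alignment].
#' @param n_blocks Number of gap blocks to inject.
#' @param len_range Integer range of block lengths, sampled uniformly.
#' @param seed Seed for reproducible placement.
#' @return List `alignment` (modified), `expected_mask` (sorted integer
#'   column indices, 1-based).
#' @export
inject_gap_blocks <- function(aln, n_blocks = 3L, len_range = c(1L, 4L), seed) {
  stopifnot(inherits(aln, "family_alignment"))
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  m <- aln$aa
  for (b in seq_len(n_blocks)) {
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    len <- min(len, ncol(m))
    row <- sample(nrow(m), 1L)
    start <- sample(ncol(m) - len + 1L, 1L)
    cols <- start:(start + len - 1L)
    m[row, cols] <- "-"
  }
  ## expected exclusions from the final per-row gap pattern (blocks may merge
  ## with each other or with pre-existing gaps): consecutive-gap runs of
  ## length >= 2, found by differencing the sorted gap positions
  expected <- integer(0)
  for (r in seq_len(nrow(m))) {
    gaps <- which(m[r, ] == "-")
    if (length(gaps) < 2L) next
    grp <- cumsum(c(1L, diff(gaps) != 1L))
    for (run in split(gaps, grp)) {
      if (length(run) >= 2L) expected <- c(expected, run)
    }
  }
  out <- family_alignment(m, family_id = aln$family_id)
  list(alignment = out, expected_mask = sort(unique(expected)))
}
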