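## Parsimony polarization. States are indices into AA_ALPHABET; gaps retained
## in unmasked columns and `X` are wildcards (NA state): they contribute no
## cost and never nominate events on their own terminal branch.

.column_states <- function(column, tip_labels) {
  if (!all(tip_labels %in% names(column))) {
    stop("column lacks states for tips: ",
         paste(setdiff(tip_labels, names(column)), collapse = ", "))
  }
  s <- match(toupper(column[tip_labels]), AA_ALPHABET)
  s
}

## Minimum-change (down-pass) cost matrix: below[v, s] = min changes in the
## subtree of v given state s at v. Unit costs, wildcards cost 0 everywhere.
.fitch_below <- function(ti, states) {
  S <- length(AA_ALPHABET)
  below <- matrix(0, ti$n_node, S)
  for (v in ti$postorder) {
    if (v <= ti$n_tip) {
      if (!is.na(states[v])) {
        row <- rep(Inf, S)
        row[states[v]] <- 0
        below[v, ] <- row
      }
    } else {
      acc <- numeric(S)
      for (c in ti$children[[v]]) {
        bc <- below[c, ]
        acc <- acc + pmin(bc, min(bc) + 1)
      }
      below[v, ] <- acc
    }
  }
  below
}

#' Fitch parsimony score of one alignment column
#'
#' Minimum number of state changes over all ancestral labelings of a rooted
#' tree under unordered (Fitch) parsimony. Leaves carrying `-` or `X` are
#' treated as missing data (any state, zero cost).
#'
#' @param column Named character vector: tip label -> residue.
#' @param tree [gene_tree] or `phylo`.
#' @return Integer parsimony score.
#' @export
fitch_score <- function(column, tree) {
  ti <- if (inherits(tree, "gene_tree")) tree$index else .tree_index(tree)
  states <- .column_states(column, ti$branch_id[seq_len(ti$n_tip)])
  below <- .fitch_below(ti, states)
  as.integer(min(below[ti$root, ]))
}

## Per-edge joint analysis: for the branch into node v (parent u), the joint
## cost of fixing u = x, v = y over the whole tree is
##   J[x, y] = Bv[x] + [x != y] + below[v, y]
## where Bv[x] = (min cost of everything outside subtree(v) given u = x).
## An event x -> y on that branch occurs in EVERY most-parsimonious
## reconstruction iff (x, y) is the unique minimiser of J and x != y; it
## occurs in SOME reconstruction iff it attains the global minimum.
.edge_events <- function(ti, states, below = NULL) {
  S <- length(AA_ALPHABET)
  if (is.null(below)) below <- .fitch_below(ti, states)
  score <- min(below[ti$root, ])
  if (score == 0) {
    return(list(score = 0L, unambiguous = NULL, pool = NULL))
  }
  ## mrow[[c]]: contribution of child c to its parent as function of parent state
  mrow <- vector("list", ti$n_node)
  for (v in seq_len(ti$n_node)) {
    bv <- below[v, ]
    mrow[[v]] <- pmin(bv, min(bv) + 1)
  }
  A <- matrix(NA_real_, ti$n_node, S)
  A[ti$root, ] <- 0
  un <- list(); pool <- list()
  offdiag <- row(diag(S)) != col(diag(S))
  for (v in ti$preorder) {
    if (v == ti$root) next
    u <- ti$parent[v]
    Bv <- A[u, ]
    for (w in ti$children[[u]]) if (w != v) Bv <- Bv + mrow[[w]]
    A[v, ] <- pmin(Bv, min(Bv) + 1)
    J <- outer(Bv, below[v, ], "+") + offdiag
    hits <- which(J == score, arr.ind = TRUE)
    dimnames(hits) <- list(NULL, c("x", "y"))
    ev <- hits[hits[, "x"] != hits[, "y"], , drop = FALSE]
    if (nrow(hits) == 1L && nrow(ev) == 1L) {
      un[[length(un) + 1L]] <- c(branch = v, x = unname(ev[1, "x"]),
                                 y = unname(ev[1, "y"]))
    } else if (nrow(ev) > 0L) {
      for (i in seq_len(nrow(ev))) {
        pool[[length(pool) + 1L]] <- c(branch = v, x = unname(ev[i, "x"]),
                                       y = unname(ev[i, "y"]))
      }
    }
  }
  list(score = as.integer(score),
       unambiguous = if (length(un)) do.call(rbind, un) else NULL,
       pool = if (length(pool)) do.call(rbind, pool) else NULL)
}

#' Enumerate most-parsimonious reconstructions of one column
#'
#' Backtracks through the minimum-cost dynamic program to list all distinct
#' ancestral labelings attaining the parsimony score. When more than `cap`
#' labelings exist the list is truncated (`cap_exceeded = TRUE`); per-branch
#' event sets remain exact in [polarize_site()], which uses DP marginals
#' rather than this list.
#'
#' @param column Named character vector: tip label -> residue.
#' @param tree [gene_tree] or `phylo`.
#' @param cap Maximum number of labelings to return (default 10000).
#' @return `mpr_set` object: list with `score`, `labelings` (each a named
#'   character vector over all nodes, branch ids as names), `cap_exceeded`.
#' @export
enumerate_mprs <- function(column, tree, cap = 10000L) {
  ti <- if (inherits(tree, "gene_tree")) tree$index else .tree_index(tree)
  states <- .column_states(column, ti$branch_id[seq_len(ti$n_tip)])
  below <- .fitch_below(ti, states)
  score <- min(below[ti$root, ])
  root_choices <- which(below[ti$root, ] == score)
  partial <- lapply(root_choices, function(s) {
    a <- integer(ti$n_node); a[ti$root] <- s; a
  })
  cap_exceeded <- FALSE
  for (v in ti$preorder) {
    if (v == ti$root) next
    nxt <- list()
    for (p in partial) {
      x <- p[ti$parent[v]]
      bv <- below[v, ]
      mv <- min(bv[x], min(bv) + 1)
      choices <- which(bv + (seq_along(bv) != x) == mv)
      for (t in choices) {
        q <- p; q[v] <- t
        nxt[[length(nxt) + 1L]] <- q
        if (length(nxt) > cap) break
      }
      if (length(nxt) > cap) break
    }
    if (length(nxt) > cap) {
      cap_exceeded <- TRUE
      nxt <- nxt[seq_len(cap)]
    }
    partial <- nxt
  }
  labelings <- lapply(partial, function(p) {
    stats::setNames(AA_ALPHABET[p], ti$branch_id)
  })
  structure(list(score = as.integer(score), labelings = labelings,
                 cap_exceeded = cap_exceeded),
            class = "mpr_set")
}

#' Events implied by one ancestral labeling
#' @param labeling Named character vector (node label -> state), as returned
#'   in an [enumerate_mprs()] `labelings` element.
#' @param tree [gene_tree] or `phylo`.
#' @return data.frame `branch_id`, `source_aa`, `dest_aa` (possibly 0 rows).
#' @export
mpr_events <- function(labeling, tree) {
  ti <- if (inherits(tree, "gene_tree")) tree$index else .tree_index(tree)
  v <- setdiff(ti$preorder, ti$root)
  src <- labeling[ti$branch_id[ti$parent[v]]]
  dst <- labeling[ti$branch_id[v]]
  keep <- src != dst
  data.frame(branch_id = ti$branch_id[v][keep], source_aa = unname(src[keep]),
             dest_aa = unname(dst[keep]), stringsAsFactors = FALSE)
}

.empty_records <- function() {
  data.frame(record_id = character(), family_id = character(), site = integer(),
             branch_id = character(), source_aa = character(),
             dest_aa = character(), ambiguous = logical(),
             n_alternatives = integer(), context = character(),
             clade_ids = character(), stringsAsFactors = FALSE)
}

.empty_alternatives <- function() {
  data.frame(record_id = character(), family_id = character(), site = integer(),
             branch_id = character(), source_aa = character(),
             dest_aa = character(), stringsAsFactors = FALSE)
}

#' Polarize one alignment column
#'
#' Emits exactly `parsimony_score` substitution records for the column. An
#' event (branch, X->Y) is unambiguous iff it occurs on the same branch in
#' the same direction in every most-parsimonious reconstruction (determined
#' exactly from DP marginals); each remaining event slot is emitted once as
#' ambiguous, carrying every candidate (branch, X->Y) as alternatives.
#' Events whose direction flips across the root are always ambiguous.
#'
#' @param column Named character vector tip -> residue.
#' @param tree [gene_tree] or `phylo`.
#' @param site 1-based column index used in record ids.
#' @param family_id Family id stamped into records.
#' @param mask Optional logical mask vector; polarizing a masked site is a
#'   contract violation.
#' @return List `records`, `alternatives` (data.frames).
#' @export
polarize_site <- function(column, tree, site = 1L, family_id = "fam",
                          mask = NULL) {
  if (!is.null(mask) && isTRUE(mask[site])) {
    stop("contract violation: site ", site, " is masked")
  }
  ti <- if (inherits(tree, "gene_tree")) tree$index else .tree_index(tree)
  states <- .column_states(column, ti$branch_id[seq_len(ti$n_tip)])
  ee <- .edge_events(ti, states)
  .site_records(ee, ti, site, family_id)
}

## shared record assembly from an .edge_events result
.site_records <- function(ee, ti, site, family_id) {
  if (ee$score == 0L) {
    return(list(records = .empty_records(), alternatives = .empty_alternatives()))
  }
  n_un <- if (is.null(ee$unambiguous)) 0L else nrow(ee$unambiguous)
  k_amb <- ee$score - n_un
  rid <- function(i) sprintf("%s:%d:%d", family_id, site, i)
  recs <- list(); alts <- list()
  i <- 0L
  if (n_un > 0L) {
    for (r in seq_len(n_un)) {
      i <- i + 1L
      e <- ee$unambiguous[r, ]
      recs[[i]] <- data.frame(
        record_id = rid(i), family_id = family_id, site = site,
        branch_id = ti$branch_id[e[["branch"]]],
        source_aa = AA_ALPHABET[e[["x"]]], dest_aa = AA_ALPHABET[e[["y"]]],
        ambiguous = FALSE, n_alternatives = 0L,
        context = NA_character_, clade_ids = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (k_amb > 0L) {
    pool <- ee$pool
    alt_df <- data.frame(
      branch_id = ti$branch_id[pool[, "branch"]],
      source_aa = AA_ALPHABET[pool[, "x"]], dest_aa = AA_ALPHABET[pool[, "y"]],
      stringsAsFactors = FALSE)
    for (s in seq_len(k_amb)) {
      i <- i + 1L
      recs[[i]] <- data.frame(
        record_id = rid(i), family_id = family_id, site = site,
        branch_id = NA_character_, source_aa = NA_character_,
        dest_aa = NA_character_, ambiguous = TRUE,
        n_alternatives = nrow(alt_df),
        context = NA_character_, clade_ids = NA_character_,
        stringsAsFactors = FALSE)
      alts[[length(alts) + 1L]] <- cbind(
        data.frame(record_id = rid(i), family_id = family_id, site = site,
                   stringsAsFactors = FALSE),
        alt_df)
    }
  }
  list(records = do.call(rbind, recs),
       alternatives = if (length(alts)) do.call(rbind, alts) else .empty_alternatives())
}

#' Mask alignment regions with runs of more than one indel
#'
#' A column is excluded when, in at least one sequence, it lies inside a
#' maximal run of two or more consecutive gap characters. Isolated
#' single-gap columns are retained (the gap is treated as missing data).
#'
#' @param aln [family_alignment].
#' @return Logical vector, length `n_columns`; `TRUE` = masked.
#' @export
mask_indel_regions <- function(aln) {
  stopifnot(inherits(aln, "family_alignment"))
  mask <- logical(aln$n_columns)
  for (r in seq_len(nrow(aln$aa))) {
    g <- aln$aa[r, ] == "-"
    if (!any(g)) next
    runs <- rle(g)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    long <- which(runs$values & runs$lengths >= 2L)
    for (j in long) mask[starts[j]:ends[j]] <- TRUE
  }
  mask
}

#' Polarize a whole family
#'
#' Masks indel regions, polarizes every retained column, tags unambiguous
#' records with their branch context (duplicated vs single-copy) and the
#' duplication clades containing their branch, and reports site totals.
#'
#' @param aln [family_alignment].
#' @param rtree `reconciled_tree` from [lca_reconcile()].
#' @param partition Optional precomputed [partition_branches()] result.
#' @param clades Optional precomputed [extract_duplications()] result.
#' @return List: `records`, `alternatives`, `mask`, and `summary` (list with
#'   `n_sites`, `n_sites_unmasked`, `n_sites_with_substitution`,
#'   `n_substitutions`, `n_unambiguous`, `n_ambiguous`).
#' @export
polarize_family <- function(aln, rtree, partition = NULL, clades = NULL) {
  stopifnot(inherits(aln, "family_alignment"),
            inherits(rtree, "reconciled_tree"))
  ti <- rtree$index
  tips <- ti$branch_id[seq_len(ti$n_tip)]
  if (!setequal(tips, rownames(aln$aa))) {
    stop("tree/alignment consistency error for family ", aln$family_id)
  }
  if (is.null(partition)) partition <- partition_branches(rtree)
  if (is.null(clades)) clades <- extract_duplications(rtree)
  mask <- mask_indel_regions(aln)
  m <- aln$aa[tips, , drop = FALSE]
  states_all <- matrix(match(m, AA_ALPHABET), nrow = nrow(m))
  unmasked <- which(!mask)
  ## group identical site patterns so the DP runs once per pattern
  keys <- apply(states_all[, unmasked, drop = FALSE], 2, paste, collapse = ",")
  recs <- list(); alts <- list()
  n_sites_with_sub <- 0L
  by_key <- split(unmasked, keys)
  for (cols in by_key) {
    st <- states_all[, cols[1]]
    nonna <- unique(st[!is.na(st)])
    if (length(nonna) < 2L) next
    ee <- .edge_events(ti, st)
    if (ee$score == 0L) next
    for (site in cols) {
      n_sites_with_sub <- n_sites_with_sub + 1L
      sr <- .site_records(ee, ti, site, aln$family_id)
      recs[[length(recs) + 1L]] <- sr$records
      if (nrow(sr$alternatives)) alts[[length(alts) + 1L]] <- sr$alternatives
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else .empty_records()
  alternatives <- if (length(alts)) do.call(rbind, alts) else .empty_alternatives()
  if (nrow(records)) {
    records <- records[order(records$site,
                             match(records$branch_id, ti$branch_id[ti$preorder]),
                             na.last = TRUE), ]
    rownames(records) <- NULL
    idx <- !records$ambiguous
    records$context[idx] <- partition[records$branch_id[idx]]
    if (nrow(clades$clade_branches)) {
      cb <- clades$clade_branches
      cl_id <- paste0(cb$dup_id, ".", cb$clade)
      cl_of_branch <- split(cl_id, cb$branch_id)
      records$clade_ids[idx] <- vapply(records$branch_id[idx], function(b) {
        v <- cl_of_branch[[b]]
        if (is.null(v)) NA_character_ else paste(sort(v), collapse = ",")
      }, "")
    }
  }
  list(
    records = records,
    alternatives = alternatives,
    mask = mask,
    summary = list(
      n_sites = aln$n_columns,
      n_sites_unmasked = sum(!mask),
      n_sites_with_substitution = n_sites_with_sub,
      n_substitutions = nrow(records),
      n_unambiguous = sum(!records$ambiguous),
      n_ambiguous = sum(records$ambiguous)
    )
  )
}
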