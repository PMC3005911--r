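## Weighted (source, dest, weight) event list from records + alternatives.
## Unambiguous records weigh 1 on their branch. Ambiguous records enter via
## their alternatives: weight 1/n_alternatives each ("split", the default,
## preserves one unit of weight per event) or 1 each ("unit").
.event_weights <- function(records, alternatives,
                           weighting = c("split", "unit"),
                           branches = NULL) {
  weighting <- match.arg(weighting)
  un <- records[!records$ambiguous, , drop = FALSE]
  ev <- data.frame(branch_id = un$branch_id, source_aa = un$source_aa,
                   dest_aa = un$dest_aa, weight = rep(1, nrow(un)),
                   record_id = un$record_id, stringsAsFactors = FALSE)
  amb_ids <- records$record_id[records$ambiguous]
  if (length(amb_ids) && nrow(alternatives)) {
    al <- alternatives[alternatives$record_id %in% amb_ids, , drop = FALSE]
    n_alt <- table(al$record_id)
    w <- if (weighting == "split") 1 / as.numeric(n_alt[al$record_id]) else 1
    ev <- rbind(ev, data.frame(branch_id = al$branch_id,
                               source_aa = al$source_aa, dest_aa = al$dest_aa,
                               weight = w, record_id = al$record_id,
                               stringsAsFactors = FALSE))
  }
  if (!is.null(branches)) ev <- ev[ev$branch_id %in% branches, , drop = FALSE]
  ev
}

#' Amino-acid flux table
#'
#' For each amino acid a, counts how often it was created (C, as destination)
#' and removed (R, as source) and computes the net relative gain
#' D = (C - R)/(C + R). For each ordered pair x->y the count N(x->y), and for
#' each unordered pair the pairwise asymmetry
#' D_pair = (N(x->y) - N(y->x))/(N(x->y) + N(y->x)), oriented toward the
#' column amino acid. Pairs with zero total count are undefined (NA) and
#' excluded from `mean_abs_pairwise_D`.
#'
#' @param records Substitution records (from [polarize_family()] or a built
#'   database).
#' @param alternatives Alternatives table matching `records`.
#' @param branches Optional character vector restricting to a branch subset
#'   (ids of the nodes the branches lead into).
#' @param weighting How ambiguous records enter: `"split"` (1/n_alternatives
#'   per alternative, default), `"unit"` (1 per alternative), or
#'   `"exclude"`.
#' @return `flux_table` object: list with `aa` (data.frame aa, C, R, D),
#'   `pair_counts` (20 x 20, source x destination), `pair_D` (antisymmetric),
#'   `mean_abs_pairwise_D`, `n_substitutions` (total weight counted).
#' @export
flux_table <- function(records, alternatives = NULL, branches = NULL,
                       weighting = c("split", "unit", "exclude")) {
  weighting <- match.arg(weighting)
  if (is.null(alternatives)) alternatives <- .empty_alternatives()
  if (weighting == "exclude") {
    records <- records[!records$ambiguous, , drop = FALSE]
    ev <- .event_weights(records, .empty_alternatives(), "split", branches)
  } else {
    ev <- .event_weights(records, alternatives, weighting, branches)
  }
  S <- length(AA_ALPHABET)
  N <- matrix(0, S, S, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  if (nrow(ev)) {
    agg <- stats::aggregate(ev$weight,
                            list(src = ev$source_aa, dst = ev$dest_aa), sum)
    N[cbind(agg$src, agg$dst)] <- agg$x
  }
  C <- colSums(N); R <- rowSums(N)
  D <- ifelse(C + R > 0, (C - R) / (C + R), NA_real_)
  tot <- N + t(N)
  pair_D <- ifelse(tot > 0, (N - t(N)) / tot, NA_real_)
  dimnames(pair_D) <- dimnames(N)
  diag(pair_D) <- NA_real_
  ut <- upper.tri(pair_D)
  defined <- ut & !is.na(pair_D)
  structure(list(
    aa = data.frame(aa = AA_ALPHABET, C = unname(C), R = unname(R),
                    D = unname(D), stringsAsFactors = FALSE),
    pair_counts = N,
    pair_D = pair_D,
    mean_abs_pairwise_D = if (any(defined)) mean(abs(pair_D[defined])) else NA_real_,
    n_substitutions = sum(N)
  ), class = "flux_table")
}

#' Polarity change of unambiguous substitutions
#'
#' Signed change `polarity(destination) - polarity(source)` and its absolute
#' value |dP|, the radicality measure. Radicality is defined for unambiguous
#' records only; passing any ambiguous record is a contract violation.
#'
#' @param records Substitution records, all with `ambiguous = FALSE`.
#' @param scales [aa_scales()] object.
#' @return data.frame `record_id`, `delta_polarity`, `abs_delta_polarity`.
#' @export
delta_polarity <- function(records, scales = aa_scales()) {
  if (any(records$ambiguous)) {
    stop("contract violation: radicality is defined for unambiguous records only")
  }
  dp <- scales$polarity[records$dest_aa] - scales$polarity[records$source_aa]
  data.frame(record_id = records$record_id, delta_polarity = unname(dp),
             abs_delta_polarity = abs(unname(dp)), stringsAsFactors = FALSE)
}

#' Exchangeability of unambiguous substitutions
#'
#' Direction-sensitive lookup `EX[source, destination]` in the loaded
#' exchangeability matrix; low values mark radical replacements.
#'
#' @inheritParams delta_polarity
#' @return data.frame `record_id`, `exchangeability`.
#' @export
exchangeability <- function(records, scales = aa_scales()) {
  if (any(records$ambiguous)) {
    stop("contract violation: radicality is defined for unambiguous records only")
  }
  ex <- scales$exchangeability[cbind(records$source_aa, records$dest_aa)]
  data.frame(record_id = records$record_id, exchangeability = unname(ex),
             stringsAsFactors = FALSE)
}

## split one unit of weight per ambiguous record across the contexts (or
## clades) its alternatives fall in
.amb_class_weights <- function(records, alternatives, class_of_branch) {
  amb <- records[records$ambiguous, , drop = FALSE]
  out <- stats::setNames(numeric(0), character(0))
  if (!nrow(amb)) return(out)
  al <- alternatives[alternatives$record_id %in% amb$record_id, , drop = FALSE]
  cls <- class_of_branch[al$branch_id]
  w <- stats::setNames(rep(1, nrow(al)), NULL) /
    as.numeric(table(al$record_id)[al$record_id])
  tapply(w[!is.na(cls)], cls[!is.na(cls)], sum)
}

#' Per-family Ka, Ks and Ka/Ks by branch class
#'
#' Ka is the number of substitutions divided by the number of retained
#' (unmasked) alignment columns; Ks is the sum of branch lengths of the
#' corresponding tree section (synonymous substitutions per 4-fold
#' degenerate site); Ka/Ks their ratio. Computed for the whole tree and for
#' the three branch classes of [partition_branches()]. Whole-tree totals
#' count each ambiguous event once; per-class tallies split each ambiguous
#' event across the classes of its alternative placements.
#'
#' @param records,alternatives Substitution tables for one family.
#' @param partition [partition_branches()] result.
#' @param mask Logical mask from [polarize_family()].
#' @param rtree `reconciled_tree` (supplies branch lengths).
#' @param scales [aa_scales()] for the per-class radicality means.
#' @return data.frame, one row per class (`whole`, and the classes present),
#'   columns `family_id`, `class`, `n_substitutions`, `n_unambiguous`,
#'   `n_sites`, `ks_sum`, `ka`, `ka_ks`, `mean_abs_dpolarity`, `mean_ex`.
#'   Classes with no branches get NA fields.
#' @export
family_ka_ks <- function(records, alternatives, partition, mask, rtree,
                         scales = aa_scales()) {
  ti <- rtree$index
  n_sites <- sum(!mask)
  brlen <- stats::setNames(ti$brlen, ti$branch_id)
  classes <- c("single_copy_no_dup_family", "single_copy_in_dup_family",
               "duplicated")
  un <- records[!records$ambiguous, , drop = FALSE]
  amb_w <- .amb_class_weights(records, alternatives, partition)
  rows <- list()
  mk_row <- function(class, n_sub, n_un, ks, sub_un) {
    ka <- if (n_sites > 0) n_sub / n_sites else NA_real_
    ka_ks <- if (!is.na(ks) && ks > 0) ka / ks else NA_real_
    if (!is.na(ks) && ks == 0 && !is.na(n_sub) && n_sub > 0) {
      warning("family ", rtree$family_id, " class ", class,
              ": substitutions present but Ks sum is 0; Ka/Ks undefined")
    }
    dp <- ex <- NA_real_
    if (!is.null(sub_un) && nrow(sub_un)) {
      dp <- mean(delta_polarity(sub_un, scales)$abs_delta_polarity)
      ex <- mean(exchangeability(sub_un, scales)$exchangeability)
    }
    data.frame(family_id = rtree$family_id, class = class,
               n_substitutions = n_sub, n_unambiguous = n_un,
               n_sites = n_sites, ks_sum = ks, ka = ka, ka_ks = ka_ks,
               mean_abs_dpolarity = dp, mean_ex = ex,
               stringsAsFactors = FALSE)
  }
  rows[["whole"]] <- mk_row("whole", nrow(records), nrow(un),
                            sum(brlen[names(partition)]), un)
  for (cl in classes) {
    br <- names(partition)[partition == cl]
    if (!length(br)) {
      rows[[cl]] <- mk_row(cl, NA_real_, NA_integer_, NA_real_, NULL)
      next
    }
    un_cl <- un[un$branch_id %in% br, , drop = FALSE]
    n_sub <- nrow(un_cl) + sum(amb_w[cl], na.rm = TRUE)
    rows[[cl]] <- mk_row(cl, n_sub, nrow(un_cl), sum(brlen[br]), un_cl)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-duplication clade statistics and asymmetry
#'
#' For each clade of a duplication: total and unambiguous substitution
#' counts (ambiguous events split across clades by their alternative
#' placements), rate = count / clade Ks, and mean radicality over the
#' unambiguous records. Asymmetry of a statistic x between clades is
#' A = |x1 - x2| / (x1 + x2), bounded in [0, 1] (undefined at 0/0).
#'
#' @param dups [extract_duplications()] result for the family.
#' @param records,alternatives Substitution tables for the family.
#' @param scales [aa_scales()].
#' @param weighting Ambiguous weighting, `"split"` or `"unit"`.
#' @return data.frame, one row per duplication: per-clade counts, Ks, rates,
#'   radicality means, and `A_rate`, `A_polarity`, `A_ex`.
#' @export
clade_stats <- function(dups, records, alternatives, scales = aa_scales(),
                        weighting = c("split", "unit")) {
  weighting <- match.arg(weighting)
  dd <- dups$duplications
  cb <- dups$clade_branches
  out <- list()
  asym <- function(x1, x2) {
    if (is.na(x1) || is.na(x2) || x1 + x2 == 0) NA_real_ else abs(x1 - x2) / (x1 + x2)
  }
  for (i in seq_len(nrow(dd))) {
    dup_id <- dd$dup_id[i]
    row <- list(family_id = dd$family_id[i], dup_id = dup_id)
    per <- list()
    for (k in 1:2) {
      br <- cb$branch_id[cb$dup_id == dup_id & cb$clade == k]
      ev <- .event_weights(records, alternatives, weighting, branches = br)
      un <- records[!records$ambiguous & records$branch_id %in% br, , drop = FALSE]
      ks <- dd[[paste0("clade", k, "_ks")]][i]
      n_tot <- sum(ev$weight)
      dp <- ex <- NA_real_
      if (nrow(un) > 0) {
        dp <- mean(delta_polarity(un, scales)$abs_delta_polarity)
        ex <- mean(exchangeability(un, scales)$exchangeability)
      }
      per[[k]] <- list(n_total = n_tot, n_unambiguous = nrow(un), ks = ks,
                       rate = if (ks > 0) n_tot / ks else NA_real_,
                       mean_dp = dp, mean_ex = ex)
    }
    out[[i]] <- data.frame(
      family_id = dd$family_id[i], dup_id = dup_id,
      terminal = dd$terminal[i], depth_ks = dd$depth_ks[i],
      clade1_n_total = per[[1]]$n_total, clade2_n_total = per[[2]]$n_total,
      clade1_n_unambiguous = per[[1]]$n_unambiguous,
      clade2_n_unambiguous = per[[2]]$n_unambiguous,
      clade1_ks = per[[1]]$ks, clade2_ks = per[[2]]$ks,
      clade1_rate = per[[1]]$rate, clade2_rate = per[[2]]$rate,
      clade1_mean_dpolarity = per[[1]]$mean_dp,
      clade2_mean_dpolarity = per[[2]]$mean_dp,
      clade1_mean_ex = per[[1]]$mean_ex, clade2_mean_ex = per[[2]]$mean_ex,
      A_rate = asym(per[[1]]$rate, per[[2]]$rate),
      A_polarity = asym(per[[1]]$mean_dp, per[[2]]$mean_dp),
      A_ex = asym(per[[1]]$mean_ex, per[[2]]$mean_ex),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(family_id = character(), dup_id = character(),
                      terminal = logical(), depth_ks = numeric(),
                      clade1_n_total = numeric(), clade2_n_total = numeric(),
                      clade1_n_unambiguous = integer(),
                      clade2_n_unambiguous = integer(),
                      clade1_ks = numeric(), clade2_ks = numeric(),
                      clade1_rate = numeric(), clade2_rate = numeric(),
                      clade1_mean_dpolarity = numeric(),
                      clade2_mean_dpolarity = numeric(),
                      clade1_mean_ex = numeric(), clade2_mean_ex = numeric(),
                      A_rate = numeric(), A_polarity = numeric(),
                      A_ex = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Unweighted per-category means of a family statistic
#'
#' Families without annotation are excluded; a family contributes one entry
#' per annotated reference-species paralog (a family annotated twice counts
#' twice). Means are unweighted across those entries; standard errors
#' reflect variance among them.
#'
#' @param family_stats data.frame with `family_id` and the statistic column.
#' @param annotation data.frame `family_id`, `category` from
#'   [read_annotation()].
#' @param statistic Name of the statistic column to aggregate.
#' @param vocabulary Optional controlled vocabulary for category labels.
#' @return data.frame `category`, `n`, `mean`, `se`.
#' @export
category_aggregate <- function(family_stats, annotation, statistic = "ka_ks",
                               vocabulary = NULL) {
  if (!statistic %in% names(family_stats)) {
    stop("no column '", statistic, "' in family_stats")
  }
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(annotation$category), vocabulary)
    if (length(bad)) stop("unknown category label(s): ",
                          paste(bad, collapse = ", "))
  }
  joined <- merge(annotation, family_stats, by = "family_id")
  joined <- joined[!is.na(joined[[statistic]]), , drop = FALSE]
  if (!nrow(joined)) {
    return(data.frame(category = character(), n = integer(),
                      mean = numeric(), se = numeric(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(joined[[statistic]], joined$category)
  data.frame(
    category = names(sp),
    n = lengths(sp),
    mean = vapply(sp, mean, 0),
    se = vapply(sp, function(x) stats::sd(x) / sqrt(length(x)), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired vectors for flux correlations
#'
#' Builds the inputs of the flux correlation analyses: per amino acid, D
#' against a covariate (e.g. amino-acid frequency); per unordered pair,
#' D_pair against the polarity difference destination - source (up to
#' C(20,2) = 190 pairs, oriented alphabetically source < destination).
#' Entries with undefined D are dropped and the retained length reported.
#'
#' @param flux `flux_table`.
#' @param covariate `"frequency"` (requires `values`), `"polarity"`
#'   (pairwise, uses `scales`), or `"external"` (requires `values`, named by
#'   amino acid).
#' @param values Named numeric vector for `frequency`/`external`.
#' @param scales [aa_scales()] for the polarity covariate.
#' @return data.frame with columns `label`, `D`, `covariate` plus attributes
#'   `n_dropped` and `constant_covariate`.
#' @export
flux_correlations <- function(flux, covariate = c("frequency", "polarity",
                                                  "external"),
                              values = NULL, scales = aa_scales()) {
  covariate <- match.arg(covariate)
  if (covariate == "polarity") {
    pol <- scales$polarity
    combs <- utils::combn(AA_ALPHABET, 2)
    lab <- paste0(combs[1, ], ">", combs[2, ])
    D <- flux$pair_D[cbind(combs[1, ], combs[2, ])]
    cov <- pol[combs[2, ]] - pol[combs[1, ]]
    out <- data.frame(label = lab, D = unname(D), covariate = unname(cov),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(values)) stop("covariate '", covariate, "' requires 'values'")
    missing <- setdiff(AA_ALPHABET, names(values))
    if (length(missing)) {
      stop("covariate lacks entries for: ", paste(missing, collapse = ", "))
    }
    out <- data.frame(label = flux$aa$aa, D = flux$aa$D,
                      covariate = unname(values[flux$aa$aa]),
                      stringsAsFactors = FALSE)
  }
  keep <- !is.na(out$D) & !is.na(out$covariate)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- sum(!keep)
  attr(res, "constant_covariate") <-
    nrow(res) > 0 && length(unique(res$covariate)) == 1L
  res
}

#' Amino-acid frequencies of an alignment set
#'
#' @param alignments List of [family_alignment] objects.
#' @param masked If TRUE (default) indel-masked columns are excluded.
#' @return Named numeric vector of relative frequencies over the 20 states.
#' @export
aa_frequencies <- function(alignments, masked = TRUE) {
  counts <- stats::setNames(numeric(length(AA_ALPHABET)), AA_ALPHABET)
  for (aln in alignments) {
    m <- aln$aa
    if (masked) m <- m[, !mask_indel_regions(aln), drop = FALSE]
    tab <- table(factor(m, levels = AA_ALPHABET))
    counts <- counts + as.numeric(tab)
  }
  counts / sum(counts)
}
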