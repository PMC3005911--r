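#' Run configuration
#'
#' All tunable keys of the pipeline, validated up front; unknown keys are
#' rejected. Also loadable from a YAML file with [read_run_config()].
#'
#' @param polarity_file,exchangeability_file Optional scale files, see
#'   [aa_scales()].
#' @param ambiguous_weighting `"split"` (default) or `"unit"`: how ambiguous
#'   substitutions enter branch-resolved tallies.
#' @param chi2_null `"ks_weighted"` (expected counts proportional to clade
#'   branch-length sums, default) or `"equal"`.
#' @param chi2_yates Continuity correction for the heterogeneity test.
#' @param pooled_t Pooled-variance t-test instead of Welch.
#' @param fdr_levels False discovery rates for the asymmetry battery.
#' @param bonferroni_alpha Family-wise level for Bonferroni control.
#' @param mpr_cap Cap on enumerated reconstructions per site.
#' @param seed Seed for any randomized step.
#' @return `aaflux_config` list.
#' @export
run_config <- function(polarity_file = NULL, exchangeability_file = NULL,
                       ambiguous_weighting = "split",
                       chi2_null = "ks_weighted", chi2_yates = FALSE,
                       pooled_t = FALSE, fdr_levels = c(0.01, 0.05),
                       bonferroni_alpha = 0.01, mpr_cap = 10000L, seed = 1L) {
  stopifnot(ambiguous_weighting %in% c("split", "unit"),
            chi2_null %in% c("ks_weighted", "equal"),
            is.logical(chi2_yates), is.logical(pooled_t),
            all(fdr_levels > 0 & fdr_levels < 1),
            bonferroni_alpha > 0, bonferroni_alpha < 1, mpr_cap >= 1)
  structure(list(polarity_file = polarity_file,
                 exchangeability_file = exchangeability_file,
                 ambiguous_weighting = ambiguous_weighting,
                 chi2_null = chi2_null, chi2_yates = chi2_yates,
                 pooled_t = pooled_t, fdr_levels = fdr_levels,
                 bonferroni_alpha = bonferroni_alpha,
                 mpr_cap = as.integer(mpr_cap), seed = as.integer(seed)),
            class = "aaflux_config")
}

#' Load a run configuration from YAML
#' @param path YAML file of `key: value` pairs; keys must be arguments of
#'   [run_config()].
#' @return `aaflux_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Process one family through the full pipeline
#'
#' mask -> LCA reconcile -> polarize -> partition -> per-family statistics.
#'
#' @param aln [family_alignment].
#' @param gtree [gene_tree].
#' @param stree [species_tree].
#' @param config [run_config()].
#' @param scales Preloaded [aa_scales()] (defaults from `config`).
#' @return List of per-family tables: `family`, `tree_nodes`,
#'   `substitutions`, `substitution_alternatives`, `duplications`,
#'   `dup_clades`, `family_stats`.
#' @export
build_family <- function(aln, gtree, stree, config = run_config(),
                         scales = NULL) {
  if (is.null(scales)) {
    scales <- aa_scales(config$polarity_file, config$exchangeability_file)
  }
  rtree <- lca_reconcile(gtree, stree)
  partition <- partition_branches(rtree)
  dups <- extract_duplications(rtree)
  pol <- polarize_family(aln, rtree, partition = partition, clades = dups)
  fam_stats <- family_ka_ks(pol$records, pol$alternatives, partition,
                            pol$mask, rtree, scales)
  nodes <- rtree$nodes
  nodes$family_id <- aln$family_id
  nodes$context <- ifelse(is.na(nodes$parent_branch_id), NA_character_,
                          unname(partition[nodes$branch_id]))
  nodes <- .coerce_schema(nodes, .db_schema$tree_nodes)
  fam <- data.frame(
    family_id = aln$family_id, n_genes = nrow(aln$aa),
    n_columns = aln$n_columns,
    n_sites_unmasked = pol$summary$n_sites_unmasked,
    n_sites_with_substitution = pol$summary$n_sites_with_substitution,
    n_substitutions = pol$summary$n_substitutions,
    n_unambiguous = pol$summary$n_unambiguous,
    n_ambiguous = pol$summary$n_ambiguous,
    n_duplications = nrow(dups$duplications), stringsAsFactors = FALSE)
  list(family = fam, tree_nodes = nodes,
       substitutions = .coerce_schema(pol$records, .db_schema$substitutions),
       substitution_alternatives = .coerce_schema(
         pol$alternatives, .db_schema$substitution_alternatives),
       duplications = .coerce_schema(dups$duplications, .db_schema$duplications),
       dup_clades = .coerce_schema(dups$clade_branches, .db_schema$dup_clades),
       family_stats = .coerce_schema(fam_stats, .db_schema$family_stats))
}

#' Build the substitution database for a set of families
#'
#' @param families List of `list(alignment =, tree =)` pairs as returned by
#'   [read_family()] or [simulate_family()].
#' @param stree [species_tree].
#' @param config [run_config()].
#' @return `aaflux_db` object; failed families are skipped, recorded in
#'   `attr(db, "failures")` (named character vector of error messages) and
#'   reported in a warning.
#' @export
build_database <- function(families, stree, config = run_config()) {
  scales <- aa_scales(config$polarity_file, config$exchangeability_file)
  parts <- list(); failures <- character()
  for (fam in families) {
    fid <- fam$alignment$family_id
    res <- tryCatch(build_family(fam$alignment, fam$tree, stree, config,
                                 scales = scales),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[fid] <- conditionMessage(res)
      message("family ", fid, " failed: ", conditionMessage(res))
    } else {
      parts[[fid]] <- res
    }
  }
  if (!length(parts) && !length(failures)) stop("no families supplied")
  bindt <- function(nm) {
    got <- lapply(parts, `[[`, nm)
    if (!length(got)) return(.empty_table(if (nm == "family") "families" else nm))
    out <- do.call(rbind, got)
    rownames(out) <- NULL
    out
  }
  db <- structure(list(
    families = bindt("family"),
    tree_nodes = bindt("tree_nodes"),
    substitutions = bindt("substitutions"),
    substitution_alternatives = bindt("substitution_alternatives"),
    duplications = bindt("duplications"),
    dup_clades = bindt("dup_clades"),
    family_stats = bindt("family_stats"),
    flux = NULL, flux_pairs = NULL, asymmetry_tests = NULL,
    species_newick = ape::write.tree(stree$phy),
    config = unclass(config)), class = "aaflux_db")
  if (length(failures)) {
    warning(length(failures), " famil",
            if (length(failures) == 1) "y" else "ies", " failed and ",
            if (length(failures) == 1) "was" else "were", " skipped")
    attr(db, "failures") <- failures
  }
  db
}

#' Build a database from an input directory
#'
#' Expects per-family files `<id>.fasta` + `<id>.nwk` and one `species.nwk`.
#'
#' @param input_dir Directory with the layout above.
#' @param config [run_config()].
#' @return `aaflux_db`.
#' @export
run_build <- function(input_dir, config = run_config()) {
  if (!dir.exists(input_dir)) stop("input directory does not exist: ", input_dir)
  sp_path <- file.path(input_dir, "species.nwk")
  if (!file.exists(sp_path)) stop("species tree file missing: ", sp_path)
  stree <- read_species_tree(sp_path)
  fastas <- sort(list.files(input_dir, pattern = "\\.fasta$", full.names = TRUE))
  if (!length(fastas)) stop("no family alignments (*.fasta) in ", input_dir)
  families <- list(); failures <- character()
  for (f in fastas) {
    id <- sub("\\.fasta$", "", basename(f))
    nwk <- file.path(input_dir, paste0(id, ".nwk"))
    res <- tryCatch({
      if (!file.exists(nwk)) stop("missing tree file ", nwk)
      read_family(f, nwk, family_id = id)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      message("family ", id, " failed: ", conditionMessage(res))
    } else families[[id]] <- res
  }
  db <- build_database(families, stree, config)
  attr(db, "failures") <- c(failures, attr(db, "failures"))
  db
}

#' Genome-wide flux analysis of a built database
#'
#' @param db `aaflux_db`.
#' @param branches Optional branch filter: character vector of branch ids,
#'   or a data.frame `family_id`, `branch_id` for per-family selections.
#' @return The `aaflux_db` with `flux` and `flux_pairs` tables filled;
#'   the `flux_table` object is attached as `attr(db, "flux_table")`.
#' @export
analyze_flux <- function(db, branches = NULL) {
  recs <- db$substitutions
  alts <- db$substitution_alternatives
  if (is.data.frame(branches)) {
    ## namespace branch ids by family so per-family selections do not collide
    ns <- function(f, b) ifelse(is.na(b), NA_character_, paste(f, b, sep = "\r"))
    recs$branch_id <- ns(recs$family_id, recs$branch_id)
    alts$branch_id <- ns(alts$family_id, alts$branch_id)
    branches <- ns(branches$family_id, branches$branch_id)
  }
  ft <- flux_table(recs, alts, branches = branches,
                   weighting = db$config$ambiguous_weighting)
  db$flux <- .coerce_schema(ft$aa, .db_schema$flux)
  idx <- which(ft$pair_counts + t(ft$pair_counts) > 0, arr.ind = TRUE)
  db$flux_pairs <- .coerce_schema(data.frame(
    source_aa = rownames(ft$pair_counts)[idx[, 1]],
    dest_aa = colnames(ft$pair_counts)[idx[, 2]],
    n = ft$pair_counts[idx], pair_D = ft$pair_D[idx],
    stringsAsFactors = FALSE), .db_schema$flux_pairs)
  attr(db, "flux_table") <- ft
  db
}

#' Per-family duplication statistics and category aggregates
#'
#' @param db `aaflux_db`.
#' @param annotation Optional annotation data.frame from [read_annotation()].
#' @param statistic Family statistic to aggregate by category.
#' @param class Branch class of the statistic (`"whole"`, `"duplicated"`, ...).
#' @return List: `family_stats` (all classes), `by_category` (NULL without
#'   annotation).
#' @export
analyze_dupstats <- function(db, annotation = NULL, statistic = "ka_ks",
                             class = "whole") {
  fs <- db$family_stats
  by_cat <- NULL
  if (!is.null(annotation)) {
    by_cat <- category_aggregate(fs[fs$class == class, , drop = FALSE],
                                 annotation, statistic = statistic)
  }
  list(family_stats = fs, by_category = by_cat)
}

#' Duplication-clade asymmetry test battery
#'
#' For every duplication: chi-square heterogeneity of total and of
#' unambiguous substitution counts between the two clades (null expectation
#' proportional to clade Ks sums by default), and Welch t-tests of |dP| and
#' exchangeability over unambiguous substitutions (only when both clades
#' hold at least two). Benjamini-Hochberg and Bonferroni control are applied
#' per statistic over the tests actually performed.
#'
#' @param db `aaflux_db`.
#' @param exclude_terminal Drop duplications whose clades are both single
#'   terminal branches.
#' @return The `aaflux_db` with the `asymmetry_tests` table filled; the
#'   per-duplication clade statistics are attached as
#'   `attr(db, "clade_stats")`.
#' @export
analyze_asymmetry <- function(db, exclude_terminal = FALSE) {
  cfg <- db$config
  scales <- aa_scales(cfg$polarity_file, cfg$exchangeability_file)
  dd <- db$duplications
  if (exclude_terminal) dd <- dd[!dd$terminal, , drop = FALSE]
  rows <- list(); cs_all <- list()
  for (fid in unique(dd$family_id)) {
    dups <- list(duplications = dd[dd$family_id == fid, , drop = FALSE],
                 clade_branches = db$dup_clades[db$dup_clades$family_id == fid, ,
                                                drop = FALSE])
    recs <- db$substitutions[db$substitutions$family_id == fid, , drop = FALSE]
    alts <- db$substitution_alternatives[
      db$substitution_alternatives$family_id == fid, , drop = FALSE]
    cs <- clade_stats(dups, recs, alts, scales = scales,
                      weighting = cfg$ambiguous_weighting)
    cs_all[[fid]] <- cs
    for (i in seq_len(nrow(cs))) {
      weights <- if (cfg$chi2_null == "ks_weighted") {
        c(cs$clade1_ks[i], cs$clade2_ks[i])
      } else c(1, 1)
      dup_id <- cs$dup_id[i]
      add <- function(stat_name, tr, eligible) {
        rows[[length(rows) + 1L]] <<- data.frame(
          family_id = fid, dup_id = dup_id, statistic_name = stat_name,
          statistic = if (eligible) tr$statistic else NA_real_,
          df = if (eligible) tr$df else NA_real_,
          p = if (eligible) tr$p else NA_real_,
          eligible = eligible, stringsAsFactors = FALSE)
      }
      ok_w <- all(weights > 0)
      tot <- c(cs$clade1_n_total[i], cs$clade2_n_total[i])
      add("total_substitutions",
          if (ok_w && sum(tot) > 0)
            chi2_heterogeneity(tot, weights, correct = cfg$chi2_yates)
          else NULL,
          ok_w && sum(tot) > 0)
      un <- c(cs$clade1_n_unambiguous[i], cs$clade2_n_unambiguous[i])
      add("unambiguous_substitutions",
          if (ok_w && sum(un) > 0)
            chi2_heterogeneity(un, weights, correct = cfg$chi2_yates)
          else NULL,
          ok_w && sum(un) > 0)
      ## radicality t-tests need >= 2 unambiguous substitutions per clade
      g <- lapply(1:2, function(k) {
        br <- dups$clade_branches$branch_id[
          dups$clade_branches$dup_id == dup_id & dups$clade_branches$clade == k]
        recs[!recs$ambiguous & recs$branch_id %in% br, , drop = FALSE]
      })
      elig_t <- all(vapply(g, nrow, 0L) >= 2L)
      for (spec in list(
        c("abs_dpolarity", "dp"), c("exchangeability", "ex"))) {
        if (elig_t) {
          vals <- lapply(g, function(r) {
            if (spec[2] == "dp") delta_polarity(r, scales)$abs_delta_polarity
            else exchangeability(r, scales)$exchangeability
          })
          add(spec[1], welch_t(vals[[1]], vals[[2]], pooled = cfg$pooled_t), TRUE)
        } else add(spec[1], NULL, FALSE)
      }
    }
  }
  at <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), dup_id = character(),
               statistic_name = character(), statistic = numeric(),
               df = numeric(), p = numeric(), eligible = logical(),
               stringsAsFactors = FALSE)
  ## multiple-test control per statistic, m = tests actually performed
  for (q in cfg$fdr_levels) {
    col <- sprintf("fdr_reject_q%02.0f", q * 100)
    at[[col]] <- rep(NA, nrow(at))
    for (s in unique(at$statistic_name)) {
      idx <- at$statistic_name == s
      at[[col]][idx] <- bh_fdr(at$p[idx], q)
    }
  }
  bcol <- sprintf("bonferroni_reject_p%02.0f", cfg$bonferroni_alpha * 100)
  at[[bcol]] <- rep(NA, nrow(at))
  for (s in unique(at$statistic_name)) {
    idx <- at$statistic_name == s
    at[[bcol]][idx] <- bonferroni(at$p[idx], cfg$bonferroni_alpha)
  }
  db$asymmetry_tests <- at
  attr(db, "clade_stats") <- if (length(cs_all)) {
    out <- do.call(rbind, cs_all); rownames(out) <- NULL; out
  } else NULL
  db
}

#' Write a simulated family to disk (FASTA + Newick + truth TSV)
#'
#' @param sim Result of [simulate_family()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sim$alignment$family_id
  write_family_fasta(sim$alignment, file.path(dir, paste0(id, ".fasta")))
  ape::write.tree(sim$tree$phy, file.path(dir, paste0(id, ".nwk")))
  ape::write.tree(sim$species_tree$phy, file.path(dir, "species.nwk"))
  utils::write.table(sim$truth$events,
                     file.path(dir, paste0(id, ".truth.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$duplications,
             file.path(dir, paste0(id, ".duplications.txt")))
  invisible(dir)
}
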