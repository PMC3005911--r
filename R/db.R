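## Relational data model. A built database is an `aaflux_db`: a list of
## plain data.frames mirroring the output tables, plus the run config and
## the species tree. Tables use 1-based alignment columns.

.db_schema <- list(
  families = c(family_id = "character", n_genes = "integer",
               n_columns = "integer", n_sites_unmasked = "integer",
               n_sites_with_substitution = "integer",
               n_substitutions = "integer", n_unambiguous = "integer",
               n_ambiguous = "integer", n_duplications = "integer"),
  tree_nodes = c(family_id = "character", branch_id = "character",
                 parent_branch_id = "character", length = "numeric",
                 is_leaf = "logical", species = "character",
                 event = "character", gene_id = "character",
                 context = "character"),
  substitutions = c(record_id = "character", family_id = "character",
                    site = "integer", branch_id = "character",
                    source_aa = "character", dest_aa = "character",
                    ambiguous = "logical", n_alternatives = "integer",
                    context = "character", clade_ids = "character"),
  substitution_alternatives = c(record_id = "character",
                                family_id = "character", site = "integer",
                                branch_id = "character",
                                source_aa = "character",
                                dest_aa = "character"),
  duplications = c(family_id = "character", dup_id = "character",
                   clade1_ks = "numeric", clade2_ks = "numeric",
                   clade1_n_branches = "integer",
                   clade2_n_branches = "integer", depth_ks = "numeric",
                   terminal = "logical"),
  dup_clades = c(family_id = "character", dup_id = "character",
                 clade = "integer", branch_id = "character"),
  family_stats = c(family_id = "character", class = "character",
                   n_substitutions = "numeric", n_unambiguous = "integer",
                   n_sites = "integer", ks_sum = "numeric", ka = "numeric",
                   ka_ks = "numeric", mean_abs_dpolarity = "numeric",
                   mean_ex = "numeric"),
  flux = c(aa = "character", C = "numeric", R = "numeric", D = "numeric"),
  flux_pairs = c(source_aa = "character", dest_aa = "character",
                 n = "numeric", pair_D = "numeric"),
  ## default column set; extra fdr_reject_* columns appear for non-default
  ## correction levels and are preserved as-is
  asymmetry_tests = c(family_id = "character", dup_id = "character",
                      statistic_name = "character", statistic = "numeric",
                      df = "numeric", p = "numeric", eligible = "logical",
                      fdr_reject_q01 = "logical", fdr_reject_q05 = "logical",
                      bonferroni_reject_p01 = "logical")
)

.coerce_schema <- function(df, schema, add_missing = TRUE) {
  if (is.null(schema)) return(df)
  nms <- if (add_missing) names(schema) else intersect(names(schema), names(df))
  for (nm in nms) {
    if (!nm %in% names(df)) df[[nm]] <- vector(schema[[nm]], nrow(df))
    df[[nm]] <- switch(schema[[nm]],
                       character = as.character(df[[nm]]),
                       integer = as.integer(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       logical = as.logical(df[[nm]]))
  }
  df[, c(nms, setdiff(names(df), nms)), drop = FALSE]
}

.empty_table <- function(name) {
  sch <- .db_schema[[name]]
  if (is.null(sch)) return(data.frame())
  .coerce_schema(data.frame(), sch)
}

DB_TABLES <- c("families", "tree_nodes", "substitutions",
               "substitution_alternatives", "duplications", "dup_clades",
               "family_stats", "flux", "flux_pairs", "asymmetry_tests")

#' Write a built database as SQLite or TSV
#'
#' Emits the relational tables `families`, `tree_nodes`, `substitutions`,
#' `substitution_alternatives`, `duplications`, `dup_clades`,
#' `family_stats`, `flux` (+`flux_pairs`) and `asymmetry_tests` (analysis
#' tables are written empty when not yet computed), plus a `meta` table
#' holding the species tree and configuration. [read_database()] of the
#' result returns identical records.
#'
#' @param db `aaflux_db` from [build_database()].
#' @param path SQLite file path, or a directory for `format = "tsv"`.
#' @param format `"sqlite"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path, format = c("sqlite", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(db, "aaflux_db"))
  tables <- lapply(stats::setNames(DB_TABLES, DB_TABLES), function(nm) {
    t <- db[[nm]]
    if (is.null(t) || !nrow(t)) t <- if (is.null(db[[nm]])) .empty_table(nm) else t
    t
  })
  meta <- data.frame(
    key = c("species_newick", "config_yaml"),
    value = c(db$species_newick, yaml::as.yaml(db$config)),
    stringsAsFactors = FALSE)
  if (format == "sqlite") {
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    for (nm in names(tables)) {
      DBI::dbWriteTable(con, nm, tables[[nm]], overwrite = TRUE)
    }
    DBI::dbWriteTable(con, "meta", meta, overwrite = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      utils::write.table(tables[[nm]], file.path(path, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         na = "NA")
    }
    utils::write.table(meta, file.path(path, "meta.tsv"), sep = "\t",
                       quote = TRUE, row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read a database written by [write_database()]
#'
#' @param path SQLite file or TSV directory.
#' @return `aaflux_db` object.
#' @export
read_database <- function(path) {
  if (dir.exists(path)) {
    tables <- lapply(stats::setNames(DB_TABLES, DB_TABLES), function(nm) {
      f <- file.path(path, paste0(nm, ".tsv"))
      if (!file.exists(f)) return(.empty_table(nm))
      df <- utils::read.delim(f, stringsAsFactors = FALSE,
                              na.strings = "NA", quote = "")
      .coerce_schema(df, .db_schema[[nm]],
                     add_missing = nm != "asymmetry_tests" || nrow(df) == 0L)
    })
    meta <- utils::read.delim(file.path(path, "meta.tsv"),
                              stringsAsFactors = FALSE, quote = "\"")
  } else {
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    tables <- lapply(stats::setNames(DB_TABLES, DB_TABLES), function(nm) {
      df <- DBI::dbReadTable(con, nm)
      .coerce_schema(df, .db_schema[[nm]],
                     add_missing = nm != "asymmetry_tests" || nrow(df) == 0L)
    })
    meta <- DBI::dbReadTable(con, "meta")
  }
  config <- yaml::yaml.load(meta$value[meta$key == "config_yaml"])
  db <- c(tables, list(
    species_newick = meta$value[meta$key == "species_newick"],
    config = config))
  ## asymmetry_tests logical flag columns come back as integers from SQLite
  at <- db$asymmetry_tests
  if (!is.null(at) && nrow(at)) {
    for (nm in grep("_reject_|^eligible$", names(at), value = TRUE)) {
      at[[nm]] <- as.logical(at[[nm]])
    }
    db$asymmetry_tests <- at
  }
  structure(db, class = "aaflux_db")
}

#' Relational integrity check
#'
#' Verifies that every substitution row (and alternative) references an
#' existing tree node of its family and that every clade id references a
#' duplication record.
#'
#' @param db `aaflux_db`.
#' @return TRUE invisibly; stops with a message on a violation.
#' @export
check_integrity <- function(db) {
  key <- function(f, b) paste(f, b, sep = "\r")
  nodes <- key(db$tree_nodes$family_id, db$tree_nodes$branch_id)
  s <- db$substitutions[!is.na(db$substitutions$branch_id), ]
  bad <- !key(s$family_id, s$branch_id) %in% nodes
  if (any(bad)) stop("substitutions reference unknown branches: ",
                     paste(utils::head(s$record_id[bad]), collapse = ", "))
  a <- db$substitution_alternatives
  bad <- !key(a$family_id, a$branch_id) %in% nodes
  if (any(bad)) stop("alternatives reference unknown branches")
  dups <- key(db$duplications$family_id, db$duplications$dup_id)
  cl <- db$substitutions$clade_ids
  cl_ref <- !is.na(cl) & nzchar(cl)
  if (any(cl_ref)) {
    refs <- unlist(mapply(function(f, ids) {
      paste(f, sub("\\.[12]$", "", strsplit(ids, ",")[[1]]), sep = "\r")
    }, db$substitutions$family_id[cl_ref], cl[cl_ref], SIMPLIFY = FALSE))
    if (!all(refs %in% dups)) stop("clade ids reference unknown duplications")
  }
  bad <- !key(db$dup_clades$family_id, db$dup_clades$dup_id) %in% dups
  if (any(bad)) stop("dup_clades reference unknown duplications")
  invisible(TRUE)
}
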