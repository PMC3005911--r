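#' Construct a family alignment
#'
#' @param seqs Named character vector of aligned amino-acid strings, or a
#'   character matrix (rows = genes, columns = alignment columns).
#' @param family_id Family identifier.
#' @return A `family_alignment` object: list with `family_id`, `aa` (character
#'   matrix, rownames = gene ids) and `n_columns`. Columns are 1-based in all
#'   user-facing tables.
#' @export
family_alignment <- function(seqs, family_id = "fam") {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      stop("sequences must carry unique gene ids")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("alignment format error: sequences have unequal lengths (",
           paste(range(lens), collapse = "-"), ")")
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("sequences must carry unique gene ids")
  }
  if (ncol(m) < 1L) stop("alignment must have at least one column")
  bad <- setdiff(unique(as.vector(m)), ALLOWED_CHARS)
  if (length(bad)) {
    stop("alignment contains characters outside the amino-acid alphabet: ",
         paste(bad, collapse = " "))
  }
  structure(list(family_id = family_id, aa = m, n_columns = ncol(m)),
            class = "family_alignment")
}

#' Construct a gene tree
#'
#' @param phy Rooted `phylo` tree; branch lengths are Ks units (synonymous
#'   substitutions per 4-fold degenerate site).
#' @param species Named character vector mapping gene id (tip label) to
#'   species id. Defaults to the tip-label prefix before the first `_`.
#' @param family_id Family identifier.
#' @return A `gene_tree` object wrapping the tree, its index, and the
#'   gene-to-species map.
#' @export
gene_tree <- function(phy, species = NULL, family_id = "fam") {
  ti <- .tree_index(phy)
  if (!is.null(ti$brlen) && any(!is.na(ti$brlen) & (ti$brlen < 0 | !is.finite(ti$brlen)))) {
    stop("branch lengths must be finite and non-negative")
  }
  tips <- phy$tip.label
  if (is.null(species)) {
    species <- stats::setNames(sub("_.*$", "", tips), tips)
  }
  if (!all(tips %in% names(species))) {
    stop("species map lacks genes: ",
         paste(setdiff(tips, names(species)), collapse = ", "))
  }
  structure(list(family_id = family_id, phy = phy, index = ti,
                 species = species[tips]),
            class = "gene_tree")
}

#' Read one gene family (aligned FASTA + rooted Newick)
#'
#' Validates that the tree and alignment describe the same gene set, that all
#' sequences are of equal length over the amino-acid alphabet (`-` gap, `X`
#' unknown), and that the tree is rooted (basal bifurcation).
#'
#' @param alignment_path Aligned FASTA file.
#' @param tree_path Newick file with branch lengths in Ks units.
#' @param family_id Family id; default the alignment file stem.
#' @param species Optional named gene-to-species map (default: tip-label
#'   prefix before the first underscore).
#' @return List with elements `alignment` ([family_alignment]) and `tree`
#'   ([gene_tree]).
#' @export
read_family <- function(alignment_path, tree_path, family_id = NULL,
                        species = NULL) {
  if (is.null(family_id)) {
    family_id <- sub("\\.[^.]*$", "", basename(alignment_path))
  }
  ss <- Biostrings::readAAStringSet(alignment_path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L) {
    stop("alignment format error in ", alignment_path,
         ": sequences have unequal lengths")
  }
  seqs <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  aln <- family_alignment(seqs, family_id)
  phy <- ape::read.tree(tree_path)
  if (is.null(phy)) stop("could not parse Newick tree in ", tree_path)
  gt <- gene_tree(phy, species = species, family_id = family_id)
  in_tree <- phy$tip.label
  in_aln <- rownames(aln$aa)
  if (!setequal(in_tree, in_aln)) {
    stop("tree/alignment consistency error for family ", family_id,
         ": only in tree {", paste(setdiff(in_tree, in_aln), collapse = ","),
         "}, only in alignment {",
         paste(setdiff(in_aln, in_tree), collapse = ","), "}")
  }
  list(alignment = aln, tree = gt)
}

#' Read a rooted species tree
#'
#' @param path Newick file.
#' @return A `species_tree` object (tree plus index).
#' @export
read_species_tree <- function(path) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick tree in ", path)
  species_tree(phy)
}

#' Construct a species tree object
#' @param phy Rooted `phylo`; tip labels are species ids (must be unique).
#' @return `species_tree` object.
#' @export
species_tree <- function(phy) {
  ti <- .tree_index(phy)
  if (anyDuplicated(phy$tip.label)) stop("species ids must be unique")
  structure(list(phy = phy, index = ti), class = "species_tree")
}

#' Read a family-to-category annotation table
#'
#' TSV with header `family_id<TAB>category`; one row per annotated
#' reference-species paralog, so a family may appear several times and then
#' contributes that many entries to category aggregates.
#'
#' @param path TSV file.
#' @param vocabulary Optional controlled vocabulary; labels outside it are an
#'   error naming the offenders.
#' @return data.frame with columns `family_id`, `category`.
#' @export
read_annotation <- function(path, vocabulary = NULL) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("family_id", "category") %in% names(ann))) {
    stop("annotation file must have columns 'family_id' and 'category'")
  }
  ann <- ann[, c("family_id", "category")]
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(ann$category), vocabulary)
    if (length(bad)) {
      stop("unknown category label(s): ", paste(bad, collapse = ", "))
    }
  }
  ann
}

#' Write a family alignment as aligned FASTA
#' @param aln [family_alignment].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_family_fasta <- function(aln, path) {
  seqs <- apply(aln$aa, 1, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}
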