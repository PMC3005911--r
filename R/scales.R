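#' Standard amino-acid alphabet
#'
#' @return Character vector of the 20 standard one-letter amino-acid codes,
#'   in the fixed order used by all matrices in the package.
#' @export
aa_alphabet <- function() AA_ALPHABET

#' Grantham (1974) amino-acid property table
#'
#' Side-chain composition, polarity and volume for the 20 standard amino
#' acids. The polarity column is the scale used as the default radicality
#' reference (AAIndex accession GRAR740102).
#'
#' @param path Optional path to an alternative property table with columns
#'   `aa`, `composition`, `polarity`, `volume`.
#' @return data.frame with one row per amino acid, rownames = one-letter code.
#' @export
grantham_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "grantham_properties.tsv",
                        package = "aaflux", mustWork = TRUE)
  }
  props <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  need <- c("aa", "composition", "polarity", "volume")
  if (!all(need %in% names(props))) {
    stop("property table must have columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(AA_ALPHABET, props$aa)
  if (length(missing)) {
    stop("property table lacks amino acids: ", paste(missing, collapse = ", "))
  }
  props <- props[match(AA_ALPHABET, props$aa), ]
  rownames(props) <- props$aa
  props
}

#' Grantham chemical distance matrix
#'
#' Classical composition/polarity/volume distance
#' `d = rho * sqrt(a*(c1-c2)^2 + b*(p1-p2)^2 + g*(v1-v2)^2)`
#' with the original coefficients (a = 1.833, b = 0.1018, g = 0.000399) and
#' rho scaled so that the mean inter-amino-acid distance is 100. Reproduces
#' the published values (e.g. Leu-Ile = 5, Cys-Trp = 215) to rounding.
#'
#' @param props Property table from [grantham_properties()].
#' @return Symmetric 20 x 20 numeric matrix, zero diagonal.
#' @export
grantham_distance_matrix <- function(props = grantham_properties()) {
  c2 <- outer(props$composition, props$composition, "-")^2
  p2 <- outer(props$polarity, props$polarity, "-")^2
  v2 <- outer(props$volume, props$volume, "-")^2
  d <- sqrt(1.833 * c2 + 0.1018 * p2 + 0.000399 * v2)
  rho <- 100 / mean(d[upper.tri(d)])
  d <- d * rho
  dimnames(d) <- list(props$aa, props$aa)
  d
}

#' Synthetic amino-acid exchangeability matrix
#'
#' A monotone transform of the Grantham distance,
#' `EX(x, y) = exp(-d(x, y) / tau)`, giving values in (0, 1]: high for
#' chemically conservative replacements (Leu->Ile ~ 0.95) and low for
#' radical ones (Cys->Trp ~ 0.12). This is a synthetic stand-in constructed
#' from the bundled property table, not the experimentally measured
#' exchangeability index; it is symmetric, whereas measured exchangeability
#' is direction-sensitive. All lookups in the package are nevertheless
#' performed as `EX[source, destination]` so that a user-supplied asymmetric
#' matrix (see [aa_scales()]) is honoured.
#'
#' @param tau Decay constant in Grantham-distance units (default 100, the
#'   mean inter-amino-acid distance).
#' @param props Property table from [grantham_properties()].
#' @return 20 x 20 numeric matrix, rows = source, columns = destination.
#' @export
synthetic_exchangeability <- function(tau = 100, props = grantham_properties()) {
  stopifnot(is.numeric(tau), tau > 0)
  ex <- exp(-grantham_distance_matrix(props) / tau)
  diag(ex) <- NA_real_
  ex
}

#' Load the radicality scales used by the metrics layer
#'
#' Bundles a polarity vector and an exchangeability matrix into a validated
#' `aa_scales` object. Defaults: Grantham polarity (AAIndex GRAR740102) and
#' the synthetic exchangeability of [synthetic_exchangeability()].
#'
#' @param polarity_file Optional TSV with columns `aa`, `polarity`.
#' @param exchangeability_file Optional TSV holding a 20 x 20 matrix with
#'   amino-acid row and column names (rows = source, columns = destination);
#'   use this to supply a published, direction-sensitive index.
#' @return List with elements `polarity` (named numeric, 20 entries),
#'   `exchangeability` (20 x 20 matrix, NA diagonal) and `provenance`.
#'   Fails at load time if any amino acid or off-diagonal cell is missing.
#' @export
aa_scales <- function(polarity_file = NULL, exchangeability_file = NULL) {
  if (is.null(polarity_file)) {
    props <- grantham_properties()
    polarity <- stats::setNames(props$polarity, props$aa)
    pol_src <- "Grantham polarity (AAIndex GRAR740102), bundled"
  } else {
    tab <- utils::read.delim(polarity_file, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (!all(c("aa", "polarity") %in% names(tab))) {
      stop("polarity file must have columns 'aa' and 'polarity'")
    }
    polarity <- stats::setNames(tab$polarity, tab$aa)[AA_ALPHABET]
    pol_src <- polarity_file
  }
  if (anyNA(polarity) || !all(AA_ALPHABET %in% names(polarity))) {
    stop("polarity scale does not cover all 20 amino acids")
  }
  if (is.null(exchangeability_file)) {
    ex <- synthetic_exchangeability()
    ex_src <- "synthetic (Grantham-distance transform), bundled"
  } else {
    ex <- as.matrix(utils::read.delim(exchangeability_file, row.names = 1,
                                      comment.char = "#"))
    colnames(ex) <- sub("^X\\.?", "", colnames(ex))
    ex_src <- exchangeability_file
  }
  if (!all(AA_ALPHABET %in% rownames(ex)) || !all(AA_ALPHABET %in% colnames(ex))) {
    stop("exchangeability matrix must have all 20 amino acids as rows and columns")
  }
  ex <- ex[AA_ALPHABET, AA_ALPHABET]
  off <- ex[row(ex) != col(ex)]
  if (anyNA(off)) {
    stop("exchangeability matrix has missing off-diagonal cells")
  }
  if (any(off <= 0)) {
    stop("exchangeability values must be positive")
  }
  structure(
    list(polarity = polarity[AA_ALPHABET], exchangeability = ex,
         provenance = c(polarity = pol_src, exchangeability = ex_src)),
    class = "aa_scales"
  )
}
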