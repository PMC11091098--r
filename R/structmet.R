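#' Weighted contact number per residue
#'
#' For each residue i, `wcn_i = sum_{j != i} 1 / r_ij^2`, where `r_ij` is the
#' distance between residue representative points (C-alpha), with no distance
#' cutoff. High WCN marks densely packed (buried) residues; surface residues
#' score low.
#'
#' @param coords numeric matrix, one row per residue, columns x/y/z in
#'   Angstrom.
#' @return Numeric vector of WCN values, one per residue.
#' @examples
#' compute_wcn(rbind(c(0, 0, 0), c(1, 0, 0)))  # 1 1
#' @export
compute_wcn <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) >= 2)
  d <- as.matrix(dist(coords))
  if (any(d[upper.tri(d)] == 0)) {
    stop("duplicate residue coordinates (zero inter-residue distance)")
  }
  w <- 1 / d^2
  diag(w) <- 0
  unname(rowSums(w))
}

#' Weighted contact number from a PDB file
#'
#' Reads the structure, selects C-alpha atoms of the requested chains, and
#' computes the WCN over all selected chains together, so residues at
#' subunit interfaces gain contacts from the partner chain (use both chains
#' of a dimer for the biologically assembled form).
#'
#' @param pdb_file path to a PDB file.
#' @param chains character vector of chain identifiers, or `NULL` for all.
#' @return Tibble `chain`, `resno`, `wcn`.
#' @export
wcn_from_pdb <- function(pdb_file, chains = NULL) {
  pdb <- bio3d::read.pdb(pdb_file)
  sel <- if (is.null(chains)) bio3d::atom.select(pdb, "calpha")
         else bio3d::atom.select(pdb, "calpha", chain = chains)
  atoms <- pdb$atom[sel$atom, ]
  wcn <- compute_wcn(as.matrix(atoms[, c("x", "y", "z")]))
  tibble::tibble(chain = atoms$chain, resno = atoms$resno, wcn = wcn)
}

#' Rescale and truncate predicted stability changes
#'
#' Converts raw structure-based stability predictions from Rosetta energy
#' units to an approximate kcal/mol scale by dividing by 2.9, then truncates
#' to the range 0-5 kcal/mol (values outside carry little extra information
#' about degradation propensity).
#'
#' @param raw numeric vector in Rosetta energy units.
#' @return Numeric vector in `[0, 5]` kcal/mol.
#' @examples
#' postprocess_ddg(c(2.9, 29, -2.9))  # 1 5 0
#' @export
postprocess_ddg <- function(raw) {
  stopifnot(all(is.finite(raw)))
  pmin(pmax(raw / 2.9, 0), 5)
}

#' Filter gappy sequences from a multiple sequence alignment
#'
#' Drops sequences whose gap fraction exceeds `max_gap_fraction` (strictly
#' more than; a sequence at exactly the threshold is retained). Columns are
#' left untouched.
#'
#' @param alignment character vector of equal-length aligned sequences
#'   (possibly named), or a character matrix with one row per sequence.
#' @param max_gap_fraction maximum tolerated gap fraction (default 0.5).
#' @param gap_chars characters counted as gaps.
#' @return The filtered alignment, same type as the input. An empty result
#'   triggers a warning.
#' @export
filter_msa <- function(alignment, max_gap_fraction = 0.5,
                       gap_chars = c("-", ".")) {
  if (is.matrix(alignment)) {
    gapfrac <- rowMeans(matrix(alignment %in% gap_chars, nrow(alignment)))
    keep <- gapfrac <= max_gap_fraction
    out <- alignment[keep, , drop = FALSE]
  } else {
    stopifnot(is.character(alignment))
    if (length(unique(nchar(alignment))) > 1L) {
      stop("alignment is not rectangular")
    }
    pat <- paste0("[", paste(gap_chars, collapse = ""), "]")
    gapfrac <- vapply(alignment, function(s) {
      mean(split_chars(s) %in% gap_chars)
    }, double(1), USE.NAMES = FALSE)
    keep <- gapfrac <= max_gap_fraction
    out <- alignment[keep]
  }
  if (length(out) == 0L || (is.matrix(out) && nrow(out) == 0L)) {
    warning("all sequences removed by gap filter")
  }
  out
}

#' Residue-level metric table
#'
#' Joins per-residue structural covariates with per-position score medians
#' into one tidy table, keyed by position.
#'
#' @param positions integer vector of residue positions.
#' @param wcn optional named/ordered WCN vector aligned to `positions`.
#' @param median_abundance,median_toxicity optional per-position medians.
#' @return Tibble `position`, plus whichever metric columns were supplied;
#'   positions without a value (e.g. unresolved in the structure) carry `NA`.
#' @export
residue_metrics <- function(positions, wcn = NULL, median_abundance = NULL,
                            median_toxicity = NULL) {
  out <- tibble::tibble(position = as.integer(positions))
  add <- function(out, x, name) {
    if (is.null(x)) return(out)
    stopifnot(length(x) == nrow(out))
    out[[name]] <- x
    out
  }
  out <- add(out, wcn, "wcn")
  out <- add(out, median_abundance, "median_abundance")
  add(out, median_toxicity, "median_toxicity")
}
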