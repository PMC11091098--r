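# Placeholder 30-nt Gibson adapters; the real vendor adapters are
# construct-specific and configurable wherever tiles are designed.
DEFAULT_ADAPTERS <- list(
  left  = "ACGTTGCAACCGGTACGTGCAACTGCAGGT",
  right = "TGCAGGTACCGTTGCAACGTACGGTTGCAA")

# Synthetic stand-in for the 22-residue APPY-based control peptide; only the
# last four residues (the degron-strength-determining -RLLL/-RAAA/-DAAA
# suffix) are meaningful for the renormalization logic.
APPY_CORE_SYNTHETIC <- "SIFSTFKNQWGQLP"

#' Design an overlapping peptide-tile library
#'
#' Splits a protein into 24-residue tiles stepping by 12 residues (so
#' consecutive tiles overlap by 12). If the last regular tile does not reach
#' the C-terminus, a C-terminal (CT) tile spanning the final `tile_len`
#' residues is appended; it may overlap its predecessor by more than the
#' regular step. Tiles are assigned to the Odds or Evens library by serial
#' parity (CT flagged separately) so overlapping tiles of one protein never
#' share a library pool. Each tile is reverse-translated with a fixed codon
#' table into a 72-nt insert and flanked by two 30-nt adapters, giving
#' 132-nt oligos.
#'
#' @param protein_seq protein sequence, length >= `tile_len`.
#' @param tile_len tile length in residues (default 24).
#' @param step start-to-start offset in residues (default 12).
#' @param adapters list with `left` and `right` 30-nt adapter sequences.
#' @return Tibble `index`, `start`, `end`, `aa_seq`, `library`
#'   (`odds`/`evens`/`ct`), `nt_seq`, `oligo_seq`.
#' @examples
#' nrow(design_tiles(strrep("A", 313)))  # 26
#' @export
design_tiles <- function(protein_seq, tile_len = 24L, step = 12L,
                         adapters = DEFAULT_ADAPTERS) {
  L <- nchar(protein_seq)
  if (L < tile_len) stop("protein shorter than one tile")
  starts <- seq(1L, L - tile_len + 1L, by = step)
  is_ct <- rep(FALSE, length(starts))
  if (starts[length(starts)] + tile_len - 1L < L) {
    starts <- c(starts, L - tile_len + 1L)
    is_ct <- c(is_ct, TRUE)
  } else if (length(starts) > 1L) {
    is_ct[length(is_ct)] <- starts[length(starts)] + tile_len - 1L == L
  }
  idx <- seq_along(starts)
  aa <- substring(protein_seq, starts, starts + tile_len - 1L)
  nt <- vapply(aa, function(s) {
    paste(CODON_PRIMARY[split_chars(s)], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    index = idx,
    start = starts,
    end = starts + tile_len - 1L,
    aa_seq = aa,
    library = ifelse(is_ct, "ct", ifelse(idx %% 2L == 1L, "odds", "evens")),
    nt_seq = nt,
    oligo_seq = paste0(adapters$left, nt, adapters$right))
}

#' Control degron tiles for cross-library renormalization
#'
#' Three 22-residue control peptides based on a well-characterized degron,
#' differing only in their C-terminal four residues: the active degron
#' (-RLLL), a mildly stabilized variant (-RAAA) and a strongly stabilized
#' variant (-DAAA). They are spiked into every library pool; the RLLL and
#' DAAA tiles are the two-point anchors of the affine renormalization, RAAA
#' is carried but not used in the fit. The peptide core is a synthetic
#' stand-in; only the suffixes drive the logic.
#'
#' @param adapters as in [design_tiles()].
#' @return Tibble with the same columns as [design_tiles()], `library`
#'   `"control"`, 66-nt inserts and 126-nt oligos.
#' @export
control_tiles <- function(adapters = DEFAULT_ADAPTERS) {
  suffixes <- c(RLLL = "RLLL", RAAA = "RAAA", DAAA = "DAAA")
  aa <- paste0(APPY_CORE_SYNTHETIC, "GSQV", suffixes)
  aa <- substr(aa, nchar(aa) - 21L, nchar(aa))  # 22 residues
  nt <- vapply(aa, function(s) {
    paste(CODON_PRIMARY[split_chars(s)], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    index = NA_integer_, start = NA_integer_, end = NA_integer_,
    aa_seq = aa, library = "control",
    nt_seq = nt, oligo_seq = paste0(adapters$left, nt, adapters$right),
    control = names(suffixes))
}

#' TSI per tile and replicate from sorting frequencies
#'
#' Identical in form to [psi_table()]: the frequency-weighted mean bin index,
#' per (library, replicate, tile). Tiles observed in a different library's
#' sorting are assumed to be non-sorted contaminants and dropped before this
#' step.
#'
#' @param freq_tbl tibble `library`, `replicate`, `bin`, `tile`, `count`,
#'   `freq`.
#' @return Tibble `library`, `replicate`, `tile`, `tsi`, `n_reads`.
#' @export
tsi_table <- function(freq_tbl) {
  freq_tbl |>
    dplyr::group_by(.data$library, .data$replicate, .data$tile) |>
    dplyr::summarise(tsi = compute_tsi(.data$freq, .data$bin),
                     n_reads = sum(.data$count), .groups = "drop") |>
    dplyr::filter(!is.na(.data$tsi))
}

#' Fit the two-point control renormalization between libraries
#'
#' Solves for the unique affine map `m(x) = a + b * x` sending the target
#' library's RLLL and DAAA control TSIs onto the reference library's, so that
#' after mapping, both controls agree exactly across libraries.
#'
#' @param ref_controls,target_controls named numeric vectors with elements
#'   `RLLL` and `DAAA`: control TSIs in the reference and target library.
#' @return Named numeric vector `c(a = , b = )`.
#' @examples
#' fit_control_renormalization(c(RLLL = 1, DAAA = 0),
#'                             c(RLLL = 0.5, DAAA = 0.25))  # a = -1, b = 4
#' @export
fit_control_renormalization <- function(ref_controls, target_controls) {
  stopifnot(all(c("RLLL", "DAAA") %in% names(ref_controls)),
            all(c("RLLL", "DAAA") %in% names(target_controls)))
  dx <- target_controls[["RLLL"]] - target_controls[["DAAA"]]
  if (dx == 0) stop("degenerate fit: coincident control TSIs in target library")
  b <- (ref_controls[["RLLL"]] - ref_controls[["DAAA"]]) / dx
  a <- ref_controls[["RLLL"]] - b * target_controls[["RLLL"]]
  c(a = a, b = b)
}

#' Renormalize TSI tables across libraries via the control tiles
#'
#' Per replicate, fits the RLLL/DAAA affine map from each non-reference
#' library onto the reference library and applies it to all of that library's
#' tiles; replicates are renormalized individually, then averaged.
#'
#' @param tsi_tbl output of [tsi_table()]; control tiles must be named
#'   `"RLLL"`, `"RAAA"`, `"DAAA"` in the `tile` column.
#' @param ref_library library whose scale is kept (default `"odds"`).
#' @return A list with `scores` (tibble `tile`, `tsi`, `sd`, `n_rep`) and
#'   `replicate_scores` (per-replicate renormalized TSIs).
#' @export
renormalize_tsi <- function(tsi_tbl, ref_library = "odds") {
  ctrl <- tsi_tbl |>
    dplyr::filter(.data$tile %in% c("RLLL", "DAAA")) |>
    dplyr::select("library", "replicate", "tile", "tsi")
  get_ctrl <- function(lib, rep) {
    x <- ctrl[ctrl$library == lib & ctrl$replicate == rep, ]
    setNames(x$tsi, x$tile)
  }
  mapped <- tsi_tbl |>
    dplyr::group_by(.data$library, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      if (key$library == ref_library) return(d)
      fit <- fit_control_renormalization(
        get_ctrl(ref_library, key$replicate),
        get_ctrl(key$library, key$replicate))
      d$tsi <- fit[["a"]] + fit[["b"]] * d$tsi
      d
    }) |>
    dplyr::ungroup()
  scores <- mapped |>
    dplyr::group_by(.data$tile) |>
    dplyr::summarise(sd = sd(.data$tsi), tsi = mean(.data$tsi),
                     n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::select("tile", "tsi", "sd", "n_rep")
  list(scores = scores, replicate_scores = mapped)
}
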