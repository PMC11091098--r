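#' Protein stability index (PSI): frequency-weighted mean bin
#'
#' For one variant in one replicate, the PSI is the weighted mean of the FACS
#' bin indices with the variant's per-bin frequencies as weights:
#' `sum(g * f_g) / sum(f_g)`. Higher PSI means more of the variant's cells
#' sort into high-fluorescence bins, i.e. higher steady-state abundance.
#'
#' @param f numeric vector of per-bin frequencies (need not be normalized).
#' @param bins bin indices (default `seq_along(f)`).
#' @return PSI in `[min(bins), max(bins)]`, or `NA` if all frequencies are 0.
#' @examples
#' compute_psi(c(0.1, 0.2, 0.3, 0.4))  # 3
#' @export
compute_psi <- function(f, bins = seq_along(f)) {
  stopifnot(length(f) == length(bins), all(f >= 0))
  s <- sum(f)
  if (s == 0) return(NA_real_)
  sum(bins * f) / s
}

#' Tile stability index (TSI)
#'
#' The TSI is computed by the same frequency-weighted mean bin formula as the
#' PSI, applied to peptide tiles rather than full-length variants.
#' @inheritParams compute_psi
#' @export
compute_tsi <- compute_psi

#' PSI per variant and replicate from a frequency table
#'
#' @param freq_tbl output of [merge_and_normalize()] (after
#'   [apply_read_threshold()]), with columns `replicate`, `bin`, `variant`,
#'   `var_class`, `count`, `freq`.
#' @return Tibble `replicate`, `variant`, `var_class`, `psi`, `n_reads`.
#' @export
psi_table <- function(freq_tbl) {
  freq_tbl |>
    dplyr::group_by(.data$replicate, .data$variant, .data$var_class) |>
    dplyr::summarise(psi = compute_psi(.data$freq, .data$bin),
                     n_reads = sum(.data$count), .groups = "drop") |>
    dplyr::filter(!is.na(.data$psi))
}

#' Stop-variant PSI anchor
#'
#' Within each replicate, takes the median PSI over the nonsense variants
#' (one per residue where scored), then averages the per-replicate medians
#' over replicates. Set `per_replicate = FALSE` to pool all replicate-level
#' stop PSIs and take a single median instead (the alternative reading of the
#' anchor definition).
#'
#' @param psi_tbl output of [psi_table()].
#' @param per_replicate median within replicate first (default), then average.
#' @return Scalar PSI_stop.
#' @export
compute_psi_stop <- function(psi_tbl, per_replicate = TRUE) {
  stops <- psi_tbl[psi_tbl$var_class == "nonsense", ]
  if (nrow(stops) == 0L) {
    stop("no nonsense variants scored; supply explicit anchors instead")
  }
  if (!per_replicate) return(median(stops$psi))
  meds <- tapply(stops$psi, stops$replicate, median)
  mean(meds)
}

#' Wild-type PSI anchor
#'
#' The PSI of the wild-type amino-acid sequence, averaged over replicates.
#' When synonymous entries were kept separate upstream
#' (`collapse_synonymous = FALSE`), they are averaged in here, since they
#' encode the wild-type protein.
#'
#' @inheritParams compute_psi_stop
#' @param include_synonymous include separate synonymous entries (default).
#' @return Scalar PSI_WT.
#' @export
compute_psi_wt <- function(psi_tbl, include_synonymous = TRUE) {
  classes <- if (include_synonymous) c("wt", "synonymous") else "wt"
  wt <- psi_tbl[psi_tbl$var_class %in% classes, ]
  if (nrow(wt) == 0L) stop("no wild-type entries scored")
  means <- tapply(wt$psi, wt$replicate, mean)
  mean(means)
}

#' Normalize PSI values to abundance scores
#'
#' Applies the anchored rescaling
#' `score = (PSI - PSI_stop) / (PSI_WT - PSI_stop)` to every replicate's PSI,
#' so wild type scores 1 and the stop-variant anchor scores 0, then reports
#' the per-variant mean, standard deviation and replicate count. Scores are
#' not clamped: variants more abundant than wild type exceed 1.
#'
#' @param psi_tbl output of [psi_table()].
#' @param psi_wt,psi_stop anchors; computed from `psi_tbl` when `NULL`.
#' @return A list with `scores` (tibble `variant`, `var_class`, `score`,
#'   `sd`, `n_rep`), `replicate_scores` (tibble `replicate`, `variant`,
#'   `var_class`, `score`), `psi_wt`, `psi_stop`.
#' @export
normalize_abundance <- function(psi_tbl, psi_wt = NULL, psi_stop = NULL) {
  if (is.null(psi_stop)) psi_stop <- compute_psi_stop(psi_tbl)
  if (is.null(psi_wt)) psi_wt <- compute_psi_wt(psi_tbl)
  if (isTRUE(all.equal(psi_wt, psi_stop))) {
    stop("degenerate anchors: PSI_WT equals PSI_stop")
  }
  rep_scores <- psi_tbl |>
    dplyr::mutate(score = (.data$psi - psi_stop) / (psi_wt - psi_stop)) |>
    dplyr::select("replicate", "variant", "var_class", "score")
  scores <- rep_scores |>
    dplyr::group_by(.data$variant, .data$var_class) |>
    dplyr::summarise(sd = sd(.data$score), score = mean(.data$score),
                     n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::select("variant", "var_class", "score", "sd", "n_rep")
  list(scores = scores, replicate_scores = rep_scores,
       psi_wt = psi_wt, psi_stop = psi_stop)
}

#' Abundance scores from raw bin counts
#'
#' Convenience wrapper: merge/normalize counts, apply the minimum-read filter
#' per replicate, compute PSIs and anchor-normalize.
#'
#' @param counts bin count table (see [merge_and_normalize()]).
#' @param map optional barcode map when `counts` is barcode-keyed.
#' @param min_reads per-replicate read threshold (default 20).
#' @param ... passed to [merge_and_normalize()].
#' @return See [normalize_abundance()].
#' @export
abundance_scores <- function(counts, map = NULL, min_reads = 20, ...) {
  freq <- merge_and_normalize(counts, map, unit = "bin", ...)
  freq <- apply_read_threshold(freq, min_reads, unit = "bin")
  normalize_abundance(psi_table(freq))
}
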