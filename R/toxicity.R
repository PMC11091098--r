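#' Normalize a frequency trajectory over days
#'
#' Divides each day's frequency by the variant's summed frequency across
#' days, so the trajectory sums to one like a distribution over time points.
#' No further normalization is applied: since every sequenced pool is based
#' on the same number of cells, non-depleting variants are expected to drift
#' slightly upward as library complexity falls.
#'
#' @param f numeric vector of per-day frequencies.
#' @return Normalized trajectory, or all-`NA` when the sum is zero (the
#'   variant is unscored in that replicate).
#' @examples
#' normalize_trajectory(c(0.01, 0.02, 0.03, 0.04))  # 0.1 0.2 0.3 0.4
#' @export
normalize_trajectory <- function(f) {
  stopifnot(all(f >= 0))
  s <- sum(f)
  if (s == 0) return(rep(NA_real_, length(f)))
  f / s
}

#' Ordinary least-squares slope of a trajectory
#'
#' The depletion statistic is the unweighted OLS slope of the normalized
#' frequency against day. Weighted least squares is deliberately avoided:
#' the Poisson uncertainty of a frequency is correlated with the frequency
#' itself, so weighting would systematically discount the late, low-frequency
#' time points of depleting variants. Days with zero observed count enter as
#' zeros, not missing values.
#'
#' @param y numeric trajectory values (typically from
#'   [normalize_trajectory()]).
#' @param days numeric day vector, same length as `y`, at least 2 distinct.
#' @return Slope in fraction per day.
#' @export
fit_slope <- function(y, days = c(0, 5, 7, 9)) {
  stopifnot(length(y) == length(days))
  if (length(unique(days)) < 2L) stop("need at least two distinct days")
  dbar <- mean(days)
  sum((days - dbar) * (y - mean(y))) / sum((days - dbar)^2)
}

#' Per-variant, per-replicate depletion slopes
#'
#' @param freq_tbl output of [merge_and_normalize()] with `unit = "day"`
#'   (after [apply_read_threshold()]); columns `replicate`, `day`, `variant`,
#'   `var_class`, `count`, `freq`.
#' @return Tibble `replicate`, `variant`, `var_class`, `alpha`, `n_reads`.
#'   Variants with zero reads at every day in a replicate are unscored there.
#' @export
slope_table <- function(freq_tbl) {
  freq_tbl |>
    dplyr::group_by(.data$replicate, .data$variant, .data$var_class) |>
    dplyr::summarise(
      alpha = fit_slope(normalize_trajectory(.data$freq), .data$day),
      n_reads = sum(.data$count), .groups = "drop") |>
    dplyr::filter(!is.na(.data$alpha))
}

#' Normalize slopes to toxicity scores
#'
#' Rescales each replicate's slopes so that the wild-type anchor scores
#' exactly 0 and the toxic anchor variant scores exactly 1:
#' `score = (alpha - alpha_WT) / (alpha_toxic - alpha_WT)`. Anchoring is per
#' replicate, so both anchors are exact in every replicate.
#'
#' @param slope_tbl output of [slope_table()].
#' @param wt_anchor variant string of the neutral anchor (default `"WT"`).
#' @param toxic_anchor variant string of the toxic anchor (e.g. `"C152W"`).
#' @return A list with `scores` (tibble `variant`, `var_class`, `score`,
#'   `sd`, `n_rep`) and `replicate_scores`.
#' @export
normalize_toxicity <- function(slope_tbl, wt_anchor = "WT", toxic_anchor) {
  anchors <- slope_tbl |>
    dplyr::filter(.data$variant %in% c(wt_anchor, toxic_anchor)) |>
    dplyr::select("replicate", "variant", "alpha") |>
    tidyr::pivot_wider(names_from = "variant", values_from = "alpha")
  if (!all(c(wt_anchor, toxic_anchor) %in% names(anchors))) {
    stop("anchor variants not scored in the slope table")
  }
  anchors <- dplyr::rename(anchors, alpha_wt = !!wt_anchor,
                           alpha_tox = !!toxic_anchor)
  if (any(is.na(anchors$alpha_wt)) || any(is.na(anchors$alpha_tox))) {
    stop("anchor variants missing in some replicates")
  }
  if (any(anchors$alpha_wt == anchors$alpha_tox)) {
    stop("degenerate anchors: identical slopes for WT and toxic anchor")
  }
  rep_scores <- slope_tbl |>
    dplyr::inner_join(anchors, by = "replicate") |>
    dplyr::mutate(score = (.data$alpha - .data$alpha_wt) /
                    (.data$alpha_tox - .data$alpha_wt)) |>
    dplyr::select("replicate", "variant", "var_class", "score")
  scores <- rep_scores |>
    dplyr::group_by(.data$variant, .data$var_class) |>
    dplyr::summarise(sd = sd(.data$score), score = mean(.data$score),
                     n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::select("variant", "var_class", "score", "sd", "n_rep")
  list(scores = scores, replicate_scores = rep_scores)
}

#' Toxicity scores from raw time-course counts
#'
#' Convenience wrapper: merge/normalize counts per day, apply the
#' minimum-read filter (summed across days per replicate, mirroring the
#' abundance filter), fit slopes and anchor-normalize.
#'
#' @param counts time-course count table with a `day` column.
#' @param map optional barcode map when `counts` is barcode-keyed.
#' @param min_reads per-replicate read threshold (default 20).
#' @inheritParams normalize_toxicity
#' @param ... passed to [merge_and_normalize()].
#' @export
toxicity_scores <- function(counts, map = NULL, min_reads = 20,
                            wt_anchor = "WT", toxic_anchor, ...) {
  freq <- merge_and_normalize(counts, map, unit = "day", ...)
  freq <- apply_read_threshold(freq, min_reads, unit = "day")
  normalize_toxicity(slope_table(freq), wt_anchor, toxic_anchor)
}
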