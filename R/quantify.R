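#' Count exact-match barcodes in a sample
#'
#' Reads contribute only when their extracted barcode is an exact (full
#' string) match to a key of the barcode map; near-matches are never rescued.
#'
#' @param barcodes character vector of observed barcodes, one per read.
#' @param map barcode map tibble (see [build_barcode_map()]).
#' @return A list with `counts` (tibble `barcode`, `count`, covering every map
#'   barcode, zeros included), `n_total`, `n_matched`, `n_unmatched`.
#' @export
count_barcodes <- function(barcodes, map) {
  if (nrow(map) == 0L) stop("barcode map is empty")
  matched <- barcodes[barcodes %in% map$barcode]
  tab <- table(factor(matched, levels = map$barcode))
  counts <- tibble::tibble(barcode = map$barcode,
                           count = as.integer(tab))
  list(counts = counts,
       n_total = length(barcodes),
       n_matched = length(matched),
       n_unmatched = length(barcodes) - length(matched))
}

#' Merge technical replicates and barcodes into variant frequencies
#'
#' Sums counts over technical replicates and over barcodes sharing an
#' amino-acid variant, then normalizes to frequencies within each
#' (replicate, bin/day) without pseudocounts. By default, synonymous entries
#' are merged into the wild-type amino-acid entry, since counts are merged at
#' the amino-acid level; set `collapse_synonymous = FALSE` to keep the
#' synonymous track separate (useful for showing the wild-type mode of the
#' score distribution).
#'
#' @param counts tibble with columns `replicate`, the unit column (`bin` or
#'   `day`), `count`, and either `barcode` (joined to `map`) or `variant` +
#'   `var_class` directly; an optional `tech_rep` column marks technical
#'   replicates to be summed.
#' @param map barcode map, required when `counts` is keyed by barcode.
#' @param unit name of the sorting/time unit column, `"bin"` or `"day"`.
#' @param collapse_synonymous merge synonymous entries into `"WT"` (default).
#' @return Tidy tibble `replicate`, unit, `variant`, `var_class`, `count`,
#'   `freq`, completed so every variant appears in every (replicate, unit)
#'   with zero count where unobserved.
#' @export
merge_and_normalize <- function(counts, map = NULL, unit = "bin",
                                collapse_synonymous = TRUE) {
  stopifnot(unit %in% names(counts), "replicate" %in% names(counts),
            "count" %in% names(counts))
  if (!"variant" %in% names(counts)) {
    if (is.null(map)) stop("barcode-keyed counts require a barcode map")
    counts <- dplyr::inner_join(counts,
                                map[, c("barcode", "variant", "var_class")],
                                by = "barcode")
  } else if (!"var_class" %in% names(counts)) {
    counts$var_class <- parse_variant(counts$variant)$var_class
  }
  if (collapse_synonymous) {
    syn <- counts$var_class == "synonymous"
    counts$variant[syn] <- "WT"
    counts$var_class[syn] <- "wt"
  }
  merged <- counts |>
    dplyr::group_by(.data$replicate, .data[[unit]], .data$variant,
                    .data$var_class) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  merged <- tidyr::complete(merged, !!rlang::sym("replicate"),
                            !!rlang::sym(unit),
                            tidyr::nesting(variant, var_class),
                            fill = list(count = 0L))
  merged |>
    dplyr::group_by(.data$replicate, .data[[unit]]) |>
    dplyr::mutate(freq = if (sum(.data$count) > 0)
                    .data$count / sum(.data$count) else 0) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$replicate, .data[[unit]], .data$variant)
}

#' Apply the minimum-read filter per replicate
#'
#' A variant is scored in a replicate only when its summed count across bins
#' (or days) in that replicate reaches `min_reads`; filtering is per
#' replicate, so a variant can be scored in some replicates and not others.
#'
#' @param tbl merged frequency table from [merge_and_normalize()].
#' @param min_reads minimum summed reads per replicate (default 20).
#' @param unit name of the bin/day column.
#' @return `tbl` restricted to retained (replicate, variant) combinations.
#' @export
apply_read_threshold <- function(tbl, min_reads = 20, unit = "bin") {
  tbl |>
    dplyr::group_by(.data$replicate, .data$variant) |>
    dplyr::filter(sum(.data$count) >= min_reads) |>
    dplyr::ungroup()
}
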