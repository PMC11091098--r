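#' Per-position median score
#'
#' The positional summary shown above variant-effect heat maps: the median of
#' the scored substitutions at each residue. Nonsense variants are excluded
#' by default (the stop row is a separate anchor class, not a substitution
#' tolerance readout); include them via `classes`.
#'
#' @param score_tbl tibble with at least `variant`, `score` (and optionally
#'   `var_class`, `position`; both are derived from `variant` if absent).
#' @param classes variant classes entering the median (default `"missense"`).
#' @return Tibble `position`, `median_score`, `n_variants`.
#' @export
per_position_median <- function(score_tbl, classes = "missense") {
  tbl <- ensure_variant_fields(score_tbl)
  tbl |>
    dplyr::filter(.data$var_class %in% classes, !is.na(.data$score)) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(median_score = median(.data$score),
                     n_variants = dplyr::n(), .groups = "drop")
}

ensure_variant_fields <- function(tbl) {
  if (!all(c("position", "var_class") %in% names(tbl))) {
    parsed <- parse_variant(tbl$variant)
    if (!"position" %in% names(tbl)) tbl$position <- parsed$position
    if (!"var_class" %in% names(tbl)) tbl$var_class <- parsed$var_class
  }
  tbl
}

#' Variance in variant scores explained by position
#'
#' Quantifies how much of the variant-to-variant score variation is carried
#' by residue position alone, using the per-position median as the positional
#' predictor. Two estimators are reported: the squared Pearson correlation
#' between each variant's score and its positional median, and the regression
#' flavor `1 - SSE/SST` with the positional median as the prediction. They
#' agree when the medians are an unbiased linear predictor and differ
#' otherwise, so both are returned rather than hiding the choice.
#'
#' @param score_tbl as in [per_position_median()].
#' @param medians optional precomputed output of [per_position_median()].
#' @param classes variant classes included (default `"missense"`).
#' @return List with `r` (Pearson correlation), `r_squared`,
#'   `frac_sse` (`1 - SSE/SST`), and `n` variants used.
#' @export
variance_explained <- function(score_tbl, medians = NULL,
                               classes = "missense") {
  tbl <- ensure_variant_fields(score_tbl)
  tbl <- tbl[tbl$var_class %in% classes & !is.na(tbl$score), ]
  if (is.null(medians)) medians <- per_position_median(tbl, classes)
  joined <- dplyr::inner_join(tbl, medians, by = "position")
  if (length(unique(joined$position)) < 2L) stop("need >= 2 positions")
  r <- cor(joined$score, joined$median_score)
  sse <- sum((joined$score - joined$median_score)^2)
  sst <- sum((joined$score - mean(joined$score))^2)
  list(r = r, r_squared = r^2, frac_sse = 1 - sse / sst, n = nrow(joined))
}

#' Correlation with a percentile bootstrap confidence interval
#'
#' Rank (Spearman) or linear (Pearson) correlation over the paired
#' observations where both values are defined, with a seed-reproducible
#' percentile bootstrap CI.
#'
#' @param x,y numeric vectors of equal length; pairs with any `NA` are
#'   dropped.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf_level CI coverage (default 0.95).
#' @param seed optional integer seed for the bootstrap.
#' @return List `estimate`, `ci` (length-2), `method`, `n`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson"),
                      n_boot = 1000, conf_level = 0.95, seed = NULL) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  est <- cor(x, y, method = method)
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    suppressWarnings(cor(x[i], y[i], method = method))
  }, double(1))
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  list(estimate = est, ci = ci, method = method, n = n)
}

#' Clinical-class summary of variant scores
#'
#' Joins clinical annotations (pathogenic / benign / VUS) onto scored
#' variants and summarizes each class: size, number strictly below the score
#' threshold, quartiles, and the box-and-whisker bounds (1.5 IQR convention)
#' with outlier count.
#'
#' @param score_tbl tibble with `variant`, `score`.
#' @param annotations tibble with `variant`, `label` and optionally
#'   `allele_frequency`.
#' @param threshold score cut (default 0.5); the comparison is strict (`<`).
#' @return Tibble per label: `label`, `n`, `n_below`, `q25`, `median`, `q75`,
#'   `whisker_lo`, `whisker_hi`, `n_outliers`.
#' @export
clinical_summary <- function(score_tbl, annotations, threshold = 0.5) {
  joined <- dplyr::inner_join(annotations, score_tbl[, c("variant", "score")],
                              by = "variant")
  joined <- joined[!is.na(joined$score), ]
  joined |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_below = sum(.data$score < threshold),
      q25 = quantile(.data$score, 0.25),
      median = median(.data$score),
      q75 = quantile(.data$score, 0.75),
      whisker_lo = max(min(.data$score),
                       quantile(.data$score, 0.25) - 1.5 * stats::IQR(.data$score)),
      whisker_hi = min(max(.data$score),
                       quantile(.data$score, 0.75) + 1.5 * stats::IQR(.data$score)),
      n_outliers = sum(.data$score < quantile(.data$score, 0.25) -
                         1.5 * stats::IQR(.data$score) |
                       .data$score > quantile(.data$score, 0.75) +
                         1.5 * stats::IQR(.data$score)),
      .groups = "drop")
}

#' Replicate agreement statistics
#'
#' Average pairwise Pearson correlation and mean absolute difference between
#' replicate score vectors, each pair computed on the variants scored in both
#' members.
#'
#' @param rep_matrix numeric matrix, variants x replicates (`NA` where a
#'   variant was not scored in a replicate), or a tidy tibble with columns
#'   `replicate`, `variant`, `score`.
#' @param method correlation method (default `"pearson"`).
#' @return List `mean_r`, `mean_mae`, `n_pairs`.
#' @export
replicate_stats <- function(rep_matrix, method = "pearson") {
  m <- as_replicate_matrix(rep_matrix)
  k <- ncol(m)
  if (k < 2L) stop("need at least two replicates")
  pairs <- utils::combn(k, 2)
  rs <- maes <- double(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- m[, pairs[1, p]]; b <- m[, pairs[2, p]]
    ok <- complete.cases(a, b)
    rs[p] <- cor(a[ok], b[ok], method = method)
    maes[p] <- mean(abs(a[ok] - b[ok]))
  }
  list(mean_r = mean(rs), mean_mae = mean(maes), n_pairs = ncol(pairs))
}

as_replicate_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(all(c("replicate", "variant", "score") %in% names(x)))
  wide <- tidyr::pivot_wider(x[, c("replicate", "variant", "score")],
                             names_from = "replicate",
                             values_from = "score")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$variant
  m
}

#' Replicate correlation stratified by score class
#'
#' Partitions variants into strata (e.g. toxic vs non-toxic among
#' low-abundance variants) and reports the mean pairwise replicate rank
#' correlation within each stratum. Pairs where either replicate vector has
#' zero variance within a stratum are flagged as `NA` rather than silently
#' reported as perfect agreement.
#'
#' @param rep_matrix as in [replicate_stats()].
#' @param strata factor/character vector, one entry per variant (matrix row),
#'   `NA` rows are dropped.
#' @param method correlation method (default `"spearman"`).
#' @return Tibble `stratum`, `n_variants`, `mean_rho`, `n_pairs_defined`.
#' @export
stratified_replicate_correlation <- function(rep_matrix, strata,
                                             method = "spearman") {
  m <- as_replicate_matrix(rep_matrix)
  stopifnot(length(strata) == nrow(m))
  keep <- !is.na(strata)
  m <- m[keep, , drop = FALSE]
  strata <- strata[keep]
  out <- lapply(split(seq_len(nrow(m)), strata), function(idx) {
    sm <- m[idx, , drop = FALSE]
    pairs <- utils::combn(ncol(sm), 2)
    rho <- vapply(seq_len(ncol(pairs)), function(p) {
      a <- sm[, pairs[1, p]]; b <- sm[, pairs[2, p]]
      ok <- complete.cases(a, b)
      if (sum(ok) < 3L || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
      cor(a[ok], b[ok], method = method)
    }, double(1))
    tibble::tibble(n_variants = length(idx),
                   mean_rho = mean(rho, na.rm = TRUE),
                   n_pairs_defined = sum(!is.na(rho)))
  })
  dplyr::bind_rows(out, .id = "stratum")
}
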