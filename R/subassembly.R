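#' Extract barcode and coding sequence from long reads
#'
#' Locates the 18-nt random barcode and the downstream coding sequence in a
#' raw long read using exact matches to the constant flanking sequences of the
#' construct. Reads lacking a flank, with an ambiguous (multiply matching)
#' flank, or with a barcode of the wrong length are rejected with a reason
#' code rather than rescued.
#'
#' @param reads character vector of raw read sequences.
#' @param flanks list with elements `bc_left` and `bc_right`, the constant
#'   sequences immediately bounding the barcode; the CDS is taken as
#'   everything after `bc_right` (optionally up to `cds_right` when given).
#' @param barcode_length expected barcode length (default 18 nt).
#' @return A tibble with one row per read: `read`, `barcode`, `cds`,
#'   `status` (`"ok"`/`"rejected"`) and `reason`.
#' @export
extract_barcode_and_cds <- function(reads, flanks, barcode_length = 18L) {
  stopifnot(is.list(flanks), !is.null(flanks$bc_left), !is.null(flanks$bc_right))
  cds_right <- flanks$cds_right
  n <- length(reads)
  barcode <- cds <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  locate_unique <- function(read, pattern) {
    hits <- gregexpr(pattern, read, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NULL)
    if (length(hits) > 1L) return(NA_integer_)
    as.integer(hits[1])
  }

  for (i in seq_len(n)) {
    rd <- reads[i]
    lpos <- locate_unique(rd, flanks$bc_left)
    if (is.null(lpos)) { reason[i] <- "no_left_flank"; next }
    if (is.na(lpos)) { reason[i] <- "ambiguous_flank"; next }
    rpos <- locate_unique(rd, flanks$bc_right)
    if (is.null(rpos)) { reason[i] <- "no_right_flank"; next }
    if (is.na(rpos)) { reason[i] <- "ambiguous_flank"; next }
    bc_start <- lpos + nchar(flanks$bc_left)
    if (rpos < bc_start) { reason[i] <- "no_right_flank"; next }
    bc <- substr(rd, bc_start, rpos - 1L)
    if (nchar(bc) != barcode_length) { reason[i] <- "bad_barcode_length"; next }
    cds_start <- rpos + nchar(flanks$bc_right)
    cds_end <- nchar(rd)
    if (!is.null(cds_right)) {
      cpos <- locate_unique(rd, cds_right)
      if (is.null(cpos) || is.na(cpos) || cpos <= cds_start) {
        reason[i] <- "no_cds_flank"; next
      }
      cds_end <- cpos - 1L
    }
    barcode[i] <- bc
    cds[i] <- substr(rd, cds_start, cds_end)
  }
  tibble::tibble(read = reads, barcode = barcode, cds = cds,
                 status = ifelse(is.na(reason), "ok", "rejected"),
                 reason = reason)
}

#' Call the amino-acid variant encoded by a CDS read
#'
#' Compares each read-derived coding sequence to the reference CDS by global
#' position-wise comparison (no alignment). Reads whose length differs from
#' the reference are treated as indel-containing and rejected; reads with ten
#' or more nucleotide substitutions are rejected; reads encoding two or more
#' amino-acid changes are rejected as multi-variant. The remainder are
#' classified as wild type, synonymous, missense or nonsense.
#'
#' @param cds character vector of coding sequences (may include the stop codon).
#' @param reference_cds reference coding sequence; length divisible by 3.
#' @param max_subs reads with `n_subs >= max_subs` are rejected (default 10).
#' @return A tibble with `cds`-parallel rows: `variant`, `var_class`,
#'   `n_subs`, `status`, `reason`.
#' @export
call_variant <- function(cds, reference_cds, max_subs = 10L) {
  if (nchar(reference_cds) %% 3L != 0L) {
    stop("reference CDS length must be divisible by 3")
  }
  n <- length(cds)
  out <- tibble::tibble(cds = cds, variant = NA_character_,
                        var_class = NA_character_, n_subs = NA_integer_,
                        status = "rejected", reason = NA_character_)
  ref_raw <- charToRaw(reference_cds)
  ref_prot <- translate_nt(reference_cds)

  ref_has_stop <- ref_prot[length(ref_prot)] == "*"

  for (i in seq_len(n)) {
    s <- cds[i]
    if (grepl("[^ACGT]", s)) { out$reason[i] <- "non_acgt"; next }
    if (nchar(s) != length(ref_raw)) { out$reason[i] <- "indel"; next }
    raw <- charToRaw(s)
    diffs <- which(raw != ref_raw)
    out$n_subs[i] <- length(diffs)
    if (length(diffs) >= max_subs) { out$reason[i] <- "too_many_subs"; next }
    if (length(diffs) == 0L) {
      out$variant[i] <- "WT"; out$var_class[i] <- "wt"; out$status[i] <- "ok"
      next
    }
    # changes inside the terminal stop codon are outside the variant universe
    if (ref_has_stop && any(diffs > length(ref_raw) - 3L)) {
      out$reason[i] <- "stop_codon_change"; next
    }
    prot <- translate_nt(s)
    aa_diff <- which(prot != ref_prot)
    if (length(aa_diff) == 0L) {
      pos <- (diffs[1] - 1L) %/% 3L + 1L
      out$variant[i] <- paste0(ref_prot[pos], pos, "=")
      out$var_class[i] <- "synonymous"; out$status[i] <- "ok"
    } else if (length(aa_diff) == 1L) {
      pos <- aa_diff
      alt <- prot[pos]
      out$variant[i] <- paste0(ref_prot[pos], pos, if (alt == "*") "*" else alt)
      out$var_class[i] <- if (alt == "*") "nonsense" else "missense"
      out$status[i] <- "ok"
    } else {
      out$reason[i] <- "multi_variant"
    }
  }
  out
}

# Translate a nucleotide string to a character vector of residues
# (internal and terminal stops kept as "*").
translate_nt <- function(x) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                           no.init.codon = TRUE))
  split_chars(aa)
}

#' Build the barcode-to-variant map by majority rule
#'
#' Groups variant-called reads by barcode. Barcodes whose reads all agree map
#' directly; discordant barcodes map to the strict-majority variant (dominant
#' read fraction > 0.5); barcodes with no strict majority (ties) are dropped.
#'
#' @param calls tibble with columns `barcode`, `variant`, `var_class`
#'   (typically the `status == "ok"` rows from [call_variant()] joined to
#'   their barcodes).
#' @return A tibble (the barcode map) with columns `barcode`, `variant`,
#'   `var_class`, `n_reads` (supporting the dominant variant),
#'   `n_total_reads`, `dominant_fraction`.
#' @export
build_barcode_map <- function(calls) {
  if (nrow(calls) == 0L) {
    return(tibble::tibble(barcode = character(), variant = character(),
                          var_class = character(), n_reads = integer(),
                          n_total_reads = integer(),
                          dominant_fraction = double()))
  }
  calls |>
    dplyr::count(.data$barcode, .data$variant, .data$var_class,
                 name = "n_reads") |>
    dplyr::group_by(.data$barcode) |>
    dplyr::mutate(n_total_reads = sum(.data$n_reads),
                  dominant_fraction = .data$n_reads / .data$n_total_reads,
                  n_top = sum(.data$n_reads == max(.data$n_reads))) |>
    dplyr::filter(.data$n_reads == max(.data$n_reads), .data$n_top == 1L,
                  .data$dominant_fraction > 0.5) |>
    dplyr::ungroup() |>
    dplyr::select("barcode", "variant", "var_class", "n_reads",
                  "n_total_reads", "dominant_fraction") |>
    dplyr::arrange(.data$barcode)
}

#' Subassemble a barcode map from raw long reads
#'
#' End-to-end wrapper: flank-based extraction, variant calling with the
#' substitution/indel filters, and majority-rule map construction, with a
#' per-filter accounting log.
#'
#' @inheritParams extract_barcode_and_cds
#' @inheritParams call_variant
#' @return A list with elements `map` (see [build_barcode_map()]) and `log`,
#'   a named list of counts: reads in, rejected per reason, reads mapped,
#'   barcodes kept, discordant barcodes resolved by majority, and barcodes
#'   dropped for lack of a strict majority.
#' @export
subassemble <- function(reads, reference_cds, flanks,
                        barcode_length = 18L, max_subs = 10L) {
  ext <- extract_barcode_and_cds(reads, flanks, barcode_length)
  ok <- ext[ext$status == "ok", ]
  calls <- call_variant(ok$cds, reference_cds, max_subs)
  calls$barcode <- ok$barcode
  kept <- calls[calls$status == "ok", ]
  map <- build_barcode_map(kept)

  count_reason <- function(tbl, r) sum(tbl$reason == r, na.rm = TRUE)
  by_bc <- dplyr::count(kept, .data$barcode, .data$variant)
  n_bc_seen <- length(unique(kept$barcode))
  discordant <- by_bc |>
    dplyr::count(.data$barcode) |>
    dplyr::filter(.data$n > 1L)
  log <- list(
    n_reads = length(reads),
    n_flank_rejected = sum(ext$status == "rejected"),
    n_indel = count_reason(calls, "indel"),
    n_too_many_subs = count_reason(calls, "too_many_subs"),
    n_multi_variant = count_reason(calls, "multi_variant"),
    n_non_acgt = count_reason(calls, "non_acgt"),
    n_reads_mapped = nrow(kept),
    n_barcodes_seen = n_bc_seen,
    n_barcodes_kept = nrow(map),
    n_barcodes_discordant = nrow(discordant),
    n_barcodes_dropped_no_majority = n_bc_seen - nrow(map),
    mean_dominant_fraction = if (nrow(map)) mean(map$dominant_fraction) else NA_real_
  )
  list(map = map, log = log)
}
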