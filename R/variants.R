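#' @importFrom rlang .data
#' @importFrom stats cor median quantile rnorm rpois rbeta rbinom runif sd
#'   setNames complete.cases dist qnorm pnorm rmultinom
#' @importFrom utils head
NULL

#' The twenty standard amino acids
#'
#' One-letter codes in alphabetical order, used throughout to enumerate
#' substitutions.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Fixed codon-per-amino-acid table (human-preferred codons). nt sequences only
# matter for oligo-length checks and simulated read construction, so one codon
# per residue suffices; CODON_ALT provides a synonymous alternative where the
# genetic code allows one (none for M and W).
CODON_PRIMARY <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCC", Q = "CAG", R = "CGG", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC", `*` = "TGA")

CODON_ALT <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGA",
  H = "CAT", I = "ATT", K = "AAA", L = "CTC", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGA", S = "TCC", T = "ACA", V = "GTC",
  Y = "TAT")

#' Reverse-translate a protein sequence with the fixed codon table
#'
#' @param protein_seq character scalar of one-letter amino acids (no stop).
#' @return Nucleotide string of length `3 * nchar(protein_seq) + 3` including
#'   the terminal stop codon.
#' @export
reverse_translate <- function(protein_seq) {
  aa <- split_chars(protein_seq)
  bad <- setdiff(aa, AA_STANDARD)
  if (length(bad) > 0) {
    stop("non-standard residues in protein sequence: ",
         paste(unique(bad), collapse = ", "))
  }
  paste0(paste(CODON_PRIMARY[aa], collapse = ""), CODON_PRIMARY[["*"]])
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Parse compact variant strings
#'
#' Accepts the compact naming used for single amino-acid variants:
#' `"C152W"` (missense), `"W64*"` (nonsense), `"L10="` (synonymous) and
#' `"WT"`. Vectorized; malformed strings raise an error naming the offender.
#'
#' @param x character vector of variant strings.
#' @return A tibble with columns `variant`, `position`, `wt_aa`, `alt_aa`,
#'   `var_class`. For `"WT"` the position is `NA`; for synonymous entries
#'   `alt_aa` equals `wt_aa`.
#' @examples
#' parse_variant(c("C152W", "W64*", "WT", "L10="))
#' @export
parse_variant <- function(x) {
  stopifnot(is.character(x), length(x) > 0)
  out <- tibble::tibble(variant = x,
                        position = NA_integer_,
                        wt_aa = NA_character_,
                        alt_aa = NA_character_,
                        var_class = NA_character_)
  is_wt <- x == "WT"
  out$var_class[is_wt] <- "wt"

  m <- regexec("^([A-Y])([0-9]+)([A-Y*=])$", x)
  parts <- regmatches(x, m)
  for (i in which(!is_wt)) {
    p <- parts[[i]]
    if (length(p) != 4 || !p[2] %in% AA_STANDARD) {
      stop("malformed variant string: '", x[i], "'")
    }
    wt <- p[2]; pos <- as.integer(p[3]); alt <- p[4]
    cls <- if (alt == "*") "nonsense"
           else if (alt == "=") "synonymous"
           else if (alt %in% AA_STANDARD) "missense"
           else stop("malformed variant string: '", x[i], "'")
    if (cls == "missense" && alt == wt) {
      stop("alt equals wt outside synonymous form: '", x[i], "'")
    }
    if (cls == "synonymous") alt <- wt
    out$position[i] <- pos
    out$wt_aa[i] <- wt
    out$alt_aa[i] <- alt
    out$var_class[i] <- cls
  }
  out
}

#' Format a VariantId as a compact string
#'
#' Inverse of [parse_variant()].
#' @param position integer vector (ignored for class `"wt"`).
#' @param wt_aa,alt_aa one-letter codes.
#' @param var_class one of `"wt"`, `"synonymous"`, `"missense"`, `"nonsense"`.
#' @export
format_variant <- function(position, wt_aa, alt_aa, var_class) {
  ifelse(var_class == "wt", "WT",
    ifelse(var_class == "synonymous", paste0(wt_aa, position, "="),
      paste0(wt_aa, position,
             ifelse(var_class == "nonsense", "*", alt_aa))))
}

#' Enumerate the single amino-acid variant universe of a protein
#'
#' For a protein of length L this is 19 substitutions per residue, one
#' premature stop per residue except the last, and a single wild-type entry:
#' `19 L + (L - 1) + 1 = 20 L` variants in total (6260 for L = 313).
#'
#' @param protein_seq character scalar of one-letter amino acids, length >= 2.
#' @return A tibble with one row per variant: `variant`, `position`, `wt_aa`,
#'   `alt_aa`, `var_class`.
#' @examples
#' nrow(enumerate_variant_universe("MC"))  # 40
#' @export
enumerate_variant_universe <- function(protein_seq) {
  aa <- split_chars(protein_seq)
  L <- length(aa)
  if (L < 2) stop("protein sequence must have length >= 2")
  bad <- setdiff(aa, AA_STANDARD)
  if (length(bad) > 0) {
    stop("non-standard residues in protein sequence: ",
         paste(unique(bad), collapse = ", "))
  }
  mis <- tibble::tibble(
    position = rep(seq_len(L), each = length(AA_STANDARD) - 1L),
    wt_aa = rep(aa, each = length(AA_STANDARD) - 1L),
    alt_aa = unlist(lapply(aa, function(w) setdiff(AA_STANDARD, w))),
    var_class = "missense")
  non <- tibble::tibble(position = seq_len(L - 1L), wt_aa = aa[seq_len(L - 1L)],
                        alt_aa = "*", var_class = "nonsense")
  wt <- tibble::tibble(position = NA_integer_, wt_aa = NA_character_,
                       alt_aa = NA_character_, var_class = "wt")
  out <- dplyr::bind_rows(wt, mis, non)
  out$variant <- format_variant(out$position, out$wt_aa, out$alt_aa,
                                out$var_class)
  out[, c("variant", "position", "wt_aa", "alt_aa", "var_class")]
}
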