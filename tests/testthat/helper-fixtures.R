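# Shared fixtures: all synthetic, built in code at test time.

toy_flanks <- list(bc_left = "AAGGCCTTACGG", bc_right = "TTCCGGAACGTA")

# A small simulation config sized for fast unit tests.
small_config <- function(seed = 11L, L = 30L, n_synonymous = 5L,
                         replicates_abundance = 3L, ...) {
  sim_config(seed = seed, protein_seq = default_protein(L),
             n_barcodes_per_variant = 4, reads_per_bin = 5e4,
             reads_per_day = 1e5, n_cells = 5e4,
             replicates_abundance = replicates_abundance,
             replicates_toxicity = 2,
             n_synonymous = n_synonymous, toxic_anchor = NA_character_, ...)
}

ref_codons <- function(ref_cds) {
  substring(ref_cds, seq(1, nchar(ref_cds), 3), seq(3, nchar(ref_cds), 3))
}

# Construct the CDS encoding a given compact variant string relative to the
# fixed codon table used by reverse_translate().
mutate_cds <- function(variant, ref_cds) {
  p <- parse_variant(variant)
  if (p$var_class == "wt") return(ref_cds)
  codons <- ref_codons(ref_cds)
  codons[p$position] <- switch(p$var_class,
    synonymous = vampseqr:::CODON_ALT[[p$wt_aa]],
    nonsense = vampseqr:::CODON_PRIMARY[["*"]],
    missense = vampseqr:::CODON_PRIMARY[[p$alt_aa]])
  paste(codons, collapse = "")
}

# Assemble full-length reads (left flank + barcode + right flank + CDS).
make_reads <- function(barcodes, cds, flanks = toy_flanks) {
  paste0(flanks$bc_left, barcodes, flanks$bc_right, cds)
}

# Independent OLS oracle: solve the normal equations explicitly.
ols_slope_oracle <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  unname(beta[2, 1])
}

# Tidy bin-count table from a matrix of counts (variants x bins) for one
# replicate.
counts_from_matrix <- function(m, variants, replicate = 1L,
                               var_class = NULL) {
  if (is.null(var_class)) var_class <- parse_variant(variants)$var_class
  tibble::tibble(
    replicate = replicate,
    bin = rep(seq_len(ncol(m)), each = nrow(m)),
    variant = rep(variants, ncol(m)),
    var_class = rep(var_class, ncol(m)),
    count = as.integer(m))
}
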