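ref8 <- default_protein(8)
ref8_cds <- reverse_translate(ref8)

test_that("flank-based extraction returns barcode and CDS or a reason", {
  bc <- strrep("ACGT", 4L)  # 16 nt -> use proper 18-mer below
  bc18 <- paste0(bc, "GG")
  read_ok <- make_reads(bc18, ref8_cds)
  ext <- extract_barcode_and_cds(read_ok, toy_flanks)
  expect_equal(ext$status, "ok")
  expect_equal(ext$barcode, bc18)
  expect_equal(ext$cds, ref8_cds)

  missing_left <- paste0(bc18, toy_flanks$bc_right, ref8_cds)
  short_bc <- make_reads(substr(bc18, 1, 17), ref8_cds)
  ambiguous <- paste0(toy_flanks$bc_left, read_ok)
  ext2 <- extract_barcode_and_cds(c(missing_left, short_bc, ambiguous),
                                  toy_flanks)
  expect_equal(ext2$status, rep("rejected", 3))
  expect_equal(ext2$reason,
               c("no_left_flank", "bad_barcode_length", "ambiguous_flank"))
})

test_that("variant calling classifies single-codon changes and filters", {
  prot313 <- default_protein(313)
  cds313 <- reverse_translate(prot313)
  # C152 TGC -> TGG is the canonical toxic missense variant
  called <- call_variant(mutate_cds("C152W", cds313), cds313)
  expect_equal(called$variant, "C152W")
  expect_equal(called$var_class, "missense")
  expect_equal(called$n_subs, 1L)

  # indel (1-nt deletion), >= 10 scattered substitutions, 9 substitutions
  del <- sub("TGC", "TG", cds313, fixed = TRUE)
  scatter <- function(cds, n) {
    s <- strsplit(cds, "")[[1]]
    idx <- seq(2, by = 30, length.out = n)
    s[idx] <- ifelse(s[idx] == "A", "C", "A")
    paste(s, collapse = "")
  }
  res <- call_variant(c(del, scatter(cds313, 10), "AC GT"), cds313)
  expect_equal(res$status, rep("rejected", 3))
  expect_equal(res$reason, c("indel", "too_many_subs", "non_acgt"))
  # 9 substitutions pass the filter (but are multi-variant here)
  res9 <- call_variant(scatter(cds313, 9), cds313)
  expect_equal(res9$reason, "multi_variant")
})

test_that("variant calling distinguishes wt, synonymous and nonsense", {
  syn_pos <- which(strsplit(ref8, "")[[1]] %in% names(vampseqr:::CODON_ALT))[1]
  cls <- c("WT", paste0(substr(ref8, syn_pos, syn_pos), syn_pos, "="),
           paste0(substr(ref8, 4, 4), 4, "*"))
  res <- call_variant(vapply(cls, mutate_cds, "", ref_cds = ref8_cds),
                      ref8_cds)
  expect_equal(res$status, rep("ok", 3))
  expect_equal(res$variant, cls)
  expect_equal(res$var_class, c("wt", "synonymous", "nonsense"))
})

test_that("majority rule maps concordant and dominant barcodes, drops ties", {
  calls <- tibble::tibble(
    barcode = c(rep("b1", 10), rep("b2", 2), rep("b3", 5)),
    variant = c(rep("A5G", 9), "A5T", "A5G", "A5T", rep("C3W", 5)),
    var_class = "missense")
  map <- build_barcode_map(calls)
  expect_equal(nrow(map), 2L)
  b1 <- map[map$barcode == "b1", ]
  expect_equal(b1$variant, "A5G")
  expect_equal(b1$dominant_fraction, 0.9)
  expect_equal(b1$n_reads, 9L)
  expect_false("b2" %in% map$barcode)  # 1:1 tie has no strict majority
  expect_equal(map$dominant_fraction[map$barcode == "b3"], 1.0)
  expect_equal(nrow(build_barcode_map(calls[0, ])), 0L)
})

test_that("simulated library round-trips through subassembly at zero error", {
  lib <- simulate_library(small_config(seed = 5L, L = 8L))
  cds <- vapply(lib$map$variant, mutate_cds, "", ref_cds = ref8_cds)
  reads <- make_reads(lib$map$barcode, cds)
  sa <- subassemble(reads, ref8_cds, toy_flanks)
  expect_equal(nrow(sa$map), nrow(lib$map))
  expected <- dplyr::arrange(lib$map, barcode)
  expect_equal(sa$map$barcode, expected$barcode)
  expect_equal(sa$map$variant, expected$variant)
  expect_equal(sa$map$var_class, expected$var_class)
  expect_true(all(sa$map$dominant_fraction == 1))
})

test_that("loosening the substitution threshold never removes barcodes", {
  lib <- simulate_library(small_config(seed = 6L, L = 8L))
  cds <- vapply(lib$map$variant, mutate_cds, "", ref_cds = ref8_cds)
  reads <- make_reads(lib$map$barcode, cds)
  strict <- subassemble(reads, ref8_cds, toy_flanks, max_subs = 2L)
  loose <- subassemble(reads, ref8_cds, toy_flanks, max_subs = 10L)
  expect_true(all(strict$map$barcode %in% loose$map$barcode))
  expect_gte(nrow(loose$map), nrow(strict$map))
})
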