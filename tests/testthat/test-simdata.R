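test_that("configuration invariants are enforced", {
  expect_error(sim_config(bin_occupancy = c(0.5, 0.5, 0.2)),
               "length")
  expect_error(sim_config(n_bins = 4, bin_occupancy = c(0.5, 0.3, 0.1, 0.2)))
  expect_error(sim_config(days = c(0, 5, 5, 9)))
  expect_error(sim_config(days = c(5, 7, 9)))
  expect_error(sim_config(reads_per_bin = 0))
  expect_error(sim_config(toxicity_link = list(threshold = 0.3,
                                               max_deficit = -1,
                                               p_toxic = 0.5)))
})

test_that("the same seed gives byte-identical libraries", {
  cfg <- small_config(seed = 101L)
  a <- simulate_library(cfg)
  b <- simulate_library(cfg)
  expect_identical(a, b)
  c2 <- simulate_library(small_config(seed = 102L))
  expect_false(identical(a$map$barcode, c2$map$barcode))
})

test_that("library structure: coverage, barcode arithmetic, anchors", {
  cfg <- small_config(seed = 7L, L = 20L)
  lib <- simulate_library(cfg)
  uni <- enumerate_variant_universe(cfg$protein_seq)
  # every variant of the universe receives at least one barcode
  expect_true(all(uni$variant %in% lib$map$variant))
  expect_false(any(duplicated(lib$map$barcode)))
  expect_true(all(nchar(lib$map$barcode) == cfg$barcode_length))
  # L = 2: every barcode maps into the 40-variant universe
  lib2 <- simulate_library(small_config(seed = 8L, L = 2L, n_synonymous = 0))
  uni2 <- enumerate_variant_universe(default_protein(2L))
  expect_true(all(lib2$map$variant %in% uni2$variant))
  # stops forced low, WT high, deficits only below the latent threshold
  tr <- lib$truth
  expect_true(all(tr$latent_abundance[tr$var_class == "nonsense"] < 0.5))
  expect_equal(tr$latent_abundance[tr$var_class == "wt"],
               cfg$mode_params$stable_mean)
  expect_true(all(tr$deficit >= 0))
  expect_true(all(tr$deficit[tr$latent_abundance >=
                               cfg$toxicity_link$threshold] == 0))
  expect_true(all(tr$deficit[tr$var_class == "nonsense"] == 0))
})

test_that("mean barcode count matches the configured sampling law", {
  # 1 + Poisson(mean - 1) per variant: Monte-Carlo mean over 20 seeds
  means <- vapply(1:20, function(s) {
    lib <- simulate_library(small_config(seed = s, L = 10L,
                                         n_synonymous = 0))
    nrow(lib$map) / sum(lib$truth$var_class != "synonymous")
  }, double(1))
  expect_equal(mean(means), 4, tolerance = 0.03)  # small_config mean is 4
})

test_that("barcode space exhaustion is a configuration error", {
  cfg <- small_config(seed = 1L, L = 10L)
  cfg$barcode_length <- 2L  # 16 barcodes cannot cover a 200-variant library
  expect_error(simulate_library(cfg), "barcode space exhausted")
})

test_that("FACS simulation: exact bin totals and symmetric equal-latent reads", {
  cfg <- small_config(seed = 51L, L = 10L)
  lib <- simulate_library(cfg)
  facs <- simulate_facs_counts(lib$truth, lib$map, cfg)
  totals <- facs |>
    dplyr::group_by(replicate, bin) |>
    dplyr::summarise(n = sum(count), .groups = "drop")
  expect_true(all(totals$n == cfg$reads_per_bin))
  # identical latent abundance: expected read share equal across bins
  truth_flat <- tibble::tibble(
    variant = c("WT", paste0("A", 2:20, "G")),
    var_class = c("wt", rep("missense", 19)),
    position = 1:20, latent_abundance = 0.5, deficit = 0, n_barcodes = 1L)
  flat <- simulate_facs_counts(truth_flat, map = NULL, config = cfg)
  share <- flat |>
    dplyr::filter(variant == "A2G") |>
    dplyr::group_by(bin) |>
    dplyr::summarise(n = sum(count), .groups = "drop")
  expect_lt(diff(range(share$n)) / mean(share$n), 0.15)
})

test_that("high and low latent modes land in opposite bins", {
  cfg <- small_config(seed = 61L, L = 30L)
  lib <- simulate_library(cfg)
  facs <- simulate_facs_counts(lib$truth, lib$map, cfg)
  freq <- merge_and_normalize(facs, unit = "bin")
  psis <- psi_table(apply_read_threshold(freq, 20))
  j <- dplyr::inner_join(psis, lib$truth, by = "variant")
  hi <- j$psi[j$latent_abundance > 0.7]
  lo <- j$psi[j$latent_abundance < 0.3]
  expect_gt(mean(hi > 2.5), 0.99)
  expect_gt(mean(lo < 2.5), 0.99)
})

test_that("abundance scores are bimodal with anchored modes", {
  cfg <- small_config(seed = 71L, L = 60L)
  lib <- simulate_library(cfg)
  facs <- simulate_facs_counts(lib$truth, lib$map, cfg)
  ab <- abundance_scores(facs, collapse_synonymous = FALSE)
  sc <- ab$scores
  # two modes separated by a density trough
  d <- stats::density(sc$score, bw = 0.05)
  mid <- d$y[which.min(abs(d$x - 0.5))]
  peak_lo <- max(d$y[d$x > -0.2 & d$x < 0.2])
  peak_hi <- max(d$y[d$x > 0.8 & d$x < 1.2])
  expect_lt(mid, 0.5 * peak_lo)
  expect_lt(mid, 0.5 * peak_hi)
  # stop variants anchor 0, WT/synonymous mode anchors 1
  expect_lt(abs(mean(sc$score[sc$var_class == "nonsense"])), 0.1)
  syn_wt <- sc$score[sc$var_class %in% c("wt", "synonymous")]
  expect_gt(mean(syn_wt), 0.9)
  expect_lt(mean(syn_wt), 1.1)
})

test_that("predictor tracks hit the configured rank correlations", {
  cfg <- sim_config(seed = 81L, protein_seq = default_protein(313),
                    n_barcodes_per_variant = 1, toxic_anchor = NA_character_)
  lib <- simulate_library(cfg)
  pred <- simulate_predictor_tracks(lib$truth, cfg)
  expect_equal(nrow(pred), 5947L)
  expect_true(all(pred$ddg >= 0 & pred$ddg <= 5))
  expect_true(all(pred$conservation <= 0 & pred$conservation >= -4))
  j <- dplyr::inner_join(pred, lib$truth, by = "variant")
  rho <- cor(j$ddg, j$latent_abundance, method = "spearman")
  expect_gt(rho, -0.52); expect_lt(rho, -0.42)
  rho_c <- cor(j$conservation, j$latent_abundance, method = "spearman")
  expect_gt(rho_c, 0.40); expect_lt(rho_c, 0.50)
  # achieved correlation is stable over seeds
  rhos <- vapply(1:20, function(s) {
    cfg_s <- sim_config(seed = s, protein_seq = default_protein(313),
                        n_barcodes_per_variant = 1,
                        toxic_anchor = NA_character_)
    lib_s <- simulate_library(cfg_s)
    p <- simulate_predictor_tracks(lib_s$truth, cfg_s)
    jj <- dplyr::inner_join(p, lib_s$truth, by = "variant")
    cor(jj$ddg, jj$latent_abundance, method = "spearman")
  }, double(1))
  expect_lt(abs(mean(rhos) - (-0.47)), 0.02)
  # zero-noise copula is a perfect monotone map
  cfg0 <- small_config(seed = 9L)
  cfg0$predictor_link$rho_ddg <- -1
  lib0 <- simulate_library(cfg0)
  p0 <- simulate_predictor_tracks(lib0$truth, cfg0)
  j0 <- dplyr::inner_join(p0, lib0$truth, by = "variant")
  expect_equal(cor(j0$ddg, j0$latent_abundance, method = "spearman"), -1)
})

test_that("flat time courses stay flat; depletion is monotone in expectation", {
  cfg <- small_config(seed = 91L, L = 10L)
  truth <- tibble::tibble(
    variant = c("WT", paste0("A", 2:50, "G")),
    var_class = c("wt", rep("missense", 49)),
    position = 1:50, latent_abundance = 0.5, deficit = 0, n_barcodes = 1L)
  tc <- simulate_timecourse(truth, map = NULL, config = cfg)
  freq <- merge_and_normalize(tc, unit = "day")
  slopes <- slope_table(freq)
  expect_lt(max(abs(slopes$alpha)), 0.01)  # flat up to sampling noise
  truth$deficit[2] <- 0.5
  tc2 <- simulate_timecourse(truth, map = NULL, config = cfg)
  f2 <- merge_and_normalize(tc2, unit = "day")
  v <- f2[f2$variant == "A2G", ]
  by_day <- tapply(v$freq, v$day, mean)
  expect_lt(by_day[["9"]], by_day[["0"]])
  expect_error(simulate_timecourse(dplyr::mutate(truth, deficit = -0.1),
                                   map = NULL, config = cfg),
               "negative")
})
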