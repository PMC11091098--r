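make_scores <- function(variants, scores) {
  tibble::tibble(variant = variants, score = scores)
}

test_that("positional medians summarize missense substitutions", {
  sc <- make_scores(c("A1C", "A1D", "A2C", "A2D", "A2*", "WT"),
                    c(0.1, 0.9, 0.4, 0.4, 0.0, 1.0))
  med <- per_position_median(sc)
  expect_equal(med$median_score[med$position == 1], 0.5)
  expect_equal(med$median_score[med$position == 2], 0.4)
  # nonsense excluded by default, included on request
  med_all <- per_position_median(sc, classes = c("missense", "nonsense"))
  expect_equal(med_all$median_score[med_all$position == 2], 0.4)
  expect_equal(med_all$n_variants[med_all$position == 2], 3L)
  # position with nothing scored is absent
  expect_false(3 %in% med$position)
})

test_that("variance explained reports both estimators", {
  # scores exactly equal to their positional medians
  sc <- make_scores(c("A1C", "A1D", "A2C", "A2D"), c(0.3, 0.3, 0.8, 0.8))
  ve <- variance_explained(sc)
  expect_equal(ve$r_squared, 1)
  expect_equal(ve$frac_sse, 1)
  # shuffled scores carry ~ no positional signal
  set.seed(8)
  pos <- rep(1:100, each = 19)
  alts <- setdiff(AA_STANDARD, "A")
  sc2 <- make_scores(paste0("A", pos, alts), sample(runif(1900)))
  ve2 <- variance_explained(sc2)
  # each score enters its own 19-variant positional median, leaving a
  # ~ sqrt(1/19) residual correlation even under the null
  expect_lt(abs(ve2$r), 0.3)
  expect_error(variance_explained(make_scores(c("A1C", "A1D"), c(1, 2))),
               ">= 2 positions")
})

test_that("correlate computes rank/linear coefficients with bootstrap CIs", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 3)$estimate, 1)
  expect_equal(correlate(x, -x, n_boot = 10)$estimate, -1)
  r <- correlate(c(1, 2, 3), c(2, 1, 3), n_boot = 10)
  expect_equal(r$estimate, 0.5)
  set.seed(99)
  a <- rnorm(200); b <- a + rnorm(200)
  c1 <- correlate(a, b, seed = 4L)
  c2 <- correlate(a, b, seed = 4L)
  expect_identical(c1$ci, c2$ci)
  expect_true(c1$ci[1] <= c1$estimate && c1$estimate <= c1$ci[2])
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("clinical summaries count strictly-below-threshold variants", {
  sc <- make_scores(paste0("A", 1:6, "C"),
                    c(0.1, 0.2, 0.3, 0.5, 0.4, 0.9))
  ann <- tibble::tibble(
    variant = paste0("A", 1:6, "C"),
    label = c("pathogenic", "pathogenic", "pathogenic", "pathogenic",
              "benign", "vus"))
  cs <- clinical_summary(sc, ann, threshold = 0.5)
  path <- cs[cs$label == "pathogenic", ]
  expect_equal(path$n, 4L)
  expect_equal(path$n_below, 3L)  # the exact-0.5 score is not below
  expect_equal(cs$n_below[cs$label == "benign"], 1L)
  all_below <- clinical_summary(sc, ann, threshold = 2)
  expect_equal(all_below$n_below, all_below$n)
})

test_that("replicate statistics average pairwise correlation and MAE", {
  m <- cbind(r1 = c(0.1, 0.5, 0.9, 0.2), r2 = c(0.1, 0.5, 0.9, 0.2))
  rs <- replicate_stats(m)
  expect_equal(rs$mean_r, 1)
  expect_equal(rs$mean_mae, 0)
  shifted <- cbind(m[, 1], m[, 1] + 0.1)
  rs2 <- replicate_stats(shifted)
  expect_equal(rs2$mean_r, 1)
  expect_equal(rs2$mean_mae, 0.1)
  # one discordant variant: MAE = |delta| / n
  disc <- cbind(c(0.1, 0.5, 0.9, 0.2), c(0.1, 0.5, 0.9, 0.6))
  expect_equal(replicate_stats(disc)$mean_mae, 0.4 / 4)
  expect_error(replicate_stats(m[, 1, drop = FALSE]), "two replicates")
})

test_that("stratified replicate correlation flags zero-variance strata", {
  set.seed(12)
  sig <- runif(50)
  m <- cbind(sig + rnorm(50, 0, 0.01), sig + rnorm(50, 0, 0.01))
  flat <- matrix(0.5, nrow = 20, ncol = 2)
  mat <- rbind(m, flat)
  strata <- rep(c("variable", "flat"), c(50, 20))
  out <- stratified_replicate_correlation(mat, strata)
  expect_gt(out$mean_rho[out$stratum == "variable"], 0.9)
  expect_equal(out$n_pairs_defined[out$stratum == "flat"], 0L)
  expect_true(is.nan(out$mean_rho[out$stratum == "flat"]))
})

test_that("toxicity-depleted representation degrades low-abundance replicate agreement", {
  cfg <- small_config(seed = 41L, L = 30L, replicates_abundance = 4)
  lib <- simulate_library(cfg)
  # toxic cells are strongly under-represented in the sorted pool
  w <- ifelse(lib$truth$deficit > 0, 0.02, 1) * lib$truth$n_barcodes
  facs <- simulate_facs_counts(lib$truth, lib$map, cfg, cell_weights = w)
  ab <- abundance_scores(facs, min_reads = 5)
  mat <- vampseqr:::as_replicate_matrix(ab$replicate_scores)
  truth_idx <- match(rownames(mat), lib$truth$variant)
  low <- lib$truth$latent_abundance[truth_idx] < cfg$toxicity_link$threshold
  strata <- ifelse(!low, NA_character_,
                   ifelse(lib$truth$deficit[truth_idx] > 0,
                          "toxic", "non_toxic"))
  out <- stratified_replicate_correlation(mat, strata)
  expect_lt(out$mean_rho[out$stratum == "toxic"],
            out$mean_rho[out$stratum == "non_toxic"])
})
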