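#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults reproduce the study conditions the scoring pipeline assumes: a
#' 313-residue protein (6260-variant universe), on average 21 barcodes per
#' variant (18-nt random barcodes), four equal-occupancy FACS bins, 11
#' abundance replicates, and a 4-replicate time course sampled on days
#' 0/5/7/9 in which growth-rate deficits are confined to low-abundance
#' missense variants. The latent abundance (normalized reporter ratio) is a
#' two-component Beta mixture: a wild-type-like mode and a stop-like mode.
#'
#' @param seed integer master seed; all sub-generators derive their seeds
#'   from it, so equal configs give byte-identical outputs.
#' @param protein_seq reference protein (default: [default_protein()] of 313
#'   residues with a cysteine at position 152, so `"C152W"` can serve as the
#'   toxic anchor).
#' @param n_barcodes_per_variant mean barcodes per variant (default 21);
#'   drawn as `1 + Poisson(mean - 1)` so every variant has at least one.
#' @param barcode_length barcode length in nt (default 18).
#' @param n_bins number of FACS bins (default 4).
#' @param bin_occupancy per-bin population fractions, summing to 1.
#' @param reads_per_bin sequencing reads per sorted bin (default 1e6).
#' @param reads_per_day sequencing reads per time-course day (default 1e6).
#' @param n_cells sorted cells per replicate (default 1e6).
#' @param replicates_abundance abundance replicates (default 11).
#' @param replicates_toxicity toxicity replicates (default 4).
#' @param days sampling days, strictly increasing, day 0 first.
#' @param mode_weights fractions of missense variants in the stable vs
#'   unstable latent mode.
#' @param mode_params Beta-mixture location/concentration:
#'   `stable_mean`, `unstable_mean`, `concentration`.
#' @param noise_sd cell-to-cell spread of the fluorescence ratio around the
#'   latent abundance (same units as the latent scale).
#' @param toxicity_link list: `threshold` (latent abundance above which the
#'   deficit is exactly 0), `max_deficit` (per day), `p_toxic` (probability
#'   that a low-abundance missense variant is toxic at all; nonsense
#'   variants, making no full-length protein, are never toxic).
#' @param predictor_link list: target Spearman correlations of the synthetic
#'   predictor tracks with latent abundance (`rho_ddg`, `rho_conservation`)
#'   and output scales (`ddg_max`, `conservation_min`).
#' @param n_synonymous number of synonymous wild-type entries carried in the
#'   library (default 100).
#' @param toxic_anchor variant string used as the toxicity score anchor.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       protein_seq = default_protein(),
                       n_barcodes_per_variant = 21,
                       barcode_length = 18L,
                       n_bins = 4L,
                       bin_occupancy = rep(1 / n_bins, n_bins),
                       reads_per_bin = 1e6,
                       reads_per_day = 1e6,
                       n_cells = 1e6,
                       replicates_abundance = 11L,
                       replicates_toxicity = 4L,
                       days = c(0, 5, 7, 9),
                       mode_weights = c(stable = 0.5, unstable = 0.5),
                       mode_params = list(stable_mean = 0.85,
                                          unstable_mean = 0.15,
                                          concentration = 25),
                       noise_sd = 0.1,
                       toxicity_link = list(threshold = 0.3,
                                            max_deficit = 0.5,
                                            p_toxic = 0.6),
                       predictor_link = list(rho_ddg = -0.47,
                                             rho_conservation = 0.45,
                                             ddg_max = 5,
                                             conservation_min = -4),
                       n_synonymous = 100L,
                       toxic_anchor = "C152W") {
  cfg <- list(seed = as.integer(seed), protein_seq = protein_seq,
              n_barcodes_per_variant = n_barcodes_per_variant,
              barcode_length = as.integer(barcode_length),
              n_bins = as.integer(n_bins), bin_occupancy = bin_occupancy,
              reads_per_bin = reads_per_bin, reads_per_day = reads_per_day,
              n_cells = n_cells,
              replicates_abundance = as.integer(replicates_abundance),
              replicates_toxicity = as.integer(replicates_toxicity),
              days = days, mode_weights = mode_weights,
              mode_params = mode_params, noise_sd = noise_sd,
              toxicity_link = toxicity_link, predictor_link = predictor_link,
              n_synonymous = as.integer(n_synonymous),
              toxic_anchor = toxic_anchor)
  stopifnot(length(cfg$bin_occupancy) == cfg$n_bins,
            all(cfg$bin_occupancy > 0),
            isTRUE(all.equal(sum(cfg$bin_occupancy), 1)),
            cfg$n_barcodes_per_variant >= 1,
            cfg$barcode_length >= 1,
            cfg$reads_per_bin > 0, cfg$reads_per_day > 0, cfg$n_cells > 0,
            cfg$replicates_abundance >= 1, cfg$replicates_toxicity >= 1,
            length(cfg$days) >= 2, all(diff(cfg$days) > 0), cfg$days[1] == 0,
            cfg$toxicity_link$max_deficit >= 0,
            cfg$noise_sd > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Deterministic synthetic reference protein
#'
#' A fixed pseudo-random 313-residue sequence (methionine first, cysteine at
#' position 152 when long enough) used as the default simulation reference.
#' It is a synthetic stand-in, not a natural protein sequence.
#'
#' @param length protein length in residues (default 313).
#' @return Character scalar.
#' @export
default_protein <- function(length = 313L) {
  stopifnot(length >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(20530L)
  aa <- sample(AA_STANDARD, length, replace = TRUE)
  aa[1] <- "M"
  if (length >= 152) aa[152] <- "C"
  paste(aa, collapse = "")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Derived stage seeds: the master seed drives every sub-generator through a
# fixed splitting scheme (stage offset in hundreds, replicate index added).
# Kept < 2^31 so set.seed() always receives a valid integer.
stage_seed <- function(seed, stage, rep = 0L) {
  offsets <- c(library = 0L, facs = 100L, timecourse = 200L,
               predictors = 300L, tiles = 400L, pipeline = 500L)
  (seed %% 2000000L) * 1000 + offsets[[stage]] + rep
}

random_barcodes <- function(n, length, max_tries = 20L) {
  if (n > 4^length) stop("barcode space exhausted: requested ", n,
                         " barcodes of length ", length)
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * length, replace = TRUE),
                nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  bc <- unique(draw(n))
  tries <- 0L
  while (length(bc) < n) {
    tries <- tries + 1L
    if (tries > max_tries) stop("failed to draw unique barcodes")
    bc <- unique(c(bc, draw(n - length(bc))))
  }
  bc[seq_len(n)]
}

#' Simulate the barcoded variant library and its latent truth
#'
#' Enumerates the full variant universe of the configured protein, adds
#' synonymous wild-type entries at positions with an alternative codon,
#' assigns each entry `1 + Poisson(mean - 1)` unique random barcodes, and
#' draws the latent per-variant truth: abundance from the two-mode Beta
#' mixture (wild type and synonymous entries in the stable mode, nonsense
#' variants forced into the unstable mode), plus a growth-rate deficit that
#' is nonzero only for low-abundance missense variants. The configured toxic
#' anchor is forced to be a low-abundance, maximally toxic variant.
#'
#' @param config a [sim_config()].
#' @return List with `map` (tibble `barcode`, `variant`, `var_class`) and
#'   `truth` (tibble `variant`, `var_class`, `position`, `latent_abundance`,
#'   `deficit`, `n_barcodes`).
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "library"))
  uni <- enumerate_variant_universe(config$protein_seq)

  # synonymous WT entries at positions whose residue has an alternative codon
  aa <- split_chars(config$protein_seq)
  syn_ok <- which(aa %in% names(CODON_ALT))
  n_syn <- min(config$n_synonymous, length(syn_ok))
  syn_pos <- sort(sample(syn_ok, n_syn))
  syn <- tibble::tibble(variant = paste0(aa[syn_pos], syn_pos, "="),
                        position = syn_pos, wt_aa = aa[syn_pos],
                        alt_aa = aa[syn_pos], var_class = "synonymous")
  uni <- dplyr::bind_rows(uni, syn)

  nv <- nrow(uni)
  mp <- config$mode_params
  shape <- function(mean) c(mean * mp$concentration,
                            (1 - mean) * mp$concentration)
  s_hi <- shape(mp$stable_mean); s_lo <- shape(mp$unstable_mean)
  stable <- rbinom(nv, 1L, config$mode_weights[["stable"]]) == 1L
  stable[uni$var_class %in% c("wt", "synonymous")] <- TRUE
  stable[uni$var_class == "nonsense"] <- FALSE
  latent <- ifelse(stable, rbeta(nv, s_hi[1], s_hi[2]),
                   rbeta(nv, s_lo[1], s_lo[2]))
  latent[uni$var_class == "wt"] <- mp$stable_mean

  tl <- config$toxicity_link
  toxic <- uni$var_class == "missense" & latent < tl$threshold &
    rbinom(nv, 1L, tl$p_toxic) == 1L
  deficit <- ifelse(toxic,
                    tl$max_deficit * (tl$threshold - latent) / tl$threshold,
                    0)
  anchor <- match(config$toxic_anchor, uni$variant)
  if (!is.na(anchor)) {
    latent[anchor] <- 0.02
    deficit[anchor] <- tl$max_deficit
  }

  n_bc <- 1L + rpois(nv, config$n_barcodes_per_variant - 1)
  barcodes <- random_barcodes(sum(n_bc), config$barcode_length)
  map <- tibble::tibble(
    barcode = barcodes,
    variant = rep(uni$variant, n_bc),
    var_class = rep(uni$var_class, n_bc))
  truth <- tibble::tibble(variant = uni$variant, var_class = uni$var_class,
                          position = uni$position,
                          latent_abundance = latent, deficit = deficit,
                          n_barcodes = n_bc)
  list(map = map, truth = truth)
}

# Shared sorting simulator: cells carry a latent value plus Gaussian ratio
# noise, are cut at the empirical occupancy quantiles into bins, and per-bin
# reads are drawn multinomially from the bin's cell composition.
sort_and_sequence <- function(latent, cell_weights, n_cells, noise_sd,
                              bin_occupancy, reads_per_bin) {
  nv <- length(latent)
  n_bins <- length(bin_occupancy)
  cells_per_variant <- as.integer(rmultinom(1, n_cells,
                                            cell_weights / sum(cell_weights)))
  vidx <- rep.int(seq_len(nv), cells_per_variant)
  fluor <- latent[vidx] + rnorm(length(vidx), 0, noise_sd)
  cuts <- quantile(fluor, cumsum(bin_occupancy)[-n_bins])
  bin <- findInterval(fluor, cuts) + 1L
  counts <- matrix(0L, nrow = nv, ncol = n_bins)
  for (g in seq_len(n_bins)) {
    in_bin <- tabulate(vidx[bin == g], nbins = nv)
    if (sum(in_bin) == 0) next
    counts[, g] <- as.integer(rmultinom(1, reads_per_bin, in_bin))
  }
  counts
}

#' Simulate FACS-bin read counts
#'
#' For each abundance replicate: cells (one barcode each, sampled with
#' probability proportional to the variant's barcode representation, or to
#' `cell_weights` when given) acquire a noisy fluorescence ratio around their
#' variant's latent abundance, are sorted at the empirical occupancy
#' quantiles into bins, and each bin is sequenced to exactly
#' `reads_per_bin` multinomial reads.
#'
#' @param truth,map from [simulate_library()]; `map = NULL` gives every
#'   variant equal representation.
#' @param config a [sim_config()].
#' @param cell_weights optional per-variant cell sampling weights overriding
#'   the barcode representation (e.g. to emulate toxicity-depleted cell
#'   numbers in the sorted pool).
#' @return Tidy tibble `replicate`, `bin`, `variant`, `var_class`, `count`.
#' @export
simulate_facs_counts <- function(truth, map = NULL, config,
                                 cell_weights = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(map) && !all(map$variant %in% truth$variant)) {
    stop("truth does not cover all variants in map")
  }
  w <- if (!is.null(cell_weights)) cell_weights
       else if (!is.null(map)) truth$n_barcodes
       else rep(1, nrow(truth))
  stopifnot(length(w) == nrow(truth), all(w >= 0), sum(w) > 0)
  out <- vector("list", config$replicates_abundance)
  for (r in seq_len(config$replicates_abundance)) {
    set.seed(stage_seed(config$seed, "facs", r))
    counts <- sort_and_sequence(truth$latent_abundance, w, config$n_cells,
                                config$noise_sd, config$bin_occupancy,
                                config$reads_per_bin)
    out[[r]] <- tibble::tibble(
      replicate = r,
      bin = rep(seq_len(config$n_bins), each = nrow(truth)),
      variant = rep(truth$variant, config$n_bins),
      var_class = rep(truth$var_class, config$n_bins),
      count = as.integer(counts))
  }
  dplyr::bind_rows(out)
}

#' Simulate time-course read counts under exponential depletion
#'
#' Variant cell fractions evolve as exponential growth with per-variant rate
#' `base - deficit`; the base rate cancels in the relative frequencies, which
#' at day t are proportional to `w0 * exp(-deficit * t)`. The same number of
#' cells is sequenced each day, so non-depleting variants drift slightly
#' upward as toxic variants vanish. Reads are multinomial per day with total
#' `reads_per_day`. A mild lognormal replicate-level jitter on the initial
#' representation emulates the transfection bottleneck (it cancels exactly in
#' the per-variant trajectory normalization).
#'
#' @inheritParams simulate_facs_counts
#' @return Tidy tibble `replicate`, `day`, `variant`, `var_class`, `count`.
#' @export
simulate_timecourse <- function(truth, map = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(truth$deficit < 0)) stop("negative growth-rate deficits")
  w0_base <- if (!is.null(map)) truth$n_barcodes else rep(1, nrow(truth))
  out <- vector("list", config$replicates_toxicity)
  for (r in seq_len(config$replicates_toxicity)) {
    set.seed(stage_seed(config$seed, "timecourse", r))
    w0 <- w0_base * exp(rnorm(nrow(truth), 0, 0.2))
    counts <- vapply(config$days, function(t) {
      q <- w0 * exp(-truth$deficit * t)
      as.integer(rmultinom(1, config$reads_per_day, q / sum(q)))
    }, integer(nrow(truth)))
    out[[r]] <- tibble::tibble(
      replicate = r,
      day = rep(config$days, each = nrow(truth)),
      variant = rep(truth$variant, length(config$days)),
      var_class = rep(truth$var_class, length(config$days)),
      count = as.integer(counts))
  }
  dplyr::bind_rows(out)
}

#' Simulate predictor tracks correlated with latent abundance
#'
#' Generates per-missense-variant synthetic stability predictions (a
#' destabilization energy on a 0-5 kcal/mol scale, decreasing with latent
#' abundance) and conservation scores (0 = tolerated, strongly negative =
#' disfavored, increasing with latent abundance) through a Gaussian copula on
#' the latent-abundance ranks, calibrated so the realized Spearman
#' correlation matches the configured target in expectation.
#'
#' @inheritParams simulate_facs_counts
#' @return Tibble `variant`, `ddg`, `conservation` (missense variants only).
#' @export
simulate_predictor_tracks <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "predictors"))
  pl <- config$predictor_link
  mis <- truth[truth$var_class == "missense", ]
  n <- nrow(mis)
  z1 <- qnorm((rank(mis$latent_abundance, ties.method = "average") - 0.5) / n)
  copula_draw <- function(rho_target) {
    # Pearson correlation of the latent Gaussians that yields the requested
    # Spearman: rho_s = (6 / pi) * asin(r / 2)
    r <- 2 * sin(pi * rho_target / 6)
    r * z1 + sqrt(1 - r^2) * rnorm(n)
  }
  ddg <- pl$ddg_max * pnorm(copula_draw(pl$rho_ddg))
  cons <- pl$conservation_min * pnorm(-copula_draw(pl$rho_conservation))
  tibble::tibble(variant = mis$variant, ddg = ddg, conservation = cons)
}

#' Simulate tile-sorting counts for the three tile libraries
#'
#' Assigns each designed tile a latent stability decreasing in its mean
#' side-chain hydrophobicity (hydrophobic tiles behave like degrons), fixes
#' the control tiles at their characteristic levels (RLLL low, RAAA
#' intermediate, DAAA high), then simulates sorting and sequencing of each
#' library pool (its own tiles plus all three controls) with the same
#' cell-noise-bin-multinomial model as the FACS screen.
#'
#' @param tiles output of [design_tiles()].
#' @param config a [sim_config()].
#' @param n_replicates sorting replicates per library (default 6, emulating
#'   3 biological x 2 FACS replicates).
#' @param reads_per_bin reads per bin per library (default 2e5).
#' @param cells_per_library sorted cells per library pool (default 2e5).
#' @return List with `counts` (tibble `library`, `replicate`, `bin`, `tile`,
#'   `count`, `freq`) and `truth` (tibble `tile`, `library`,
#'   `latent_stability`).
#' @export
simulate_tile_counts <- function(tiles, config, n_replicates = 6L,
                                 reads_per_bin = 2e5, cells_per_library = 2e5) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "tiles"))
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
          H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
          P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
          W = -0.9, Y = -1.3)
  hyd <- vapply(tiles$aa_seq, function(s) mean(kd[split_chars(s)]),
                double(1), USE.NAMES = FALSE)
  # map hydrophobicity to (0, 1): hydrophobic tiles -> low latent stability
  lat <- 1 - stats::plogis((hyd - mean(kd)) / stats::sd(kd) * 2)
  lat <- pmin(pmax(lat + rnorm(length(lat), 0, 0.05), 0.02), 0.98)
  tile_id <- paste0("tile", tiles$index)
  ctrl_lat <- c(RLLL = 0.1, RAAA = 0.55, DAAA = 0.9)

  out <- list()
  for (lib in c("odds", "evens", "ct")) {
    in_lib <- tiles$library == lib
    ids <- c(tile_id[in_lib], names(ctrl_lat))
    latv <- c(lat[in_lib], ctrl_lat)
    for (r in seq_len(n_replicates)) {
      set.seed(stage_seed(config$seed, "tiles",
                          r + 10L * match(lib, c("odds", "evens", "ct"))))
      counts <- sort_and_sequence(latv, rep(1, length(latv)),
                                  cells_per_library, config$noise_sd,
                                  config$bin_occupancy, reads_per_bin)
      out[[paste(lib, r)]] <- tibble::tibble(
        library = lib, replicate = r,
        bin = rep(seq_len(config$n_bins), each = length(ids)),
        tile = rep(ids, config$n_bins),
        count = as.integer(counts))
    }
  }
  counts <- dplyr::bind_rows(out) |>
    dplyr::group_by(.data$library, .data$replicate, .data$bin) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  truth <- tibble::tibble(
    tile = c(tile_id, names(ctrl_lat)),
    library = c(tiles$library, rep("control", length(ctrl_lat))),
    latent_stability = c(lat, unname(ctrl_lat)))
  list(counts = counts, truth = truth)
}

#' Synthetic compact globule coordinates
#'
#' Uniform random points in a ball of the given radius, a minimal stand-in
#' for a folded domain when exercising structure-based metrics: interior
#' points have high weighted contact numbers, surface points low.
#'
#' @param n number of residues.
#' @param radius ball radius in Angstrom (default 20).
#' @param seed integer seed.
#' @return `n` x 3 coordinate matrix.
#' @export
make_synthetic_globule <- function(n, radius = 20, seed = 1L) {
  set.seed(seed)
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * radius * runif(n)^(1 / 3)
  pts
}
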