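# Synthetic-data generators. These emulate the statistical structure of the
# pipeline's inputs: per-nucleus two-colour spot geometries with a per-allele
# colocalization probability p_cis and per-nucleus inter-allele proximity
# probability p_trans; 3C / control-template band intensities with
# multiplicative noise around a truth profile; and mono-/biallelic SNP signal
# mixtures. A single root seed feeds per-unit substreams derived by counter,
# so any subset of nuclei or fragments is reproducible independently of
# iteration order.

#' Simulation scenario
#'
#' @param label Scenario name.
#' @param n_nuclei Nuclei per simulated line.
#' @param p_cis Per-allele probability that the green-red doublet
#'   colocalizes (intra-doublet distance at or below the cis cutoff).
#' @param p_trans Per-nucleus probability that the two allele midpoints lie
#'   within the trans cutoff.
#' @param cis_noise_sigma SD (um) of the half-normal intra-doublet distance
#'   of colocalized alleles, capped at the cis cutoff.
#' @param far_distance_range Range (um) of intra-doublet distances for
#'   non-colocalized alleles; its lower bound must exceed the cis cutoff so
#'   that p_cis is exactly the expected colocalization rate.
#' @param nucleus_radius Radius (um) of the spherical nucleus.
#' @param truth_profile Named non-negative vector of true interaction
#'   frequencies per test fragment.
#' @param band_noise_cv Coefficient of variation of the multiplicative
#'   log-normal band noise.
#' @param snp_mode `"monoallelic"` (true major fraction 0.95) or
#'   `"biallelic"` (0.5).
#' @param seed Root seed (integer).
#' @param cis_cutoff,trans_cutoff Cutoffs (um) the geometry is built
#'   around; defaults match [fish_config()].
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(label = "scenario", n_nuclei = 300, p_cis = 0.44,
                         p_trans = 0.05, cis_noise_sigma = 0.1,
                         far_distance_range = c(0.5, 2),
                         nucleus_radius = 3,
                         truth_profile = c(frag_2 = 1, frag_3 = 0.4,
                                           frag_4 = 1.6),
                         band_noise_cv = 0.1,
                         snp_mode = c("monoallelic", "biallelic"),
                         seed = 1, cis_cutoff = 0.35, trans_cutoff = 1) {
  snp_mode <- match.arg(snp_mode)
  if (p_cis < 0 || p_cis > 1 || p_trans < 0 || p_trans > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (far_distance_range[1] <= cis_cutoff) {
    stop("far_distance_range lower bound must exceed the cis cutoff",
         call. = FALSE)
  }
  if (any(truth_profile < 0)) stop("truth profile must be non-negative",
                                   call. = FALSE)
  if (band_noise_cv < 0) stop("band_noise_cv must be non-negative",
                              call. = FALSE)
  structure(list(label = label, n_nuclei = as.integer(n_nuclei),
                 p_cis = p_cis, p_trans = p_trans,
                 cis_noise_sigma = cis_noise_sigma,
                 far_distance_range = far_distance_range,
                 nucleus_radius = nucleus_radius,
                 truth_profile = truth_profile,
                 band_noise_cv = band_noise_cv, snp_mode = snp_mode,
                 seed = as.integer(seed), cis_cutoff = cis_cutoff,
                 trans_cutoff = trans_cutoff),
            class = "sim_scenario")
}

# counter-derived substream seed below 2^31
substream_seed <- function(root, counter) {
  (as.double(root) * 48271 + counter * 104729) %% 2147483629
}

# generators drive the RNG through per-unit set.seed calls; callers get
# their RNG state back afterwards
snapshot_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
}

restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  invisible(NULL)
}

runit_sphere <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Simulate a FISH spot table for one cell line
#'
#' Per nucleus: the first allele midpoint is uniform in a sphere of
#' `nucleus_radius`; with probability `p_trans` the second midpoint is
#' placed within the trans cutoff of the first (uniform distance, random
#' direction), otherwise uniformly in the sphere conditional on separation
#' beyond the cutoff. Per allele, Bernoulli(`p_cis`) decides colocalized
#' (intra-doublet separation = |N(0, cis_noise_sigma)| capped at the cis
#' cutoff) versus not (separation uniform in `far_distance_range`); green
#' and red spots sit symmetric about the midpoint along a random direction.
#' Deterministic given the scenario seed.
#'
#' @param s A [sim_scenario()].
#' @return Spot tibble in the [read_spots()] schema.
#' @export
simulate_fish_line <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  old <- snapshot_rng()
  on.exit(restore_rng(old), add = TRUE)
  n <- s$n_nuclei
  coords <- matrix(NA_real_, nrow = 4 * n, ncol = 3)
  for (i in seq_len(n)) {
    set.seed(substream_seed(s$seed, i))
    draw_in_sphere <- function() {
      runit_sphere() * s$nucleus_radius * stats::runif(1)^(1 / 3)
    }
    m1 <- draw_in_sphere()
    if (stats::runif(1) < s$p_trans) {
      m2 <- m1 + runit_sphere() * stats::runif(1, 0, s$trans_cutoff)
    } else {
      repeat {
        m2 <- draw_in_sphere()
        if (sqrt(sum((m2 - m1)^2)) > s$trans_cutoff) break
      }
    }
    mids <- rbind(m1, m2)
    for (a in 1:2) {
      if (stats::runif(1) < s$p_cis) {
        sep <- min(abs(stats::rnorm(1, 0, s$cis_noise_sigma)), s$cis_cutoff)
      } else {
        sep <- stats::runif(1, s$far_distance_range[1],
                            s$far_distance_range[2])
      }
      dir <- runit_sphere()
      row <- (i - 1) * 4 + (a - 1) * 2
      coords[row + 1, ] <- mids[a, ] - sep / 2 * dir
      coords[row + 2, ] <- mids[a, ] + sep / 2 * dir
    }
  }
  tibble::tibble(
    nucleus_id = rep(sprintf("%s_nuc%04d", s$label, seq_len(n)), each = 4),
    channel = rep(c(FISH_CHANNELS[1], FISH_CHANNELS[2]), times = 2 * n),
    x_um = coords[, 1], y_um = coords[, 2], z_um = coords[, 3]
  )
}

#' Simulate a 3C band-intensity table
#'
#' Per fragment and replicate the control-template intensity is log-normal
#' around a base level, and the 3C intensity is the truth frequency times
#' that control intensity times a mean-one log-normal noise factor with the
#' scenario's CV. With zero CV, normalization recovers the truth exactly.
#'
#' @param s A [sim_scenario()] (uses `truth_profile`, `band_noise_cv`,
#'   `seed`).
#' @param sample Cell-line label.
#' @param anchor Anchor label.
#' @param n_replicates Replicates to generate (default 2).
#' @param base_ctrl Base control-template intensity (arbitrary units).
#' @return Band tibble in the [read_bands()] schema.
#' @export
simulate_3c_bands <- function(s, sample = s$label, anchor = "ICR1",
                              n_replicates = 2, base_ctrl = 1000) {
  stopifnot(inherits(s, "sim_scenario"))
  old <- snapshot_rng()
  on.exit(restore_rng(old), add = TRUE)
  truth <- s$truth_profile
  if (length(truth) == 0) stop("empty truth profile", call. = FALSE)
  cv <- s$band_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  rows <- vector("list", length(truth) * n_replicates)
  k <- 0
  for (f in seq_along(truth)) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1
      set.seed(substream_seed(s$seed, 100000 + f * 1000 + r))
      ctrl <- base_ctrl * stats::rlnorm(1, meanlog = -0.02, sdlog = 0.2)
      noise <- if (cv == 0) 1 else
        stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      rows[[k]] <- tibble::tibble(
        sample = sample, replicate = as.integer(r), anchor = anchor,
        test = names(truth)[f],
        intensity_3c = truth[[f]] * ctrl * noise,
        intensity_ctrl = ctrl)
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate quantitative SNP signal records
#'
#' Monoallelic mode draws signals around a true major-allele fraction of
#' 0.95, biallelic around 0.5; each allele signal gets independent mean-one
#' log-normal noise with 10% CV.
#'
#' @param s A [sim_scenario()] (uses `snp_mode`, `seed`).
#' @param n_records Number of records to draw.
#' @param base_intensity Total signal scale (> 0).
#' @param noise_cv Per-allele multiplicative noise CV (default 0.1).
#' @return Tibble: `interaction`, `snp_id`, `allele_a`, `allele_b`,
#'   `signal_a`, `signal_b`.
#' @export
simulate_snp_signals <- function(s, n_records = 1, base_intensity = 1000,
                                 noise_cv = 0.1) {
  stopifnot(inherits(s, "sim_scenario"))
  if (base_intensity <= 0) stop("base_intensity must be positive",
                                call. = FALSE)
  old <- snapshot_rng()
  on.exit(restore_rng(old), add = TRUE)
  frac <- if (s$snp_mode == "monoallelic") 0.95 else 0.5
  sdlog <- sqrt(log(1 + noise_cv^2))
  sa <- sb <- numeric(n_records)
  for (i in seq_len(n_records)) {
    set.seed(substream_seed(s$seed, 200000 + i))
    nz <- stats::rlnorm(2, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    sa[i] <- base_intensity * frac * nz[1]
    sb[i] <- base_intensity * (1 - frac) * nz[2]
  }
  tibble::tibble(
    interaction = sprintf("%s_int%04d", s$label, seq_len(n_records)),
    snp_id = "rs_sim", allele_a = "T", allele_b = "A",
    signal_a = sa, signal_b = sb
  )
}

#' Named preset scenarios
#'
#' Presets calibrated to the two FISH cohorts the pipeline is aimed at: a
#' control-like line (allele colocalization rate 0.44, trans rate 0.05) and
#' an ICR2-hypomethylated BWS-like line (0.29 and 0.03), 300 nuclei each.
#'
#' @param name Preset name.
#' @param seed Optional seed overriding the preset's documented seed.
#' @return A [sim_scenario()].
#' @export
#' @examples
#' preset_scenarios("CTRL-like")$p_cis
preset_scenarios <- function(name, seed = NULL) {
  presets <- list(
    "CTRL-like" = list(p_cis = 0.44, p_trans = 0.05, n_nuclei = 300,
                       seed = 101),
    "BWS-ICR2-like" = list(p_cis = 0.29, p_trans = 0.03, n_nuclei = 300,
                           seed = 202)
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  sim_scenario(label = name, n_nuclei = p$n_nuclei, p_cis = p$p_cis,
               p_trans = p$p_trans,
               seed = if (is.null(seed)) p$seed else seed)
}

#' Write a scenario's simulated inputs to a directory
#'
#' Emits `spots.tsv`, `bands.tsv` and `snp.tsv` in the schemas the analysis
#' functions consume, plus a `scenario.yaml` sidecar echoing the generative
#' parameters.
#'
#' @param s A [sim_scenario()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_sim_inputs <- function(s, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(spots = file.path(dir, "spots.tsv"),
             bands = file.path(dir, "bands.tsv"),
             snp = file.path(dir, "snp.tsv"),
             scenario = file.path(dir, "scenario.yaml"))
  readr::write_tsv(simulate_fish_line(s), paths["spots"])
  readr::write_tsv(simulate_3c_bands(s), paths["bands"])
  readr::write_tsv(simulate_snp_signals(s, n_records = 10), paths["snp"])
  meta <- s
  class(meta) <- NULL
  meta$truth_profile <- as.list(meta$truth_profile)
  yaml::write_yaml(meta, paths["scenario"])
  invisible(paths)
}
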