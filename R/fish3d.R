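# Two-colour 3D DNA FISH analysis. Each allele appears as a green-red
# doublet (green = distal-domain probe, red = proximal-domain probe); the
# 3D centroid distance within a doublet reads out the cis interaction
# (colocalized when <= 0.35 um), and the distance between the two alleles'
# doublets reads out trans association (<= 1 um). Nuclei are classified
# +/+, +/- or -/- by how many alleles colocalize.

#' FISH analysis configuration
#'
#' @param cis_cutoff Colocalization cutoff on the intra-doublet distance,
#'   um (default 0.35, boundary inclusive).
#' @param trans_cutoff Trans-association cutoff on the inter-doublet
#'   distance, um (default 1, boundary inclusive).
#' @param spots_per_channel Expected spots per channel per nucleus
#'   (default 2, one per allele).
#' @param doublet_reference Point representing a doublet for the trans
#'   distance: `"midpoint"` of the two spots (default), `"green_spot"` or
#'   `"red_spot"`.
#' @return A list of class `fish_config`.
#' @export
fish_config <- function(cis_cutoff = 0.35, trans_cutoff = 1,
                        spots_per_channel = 2,
                        doublet_reference = c("midpoint", "green_spot",
                                              "red_spot")) {
  if (!(cis_cutoff > 0 && cis_cutoff < trans_cutoff)) {
    stop("require 0 < cis_cutoff < trans_cutoff", call. = FALSE)
  }
  structure(list(cis_cutoff = cis_cutoff, trans_cutoff = trans_cutoff,
                 spots_per_channel = spots_per_channel,
                 doublet_reference = match.arg(doublet_reference)),
            class = "fish_config")
}

FISH_CHANNELS <- c("green_ICR1", "red_ICR2")

#' Read a spot-centroid table
#'
#' TSV with columns `nucleus_id`, `channel` (green_ICR1 / red_ICR2),
#' `x_um`, `y_um`, `z_um`. Coordinates must already be in micrometres.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_spots <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    nucleus_id = readr::col_character(),
                    channel = readr::col_character(),
                    x_um = readr::col_double(),
                    y_um = readr::col_double(),
                    z_um = readr::col_double()
                  ))
}

#' Per-nucleus spot-count QC
#'
#' A nucleus passes when it has exactly the expected number of spots in each
#' channel (default 2 + 2); anything else is excluded with a reason. QC never
#' raises.
#'
#' @param spots Spot tibble (see [read_spots()]).
#' @param cfg A [fish_config()].
#' @return Tibble: `nucleus_id`, `n_green`, `n_red`, `pass`, `reason`.
#' @export
qc_nuclei <- function(spots, cfg = fish_config()) {
  k <- cfg$spots_per_channel
  out <- spots |>
    dplyr::group_by(.data$nucleus_id) |>
    dplyr::summarise(
      n_green = sum(.data$channel == FISH_CHANNELS[1]),
      n_red = sum(.data$channel == FISH_CHANNELS[2]),
      n_other = sum(!.data$channel %in% FISH_CHANNELS),
      bad_coord = any(!is.finite(.data$x_um) | !is.finite(.data$y_um) |
                        !is.finite(.data$z_um)),
      .groups = "drop"
    )
  out$pass <- out$n_green == k & out$n_red == k & out$n_other == 0 &
    !out$bad_coord
  out$reason <- dplyr::case_when(
    out$pass ~ NA_character_,
    out$bad_coord ~ "non-finite coordinates",
    out$n_other > 0 ~ "unknown channel",
    TRUE ~ sprintf("expected %d+%d spots, found %d green + %d red",
                   k, k, out$n_green, out$n_red)
  )
  out[, c("nucleus_id", "n_green", "n_red", "pass", "reason")]
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

#' Pair green and red spots into allele doublets
#'
#' With two spots per channel there are exactly two perfect matchings of
#' green to red spots; the one minimizing the summed green-red distance is
#' chosen (ties pair lowest-index green with lowest-index red). The chosen
#' matching is invariant under rigid motion of the nucleus's spots.
#'
#' @param spots Spot tibble for one or more nuclei.
#' @param cfg A [fish_config()].
#' @param qc Optional precomputed [qc_nuclei()] table.
#' @return Allele-level tibble: `nucleus_id`, `allele` (1, 2),
#'   `cis_distance`, `colocalized`, `mid_x`, `mid_y`, `mid_z`. QC-failing
#'   nuclei are omitted (error if *all* fail).
#' @export
pair_doublets <- function(spots, cfg = fish_config(), qc = NULL) {
  if (is.null(qc)) qc <- qc_nuclei(spots, cfg)
  keep <- qc$nucleus_id[qc$pass]
  if (length(keep) == 0) stop("no nucleus passed QC", call. = FALSE)
  spots <- spots[spots$nucleus_id %in% keep, ]
  # stable sort: nuclei in id order, channels green then red, original
  # within-channel order preserved (the spot "index" used for tie-breaks)
  sp <- spots[order(spots$nucleus_id, match(spots$channel, FISH_CHANNELS)), ]
  xyz <- as.matrix(sp[, c("x_um", "y_um", "z_um")])
  is_g <- sp$channel == FISH_CHANNELS[1]
  g <- xyz[is_g, , drop = FALSE]
  r <- xyz[!is_g, , drop = FALSE]
  n <- nrow(g) / 2
  i1 <- seq(1, 2 * n, by = 2)
  g1 <- g[i1, , drop = FALSE]; g2 <- g[i1 + 1, , drop = FALSE]
  r1 <- r[i1, , drop = FALSE]; r2 <- r[i1 + 1, , drop = FALSE]
  rowdist <- function(a, b) sqrt(rowSums((a - b)^2))
  d11 <- rowdist(g1, r1); d22 <- rowdist(g2, r2)
  d12 <- rowdist(g1, r2); d21 <- rowdist(g2, r1)
  # matching A: g1-r1, g2-r2; matching B: g1-r2, g2-r1; ties keep A
  use_b <- (d12 + d21) < (d11 + d22)
  p1 <- ifelse(use_b, d12, d11)  # allele 1 = lowest-index green
  p2 <- ifelse(use_b, d21, d22)
  r_for_g1 <- r1; r_for_g1[use_b, ] <- r2[use_b, ]
  r_for_g2 <- r2; r_for_g2[use_b, ] <- r1[use_b, ]
  mid1 <- (g1 + r_for_g1) / 2
  mid2 <- (g2 + r_for_g2) / 2
  interleave <- function(a, b) {
    out <- numeric(2 * n)
    out[i1] <- a; out[i1 + 1] <- b
    out
  }
  out <- tibble::tibble(
    nucleus_id = rep(sp$nucleus_id[is_g][i1], each = 2),
    allele = rep(1:2, n),
    cis_distance = interleave(p1, p2),
    mid_x = interleave(mid1[, 1], mid2[, 1]),
    mid_y = interleave(mid1[, 2], mid2[, 2]),
    mid_z = interleave(mid1[, 3], mid2[, 3]),
    g_x = interleave(g1[, 1], g2[, 1]),
    g_y = interleave(g1[, 2], g2[, 2]),
    g_z = interleave(g1[, 3], g2[, 3]),
    r_x = interleave(r_for_g1[, 1], r_for_g2[, 1]),
    r_y = interleave(r_for_g1[, 2], r_for_g2[, 2]),
    r_z = interleave(r_for_g1[, 3], r_for_g2[, 3])
  )
  out$colocalized <- classify_allele(out$cis_distance, cfg)
  out
}

#' Cis-colocalization call for an allele
#'
#' @param d Intra-doublet distance(s), um, non-negative.
#' @param cfg A [fish_config()].
#' @return Logical: distance at or below the cis cutoff.
#' @export
classify_allele <- function(d, cfg = fish_config()) {
  if (any(d < 0)) stop("negative distance", call. = FALSE)
  d <= cfg$cis_cutoff
}

#' Nucleus category from the two allele flags
#'
#' @param a1,a2 Logical colocalization flags (vectorized).
#' @return `"plus_plus"`, `"plus_minus"` or `"minus_minus"`.
#' @export
classify_nucleus <- function(a1, a2) {
  c("minus_minus", "plus_minus", "plus_plus")[a1 + a2 + 1L]
}

#' Classify nuclei: categories and trans association
#'
#' Computes, per nucleus, the category from the two alleles' colocalization
#' flags and the inter-doublet distance between the two doublets' reference
#' points (midpoints by default); trans association holds when that distance
#' is at or below the trans cutoff (inclusive).
#'
#' @param alleles Allele tibble from [pair_doublets()].
#' @param cfg A [fish_config()].
#' @return Nucleus tibble: `nucleus_id`, `category`,
#'   `inter_doublet_distance`, `trans`.
#' @export
classify_nuclei <- function(alleles, cfg = fish_config()) {
  ref_cols <- switch(cfg$doublet_reference,
                     midpoint = c("mid_x", "mid_y", "mid_z"),
                     green_spot = c("g_x", "g_y", "g_z"),
                     red_spot = c("r_x", "r_y", "r_z"))
  alleles <- dplyr::rename(alleles, ref_x = !!ref_cols[1],
                           ref_y = !!ref_cols[2], ref_z = !!ref_cols[3])
  alleles <- dplyr::arrange(alleles, .data$nucleus_id, .data$allele)
  i1 <- seq(1, nrow(alleles), by = 2)
  a1 <- alleles[i1, ]; a2 <- alleles[i1 + 1, ]
  stopifnot(identical(a1$nucleus_id, a2$nucleus_id))
  wide <- tibble::tibble(
    nucleus_id = a1$nucleus_id,
    category = classify_nucleus(a1$colocalized, a2$colocalized),
    inter_doublet_distance = sqrt((a1$ref_x - a2$ref_x)^2 +
                                    (a1$ref_y - a2$ref_y)^2 +
                                    (a1$ref_z - a2$ref_z)^2)
  )
  wide$trans <- wide$inter_doublet_distance <= cfg$trans_cutoff
  wide
}

#' Full FISH analysis of a spot table
#'
#' QC, doublet pairing, allele and nucleus classification in one call.
#'
#' @param spots Spot tibble.
#' @param cfg A [fish_config()].
#' @param line Cell-line label attached to the outputs.
#' @return List of class `fish_result`: `qc`, `alleles`, `nuclei`,
#'   `summary` ([summarize_line()] output).
#' @export
analyze_fish <- function(spots, cfg = fish_config(), line = "line") {
  qc <- qc_nuclei(spots, cfg)
  alleles <- pair_doublets(spots, cfg, qc)
  nuclei <- classify_nuclei(alleles, cfg)
  structure(list(qc = qc, alleles = alleles, nuclei = nuclei,
                 summary = summarize_line(nuclei, line = line),
                 line = line, cfg = cfg),
            class = "fish_result")
}

#' @export
print.fish_result <- function(x, ...) {
  cat("FISH analysis of line", x$line, "-", nrow(x$nuclei),
      "nuclei (", sum(!x$qc$pass), "failed QC )\n")
  print(x$summary)
  invisible(x)
}

#' Cohort summary for one cell line
#'
#' Category counts and percentages, the allele colocalization rate
#' `(2 N++ + N+-) / (2 n) * 100`, and the trans rate.
#'
#' @param nuclei Nucleus tibble from [classify_nuclei()], or a counts
#'   tibble with columns `n_plus_plus`, `n_plus_minus`, `n_minus_minus`
#'   (and optionally `n_trans`) as produced by [fish_reference_counts()].
#' @param line Cell-line label.
#' @return One-row `cohort_summary` tibble.
#' @export
summarize_line <- function(nuclei, line = "line") {
  if (all(c("n_plus_plus", "n_plus_minus", "n_minus_minus") %in%
          names(nuclei))) {
    npp <- nuclei$n_plus_plus; npm <- nuclei$n_plus_minus
    nmm <- nuclei$n_minus_minus
    ntr <- if ("n_trans" %in% names(nuclei)) nuclei$n_trans else NA_integer_
    if ("line" %in% names(nuclei) && missing(line)) line <- nuclei$line
  } else {
    if (nrow(nuclei) == 0) stop("no nuclei", call. = FALSE)
    npp <- sum(nuclei$category == "plus_plus")
    npm <- sum(nuclei$category == "plus_minus")
    nmm <- sum(nuclei$category == "minus_minus")
    ntr <- sum(nuclei$trans)
  }
  n <- npp + npm + nmm
  if (any(n < 1)) stop("empty cohort", call. = FALSE)
  out <- tibble::tibble(
    line = line, n_nuclei = n,
    n_plus_plus = npp, n_plus_minus = npm, n_minus_minus = nmm,
    pct_plus_plus = 100 * npp / n,
    pct_plus_minus = 100 * npm / n,
    pct_minus_minus = 100 * nmm / n,
    allele_coloc_pct = 100 * (2 * npp + npm) / (2 * n),
    n_trans = ntr,
    trans_pct = 100 * ntr / n
  )
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Pool cohort summaries across lines
#'
#' `pooled_counts` sums the integer counts and recomputes percentages (the
#' convention behind pooled category percentages); `mean_of_lines` averages
#' the per-line rates unweighted (the convention behind a mean-of-controls
#' allele rate).
#'
#' @param summaries `cohort_summary` rows bound together.
#' @param mode `"pooled_counts"` or `"mean_of_lines"`.
#' @param label Label for the pooled row.
#' @return One-row `cohort_summary` tibble with a `mode` column.
#' @export
pool_lines <- function(summaries, mode = c("pooled_counts",
                                           "mean_of_lines"),
                       label = "pooled") {
  mode <- match.arg(mode)
  if (nrow(summaries) == 0) stop("no summaries to pool", call. = FALSE)
  if (mode == "pooled_counts") {
    out <- summarize_line(tibble::tibble(
      n_plus_plus = sum(summaries$n_plus_plus),
      n_plus_minus = sum(summaries$n_plus_minus),
      n_minus_minus = sum(summaries$n_minus_minus),
      n_trans = if (all(!is.na(summaries$n_trans)))
        sum(summaries$n_trans) else NA_integer_
    ), line = label)
  } else {
    out <- tibble::tibble(
      line = label, n_nuclei = sum(summaries$n_nuclei),
      n_plus_plus = sum(summaries$n_plus_plus),
      n_plus_minus = sum(summaries$n_plus_minus),
      n_minus_minus = sum(summaries$n_minus_minus),
      pct_plus_plus = mean(summaries$pct_plus_plus),
      pct_plus_minus = mean(summaries$pct_plus_minus),
      pct_minus_minus = mean(summaries$pct_minus_minus),
      allele_coloc_pct = mean(summaries$allele_coloc_pct),
      n_trans = if (all(!is.na(summaries$n_trans)))
        sum(summaries$n_trans) else NA_integer_,
      trans_pct = mean(summaries$trans_pct)
    )
    class(out) <- c("cohort_summary", class(out))
  }
  out$mode <- mode
  out
}

#' Cumulative distance distribution table
#'
#' Percentage of distances at or below each grid point; non-decreasing and
#' reaching 100% at the maximum distance.
#'
#' @param distances Non-negative distances, um.
#' @param step Grid step, um (default 0.05).
#' @return Tibble: `distance_um`, `cum_pct`.
#' @export
ecdf_table <- function(distances, step = 0.05) {
  if (length(distances) == 0) stop("no distances", call. = FALSE)
  if (any(distances < 0)) stop("negative distance", call. = FALSE)
  grid <- round(seq(0, (ceiling(max(distances) / step) + 1) * step,
                    by = step), 10)
  f <- stats::ecdf(distances)
  tibble::tibble(distance_um = grid, cum_pct = 100 * f(grid))
}

#' Compare two cell lines: distances and category proportions
#'
#' Runs (i) an unpaired two-sided t-test on per-allele cis distances (when
#' distance vectors are supplied), (ii) a two-sided Fisher's exact test per
#' nucleus category on the 2x2 table in-category vs not by group, and
#' (iii) Fisher's exact on trans counts when available. Degenerate 2x2
#' tables with a zero margin report p = 1 with a warning.
#'
#' @param ctrl,case `cohort_summary` rows (one each).
#' @param ctrl_distances,case_distances Optional per-allele cis distances.
#' @param cfg A [stat_config()] for star codes.
#' @return Object of class `fish_comparison`; `tidy()` gives the per-test
#'   table, `glance()` a one-row overview.
#' @export
compare_lines <- function(ctrl, case, ctrl_distances = NULL,
                          case_distances = NULL, cfg = stat_config()) {
  stopifnot(nrow(ctrl) == 1, nrow(case) == 1)
  fisher_p <- function(a, b, c, d) {
    m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      warning("degenerate 2x2 table (zero margin); p = 1", call. = FALSE)
      return(1)
    }
    stats::fisher.test(m)$p.value
  }
  rows <- list()
  for (cat in c("plus_plus", "plus_minus", "minus_minus")) {
    a <- ctrl[[paste0("n_", cat)]]
    c_ <- case[[paste0("n_", cat)]]
    p <- fisher_p(a, ctrl$n_nuclei - a, c_, case$n_nuclei - c_)
    rows[[cat]] <- tibble::tibble(
      test = paste0("fisher_", cat), statistic = NA_real_, p_value = p,
      ctrl_value = 100 * a / ctrl$n_nuclei,
      case_value = 100 * c_ / case$n_nuclei)
  }
  if (!is.na(ctrl$n_trans) && !is.na(case$n_trans)) {
    p <- fisher_p(ctrl$n_trans, ctrl$n_nuclei - ctrl$n_trans,
                  case$n_trans, case$n_nuclei - case$n_trans)
    rows$trans <- tibble::tibble(
      test = "fisher_trans", statistic = NA_real_, p_value = p,
      ctrl_value = ctrl$trans_pct, case_value = case$trans_pct)
  }
  if (!is.null(ctrl_distances) && !is.null(case_distances)) {
    tt <- stats::t.test(ctrl_distances, case_distances)
    rows$ttest <- tibble::tibble(
      test = "t_cis_distance", statistic = unname(tt$statistic),
      p_value = tt$p.value,
      ctrl_value = mean(ctrl_distances), case_value = mean(case_distances))
  }
  tab <- dplyr::bind_rows(rows)
  tab$stars <- star_code(tab$p_value, cfg)
  structure(list(table = tab, ctrl = ctrl, case = case),
            class = "fish_comparison")
}

#' @export
print.fish_comparison <- function(x, ...) {
  cat("FISH comparison:", x$ctrl$line, "vs", x$case$line, "\n")
  print(x$table)
  invisible(x)
}

#' Tidy a `fish_comparison`
#'
#' @param x A `fish_comparison`.
#' @param ... Unused.
#' @return The per-test tibble (test, statistic, p_value, group values,
#'   stars).
#' @method tidy fish_comparison
#' @export
tidy.fish_comparison <- function(x, ...) x$table

#' Glance at a `fish_comparison`
#'
#' @param x A `fish_comparison`.
#' @param ... Unused.
#' @return One-row tibble with group sizes and the smallest category p.
#' @method glance fish_comparison
#' @export
glance.fish_comparison <- function(x, ...) {
  tibble::tibble(
    ctrl_line = x$ctrl$line, case_line = x$case$line,
    n_ctrl = x$ctrl$n_nuclei, n_case = x$case$n_nuclei,
    min_category_p = min(x$table$p_value[startsWith(x$table$test,
                                                    "fisher_")]))
}

#' Reference nucleus-category counts for the lymphoblastoid FISH cohorts
#'
#' Integer counts of +/+, +/- and -/- nuclei for the two control
#' lymphoblastoid lines (302 and 290 nuclei) and the ICR2-hypomethylated
#' BWS line (308 nuclei), as determined by the per-line category percentages
#' and cohort sizes of the study these cohorts come from. These counts are
#' the inputs for recomputing the pooled and mean cohort statistics.
#'
#' @return Tibble: `line`, `n_plus_plus`, `n_plus_minus`, `n_minus_minus`.
#' @export
#' @examples
#' summarize_line(fish_reference_counts()[1, ])
fish_reference_counts <- function() {
  tibble::tibble(
    line = c("CTRL1", "CTRL2", "BWS-ICR2"),
    n_plus_plus = c(77L, 59L, 23L),
    n_plus_minus = c(121L, 129L, 131L),
    n_minus_minus = c(104L, 102L, 154L)
  )
}

#' Plot nucleus-category percentages per line
#'
#' @param summaries `cohort_summary` rows bound together.
#' @return A ggplot object.
#' @export
plot_fish_categories <- function(summaries) {
  long <- tidyr::pivot_longer(
    as.data.frame(summaries)[, c("line", "pct_plus_plus", "pct_plus_minus",
                                 "pct_minus_minus")],
    -"line", names_to = "category", values_to = "pct")
  long$category <- factor(long$category,
                          levels = c("pct_plus_plus", "pct_plus_minus",
                                     "pct_minus_minus"),
                          labels = c("+/+", "+/-", "-/-"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$pct,
                                     fill = .data$line)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of nuclei", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cumulative cis-distance distribution
#'
#' @param distances Named list of per-allele distance vectors (one per
#'   line).
#' @param cfg A [fish_config()]; the cis cutoff is drawn as a vertical line.
#' @param step Grid step for [ecdf_table()].
#' @return A ggplot object.
#' @export
plot_cis_ecdf <- function(distances, cfg = fish_config(), step = 0.05) {
  df <- dplyr::bind_rows(lapply(names(distances), function(nm) {
    tibble::add_column(ecdf_table(distances[[nm]], step), line = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_um, y = .data$cum_pct,
                                   colour = .data$line)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = cfg$cis_cutoff, linetype = 2) +
    ggplot2::labs(x = "inter-probe distance (um)", y = "% of alleles",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
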