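# 3C quantification: band intensities -> normalized interaction frequencies
# -> per-anchor looping profiles. The frequency of a contact is the amount of
# PCR product from the 3C ligation library divided by the amount from the
# equimolar control-template library for the same primer pair, which cancels
# primer-pair PCR efficiency.

#' Normalize 3C band intensities against the control template
#'
#' Adds a `frequency` column (`intensity_3c / intensity_ctrl`) to a band
#' table. Records with an undetectable control band (`intensity_ctrl == 0`)
#' are flagged (`undetectable_ctrl`), get `frequency = NA`, and are excluded
#' by downstream profile construction.
#'
#' @param bands Tibble with columns `sample`, `replicate`, `anchor`, `test`,
#'   `intensity_3c`, `intensity_ctrl`.
#' @return The input with `frequency` and `undetectable_ctrl` columns.
#' @export
#' @examples
#' normalize_bands(tibble::tibble(sample = "CTRL1", replicate = 1,
#'   anchor = "ICR1", test = "frag_2", intensity_3c = 1200,
#'   intensity_ctrl = 600))
normalize_bands <- function(bands) {
  required <- c("sample", "replicate", "anchor", "test",
                "intensity_3c", "intensity_ctrl")
  missing <- setdiff(required, names(bands))
  if (length(missing) > 0) {
    stop("band table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(bands$intensity_3c)) ||
      any(!is.finite(bands$intensity_ctrl)) ||
      any(bands$intensity_3c < 0) || any(bands$intensity_ctrl < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  key <- paste(bands$sample, bands$replicate, bands$anchor, bands$test)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, replicate, anchor, test) measurement",
         call. = FALSE)
  }
  out <- dplyr::mutate(
    tibble::as_tibble(bands),
    undetectable_ctrl = .data$intensity_ctrl == 0,
    frequency = dplyr::if_else(.data$undetectable_ctrl, NA_real_,
                               .data$intensity_3c / .data$intensity_ctrl)
  )
  if (any(out$undetectable_ctrl)) {
    warning(sum(out$undetectable_ctrl),
            " record(s) with undetectable control band flagged and excluded",
            call. = FALSE)
  }
  out
}

#' Mean, sample SD and n over replicate frequencies
#'
#' @param freqs Numeric vector of replicate frequencies (length >= 1).
#' @return A one-row tibble with `mean`, `sd` (n-1 denominator; 0 when
#'   n = 1) and `n_reps`.
#' @export
aggregate_replicates <- function(freqs) {
  freqs <- freqs[!is.na(freqs)]
  if (length(freqs) == 0) stop("no replicate frequencies", call. = FALSE)
  tibble::tibble(
    mean = mean(freqs),
    sd = if (length(freqs) > 1) stats::sd(freqs) else 0,
    n_reps = length(freqs)
  )
}

#' Build a looping profile for one anchor
#'
#' One interaction frequency (mean +/- sample SD over replicates) per axis
#' fragment, in axis order. Fragments with no usable measurement are kept as
#' explicit gaps (`NA` mean, `n_reps = 0`), never imputed as zero.
#'
#' @param bands Normalized band table ([normalize_bands()] output) or raw
#'   band table (normalized on the fly).
#' @param sample Cell-line label to profile.
#' @param anchor Anchor fragment label.
#' @param axis Fragment axis: [locate_fragments()] output, or a character
#'   vector of test-fragment labels.
#' @return Tibble of class `loop_profile`: `sample`, `anchor`, `test`,
#'   optional coordinates, `mean`, `sd`, `n_reps`.
#' @export
build_looping_profile <- function(bands, sample, anchor, axis) {
  if (!"frequency" %in% names(bands)) bands <- normalize_bands(bands)
  if (is.data.frame(axis)) {
    axis_tbl <- axis[axis$role == "test",
                     c("fragment", "chrom", "start", "end")]
    names(axis_tbl)[1] <- "test"
  } else {
    axis_tbl <- tibble::tibble(test = as.character(axis))
  }
  sub <- bands[bands$sample == sample & bands$anchor == anchor &
                 !bands$undetectable_ctrl, ]
  if (nrow(sub) == 0) {
    stop("no measurements for sample '", sample, "', anchor '", anchor, "'",
         call. = FALSE)
  }
  stats_tbl <- sub |>
    dplyr::group_by(.data$test) |>
    dplyr::summarise(aggregate_replicates(.data$frequency),
                     .groups = "drop")
  out <- dplyr::left_join(axis_tbl, stats_tbl, by = "test")
  out$n_reps[is.na(out$n_reps)] <- 0L
  if (any(out$n_reps == 0)) {
    warning("axis fragment(s) without measurements reported as gaps: ",
            paste(out$test[out$n_reps == 0], collapse = ", "),
            call. = FALSE)
  }
  out <- tibble::add_column(out, sample = sample, anchor = anchor,
                            .before = 1)
  class(out) <- c("loop_profile", class(out))
  out
}

#' Pool control looping profiles into a "controls mean" profile
#'
#' Pools the individual assay values (replicates, not line means) of several
#' control profiles and reports per-fragment mean and sample SD over all
#' constituent assays, matching a controls-mean of four independent assays,
#' two per control line.
#'
#' @param bands Normalized band table covering the control samples.
#' @param samples Character vector of control line labels.
#' @param anchor Anchor label.
#' @param axis Fragment axis (see [build_looping_profile()]).
#' @param label Group label for the pooled profile.
#' @return A `loop_profile` tibble for the pooled group.
#' @export
pool_control_profiles <- function(bands, samples, anchor, axis,
                                  label = "controls mean") {
  if (!"frequency" %in% names(bands)) bands <- normalize_bands(bands)
  if (length(samples) < 2) {
    warning("pooling a single control line: mean over its replicates only",
            call. = FALSE)
  }
  pooled <- bands[bands$sample %in% samples, ]
  pooled$sample <- label
  build_looping_profile(pooled, label, anchor, axis)
}

#' Check that two profiles share an identical fragment axis
#' @noRd
check_same_axis <- function(a, b) {
  if (!identical(a$test, b$test) || !identical(a$anchor[1], b$anchor[1])) {
    stop("profiles do not share the same anchor and fragment axis",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Control-template uniformity check
#'
#' The control template is an equimolar ligation of all junctions, so the
#' control band intensities across primer pairs should be comparable. Reports
#' the coefficient of variation and fails when it exceeds `max_cv`.
#'
#' @param intensities Numeric vector of control band intensities (>= 2).
#' @param max_cv Failure threshold on CV (default 0.5).
#' @return One-row tibble: `n`, `mean`, `sd`, `cv`, `pass`.
#' @export
validate_control_template <- function(intensities, max_cv = 0.5) {
  if (length(intensities) < 2) {
    stop("need at least two control intensities", call. = FALSE)
  }
  if (all(intensities == 0)) {
    stop("all control intensities are zero", call. = FALSE)
  }
  m <- mean(intensities)
  s <- stats::sd(intensities)
  cv <- s / m
  tibble::tibble(n = length(intensities), mean = m, sd = s, cv = cv,
                 pass = cv <= max_cv)
}

#' Optional per-profile max-normalization
#'
#' Rescales a profile so its largest mean equals 1, for cross-panel visual
#' comparison. Off by default everywhere; frequencies are otherwise reported
#' on the raw relative scale.
#'
#' @param profile A `loop_profile` tibble.
#' @return The profile with `mean` and `sd` divided by the maximum mean.
#' @export
max_normalize_profile <- function(profile) {
  mx <- max(profile$mean, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("profile has no positive signal",
                                      call. = FALSE)
  profile$mean <- profile$mean / mx
  profile$sd <- profile$sd / mx
  profile
}

#' Read / write band and profile tables
#'
#' `read_bands()` reads the TSV schema `sample, replicate, anchor, test,
#' intensity_3c, intensity_ctrl`; `write_profile()` writes a profile as TSV.
#'
#' @param path File path.
#' @return `read_bands()`: a tibble; `write_profile()`: `path`, invisibly.
#' @export
read_bands <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample = readr::col_character(),
                    replicate = readr::col_integer(),
                    anchor = readr::col_character(),
                    test = readr::col_character(),
                    intensity_3c = readr::col_double(),
                    intensity_ctrl = readr::col_double()
                  ))
}

#' @rdname read_bands
#' @param profile A `loop_profile` tibble.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(as.data.frame(profile), path)
  invisible(path)
}

#' Plot a looping profile
#'
#' Mean interaction frequency with +/- SD ribbon along the fragment axis.
#' Gap fragments break the line rather than being drawn at zero.
#'
#' @param profile A `loop_profile` tibble (or several row-bound together,
#'   distinguished by `sample`).
#' @return A ggplot object.
#' @export
plot_looping_profile <- function(profile) {
  df <- as.data.frame(profile)
  df$x <- if ("start" %in% names(df) && !all(is.na(df$start))) {
    (df$start + df$end) / 2
  } else {
    stats::ave(seq_len(nrow(df)), df$sample, FUN = seq_along)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$mean,
                                   colour = .data$sample,
                                   group = .data$sample)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd,
                                      fill = .data$sample),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "position along fragment axis",
                  y = "association frequency",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
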