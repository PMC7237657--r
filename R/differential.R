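# Differential interactome calling: two-way ANOVA (group x fragment) on
# individual assay values, Bonferroni-adjusted per-fragment group contrasts
# with the pooled residual error, and classification of each region of
# interaction (ROI) as unchanged / increased / decreased / novel / lost.

#' Statistical configuration for differential calling
#'
#' @param alpha_levels Strictly decreasing significance thresholds mapped to
#'   `*`, `**`, `***`, `****`.
#' @param presence_epsilon_fraction Fraction of the profile maximum below
#'   which a mean counts as absent, the floor for novel/lost calls. Mimics
#'   band detectability on a gel.
#' @return A list of class `stat_config`.
#' @export
stat_config <- function(alpha_levels = c(0.05, 0.01, 0.001, 0.0001),
                        presence_epsilon_fraction = 0.05) {
  if (any(diff(alpha_levels) >= 0)) {
    stop("alpha_levels must be strictly decreasing", call. = FALSE)
  }
  if (presence_epsilon_fraction <= 0 || presence_epsilon_fraction >= 1) {
    stop("presence_epsilon_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(alpha_levels = alpha_levels,
                 presence_epsilon_fraction = presence_epsilon_fraction),
            class = "stat_config")
}

#' Star code for an adjusted p-value
#'
#' @param p Numeric vector of p-values.
#' @param cfg A [stat_config()].
#' @return Character vector in `ns`, `*`, `**`, `***`, `****`.
#' @export
star_code <- function(p, cfg = stat_config()) {
  stars <- c("*", "**", "***", "****")[seq_along(cfg$alpha_levels)]
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    hit <- which(pi <= cfg$alpha_levels)
    if (length(hit) == 0) "ns" else stars[max(hit)]
  }, "")
}

#' Two-way ANOVA with Bonferroni per-fragment group contrasts
#'
#' Fits a fixed-effects two-way ANOVA (group x fragment, interaction
#' included) on the individual assay frequencies, then tests the group
#' contrast at each fragment with the pooled residual error; raw two-sided p
#' values are Bonferroni-multiplied by the number of fragments on the axis
#' (the family for one pairwise control-vs-line comparison) and clipped at 1.
#'
#' Degenerate designs with zero residual variance everywhere are flagged
#' (`zero_variance`): fragments whose group means coincide get p = 1, those
#' that differ get p = 0.
#'
#' @param control,case Long tibbles of individual assay values with columns
#'   `test` (fragment label) and `frequency`; at least two assays per group,
#'   both groups on the same fragment axis.
#' @param cfg A [stat_config()] used for star codes.
#' @return An object of class `loop_anova`: use [generics::tidy()] for the
#'   per-fragment table and [generics::glance()] for the ANOVA F table.
#' @export
anova_profiles <- function(control, case, cfg = stat_config()) {
  check_group <- function(x, lab) {
    if (!all(c("test", "frequency") %in% names(x))) {
      stop(lab, " must have columns 'test' and 'frequency'", call. = FALSE)
    }
    n_assay <- table(x$test)
    if (any(n_assay < 2)) {
      stop(lab, " has fewer than two assays at some fragment", call. = FALSE)
    }
  }
  check_group(control, "control")
  check_group(case, "case")
  frags <- unique(control$test)
  if (!setequal(frags, unique(case$test))) {
    stop("control and case are not measured on the same fragment axis",
         call. = FALSE)
  }
  dat <- dplyr::bind_rows(
    dplyr::mutate(control[, c("test", "frequency")], group = "control"),
    dplyr::mutate(case[, c("test", "frequency")], group = "case")
  )
  dat$test <- factor(dat$test, levels = frags)
  dat$group <- factor(dat$group, levels = c("control", "case"))

  fit <- stats::aov(frequency ~ group * test, data = dat)
  aov_tbl <- summary(fit)[[1]]
  rownames(aov_tbl) <- trimws(rownames(aov_tbl))
  mse <- aov_tbl["Residuals", "Mean Sq"]
  df_res <- aov_tbl["Residuals", "Df"]

  cell <- dat |>
    dplyr::group_by(.data$test, .data$group) |>
    dplyr::summarise(m = mean(.data$frequency),
                     s = stats::sd(.data$frequency),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = c("m", "s", "n"))

  k <- length(frags)
  zero_var <- !is.finite(mse) || mse <= .Machine$double.eps
  delta <- cell$m_case - cell$m_control
  if (zero_var) {
    p_adj <- ifelse(abs(delta) <= .Machine$double.eps^0.5, 1, 0)
    t_stat <- rep(NA_real_, k)
  } else {
    se <- sqrt(mse * (1 / cell$n_control + 1 / cell$n_case))
    t_stat <- delta / se
    p_raw <- 2 * stats::pt(-abs(t_stat), df_res)
    p_adj <- pmin(1, k * p_raw)
  }
  per_fragment <- tibble::tibble(
    test = as.character(cell$test),
    control_mean = cell$m_control, control_sd = cell$s_control,
    control_n = cell$n_control,
    case_mean = cell$m_case, case_sd = cell$s_case, case_n = cell$n_case,
    diff = delta, t = t_stat, df = if (zero_var) NA_real_ else df_res,
    p_adj = p_adj,
    zero_variance = zero_var,
    stars = star_code(p_adj, cfg)
  )
  # preserve axis order
  per_fragment <- per_fragment[match(frags, per_fragment$test), ]
  structure(list(per_fragment = per_fragment,
                 anova_table = aov_tbl,
                 family_size = k,
                 cfg = cfg),
            class = "loop_anova")
}

#' @export
print.loop_anova <- function(x, ...) {
  cat("Two-way ANOVA (group x fragment), Bonferroni family =",
      x$family_size, "fragments\n")
  print(x$per_fragment)
  invisible(x)
}

#' Tidy a `loop_anova`
#'
#' @param x A `loop_anova` object.
#' @param ... Unused.
#' @return The per-fragment contrast tibble.
#' @method tidy loop_anova
#' @export
tidy.loop_anova <- function(x, ...) x$per_fragment

#' Glance at a `loop_anova`
#'
#' @param x A `loop_anova` object.
#' @param ... Unused.
#' @return One-row tibble with the omnibus F statistics and p values for the
#'   group, fragment and interaction terms.
#' @method glance loop_anova
#' @export
glance.loop_anova <- function(x, ...) {
  tb <- x$anova_table
  tibble::tibble(
    f_group = tb["group", "F value"],
    f_fragment = tb["test", "F value"],
    f_interaction = tb["group:test", "F value"],
    p_group = tb["group", "Pr(>F)"],
    p_fragment = tb["test", "Pr(>F)"],
    p_interaction = tb["group:test", "Pr(>F)"],
    df_residual = tb["Residuals", "Df"],
    mse = tb["Residuals", "Mean Sq"]
  )
}

#' Classify regions of interaction
#'
#' Applies the category rules to a per-fragment contrast table: a fragment is
#' `unchanged` when its adjusted p exceeds 0.05; otherwise `novel` when the
#' control mean sits below the presence floor while the case mean does not,
#' `lost` in the mirror situation, and `increased` / `decreased` by the sign
#' of (case - control). The presence floor is
#' `presence_epsilon_fraction * profile_max`; a mean exactly at the floor
#' counts as present.
#'
#' @param contrasts Per-fragment tibble ([tidy()][tidy.loop_anova] of
#'   [anova_profiles()], or any tibble with `control_mean`, `case_mean`,
#'   `p_adj`).
#' @param cfg A [stat_config()].
#' @param profile_max Maximum control-or-case mean of the anchor profile;
#'   computed from `contrasts` when `NULL`.
#' @return `contrasts` with `category` and `stars` columns, class
#'   `roi_table`.
#' @export
classify_rois <- function(contrasts, cfg = stat_config(),
                          profile_max = NULL) {
  if (any(contrasts$control_mean < 0 | contrasts$case_mean < 0,
          na.rm = TRUE)) {
    stop("negative interaction means", call. = FALSE)
  }
  if (is.null(profile_max)) {
    profile_max <- max(c(contrasts$control_mean, contrasts$case_mean),
                       na.rm = TRUE)
  }
  if (!is.finite(profile_max) || profile_max <= 0) {
    stop("profile_max must be positive", call. = FALSE)
  }
  eps <- cfg$presence_epsilon_fraction * profile_max
  cat_one <- function(ctrl, cs, p) {
    if (is.na(p) || p > 0.05) return("unchanged")
    ctrl_absent <- ctrl < eps
    case_absent <- cs < eps
    if (ctrl_absent && !case_absent) return("novel")
    if (case_absent && !ctrl_absent) return("lost")
    if (cs > ctrl) "increased" else "decreased"
  }
  out <- tibble::as_tibble(contrasts)
  out$category <- mapply(cat_one, out$control_mean, out$case_mean, out$p_adj)
  out$stars <- star_code(out$p_adj, cfg)
  class(out) <- c("roi_table", class(out))
  out
}

#' Differential calling in one step
#'
#' Runs [anova_profiles()] then [classify_rois()] on two groups of per-assay
#' frequencies.
#'
#' @inheritParams anova_profiles
#' @inheritParams classify_rois
#' @return A `roi_table` tibble.
#' @export
call_rois <- function(control, case, cfg = stat_config(),
                      profile_max = NULL) {
  fit <- anova_profiles(control, case, cfg)
  classify_rois(fit$per_fragment, cfg, profile_max)
}

#' Summarize ROIs by annotated element pairs
#'
#' Maps each test fragment to its enclosing annotated element, or to the
#' nearest element by midpoint distance when none encloses it (ties go to the
#' upstream element); fragments beyond the annotation span are labelled
#' `unannotated`, never dropped. Rows are ordered by fragment coordinate.
#'
#' @param rois A `roi_table` carrying fragment coordinates (`chrom`, `start`,
#'   `end`) and an `anchor` column.
#' @param elements Element tibble ([read_elements()] output) excluding
#'   primer rows.
#' @return Tibble keyed by (anchor element, test element) with category and
#'   statistics.
#' @export
build_interactome_table <- function(rois, elements) {
  if (nrow(rois) == 0) {
    return(tibble::tibble(anchor_element = character(),
                          test_element = character()))
  }
  ann <- elements[!elements$kind %in% c("anchor_primer", "test_primer"), ]
  map_element <- function(start, end) {
    if (is.na(start) || nrow(ann) == 0) return("unannotated")
    mid <- (start + end) / 2
    enclosing <- which(ann$start <= mid & mid < ann$end)
    if (length(enclosing) > 0) return(ann$name[enclosing[1]])
    span <- range(c(ann$start, ann$end))
    if (mid < span[1] - (span[2] - span[1]) || mid > span[2] +
        (span[2] - span[1])) {
      return("unannotated")
    }
    d <- abs((ann$start + ann$end) / 2 - mid)
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[which.min(ann$start[best])]
    ann$name[best]
  }
  out <- tibble::as_tibble(rois)
  out$test_element <- mapply(map_element, out$start, out$end)
  out$anchor_element <- out$anchor
  dplyr::arrange(out, .data$start)
}
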