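# Independent oracles used to check the implementation by a different route.

# character-by-character motif scan digestion (left-to-right greedy)
naive_digest <- function(seq, region_start, motif, cut_offset) {
  seq <- toupper(seq)
  n <- nchar(seq)
  m <- nchar(motif)
  cuts <- integer(0)
  i <- 1
  while (i <= n - m + 1) {
    if (substr(seq, i, i + m - 1) == motif) {
      cuts <- c(cuts, (i - 1) + cut_offset)  # 0-based cut position
      i <- i + m  # greedy: skip past the accepted occurrence
    } else {
      i <- i + 1
    }
  }
  cuts <- cuts[cuts > 0 & cuts < n]
  bounds <- c(0L, cuts, n)
  data.frame(start = region_start + bounds[-length(bounds)],
             end = region_start + bounds[-1])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# explicit sums-of-squares two-way ANOVA for a balanced design, plus the
# Bonferroni per-fragment group contrasts with pooled error
hand_anova <- function(dat, n_frag) {
  y <- dat$frequency
  grand <- mean(y)
  ss_tot <- sum((y - grand)^2)
  grp_means <- tapply(y, dat$group, mean)
  grp_n <- tapply(y, dat$group, length)
  ss_a <- sum(grp_n * (grp_means - grand)^2)
  frg_means <- tapply(y, dat$test, mean)
  frg_n <- tapply(y, dat$test, length)
  ss_b <- sum(frg_n * (frg_means - grand)^2)
  cellkey <- interaction(dat$group, dat$test)
  cell_means <- tapply(y, cellkey, mean)
  cell_n <- tapply(y, cellkey, length)
  ss_cells <- sum(cell_n * (cell_means - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- ss_tot - ss_cells
  df_a <- length(grp_means) - 1
  df_b <- length(frg_means) - 1
  df_ab <- df_a * df_b
  df_e <- length(y) - length(cell_means)
  mse <- ss_e / df_e
  list(
    f_group = (ss_a / df_a) / mse,
    f_fragment = (ss_b / df_b) / mse,
    f_interaction = (ss_ab / df_ab) / mse,
    mse = mse, df_e = df_e,
    contrast_p = vapply(levels(factor(dat$test)), function(f) {
      yc <- y[dat$test == f & dat$group == "control"]
      ys <- y[dat$test == f & dat$group == "case"]
      tstat <- (mean(ys) - mean(yc)) /
        sqrt(mse * (1 / length(yc) + 1 / length(ys)))
      min(1, n_frag * 2 * stats::pt(-abs(tstat), df_e))
    }, 0)
  )
}

# exhaustive minimum over the two possible green-red matchings
brute_force_pairing <- function(g, r) {
  dA <- sqrt(sum((g[1, ] - r[1, ])^2)) + sqrt(sum((g[2, ] - r[2, ])^2))
  dB <- sqrt(sum((g[1, ] - r[2, ])^2)) + sqrt(sum((g[2, ] - r[1, ])^2))
  if (dB < dA) {
    c(sqrt(sum((g[1, ] - r[2, ])^2)), sqrt(sum((g[2, ] - r[1, ])^2)))
  } else {
    c(sqrt(sum((g[1, ] - r[1, ])^2)), sqrt(sum((g[2, ] - r[2, ])^2)))
  }
}

random_spot_table <- function(n_nuclei, spread = 2) {
  tibble::tibble(
    nucleus_id = rep(sprintf("n%04d", seq_len(n_nuclei)), each = 4),
    channel = rep(c("green_ICR1", "red_ICR2"), times = 2 * n_nuclei),
    x_um = stats::runif(4 * n_nuclei, -spread, spread),
    y_um = stats::runif(4 * n_nuclei, -spread, spread),
    z_um = stats::runif(4 * n_nuclei, -spread, spread)
  )
}

# random balanced two-group frequency design in long form
random_balanced_design <- function(n_frag, n_per_cell) {
  frags <- paste0("frag_", seq_len(n_frag))
  expand_g <- function(group) {
    tibble::tibble(
      test = rep(frags, each = n_per_cell),
      frequency = stats::runif(n_frag * n_per_cell, 0, 2),
      group = group
    )
  }
  rbind(expand_g("control"), expand_g("case"))
}
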