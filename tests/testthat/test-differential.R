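long_group <- function(values_by_frag) {
  # values_by_frag: named list frag -> numeric vector of assay values
  tibble::tibble(
    test = rep(names(values_by_frag), lengths(values_by_frag)),
    frequency = unlist(values_by_frag, use.names = FALSE)
  )
}

test_that("identical groups give adjusted p = 1 everywhere", {
  g <- long_group(list(frag_2 = c(1, 1), frag_3 = c(1, 1),
                       frag_4 = c(1, 1)))
  fit <- anova_profiles(g, g)
  expect_equal(tidy(fit)$p_adj, rep(1, 3))
  expect_equal(tidy(fit)$stars, rep("ns", 3))
  expect_true(all(tidy(fit)$zero_variance))
})

test_that("a single strongly shifted fragment is the only significant one", {
  withr::local_seed(3)
  noise <- function() rnorm(2, 0, 0.05)
  ctrl <- long_group(list(frag_2 = 1 + noise(), frag_3 = 1 + noise(),
                          frag_4 = 1 + noise()))
  case <- long_group(list(frag_2 = 1 + noise(), frag_3 = 2 + noise(),
                          frag_4 = 1 + noise()))
  fit <- anova_profiles(ctrl, case)
  td <- tidy(fit)
  expect_true(td$p_adj[td$test == "frag_3"] < 0.05)
  expect_true(all(td$p_adj[td$test != "frag_3"] > 0.05))
})

test_that("F statistics and Bonferroni contrasts match the sums-of-squares oracle", {
  withr::local_seed(19)
  for (i in 1:8) {
    n_frag <- sample(2:4, 1)
    n_cell <- sample(2:6, 1)
    dat <- random_balanced_design(n_frag, n_cell)
    ctrl <- dat[dat$group == "control", c("test", "frequency")]
    case <- dat[dat$group == "case", c("test", "frequency")]
    fit <- anova_profiles(ctrl, case)
    oracle <- hand_anova(dat, n_frag)
    gl <- glance(fit)
    expect_equal(gl$f_group, oracle$f_group)
    expect_equal(gl$f_fragment, oracle$f_fragment)
    expect_equal(gl$f_interaction, oracle$f_interaction)
    expect_equal(gl$mse, oracle$mse)
    td <- tidy(fit)
    expect_equal(td$p_adj, unname(oracle$contrast_p[td$test]))
  }
})

test_that("singleton groups and mismatched axes are rejected", {
  g1 <- long_group(list(frag_2 = 1))
  g2 <- long_group(list(frag_2 = c(1, 1)))
  expect_error(anova_profiles(g1, g2), "fewer than two assays")
  g3 <- long_group(list(frag_9 = c(1, 1)))
  expect_error(anova_profiles(g2, g3), "same fragment axis")
})

test_that("ROI categories follow the presence floor and significance rules", {
  base <- tibble::tibble(
    test = c("a", "b", "c"),
    control_mean = c(1.0, 0.02, 0.9),
    case_mean = c(1.8, 0.9, 0.9),
    p_adj = c(0.001, 1e-5, 0.6)
  )
  rois <- classify_rois(base, profile_max = 1.0)
  expect_equal(rois$category, c("increased", "novel", "unchanged"))
  expect_equal(rois$stars, c("***", "****", "ns"))

  lost <- classify_rois(tibble::tibble(
    test = "a", control_mean = 0.9, case_mean = 0.02, p_adj = 1e-5),
    profile_max = 1.0)
  expect_equal(lost$category, "lost")

  # exactly at the floor counts as present -> decreased, not lost
  at_floor <- classify_rois(tibble::tibble(
    test = "a", control_mean = 0.9, case_mean = 0.05, p_adj = 1e-5),
    profile_max = 1.0)
  expect_equal(at_floor$category, "decreased")

  expect_error(classify_rois(tibble::tibble(
    test = "a", control_mean = -1, case_mean = 1, p_adj = 0.5)),
    "negative")
})

test_that("lowering the presence floor only moves novel/lost to increased/decreased", {
  withr::local_seed(5)
  for (i in 1:20) {
    tbl <- tibble::tibble(
      test = paste0("f", 1:6),
      control_mean = runif(6, 0, 1),
      case_mean = runif(6, 0, 1),
      p_adj = runif(6, 0, 0.2)
    )
    hi <- classify_rois(tbl, stat_config(presence_epsilon_fraction = 0.2),
                        profile_max = 1)
    lo <- classify_rois(tbl, stat_config(presence_epsilon_fraction = 0.02),
                        profile_max = 1)
    moved <- hi$category != lo$category
    expect_true(all(hi$category[moved] %in% c("novel", "lost")))
    expect_true(all(lo$category[moved] %in% c("increased", "decreased")))
    # direction preserved
    expect_true(all((hi$category == "novel")[moved] ==
                      (lo$category == "increased")[moved]))
  }
})

test_that("swapping control and case mirrors the calls and keeps p-values", {
  withr::local_seed(23)
  dat <- random_balanced_design(4, 3)
  ctrl <- dat[dat$group == "control", c("test", "frequency")]
  case <- dat[dat$group == "case", c("test", "frequency")]
  fwd <- call_rois(ctrl, case, profile_max = 2)
  rev <- call_rois(case, ctrl, profile_max = 2)
  expect_equal(fwd$p_adj, rev$p_adj)
  swap <- c(unchanged = "unchanged", increased = "decreased",
            decreased = "increased", novel = "lost", lost = "novel")
  expect_equal(unname(swap[fwd$category]), rev$category)
})

test_that("interactome table maps fragments to enclosing or nearest elements", {
  elements <- tibble::tibble(
    chrom = "chr11",
    start = c(100, 500), end = c(200, 600),
    name = c("Enh_A", "ICR1"), kind = c("enhancer", "ICR")
  )
  rois <- tibble::tibble(
    anchor = "ICR1", test = c("f1", "f2", "f3"),
    control_mean = 1, case_mean = 1, p_adj = 1,
    category = "unchanged", chrom = "chr11",
    start = c(120, 320, 5000), end = c(180, 400, 5100)
  )
  tab <- build_interactome_table(rois, elements)
  expect_equal(tab$test_element, c("Enh_A", "ICR1", "unannotated"))
  expect_equal(tab$anchor_element, rep("ICR1", 3))
  # midpoint tie between the two elements goes to the upstream one
  tie <- rois[1, ]
  tie$start <- 300; tie$end <- 400  # midpoint 350, equidistant from 150/550
  expect_equal(build_interactome_table(tie, elements)$test_element, "Enh_A")
  empty <- build_interactome_table(rois[0, ], elements)
  expect_equal(nrow(empty), 0)
})
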