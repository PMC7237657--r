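spot_rows <- function(id, g, r) {
  tibble::tibble(
    nucleus_id = id,
    channel = rep(c("green_ICR1", "red_ICR2"), c(nrow(g), nrow(r))),
    x_um = c(g[, 1], r[, 1]), y_um = c(g[, 2], r[, 2]),
    z_um = c(g[, 3], r[, 3])
  )
}

test_that("nucleus QC requires exactly two spots per channel", {
  ok <- spot_rows("n1", matrix(0, 2, 3), matrix(1, 2, 3))
  miss <- spot_rows("n2", matrix(0, 1, 3), matrix(1, 2, 3))
  extra <- spot_rows("n3", matrix(0, 3, 3), matrix(1, 2, 3))
  qc <- qc_nuclei(rbind(ok, miss, extra))
  expect_equal(qc$pass, c(TRUE, FALSE, FALSE))
  expect_match(qc$reason[2], "1 green")
  expect_error(pair_doublets(rbind(miss, extra)), "no nucleus passed QC")
})

test_that("doublet pairing picks the distance-minimizing matching", {
  g <- rbind(c(0, 0, 0), c(5, 0, 0))
  r <- rbind(c(0.1, 0, 0), c(5.2, 0, 0))
  al <- pair_doublets(spot_rows("n1", g, r))
  expect_equal(al$cis_distance, c(0.1, 0.2))
  # crossed input order still pairs nearest
  al2 <- pair_doublets(spot_rows("n1", g, r[c(2, 1), ]))
  expect_equal(sort(al2$cis_distance), c(0.1, 0.2))
})

test_that("pairing equals the brute-force matching oracle on random nuclei", {
  withr::local_seed(99)
  spots <- random_spot_table(200)
  al <- pair_doublets(spots)
  for (id in unique(spots$nucleus_id)) {
    df <- spots[spots$nucleus_id == id, ]
    g <- as.matrix(df[df$channel == "green_ICR1", c("x_um", "y_um", "z_um")])
    r <- as.matrix(df[df$channel == "red_ICR2", c("x_um", "y_um", "z_um")])
    want <- brute_force_pairing(g, r)
    got <- al$cis_distance[al$nucleus_id == id]
    expect_equal(sum(got), sum(want), tolerance = 1e-12)
  }
})

test_that("pairing is tie-broken by index and invariant to rigid motion", {
  # unit square: both matchings cost 2 -> index-order pairing g1-r1
  g <- rbind(c(0, 0, 0), c(1, 1, 0))
  r <- rbind(c(1, 0, 0), c(0, 1, 0))
  al <- pair_doublets(spot_rows("n1", g, r))
  expect_equal(al$cis_distance, c(1, 1))
  expect_equal(al$g_x, c(0, 1))
  expect_equal(al$r_x, c(1, 0))

  withr::local_seed(17)
  spots <- random_spot_table(30)
  base <- pair_doublets(spots)
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, byrow = TRUE)
  xyz <- as.matrix(spots[, c("x_um", "y_um", "z_um")]) %*% t(rot)
  moved <- spots
  moved$x_um <- xyz[, 1] + 5; moved$y_um <- xyz[, 2] - 3
  moved$z_um <- xyz[, 3] + 0.5
  expect_equal(pair_doublets(moved)$cis_distance, base$cis_distance,
               tolerance = 1e-9)
})

test_that("cis and trans cutoffs are boundary-inclusive", {
  cfg <- fish_config()
  expect_true(classify_allele(0.35, cfg))
  expect_false(classify_allele(0.3501, cfg))
  expect_true(classify_allele(0, cfg))
  expect_error(classify_allele(-0.1, cfg), "negative")

  expect_equal(classify_nucleus(TRUE, TRUE), "plus_plus")
  expect_equal(classify_nucleus(TRUE, FALSE), "plus_minus")
  expect_equal(classify_nucleus(FALSE, FALSE), "minus_minus")

  # two doublets exactly 1 um apart -> trans; 2.5 um -> not
  mk <- function(sep) {
    g <- rbind(c(0, 0, 0), c(sep, 0, 0))
    r <- rbind(c(0, 0, 0), c(sep, 0, 0))
    classify_nuclei(pair_doublets(spot_rows("n1", g, r)), cfg)
  }
  expect_true(mk(0.9)$trans)
  expect_true(mk(1.0)$trans)
  expect_false(mk(2.5)$trans)
})

test_that("line summaries reproduce the reference cohort percentages", {
  counts <- fish_reference_counts()
  s <- summarize_line(counts)
  expect_equal(s$n_nuclei, c(302L, 290L, 308L))
  expect_equal(round(s$pct_plus_plus, 2), c(25.50, 20.34, 7.47))
  expect_equal(round(s$pct_plus_minus, 2), c(40.07, 44.48, 42.53))
  expect_equal(round(s$pct_minus_minus, 2), c(34.44, 35.17, 50.00))
  expect_equal(round(s$allele_coloc_pct, 2), c(45.53, 42.59, 28.73))
})

test_that("pooling counts versus averaging line rates follow their conventions", {
  s <- summarize_line(fish_reference_counts())
  pooled <- pool_lines(s[1:2, ], "pooled_counts", label = "CTRLs")
  expect_equal(round(pooled$pct_plus_plus, 2), 22.97)
  expect_equal(round(pooled$pct_plus_minus, 2), 42.23)
  expect_equal(round(pooled$pct_minus_minus, 2), 34.80)
  ml <- pool_lines(s[1:2, ], "mean_of_lines", label = "CTRLs")
  expect_equal(round(ml$allele_coloc_pct, 2), 44.06)
  # single line: both modes are the identity
  one_p <- pool_lines(s[1, ], "pooled_counts")
  one_m <- pool_lines(s[1, ], "mean_of_lines")
  expect_equal(one_p$pct_plus_plus, s$pct_plus_plus[1])
  expect_equal(one_m$allele_coloc_pct, s$allele_coloc_pct[1])
  expect_error(pool_lines(s[0, ]), "no summaries")
})

test_that("summary counts conserve nuclei and alleles on simulated data", {
  s <- sim_scenario(n_nuclei = 120, p_cis = 0.5, seed = 31)
  res <- analyze_fish(simulate_fish_line(s), line = "sim")
  sm <- res$summary
  expect_equal(sm$n_plus_plus + sm$n_plus_minus + sm$n_minus_minus,
               sm$n_nuclei)
  expect_equal(2 * sm$n_plus_plus + sm$n_plus_minus,
               sum(res$alleles$colocalized))
  expect_equal(sm$allele_coloc_pct,
               100 * mean(res$alleles$colocalized))
})

test_that("the cumulative distance table is a proper ECDF in percent", {
  tab <- ecdf_table(c(0.1, 0.2, 0.3), step = 0.05)
  expect_equal(tab$cum_pct[tab$distance_um == 0.35], 100)
  tab2 <- ecdf_table(c(0.1, 0.5), step = 0.05)
  expect_equal(tab2$cum_pct[tab2$distance_um == 0.35], 50)
  withr::local_seed(4)
  d <- runif(200, 0, 2)
  tab3 <- ecdf_table(d)
  expect_true(all(diff(tab3$cum_pct) >= 0))
  expect_equal(max(tab3$cum_pct), 100)
  # ECDF at the cis cutoff equals the allele colocalization rate
  expect_equal(tab3$cum_pct[tab3$distance_um == 0.35],
               100 * mean(d <= 0.35))
  expect_error(ecdf_table(numeric()), "no distances")
})

test_that("line comparisons run Fisher and t tests with degenerate guards", {
  mk_sum <- function(line, pp, pm, mm, tr = NA_integer_) {
    summarize_line(tibble::tibble(n_plus_plus = pp, n_plus_minus = pm,
                                  n_minus_minus = mm, n_trans = tr),
                   line = line)
  }
  # perfectly separated 10-vs-10 table: p = 2 / C(20,10)
  a <- mk_sum("A", 10, 0, 0)
  b <- mk_sum("B", 0, 10, 0)
  cmp <- suppressWarnings(compare_lines(a, b))  # -/- table is degenerate
  p_pp <- tidy(cmp)$p_value[tidy(cmp)$test == "fisher_plus_plus"]
  expect_equal(p_pp, 2 / choose(20, 10), tolerance = 1e-9)

  # identical proportions -> p = 1
  same <- compare_lines(mk_sum("A", 5, 5, 10), mk_sum("B", 5, 5, 10))
  expect_equal(tidy(same)$p_value, rep(1, 3))

  # zero-margin category table -> warning and p = 1
  expect_warning(z <- compare_lines(mk_sum("A", 0, 10, 10),
                                    mk_sum("B", 0, 5, 15)),
                 "degenerate")
  expect_equal(tidy(z)$p_value[tidy(z)$test == "fisher_plus_plus"], 1)

  # distances engage the unpaired t-test
  withr::local_seed(8)
  cmp_t <- suppressWarnings(
    compare_lines(a, b, ctrl_distances = rnorm(50, 0.3, 0.05),
                  case_distances = rnorm(50, 0.6, 0.05)))
  td <- tidy(cmp_t)
  expect_true(td$p_value[td$test == "t_cis_distance"] < 1e-6)
  expect_equal(td$stars[td$test == "t_cis_distance"], "****")
})

test_that("plot helpers return ggplot objects", {
  s <- summarize_line(fish_reference_counts())
  expect_s3_class(plot_fish_categories(s), "ggplot")
  expect_s3_class(plot_cis_ecdf(list(a = runif(20, 0, 2))), "ggplot")
})
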