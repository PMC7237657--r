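band_row <- function(i3c, ictrl, sample = "CTRL1", replicate = 1,
                     test = "frag_2") {
  tibble::tibble(sample = sample, replicate = replicate, anchor = "ICR1",
                 test = test, intensity_3c = i3c, intensity_ctrl = ictrl)
}

test_that("normalization is the 3C / control-template intensity ratio", {
  expect_equal(normalize_bands(band_row(1200, 600))$frequency, 2)
  expect_equal(normalize_bands(band_row(0, 600))$frequency, 0)
  expect_warning(out <- normalize_bands(band_row(500, 0)), "undetectable")
  expect_true(out$undetectable_ctrl)
  expect_true(is.na(out$frequency))
  expect_error(normalize_bands(band_row(-1, 10)), "non-negative")
  dup <- rbind(band_row(1, 1), band_row(2, 1))
  expect_error(normalize_bands(dup), "duplicate")
})

test_that("frequencies are invariant to rescaling a replicate's intensities", {
  withr::local_seed(7)
  b <- dplyr::bind_rows(lapply(1:4, function(r) {
    band_row(runif(3, 0, 100), runif(3, 1, 50), replicate = r,
             test = paste0("frag_", 2:4))
  }))
  f1 <- normalize_bands(b)$frequency
  b2 <- b
  scale_by <- rep(c(3.7, 0.2, 11, 1.5), each = 3)
  b2$intensity_3c <- b2$intensity_3c * scale_by
  b2$intensity_ctrl <- b2$intensity_ctrl * scale_by
  expect_equal(normalize_bands(b2)$frequency, f1)
  expect_true(all(f1 >= 0))
})

test_that("replicate aggregation gives mean and sample SD", {
  expect_equal(aggregate_replicates(c(1, 1)),
               tibble::tibble(mean = 1, sd = 0, n_reps = 2L))
  agg <- aggregate_replicates(c(0.8, 1.2))
  expect_equal(agg$mean, 1)
  expect_equal(agg$sd, sqrt(sum((c(0.8, 1.2) - 1)^2) / 1))  # 0.2828...
  expect_equal(round(agg$sd, 4), 0.2828)
  expect_error(aggregate_replicates(numeric()), "no replicate")
})

test_that("looping profiles cover the axis with gaps kept explicit", {
  b <- dplyr::bind_rows(
    band_row(c(10, 20, 30), c(10, 10, 10), replicate = 1,
             test = paste0("frag_", 2:4)),
    band_row(c(12, 18, 30), c(10, 10, 10), replicate = 2,
             test = paste0("frag_", 2:4))
  )
  prof <- build_looping_profile(b, "CTRL1", "ICR1", paste0("frag_", 2:4))
  expect_equal(nrow(prof), 3)
  expect_equal(prof$n_reps, rep(2L, 3))
  expect_equal(prof$mean, c(1.1, 1.9, 3.0))
  expect_equal(prof$sd[3], 0)  # equal replicates

  expect_warning(
    gap <- build_looping_profile(b, "CTRL1", "ICR1", paste0("frag_", 2:5)),
    "gaps")
  expect_true(is.na(gap$mean[4]))
  expect_equal(gap$n_reps[4], 0L)

  expect_error(build_looping_profile(b, "CTRL1", "ICR2", "frag_2"),
               "no measurements")
})

test_that("control pooling averages individual assays, not line means", {
  b <- dplyr::bind_rows(
    band_row(1, 1, "CTRL1", 1), band_row(1, 1, "CTRL1", 2),
    band_row(2, 1, "CTRL2", 1), band_row(2, 1, "CTRL2", 2)
  )
  pooled <- pool_control_profiles(b, c("CTRL1", "CTRL2"), "ICR1", "frag_2")
  expect_equal(pooled$mean, 1.5)
  expect_equal(pooled$n_reps, 4L)
  expect_equal(pooled$sd, sd(c(1, 1, 2, 2)))
  expect_warning(
    single <- pool_control_profiles(b[1:2, ], "CTRL1", "ICR1", "frag_2"),
    "single control line")
  expect_equal(single$n_reps, 2L)
})

test_that("control-template uniformity check reports CV", {
  eq <- validate_control_template(c(50, 50, 50))
  expect_equal(eq$cv, 0)
  expect_true(eq$pass)
  cv <- validate_control_template(c(100, 300))
  expect_equal(round(cv$cv, 3), 0.707)
  expect_false(cv$pass)
  expect_error(validate_control_template(c(0, 0)), "zero")
  expect_error(validate_control_template(100), "at least two")
})

test_that("noise-free synthetic bands recover the truth profile exactly", {
  truth <- c(frag_2 = 0.8, frag_3 = 0, frag_4 = 2.3)
  s <- sim_scenario(truth_profile = truth, band_noise_cv = 0, seed = 11)
  bands <- simulate_3c_bands(s, sample = "SIM", anchor = "ICR1")
  prof <- build_looping_profile(bands, "SIM", "ICR1", names(truth))
  expect_equal(prof$mean, unname(truth))
  expect_equal(prof$sd, c(0, 0, 0))
})

test_that("max-normalization rescales the profile peak to one", {
  b <- dplyr::bind_rows(
    band_row(c(10, 40), c(10, 10), replicate = 1, test = c("frag_2", "frag_3")),
    band_row(c(10, 40), c(10, 10), replicate = 2, test = c("frag_2", "frag_3")))
  prof <- build_looping_profile(b, "CTRL1", "ICR1", c("frag_2", "frag_3"))
  norm <- max_normalize_profile(prof)
  expect_equal(max(norm$mean), 1)
  expect_equal(norm$mean, c(0.25, 1))
})

test_that("band and profile tables round-trip through TSV", {
  b <- normalize_bands(band_row(10, 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(b[, 1:6], path)
  expect_equal(read_bands(path)$intensity_3c, 10)
  prof <- build_looping_profile(b, "CTRL1", "ICR1", "frag_2")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, p2)
  expect_equal(readr::read_tsv(p2, show_col_types = FALSE)$mean, 2)
})
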