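test_that("toy series cover the stated kinds and are reproducible", {
  expect_equal(gen_toy_series("constant", length = 10, value = 1), rep(1, 10))

  x <- gen_toy_series("sine", length = 100, period = 10, noise_sd = 0)
  ac <- stats::cor(x[1:90], x[11:100])  # lag-10 autocorrelation
  expect_gt(ac, 0.95)

  expect_identical(gen_toy_series("white_noise", length = 50, seed = 7),
                   gen_toy_series("white_noise", length = 50, seed = 7))

  d <- gen_toy_series("disrupted", length = 90, n_breaks = 2, jump = 5,
                      noise_sd = 0.01, seed = 1)
  expect_gt(mean(d[31:60]), mean(d[1:30]) + 3)  # level shift in middle segment

  expect_true(all(is.finite(gen_toy_series("drift", length = 50, seed = 2))))
  expect_error(gen_toy_series("sawtooth", length = 10), "unknown toy series kind")
  expect_error(gen_toy_series("constant", length = 1), "length")
})

test_that("gen_volume honours shape, bounds, masks and the zero-sill case", {
  spec <- small_volume_spec(n_slices = 3, side = 32, sill = 0)
  v <- gen_volume(spec)
  expect_equal(c(v$n_slices, v$height, v$width), c(3, 32, 32))
  expect_true(all(vapply(v$slices, function(s) all(s >= 0 & s <= 1), logical(1))))
  # rows above the bone region are pure background, below the 0.5 mask
  top <- v$slices[[1]][seq_len(spec$bone_row_start - 1L), ]
  expect_true(all(top < 0.5))
  # zero sill: constant foreground, zero semi-variogram
  fg <- v$slices[[2]][spec$bone_row_start:32, ]
  expect_true(all(fg == 0.75))
  sv <- slice_semivariogram(v$slices[[2]], small_variogram_config(side = 32))
  expect_identical(sv$gamma, 0)
})

test_that("gen_volume foreground variance tracks the sill", {
  spec <- small_volume_spec(n_slices = 1, side = 128, sill = 0.005, seed = 11)
  v <- gen_volume(spec)
  fg <- v$slices[[1]][spec$bone_row_start:128, ]
  expect_lt(abs(stats::var(as.vector(fg)) - spec$sill) / spec$sill, 0.25)
})

test_that("mean semi-variogram is increasing in sill (Monte Carlo)", {
  cfg <- small_variogram_config(side = 48, n_slices = 4)
  mean_gamma <- function(sill, seed) {
    v <- gen_volume(small_volume_spec(n_slices = 4, side = 48, sill = sill,
                                      seed = seed))
    mean(semivariogram_series(v, cfg)$values)
  }
  lo <- vapply(1:10, function(s) mean_gamma(0.01, s), numeric(1))
  hi <- vapply(1:10, function(s) mean_gamma(0.04, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("gen_cohort produces a labelled, reproducible two-group design", {
  spec <- cohort_spec(n_per_group = 5, base = small_volume_spec(n_slices = 2,
                                                               side = 16),
                      group_effect = 0.002, seed = 3)
  coh <- gen_cohort(spec)
  expect_length(coh, 10)
  expect_equal(vapply(coh, `[[`, character(1), "group"),
               rep(c("low", "high"), each = 5))
  coh2 <- gen_cohort(spec)
  expect_identical(coh, coh2)
})

test_that("zero group effect gives no systematic group difference", {
  cfg <- small_variogram_config(side = 32, n_slices = 3)
  diffs <- vapply(1:20, function(s) {
    coh <- gen_cohort(cohort_spec(n_per_group = 2,
                                  base = small_volume_spec(n_slices = 3,
                                                           side = 32, seed = 1),
                                  group_effect = 0, seed = s))
    gm <- vapply(coh, function(el)
      mean(semivariogram_series(el$volume, cfg)$values), numeric(1))
    grp <- vapply(coh, `[[`, character(1), "group")
    mean(gm[grp == "high"]) - mean(gm[grp == "low"])
  }, numeric(1))
  wins <- sum(diffs > 0)
  expect_gte(wins, 3)   # a systematic effect would push this toward 0 or 20
  expect_lte(wins, 17)
})

test_that("invalid specs are rejected", {
  expect_error(volume_spec(background_level = 0.6), "background_level")
  expect_error(volume_spec(sill = -1), "sill")
  expect_error(volume_spec(corr_range = 0), "corr_range")
  expect_error(volume_spec(n_slices = 0), "n_slices")
  expect_error(cohort_spec(n_per_group = 0), "n_per_group")
  expect_error(cohort_spec(group_effect = -0.1), "group_effect")
})
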