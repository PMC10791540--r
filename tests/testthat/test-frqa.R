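test_that("binarization separates modes and handles degenerate input", {
  # already binary: idempotent
  set.seed(1)
  B0 <- random_binary_matrix(15)
  expect_equal(unclass(binarize(B0 * 1.0)), B0, ignore_attr = TRUE)
  # bimodal {0.1, 0.9}: any between-mode threshold separates exactly
  R <- matrix(sample(c(0.1, 0.9), 100, TRUE), 10, 10)
  B <- binarize(R)
  expect_equal(unclass(B), matrix(as.integer(R == 0.9), 10, 10),
               ignore_attr = TRUE)
  thr <- attr(B, "threshold")
  expect_true(thr > 0.1 && thr <= 0.9)
  # constant matrix: documented 0.5 fallback
  expect_warning(Bc <- binarize(matrix(0.7, 5, 5)), "constant")
  expect_true(all(unclass(Bc) == 1L))
  expect_warning(Bz <- binarize(matrix(0.3, 5, 5)), "constant")
  expect_true(all(unclass(Bz) == 0L))
})

test_that("line histograms count maximal runs correctly", {
  # all zeros: empty histograms
  h0 <- line_histograms(matrix(0L, 8, 8))
  expect_equal(sum(h0$diagonal), 0)
  expect_equal(sum(h0$vertical), 0)
  # all ones, L = 10, LOI excluded: two diagonals of each length 1..9;
  # ten vertical runs of length 10
  h1 <- line_histograms(matrix(1L, 10, 10), exclude_loi = TRUE)
  expect_equal(h1$diagonal, rep(2L, 9))
  expect_equal(h1$vertical, c(rep(0L, 9), 10L))
  expect_equal(h1$N_D, 9)
  # a single off-diagonal run of length 7
  B <- matrix(0L, 10, 10)
  B[cbind(1:7, 2:8)] <- 1L
  h7 <- line_histograms(B)
  expect_equal(h7$diagonal[7], 1L)
  expect_equal(sum(h7$diagonal), 1L)
  # LOI inclusion extends the diagonal cap to L
  h_loi <- line_histograms(matrix(1L, 6, 6), exclude_loi = FALSE)
  expect_equal(h_loi$N_D, 6)
  expect_equal(h_loi$diagonal[6], 1L)
})

test_that("run extraction matches the naive scan oracle", {
  set.seed(21)
  for (rep in 1:8) {
    L <- sample(5:60, 1)
    B <- random_binary_matrix(L, p = runif(1, 0.2, 0.8))
    for (loi in c(TRUE, FALSE)) {
      got <- line_histograms(B, exclude_loi = loi)
      want <- oracle_line_histograms(B, exclude_loi = loi)
      expect_identical(got$diagonal, want$diagonal)
      expect_identical(got$vertical, want$vertical)
    }
  }
})

test_that("fRR evaluates the thresholded mean", {
  expect_equal(f_rr(matrix(1, 5, 5), 0.5), 1.0)
  expect_equal(f_rr(matrix(0.3, 5, 5), 0.5), 0.0)
  expect_equal(f_rr(matrix(0.6, 5, 5), 0.5), 0.6)
  # retained cells keep their grade; zeroed cells contribute nothing
  R <- matrix(c(0.9, 0.2, 0.7, 0.4), 2, 2)
  expect_equal(f_rr(R, 0.5), (0.9 + 0.7) / 4)
  expect_error(f_rr(R, 1.5), "omega")
})

test_that("diagonal measures agree with single-line hand computations", {
  B <- matrix(0L, 10, 10)
  B[cbind(1:7, 2:8)] <- 1L
  d <- diag_measures(line_histograms(B), lmin_d = 5)
  expect_equal(d$fDET, 1)
  expect_equal(d$fDIV, 1 / 7)
  expect_equal(d$fENT, 0)
  # all runs shorter than lmin: empty numerator
  B2 <- matrix(0L, 10, 10)
  B2[cbind(1:3, 2:4)] <- 1L
  expect_equal(diag_measures(line_histograms(B2), lmin_d = 5)$fDET, 0)
  # all ones, LOI excluded: longest diagonal is L - 1
  d1 <- diag_measures(line_histograms(matrix(1L, 10, 10)), lmin_d = 5)
  expect_equal(d1$fDIV, 1 / 9)
  # no diagonal runs at all: fDIV undefined
  expect_true(is.na(diag_measures(line_histograms(matrix(0L, 6, 6)))$fDIV))
})

test_that("vertical measures agree with single-line hand computations", {
  B <- matrix(0L, 10, 10)
  B[2:7, 3] <- 1L
  v <- vert_measures(line_histograms(B), lmin_v = 5)
  expect_equal(v$fLAM, 1)
  expect_equal(v$fTT, 6)
  # isolated points only
  B2 <- diag(10); diag(B2) <- 0L; B2[1, 4] <- B2[6, 9] <- 1L
  v2 <- vert_measures(line_histograms(B2), lmin_v = 5)
  expect_equal(v2$fLAM, 0)
  expect_equal(v2$fTT, 0)
  # all ones: every column is one run of length L
  v3 <- vert_measures(line_histograms(matrix(1L, 10, 10)), lmin_v = 5)
  expect_equal(v3$fLAM, 1)
  expect_equal(v3$fTT, 10)
})

test_that("measures respect their ranges and monotonicity in lmin", {
  set.seed(33)
  for (rep in 1:5) {
    B <- random_binary_matrix(30, p = 0.5)
    h <- line_histograms(B)
    prev_det <- Inf; prev_lam <- Inf
    for (lmin in 1:6) {
      d <- diag_measures(h, lmin_d = lmin)
      v <- vert_measures(h, lmin_v = lmin)
      expect_true(d$fDET >= 0 && d$fDET <= 1)
      expect_true(v$fLAM >= 0 && v$fLAM <= 1)
      expect_true(is.na(d$fDIV) || (d$fDIV > 0 && d$fDIV <= 1))
      expect_gte(d$fENT, 0)
      expect_lte(d$fDET, prev_det + 1e-12)
      expect_lte(v$fLAM, prev_lam + 1e-12)
      if (v$fLAM > 0) expect_gte(v$fTT, lmin)
      prev_det <- d$fDET; prev_lam <- v$fLAM
    }
  }
})

test_that("the frqa wrapper assembles all six measures with its parameters", {
  x <- gen_toy_series("sine", length = 60, period = 10, noise_sd = 0.05, seed = 2)
  R <- frp(fcm_partition(embed_series(x, 3, 1), c = 6, seed = 1))
  q <- frqa(R, omega = 0.5, lmin_d = 5, lmin_v = 5)
  expect_setequal(intersect(c("fRR", "fDET", "fLAM", "fTT", "fDIV", "fENT"),
                            names(q)),
                  c("fRR", "fDET", "fLAM", "fTT", "fDIV", "fENT"))
  expect_true(all(is.finite(unlist(q[c("fRR", "fDET", "fLAM", "fTT", "fENT")]))))
  expect_equal(q$omega, 0.5)
  # the alternative (unrenormalized) entropy reading is available
  q2 <- frqa(R, entropy_all_lengths = TRUE)
  expect_true(is.finite(q2$fENT))
})
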