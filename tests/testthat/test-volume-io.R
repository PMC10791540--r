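test_that("TIFF stacks round-trip bit-identically", {
  set.seed(42)
  for (bits in c(8L, 16L)) {
    maxv <- 2^bits - 1
    pages <- lapply(1:3, function(i) matrix(sample(0:maxv, 12 * 9, TRUE), 12, 9))
    tf <- withr::local_tempfile(fileext = ".tif")
    write_tiff_stack(pages, tf, bits = bits)
    v <- read_tiff_stack(tf, normalize_mode = "none")
    expect_identical(v$intensity_domain, "raw")
    expect_equal(v$n_slices, 3)
    for (i in 1:3) expect_equal(unname(v$slices[[i]]), pages[[i]] * 1.0)
    # dtype_max: the type's maximum maps to 1.0
    vn <- read_tiff_stack(tf, normalize_mode = "dtype_max")
    expect_equal(unname(vn$slices[[1]]), pages[[1]] / maxv)
  }
})

test_that("normalization modes are monotone and bounded", {
  set.seed(7)
  pages <- list(matrix(sample(100:60000, 64, TRUE), 8, 8))
  tf <- withr::local_tempfile(fileext = ".tif")
  write_tiff_stack(pages, tf, bits = 16)
  raw <- as.vector(read_tiff_stack(tf, "none")$slices[[1]])
  for (mode in c("dtype_max", "minmax")) {
    norm <- as.vector(read_tiff_stack(tf, mode)$slices[[1]])
    expect_true(all(norm >= 0 & norm <= 1))
    expect_identical(order(norm), order(raw))
  }
  # minmax maps extremes exactly
  mm <- as.vector(read_tiff_stack(tf, "minmax")$slices[[1]])
  expect_equal(range(mm), c(0, 1))
})

test_that("I/O errors name the offending path", {
  expect_error(read_tiff_stack("/nonexistent/file.tif"), "no such file")
  bad <- withr::local_tempfile(fileext = ".tif")
  writeBin(as.raw(1:4), bad)
  expect_error(read_tiff_stack(bad), "corrupt TIFF")
})

test_that("mixed slice shapes are rejected", {
  tf <- withr::local_tempfile(fileext = ".tif")
  georecur:::tiff_write(list(matrix(1L, 4, 4), matrix(1L, 5, 5)), tf, bits = 8L)
  expect_error(read_tiff_stack(tf), "height and width")
})

test_that("the independent TIFF reader agrees with ours in both directions", {
  # tifffile (Python, same image) as the external oracle for the format
  set.seed(9)
  pages <- lapply(1:2, function(i) matrix(sample(0:65535, 10 * 7, TRUE), 10, 7))
  tf <- withr::local_tempfile(fileext = ".tif")
  csv1 <- withr::local_tempfile(fileext = ".csv")
  csv2 <- withr::local_tempfile(fileext = ".csv")
  pytif <- withr::local_tempfile(fileext = ".tif")
  write_tiff_stack(pages, tf, bits = 16)
  code <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = tifffile.imread(r'%s'); np.savetxt(r'%s', a[1], fmt='%%d', delimiter=',')\n",
    "rng = np.random.default_rng(5)\n",
    "b = rng.integers(0, 65536, size=(2, 6, 11), dtype=np.uint16)\n",
    "tifffile.imwrite(r'%s', b, photometric='minisblack')\n",
    "np.savetxt(r'%s', b[0], fmt='%%d', delimiter=',')\n"),
    tf, csv1, pytif, csv2)
  status <- system2("python", "-", input = code)
  expect_identical(status, 0L)
  py_read <- unname(as.matrix(utils::read.csv(csv1, header = FALSE)))
  expect_equal(py_read, pages[[2]], ignore_attr = TRUE)
  ours <- read_tiff_stack(pytif, "none")
  py_written <- unname(as.matrix(utils::read.csv(csv2, header = FALSE)))
  expect_equal(unname(ours$slices[[1]]), py_written * 1.0, ignore_attr = TRUE)
})

test_that("series CSVs read back in all accepted layouts", {
  x <- c(0.1, 0.25, 0.3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(x, f)
  expect_equal(read_series_csv(f), x)
  writeLines(c("0.5", "0.75", "1"), f)
  expect_equal(read_series_csv(f), c(0.5, 0.75, 1))
  writeLines(c("gamma", "0.5", "0.75"), f)
  expect_equal(read_series_csv(f), c(0.5, 0.75))
  expect_error(read_series_csv("/nope.csv"), "no such file")
})
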