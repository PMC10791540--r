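#' CT volume container
#'
#' An ordered stack of 2-D intensity slices. Row 1 is the top edge of the
#' image, matching radiological display; all row indices in this package
#' (e.g. the bone mask's starting row) are 1-based from the top.
#'
#' @param slices list of numeric matrices, all the same dimensions.
#' @param intensity_domain `"normalized"` (all values in \[0, 1\]) or `"raw"`.
#' @return An object of class `ct_volume` with fields `slices`, `height`,
#'   `width`, `n_slices`, `intensity_domain`.
#' @export
ct_volume <- function(slices, intensity_domain = c("normalized", "raw")) {
  intensity_domain <- match.arg(intensity_domain)
  if (!is.list(slices) || !length(slices))
    stop_input("a ct_volume needs at least one slice")
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_input("all slices must share the same height and width")
  if (intensity_domain == "normalized") {
    rng <- range(vapply(slices, range, numeric(2)))
    if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
      stop_input("normalized volume has intensities outside [0, 1]")
  }
  structure(list(slices = slices, height = dims[1, 1], width = dims[2, 1],
                 n_slices = length(slices), intensity_domain = intensity_domain),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %d slices of %d x %d (%s intensities)\n",
              x$n_slices, x$height, x$width, x$intensity_domain))
  invisible(x)
}

#' Read a stacked (multi-page) TIFF CT volume
#'
#' Reads grayscale, uncompressed, 8- or 16-bit multi-page TIFF — the format
#' in which analysis-ready CT stacks are commonly deposited. Intensities can
#' be normalized to \[0, 1\] on read.
#'
#' @param path path to a multi-page TIFF file.
#' @param normalize_mode `"dtype_max"` divides by the pixel type's maximum
#'   (255 or 65535), so the mapping is deterministic and independent of the
#'   particular volume; `"minmax"` maps the volume's min/max affinely onto
#'   \[0, 1\]; `"none"` keeps raw integer values. Default `"dtype_max"`: a
#'   fixed intensity threshold (such as the 0.5 bone mask) then means the
#'   same physical thing for every volume, which min/max scaling would not
#'   guarantee.
#' @return A [ct_volume].
#' @export
read_tiff_stack <- function(path, normalize_mode = c("dtype_max", "minmax", "none")) {
  normalize_mode <- match.arg(normalize_mode)
  pages <- tiff_read(path)
  bits <- attr(pages, "bits")
  if (length(unique(bits)) > 1L)
    stop_io("mixed bit depths across TIFF pages in ", path)
  slices <- lapply(pages, function(m) m * 1.0)
  if (normalize_mode == "dtype_max") {
    maxv <- 2^bits[1] - 1
    slices <- lapply(slices, function(m) m / maxv)
    ct_volume(slices, "normalized")
  } else if (normalize_mode == "minmax") {
    rng <- range(vapply(slices, range, numeric(2)))
    span <- diff(rng)
    slices <- if (span == 0) lapply(slices, function(m) m * 0)
              else lapply(slices, function(m) (m - rng[1]) / span)
    ct_volume(slices, "normalized")
  } else {
    ct_volume(slices, "raw")
  }
}

#' Write a volume as a stacked TIFF
#'
#' Normalized volumes are quantized to the full range of the chosen bit
#' depth; raw volumes must already hold integers within range.
#'
#' @param volume a [ct_volume] or plain list of matrices.
#' @param path output file path.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(volume, path, bits = 16L) {
  slices <- if (inherits(volume, "ct_volume")) volume$slices else volume
  normalized <- inherits(volume, "ct_volume") &&
    volume$intensity_domain == "normalized"
  maxv <- 2^bits - 1
  pages <- lapply(slices, function(m) {
    if (normalized) round(m * maxv) else round(m)
  })
  tiff_write(pages, path, bits = as.integer(bits))
}

#' Read a plain numeric series from CSV
#'
#' Accepts one value per line (header optional) or the two-column
#' `slice_index,gamma` layout written by [write_series_csv()].
#'
#' @param path path to the CSV file.
#' @return numeric vector.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop_io("cannot read series: no such file: ", path)
  first <- readLines(path, n = 1L)
  header <- !grepl("^\\s*-?[0-9.eE+,\\s-]+$", first)
  df <- utils::read.csv(path, header = header)
  x <- if (ncol(df) >= 2L) df[[2L]] else df[[1L]]
  if (!is.numeric(x)) stop_io("series file is not numeric: ", path)
  as.numeric(x)
}

#' Write a semi-variogram (or any) series to CSV
#'
#' @param x numeric vector.
#' @param path output path; layout is `slice_index,gamma`.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  utils::write.csv(data.frame(slice_index = seq_along(x), gamma = as.numeric(x)),
                   path, row.names = FALSE)
  invisible(path)
}
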