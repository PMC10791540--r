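# Masked per-slice semi-variogram and per-volume series assembly.
#
# The semi-variogram at lag h is half the mean squared difference between
# intensity values separated by h pixels:
#
#   gamma(h) = 1 / (2 N(h)) * sum_i [ f(i) - f(i + h) ]^2
#
# Pairs are taken along image rows (horizontal lag of h pixels, never
# wrapping across row ends), and a pair contributes only when BOTH pixels
# pass the intensity and row masks. Small gamma = high spatial correlation.

#' Configuration of the masked semi-variogram
#'
#' Defaults follow the standard mandibular-CT setting: lag `h = 1` pixel
#' (maximizing the autocorrelation signal), intensities at or above 0.5 on a
#' \[0, 1\] scale (bone), rows from 150 down (skipping image background and
#' non-mandible anatomy at the top of the frame), and the first 100 slices.
#'
#' @param h integer lag in pixels (>= 1).
#' @param intensity_min inclusion threshold in \[0, 1\]; both pixels of a
#'   pair must be at or above it.
#' @param row_min first included row, 1-based from the top edge.
#' @param n_slices number of leading slices to use from a volume.
#' @return A `variogram_config` list.
#' @export
variogram_config <- function(h = 1L, intensity_min = 0.5, row_min = 150L,
                             n_slices = 100L) {
  if (!is_count(h)) stop_config("h must be an integer >= 1")
  if (!is_prob(intensity_min)) stop_config("intensity_min must lie in [0, 1]")
  if (!is_count(row_min)) stop_config("row_min must be an integer >= 1")
  if (!is_count(n_slices)) stop_config("n_slices must be an integer >= 1")
  structure(list(h = as.integer(h), intensity_min = intensity_min,
                 row_min = as.integer(row_min), n_slices = as.integer(n_slices)),
            class = "variogram_config")
}

#' Semi-variogram of a single slice
#'
#' @param slice numeric matrix with intensities in \[0, 1\].
#' @param config a [variogram_config].
#' @return `list(gamma, n_pairs)`. When no pixel pair passes the masks,
#'   `gamma` is `NA` and `n_pairs` is 0; the caller decides the policy
#'   (see [semivariogram_series()]).
#' @export
slice_semivariogram <- function(slice, config = variogram_config()) {
  stopifnot(is.matrix(slice), inherits(config, "variogram_config"))
  h <- config$h
  if (config$row_min > nrow(slice) || h >= ncol(slice))
    return(list(gamma = NA_real_, n_pairs = 0L))
  sub <- slice[config$row_min:nrow(slice), , drop = FALSE]
  a <- sub[, seq_len(ncol(sub) - h), drop = FALSE]
  b <- sub[, (h + 1L):ncol(sub), drop = FALSE]
  ok <- a >= config$intensity_min & b >= config$intensity_min
  n <- sum(ok)
  if (n == 0L) return(list(gamma = NA_real_, n_pairs = 0L))
  list(gamma = sum((a[ok] - b[ok])^2) / (2 * n), n_pairs = n)
}

#' Per-volume semi-variogram series
#'
#' Applies [slice_semivariogram()] to the first `config$n_slices` slices.
#' A slice with no qualifying pixel pairs gets its value imputed from the
#' nearest slice with a valid value (ties broken toward the earlier slice);
#' if no slice is valid the series cannot be formed and an error is raised.
#'
#' @param volume a normalized [ct_volume].
#' @param config a [variogram_config].
#' @return A `semivariogram_series` object: numeric vector `values` of
#'   length `min(n_slices, volume$n_slices)`, plus `n_pairs`, the indices
#'   `imputed`, and the `config` used.
#' @export
semivariogram_series <- function(volume, config = variogram_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  if (volume$intensity_domain != "normalized")
    stop_input("semivariogram_series needs a normalized volume")
  if (volume$n_slices < 1L) stop_input("volume has no slices")
  n <- min(config$n_slices, volume$n_slices)
  per <- lapply(volume$slices[seq_len(n)], slice_semivariogram, config = config)
  values <- vapply(per, `[[`, numeric(1), "gamma")
  n_pairs <- vapply(per, `[[`, integer(1), "n_pairs")
  missing <- which(is.na(values))
  if (length(missing) == n)
    stop_input("no slice has qualifying pixel pairs; cannot form a series")
  if (length(missing)) {
    valid <- which(!is.na(values))
    for (i in missing) {
      nearest <- valid[which.min(abs(valid - i))]
      values[i] <- values[nearest]
    }
  }
  structure(list(values = values, n_pairs = n_pairs, imputed = missing,
                 config = config),
            class = "semivariogram_series")
}

#' @export
print.semivariogram_series <- function(x, ...) {
  cat(sprintf("<semivariogram_series> T = %d, mean gamma = %.4g%s\n",
              length(x$values), mean(x$values),
              if (length(x$imputed)) sprintf(" (%d imputed)", length(x$imputed))
              else ""))
  invisible(x)
}
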