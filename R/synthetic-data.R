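# Synthetic CT-like volumes, two-group cohorts, and toy 1-D series with known
# statistical structure. The generator states a world the pipeline can be
# tested in: a "bone" foreground confined to the lower image rows, intensities
# in [0, 1] with background below the 0.5 mask, a Gaussian random field
# foreground with a controllable variogram sill and correlation range, and a
# cohort design where one group's spatial variance is systematically elevated.

#' Specification of a synthetic CT-like volume
#'
#' @param n_slices number of slices (default 100, matching the number of
#'   leading slices the analysis consumes).
#' @param height,width slice dimensions in pixels (default 512, the usual CT
#'   matrix size; tests use smaller slices for speed).
#' @param bone_row_start first row (1-based from the top) containing the bone
#'   foreground; rows above hold only background.
#' @param sill variance of the foreground intensity field (intensities are
#'   dimensionless in \[0, 1\]).
#' @param corr_range correlation length of the foreground field in pixels.
#' @param background_level background intensity, strictly below 0.5 so the
#'   standard bone mask excludes it.
#' @param drift additive per-slice linear trend in the sill: slice t is
#'   generated with variance `sill + drift * (t - 1)`.
#' @param seed RNG seed; all randomness in the generated volume flows from it.
#' @return A `volume_spec` list.
#' @export
volume_spec <- function(n_slices = 100L, height = 512L, width = 512L,
                        bone_row_start = 150L, sill = 0.005, corr_range = 4,
                        background_level = 0.1, drift = 0, seed = 1L) {
  if (!is_count(n_slices)) stop_config("n_slices must be a positive integer")
  if (!is_count(height) || !is_count(width))
    stop_config("height and width must be positive integers")
  if (!is_count(bone_row_start) || bone_row_start > height)
    stop_config("bone_row_start must lie in 1..height")
  if (!is.numeric(sill) || sill < 0) stop_config("sill must be >= 0")
  if (!is.numeric(corr_range) || corr_range <= 0)
    stop_config("corr_range must be > 0")
  if (!is_prob(background_level) || background_level >= 0.5)
    stop_config("background_level must lie in [0, 0.5)")
  if (sill + drift * (n_slices - 1) < 0)
    stop_config("drift drives the per-slice sill negative")
  structure(list(n_slices = as.integer(n_slices), height = as.integer(height),
                 width = as.integer(width),
                 bone_row_start = as.integer(bone_row_start), sill = sill,
                 corr_range = corr_range, background_level = background_level,
                 drift = drift, seed = seed),
            class = "volume_spec")
}

# separable Gaussian smoothing with edge replication
smooth2d <- function(m, range) {
  sd <- range / 2
  r <- max(1L, ceiling(2.5 * sd))
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  pad <- function(v) c(rep(v[1], r), v, rep(v[length(v)], r))
  conv1 <- function(v) stats::filter(pad(v), k, sides = 2)[(r + 1):(r + length(v))]
  m <- apply(m, 2L, conv1)
  t(apply(t(m), 2L, conv1))
}

#' Generate a synthetic CT-like volume
#'
#' Each slice is `background_level` everywhere except rows at or below
#' `bone_row_start`, which hold a Gaussian random field: white noise smoothed
#' by an isotropic Gaussian kernel of width `corr_range`, affinely mapped to
#' mean 0.75 and variance equal to the slice's sill, then clipped to
#' \[0.5, 1\]. A zero sill yields a constant foreground at 0.75.
#'
#' @param spec a [volume_spec].
#' @return A normalized [ct_volume].
#' @export
gen_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_spec"))
  fg_rows <- spec$bone_row_start:spec$height
  with_seed(spec$seed, {
    slices <- lapply(seq_len(spec$n_slices), function(t) {
      s <- matrix(spec$background_level, spec$height, spec$width)
      sill_t <- spec$sill + spec$drift * (t - 1)
      fg <- matrix(0.75, length(fg_rows), spec$width)
      if (sill_t > 0) {
        z <- smooth2d(matrix(stats::rnorm(length(fg_rows) * spec$width),
                             length(fg_rows), spec$width),
                      spec$corr_range)
        z <- (z - mean(z)) / stats::sd(z)
        fg <- pmin(pmax(0.75 + sqrt(sill_t) * z, 0.5), 1)
      }
      s[fg_rows, ] <- fg
      s
    })
    ct_volume(slices, "normalized")
  })
}

#' Specification of a two-group synthetic cohort
#'
#' Emulates a balanced two-group design in which one group's per-slice
#' spatial variance is systematically elevated: the `"high"` group is
#' generated with `base$sill + group_effect`.
#'
#' @param n_per_group subjects per group (default 5, a typical small-cohort
#'   imaging design).
#' @param base a [volume_spec] shared by both groups.
#' @param group_effect additive sill offset for the `"high"` group; default
#'   0.003 (about a 60% elevation over the default sill, comparable to the
#'   clear but overlapping separation seen between real cohorts).
#' @param seed RNG seed for the whole cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 5L, base = volume_spec(),
                        group_effect = 0.003, seed = 1L) {
  if (!is_count(n_per_group)) stop_config("n_per_group must be >= 1")
  if (!is.numeric(group_effect) || group_effect < 0)
    stop_config("group_effect must be >= 0")
  stopifnot(inherits(base, "volume_spec"))
  structure(list(n_per_group = as.integer(n_per_group), base = base,
                 group_effect = group_effect, seed = seed),
            class = "cohort_spec")
}

#' Generate a labelled two-group cohort of synthetic volumes
#'
#' @param spec a [cohort_spec].
#' @return A list of `2 * n_per_group` elements, each
#'   `list(volume, group, subject)` with group `"low"` or `"high"`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  sub_seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, 2L * n))
  out <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    group <- if (i <= n) "low" else "high"
    vs <- spec$base
    vs$sill <- vs$sill + if (group == "high") spec$group_effect else 0
    vs$seed <- sub_seeds[i]
    out[[i]] <- list(volume = gen_volume(vs), group = group,
                     subject = sprintf("S%d", i))
  }
  out
}

#' Generate a toy one-dimensional series
#'
#' Fixture series spanning the classic recurrence-plot typology: a constant
#' (degenerate) series, a periodic sine, white noise (homogeneous plot), a
#' slow drift, and a level-shifted "disrupted" series with abrupt jumps.
#'
#' @param kind one of `"constant"`, `"sine"`, `"white_noise"`, `"drift"`,
#'   `"disrupted"`.
#' @param length series length (>= 2).
#' @param seed RNG seed for stochastic kinds.
#' @param value constant level (`constant`).
#' @param period,amplitude sine parameters, in samples / signal units.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param sd standard deviation of the white-noise series itself.
#' @param slope total rise of the linear trend over the series (`drift`).
#' @param n_breaks,jump number of level shifts and their height (`disrupted`).
#' @return numeric vector of length `length`.
#' @export
gen_toy_series <- function(kind, length = 100L, seed = 1L, value = 1,
                           period = 10, amplitude = 1, noise_sd = 0.1,
                           sd = 1, slope = 1, n_breaks = 2L, jump = 5) {
  if (!is_count(length, min = 2L)) stop_config("length must be >= 2")
  t <- seq_len(length)
  with_seed(seed, switch(kind,
    constant = rep(value, length),
    sine = amplitude * sin(2 * pi * t / period) +
      if (noise_sd > 0) stats::rnorm(length, sd = noise_sd) else 0,
    white_noise = stats::rnorm(length, sd = sd),
    drift = slope * (t - 1) / (length - 1) + stats::rnorm(length, sd = noise_sd),
    disrupted = {
      seg <- floor((t - 1) * (n_breaks + 1L) / length)
      jump * (seg %% 2L) + stats::rnorm(length, sd = noise_sd)
    },
    stop_config("unknown toy series kind: ", kind)
  ))
}
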