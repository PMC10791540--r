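# Desk-scale fixtures: tiny volumes so the suite stays fast. Full 512x512
# geometry is supported by the generator but not needed for correctness.

small_volume_spec <- function(n_slices = 20L, side = 64L, seed = 1L, ...) {
  volume_spec(n_slices = n_slices, height = side, width = side,
              bone_row_start = as.integer(ceiling(side * 0.3)),
              seed = seed, ...)
}

small_variogram_config <- function(side = 64L, n_slices = 20L, ...) {
  variogram_config(row_min = as.integer(ceiling(side * 0.3)),
                   n_slices = n_slices, ...)
}

random_binary_matrix <- function(L, p = 0.3) {
  matrix(rbinom(L * L, 1L, p), L, L)
}

random_membership_matrix <- function(L, c_) {
  U <- matrix(runif(L * c_), L, c_)
  U / rowSums(U)
}
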