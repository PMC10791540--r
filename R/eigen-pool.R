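# Largest recurrence eigenvalue: the fuzzy recurrence plot is reduced by
# iterated sharpening convolution + ReLU + max pooling until its side length
# is at most a target size, and the spectral size of the reduced matrix is
# reported. The default 3x3 sharpening kernel [0 -1 0; -1 5 -1; 0 -1 0]
# accentuates local recurrence structure; ReLU keeps the matrix
# non-negative; max pooling downsamples.

#' Reduction schedule for the largest recurrence eigenvalue
#'
#' Defaults mirror the conventional analysis setting: the 3x3 sharpening
#' kernel, pooling size 5, and a target final side of 70. The stride is 1
#' with `"valid"` convolution: each iteration then shrinks the side by 6
#' (2 from the kernel, 4 from pooling), the smallest schedule consistent
#' with a 98 x 98 plot stopping near 70 (a pooling stride of 5 would
#' overshoot far below the target in one step).
#'
#' @param kernel convolution kernel matrix.
#' @param pool_size pooling window side `s` (>= 2).
#' @param stride pooling step (>= 1).
#' @param final_size target side length `n` (>= 2); reduction runs while
#'   the side exceeds it.
#' @param boundary `"valid"` (output shrinks by the kernel size) or
#'   `"same"` (zero-padded, size preserved).
#' @return An `eigen_config` list.
#' @export
eigen_config <- function(kernel = matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3),
                         pool_size = 5L, stride = 1L, final_size = 70L,
                         boundary = c("valid", "same")) {
  boundary <- match.arg(boundary)
  if (!is_count(pool_size, min = 2L)) stop_config("pool_size must be >= 2")
  if (!is_count(stride)) stop_config("stride must be >= 1")
  if (!is_count(final_size, min = 2L)) stop_config("final_size must be >= 2")
  stopifnot(is.matrix(kernel))
  structure(list(kernel = kernel, pool_size = as.integer(pool_size),
                 stride = as.integer(stride), final_size = as.integer(final_size),
                 boundary = boundary),
            class = "eigen_config")
}

#' 2-D convolution followed by ReLU
#'
#' Cross-correlates `M` with the kernel (no kernel flip) and rectifies:
#' `u(y) = max(0, y)` elementwise, so the output is non-negative.
#'
#' @param M numeric matrix, at least as large as the kernel.
#' @param kernel numeric kernel matrix.
#' @param boundary `"valid"` or `"same"` (zero padding).
#' @return numeric matrix.
#' @export
relu_convolve <- function(M, kernel = matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3),
                          boundary = c("valid", "same")) {
  boundary <- match.arg(boundary)
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (nrow(M) < kh || ncol(M) < kw)
    stop_input("matrix (", nrow(M), "x", ncol(M),
               ") smaller than kernel (", kh, "x", kw, ")")
  if (boundary == "same") {
    pt <- (kh - 1L) %/% 2L; pb <- kh - 1L - pt
    pl <- (kw - 1L) %/% 2L; pr <- kw - 1L - pl
    P <- matrix(0, nrow(M) + kh - 1L, ncol(M) + kw - 1L)
    P[(pt + 1L):(pt + nrow(M)), (pl + 1L):(pl + ncol(M))] <- M
    M <- P
  }
  oh <- nrow(M) - kh + 1L
  ow <- ncol(M) - kw + 1L
  out <- matrix(0, oh, ow)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      if (kernel[a, b] != 0)
        out <- out + kernel[a, b] * M[a:(a + oh - 1L), b:(b + ow - 1L)]
    }
  }
  pmax(out, 0)
}

pool_starts <- function(side, pool_size, stride) {
  if (pool_size >= side) return(1L)
  n_full <- (side - pool_size) %/% stride + 1L
  starts <- 1L + (seq_len(n_full) - 1L) * stride
  last_end <- starts[n_full] + pool_size - 1L
  if (last_end < side) starts <- c(starts, starts[n_full] + stride)
  starts
}

#' Max pooling of a matrix
#'
#' Each output cell is the maximum over an `s x s` window; windows advance
#' by `stride`. When the stride does not tile the matrix exactly, a trailing
#' partial window (truncated at the edge) is included rather than discarding
#' rows or columns.
#'
#' @param M numeric matrix.
#' @param pool_size window side `s`.
#' @param stride step between windows.
#' @return numeric matrix of the pooled maxima.
#' @export
max_pool <- function(M, pool_size = 5L, stride = 1L) {
  if (pool_size > max(nrow(M), ncol(M)))
    stop_input("pool_size exceeds both matrix dimensions")
  rs <- pool_starts(nrow(M), pool_size, stride)
  cs <- pool_starts(ncol(M), pool_size, stride)
  out <- matrix(0, length(rs), length(cs))
  for (i in seq_along(rs)) {
    ri <- rs[i]:min(rs[i] + pool_size - 1L, nrow(M))
    for (j in seq_along(cs)) {
      cj <- cs[j]:min(cs[j] + pool_size - 1L, ncol(M))
      out[i, j] <- max(M[ri, cj])
    }
  }
  out
}

#' Iterated convolve-rectify-pool reduction of a recurrence matrix
#'
#' While the side length exceeds `config$final_size`, applies
#' [relu_convolve()] then [max_pool()]. Every iteration must strictly
#' shrink the matrix, otherwise the schedule cannot terminate and a
#' configuration error is raised.
#'
#' @param R square numeric matrix.
#' @param config an [eigen_config()].
#' @return `list(cR, history)`: the reduced matrix and the sequence of side
#'   lengths traversed (starting at the input size).
#' @export
reduce_recurrence_matrix <- function(R, config = eigen_config()) {
  M <- unclass(R)
  if (nrow(M) != ncol(M)) stop_input("R must be square")
  history <- nrow(M)
  while (nrow(M) > config$final_size) {
    M <- relu_convolve(M, config$kernel, config$boundary)
    M <- max_pool(M, config$pool_size, config$stride)
    if (nrow(M) >= history[length(history)])
      stop_config("reduction schedule does not shrink the matrix ",
                  "(side ", history[length(history)], " -> ", nrow(M),
                  "); adjust pool_size/stride/boundary")
    history <- c(history, nrow(M))
  }
  list(cR = M, history = history)
}

#' Largest recurrence eigenvalue
#'
#' Reduces the recurrence matrix with [reduce_recurrence_matrix()] and
#' returns the modulus of its largest-magnitude eigenvalue (for the
#' symmetric non-negative matrices arising here, this is the usual largest
#' eigenvalue). The reduction history is attached as an attribute.
#'
#' @param R square numeric matrix (typically an `frp_matrix`).
#' @param config an [eigen_config()].
#' @return numeric scalar with attribute `"history"`.
#' @export
largest_recurrence_eigenvalue <- function(R, config = eigen_config()) {
  red <- reduce_recurrence_matrix(R, config)
  lam <- max(Mod(eigen(red$cR, only.values = TRUE)$values))
  structure(lam, history = red$history)
}
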