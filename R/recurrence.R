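# Time-delay embedding, fuzzy c-means partitioning, and fuzzy recurrence
# plot construction.
#
# A scalar series x of length T is embedded into m-dimensional phase space
# with delay tau: y_i = (x_i, x_{i+tau}, ..., x_{i+(m-1)tau}), giving
# L = T - (m-1) tau points. Fuzzy c-means assigns each point graded
# memberships mu(y_i, v_k) to c cluster centres; the fuzzy recurrence plot
# R(i, j) is then inferred through the fuzzy similarity relations:
# reflexivity R(i, i) = 1, symmetry, and max-min transitive composition
# R(i, j) = max_k min( mu(y_i, v_k), mu(v_k, y_j) ).

#' Time-delay embedding of a scalar series
#'
#' @param series numeric vector (or a `semivariogram_series`).
#' @param m embedding dimension (>= 1).
#' @param tau time delay (>= 1).
#' @return A `phase_space` object: `points` (L x m matrix, one point per
#'   row), `L`, `m`, `tau`, `T`.
#' @export
embed_series <- function(series, m = 3L, tau = 1L) {
  if (inherits(series, "semivariogram_series")) series <- series$values
  if (!is.numeric(series)) stop_input("series must be numeric")
  if (!is_count(m) || !is_count(tau)) stop_input("m and tau must be integers >= 1")
  T_ <- length(series)
  L <- T_ - (m - 1L) * tau
  if (L < 1L)
    stop_input("series too short: need length > (m-1)*tau = ", (m - 1L) * tau,
               ", got ", T_)
  pts <- vapply(seq_len(m), function(j) series[(1L + (j - 1L) * tau):
                                               ((j - 1L) * tau + L)],
                numeric(L))
  pts <- matrix(pts, nrow = L)
  structure(list(points = pts, L = as.integer(L), m = as.integer(m),
                 tau = as.integer(tau), T = T_),
            class = "phase_space")
}

#' Construct a fuzzy partition object directly
#'
#' Mostly useful for worked examples and tests; [fcm_partition()] is the
#' estimation route.
#'
#' @param memberships L x c matrix of grades in \[0, 1\], rows summing to 1.
#' @param centres c x m matrix of cluster centres (optional).
#' @param converged logical flag.
#' @param seed seed recorded for provenance.
#' @return A `fuzzy_partition` object.
#' @export
fuzzy_partition <- function(memberships, centres = NULL, converged = TRUE,
                            seed = NULL) {
  memberships <- as.matrix(memberships)
  if (any(memberships < -1e-9) || any(memberships > 1 + 1e-9))
    stop_input("membership grades must lie in [0, 1]")
  if (any(abs(rowSums(memberships) - 1) > 1e-9))
    stop_input("membership rows must sum to 1")
  structure(list(memberships = memberships, centres = centres,
                 c = ncol(memberships), converged = converged, seed = seed),
            class = "fuzzy_partition")
}

fcm_once <- function(Y, c, fuzzifier, tol, max_iter) {
  L <- nrow(Y)
  U <- matrix(stats::runif(L * c), L, c)
  U <- U / rowSums(U)
  converged <- FALSE
  V <- NULL
  for (it in seq_len(max_iter)) {
    Uf <- U^fuzzifier
    V <- crossprod(Uf, Y) / colSums(Uf)
    D2 <- outer(rowSums(Y^2), rep(1, c)) + outer(rep(1, L), rowSums(V^2)) -
      2 * Y %*% t(V)
    D2 <- pmax(D2, 0)
    zero <- D2 < .Machine$double.eps
    W <- D2^(-1 / (fuzzifier - 1))
    U_new <- W / rowSums(W)
    if (any(zero)) {
      for (i in which(rowSums(zero) > 0L)) {
        U_new[i, ] <- 0
        U_new[i, zero[i, ]] <- 1 / sum(zero[i, ])
      }
    }
    delta <- max(abs(U_new - U))
    U <- U_new
    if (delta < tol) { converged <- TRUE; break }
  }
  Uf <- U^fuzzifier
  D2 <- outer(rowSums(Y^2), rep(1, c)) + outer(rep(1, L), rowSums(V^2)) -
    2 * Y %*% t(V)
  list(U = U, V = V, objective = sum(Uf * pmax(D2, 0)), converged = converged)
}

#' Fuzzy c-means partition of a phase space
#'
#' Standard Bezdek fuzzy c-means: memberships minimize
#' `sum_i sum_k mu_ik^fuzzifier * ||y_i - v_k||^2` under row normalization,
#' iterating centre and membership updates until the largest membership
#' change drops below `tol` or `max_iter` is hit. The membership matrix is
#' initialized at random from the seeded stream, so identical seeds give
#' identical partitions. On non-convergence or a degenerate fit the
#' algorithm restarts (up to `restarts` fresh initializations) and keeps the
#' best objective; a never-converged result is returned with
#' `converged = FALSE` and a warning. A phase space whose points are all
#' coincident carries no cluster structure: every point is assigned fully to
#' a single cluster (with a warning), so downstream similarity is total.
#'
#' @param ps a `phase_space` (or plain numeric matrix, one point per row).
#' @param c number of clusters, `1 <= c <= L`.
#' @param fuzzifier fuzzification exponent (> 1); 2 is the field standard.
#' @param tol convergence tolerance on memberships.
#' @param max_iter iteration cap per restart.
#' @param restarts extra random restarts on failure.
#' @param seed RNG seed.
#' @return A `fuzzy_partition`.
#' @export
fcm_partition <- function(ps, c = 10L, fuzzifier = 2, tol = 1e-5,
                          max_iter = 1000L, restarts = 5L, seed = 1L) {
  Y <- if (inherits(ps, "phase_space")) ps$points else as.matrix(ps)
  L <- nrow(Y)
  if (!is_count(c) || c > L) stop_input("need 1 <= c <= L = ", L)
  if (fuzzifier <= 1) stop_input("fuzzifier must be > 1")
  if (c == 1L) {
    return(fuzzy_partition(matrix(1, L, 1L),
                           centres = matrix(colMeans(Y), 1L), seed = seed))
  }
  if (max(apply(Y, 2L, stats::var)) < .Machine$double.eps) {
    warning("all phase-space points coincide; returning a single-cluster partition")
    U <- matrix(0, L, c)
    U[, 1L] <- 1
    return(fuzzy_partition(U, centres = matrix(Y[1L, ], c, ncol(Y), byrow = TRUE),
                           seed = seed))
  }
  best <- NULL
  with_seed(seed, {
    for (attempt in seq_len(restarts + 1L)) {
      fit <- fcm_once(Y, c, fuzzifier, tol, max_iter)
      finite <- all(is.finite(fit$U)) && is.finite(fit$objective)
      if (finite && (is.null(best) || fit$objective < best$objective))
        best <- fit
      if (finite && fit$converged) break
    }
  })
  if (is.null(best)) stop_input("fuzzy c-means produced no finite fit")
  if (!best$converged)
    warning("fuzzy c-means did not converge in ", max_iter,
            " iterations (over ", restarts + 1L, " starts)")
  fuzzy_partition(best$U, centres = best$V, converged = best$converged,
                  seed = seed)
}

#' Fuzzy recurrence plot from a fuzzy partition
#'
#' `R(i, i) = 1` (reflexivity); for `i != j`,
#' `R(i, j) = max_k min( mu(y_i, v_k), mu(v_k, y_j) )` — the max-min
#' transitive composition of the point-to-cluster memberships, symmetric by
#' construction.
#'
#' @param partition a `fuzzy_partition`.
#' @return An `frp_matrix`: L x L numeric matrix in \[0, 1\] with unit
#'   diagonal, carrying the partition's `c` and `seed` as attributes.
#' @export
frp <- function(partition) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  U <- partition$memberships
  L <- nrow(U)
  R <- matrix(0, L, L)
  for (k in seq_len(ncol(U)))
    R <- pmax(R, outer(U[, k], U[, k], pmin))
  diag(R) <- 1
  structure(R, class = c("frp_matrix", class(R)),
            c = partition$c, seed = partition$seed)
}
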