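# Independent brute-force oracles. These deliberately re-derive each
# quantity with naive loops, never touching the production code paths.

oracle_semivariogram <- function(slice, config) {
  s <- 0; n <- 0L
  for (r in seq_len(nrow(slice))) {
    if (r < config$row_min) next
    for (cc in seq_len(ncol(slice))) {
      if (cc + config$h > ncol(slice)) next
      a <- slice[r, cc]; b <- slice[r, cc + config$h]
      if (a >= config$intensity_min && b >= config$intensity_min) {
        s <- s + (a - b)^2
        n <- n + 1L
      }
    }
  }
  if (n == 0L) list(gamma = NA_real_, n_pairs = 0L)
  else list(gamma = s / (2 * n), n_pairs = n)
}

oracle_maxmin_frp <- function(U) {
  L <- nrow(U); c_ <- ncol(U)
  R <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) { R[i, j] <- 1; next }
      best <- 0
      for (k in seq_len(c_)) best <- max(best, min(U[i, k], U[j, k]))
      R[i, j] <- best
    }
  }
  R
}

# maximal runs of 1s scanned cell by cell
.oracle_scan_runs <- function(v) {
  runs <- integer(0); cur <- 0L
  for (x in v) {
    if (x == 1L) cur <- cur + 1L
    else if (cur > 0L) { runs <- c(runs, cur); cur <- 0L }
  }
  if (cur > 0L) runs <- c(runs, cur)
  runs
}

oracle_line_histograms <- function(B, exclude_loi = TRUE) {
  L <- nrow(B)
  N_D <- if (exclude_loi) L - 1L else L
  drs <- integer(0)
  for (d in -(L - 1L):(L - 1L)) {
    if (exclude_loi && d == 0L) next
    cells <- integer(0)
    for (i in seq_len(L)) {
      j <- i + d
      if (j >= 1L && j <= L) cells <- c(cells, B[i, j])
    }
    drs <- c(drs, .oracle_scan_runs(cells))
  }
  vrs <- integer(0)
  for (j in seq_len(L)) vrs <- c(vrs, .oracle_scan_runs(B[, j]))
  list(diagonal = tabulate(drs, nbins = max(N_D, 1L)),
       vertical = tabulate(vrs, nbins = L))
}

oracle_graph_properties <- function(A) {
  n <- nrow(A)
  if (sum(A) == 0)
    return(list(characteristic_path_length = 0,
                average_clustering_coefficient = 0))
  dists <- c()
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(A[u, ] == 1)) {
          if (d[v] > d[u] + 1) { d[v] <- d[u] + 1; nxt <- c(nxt, v) }
        }
      }
      frontier <- nxt
    }
    dists <- c(dists, d[-s][is.finite(d[-s])])
  }
  cc <- numeric(n)
  for (u in seq_len(n)) {
    nb <- which(A[u, ] == 1)
    k <- length(nb)
    if (k < 2) { cc[u] <- 0; next }
    links <- 0
    for (a in nb) for (b in nb) if (a < b && A[a, b] == 1) links <- links + 1
    cc[u] <- 2 * links / (k * (k - 1))
  }
  list(characteristic_path_length = if (length(dists)) mean(dists) else 0,
       average_clustering_coefficient = mean(cc))
}

oracle_reduce <- function(M, config) {
  conv <- function(X, k) {
    kh <- nrow(k); kw <- ncol(k)
    out <- matrix(0, nrow(X) - kh + 1L, ncol(X) - kw + 1L)
    for (i in seq_len(nrow(out))) {
      for (j in seq_len(ncol(out))) {
        acc <- 0
        for (a in seq_len(kh)) for (b in seq_len(kw))
          acc <- acc + X[i + a - 1L, j + b - 1L] * k[a, b]
        out[i, j] <- max(acc, 0)
      }
    }
    out
  }
  pool <- function(X, s, stride) {
    starts <- function(side) {
      if (s >= side) return(1L)
      st <- seq(1L, side - s + 1L, by = stride)
      if (st[length(st)] + s - 1L < side) st <- c(st, st[length(st)] + stride)
      st
    }
    rs <- starts(nrow(X)); cs <- starts(ncol(X))
    out <- matrix(0, length(rs), length(cs))
    for (i in seq_along(rs)) for (j in seq_along(cs)) {
      out[i, j] <- max(X[rs[i]:min(rs[i] + s - 1L, nrow(X)),
                         cs[j]:min(cs[j] + s - 1L, ncol(X))])
    }
    out
  }
  while (nrow(M) > config$final_size) {
    M <- conv(M, config$kernel)
    M <- pool(M, config$pool_size, config$stride)
  }
  M
}
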