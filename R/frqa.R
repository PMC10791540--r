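# Fuzzy recurrence quantification: binarization of the fuzzy recurrence plot
# and the six measures computed from R and its binary counterpart B —
# recurrence rate (on R, thresholded at omega), determinism and entropy and
# divergence (diagonal line structure of B), laminarity and trapping time
# (vertical line structure of B).

otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- counts / sum(counts)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  br[which.max(between) + 1L]  # upper edge of the best split bin
}

#' Binarize a fuzzy recurrence plot
#'
#' `B(i, j) = 1` iff `R(i, j) >= threshold`. The default threshold is Otsu's
#' histogram split of R's values — the standard parameter-free segmentation
#' of a bimodal grayscale image. A constant R carries no contrast to
#' segment; it falls back to a fixed threshold of 0.5 with a warning.
#'
#' @param R an `frp_matrix` (or any numeric matrix in \[0, 1\]).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold cut level used when `method = "fixed"`.
#' @return A `binary_rp`: integer 0/1 matrix with the applied threshold in
#'   `attr(, "threshold")`.
#' @export
binarize <- function(R, method = c("otsu", "fixed"), threshold = 0.5) {
  method <- match.arg(method)
  R <- unclass(R)
  thr <- if (method == "fixed") threshold else otsu_threshold(as.vector(R))
  if (is.na(thr)) {
    warning("constant recurrence matrix; falling back to fixed threshold 0.5")
    thr <- 0.5
  }
  B <- matrix(as.integer(R >= thr), nrow(R), ncol(R))
  structure(B, class = c("binary_rp", class(B)), threshold = thr,
            method = method)
}

runs_of_ones <- function(v) {
  r <- rle(v)
  r$lengths[r$values == 1L]
}

#' Diagonal and vertical line-length histograms of a binary recurrence plot
#'
#' Counts maximal runs of 1s along every diagonal of B (excluding the main
#' diagonal — the line of identity — when `exclude_loi`) and along every
#' column. A run split by any 0 counts as separate runs.
#'
#' @param B a square 0/1 matrix ([binarize()] output or plain matrix).
#' @param exclude_loi drop the main diagonal from the diagonal statistics
#'   (default TRUE, which caps diagonal runs at L - 1).
#' @return A `line_histograms` object: `diagonal` and `vertical` are count
#'   vectors indexed by run length (lengths 1..N_D and 1..K), with `N_D`,
#'   `K`, and `exclude_loi` recorded.
#' @export
line_histograms <- function(B, exclude_loi = TRUE) {
  B <- unclass(B)
  if (nrow(B) != ncol(B)) stop_input("B must be square")
  L <- nrow(B)
  storage.mode(B) <- "integer"
  N_D <- if (exclude_loi) L - 1L else L
  K <- L
  offs <- setdiff(-(L - 1L):(L - 1L), if (exclude_loi) 0L else integer(0))
  diag_runs <- unlist(lapply(offs, function(d) {
    i <- if (d >= 0L) seq_len(L - d) else (1L - d):L
    j <- i + d
    runs_of_ones(B[cbind(i, j)])
  }))
  vert_runs <- unlist(lapply(seq_len(L), function(j) runs_of_ones(B[, j])))
  structure(list(diagonal = tabulate(diag_runs, nbins = max(N_D, 1L)),
                 vertical = tabulate(vert_runs, nbins = K),
                 N_D = N_D, K = K, exclude_loi = exclude_loi),
            class = "line_histograms")
}

#' Fuzzy recurrence rate
#'
#' Mean over all L^2 cells of R after zeroing every value below `omega`;
#' retained cells keep their fuzzy grade (they are not crisped to 1).
#'
#' @param R fuzzy recurrence matrix.
#' @param omega recurrence cut level in \[0, 1\]. The analysis convention
#'   here is 0.5, the midpoint of the membership scale.
#' @return fRR in \[0, 1\].
#' @export
f_rr <- function(R, omega = 0.5) {
  if (!is_prob(omega)) stop_input("omega must lie in [0, 1]")
  R <- unclass(R)
  mean(R * (R >= omega))
}

#' Diagonal-line measures: determinism, divergence, entropy
#'
#' With `p(L_D)` the histogram of maximal diagonal run lengths:
#' `fDET = sum_{L_D >= lmin_d} L_D p(L_D) / sum_{L_D >= 1} L_D p(L_D)`
#' (fraction of diagonal recurrence mass in lines of at least `lmin_d`);
#' `fDIV = 1 / L_Dmax` over observed runs; `fENT` is the Shannon entropy
#' (bits) of the run-length distribution restricted to `L_D >= lmin_d` and
#' renormalized (set `entropy_all_lengths = TRUE` to instead sum the
#' unrenormalized all-run probabilities over `L_D >= lmin_d`).
#' Empty numerators or denominators yield 0; with no diagonal runs at all,
#' `fDIV` is `NA`.
#'
#' @param hist a [line_histograms()] result.
#' @param lmin_d minimum diagonal line length (default 5).
#' @param entropy_all_lengths alternative entropy reading (see above).
#' @return `list(fDET, fDIV, fENT)`.
#' @export
diag_measures <- function(hist, lmin_d = 5L, entropy_all_lengths = FALSE) {
  stopifnot(inherits(hist, "line_histograms"))
  if (!is_count(lmin_d)) stop_input("lmin_d must be an integer >= 1")
  n <- hist$diagonal
  len <- seq_along(n)
  denom <- sum(len * n)
  keep <- len >= lmin_d
  fDET <- if (denom > 0) sum(len[keep] * n[keep]) / denom else 0
  fDIV <- if (sum(n) > 0) 1 / max(len[n > 0]) else NA_real_
  if (entropy_all_lengths) {
    p <- if (sum(n) > 0) n / sum(n) else n
    pk <- p[keep & p > 0]
  } else {
    nk <- n[keep]
    pk <- if (sum(nk) > 0) nk[nk > 0] / sum(nk) else numeric(0)
  }
  fENT <- if (length(pk)) -sum(pk * log2(pk)) else 0
  list(fDET = fDET, fDIV = fDIV, fENT = fENT)
}

#' Vertical-line measures: laminarity and trapping time
#'
#' `fLAM = sum_{L_V >= lmin_v} L_V p(L_V) / sum_{L_V >= 1} L_V p(L_V)`;
#' `fTT` is the mean length of vertical runs of at least `lmin_v`
#' (recurrence-plot cells). 0/0 cases return 0.
#'
#' @param hist a [line_histograms()] result.
#' @param lmin_v minimum vertical line length (default 5).
#' @return `list(fLAM, fTT)`.
#' @export
vert_measures <- function(hist, lmin_v = 5L) {
  stopifnot(inherits(hist, "line_histograms"))
  if (!is_count(lmin_v)) stop_input("lmin_v must be an integer >= 1")
  n <- hist$vertical
  len <- seq_along(n)
  denom <- sum(len * n)
  keep <- len >= lmin_v
  fLAM <- if (denom > 0) sum(len[keep] * n[keep]) / denom else 0
  n_keep <- sum(n[keep])
  fTT <- if (n_keep > 0) sum(len[keep] * n[keep]) / n_keep else 0
  list(fLAM = fLAM, fTT = fTT)
}

#' All six fuzzy recurrence quantification measures
#'
#' Convenience wrapper: binarizes R, extracts the line histograms, and
#' returns fRR, fDET, fLAM, fTT, fDIV, fENT together with the parameters
#' used.
#'
#' @param R an `frp_matrix`.
#' @param omega fRR cut level.
#' @param lmin_d,lmin_v minimum diagonal / vertical line lengths.
#' @param method,threshold binarization settings, see [binarize()].
#' @param exclude_loi see [line_histograms()].
#' @param entropy_all_lengths see [diag_measures()].
#' @return A one-row `data.frame` of the six measures plus `omega`,
#'   `lmin_d`, `lmin_v`, and the binarization `threshold` applied.
#' @export
frqa <- function(R, omega = 0.5, lmin_d = 5L, lmin_v = 5L,
                 method = c("otsu", "fixed"), threshold = 0.5,
                 exclude_loi = TRUE, entropy_all_lengths = FALSE) {
  B <- binarize(R, method = method, threshold = threshold)
  hist <- line_histograms(B, exclude_loi = exclude_loi)
  d <- diag_measures(hist, lmin_d = lmin_d,
                     entropy_all_lengths = entropy_all_lengths)
  v <- vert_measures(hist, lmin_v = lmin_v)
  data.frame(fRR = f_rr(R, omega), fDET = d$fDET, fLAM = v$fLAM,
             fTT = v$fTT, fDIV = d$fDIV, fENT = d$fENT, omega = omega,
             lmin_d = lmin_d, lmin_v = lmin_v,
             threshold = attr(B, "threshold"))
}
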