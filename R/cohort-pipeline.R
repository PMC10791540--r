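# End-to-end orchestration: semi-variogram series -> embedding -> fuzzy
# c-means -> fuzzy recurrence plot -> { quantification, network, eigenvalue }
# per subject, and group-level mean +/- SD summaries.

#' Full pipeline configuration
#'
#' Aggregates every stage's parameters into one serializable object, so a
#' run is reproducible from its configuration alone. Defaults are the
#' conventional mandibular-CT settings: lag-1 masked semi-variogram over the
#' first 100 slices, embedding `m = 3, tau = 1`, `c = 10` clusters,
#' `omega = 0.5`, minimum line lengths 5, `alpha = 0.4`, `beta = 0.08`, and
#' the sharpening-kernel reduction to side 70.
#'
#' @param variogram a [variogram_config()].
#' @param m,tau embedding dimension and delay.
#' @param c number of fuzzy clusters.
#' @param fuzzifier,tol,max_iter,restarts fuzzy c-means settings, see
#'   [fcm_partition()].
#' @param omega fuzzy recurrence rate cut level.
#' @param lmin_d,lmin_v minimum diagonal / vertical line lengths.
#' @param binarize_method,binarize_threshold see [binarize()].
#' @param alpha,beta network cut level and membership floor.
#' @param eigen an [eigen_config()].
#' @param seed seed for the stochastic clustering stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(variogram = variogram_config(), m = 3L, tau = 1L,
                            c = 10L, fuzzifier = 2, tol = 1e-5,
                            max_iter = 1000L, restarts = 5L, omega = 0.5,
                            lmin_d = 5L, lmin_v = 5L,
                            binarize_method = "otsu", binarize_threshold = 0.5,
                            alpha = 0.4, beta = 0.08,
                            eigen = eigen_config(), seed = 1L) {
  stopifnot(inherits(variogram, "variogram_config"),
            inherits(eigen, "eigen_config"))
  if (!is_count(m) || !is_count(tau) || !is_count(c))
    stop_config("m, tau and c must be positive integers")
  structure(list(variogram = variogram, m = as.integer(m),
                 tau = as.integer(tau), c = as.integer(c),
                 fuzzifier = fuzzifier, tol = tol,
                 max_iter = as.integer(max_iter), restarts = as.integer(restarts),
                 omega = omega, lmin_d = as.integer(lmin_d),
                 lmin_v = as.integer(lmin_v),
                 binarize_method = binarize_method,
                 binarize_threshold = binarize_threshold,
                 alpha = alpha, beta = beta, eigen = eigen, seed = seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_input("[stage: ", name, "] ", conditionMessage(e))
  })
}

#' Run the full analysis for one subject
#'
#' @param volume a normalized [ct_volume].
#' @param group group label (e.g. `"F"` / `"M"`).
#' @param config a [pipeline_config()].
#' @param subject subject identifier.
#' @return A one-row `data.frame` (class `subject_features`): the six
#'   recurrence quantification measures, the two graph properties,
#'   `lambda_max`, and the sizes `T` and `L`.
#' @export
run_subject <- function(volume, group = NA_character_,
                        config = pipeline_config(), subject = "S1") {
  stopifnot(inherits(config, "pipeline_config"))
  series <- stage("geostatistics", semivariogram_series(volume, config$variogram))
  ps <- stage("embedding", embed_series(series, m = config$m, tau = config$tau))
  part <- stage("fcm", fcm_partition(ps, c = config$c,
                                     fuzzifier = config$fuzzifier,
                                     tol = config$tol,
                                     max_iter = config$max_iter,
                                     restarts = config$restarts,
                                     seed = config$seed))
  R <- stage("frp", frp(part))
  q <- stage("frqa", frqa(R, omega = config$omega, lmin_d = config$lmin_d,
                          lmin_v = config$lmin_v,
                          method = config$binarize_method,
                          threshold = config$binarize_threshold))
  S <- stage("network", cluster_similarity(part, beta = config$beta))
  net <- stage("network", alpha_cut_adjacency(S, alpha = config$alpha))
  gp <- stage("network", graph_properties(net))
  lam <- stage("eigen", largest_recurrence_eigenvalue(R, config$eigen))
  out <- data.frame(subject = subject, group = group,
                    fRR = q$fRR, fDET = q$fDET, fLAM = q$fLAM, fTT = q$fTT,
                    fDIV = q$fDIV, fENT = q$fENT,
                    characteristic_path_length = gp$characteristic_path_length,
                    average_clustering_coefficient =
                      gp$average_clustering_coefficient,
                    lambda_max = as.numeric(lam),
                    T = length(series$values), L = ps$L)
  class(out) <- c("subject_features", class(out))
  out
}

#' Group-level summary of subject features
#'
#' Per-group arithmetic mean and sample standard deviation (n - 1
#' denominator) of every numeric feature column. Values are kept at full
#' precision; round only for presentation.
#'
#' @param features a `data.frame` with a `group` column and numeric feature
#'   columns (e.g. rbind-ed [run_subject()] rows, or printed per-subject
#'   values being checked).
#' @return A `cohort_report`: `list(per_subject, summary)` where `summary`
#'   is a long `data.frame` with columns `group`, `feature`, `mean`, `sd`
#'   (sd 0 for single-subject groups).
#' @export
summarize_cohort <- function(features) {
  features <- as.data.frame(features)
  if (!nrow(features)) stop_input("no subjects to summarize")
  if (is.null(features$group) || anyNA(features$group))
    stop_input("every subject needs a group label")
  num_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("T", "L"))
  if (!length(num_cols)) stop_input("no numeric feature columns to summarize")
  groups <- unique(features$group)
  rows <- list()
  for (g in groups) {
    sub <- features[features$group == g, , drop = FALSE]
    for (col in num_cols) {
      v <- sub[[col]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, feature = col, mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else 0, n = length(v))
    }
  }
  structure(list(per_subject = features, summary = do.call(rbind, rows)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat("<cohort_report>\n")
  s <- x$summary
  for (g in unique(s$group)) {
    cat(sprintf("group %s (n = %d):\n", g, s$n[s$group == g][1]))
    sub <- s[s$group == g, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %-32s %s ± %s\n", sub$feature[i],
                  format(round(sub$mean[i], digits), nsmall = digits),
                  format(round(sub$sd[i], digits), nsmall = digits)))
  }
  invisible(x)
}
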