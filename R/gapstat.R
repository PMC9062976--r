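## ---------------------------------------------------------------------
## Gap statistic with block-bootstrap surrogate series for selecting the
## number of clusters, and the one-standard-error selection rule.
## ---------------------------------------------------------------------

#' Within-cluster dispersion from a distance matrix
#'
#' `W = sum_r D_r / (2 n_r)` where `D_r` is the sum of all pairwise
#' distances within cluster r (both orderings) and `n_r` its size — the
#' pooled within-cluster dispersion of the gap statistic, applied to DTW
#' distances.
#'
#' @param labels Integer cluster labels, one per case (every case
#'   labelled, every cluster non-empty).
#' @param dist_matrix Symmetric distance matrix with zero diagonal.
#' @return Non-negative scalar dispersion.
#' @export
within_cluster_dispersion <- function(labels, dist_matrix) {
  D <- as.matrix(dist_matrix)
  n <- nrow(D)
  if (length(labels) != n) stop("labels do not match the distance matrix")
  if (anyNA(labels)) stop("every case must be labelled")
  W <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) == 0L) stop("empty cluster ", cl)
    W <- W + sum(D[idx, idx, drop = FALSE]) / (2 * length(idx))
  }
  W
}

#' Build one block-bootstrap surrogate series
#'
#' Concatenates consecutive segments ("blocks") of `block_length` time
#' points, each drawn from a uniformly chosen pool series at a uniformly
#' chosen valid start position (with replacement, blocks independent).
#' When the series length is not a multiple of `block_length` the last
#' block is truncated. Uses the current RNG stream; seed management is
#' the caller's responsibility (see [gap_curve()]).
#'
#' @param pool Non-empty list of equal-length numeric series.
#' @param block_length Block size in time points (default 10).
#' @return Numeric surrogate series of the pool series' length.
#' @export
make_reference_series <- function(pool, block_length = 10L) {
  if (!is.list(pool) || length(pool) == 0L) stop("empty pool")
  len <- length(pool[[1L]])
  if (block_length > len)
    stop("block_length (", block_length, ") exceeds series length (",
         len, ")")
  out <- numeric(0)
  remaining <- len
  n_starts <- len - block_length + 1L
  while (remaining > 0L) {
    take <- min(block_length, remaining)
    src <- pool[[sample.int(length(pool), 1L)]]
    start <- sample.int(n_starts, 1L)
    out <- c(out, src[start:(start + take - 1L)])
    remaining <- remaining - take
  }
  out
}

#' Gap curve over candidate cluster numbers
#'
#' For the observed series, clusters are built once with the DTW
#' mean-linkage algorithm and cut at k = 1..`k_max`, giving dispersions
#' `W_k`. For each of `B` reference sets, `reference_size` block-bootstrap
#' surrogates are drawn from the observed series and passed through the
#' identical clustering pipeline, giving `log W*_kb`. Then
#' `gap_k = mean_b log W*_kb - log W_k` and
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`.
#'
#' @param series Named list of equal-length scaled series (at least
#'   `k_max + 1`).
#' @param k_max Largest candidate k (default 10).
#' @param B Number of reference sets (default 100).
#' @param block_length Bootstrap block size in time points (default 10).
#' @param reference_size Surrogates per reference set (default: the
#'   number of observed series).
#' @param config A [dtw_config()].
#' @param seed Integer seed; each reference set uses a child seed derived
#'   from it, so the curve is reproducible bit for bit.
#' @param log_scale Compare dispersions on the log scale (default `TRUE`,
#'   the standard formulation); `FALSE` uses the linear scale for
#'   sensitivity analysis.
#' @return A `gap_curve` object: data frame with columns `k`, `W`,
#'   `log_W`, `logW_ref_mean`, `gap`, `s`, `ose_criterion`
#'   (`gap_k - (gap_[k+1] - s_[k+1])`, `NA` at `k_max`), with the data
#'   cluster model attached as attribute `model`.
#' @export
gap_curve <- function(series, k_max = 10L, B = 100L, block_length = 10L,
                      reference_size = length(series),
                      config = dtw_config(), seed = 1L,
                      log_scale = TRUE) {
  n <- length(series)
  if (n < k_max + 1L)
    stop("need at least k_max + 1 series (got ", n, ")")
  if (B < 2L) stop("B must be at least 2")
  ks <- seq_len(k_max)

  D <- dtw_matrix(series, config)
  model <- agglomerate(series, config, D0 = D)
  W <- vapply(ks, function(k)
    within_cluster_dispersion(cut_clusters(model, k)$labels, D), 1.0)
  if (any(W <= 0))
    stop("zero within-cluster dispersion at k = ",
         ks[which(W <= 0)[1L]],
         ": series are degenerate (identical) at that resolution")

  f <- if (log_scale) log else identity
  logW_ref <- matrix(NA_real_, nrow = B, ncol = k_max)
  for (b in seq_len(B)) {
    ref <- with_seed(child_seed(seed, b), {
      lapply(seq_len(reference_size), function(i)
        make_reference_series(series, block_length))
    })
    Dref <- dtw_matrix(ref, config)
    mref <- agglomerate(ref, config, D0 = Dref)
    logW_ref[b, ] <- vapply(ks, function(k) {
      w <- within_cluster_dispersion(cut_clusters(mref, k)$labels, Dref)
      f(w)
    }, 1.0)
  }
  logW_ref_mean <- colMeans(logW_ref)
  gap <- logW_ref_mean - f(W)
  s <- apply(logW_ref, 2, sd) * sqrt(1 + 1 / B)
  ose <- c(gap[-k_max] - (gap[-1L] - s[-1L]), NA_real_)
  out <- data.frame(k = ks, W = W, log_W = f(W),
                    logW_ref_mean = logW_ref_mean, gap = gap, s = s,
                    ose_criterion = ose)
  structure(out, class = c("gap_curve", "data.frame"), model = model,
            B = B, block_length = block_length, seed = seed)
}

#' Select the number of clusters by the one-standard-error rule
#'
#' Returns the smallest k whose gap is within one standard error of the
#' next gap, i.e. the first k with
#' `gap_k >= gap_[k+1] - s_[k+1]` — the point where the gap between
#' observed and reference dispersion stops increasing. If no k
#' qualifies, returns `k_max` with a warning.
#'
#' @param curve A `gap_curve`.
#' @return Integer, the selected number of clusters.
#' @export
select_k <- function(curve) {
  stopifnot(inherits(curve, "gap_curve"))
  k_max <- max(curve$k)
  if (k_max < 2L) stop("gap curve must cover at least k = 2")
  ok <- which(!is.na(curve$ose_criterion) & curve$ose_criterion >= 0)
  if (length(ok) == 0L) {
    warning("gap keeps increasing through k_max = ", k_max,
            "; returning k_max")
    return(k_max)
  }
  curve$k[ok[1L]]
}
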