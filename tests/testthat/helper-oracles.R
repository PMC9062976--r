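# Independent oracles used to cross-check the package implementations.
# These deliberately use naive exhaustive formulations, never the code
# paths they verify.

# All monotone warping paths from (1,1) to (n,m) with steps
# {(1,0),(0,1),(1,1)}, as matrices of (i,j) rows. Cached per shape.
.path_cache <- new.env(parent = emptyenv())
warping_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  grow <- function(path) {
    i <- path[nrow(path), 1]; j <- path[nrow(path), 2]
    if (i == n && j == m) return(list(path))
    out <- list()
    for (step in list(c(1, 0), c(0, 1), c(1, 1))) {
      ni <- i + step[1]; nj <- j + step[2]
      if (ni <= n && nj <= m)
        out <- c(out, grow(rbind(path, c(ni, nj))))
    }
    out
  }
  res <- grow(matrix(c(1, 1), nrow = 1))
  .path_cache[[key]] <- res
  res
}

# DTW by brute-force enumeration of every warping path
dtw_oracle <- function(a, b) {
  C <- abs(outer(a, b, "-"))
  min(vapply(warping_paths(length(a), length(b)),
             function(p) sum(C[p]), 1.0))
}

# Naive within-cluster dispersion: explicit double loop
dispersion_oracle <- function(labels, D) {
  W <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    acc <- 0
    for (i in idx) for (j in idx) acc <- acc + D[i, j]
    W <- W + acc / (2 * length(idx))
  }
  W
}

# All partitions of 1..n into exactly k non-empty blocks (restricted
# growth strings), as lists of integer label vectors
partitions_into_k <- function(n, k) {
  out <- list()
  rec <- function(labels, used) {
    pos <- length(labels) + 1L
    if (pos > n) {
      if (used == k) out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(min(used + 1L, k)))
      rec(c(labels, lab), max(used, lab))
  }
  rec(integer(0), 0L)
  out
}

# Two-tailed Fisher exact p by direct hypergeometric enumeration
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ROC AUC by exhaustive pair counting (ties count one half)
roc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + if (p > q) 1 else if (p == q) 0.5 else 0
  acc / (length(pos) * length(neg))
}

# Normal-approximation rank-sum z-test (no continuity correction), used
# as an independent power oracle for the Wilcoxon test
ranksum_z_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  ties <- table(c(x, y))
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  2 * pnorm(-abs((W - mu) / sqrt(sig2)))
}

# A 47-case responder cohort from the four non-trivial archetypes,
# observed daily through day 50 (dense sampling, so group 2's 7-day
# oscillation is not aliased away by interpolation), as scaled
# clustering series plus the truth labels
responder_series <- function(seed) {
  co <- make_cohort(n_per_group = c(0L, 12L, 12L, 12L, 11L), seed = seed,
                    schedule = sampling_schedule(dense_window_days = 50,
                                                 dense_rate = 1,
                                                 p_complete = 1))
  pr <- preprocess_cohort(co$mfi)
  trajs <- Filter(function(tr) identical(tr$gate, "responder") &&
                    identical(tr$length_class, "full_50"),
                  pr$trajectories)
  list(series = clustering_series(trajs),
       truth = co$cohort$true_group[
         match(vapply(trajs, function(tr) tr$case_id, ""),
               co$cohort$case_id)])
}
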