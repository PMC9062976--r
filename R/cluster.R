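## ---------------------------------------------------------------------
## Agglomerative hierarchical clustering of scaled tDSA series under the
## DTW distance, with mean-of-joining-series linkage: each merge replaces
## the two joined nodes by the pointwise mean of their representative
## series, and distances to the new representative are recomputed.
## ---------------------------------------------------------------------

#' Agglomerative DTW clustering with mean-series linkage
#'
#' At each iteration the two closest active nodes (by DTW distance
#' between their representative series) are merged; the new node's
#' representative is the pointwise mean of the two merged
#' representatives, and DTW distances from it to every other active node
#' are recomputed. Because representatives are recomputed, merge heights
#' are not guaranteed monotone and no ultrametric structure is assumed.
#' Ties in the minimum distance are broken by the lexicographically
#' smallest pair of node ids, making the build deterministic.
#'
#' @param series Named list of equal-length numeric vectors (scaled
#'   trajectories).
#' @param config A [dtw_config()]; the default (unnormalised, no window)
#'   is appropriate for equal-length series.
#' @param D0 Optional precomputed initial DTW distance matrix between the
#'   input series (saves recomputation when the caller already has it).
#' @param member_mean If `TRUE`, representatives are the mean of all
#'   member series instead of the mean of the two joined representatives
#'   (sensitivity-analysis variant; default `FALSE`, the literal
#'   mean-of-joining-series linkage).
#' @return A `cluster_model`: list with `n`, `case_ids`, `merge_history`
#'   (data frame: `node_a`, `node_b`, `distance`, `new_node`),
#'   `representatives` (list indexed by node id, leaves 1..n then merge
#'   nodes n+1..2n-1), `members` (list of case indices per node), and the
#'   `config` used.
#' @export
agglomerate <- function(series, config = dtw_config(), D0 = NULL,
                        member_mean = FALSE) {
  if (!is.list(series) || length(series) < 2L)
    stop("agglomerate: need at least two series")
  lens <- vapply(series, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("agglomerate: series must all have the same length")
  n <- length(series)
  ids <- names(series) %||% sprintf("series_%d", seq_len(n))

  reps <- vector("list", 2L * n - 1L)
  members <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) {
    reps[[i]] <- as.numeric(series[[i]])
    members[[i]] <- i
  }
  active <- seq_len(n)            # node ids currently active
  D <- if (is.null(D0)) dtw_matrix(series, config) else as.matrix(D0)
  stopifnot(nrow(D) == n, ncol(D) == n)
  dimnames(D) <- NULL

  hist_a <- hist_b <- hist_new <- integer(n - 1L)
  hist_d <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(active)
    ## locate the minimum off-diagonal entry; ties -> smallest (id_a, id_b)
    Dm <- D
    Dm[!upper.tri(Dm)] <- Inf
    best <- which(Dm == min(Dm), arr.ind = TRUE)
    if (nrow(best) > 1L) {
      pair_ids <- cbind(pmin(active[best[, 1]], active[best[, 2]]),
                        pmax(active[best[, 1]], active[best[, 2]]))
      best <- best[order(pair_ids[, 1], pair_ids[, 2])[1L], , drop = FALSE]
    }
    ia <- best[1, 1]; ib <- best[1, 2]
    id_a <- active[ia]; id_b <- active[ib]
    new_id <- n + step
    if (member_mean) {
      mem <- c(members[[id_a]], members[[id_b]])
      reps[[new_id]] <- Reduce(`+`, lapply(mem, function(i) reps[[i]])) /
        length(mem)
    } else {
      reps[[new_id]] <- (reps[[id_a]] + reps[[id_b]]) / 2
    }
    members[[new_id]] <- sort(c(members[[id_a]], members[[id_b]]))
    hist_a[step] <- min(id_a, id_b)
    hist_b[step] <- max(id_a, id_b)
    hist_d[step] <- D[ia, ib]
    hist_new[step] <- new_id

    keep <- setdiff(seq_len(m), c(ia, ib))
    active <- c(active[keep], new_id)
    D <- D[keep, keep, drop = FALSE]
    if (length(keep) > 0L) {
      newd <- dtw_to_each(reps[[new_id]],
                          lapply(active[seq_along(keep)],
                                 function(id) reps[[id]]),
                          config)
      D <- rbind(cbind(D, newd), c(newd, 0))
    } else {
      D <- matrix(0, 1, 1)
    }
  }
  structure(list(n = n, case_ids = ids,
                 merge_history = data.frame(node_a = hist_a,
                                            node_b = hist_b,
                                            distance = hist_d,
                                            new_node = hist_new),
                 representatives = reps, members = members,
                 config = config),
            class = "cluster_model")
}

#' Cut a cluster model into k clusters
#'
#' Undoes the last `k - 1` merges; the resulting active nodes are the
#' clusters. Clusters are numbered 1..k by decreasing size, ties broken
#' by the smallest contained case index.
#'
#' @param model A `cluster_model` from [agglomerate()].
#' @param k Number of clusters, between 1 and `model$n`.
#' @return A `cluster_cut`: list with `k`, `labels` (named integer vector
#'   of cluster numbers per case), `representatives` (list of k series,
#'   the per-cluster mean representatives), and `sizes`.
#' @export
cut_clusters <- function(model, k) {
  stopifnot(inherits(model, "cluster_model"))
  n <- model$n
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop("k must be between 1 and the number of series (", n, ")")
  k <- as.integer(k)
  ## replay the first n - k merges
  active <- seq_len(n)
  h <- model$merge_history
  steps <- n - k
  if (steps > 0L) {
    for (s in seq_len(steps))
      active <- c(setdiff(active, c(h$node_a[s], h$node_b[s])),
                  h$new_node[s])
  }
  sizes <- vapply(active, function(id) length(model$members[[id]]), 1L)
  firsts <- vapply(active, function(id) min(model$members[[id]]), 1L)
  ord <- order(-sizes, firsts)
  active <- active[ord]
  labels <- integer(n)
  for (c_i in seq_along(active))
    labels[model$members[[active[c_i]]]] <- c_i
  names(labels) <- model$case_ids
  structure(list(k = k, labels = labels,
                 representatives = lapply(active,
                                          function(id)
                                            model$representatives[[id]]),
                 sizes = sizes[ord]),
            class = "cluster_cut")
}

#' Classify shorter series into existing clusters by nearest DTW
#'
#' Each (scaled) short series is assigned to the cluster whose mean
#' representative is nearest under the path-length-normalised DTW
#' distance (normalisation makes distances comparable across the unequal
#' lengths). Ties go to the lower cluster number.
#'
#' @param short_series Named list of scaled numeric vectors (each scaled
#'   by its own maximum).
#' @param cut A `cluster_cut` from [cut_clusters()].
#' @param config A [dtw_config()]; default normalises by path length.
#' @return Named integer vector of cluster assignments.
#' @export
classify_short <- function(short_series, cut,
                           config = dtw_config(normalize = TRUE)) {
  stopifnot(inherits(cut, "cluster_cut"))
  if (length(cut$representatives) == 0L) stop("empty cluster means")
  out <- vapply(short_series, function(s) {
    d <- dtw_to_each(s, cut$representatives, config)
    which.min(d)   # which.min returns the first (lowest) index on ties
  }, 1L)
  names(out) <- names(short_series)
  out
}

#' Label clusters by their nearest archetype skeleton
#'
#' Cluster numbering is structural (by size); the dynamic-response names
#' are semantic. Each cluster's mean representative is matched to the
#' nearest noise-free archetype skeleton (groups 1-4) by DTW.
#'
#' @param cut A `cluster_cut`.
#' @param config A [dtw_config()].
#' @return Character vector of archetype names, one per cluster.
#' @export
label_archetypes <- function(cut, config = dtw_config()) {
  stopifnot(inherits(cut, "cluster_cut"))
  len <- length(cut$representatives[[1L]])
  grid <- seq_len(len)
  skeletons <- lapply(1:4, archetype_skeleton, grid = grid)
  vapply(cut$representatives, function(rep) {
    archetype_names[1L + which.min(dtw_to_each(rep, skeletons, config))]
  }, "")
}
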