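#' DTW configuration
#'
#' Settings for the dynamic-time-warping distance used throughout the
#' clustering pipeline. The local cost is the absolute difference and the
#' admissible steps are \{(1,0), (0,1), (1,1)\}; the distance is the
#' cumulative cost of the optimal monotone alignment of the two series.
#'
#' @param window Sakoe-Chiba band half-width in days, or `NULL` (default)
#'   for an unconstrained alignment. The 50-point daily series used here
#'   are cheap enough that no band is needed.
#' @param normalize If `TRUE`, divide the cumulative cost by the number of
#'   cells on the optimal warping path. Used when comparing series of
#'   unequal length (short-series classification), where raw cumulative
#'   cost grows with length.
#' @return An object of class `dtw_config`.
#' @examples
#' dtw_distance(c(0, 1, 2), c(0, 2))              # 1
#' dtw_distance(c(0, 1, 2), c(0, 1, 2))           # 0
#' @export
dtw_config <- function(window = NULL, normalize = FALSE) {
  if (!is.null(window)) {
    stopifnot(is.numeric(window), length(window) == 1L, window >= 0)
    window <- as.integer(window)
  }
  structure(list(window = window, normalize = isTRUE(normalize)),
            class = "dtw_config")
}

#' Dynamic time warping distance between two series
#'
#' @param a,b Numeric vectors (non-empty).
#' @param config A [dtw_config()].
#' @return Non-negative scalar distance.
#' @export
dtw_distance <- function(a, b, config = dtw_config()) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("dtw_distance: series must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("dtw_distance: series contain NA")
  w <- if (is.null(config$window)) -1L else config$window
  cpp_dtw(a, b, w, config$normalize)
}

#' Pairwise DTW distance matrix
#'
#' @param series A list of numeric vectors (at least two).
#' @param config A [dtw_config()].
#' @return Symmetric matrix with zero diagonal; row/column names taken
#'   from `names(series)` when present.
#' @export
dtw_matrix <- function(series, config = dtw_config()) {
  if (!is.list(series) || length(series) < 2L)
    stop("dtw_matrix: need a list of at least two series")
  if (any(vapply(series, length, 1L) == 0L))
    stop("dtw_matrix: series must be non-empty")
  w <- if (is.null(config$window)) -1L else config$window
  D <- cpp_dtw_matrix(lapply(series, as.numeric), w, config$normalize)
  dimnames(D) <- list(names(series), names(series))
  D
}

## distances from one series to each element of a list
dtw_to_each <- function(x, series, config = dtw_config()) {
  w <- if (is.null(config$window)) -1L else config$window
  cpp_dtw_one_to_many(as.numeric(x), lapply(series, as.numeric), w,
                      config$normalize)
}
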