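## ---------------------------------------------------------------------
## Pre-processing: raw per-specificity MFI -> gated, scaled, daily-grid
## total-DSA (tDSA) trajectories.
## ---------------------------------------------------------------------

#' Sum per-specificity MFI into total DSA at observed days
#'
#' A day is "observed" if any specificity has a record on it; the tDSA at
#' that day is the sum of all specificities measured that day.
#'
#' @param records Data frame with columns `specificity`, `day`, `mfi` for
#'   one case (extra columns ignored).
#' @return Data frame with columns `day`, `tdsa`, sorted by day. Negative
#'   days (pre-transplant samples) are retained here and handled by
#'   [interpolate_daily()].
#' @export
aggregate_tdsa <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("specificity", "day", "mfi") %in% names(records)))
  if (nrow(records) == 0L) stop("no MFI records")
  if (any(records$mfi < 0)) stop("negative MFI value(s) in records")
  key <- paste(records$specificity, records$day, sep = "@")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (specificity, day) record(s): ",
         paste(unique(key[dup]), collapse = ", "))
  agg <- tapply(records$mfi, records$day, sum)
  data.frame(day = as.integer(names(agg)), tdsa = as.numeric(agg),
             row.names = NULL)[order(as.integer(names(agg))), , drop = FALSE]
}

#' Linearly interpolate tDSA onto a daily grid
#'
#' Fills every integer day between the first and last observed
#' post-transplant day (capped at `horizon`) by linear interpolation;
#' values at observed days are unchanged and no extrapolation is
#' performed beyond the last observation. Pre-transplant samples (day
#' < 0) contribute only the `pre_treatment_tdsa` summary (the earliest
#' available pre-transplant sum), never the grid.
#'
#' @param observed Data frame with columns `day`, `tdsa` (output of
#'   [aggregate_tdsa()]).
#' @param case_id Identifier attached to the result.
#' @param horizon Last day of the analysis window (default 50).
#' @param min_last_day Inclusion rule: the last observed post-transplant
#'   day must be at least this (default 20, i.e. days 0-20 give 21 daily
#'   points of monitoring).
#' @return A `tdsa_trajectory` object: list with `case_id`, `days`
#'   (integer grid), `tdsa`, `pre_treatment_tdsa` (NA when no
#'   pre-transplant sample exists), and placeholders for `scaled`,
#'   `gate`, `length_class`.
#' @export
interpolate_daily <- function(observed, case_id = NA_character_,
                              horizon = .DEFAULT_HORIZON,
                              min_last_day = .DEFAULT_MIN_LAST_DAY) {
  stopifnot(is.data.frame(observed),
            all(c("day", "tdsa") %in% names(observed)))
  pre <- observed[observed$day < 0, , drop = FALSE]
  post <- observed[observed$day >= 0, , drop = FALSE]
  pre_tdsa <- if (nrow(pre)) pre$tdsa[which.min(pre$day)] else NA_real_
  if (nrow(post) < 2L)
    stop("case ", case_id, ": need at least 2 observed post-transplant days")
  last_day <- max(post$day)
  if (last_day < min_last_day)
    stop("case ", case_id, " excluded: last observed day ", last_day,
         " < required ", min_last_day)
  grid <- seq(min(post$day), min(last_day, horizon))
  vals <- approx(post$day, post$tdsa, xout = grid, method = "linear",
                 rule = 1)$y
  structure(list(case_id = case_id, days = as.integer(grid), tdsa = vals,
                 pre_treatment_tdsa = pre_tdsa, scaled = NULL,
                 gate = NA_character_, length_class = NA_character_),
            class = "tdsa_trajectory")
}

#' Gate trajectories whose tDSA never reaches 1500 MFI
#'
#' Cases whose maximum post-transplant tDSA stays strictly below the
#' threshold form the "no response" group 0 and are excluded from scaling
#' and clustering.
#'
#' @param trajectory A `tdsa_trajectory`.
#' @param threshold Gate level in MFI (default 1500).
#' @return The trajectory with `gate` set to `"no_response"` or
#'   `"responder"`.
#' @export
gate_no_response <- function(trajectory, threshold = .DEFAULT_GATE_MFI) {
  stopifnot(inherits(trajectory, "tdsa_trajectory"))
  if (length(trajectory$tdsa) == 0L) stop("empty trajectory")
  mx <- max(trajectory$tdsa[trajectory$days >= 0])
  trajectory$gate <- if (mx < threshold) "no_response" else "responder"
  trajectory
}

#' Scale a responder trajectory by its maximum
#'
#' @param trajectory A gated `tdsa_trajectory` with `gate = "responder"`.
#' @return The trajectory with `scaled` set; `max(scaled) == 1`.
#' @export
scale_by_max <- function(trajectory) {
  stopifnot(inherits(trajectory, "tdsa_trajectory"))
  if (!identical(trajectory$gate, "responder"))
    stop("scale_by_max applies to gated responder trajectories only")
  mx <- max(trajectory$tdsa[trajectory$days >= 0])
  if (mx <= 0) stop("cannot scale: maximum tDSA is zero")
  trajectory$scaled <- trajectory$tdsa / mx
  trajectory
}

#' Split responder trajectories by series length
#'
#' Trajectories whose daily grid reaches `horizon` form the full-length
#' set used for clustering; the remainder (reaching at least
#' `min_last_day`) are held out for nearest-cluster classification.
#'
#' @param trajectories List of `tdsa_trajectory` objects.
#' @param horizon Day defining "full length" (default 50).
#' @return The input list with `length_class` set to `"full_50"` or
#'   `"short_20_50"` on each element.
#' @export
split_by_length <- function(trajectories, horizon = .DEFAULT_HORIZON) {
  lapply(trajectories, function(tr) {
    stopifnot(inherits(tr, "tdsa_trajectory"))
    tr$length_class <- if (max(tr$days) >= horizon) "full_50"
      else "short_20_50"
    tr
  })
}

#' Pre-process a long-format MFI table into gated, scaled trajectories
#'
#' Runs, per case: tDSA aggregation, daily linear interpolation with the
#' 21-day inclusion rule, the 1500-MFI no-response gate, max-scaling of
#' responders, and the full/short length split.
#'
#' @param mfi Long-format data frame: `case_id`, `specificity`, `day`,
#'   `mfi`.
#' @param threshold No-response gate (MFI, default 1500).
#' @param horizon Analysis window end (days, default 50).
#' @param min_last_day Inclusion rule (default 20).
#' @return A list with elements `trajectories` (all included cases, gated
#'   and, for responders, scaled and length-classified), `excluded`
#'   (data frame of excluded case ids and reasons), and `summary`
#'   (counts: input cases, gated group 0, full-length responders, short
#'   responders, excluded).
#' @export
preprocess_cohort <- function(mfi, threshold = .DEFAULT_GATE_MFI,
                              horizon = .DEFAULT_HORIZON,
                              min_last_day = .DEFAULT_MIN_LAST_DAY) {
  stopifnot(is.data.frame(mfi),
            all(c("case_id", "specificity", "day", "mfi") %in% names(mfi)))
  ids <- unique(mfi$case_id)
  trajs <- list()
  excluded <- list()
  for (id in ids) {
    rec <- mfi[mfi$case_id == id, , drop = FALSE]
    tr <- tryCatch(
      interpolate_daily(aggregate_tdsa(rec), case_id = id,
                        horizon = horizon, min_last_day = min_last_day),
      error = function(e) e)
    if (inherits(tr, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(case_id = id, reason = conditionMessage(tr),
                   stringsAsFactors = FALSE)
      next
    }
    tr <- gate_no_response(tr, threshold = threshold)
    if (identical(tr$gate, "responder")) tr <- scale_by_max(tr)
    trajs[[length(trajs) + 1L]] <- tr
  }
  gates <- vapply(trajs, function(tr) tr$gate, "")
  responders <- split_by_length(trajs[gates == "responder"],
                                horizon = horizon)
  gated <- trajs[gates == "no_response"]
  lens <- vapply(responders, function(tr) tr$length_class, "")
  out <- c(gated, responders)
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(case_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(trajectories = out,
       excluded = excluded,
       summary = c(n_input = length(ids),
                   n_gated = length(gated),
                   n_full = sum(lens == "full_50"),
                   n_short = sum(lens == "short_20_50"),
                   n_excluded = nrow(excluded)))
}

#' Extract the scaled clustering series from trajectories
#'
#' The clustering window is days 1 to `horizon` (50 daily points); the
#' transplant-day value informs the gate and the interpolation but is not
#' part of the clustered series.
#'
#' @param trajectories List of scaled responder `tdsa_trajectory` objects.
#' @param horizon Window end (default 50).
#' @return Named list of scaled numeric vectors (full-length cases give
#'   50 points; shorter cases give `max(days)` points).
#' @export
clustering_series <- function(trajectories, horizon = .DEFAULT_HORIZON) {
  out <- lapply(trajectories, function(tr) {
    stopifnot(inherits(tr, "tdsa_trajectory"))
    if (is.null(tr$scaled))
      stop("case ", tr$case_id, " has no scaled series (not a responder?)")
    keep <- tr$days >= 1 & tr$days <= horizon
    if (min(tr$days) > 1)
      stop("case ", tr$case_id, " starts after day 1; cannot form the ",
           "clustering series")
    tr$scaled[keep]
  })
  names(out) <- vapply(trajectories, function(tr) tr$case_id, "")
  out
}
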