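## ---------------------------------------------------------------------
## End-to-end orchestration: simulate -> preprocess -> cluster/select-k
## -> classify -> association stats, with stable CSV contracts.
## ---------------------------------------------------------------------

#' Pipeline configuration
#'
#' @param out_dir Output directory (`NULL` for in-memory only).
#' @param n_per_group Synthetic cohort sizes per group 0-4 (ignored when
#'   `mfi` is supplied).
#' @param mfi,cohort Optional long-format MFI data frame and covariate
#'   table to analyse instead of simulating (same schemas as
#'   [make_cohort()] output).
#' @param threshold No-response gate in MFI (default 1500).
#' @param horizon Analysis window end in days (default 50).
#' @param min_last_day Inclusion rule (default 20).
#' @param k `"auto"` (gap statistic + one-SE rule) or a fixed integer.
#' @param k_max,B,block_length Gap-statistic settings (defaults 10, 100,
#'   10).
#' @param noise_cv Simulation measurement noise (default 0.1).
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = NULL,
                            n_per_group = c(18L, 15L, 23L, 16L, 16L),
                            mfi = NULL, cohort = NULL,
                            threshold = 1500, horizon = 50,
                            min_last_day = 20,
                            k = "auto", k_max = 10L, B = 100L,
                            block_length = 10L, noise_cv = 0.1,
                            seed = 1L) {
  cfg <- list(out_dir = out_dir, n_per_group = n_per_group, mfi = mfi,
              cohort = cohort, threshold = threshold, horizon = horizon,
              min_last_day = min_last_day, k = k, k_max = k_max, B = B,
              block_length = block_length, noise_cv = noise_cv,
              seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

## stable short hash of the configuration for output provenance
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), c("out_dir", "mfi", "cohort"))]),
             collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full DSA-dynamics pipeline
#'
#' Simulates (or ingests) a cohort, pre-processes it into gated, scaled
#' daily trajectories, clusters the full-length responders with DTW
#' mean-linkage (selecting k by the gap statistic when `k = "auto"`),
#' classifies shorter responders into the learned clusters, labels the
#' clusters by archetype, and computes the group-outcome association
#' statistics (modulation vs sustained odds ratios for early rejection
#' and five-year graft failure, plus the Kaplan-Meier comparison).
#' Deterministic given `config$seed`. When `config$out_dir` is set,
#' every stage's outputs are written as CSV plus a machine-readable
#' `summary.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `assignments`, `gap` (the gap curve or
#'   `NULL`), `k`, `cut`, `stats`, `summary`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  seed <- config$seed

  ## stage 0: data
  if (is.null(config$mfi)) {
    sim <- make_cohort(n_per_group = config$n_per_group,
                       noise_cv = config$noise_cv,
                       seed = child_seed(seed, 1L))
    mfi <- sim$mfi; cohort <- sim$cohort
  } else {
    mfi <- validate_mfi(config$mfi)
    cohort <- config$cohort
  }

  ## stage 1-2: gate, scale, split
  prep <- preprocess_cohort(mfi, threshold = config$threshold,
                            horizon = config$horizon,
                            min_last_day = config$min_last_day)
  gates <- vapply(prep$trajectories, function(tr) tr$gate, "")
  lens <- vapply(prep$trajectories, function(tr)
    tr$length_class %||% NA_character_, "")
  full <- prep$trajectories[gates == "responder" &
                              !is.na(lens) & lens == "full_50"]
  short <- prep$trajectories[gates == "responder" &
                               !is.na(lens) & lens == "short_20_50"]
  gated_ids <- vapply(prep$trajectories[gates == "no_response"],
                      function(tr) tr$case_id, "")

  assignments <- data.frame(case_id = gated_ids,
                            cluster = rep(0L, length(gated_ids)),
                            archetype = rep("no_response",
                                            length(gated_ids)),
                            stage = rep("gated", length(gated_ids)),
                            stringsAsFactors = FALSE)
  gap <- NULL; k <- NA_integer_; cut <- NULL
  if (length(full) >= 2L) {
    series <- clustering_series(full, horizon = config$horizon)
    if (identical(config$k, "auto")) {
      gap <- gap_curve(series, k_max = min(config$k_max,
                                           length(series) - 1L),
                       B = config$B, block_length = config$block_length,
                       seed = child_seed(seed, 2L))
      k <- select_k(gap)
      model <- attr(gap, "model")
    } else {
      k <- as.integer(config$k)
      model <- agglomerate(series)
    }
    cut <- cut_clusters(model, k)
    labels_full <- cut$labels
    arch <- label_archetypes(cut)
    assignments <- rbind(assignments, data.frame(
      case_id = names(labels_full), cluster = as.integer(labels_full),
      archetype = arch[labels_full], stage = "clustered",
      stringsAsFactors = FALSE))
    if (length(short) > 0L) {
      short_series <- clustering_series(short, horizon = config$horizon)
      labels_short <- classify_short(short_series, cut)
      assignments <- rbind(assignments, data.frame(
        case_id = names(labels_short),
        cluster = as.integer(labels_short),
        archetype = arch[labels_short], stage = "classified",
        stringsAsFactors = FALSE))
    }
  } else {
    message("fewer than two full-length responders: clustering skipped")
  }

  stats <- if (!is.null(cohort) && nrow(assignments) > 0L && !is.na(k))
    group_outcome_stats(assignments, cohort) else NULL

  summary <- list(seed = seed, config_hash = hash,
                  n_input = unname(prep$summary["n_input"]),
                  n_gated = unname(prep$summary["n_gated"]),
                  n_full = unname(prep$summary["n_full"]),
                  n_short = unname(prep$summary["n_short"]),
                  n_excluded = unname(prep$summary["n_excluded"]),
                  selected_k = k,
                  cluster_sizes = if (!is.null(cut))
                    as.integer(table(assignments$cluster)) else NULL)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- function(path) cat(sprintf("# dsadyn run seed=%d config=%s\n",
                                      seed, hash), file = path)
    write_with_header <- function(df, name) {
      path <- file.path(config$out_dir, name)
      hdr(path)
      suppressWarnings(write.table(df, path, sep = ",", row.names = FALSE,
                                   append = TRUE, qmethod = "double"))
    }
    write_with_header(mfi, "mfi.csv")
    if (!is.null(cohort)) write_with_header(cohort, "cohort.csv")
    write_with_header(assignments, "assignments.csv")
    if (!is.null(gap)) write_with_header(as.data.frame(gap), "gap_curve.csv")
    if (!is.null(cut)) {
      means <- do.call(rbind, lapply(seq_along(cut$representatives),
        function(i) data.frame(cluster = i,
                               day = seq_along(cut$representatives[[i]]),
                               value = cut$representatives[[i]])))
      write_with_header(means, "cluster_means.csv")
    }
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(assignments = assignments, gap = gap, k = k, cut = cut,
                 stats = stats, summary = summary, config_hash = hash))
}

#' Group-outcome association statistics
#'
#' Collapses clusters into modulation (fast/slow modulation archetypes)
#' versus sustained (rise-to-sustained/sustained archetypes) and
#' computes, for early acute rejection and five-year graft failure: the
#' per-arm rates, the 2x2 odds ratio with Wald CI, the Fisher two-tailed
#' p-value, and the Kaplan-Meier comparison with log-rank p for graft
#' survival.
#'
#' @param assignments Data frame from [run_pipeline()]: `case_id`,
#'   `cluster`, `archetype`, `stage`.
#' @param cohort Covariate/outcome table with `case_id`,
#'   `rejection_30d`, `gf_5y`, `followup_days`.
#' @return List with `rates` (per-arm outcome rates), `rejection_or`,
#'   `rejection_p`, `gf_or`, `gf_p`, `km`.
#' @export
group_outcome_stats <- function(assignments, cohort) {
  stopifnot(all(c("case_id", "archetype") %in% names(assignments)),
            all(c("case_id", "rejection_30d", "gf_5y",
                  "followup_days") %in% names(cohort)))
  arm <- ifelse(assignments$archetype %in%
                  c("fast_modulation", "slow_modulation"), "modulation",
         ifelse(assignments$archetype %in%
                  c("rise_to_sustained", "sustained"), "sustained", NA))
  d <- merge(data.frame(case_id = assignments$case_id, arm = arm,
                        stringsAsFactors = FALSE),
             cohort, by = "case_id")
  d <- d[!is.na(d$arm), , drop = FALSE]
  if (!all(c("modulation", "sustained") %in% d$arm))
    stop("both modulation and sustained arms are required")
  tab_of <- function(outcome) {
    ## rows: modulation (reference), sustained; cols: outcome no / yes
    rbind(c(sum(d$arm == "modulation" & d[[outcome]] == 0),
            sum(d$arm == "modulation" & d[[outcome]] == 1)),
          c(sum(d$arm == "sustained" & d[[outcome]] == 0),
            sum(d$arm == "sustained" & d[[outcome]] == 1)))
  }
  rej <- tab_of("rejection_30d"); gf <- tab_of("gf_5y")
  rates <- data.frame(
    arm = c("modulation", "sustained"),
    n = c(sum(d$arm == "modulation"), sum(d$arm == "sustained")),
    rejection_rate = c(rej[1, 2] / sum(rej[1, ]), rej[2, 2] / sum(rej[2, ])),
    gf_rate = c(gf[1, 2] / sum(gf[1, ]), gf[2, 2] / sum(gf[2, ])),
    stringsAsFactors = FALSE)
  km <- kaplan_meier(d$followup_days, d$gf_5y, d$arm)
  list(rates = rates,
       rejection_or = odds_ratio(rej),
       rejection_p = fisher_exact_2tail(rej),
       gf_or = odds_ratio(gf),
       gf_p = fisher_exact_2tail(gf),
       km = km)
}

## ---- CSV contracts -------------------------------------------------

validate_mfi <- function(df) {
  required <- c("case_id", "specificity", "day", "mfi")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("MFI table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  day_num <- suppressWarnings(as.numeric(df$day))
  if (anyNA(day_num)) {
    bad <- which(is.na(day_num))[1L]
    stop("non-numeric day at row ", bad)
  }
  if (!is.integer(df$day)) {
    warning("day column coerced to integer")
    day_num <- floor(day_num)
  }
  df$day <- as.integer(day_num)
  mfi_num <- suppressWarnings(as.numeric(df$mfi))
  if (anyNA(mfi_num)) stop("non-numeric MFI at row ",
                           which(is.na(mfi_num))[1L])
  if (any(mfi_num < 0)) stop("negative MFI at row ",
                             which(mfi_num < 0)[1L])
  df$mfi <- mfi_num
  key <- paste(df$case_id, df$specificity, df$day)
  if (any(duplicated(key)))
    stop("duplicate (case_id, specificity, day) at row ",
         which(duplicated(key))[1L])
  df
}

#' Read a long-format MFI CSV
#'
#' Expected columns: `case_id`, `specificity`, `day`, `mfi`. Float day
#' values like "3.0" are coerced to integer with a warning; missing
#' columns, non-numeric or negative MFI and duplicate keys are rejected
#' with the offending row.
#'
#' @param path CSV path (lines starting with `#` are treated as comments).
#' @return Validated data frame.
#' @export
read_mfi_csv <- function(path) {
  validate_mfi(read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE))
}

#' Read a per-case covariate/outcome CSV
#' @param path CSV path.
#' @return Data frame with at least `case_id`.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"case_id" %in% names(df)) stop("cohort table missing case_id")
  df
}

#' Write cluster assignments to CSV
#' @param assignments Data frame (`case_id`, `cluster`, `archetype`,
#'   `stage`).
#' @param path Output path.
#' @export
write_assignments <- function(assignments, path) {
  write.csv(assignments, path, row.names = FALSE)
  invisible(path)
}
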