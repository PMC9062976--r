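## ---------------------------------------------------------------------
## Synthetic cohort generator: total-DSA trajectory archetypes, sampling
## schedules, covariates and outcomes with the association structure the
## downstream analysis assumes.
## ---------------------------------------------------------------------

#' Archetype names for the five dynamic-response groups
#' @export
archetype_names <- c("no_response", "fast_modulation", "slow_modulation",
                     "rise_to_sustained", "sustained")

#' Parameters of a total-DSA trajectory archetype
#'
#' The five archetypes describe early post-transplant total-DSA (tDSA)
#' dynamics:
#' * group 0, no response: tDSA stays below the 1500-MFI gate throughout;
#' * group 1, fast modulation: quiescence for ~5 days, sharp rise peaking
#'   around day 13, a short (3-4 day) peak, then a sharp fall back to the
#'   pre-peak level with a half-life of about 5 days;
#' * group 2, slow modulation: same early rise and peak timing but a
#'   gradual decline reaching about 30% of peak by day 50, with visible
#'   oscillations;
#' * group 3, rise to sustained: higher baseline, slower rise peaking
#'   around day 21, then persistently high levels;
#' * group 4, sustained: persistently above 1500 MFI with no substantial
#'   rise or fall.
#'
#' @param group Integer 0-4.
#' @param baseline_mfi Pre-rise tDSA level (MFI).
#' @param quiescent_days Days of post-transplant quiescence before the rise.
#' @param peak_day Day of peak tDSA.
#' @param peak_mfi Peak tDSA level (MFI); must exceed `baseline_mfi` for
#'   groups 1-3.
#' @param peak_duration Days the trajectory stays at peak before decaying
#'   (group 1: typically 3-4).
#' @param decay_half_life Post-peak exponential decay half-life in days
#'   (group 1 default 5).
#' @param plateau_fraction_day50 For group 2, the fraction of peak level
#'   reached at day 50 (default 0.30); fixes the decay rate exactly, and
#'   takes precedence over `decay_half_life` when both are given.
#' @param oscillation_amplitude Amplitude of post-peak oscillations as a
#'   fraction of the current level (group 2 default 0.15, period 7 days).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise (default 0.1).
#' @return An object of class `archetype_params`.
#' @export
archetype_params <- function(group,
                             baseline_mfi = NULL,
                             quiescent_days = 5,
                             peak_day = NULL,
                             peak_mfi = NULL,
                             peak_duration = NULL,
                             decay_half_life = NULL,
                             plateau_fraction_day50 = NULL,
                             oscillation_amplitude = NULL,
                             noise_cv = 0.1) {
  if (!is.numeric(group) || length(group) != 1L || !(group %in% 0:4))
    stop("unknown group_id: must be an integer in 0..4")
  group <- as.integer(group)
  defaults <- switch(as.character(group),
    "0" = list(baseline_mfi = 800, peak_day = NA, peak_mfi = NA,
               peak_duration = 0, decay_half_life = NA,
               plateau_fraction_day50 = NA, oscillation_amplitude = 0),
    "1" = list(baseline_mfi = 1200, peak_day = 13, peak_mfi = 16000,
               peak_duration = 3, decay_half_life = 5,
               plateau_fraction_day50 = NA, oscillation_amplitude = 0),
    "2" = list(baseline_mfi = 1200, peak_day = 13, peak_mfi = 12000,
               peak_duration = 0, decay_half_life = 23,
               plateau_fraction_day50 = 0.30, oscillation_amplitude = 0.15),
    "3" = list(baseline_mfi = 3500, peak_day = 21, peak_mfi = 14000,
               peak_duration = 0, decay_half_life = NA,
               plateau_fraction_day50 = NA, oscillation_amplitude = 0),
    "4" = list(baseline_mfi = 9000, peak_day = NA, peak_mfi = NA,
               peak_duration = 0, decay_half_life = NA,
               plateau_fraction_day50 = NA, oscillation_amplitude = 0))
  p <- list(group = group,
            baseline_mfi = baseline_mfi %||% defaults$baseline_mfi,
            quiescent_days = quiescent_days,
            peak_day = peak_day %||% defaults$peak_day,
            peak_mfi = peak_mfi %||% defaults$peak_mfi,
            peak_duration = peak_duration %||% defaults$peak_duration,
            decay_half_life = decay_half_life %||% defaults$decay_half_life,
            plateau_fraction_day50 =
              plateau_fraction_day50 %||% defaults$plateau_fraction_day50,
            oscillation_amplitude =
              oscillation_amplitude %||% defaults$oscillation_amplitude,
            noise_cv = noise_cv)
  num <- p[c("baseline_mfi", "quiescent_days", "peak_day", "peak_mfi",
             "peak_duration", "decay_half_life", "plateau_fraction_day50",
             "oscillation_amplitude", "noise_cv")]
  bad <- vapply(num, function(v) is.numeric(v) && !is.na(v) && v < 0, TRUE)
  if (any(bad))
    stop("negative archetype parameter(s): ",
         paste(names(num)[bad], collapse = ", "))
  if (group %in% 1:3) {
    if (is.na(p$peak_mfi) || is.na(p$peak_day))
      stop("groups 1-3 require peak_mfi and peak_day")
    if (p$peak_mfi <= p$baseline_mfi)
      stop("peak_mfi must exceed baseline_mfi for groups 1-3")
  }
  structure(p, class = "archetype_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic (noise-free) trajectory skeleton on an arbitrary day grid
trajectory_skeleton <- function(params, grid) {
  p <- params
  t <- as.numeric(grid)
  if (p$group %in% c(0L, 4L)) return(rep(p$baseline_mfi, length(t)))

  base <- p$baseline_mfi
  peak <- p$peak_mfi
  peak_end <- p$peak_day + p$peak_duration
  ## logistic rise: midpoint between end of quiescence and peak day,
  ## scaled so the rise reaches 95% of its span at peak_day
  t_mid <- (p$quiescent_days + p$peak_day) / 2
  s <- max((p$peak_day - t_mid) / log(19), 1e-6)
  v <- numeric(length(t))

  pre <- t < p$peak_day
  v[pre] <- base + (peak - base) / (1 + exp(-(t[pre] - t_mid) / s))
  on_peak <- t >= p$peak_day & t <= peak_end
  v[on_peak] <- peak
  post <- t > peak_end
  if (any(post)) {
    dt <- t[post] - peak_end
    v[post] <- switch(as.character(p$group),
      ## fast modulation: exponential return to the pre-peak level
      "1" = base + (peak - base) * 2^(-dt / p$decay_half_life),
      ## slow modulation: exponential decay reaching exactly
      ## plateau_fraction_day50 * peak at day 50 (half-life form as
      ## fallback when no plateau fraction is given)
      "2" = if (!is.na(p$plateau_fraction_day50) &&
                p$plateau_fraction_day50 > 0) {
              peak * p$plateau_fraction_day50^(dt / (50 - peak_end))
            } else {
              peak * 2^(-dt / p$decay_half_life)
            },
      ## rise to sustained: levels stay high
      "3" = rep(peak, sum(post)))
    if (p$group == 2L && p$oscillation_amplitude > 0) {
      v[post] <- v[post] *
        (1 + p$oscillation_amplitude * sin(2 * pi * dt / 7))
    }
  }
  v
}

#' Generate one synthetic total-DSA trajectory
#'
#' Evaluates the archetype's deterministic skeleton on `grid` and applies
#' multiplicative log-normal measurement noise with the coefficient of
#' variation `params$noise_cv` (unit mean). Group-0 values are truncated
#' just below the 1500-MFI gate and group-4 values just above it, so the
#' gate semantics of the archetypes hold for every noise realisation.
#'
#' @param params An [archetype_params()] object.
#' @param grid Strictly increasing integer days in \[0, 50\].
#' @param seed Optional integer seed for the noise draw.
#' @return Numeric vector of MFI values, one per grid day.
#' @export
make_trajectory <- function(params, grid = 0:50, seed = NULL) {
  if (!inherits(params, "archetype_params"))
    stop("params must be an archetype_params object")
  grid <- as.numeric(grid)
  if (length(grid) == 0L || any(grid != floor(grid)) ||
      any(grid < 0) || any(grid > 50) || any(diff(grid) <= 0))
    stop("grid must be strictly increasing integers in [0, 50]")
  v <- trajectory_skeleton(params, grid)
  cv <- params$noise_cv
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- with_seed(seed, rlnorm(length(v), -sdlog^2 / 2, sdlog))
    v <- v * noise
  }
  gate <- .DEFAULT_GATE_MFI
  if (params$group == 0L) v <- pmin(v, 0.995 * gate)
  if (params$group == 4L) v <- pmax(v, 1.005 * gate)
  pmax(v, 0)
}

#' Sampling schedule for synthetic antibody monitoring
#'
#' Emulates clinical monitoring that is dense early (daily-ish testing in
#' the first `dense_window_days` days) and sparser later, with a
#' per-case last-observation ("dropout") day: a fraction `p_complete` of
#' cases are followed to day 50, the rest stop uniformly between
#' `min_dropout_day` and 49.
#'
#' @param dense_window_days Length of the densely sampled early window
#'   (days, default 20; must be at most 50).
#' @param dense_rate Per-day sampling probability inside the dense window
#'   (default 0.6).
#' @param late_rate Per-day sampling probability after the dense window
#'   (default 0.15).
#' @param p_complete Probability a case is observed through day 50
#'   (default 2/3, matching a 47/70 split of full versus shorter series).
#' @param min_dropout_day Earliest possible last-observation day for
#'   incomplete cases (default 21, so generated cases meet the 21-day
#'   inclusion rule).
#' @return An object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(dense_window_days = 20, dense_rate = 0.6,
                              late_rate = 0.15, p_complete = 2 / 3,
                              min_dropout_day = 21) {
  if (dense_window_days > 50)
    stop("dense_window_days must not exceed the 50-day horizon")
  if (dense_rate <= 0) stop("dense_rate must be positive")
  if (late_rate < 0) stop("late_rate must be non-negative")
  stopifnot(p_complete >= 0, p_complete <= 1, min_dropout_day >= 1)
  structure(list(dense_window_days = dense_window_days,
                 dense_rate = min(dense_rate, 1),
                 late_rate = min(late_rate, 1),
                 p_complete = p_complete,
                 min_dropout_day = min_dropout_day),
            class = "sampling_schedule")
}

#' Draw one case's observation days
#'
#' Day 0 (transplant day) and the dropout day are always observed; every
#' other day up to the dropout day is observed independently with the
#' window-specific probability.
#'
#' @param schedule A [sampling_schedule()].
#' @param seed Optional integer seed.
#' @param dropout_day Optional fixed last-observation day; when `NULL` it
#'   is drawn from the schedule's dropout distribution.
#' @return Sorted integer vector of observation days, starting at 0.
#' @export
make_schedule <- function(schedule, seed = NULL, dropout_day = NULL) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  with_seed(seed, {
    if (is.null(dropout_day)) {
      dropout_day <- if (runif(1) < schedule$p_complete) 50L else
        sample(seq(schedule$min_dropout_day, 49L), 1L)
    }
    dropout_day <- as.integer(dropout_day)
    stopifnot(dropout_day >= 1L, dropout_day <= 50L)
    days <- seq_len(dropout_day) # candidate days 1..dropout
    p <- ifelse(days <= schedule$dense_window_days,
                schedule$dense_rate, schedule$late_rate)
    keep <- runif(length(days)) < p
    sort(unique(c(0L, days[keep], dropout_day)))
  })
}

#' Covariate and outcome model for the synthetic cohort
#'
#' Per-group probabilities and means follow the direction of the observed
#' group differences: modulation groups (1-2) have high early-rejection
#' rates and low 5-year graft-failure rates, sustained groups (3-4) the
#' reverse; female gender and fewer previous transplants are more common
#' in the modulation groups.
#'
#' @param p_female,p_prev_tx,p_rejection,p_gf5y Numeric length-5 vectors
#'   of per-group probabilities (groups 0-4).
#' @param p_crossmatch_pos,p_cdc_pos Per-group probabilities of a positive
#'   flow / CDC crossmatch (CDC-positive implies crossmatch-positive).
#' @param age_mean Per-group mean age at transplant (years).
#' @param age_sd Common age standard deviation (years).
#' @return An object of class `covariate_model`.
#' @export
covariate_model <- function(
    p_female    = c(0.556, 0.933, 0.783, 0.313, 0.438),
    p_prev_tx   = c(0.722, 0.267, 0.609, 0.813, 0.750),
    p_rejection = c(0.167, 0.800, 0.565, 0.563, 0.188),
    p_gf5y      = c(0.111, 0.067, 0.043, 0.313, 0.250),
    p_crossmatch_pos = c(0.556, 0.733, 0.696, 0.938, 0.813),
    p_cdc_pos   = c(0.111, 0.133, 0.174, 0.375, 0.250),
    age_mean    = c(43.9, 44.9, 40.2, 37.1, 39.7),
    age_sd      = 9) {
  probs <- list(p_female = p_female, p_prev_tx = p_prev_tx,
                p_rejection = p_rejection, p_gf5y = p_gf5y,
                p_crossmatch_pos = p_crossmatch_pos, p_cdc_pos = p_cdc_pos)
  for (nm in names(probs)) {
    v <- probs[[nm]]
    if (length(v) != 5L || any(v < 0) || any(v > 1))
      stop(nm, " must be 5 probabilities in [0, 1]")
  }
  if (any(p_cdc_pos > p_crossmatch_pos))
    stop("p_cdc_pos cannot exceed p_crossmatch_pos")
  if (mean(p_rejection[2:3]) <= mean(p_rejection[4:5]) ||
      mean(p_gf5y[2:3]) >= mean(p_gf5y[4:5]))
    stop(paste("default direction violated: modulation groups must have",
               "higher rejection and lower graft-failure probability",
               "than sustained groups"))
  structure(c(probs, list(age_mean = age_mean, age_sd = age_sd)),
            class = "covariate_model")
}

## per-case jitter of the archetype defaults; called inside a seeded block
draw_case_params <- function(group, noise_cv, param_jitter = TRUE) {
  if (!param_jitter)
    return(archetype_params(group, noise_cv = noise_cv))
  rl <- function(med, sdlog) rlnorm(1, log(med), sdlog)
  switch(as.character(group),
    "0" = archetype_params(0, baseline_mfi = min(rl(700, 0.25), 1350),
                           noise_cv = noise_cv),
    "1" = {
      base <- rl(1200, 0.3)
      peak <- max(rl(16000, 0.35), 8 * base)
      archetype_params(1, baseline_mfi = base, peak_mfi = peak,
                       peak_day = min(max(round(rnorm(1, 13, 1.5)), 10), 16),
                       peak_duration = sample(3:4, 1),
                       decay_half_life = rl(5, 0.15),
                       quiescent_days = sample(4:6, 1),
                       noise_cv = noise_cv)
    },
    "2" = {
      base <- rl(1200, 0.3)
      peak <- max(rl(12000, 0.35), 6 * base)
      archetype_params(2, baseline_mfi = base, peak_mfi = peak,
                       peak_day = min(max(round(rnorm(1, 13, 1.5)), 9), 17),
                       plateau_fraction_day50 =
                         min(max(rnorm(1, 0.30, 0.05), 0.20), 0.45),
                       quiescent_days = sample(4:6, 1),
                       noise_cv = noise_cv)
    },
    "3" = {
      base <- rl(3500, 0.3)
      peak <- max(rl(14000, 0.35), 2.5 * base)
      archetype_params(3, baseline_mfi = base, peak_mfi = peak,
                       peak_day = min(max(round(rnorm(1, 21, 2)), 17), 26),
                       quiescent_days = sample(4:6, 1),
                       noise_cv = noise_cv)
    },
    "4" = archetype_params(4, baseline_mfi = max(rl(9000, 0.3), 2500),
                           noise_cv = noise_cv))
}

#' Generate a synthetic cohort of DSA time series and outcomes
#'
#' Draws `n_per_group[g + 1]` cases from archetype group `g` (g = 0..4),
#' samples each case's observation days from `schedule`, evaluates a
#' per-case jittered trajectory at those days, and partitions each
#' total-DSA value across 1-7 DSA specificities by a per-case Dirichlet
#' split (only the sum is modelled mechanistically). Covariates and
#' outcomes are drawn from `covariates`. The generation is fully
#' deterministic given `seed`; true group labels are retained in the
#' `true_group` column of the covariate table.
#'
#' @param n_per_group Integer vector of length 5: cases per group 0-4.
#' @param covariates A [covariate_model()].
#' @param schedule A [sampling_schedule()].
#' @param noise_cv Measurement-noise coefficient of variation (default 0.1).
#' @param param_jitter If `TRUE` (default), archetype parameters are
#'   jittered per case (peak level and timing, baseline, decay rate)
#'   around their defaults for a more heterogeneous cohort; `FALSE`
#'   draws every case from the exact archetype defaults, so measurement
#'   noise is the only source of within-group variation (the condition
#'   used for cluster-number recovery experiments).
#' @param seed Integer seed.
#' @return A list with `mfi` (long-format data frame: `case_id`,
#'   `specificity`, `day`, `mfi`) and `cohort` (one row per case:
#'   `case_id`, `age`, `gender`, `prev_tx`, `crossmatch`, `rejection_30d`,
#'   `gf_5y`, `followup_days`, `true_group`).
#' @examples
#' cohort <- make_cohort(n_per_group = c(2, 2, 2, 2, 2), seed = 1)
#' head(cohort$mfi)
#' cohort$cohort
#' @export
make_cohort <- function(n_per_group = c(18L, 15L, 23L, 16L, 16L),
                        covariates = covariate_model(),
                        schedule = sampling_schedule(),
                        noise_cv = 0.1,
                        param_jitter = TRUE,
                        seed = 1L) {
  if (length(n_per_group) != 5L || any(n_per_group < 0))
    stop("n_per_group must be 5 non-negative counts")
  if (sum(n_per_group) == 0L) stop("n_per_group must not be all zero")
  stopifnot(inherits(covariates, "covariate_model"),
            inherits(schedule, "sampling_schedule"))
  groups <- rep(0:4, times = n_per_group)
  n <- length(groups)
  ids <- sprintf("case_%03d", seq_len(n))

  mfi_rows <- vector("list", n)
  cov_rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    mfi_rows[[i]] <- with_seed(child_seed(seed, i), {
      params <- draw_case_params(g, noise_cv, param_jitter)
      days <- make_schedule(schedule)
      tdsa <- make_trajectory(params, grid = days, seed = NULL)
      n_spec <- sample(1:7, 1)
      w <- rgamma(n_spec, shape = 1)
      w <- w / sum(w)
      spec <- sprintf("DSA%d", seq_len(n_spec))
      data.frame(case_id = ids[i],
                 specificity = rep(spec, each = length(days)),
                 day = rep(days, times = n_spec),
                 mfi = as.vector(outer(tdsa, w)),
                 stringsAsFactors = FALSE)
    })
    cov_rows[[i]] <- with_seed(child_seed(seed, 500000L + i), {
      cm <- covariates
      j <- g + 1L
      u <- runif(1)
      crossmatch <- if (u < cm$p_cdc_pos[j]) "CDC+FC+SAB+"
        else if (u < cm$p_crossmatch_pos[j]) "CDC-FC+SAB+"
        else "CDC-FC-SAB+"
      gf <- rbinom(1, 1, cm$p_gf5y[j])
      data.frame(case_id = ids[i],
                 age = min(max(round(rnorm(1, cm$age_mean[j], cm$age_sd)),
                               18), 75),
                 gender = if (rbinom(1, 1, cm$p_female[j]) == 1)
                   "female" else "male",
                 prev_tx = rbinom(1, 1, cm$p_prev_tx[j]),
                 crossmatch = crossmatch,
                 rejection_30d = rbinom(1, 1, cm$p_rejection[j]),
                 gf_5y = gf,
                 followup_days = if (gf == 1)
                   round(runif(1, 30, 1826)) else 1826,
                 true_group = g,
                 stringsAsFactors = FALSE)
    })
  }
  list(mfi = do.call(rbind, mfi_rows),
       cohort = do.call(rbind, cov_rows))
}

#' Noise-free scaled skeleton of an archetype
#'
#' Used to label clusters by their nearest archetype shape.
#'
#' @param group Integer 0-4.
#' @param grid Day grid (default 1:50, the clustering window).
#' @return Numeric vector scaled to maximum 1.
#' @export
archetype_skeleton <- function(group, grid = 1:50) {
  p <- archetype_params(group, noise_cv = 0,
                        oscillation_amplitude = 0)
  v <- trajectory_skeleton(p, grid)
  v / max(v)
}
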