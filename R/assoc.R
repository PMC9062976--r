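## ---------------------------------------------------------------------
## Association statistics: two-by-two odds ratios, exact/rank tests,
## stepwise F-test logistic regression with ROC / precision-recall
## summaries, and Kaplan-Meier survival comparison.
## ---------------------------------------------------------------------

#' Odds ratio with Wald confidence interval from a 2x2 table
#'
#' Orientation: rows are exposure levels (reference first, exposed
#' second), columns are outcome levels (negative first, positive
#' second):
#' \preformatted{
#'              outcome-     outcome+
#'   unexposed      a            b
#'   exposed        c            d
#' }
#' The returned odds ratio is `odds(outcome | exposed) /
#' odds(outcome | unexposed) = (d/c) / (b/a) = ad / (bc)`, with the
#' 95% Wald interval `exp(log OR +- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Any zero cell makes the Wald OR inestimable and an `NA` marker is
#' returned (reported as "n/a").
#'
#' @param tab 2x2 numeric matrix (or table) of counts in the orientation
#'   above.
#' @return List with `or`, `ci_low`, `ci_high`, `estimable`.
#' @examples
#' # female gender vs a sustained antibody response:
#' odds_ratio(matrix(c(6, 32, 20, 12), nrow = 2))  # OR 0.11 (0.04-0.35)
#' @export
odds_ratio <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != floor(tab)))
    stop("tab must be a 2x2 matrix of non-negative integer counts")
  if (sum(tab) == 0) stop("empty table")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  if (any(tab == 0))
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                estimable = FALSE))
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       estimable = TRUE)
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger
#' than that of the observed table (the standard two-tailed convention).
#'
#' @param tab 2x2 matrix of counts.
#' @return The p-value.
#' @export
fisher_exact_2tail <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0))
    stop("tab must be a 2x2 matrix of non-negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in contingency table")
  fisher.test(tab)$p.value
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when the combined sample size is at most 20
#' and there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y Numeric vectors (non-empty).
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(1)
  }
  use_exact <- length(all_v) <= 20L && !any(duplicated(all_v))
  suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
}

#' ROC and precision-recall AUC of a score against binary labels
#'
#' ROC-AUC by the rank (Mann-Whitney) formulation with mid-rank tie
#' handling; PR-AUC by step interpolation over the recall steps (average
#' precision), avoiding the optimism of trapezoidal PR interpolation.
#' Baselines: 0.5 for ROC; the positive-class prevalence for PR.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return List with `roc_auc`, `pr_auc`, `roc_baseline`, `pr_baseline`,
#'   `roc_ratio`, `pr_ratio`.
#' @export
auc_measures <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUCs")
  r <- rank(scores)
  roc_auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  ## average precision over unique-score thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y); cum_pp <- seq_along(y)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cum_tp[last_of_tie]; pp <- cum_pp[last_of_tie]
  recall <- tp / n_pos
  precision <- tp / pp
  pr_auc <- sum(diff(c(0, recall)) * precision)
  prev <- n_pos / length(labels)
  list(roc_auc = roc_auc, pr_auc = pr_auc,
       roc_baseline = 0.5, pr_baseline = prev,
       roc_ratio = roc_auc / 0.5, pr_ratio = pr_auc / prev)
}

## deviance F test comparing nested binomial fits:
## F = (dev_reduced - dev_full) / ddf / (dev_full / df_res_full)
deviance_f_p <- function(fit_reduced, fit_full) {
  ddev <- fit_reduced$deviance - fit_full$deviance
  ddf <- fit_reduced$df.residual - fit_full$df.residual
  if (ddf <= 0) return(1)
  denom_df <- fit_full$df.residual
  denom <- fit_full$deviance / denom_df
  if (denom <= 0) return(0)
  f <- (ddev / ddf) / denom
  pf(f, ddf, denom_df, lower.tail = FALSE)
}

fit_logistic <- function(formula, data) {
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  ## diverging coefficients betray (quasi-)separation even when glm
  ## converges without warning
  if (any(abs(coef(fit)[-1]) > 12, na.rm = TRUE)) separated <- TRUE
  attr(fit, "separated") <- separated
  fit
}

#' Stepwise logistic regression with deviance F tests
#'
#' Forward-backward variable selection for a binary outcome: at each
#' step, a candidate enters if the deviance F test for adding it has
#' p < `p_enter`, and an included term leaves if the F test for dropping
#' it has p > `p_remove`. The F statistic compares nested fits as
#' `(deviance change / df change) / (residual deviance / residual df)` of
#' the larger model. Candidates whose addition produces complete
#' separation are flagged and excluded with a warning.
#'
#' @param data Data frame with no missing values in the used columns.
#' @param outcome Name of the binary outcome column.
#' @param candidates Character vector of candidate predictor columns.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10).
#' @return An `lr_model`: list with `terms` (selected predictors), `fit`
#'   (the `glm`), `coefficients` (data frame: term, estimate, odds ratio,
#'   95% Wald CI, p), `deviance`, and the [auc_measures()] of the fitted
#'   probabilities (`roc_auc`, `pr_auc`, baselines and ratios).
#' @export
stepwise_lr <- function(data, outcome, candidates,
                        p_enter = 0.05, p_remove = 0.10) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(candidates %in% names(data)))
  used <- data[, c(outcome, candidates), drop = FALSE]
  if (anyNA(used)) stop("missing values in outcome or candidates")
  y <- used[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")

  terms <- character(0)
  excluded <- character(0)
  form <- function(t) {
    rhs <- if (length(t)) paste(t, collapse = " + ") else "1"
    stats::as.formula(paste(outcome, "~", rhs))
  }
  current <- fit_logistic(form(terms), used)
  repeat {
    changed <- FALSE
    ## backward: drop the worst term if its F-test p exceeds p_remove
    if (length(terms) > 0L) {
      p_drop <- vapply(terms, function(t) {
        reduced <- fit_logistic(form(setdiff(terms, t)), used)
        deviance_f_p(reduced, current)
      }, 1.0)
      worst <- which.max(p_drop)
      if (p_drop[worst] > p_remove) {
        terms <- setdiff(terms, terms[worst])
        current <- fit_logistic(form(terms), used)
        changed <- TRUE
        next
      }
    }
    ## forward: add the best remaining candidate if p < p_enter
    remaining <- setdiff(candidates, c(terms, excluded))
    if (length(remaining) > 0L) {
      p_add <- vapply(remaining, function(t) {
        bigger <- fit_logistic(form(c(terms, t)), used)
        if (attr(bigger, "separated")) return(NA_real_)
        deviance_f_p(current, bigger)
      }, 1.0)
      sep <- remaining[is.na(p_add)]
      if (length(sep)) {
        warning("excluding term(s) causing complete separation: ",
                paste(sep, collapse = ", "))
        excluded <- c(excluded, sep)
        remaining <- setdiff(remaining, sep)
        p_add <- p_add[!is.na(p_add)]
      }
      if (length(remaining) > 0L && min(p_add) < p_enter) {
        terms <- c(terms, remaining[which.min(p_add)])
        current <- fit_logistic(form(terms), used)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cf <- summary(current)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1],
                      or = exp(cf[, 1]),
                      ci_low = exp(cf[, 1] - 1.96 * cf[, 2]),
                      ci_high = exp(cf[, 1] + 1.96 * cf[, 2]),
                      p = cf[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  auc <- if (length(unique(y)) == 2L)
    auc_measures(predict(current, type = "response"), y) else NULL
  structure(c(list(terms = terms, fit = current, coefficients = coefs,
                   deviance = current$deviance), auc),
            class = "lr_model")
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival estimates per group and the two-group log-rank
#' test, via the survival package.
#'
#' @param time Positive follow-up times (days).
#' @param event Event indicator (1 = graft failure, 0 = censored).
#' @param group Two-level group factor (e.g. modulation vs sustained).
#' @return List with `curves` (data frame: `group`, `time`, `survival`,
#'   `n_risk`), `logrank_p`, and the `survfit` object as `fit`.
#' @export
kaplan_meier <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  group <- factor(group)
  if (any(table(group) == 0L) || nlevels(group) < 2L)
    stop("each group must contain at least one case")
  d <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (sum(event) == 0) {
    p <- NA_real_ # log-rank undefined without any events
  } else {
    sdf <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    p <- pchisq(sdf$chisq, df = length(sdf$n) - 1L, lower.tail = FALSE)
  }
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, survival = fit$surv,
                       n_risk = fit$n.risk, stringsAsFactors = FALSE)
  list(curves = curves, logrank_p = p, fit = fit)
}
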