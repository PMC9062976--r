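# 2x2 layout used throughout: rows = exposure (reference, exposed),
# columns = outcome (negative, positive), column-major entry:
# matrix(c(ref_neg, exp_neg, ref_pos, exp_pos), nrow = 2)

test_that("odds ratios reproduce the published univariate tables", {
  # modulation/sustained comparisons
  or <- function(tab) odds_ratio(tab)$or
  expect_equal(or(matrix(c(6, 32, 20, 12), 2)), 0.1125, tolerance = 1e-12)
  expect_equal(round(or(matrix(c(6, 32, 20, 12), 2)), 2), 0.11)
  expect_equal(round(or(matrix(c(20, 18, 7, 25), 2)), 0), 4)
  expect_equal(round(or(matrix(c(22, 16, 28, 4), 2)), 1), 0.2)
  expect_equal(round(or(matrix(c(11, 27, 20, 12), 2)), 2), 0.24)
  expect_equal(round(or(matrix(c(36, 2, 23, 9), 2)), 0), 7)
  # graft-failure comparisons
  expect_equal(round(or(matrix(c(29, 46, 3, 10), 2)), 1), 2.1)
  expect_equal(round(or(matrix(c(28, 47, 6, 7), 2)), 1), 0.7)

  ci <- odds_ratio(matrix(c(6, 32, 20, 12), 2))
  expect_equal(round(ci$ci_low, 2), 0.04)
  expect_equal(round(ci$ci_high, 2), 0.35)
})

test_that("zero cells yield the inestimable marker and inverses multiply
          to one", {
  na_or <- odds_ratio(matrix(c(7, 68, 0, 13), 2))
  expect_false(na_or$estimable)
  expect_true(is.na(na_or$or))

  set.seed(30)
  for (i in 1:20) {
    tab <- matrix(sample(1:40, 4, replace = TRUE), 2)
    swapped <- tab[, 2:1]
    expect_equal(odds_ratio(tab)$or * odds_ratio(swapped)$or, 1)
  }
})

test_that("Fisher two-tailed p agrees with hypergeometric enumeration", {
  expect_equal(signif(fisher_exact_2tail(matrix(c(1, 11, 9, 3), 2)), 3),
               0.00276)
  expect_equal(fisher_exact_2tail(matrix(c(5, 5, 5, 5), 2)), 1)

  set.seed(31)
  for (i in 1:50) {
    tab <- matrix(rmultinom(1, sample(8:30, 1), rep(0.25, 4)), 2) + 1
    p <- fisher_exact_2tail(tab)
    expect_equal(p, fisher_oracle(tab), tolerance = 1e-10)
    expect_equal(p, fisher_exact_2tail(t(tab)), tolerance = 1e-12)
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("Wilcoxon rank-sum handles exact, tied and degenerate cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_warning(p <- wilcoxon_rank_sum(rep(2, 5), rep(2, 4)), "tied")
  expect_equal(p, 1)
})

test_that("Wilcoxon rejection rate tracks an independent rank-sum oracle", {
  set.seed(32)
  n_rep <- 300
  rej <- orc <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(50); y <- rnorm(50, 0.5)
    rej[i] <- wilcoxon_rank_sum(x, y) < 0.05
    orc[i] <- ranksum_z_p(x, y) < 0.05
  }
  expect_lt(abs(mean(rej) - mean(orc)), 0.02)
})

test_that("AUCs match pair counting and behave at the extremes", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  a <- auc_measures(scores, labels)
  expect_equal(a$roc_auc, roc_oracle(scores, labels))
  expect_equal(a$pr_baseline, 0.5)
  expect_equal(a$roc_ratio, a$roc_auc / 0.5)

  perfect <- auc_measures(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$pr_auc, 1)

  set.seed(33)
  rnd <- auc_measures(runif(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(rnd$roc_auc - 0.5), 0.05)

  set.seed(34)
  for (i in 1:20) {
    s <- sample(seq(0, 1, by = 0.1), 12, replace = TRUE) # ties included
    l <- rbinom(12, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc_measures(s, l)$roc_auc, roc_oracle(s, l))
  }
  expect_error(auc_measures(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("stepwise logistic regression adds and removes by F tests", {
  set.seed(35)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  eta <- 1.5 * d$x1
  d$y <- rbinom(n, 1, plogis(eta))

  fit <- stepwise_lr(d, "y", c("x1", "x2", "x3"))
  expect_equal(fit$terms, "x1")
  expect_true(all(c("roc_auc", "pr_auc", "pr_ratio") %in% names(fit)))
  expect_gt(fit$roc_auc, 0.6)
  # coefficient table carries ORs with Wald intervals
  row <- fit$coefficients[fit$coefficients$term == "x1", ]
  expect_true(row$ci_low < row$or && row$or < row$ci_high)

  # p_enter = 0: nothing can enter
  empty <- stepwise_lr(d, "y", c("x1", "x2", "x3"), p_enter = 0)
  expect_length(empty$terms, 0L)

  # pure noise: intercept-only model
  set.seed(36)
  d2 <- data.frame(y = rbinom(100, 1, 0.5), a = rnorm(100), b = rnorm(100))
  expect_length(stepwise_lr(d2, "y", c("a", "b"))$terms, 0L)

  # p_enter = 1 forces the first forward step to take the best candidate
  one_step <- stepwise_lr(d2, "y", c("a", "b"), p_enter = 1,
                          p_remove = 1)
  expect_length(one_step$terms, 2L)
  f_a <- glm(y ~ a, binomial, d2)$deviance
  f_b <- glm(y ~ b, binomial, d2)$deviance
  expect_equal(one_step$terms[1], if (f_a < f_b) "a" else "b")

  expect_error(stepwise_lr(data.frame(y = c(0, 1, NA), x = 1:3), "y", "x"),
               "missing")
})

test_that("perfectly separating candidates are flagged and excluded", {
  d <- data.frame(y = c(rep(0, 20), rep(1, 20)),
                  sep = c(rep(0, 20), rep(1, 20)),
                  ok = rnorm(40))
  expect_warning(fit <- stepwise_lr(d, "y", c("sep", "ok")), "separation")
  expect_false("sep" %in% fit$terms)
})

test_that("Kaplan-Meier estimates and log-rank behave as expected", {
  # all censored: survival stays at 1, log-rank undefined
  km <- kaplan_meier(c(5, 10, 15, 20), c(0, 0, 0, 0), c("a", "a", "b", "b"))
  expect_true(all(km$curves$survival == 1))
  expect_true(is.na(km$logrank_p))

  # product-limit by hand: events at t = 1, 2 in one group of two
  km2 <- kaplan_meier(c(1, 2, 5, 6), c(1, 1, 0, 0), c("g1", "g1", "g2", "g2"))
  g1 <- km2$curves[km2$curves$group == "g1", ]
  expect_equal(g1$survival[g1$time == 1], 0.5)
  expect_equal(g1$survival[g1$time == 2], 0)

  expect_error(kaplan_meier(c(1, -1), c(1, 0), c("a", "b")), "positive")
  expect_error(kaplan_meier(c(1, 2), c(1, 0), c("a", "a")), "group")
})

test_that("log-rank type-I error is near nominal under equal hazards", {
  set.seed(37)
  n_rep <- 600
  rej <- vapply(seq_len(n_rep), function(i) {
    t1 <- rexp(40, 0.02); t2 <- rexp(40, 0.02)
    cens <- 100
    time <- pmin(c(t1, t2), cens)
    event <- as.integer(c(t1, t2) <= cens)
    kaplan_meier(time, event, rep(c("a", "b"), each = 40))$logrank_p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})
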