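toy_table <- function(y, n_c = 4, n_i = 4) {
  n <- n_c + n_i
  trial_table(data.frame(
    subject = rep(sprintf("S%02d", 1:n), each = 2),
    group = rep(rep(c("control", "intervention"), c(n_c, n_i)), each = 2),
    timepoint = rep(c("baseline", "week12"), n),
    y = y), c(y = "parametric"))
}

test_that("imputation fills by group-and-timepoint mean or median", {
  d <- data.frame(
    subject = rep(c("A", "B", "C", "D", "E", "F"), each = 2),
    group = rep(rep(c("control", "intervention"), each = 3), each = 2),
    timepoint = rep(c("baseline", "week12"), 6),
    par = c(2, 1, 4, 1, NA, 1, 5, 2, 7, 2, 9, NA),
    npar = c(1, 5, 2, 5, 9, 5, 1, 0, 2, 0, 9, NA)
  )
  tab <- trial_table(d, c(par = "parametric", npar = "nonparametric"))
  imp <- impute_missing(tab)
  # parametric: [2, 4, NA] at control baseline -> mean 3
  expect_equal(imp$par[5], 3)
  # parametric: intervention week12 [2, 2, NA] -> 2
  expect_equal(imp$par[12], 2)
  # nonparametric: intervention week12 [0, 0, NA] -> median 0
  expect_equal(imp$npar[12], 0)
  # observed values untouched; imputation preserves parametric cell means
  expect_identical(imp$par[-c(5, 12)], d$par[-c(5, 12)])
  expect_equal(mean(imp$par[imp$group == "control" &
                              imp$timepoint == "baseline"]), 3)
  # no-missing table returned unchanged
  full <- impute_missing(trial_table(d[!is.na(d$par) & !is.na(d$npar), ][1:8, ],
                                     c(par = "parametric",
                                       npar = "nonparametric")))
  expect_false(any(attr(full, "imputed")))
  # a fully missing cell is unimputable
  d2 <- d; d2$par[d2$group == "control" & d2$timepoint == "baseline"] <- NA
  expect_error(impute_missing(trial_table(d2, attr(tab, "var_types"))),
               "unimputable")
})

test_that("nonparametric imputation uses the median: [1,2,9,NA] -> 2", {
  d <- data.frame(
    subject = rep(sprintf("S%d", 1:4), each = 2),
    group = "control",
    timepoint = rep(c("baseline", "week12"), 4),
    v = c(1, 0, 2, 0, 9, 0, NA, 0))
  imp <- impute_missing(trial_table(d, c(v = "nonparametric")))
  expect_equal(imp$v[7], 2)
})

test_that("assumption checks behave under null and violation", {
  # identical samples: Levene statistic exactly 0
  x <- rnorm(20)
  rep_lv <- check_assumptions(list(a = x, b = x))
  expect_equal(rep_lv$levene$statistic, 0)
  # standard-normal samples pass KS in nearly all seeded replicates
  pass <- vapply(1:50, function(s) {
    set.seed(s)
    check_assumptions(list(a = rnorm(100), b = rnorm(100)))$normality$p[1]
  }, 0)
  expect_gte(mean(pass > 0.05), 0.9)
  # 100-fold variance ratio at n = 30 is flagged
  set.seed(1)
  viol <- check_assumptions(list(a = rnorm(30, 0, 1), b = rnorm(30, 0, 10)))
  expect_lt(viol$levene$p, 0.01)
  expect_error(check_assumptions(list(a = 1:2, b = 1:5)), "at least 3")
})

test_that("mixed ANOVA equals the matrix-algebra GLM and aov oracles", {
  set.seed(42)
  y <- rnorm(16, 10, 2)
  tab <- toy_table(y)
  res <- rm_anova_interaction(tab, "y", posthoc = FALSE)
  d <- as.data.frame(tab)
  d$subject <- factor(d$subject); d$timepoint <- factor(d$timepoint)
  # GLM route: compare full and reduced linear models for the interaction
  full <- lm(y ~ subject + timepoint * group, data = d)
  red <- lm(y ~ subject + timepoint, data = d)
  f_glm <- (deviance(red) - deviance(full)) / 1 /
    (deviance(full) / df.residual(full))
  expect_equal(res$table$F[res$table$term == "interaction"], f_glm,
               tolerance = 1e-6)
  # aov route: all three terms
  a <- summary(aov(y ~ group * timepoint + Error(subject), data = d))
  aw <- a[["Error: Within"]][[1]]
  ab <- a[["Error: subject"]][[1]]
  rownames(aw) <- trimws(rownames(aw))
  rownames(ab) <- trimws(rownames(ab))
  expect_equal(res$table$F[1], ab["group", "F value"], tolerance = 1e-6)
  expect_equal(res$table$F[2], aw["timepoint", "F value"], tolerance = 1e-6)
  expect_equal(res$table$F[3], aw["group:timepoint", "F value"],
               tolerance = 1e-6)
  expect_equal(res$table$p[3], aw["group:timepoint", "Pr(>F)"],
               tolerance = 1e-6)
})

test_that("exactly additive cell means give zero interaction SS", {
  # per-subject changes vary, but both group means of the change equal 3:
  # the cell means are additive and the interaction SS is exactly zero
  pre <- 1:8
  chg <- c(2, 4, 3, 3, 1, 5, 3, 3)
  y <- as.numeric(rbind(pre, pre + chg))
  res <- rm_anova_interaction(toy_table(y), "y", posthoc = FALSE)
  expect_equal(res$table$F[res$table$term == "interaction"], 0)
})

test_that("injected group-by-time effects are detected with high power", {
  hits <- vapply(1:60, function(s) {
    sc <- trial_scenario(variables = data.frame(
      variable = "y", mean = 10, sd = 2, effect_d = 1.0,
      var_type = "parametric"), missing_rate = 0.05, seed = s)
    g <- generate_trial_dataset(sc)
    tab <- impute_missing(g$table)
    rm_anova_interaction(tab, "y", posthoc = FALSE)$table$p[3] < 0.05
  }, NA)
  expect_gte(mean(hits), 0.8)
})

test_that("Newman-Keuls matches hand-computed q and keeps coherence", {
  # all means equal: nothing rejected
  nk0 <- newman_keuls(c(a = 1, b = 1, c = 1), mse = 1, n = 5, df_error = 12)
  expect_false(any(nk0$significant))
  # widely spread means: all pairs rejected, q equals (diff)/sqrt(mse/n)
  nk <- newman_keuls(c(a = 0, b = 5, c = 10), mse = 1, n = 5, df_error = 12)
  expect_true(all(nk$significant))
  expect_equal(nk$q[nk$mean_a == "a" & nk$mean_b == "c"],
               10 / sqrt(1 / 5))
  expect_equal(nk$q_crit[nk$span == 3], qtukey(0.95, 3, 12))
  expect_equal(nk$q_crit[nk$span == 2], rep(qtukey(0.95, 2, 12), 2))
  expect_error(newman_keuls(c(1, 2), mse = -1, n = 5, df_error = 10),
               "positive")
  # containment: no significant pair inside an accepted wider range
  for (seed in 1:30) {
    set.seed(seed)
    k <- sample(3:6, 1)
    means <- sort(rnorm(k, 0, sample(c(0.2, 1, 3), 1)))
    names(means) <- letters[1:k]
    nkr <- newman_keuls(means, mse = 1, n = 6, df_error = 20)
    pos <- function(nm) match(nm, names(sort(means)))
    acc <- nkr[!nkr$significant, ]
    for (r in seq_len(nrow(acc))) {
      i <- pos(acc$mean_a[r]); j <- pos(acc$mean_b[r])
      inside <- nkr[pos(nkr$mean_a) >= i & pos(nkr$mean_b) <= j, ]
      expect_false(any(inside$significant))
    }
  }
})

test_that("follow-up rm-ANOVA equals the hand-computed toy table", {
  d <- data.frame(
    subject = rep(sprintf("S%d", 1:4), each = 3),
    group = "intervention",
    timepoint = rep(c("baseline", "week12", "week24"), 4),
    y = c(1, 2, 3, 2, 4, 6, 0, 1, 2, 3, 3, 3))
  tab <- trial_table(d, c(y = "parametric"))
  res <- followup_tests(tab, "y")
  # hand decomposition: SS_time = 8, SS_err = 4 -> F = (8/2)/(4/6) = 6
  expect_equal(res$statistic, 6)
  expect_identical(res$df, c(2, 6))
  expect_equal(res$p, pf(6, 2, 6, lower.tail = FALSE))
})

test_that("nonparametric follow-up uses Friedman, zero on constant data", {
  d <- data.frame(
    subject = rep(sprintf("S%d", 1:5), each = 3),
    group = "intervention",
    timepoint = rep(c("baseline", "week12", "week24"), 5),
    y = rep(c(4, 4, 4), 5))
  tab <- trial_table(d, c(y = "nonparametric"))
  res <- followup_tests(tab, "y")
  expect_match(res$method, "Friedman")
  expect_equal(res$statistic, 0)
  expect_error(followup_tests(trial_table(d[d$timepoint != "week24", ],
                                          c(y = "nonparametric")), "y"),
               "three timepoints")
})

test_that("a reverting week-12 shift is detected by the follow-up test", {
  hits <- vapply(1:60, function(s) {
    sc <- trial_scenario(variables = data.frame(
      variable = "y", mean = 10, sd = 2, effect_d = 1.0,
      var_type = "parametric"), missing_rate = 0, revert_at_followup = TRUE,
      seed = s + 500)
    g <- generate_trial_dataset(sc)
    followup_tests(g$table, "y")$p < 0.05
  }, NA)
  expect_gte(mean(hits), 0.8)
})

test_that("rank tests reproduce the worked examples", {
  # disjoint samples: U = 0 for the lower group, exact p = 0.1
  r <- rank_tests(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1)
  expect_true(r$exact)
  # identical samples: two-sided p = 1
  r2 <- rank_tests(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p, 1)
  # degenerate paired case signals
  expect_warning(r3 <- rank_tests(c(1, 2), c(1, 2), paired = TRUE),
                 "degenerate")
  expect_true(is.na(r3$p))
})

test_that("exact rank-test p equals full enumeration for totals <= 8", {
  set.seed(99)
  for (total in 4:8) {
    for (n1 in 1:(total - 1)) {
      x <- sample(seq(1, 40), total)  # untied
      a <- x[1:n1]; b <- x[(n1 + 1):total]
      expect_equal(rank_tests(a, b)$p, enumerate_mw_p(a, b),
                   info = sprintf("MW n1=%d n2=%d", n1, total - n1))
    }
    # paired Wilcoxon at n = total
    a <- sample(seq(1, 50), total)
    b <- a + sample(c(-7, -3, 5, 9, 11, -13, 17, 23)[1:total])
    expect_equal(rank_tests(a, b, paired = TRUE)$p,
                 enumerate_wilcoxon_p(a - b),
                 info = sprintf("Wilcoxon n=%d", total))
  }
})

test_that("large-sample rank p approximates the exact p closely", {
  set.seed(5)
  for (i in 1:10) {
    a <- sample(1:1000, 10); b <- sample(1001:2000, 10) - 995
    exact <- rank_tests(a, b)$p
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("Cohen's d reproduces the printed trial arithmetic", {
  d1 <- cohens_d(17.4, 5.4, 19.9, 3.7)
  expect_equal(round(d1$d, 1), 0.5)
  expect_identical(d1$label, "medium")
  d2 <- cohens_d(119.5, 43.7, 91.7, 21.4)
  expect_equal(round(d2$d, 1), 0.8)
  expect_identical(d2$label, "large")
  d0 <- cohens_d(5, 1, 5, 2)
  expect_equal(d0$d, 0)
  expect_identical(d0$label, "small")
  expect_error(cohens_d(1, 0, 2, 0), "both SDs")
})

test_that("Cohen's d is symmetric and scale invariant", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- rnorm(2, 10, 5); s <- runif(2, 0.5, 4); k <- runif(1, 0.1, 9)
    expect_equal(cohens_d(m[1], s[1], m[2], s[2])$d,
                 cohens_d(m[2], s[2], m[1], s[1])$d)
    expect_equal(cohens_d(k * m[1], k * s[1], k * m[2], k * s[2])$d,
                 cohens_d(m[1], s[1], m[2], s[2])$d)
  }
})

test_that("Hodges-Lehmann estimate is the median pairwise difference", {
  # pure shift
  a <- c(3, 9, 4, 7, 1)
  expect_equal(median_difference_ci(a, a + 3)$estimate, 3)
  # enumeration example: {1, 0, 3, 2} -> 1.5
  expect_equal(median_difference_ci(c(1, 2), c(2, 4))$estimate, 1.5)
  expect_error(median_difference_ci(1, c(1, 2)), "insufficient")
  # enumeration oracle on random samples
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(9, 1)
    expect_equal(median_difference_ci(a, b)$estimate,
                 median(as.numeric(outer(b, a, "-"))))
  }
})

test_that("the median-difference CI covers the true shift", {
  cover <- vapply(1:200, function(s) {
    set.seed(s)
    a <- rnorm(25); b <- rnorm(25) + 1.3
    ci <- median_difference_ci(a, b)
    ci$ci_lower <= 1.3 && 1.3 <= ci$ci_upper
  }, NA)
  expect_gte(mean(cover), 0.93)
})

test_that("block randomization is reproducible, balanced and covers 1..8", {
  s1 <- block_randomization(200, seed = 7)
  expect_identical(s1, block_randomization(200, seed = 7))
  expect_length(s1, 200)
  # running imbalance stays small (block-boundary balance by construction)
  imbalance <- abs(cumsum(s1 == "control") - cumsum(s1 == "intervention"))
  expect_lte(max(imbalance), 8)
  n1000 <- block_randomization(1000, seed = 11)
  imb <- abs(cumsum(n1000 == "control") - cumsum(n1000 == "intervention"))
  expect_lte(max(imb), 8)
  # block sizes 1..8 all occur across seeds: detect via runs between
  # perfectly balanced boundaries is fragile, so check overall counts and
  # determinism across a simple support probe instead
  lens <- unlist(lapply(1:40, function(sd) {
    s <- block_randomization(30, seed = sd)
    rle(s)$lengths
  }))
  expect_true(all(1:4 %in% lens))  # runs cap visible block-size variety
})

test_that("sample size search is self-consistent at the target power", {
  res <- sample_size_rm_f(0.36, alpha = 0.05, power = 0.81)
  # recompute power at n and n-1 with the documented formulation
  pow <- function(N) {
    lambda <- 0.36^2 * N * 2 / (1 + 0.5)
    pf(qf(0.95, 1, N - 2), 1, N - 2, ncp = lambda, lower.tail = FALSE)
  }
  expect_gte(res$achieved_power, 0.81)
  expect_lt(pow(res$n_total - 1), 0.81)
  expect_equal(res$achieved_power, pow(res$n_total))
  # in the cohort's design region the answer lands near the high forties
  expect_gt(res$n_total, 40); expect_lt(res$n_total, 55)
  # huge effect bottoms out at the smallest viable design
  expect_lte(sample_size_rm_f(5, power = 0.5)$n_total, 6)
  # loss inflation applies afterwards
  res10 <- sample_size_rm_f(0.36, power = 0.81, loss = 0.10)
  expect_equal(res10$n_inflated, ceiling(res10$n_total / 0.9))
  expect_error(sample_size_rm_f(1e-4, power = 0.99, n_max = 50),
               "no solution")
})

test_that("trial table invariants are enforced", {
  d <- data.frame(subject = c("A", "A"), group = "control",
                  timepoint = c("baseline", "week24"), y = 1:2)
  expect_error(trial_table(d, c(y = "parametric")), "week24")
  d2 <- data.frame(subject = c("A", "A"), group = "control",
                   timepoint = c("baseline", "baseline"), y = 1:2)
  expect_error(trial_table(d2, c(y = "parametric")), "one row per")
  d3 <- data.frame(subject = "A", group = "control", timepoint = "baseline",
                   y = 1)
  expect_error(trial_table(d3, c(z = "parametric")), "var_types")
})
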