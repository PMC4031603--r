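# Intention-to-treat statistics: mixed repeated-measures ANOVA with
# Newman-Keuls post hoc, within-group follow-up tests, rank tests, Cohen's
# d with the trial's label boundaries, Hodges-Lehmann median differences,
# block randomization and repeated-measures F sample size.

#' Group-by-time mixed repeated-measures ANOVA
#'
#' Two-group (between) by two-timepoint (within: baseline vs week 12)
#' mixed-design ANOVA for one outcome variable of an imputed trial table.
#' Computed in closed form from the classical decomposition: subject means
#' carry the between stratum (group effect against subjects-within-groups),
#' difference scores carry the within stratum (time and interaction against
#' subject-by-time error). With a two-level within factor sphericity holds
#' trivially.
#'
#' @param tab A [trial_table()], imputed (no NA at baseline/week12).
#' @param variable Outcome variable name.
#' @param alpha Significance level for the post hoc step (default 0.05).
#' @param posthoc Run Newman-Keuls on the four group-by-time cell means
#'   (default TRUE).
#' @return An `anova_result`: list with `table` (data frame `term`, `df1`,
#'   `df2`, `F`, `p` for group, time, interaction), `cell_means`,
#'   `posthoc` (from [newman_keuls()], or NULL).
#' @export
rm_anova_interaction <- function(tab, variable, alpha = 0.05, posthoc = TRUE) {
  stopifnot(inherits(tab, "trial_table"), variable %in% trial_vars(tab))
  d <- tab[tab$timepoint %in% c("baseline", "week12"),
           c("subject", "group", "timepoint", variable)]
  wide <- stats::reshape(d, direction = "wide", idvar = c("subject", "group"),
                         timevar = "timepoint", v.names = variable)
  pre <- wide[[paste0(variable, ".baseline")]]
  post <- wide[[paste0(variable, ".week12")]]
  if (any(is.na(pre)) || any(is.na(post))) {
    stop("design error: missing baseline/week12 values after imputation")
  }
  g <- factor(wide$group)
  if (nlevels(g) != 2) stop("design error: need exactly two groups")
  n_g <- tabulate(g)
  if (any(n_g < 2)) stop("design error: fewer than 2 subjects in a group")
  N <- length(pre)

  # between stratum: subject means
  s <- (pre + post) / 2
  sm <- tapply(s, g, mean)
  ss_group <- 2 * sum(n_g * (sm - mean(s))^2)
  ss_subj <- 2 * sum((s - sm[g])^2)
  f_group <- (ss_group / 1) / (ss_subj / (N - 2))

  # within stratum: difference scores (week12 - baseline)
  dd <- post - pre
  dm <- tapply(dd, g, mean)
  ss_time <- sum(dd)^2 / (2 * N)
  ss_cells <- sum(tapply(dd, g, sum)^2 / n_g) / 2
  ss_int <- ss_cells - ss_time
  ss_werr <- sum(dd^2) / 2 - ss_cells
  ms_werr <- ss_werr / (N - 2)
  f_time <- (ss_time / 1) / ms_werr
  f_int <- (ss_int / 1) / ms_werr

  table <- data.frame(
    term = c("group", "time", "interaction"),
    df1 = c(1L, 1L, 1L),
    df2 = c(N - 2L, N - 2L, N - 2L),
    F = c(f_group, f_time, f_int),
    p = stats::pf(c(f_group, f_time, f_int), 1, N - 2, lower.tail = FALSE)
  )
  cells <- expand.grid(group = levels(g), timepoint = c("baseline", "week12"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$mean <- c(tapply(pre, g, mean), tapply(post, g, mean))
  cells$n <- rep(n_g, 2)
  ph <- NULL
  if (posthoc) {
    # pooled within-cell variance as the post hoc error term
    vals <- c(pre, post)
    cellf <- interaction(rep(g, 2), rep(c("a", "b"), each = N))
    mse <- sum(tapply(vals, cellf, function(x) sum((x - mean(x))^2))) /
      (2 * N - 4)
    n_h <- 1 / mean(1 / cells$n)  # harmonic mean cell size
    ph <- newman_keuls(stats::setNames(cells$mean,
                                       paste(cells$group, cells$timepoint, sep = ":")),
                       mse = mse, n = n_h, df_error = 2 * N - 4, alpha = alpha)
  }
  structure(list(table = table, cell_means = cells, posthoc = ph),
            class = "anova_result")
}

#' Newman-Keuls stepwise studentized-range procedure
#'
#' Orders the cell means and tests ranges from widest to narrowest with
#' studentized-range critical values whose parameter is the number of means
#' spanned. A range contained in a previously accepted (non-significant)
#' range is declared non-significant without testing, which enforces the
#' procedure's coherence.
#'
#' @param means Named numeric vector of cell means.
#' @param mse Error mean square from the preceding ANOVA.
#' @param n Per-cell count (harmonic mean for unequal cells).
#' @param df_error Error degrees of freedom.
#' @param alpha Significance level (default 0.05).
#' @return Data frame of all pairs: `mean_a`, `mean_b`, `diff`, `span`,
#'   `q`, `q_crit`, `significant`.
#' @export
newman_keuls <- function(means, mse, n, df_error, alpha = 0.05) {
  if (!is.numeric(mse) || mse <= 0) stop("mse must be positive")
  stopifnot(length(means) >= 2, n > 0, df_error >= 1)
  if (is.null(names(means))) names(means) <- paste0("m", seq_along(means))
  k <- length(means)
  ord <- order(means)
  mo <- means[ord]
  se <- sqrt(mse / n)
  accepted <- matrix(FALSE, k, k)  # [i, j]: range i..j accepted non-significant
  out <- list()
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      covered <- FALSE
      if (span < k) {
        for (a in seq_len(k)) {
          for (b in seq_len(k)) {
            if (accepted[a, b] && a <= i && j <= b) covered <- TRUE
          }
        }
      }
      q_obs <- (mo[j] - mo[i]) / se
      q_crit <- stats::qtukey(1 - alpha, span, df_error)
      sig <- !covered && q_obs > q_crit
      if (!sig) accepted[i, j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        mean_a = names(mo)[i], mean_b = names(mo)[j],
        diff = unname(mo[j] - mo[i]), span = span,
        q = unname(q_obs), q_crit = q_crit, significant = sig
      )
    }
  }
  do.call(rbind, out)
}

#' Within-group three-timepoint follow-up test
#'
#' For the intervention group only: tests whether the outcome changed over
#' baseline, week 12 and week 24 (and hence whether treated subjects
#' returned to their baseline condition). Parametric variables use a
#' one-way repeated-measures ANOVA (subjects as blocks); nonparametric
#' variables use Friedman's test.
#'
#' @param tab A [trial_table()], imputed.
#' @param variable Outcome variable name.
#' @return List with `method`, `statistic`, `df`, `p`.
#' @export
followup_tests <- function(tab, variable) {
  stopifnot(inherits(tab, "trial_table"), variable %in% trial_vars(tab))
  d <- tab[tab$group == "intervention", c("subject", "timepoint", variable)]
  tps <- intersect(TIMEPOINTS, unique(d$timepoint))
  if (length(tps) < 3) stop("design error: fewer than three timepoints")
  wide <- stats::reshape(d, direction = "wide", idvar = "subject",
                         timevar = "timepoint", v.names = variable)
  Y <- as.matrix(wide[, paste0(variable, ".", tps)])
  if (any(is.na(Y))) stop("design error: missing values after imputation")
  n <- nrow(Y); k <- ncol(Y)
  if (attr(tab, "var_types")[[variable]] == "parametric") {
    grand <- mean(Y)
    ss_time <- n * sum((colMeans(Y) - grand)^2)
    ss_subj <- k * sum((rowMeans(Y) - grand)^2)
    ss_tot <- sum((Y - grand)^2)
    ss_err <- ss_tot - ss_time - ss_subj
    df1 <- k - 1; df2 <- (n - 1) * (k - 1)
    F <- (ss_time / df1) / (ss_err / df2)
    list(method = "one-way repeated-measures ANOVA", statistic = F,
         df = c(df1, df2), p = stats::pf(F, df1, df2, lower.tail = FALSE))
  } else {
    ft <- stats::friedman.test(Y)
    stat <- unname(ft$statistic)
    p <- ft$p.value
    if (is.nan(stat)) {
      # fully tied data (e.g. constant across timepoints): no evidence of a
      # time effect, statistic 0 by convention
      stat <- 0
      p <- 1
    }
    list(method = "Friedman test", statistic = stat,
         df = unname(ft$parameter), p = p)
  }
}

#' Mann-Whitney / Wilcoxon rank tests
#'
#' Two-sided rank tests at the conventions of small clinical trials:
#' unpaired comparisons use the Mann-Whitney U test, paired comparisons the
#' Wilcoxon signed-rank test. Exact p-values are used for small untied
#' samples (all group sizes at most `exact_max`); otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param a,b Numeric samples; equal length when `paired`.
#' @param paired Logical.
#' @param exact_max Largest sample size for exact p-values (default 12).
#' @return List with `statistic`, `p`, `method`, `exact`. All-zero paired
#'   differences yield a degenerate-test result (`p = NA`) with a warning.
#' @export
rank_tests <- function(a, b, paired = FALSE, exact_max = 12) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    dif <- a - b
    if (all(dif == 0)) {
      warning("degenerate test: all paired differences are zero")
      return(list(statistic = NA_real_, p = NA_real_,
                  method = "Wilcoxon signed rank", exact = FALSE))
    }
    ties <- anyDuplicated(abs(dif[dif != 0])) > 0 || any(dif == 0)
    exact <- !ties && sum(dif != 0) <= exact_max
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = exact, correct = TRUE))
  } else {
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
  }
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = wt$method, exact = exact)
}

#' Cohen's d with the trial's effect-size labels
#'
#' Absolute standardized mean difference with the unweighted pooled SD,
#' `d = |m1 - m2| / sqrt((sd1^2 + sd2^2) / 2)`, labelled with the
#' boundaries used in this line of trials: small below 0.4, medium from
#' 0.4 up to (not including) 0.7, large from 0.7.
#'
#' @param mean1,sd1,mean2,sd2 Group summaries; SDs non-negative, not both
#'   zero.
#' @param boundaries Length-2 numeric: medium and large lower bounds.
#' @return An `effect_size`: list with `d` and `label`.
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2, boundaries = c(0.4, 0.7)) {
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  if (sd1 == 0 && sd2 == 0) stop("undefined effect size: both SDs are zero")
  d <- abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
  label <- if (d < boundaries[1]) "small" else
    if (d < boundaries[2]) "medium" else "large"
  structure(list(d = d, label = label), class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.2f (%s)\n", x$d, x$label))
  invisible(x)
}

#' Hodges-Lehmann median difference with distribution-free CI
#'
#' The median of all pairwise differences `b - a`, with the distribution-
#' free confidence interval read from the ordered pairwise differences
#' (Moses/Wilcoxon construction).
#'
#' @param a,b Numeric samples of at least 2 values each.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `estimate`, `ci_lower`, `ci_upper`, `conf_level`.
#' @export
median_difference_ci <- function(a, b, conf_level = 0.95) {
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient data: each sample needs at least 2 values")
  }
  wt <- suppressWarnings(stats::wilcox.test(b, a, conf.int = TRUE,
                                            conf.level = conf_level))
  list(estimate = unname(wt$estimate),
       ci_lower = wt$conf.int[1], ci_upper = wt$conf.int[2],
       conf_level = attr(wt$conf.int, "conf.level"))
}

#' Block randomization with randomly varying block sizes
#'
#' Generates a two-arm allocation sequence in consecutive blocks whose
#' sizes are drawn uniformly from `block_sizes` (default 1 to 8). Each
#' block is balanced up to rounding; the odd unit of an odd-sized block
#' goes to the currently smaller arm (random on ties), so the running
#' imbalance at block boundaries never exceeds one.
#'
#' @param n Number of allocations required.
#' @param seed Integer seed; the sequence is reproducible given the seed.
#' @param block_sizes Candidate block sizes.
#' @param groups Arm labels.
#' @return Character vector of length `n`.
#' @export
block_randomization <- function(n, seed, block_sizes = 1:8,
                                groups = c("control", "intervention")) {
  stopifnot(n >= 1, length(groups) == 2)
  seq_out <- character(0)
  count <- c(0L, 0L)
  local_rng(seed, {
    while (length(seq_out) < n) {
      s <- sample(block_sizes, 1)
      base <- s %/% 2
      block <- rep(1:2, each = base)
      if (s %% 2 == 1) {
        extra <- if (count[1] < count[2]) 1L else if (count[2] < count[1]) 2L
                 else sample(1:2, 1)
        block <- c(block, extra)
      }
      block <- sample(block)
      count <- count + tabulate(block, 2)
      seq_out <- c(seq_out, groups[block])
    }
  })
  seq_out[seq_len(n)]
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Sample size for a repeated-measures F test
#'
#' Smallest total sample size reaching the target power for a
#' repeated-measures F design under the noncentral-F formulation with a
#' compound-symmetric within-subject correlation `rho` (G*Power
#' conventions). `effect_type` selects the tested effect: `"between"`
#' (groups; noncentrality `f^2 N m / (1 + (m-1) rho)`), `"within"` (time)
#' or `"interaction"` (both `f^2 N m / (1 - rho)`). An anticipated loss
#' fraction inflates the result afterwards.
#'
#' @param effect_f Cohen's f effect size (> 0).
#' @param alpha Type-I level.
#' @param power Target power.
#' @param n_groups,n_measures Design dimensions (default 2 x 2).
#' @param rho Within-subject correlation (default 0.5).
#' @param effect_type One of "between", "within", "interaction".
#' @param loss Anticipated loss-to-follow-up fraction (default 0).
#' @param n_max Search bound (default 10000).
#' @return List with `n_total`, `n_per_group`, `achieved_power`,
#'   `n_inflated` (accounting for loss) and the `assumptions` used.
#' @export
sample_size_rm_f <- function(effect_f, alpha = 0.05, power = 0.81,
                             n_groups = 2, n_measures = 2, rho = 0.5,
                             effect_type = c("between", "within", "interaction"),
                             loss = 0, n_max = 10000) {
  effect_type <- match.arg(effect_type)
  stopifnot(effect_f > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            rho > -1, rho < 1, loss >= 0, loss < 1)
  a <- n_groups; m <- n_measures
  pow_at <- function(N) {
    if (effect_type == "between") {
      df1 <- a - 1; df2 <- N - a
      lambda <- effect_f^2 * N * m / (1 + (m - 1) * rho)
    } else {
      df1 <- if (effect_type == "within") m - 1 else (a - 1) * (m - 1)
      df2 <- (N - a) * (m - 1)
      lambda <- effect_f^2 * N * m / (1 - rho)
    }
    if (df2 < 1) return(0)
    stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda,
              lower.tail = FALSE)
  }
  for (N in (a + 1):n_max) {
    if (pow_at(N) >= power) {
      return(list(
        n_total = N, n_per_group = ceiling(N / a),
        achieved_power = pow_at(N),
        n_inflated = ceiling(N / (1 - loss)),
        assumptions = list(effect_f = effect_f, alpha = alpha, power = power,
                           n_groups = a, n_measures = m, rho = rho,
                           effect_type = effect_type, loss = loss)
      ))
    }
  }
  stop("no solution: target power unreachable within n_max subjects")
}
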