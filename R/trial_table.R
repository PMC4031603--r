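# The subject x group x timepoint outcome table feeding the
# intention-to-treat statistics, and the mean/median-of-series imputation.

TIMEPOINTS <- c("baseline", "week12", "week24")
GROUPS <- c("control", "intervention")

#' Construct a trial outcome table
#'
#' Long-by-timepoint, wide-by-variable layout: one row per subject and
#' timepoint, columns `subject`, `group`, `timepoint` plus one numeric
#' column per outcome variable (NA = missing). The follow-up timepoint
#' (`week24`) may be present only for intervention subjects, mirroring a
#' design where only the treated arm is re-assessed.
#'
#' @param data Data frame as described.
#' @param var_types Named character vector mapping each outcome variable to
#'   `"parametric"` or `"nonparametric"`; drives the imputation method and
#'   the choice of follow-up test.
#' @return A `trial_table` (data frame with a `var_types` attribute).
#' @export
trial_table <- function(data, var_types) {
  stopifnot(is.data.frame(data),
            all(c("subject", "group", "timepoint") %in% names(data)))
  data$group <- as.character(data$group)
  data$timepoint <- as.character(data$timepoint)
  if (!all(data$group %in% GROUPS)) {
    stop("group must be one of: ", paste(GROUPS, collapse = ", "))
  }
  if (!all(data$timepoint %in% TIMEPOINTS)) {
    stop("timepoint must be one of: ", paste(TIMEPOINTS, collapse = ", "))
  }
  if (anyDuplicated(data[, c("subject", "timepoint")])) {
    stop("one row per subject x timepoint required")
  }
  if (any(data$timepoint == "week24" & data$group != "intervention")) {
    stop("week24 rows are only defined for the intervention group")
  }
  vars <- setdiff(names(data), c("subject", "group", "timepoint"))
  if (!length(vars)) stop("no outcome variables in table")
  missing_types <- setdiff(vars, names(var_types))
  if (length(missing_types)) {
    stop("var_types missing for: ", paste(missing_types, collapse = ", "))
  }
  if (!all(var_types[vars] %in% c("parametric", "nonparametric"))) {
    stop("var_types must be 'parametric' or 'nonparametric'")
  }
  attr(data, "var_types") <- var_types[vars]
  class(data) <- c("trial_table", "data.frame")
  data
}

trial_vars <- function(tab) names(attr(tab, "var_types"))

#' Impute missing outcomes by the mean/median of series
#'
#' Intention-to-treat imputation under an MCAR assumption: a missing cell
#' is replaced by the mean (parametric variables) or median (nonparametric
#' variables) of the observed values of the same variable within the same
#' group and timepoint. Observed values are never altered.
#'
#' @param tab A [trial_table()].
#' @return The imputed table; the logical matrix of originally missing
#'   cells is attached as attribute `imputed`.
#' @export
impute_missing <- function(tab) {
  stopifnot(inherits(tab, "trial_table"))
  types <- attr(tab, "var_types")
  imputed <- matrix(FALSE, nrow(tab), length(types),
                    dimnames = list(NULL, names(types)))
  for (v in names(types)) {
    fun <- if (types[[v]] == "parametric") mean else stats::median
    for (g in unique(tab$group)) {
      for (tp in unique(tab$timepoint[tab$group == g])) {
        cell <- tab$group == g & tab$timepoint == tp
        vals <- tab[[v]][cell]
        nas <- is.na(vals)
        if (!any(nas)) next
        if (all(nas)) {
          stop(sprintf("unimputable: no observed values for %s in %s/%s",
                       v, g, tp))
        }
        tab[[v]][cell][nas] <- fun(vals[!nas])
        imputed[cell, v][nas] <- TRUE
      }
    }
  }
  attr(tab, "imputed") <- imputed
  tab
}

#' Normality and homoscedasticity report
#'
#' Kolmogorov-Smirnov test of each cell against a normal distribution with
#' the cell's mean and SD, plus Levene's test (mean-centred) of variance
#' homogeneity across cells.
#'
#' @param samples Named list of numeric vectors, one per design cell; each
#'   needs at least 3 observations.
#' @return List with `normality` (data frame `cell`, `statistic`, `p`) and
#'   `levene` (list `statistic`, `df1`, `df2`, `p`).
#' @export
check_assumptions <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples))) names(samples) <- paste0("cell", seq_along(samples))
  if (any(vapply(samples, length, integer(1)) < 3)) {
    stop("each cell needs at least 3 observations")
  }
  normality <- do.call(rbind, lapply(names(samples), function(nm) {
    x <- samples[[nm]]
    kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    data.frame(cell = nm, statistic = unname(kt$statistic),
               p = kt$p.value)
  }))
  df <- data.frame(
    value = unlist(samples, use.names = FALSE),
    cell = factor(rep(names(samples), vapply(samples, length, integer(1))))
  )
  lv <- car::leveneTest(value ~ cell, data = df, center = mean)
  list(normality = normality,
       levene = list(statistic = lv[1, "F value"],
                     df1 = lv[1, "Df"], df2 = lv[2, "Df"],
                     p = lv[1, "Pr(>F)"]))
}
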