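# Two-arm repeated-measures trial tables with prescribed group-by-time
# effects, compound-symmetric within-subject correlation via a shared
# subject random intercept, and MCAR missingness.

#' Trial scenario for the synthetic table generator
#'
#' Defines a two-arm trial: group sizes (defaults 29 control /
#' 26 intervention, a realistic mid-fifties cohort split), a set of outcome
#' variables with baseline mean/SD, the group-by-time intervention effect
#' in SD units applied to the intervention arm at week 12, the
#' within-subject correlation (shared random intercept), and an MCAR
#' missing-cell rate.
#'
#' @param n_control,n_intervention Arm sizes.
#' @param variables Data frame with columns `variable`, `mean`, `sd`,
#'   `effect_d`, `var_type`; the default carries a heel time-to-peak
#'   variable with a 0.5 SD effect and a null control variable.
#' @param rho Within-subject correlation in `(-1, 1)` (default 0.5).
#' @param missing_rate MCAR cell-missingness rate in `[0, 0.2]`
#'   (default 0.05).
#' @param revert_at_followup Should the intervention effect disappear at
#'   week 24 (default `TRUE`, the "return to baseline" pattern)?
#' @param seed Integer seed.
#' @return A `trial_scenario` list.
#' @export
trial_scenario <- function(n_control = 29, n_intervention = 26,
                           variables = NULL, rho = 0.5,
                           missing_rate = 0.05,
                           revert_at_followup = TRUE, seed = 1) {
  if (is.null(variables)) {
    variables <- data.frame(
      variable = c("tpp_heel", "pp_midfoot"),
      mean = c(17.6, 122), sd = c(5.7, 54),
      effect_d = c(0.5, 0), var_type = "parametric"
    )
  }
  stopifnot(n_control >= 2, n_intervention >= 2,
            rho > -1, rho < 1,
            missing_rate >= 0, missing_rate <= 0.2,
            all(variables$sd > 0))
  structure(list(n_control = n_control, n_intervention = n_intervention,
                 variables = variables, rho = rho,
                 missing_rate = missing_rate,
                 revert_at_followup = revert_at_followup, seed = seed),
            class = "trial_scenario")
}

#' Generate a synthetic two-arm trial table
#'
#' Subject outcomes are `y = mean + b_subject + effect + noise` with
#' `b_subject ~ N(0, rho sd^2)` shared across timepoints and
#' `noise ~ N(0, (1 - rho) sd^2)` independent per timepoint, so the
#' within-subject correlation is `rho` and the marginal SD is `sd`. The
#' intervention arm receives `effect_d * sd` at week 12 (and keeps or
#' loses it at week 24 per the scenario). Week-24 rows exist only for the
#' intervention arm. An MCAR mask then blanks outcome cells at the
#' scenario rate.
#'
#' @param scenario A [trial_scenario()].
#' @return List with `table` (a [trial_table()], missing cells `NA`) and
#'   `truth` (data frame `variable`, `effect_d`).
#' @export
generate_trial_dataset <- function(scenario = trial_scenario()) {
  stopifnot(inherits(scenario, "trial_scenario"))
  vars <- scenario$variables
  n_c <- scenario$n_control; n_i <- scenario$n_intervention
  subjects <- data.frame(
    subject = sprintf("S%03d", seq_len(n_c + n_i)),
    group = rep(c("control", "intervention"), c(n_c, n_i))
  )
  rows <- rbind(
    merge(subjects, data.frame(timepoint = c("baseline", "week12"))),
    data.frame(subject = subjects$subject[subjects$group == "intervention"],
               group = "intervention", timepoint = "week24")
  )
  rows <- rows[order(rows$subject, match(rows$timepoint, TIMEPOINTS)), ]
  rownames(rows) <- NULL
  local_rng(scenario$seed, {
    for (i in seq_len(nrow(vars))) {
      v <- vars[i, ]
      b <- stats::rnorm(nrow(subjects), 0, sqrt(scenario$rho) * v$sd)
      names(b) <- subjects$subject
      eff <- v$effect_d * v$sd *
        (rows$group == "intervention") *
        (rows$timepoint == "week12" |
           (!scenario$revert_at_followup & rows$timepoint == "week24"))
      y <- v$mean + b[rows$subject] + eff +
        stats::rnorm(nrow(rows), 0, sqrt(1 - scenario$rho) * v$sd)
      if (scenario$missing_rate > 0) {
        y[stats::runif(nrow(rows)) < scenario$missing_rate] <- NA
      }
      rows[[v$variable]] <- unname(y)
    }
  })
  tab <- trial_table(rows, stats::setNames(vars$var_type, vars$variable))
  list(table = tab, truth = vars[, c("variable", "effect_d")])
}
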