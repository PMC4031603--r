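# End-to-end pipeline: simulate a cohort's rollover recordings, extract
# regional metrics, build the trial table, run the intention-to-treat
# statistics, and write CSV/JSON outputs with a reproducibility manifest.

#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed for every stochastic stage.
#' @param n_per_group Subjects per arm in the simulated cohort (default 8;
#'   kept modest so a full run stays interactive).
#' @param effect_d Intervention effect injected on the heel time-to-peak
#'   variable, in SD units (default 0.5).
#' @param stance_threshold Stance detection threshold fraction.
#' @param cutoff_force,cutoff_kin Filter cutoffs, Hz.
#' @param alpha Significance level.
#' @param es_boundaries Effect-size label boundaries (medium, large).
#' @param noise_sd Pressure sensor noise SD, kPa.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, n_per_group = 8, effect_d = 0.5,
                       stance_threshold = 0.05, cutoff_force = 20,
                       cutoff_kin = 6, alpha = 0.05,
                       es_boundaries = c(0.4, 0.7), noise_sd = 4) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_per_group = n_per_group, effect_d = effect_d,
              stance_threshold = stance_threshold,
              cutoff_force = cutoff_force, cutoff_kin = cutoff_kin,
              alpha = alpha, es_boundaries = es_boundaries,
              noise_sd = noise_sd)
  stopifnot(cfg$stance_threshold > 0, cfg$stance_threshold < 1,
            cfg$cutoff_force > 0, cfg$cutoff_kin > 0,
            cfg$alpha > 0, cfg$alpha < 1, cfg$n_per_group >= 2,
            length(cfg$es_boundaries) == 2, cfg$noise_sd >= 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @return For `read_run_config`, a `run_config`; for `write_run_config`,
#'   `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full simulate-extract-analyse pipeline
#'
#' Simulates per-subject rollover recordings for a two-arm cohort at two
#' timepoints (the intervention arm's week-12 heel time-to-peak is delayed
#' by `effect_d` SD units), extracts the regional metrics through stance
#' detection, masking and the metric computations, assembles the trial
#' table, runs the group-by-time ANOVA and effect sizes, and writes
#' `metrics.csv`, `trial_table.csv`, `stats.csv` and `manifest.json` under
#' `config$out_dir`. Identical config and seed give byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return The run report (list with `metrics`, `table`, `anova`,
#'   `effect_size`, `manifest`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # per-subject heel TPP baseline spread, emulating between-subject variation
  tpp_sd <- 2.5
  subjects <- data.frame(
    subject = sprintf("S%03d", seq_len(2 * config$n_per_group)),
    group = rep(c("control", "intervention"), each = config$n_per_group)
  )
  grid <- rect_sensor_grid()
  rows <- list()
  metrics_rows <- list()
  stage("simulate+extract", {
    for (i in seq_len(nrow(subjects))) {
      base_shift <- local_rng(config$seed * 1000L + i,
                              stats::rnorm(1, 0, tpp_sd))
      for (tp in c("baseline", "week12")) {
        shift <- base_shift +
          if (tp == "week12" && subjects$group[i] == "intervention") {
            config$effect_d * tpp_sd
          } else {
            0
          }
        sc <- rollover_scenario(noise_sd = config$noise_sd,
                                seed = config$seed * 100000L + i * 10L +
                                  (tp == "week12"))
        sc$regions$peak_pct[sc$regions$region == "heel"] <-
          min(40, max(5, sc$regions$peak_pct[sc$regions$region == "heel"] +
                        shift))
        gen <- generate_rollover_recording(sc, grid)
        ph <- detect_stance_phases(gen$recording, config$stance_threshold)
        if (nrow(ph) < 1) stop("no stance detected for ", subjects$subject[i])
        masks <- build_region_masks(gen$recording, ph[1, ])
        met <- rollover_metrics(gen$recording, ph[1, ], masks)
        heel <- met$regions[met$regions$region == "heel", ]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subjects$subject[i], group = subjects$group[i],
          timepoint = tp, tpp_heel = heel$tpp)
        metrics_rows[[length(metrics_rows) + 1L]] <- cbind(
          data.frame(subject = subjects$subject[i], timepoint = tp),
          met$regions)
      }
    }
  })
  tab <- stage("trial-table", {
    trial_table(do.call(rbind, rows), c(tpp_heel = "parametric"))
  })
  res <- stage("statistics", {
    an <- rm_anova_interaction(tab, "tpp_heel", alpha = config$alpha)
    cm <- an$cell_means
    ig12 <- cm$mean[cm$group == "intervention" & cm$timepoint == "week12"]
    cg12 <- cm$mean[cm$group == "control" & cm$timepoint == "week12"]
    grp <- tab$group[tab$timepoint == "week12"]
    v12 <- tab$tpp_heel[tab$timepoint == "week12"]
    es <- cohens_d(mean(v12[grp == "intervention"]),
                   stats::sd(v12[grp == "intervention"]),
                   mean(v12[grp == "control"]),
                   stats::sd(v12[grp == "control"]),
                   boundaries = config$es_boundaries)
    list(anova = an, effect_size = es, ig12 = ig12, cg12 = cg12)
  })

  manifest <- list(
    package = "footroll",
    version = as.character(utils::packageVersion("footroll")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config)
  )
  stage("write-outputs", {
    metrics <- do.call(rbind, metrics_rows)
    utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(tab),
                     file.path(config$out_dir, "trial_table.csv"),
                     row.names = FALSE, quote = FALSE)
    st <- res$anova$table
    st$effect_size_week12 <- c(res$effect_size$d, NA, NA)
    st$effect_label <- c(res$effect_size$label, NA, NA)
    utils::write.csv(st, file.path(config$out_dir, "stats.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(list(metrics = do.call(rbind, metrics_rows), table = tab,
                 anova = res$anova, effect_size = res$effect_size,
                 manifest = manifest))
}
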