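#' Run a full synthetic experiment end to end
#'
#' Simulates a cohort (counterbalanced contingencies; Pavlovian conditioning
#' sessions with or without photometry; a PIT test), runs photometry
#' preprocessing and QC, peri-event quantification and session binning,
#' behavioral elevation-ratio scoring, and the group statistics (conditional
#' approach across sessions; Same vs Different lever at PIT), and writes tidy
#' TSV output tables plus a JSON run manifest.
#'
#' QC exclusions and undefined ratios are reported as messages, never
#' errors. Rerunning with the same config and seed reproduces byte-identical
#' outputs.
#'
#' @param config a [sim_config()] or the path to a config file
#'   (see [read_sim_config()]).
#' @param out_dir output directory (created if needed); `NULL` skips writing
#'   and just returns the result tables.
#' @param seed integer seed; overrides `config$seed`.
#' @return Invisibly, a list of tibbles: `elevation` (per subject/session
#'   Pavlovian elevation ratios), `pit` (per subject Same/Different and
#'   food-port ratios), `photometry` (per subject/session QC + peri-event
#'   summaries, when photometry is enabled), `binned` (phase-binned
#'   photometry summaries), `stats` (test results), and `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  withr::local_seed(seed)

  subjects <- seq_len(config$n_subjects)
  elevation <- list()
  photometry <- list()
  pit <- list()

  for (s in subjects) {
    contingency <- make_contingency(s - 1L)
    for (session in seq_len(config$n_conditioning_sessions)) {
      sch <- generate_conditioning_session(config, contingency, session)
      log <- simulate_behavior(sch, config, contingency)
      pe <- pavlovian_elevation(sch, log)
      elevation[[length(elevation) + 1L]] <- tibble::tibble(
        subject = s, session = session,
        elevation_ratio = attr(pe, "summary")
      )
      if (config$photometry) {
        rec <- simulate_photometry(sch, log, config)
        trace <- correct_photometry(rec)
        qc <- qc_session(trace, config$qc_min_r2,
                         config$qc_min_transient_rate_per_min)
        row <- tibble::tibble(subject = s, session = session,
                              qc_passed = qc$passed,
                              qc_reasons = paste(qc$reasons[[1]],
                                                 collapse = ","),
                              transient_rate_per_min =
                                qc$transient_rate_per_min,
                              r_squared = qc$r_squared)
        if (qc$passed) {
          qs <- quantify_session(trace, sch, log, config$window_pre_s,
                                 config$window_post_s)
          row <- dplyr::cross_join(row, tidyr::pivot_wider(
            qs$summary,
            names_from = "event_kind",
            values_from = c("peak_pre", "peak_post", "auc_pre", "auc_post")
          ))
        } else {
          rlang::inform(sprintf(
            "QC excluded subject %d session %d (%s)", s, session,
            paste(qc$reasons[[1]], collapse = ", ")))
        }
        photometry[[length(photometry) + 1L]] <- row
      }
    }
    pit_sch <- generate_pit_session(config)
    pit_log <- simulate_behavior(pit_sch, config, contingency)
    lever <- pit_lever_scores(pit_sch, pit_log, contingency)
    fp <- pit_foodport_score(pit_sch, pit_log)
    pit[[length(pit) + 1L]] <- tibble::tibble(
      subject = s,
      same_ratio = lever$same_ratio,
      different_ratio = lever$different_ratio,
      foodport_ratio = attr(fp, "summary")
    )
  }

  elevation <- dplyr::bind_rows(elevation)
  pit <- dplyr::bind_rows(pit)
  photometry <- dplyr::bind_rows(photometry)

  binned <- NULL
  if (config$photometry && nrow(photometry)) {
    usable <- photometry[photometry$qc_passed, , drop = FALSE]
    measure_cols <- grep("^(peak|auc)_", names(usable), value = TRUE)
    if (nrow(usable) && length(measure_cols)) {
      binned <- bin_sessions(
        dplyr::select(usable, "subject", "session",
                      dplyr::all_of(measure_cols))
      )
    }
  }

  stats_rows <- list()
  if (config$n_conditioning_sessions >= 2L && config$n_subjects >= 2L) {
    wide <- tidyr::pivot_wider(elevation, names_from = "session",
                               values_from = "elevation_ratio")
    y <- as.matrix(wide[, -1])
    fit <- tryCatch(rm_anova(y), error = function(e) NULL)
    if (!is.null(fit)) {
      tr <- tidy(fit)
      stats_rows[[length(stats_rows) + 1L]] <- tibble::tibble(
        test = "elevation_across_sessions_rm_anova",
        statistic = tr$statistic, df1 = tr$df_num_gg, df2 = tr$df_den_gg,
        p_value = tr$p_gg
      )
    }
  }
  if (config$n_subjects >= 2L) {
    tt <- tryCatch(paired_t(pit$same_ratio, pit$different_ratio),
                   error = function(e) NULL)
    if (!is.null(tt)) {
      stats_rows[[length(stats_rows) + 1L]] <- tibble::tibble(
        test = "pit_same_vs_different_paired_t",
        statistic = tt$statistic, df1 = tt$df, df2 = NA_real_,
        p_value = tt$p_value
      )
    }
  }
  stats <- dplyr::bind_rows(stats_rows)

  manifest <- list(
    seed = seed,
    config = unclass(config),
    n_subjects = config$n_subjects,
    tables = c("elevation.tsv", "pit_scores.tsv",
               if (config$photometry) c("photometry_summary.tsv",
                                        "binned_summary.tsv"),
               "stats.tsv")
  )

  result <- list(elevation = elevation, pit = pit, photometry = photometry,
                 binned = binned, stats = stats, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(elevation, file.path(out_dir, "elevation.tsv"))
    readr::write_tsv(pit, file.path(out_dir, "pit_scores.tsv"))
    if (config$photometry && nrow(photometry)) {
      readr::write_tsv(photometry,
                       file.path(out_dir, "photometry_summary.tsv"))
      if (!is.null(binned)) {
        readr::write_tsv(binned, file.path(out_dir, "binned_summary.tsv"))
      }
    }
    if (nrow(stats)) readr::write_tsv(stats, file.path(out_dir, "stats.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(result)
}
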