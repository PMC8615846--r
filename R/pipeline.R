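#' Full-run configuration
#'
#' @param seed master seed; every stage and subject draws from a derived
#'   substream.
#' @param n_subjects number of simulated subjects.
#' @param task a [task_config()].
#' @param agent an [agent_params()].
#' @param truth a [true_network()], a preset name for [network_preset()],
#'   or a path to a JSON file written by [write_true_network()].
#' @param search a [search_config()].
#' @param hrf_mode HRF estimation mode for the analysis stage
#'   (see [estimate_subject_hrfs()]).
#' @param out_dir output directory for [write_report()].
#' @param stages named logical toggles: simulate, behavior, hrf, search.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1, n_subjects = 11,
                       task = task_config(),
                       agent = agent_params(),
                       truth = "pit_study",
                       search = search_config(),
                       hrf_mode = "target",
                       out_dir = "results",
                       stages = c(simulate = TRUE, behavior = TRUE,
                                  hrf = TRUE, search = TRUE)) {
  if (is.character(truth) && !truth %in% c("benchmark", "pit_study")) {
    if (!file.exists(truth)) stopf("truth file '%s' does not exist", truth)
    truth <- read_true_network(truth)
  } else if (is.character(truth)) {
    truth <- network_preset(truth, n_subjects = n_subjects)
  }
  structure(list(seed = seed, n_subjects = n_subjects, task = task,
                 agent = agent, truth = truth, search = search,
                 hrf_mode = hrf_mode, out_dir = out_dir, stages = stages),
            class = "run_config")
}

#' Run the simulate -> behavior -> HRF -> search pipeline
#'
#' Executes the enabled stages in order on a simulated cohort: task
#' schedules and agent behavior, instrumental and transfer behavioral
#' statistics, per-subject sFIR HRF estimation, the group + individual
#' connectivity search, and (truth being known) recovery metrics.
#' Deterministic: rerunning with the same config reproduces identical
#' results.
#'
#' @param config a [run_config()].
#' @return object of class `run_report` with one element per enabled
#'   stage plus a provenance block.
#' @export
run_pipeline <- function(config) {
  stages <- config$stages
  report <- list(provenance = list(
    config_fingerprint = fold_fingerprint(config[setdiff(names(config), "out_dir")]),
    seed = config$seed, n_subjects = config$n_subjects,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("pitconnect"))))
  class(report) <- "run_report"
  if (!isTRUE(stages[["simulate"]])) return(report)

  n <- config$n_subjects
  sim <- list(schedules = list(), transfer_records = list(),
              attacks = list(), instrumental_records = list())
  for (s in seq_len(n)) {
    run <- gen_instrumental_run(config$task, config$agent,
                                derive_seed(config$seed, "instr", s))
    sim$attacks[[s]] <- run$attacks
    sim$instrumental_records[[s]] <- run$record
    sim$schedules[[s]] <- gen_transfer_schedule(config$task,
                                                derive_seed(config$seed, "sched", s))
    sim$transfer_records[[s]] <- gen_transfer_behavior(
      sim$schedules[[s]], config$agent,
      derive_seed(config$seed, "transfer", s), subject_id = paste0("sub", s))
  }
  sim$matrices <- simulate_bold(config$truth, sim$schedules, config$task,
                                seed = config$seed)
  report$simulate <- sim

  if (isTRUE(stages[["behavior"]])) {
    bins <- t(vapply(sim$attacks, bin_attacks,
                     numeric(config$task$session_length_s %/% 30),
                     session_length_s = config$task$session_length_s))
    rates <- do.call(rbind, lapply(seq_len(n), function(s)
      transfer_rates(sim$transfer_records[[s]], sim$schedules[[s]],
                     reps_per_cs = config$task$transfer_reps_per_cs)))
    report$behavior <- list(
      attack_bins = bins,
      learning = learning_test(bins[, 1], bins[, ncol(bins)]),
      rates = rates,
      anova = rm_anova_3way(rates),
      pairwise = pairwise_probes(rates, alpha = config$search$alpha))
  }

  hrfs <- NULL
  if (isTRUE(stages[["hrf"]])) {
    hrfs <- lapply(sim$matrices, estimate_subject_hrfs, mode = config$hrf_mode)
    report$hrf <- list(
      mode = config$hrf_mode,
      peak_times = do.call(rbind, lapply(seq_len(n), function(s) {
        h <- hrfs[[s]]
        peaks <- unlist(lapply(names(h), function(u) {
          if (is.null(h[[u]])) return(NULL)
          obj <- h[[u]]
          if (inherits(obj, "hrf_estimate")) {
            stats::setNames(hrf_peak_time(obj), u)
          } else {
            stats::setNames(mean(vapply(obj, hrf_peak_time, numeric(1))), u)
          }
        }))
        data.frame(subject = s, input = names(peaks), peak_s = unname(peaks))
      })))
  }

  if (isTRUE(stages[["search"]])) {
    res <- gimme_search(sim$matrices, hrfs, config$search)
    report$search <- res
    report$recovery <- evaluate_recovery(res, config$truth)
  }
  report
}

edge_table_of <- function(structure, fit = NULL) {
  ed <- if (is.null(fit)) structure$edges else fit$edges
  ed$id <- edge_ids(ed)
  ed
}

#' Write a run report to disk
#'
#' Layout under `dir`: `events_subN.tsv` and `matrix_subN.tsv` per subject,
#' `attack_bins.tsv`, `anova.tsv`, `pairwise.tsv`, `hrf_peaks.tsv`,
#' `group_edges.tsv`, `individual_edges.tsv`, `fit_table.tsv` (participant,
#' RMSEA, SRMR, CFI, NNFI), `audit.log`, `summary.json` and a
#' human-readable `summary.txt`.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2) != 0) {
    stopf("cannot write to directory '%s'", dir)
  }
  paths <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, path)
  }
  summary_lines <- c(sprintf("run fingerprint %s, seed %s",
                             report$provenance$config_fingerprint,
                             report$provenance$seed))
  json <- list(provenance = report$provenance)
  if (!is.null(report$simulate)) {
    for (s in seq_along(report$simulate$schedules)) {
      put(report$simulate$schedules[[s]], sprintf("events_sub%d.tsv", s))
      write_subject_matrix(report$simulate$matrices[[s]],
                           file.path(dir, sprintf("matrix_sub%d.tsv", s)))
      paths <- c(paths, file.path(dir, sprintf("matrix_sub%d.tsv", s)))
    }
  }
  if (!is.null(report$behavior)) {
    put(as.data.frame(report$behavior$attack_bins), "attack_bins.tsv")
    put(report$behavior$anova, "anova.tsv")
    put(report$behavior$pairwise, "pairwise.tsv")
    json$behavior <- list(learning = report$behavior$learning,
                          anova = report$behavior$anova,
                          pairwise = report$behavior$pairwise)
    summary_lines <- c(summary_lines, sprintf(
      "instrumental learning: t(%d) = %.2f, p = %.4f",
      report$behavior$learning$df, report$behavior$learning$t,
      report$behavior$learning$p))
  }
  if (!is.null(report$hrf)) {
    put(report$hrf$peak_times, "hrf_peaks.tsv")
  }
  if (!is.null(report$search)) {
    res <- report$search
    grp <- edge_table_of(NULL, res$subjects[[1]]$fit)
    grp <- grp[grp$level == "group" & grp$type != "ar", , drop = FALSE]
    put(grp, "group_edges.tsv")
    ind <- do.call(rbind, lapply(seq_along(res$subjects), function(s) {
      ed <- edge_table_of(NULL, res$subjects[[s]]$fit)
      ed <- ed[ed$level == "individual", , drop = FALSE]
      if (nrow(ed)) cbind(participant = s, ed) else NULL
    }))
    if (is.null(ind)) {
      ind <- data.frame(participant = integer(0), type = character(0),
                        source = character(0), target = character(0))
    }
    put(ind, "individual_edges.tsv")
    ft <- res$fit_table
    names(ft) <- c("participant", "RMSEA", "SRMR", "CFI", "NNFI", "excellent")
    put(ft, "fit_table.tsv")
    writeLines(apply(res$audit, 1, paste, collapse = "\t"),
               file.path(dir, "audit.log"))
    paths <- c(paths, file.path(dir, "audit.log"))
    json$search <- list(group_edges = grp, fit_table = ft)
    if (!is.null(report$recovery)) {
      json$recovery <- report$recovery[c("precision", "recall",
                                         "direction_accuracy", "beta_rmse")]
    }
    summary_lines <- c(summary_lines, sprintf(
      "group paths (non-AR): %d; mean CFI %.3f; mean RMSEA %.3f",
      nrow(grp), mean(ft$CFI), mean(ft$RMSEA)))
  }
  jsonlite::write_json(json, file.path(dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  paths <- c(paths, file.path(dir, "summary.json"), file.path(dir, "summary.txt"))
  invisible(paths)
}
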