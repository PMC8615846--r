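#' Search configuration for the iterative group/individual model estimation
#'
#' @param group_cutoff proportion of subjects for whom a candidate path
#'   must significantly improve fit to enter (or survive in) the group
#'   model; "75% of the sample" means ceil(group_cutoff x n) subjects.
#' @param alpha significance level for modification indices and pruning.
#' @param bonferroni divide alpha by the candidate count when judging
#'   modification indices.
#' @param max_group_paths,max_individual_paths iteration caps.
#' @param classes candidate edge classes enabled for the search.
#' @param stop_individual individual-level stopping rule:
#'   `"excellent_fit"` stops adding once the subject's model meets the
#'   two-of-four excellent-fit rule (the usual GIMME behavior);
#'   `"mi_only"` keeps adding while any candidate is significant.
#' @param prune_iter_max bound on the prune-refit loop.
#' @return object of class `search_config`.
#' @export
search_config <- function(group_cutoff = 0.75, alpha = 0.05,
                          bonferroni = FALSE,
                          max_group_paths = 20, max_individual_paths = 20,
                          classes = c("contemporaneous", "lagged",
                                      "direct", "bilinear"),
                          stop_individual = c("excellent_fit", "mi_only"),
                          prune_iter_max = 50) {
  if (group_cutoff < 0.5 || group_cutoff > 1) {
    stopf("group_cutoff must lie in [0.5, 1]")
  }
  if (max_group_paths < 0 || max_individual_paths < 0 || prune_iter_max < 1) {
    stopf("iteration caps must be positive")
  }
  structure(list(group_cutoff = group_cutoff, alpha = alpha,
                 bonferroni = bonferroni,
                 max_group_paths = max_group_paths,
                 max_individual_paths = max_individual_paths,
                 classes = classes,
                 stop_individual = match.arg(stop_individual),
                 prune_iter_max = prune_iter_max),
            class = "search_config")
}

audit_row <- function(stage, action, edge_id, detail) {
  data.frame(stage = stage, action = action, edge = edge_id,
             detail = detail, stringsAsFactors = FALSE)
}

#' Group-level forward selection and pruning
#'
#' Starting from the null model (the five autoregressive paths), the
#' candidate whose modification index is significant for the largest
#' number of subjects is added - provided that count reaches
#' ceil(group_cutoff x n) - with ties broken by summed MI and then by
#' lexicographic edge id, until no candidate qualifies or the cap is hit.
#' Group edges are then pruned: any edge whose estimate is significant for
#' fewer than ceil(group_cutoff x n) subjects is removed, iterating
#' prune-and-refit to a fixed point.
#'
#' @param matrices list of `subject_matrix` objects.
#' @param hrfs list of per-subject HRF sets (see
#'   [estimate_subject_hrfs()]), or NULL.
#' @param config a [search_config()].
#' @return list with `structure` (the group [network_structure()]) and
#'   `audit` (decision log).
#' @export
run_group_search <- function(matrices, hrfs = NULL, config = search_config()) {
  n_sub <- length(matrices)
  if (n_sub < 2) stopf("group search needs at least 2 subjects")
  hrfs <- hrfs %||% vector("list", n_sub)
  m1 <- matrices[[1]]
  n_in <- attr(m1, "n_inputs") %||% 2
  p <- ncol(m1) - n_in
  rois <- colnames(m1)[seq_len(p)]
  inputs <- colnames(m1)[p + seq_len(n_in)]
  struct <- network_structure(rois, inputs)
  need <- ceiling(config$group_cutoff * n_sub)
  audit <- list()

  fit_all <- function(st) {
    lapply(seq_len(n_sub), function(s) {
      f <- tryCatch(
        estimate_model(matrices[[s]], st, hrfs[[s]], warn_ratio = FALSE),
        error = function(e) e)
      if (inherits(f, "error") || !f$converged) {
        if (nrow(st$edges) == sum(st$edges$type == "ar")) {
          stopf("null model failed for subject %d: %s", s,
                if (inherits(f, "error")) conditionMessage(f) else "non-convergence")
        }
      }
      f
    })
  }

  # forward selection
  repeat {
    n_group <- sum(struct$edges$type != "ar" & struct$edges$level == "group")
    if (n_group >= config$max_group_paths) {
      audit[[length(audit) + 1]] <- audit_row("group", "stop", NA, "cap reached")
      break
    }
    fits <- fit_all(struct)
    cands <- candidate_edges(struct, config$classes)
    if (nrow(cands) == 0) break
    sig <- matrix(FALSE, n_sub, nrow(cands))
    mis <- matrix(0, n_sub, nrow(cands))
    for (s in seq_len(n_sub)) {
      if (inherits(fits[[s]], "error")) next
      m <- modification_indices(fits[[s]], cands, alpha = config$alpha,
                                bonferroni = config$bonferroni)
      sig[s, ] <- m$significant
      mis[s, ] <- m$mi
    }
    counts <- colSums(sig)
    if (max(counts) < need) {
      audit[[length(audit) + 1]] <- audit_row(
        "group", "stop", NA,
        sprintf("no candidate significant for >= %d/%d subjects", need, n_sub))
      break
    }
    sums <- colSums(mis)
    ids <- edge_ids(cands)
    ord <- order(-counts, -sums, ids)
    best <- ord[1]
    struct <- add_edge(struct, cands$type[best], cands$source[best],
                       cands$target[best], cands$input[best], level = "group")
    audit[[length(audit) + 1]] <- audit_row(
      "group", "add", ids[best],
      sprintf("significant for %d/%d subjects, summed MI %.2f",
              counts[best], n_sub, sums[best]))
  }

  # group pruning to a fixed point
  for (iter in seq_len(config$prune_iter_max)) {
    fits <- fit_all(struct)
    ed <- struct$edges
    grp <- which(ed$type != "ar" & ed$level == "group")
    if (length(grp) == 0) break
    sig_counts <- vapply(grp, function(i) {
      id <- edge_ids(ed)[i]
      sum(vapply(fits, function(f) {
        if (inherits(f, "error") || !f$converged) return(FALSE)
        row <- match(id, edge_ids(f$edges))
        !is.na(f$edges$p[row]) && f$edges$p[row] < config$alpha
      }, logical(1)))
    }, numeric(1))
    drop <- grp[sig_counts < need]
    if (length(drop) == 0) break
    worst <- drop[which.min(sig_counts[match(drop, grp)])]
    id <- edge_ids(ed)[worst]
    struct <- remove_edge(struct, id)
    audit[[length(audit) + 1]] <- audit_row(
      "group", "prune", id,
      sprintf("significant for only %d/%d subjects",
              sig_counts[match(worst, grp)], n_sub))
    if (iter == config$prune_iter_max) {
      audit[[length(audit) + 1]] <- audit_row("group", "flag", NA,
                                              "prune iteration cap hit")
    }
  }

  list(structure = struct,
       audit = if (length(audit)) do.call(rbind, audit) else
         audit_row(character(0), character(0), character(0), character(0)))
}

#' Individual-level forward selection and pruning
#'
#' Fits the final group model to one subject, then forward-selects
#' individual paths by largest significant modification index. Under the
#' default stopping rule no path is added once the model already meets the
#' two-of-four excellent-fit criterion. Individual (never group) paths
#' that lose significance are pruned, with an oscillation guard.
#'
#' @param matrix a `subject_matrix`.
#' @param hrfs this subject's HRF set, or NULL.
#' @param group the group [network_structure()].
#' @param config a [search_config()].
#' @return list with `structure`, `fit`, `indices` (fit indices), `audit`.
#' @export
run_individual_search <- function(matrix, hrfs = NULL, group,
                                  config = search_config()) {
  struct <- group
  audit <- list()
  seen <- character(0)
  fit <- estimate_model(matrix, struct, hrfs, warn_ratio = FALSE)
  if (!fit$converged) stopf("group structure did not converge for this subject")
  repeat {
    n_ind <- sum(struct$edges$level == "individual")
    if (n_ind >= config$max_individual_paths) {
      audit[[length(audit) + 1]] <- audit_row("individual", "stop", NA, "cap reached")
      break
    }
    if (config$stop_individual == "excellent_fit") {
      fi <- fit_indices(fit)
      if (fi$excellent) {
        audit[[length(audit) + 1]] <- audit_row("individual", "stop", NA,
                                                "excellent fit reached")
        break
      }
    }
    cands <- candidate_edges(struct, config$classes)
    if (nrow(cands) == 0) break
    m <- modification_indices(fit, cands, alpha = config$alpha,
                              bonferroni = config$bonferroni)
    if (!any(m$significant)) {
      audit[[length(audit) + 1]] <- audit_row("individual", "stop", NA,
                                              "no significant candidate")
      break
    }
    ids <- edge_ids(cands)
    ord <- order(-m$mi, ids)
    best <- ord[1]
    struct <- add_edge(struct, cands$type[best], cands$source[best],
                       cands$target[best], cands$input[best],
                       level = "individual")
    key <- paste(sort(edge_ids(struct$edges)), collapse = "|")
    osc <- key %in% seen
    seen <- c(seen, key)
    audit[[length(audit) + 1]] <- audit_row("individual", "add", ids[best],
                                            sprintf("MI %.2f", m$mi[best]))
    fit <- estimate_model(matrix, struct, hrfs, warn_ratio = FALSE)
    if (osc) {
      audit[[length(audit) + 1]] <- audit_row("individual", "flag", NA,
                                              "add/prune oscillation; stopped")
      break
    }
    # prune individual edges that lost significance
    for (iter in seq_len(config$prune_iter_max)) {
      bad <- prune_check(fit, config$alpha)
      bad <- bad[bad$level == "individual", , drop = FALSE]
      if (nrow(bad) == 0) break
      id <- edge_ids(bad)[which.max(bad$p)]
      struct <- remove_edge(struct, id)
      audit[[length(audit) + 1]] <- audit_row("individual", "prune", id,
                                              "lost significance")
      fit <- estimate_model(matrix, struct, hrfs, warn_ratio = FALSE)
    }
  }
  # final prune pass
  for (iter in seq_len(config$prune_iter_max)) {
    bad <- prune_check(fit, config$alpha)
    bad <- bad[bad$level == "individual", , drop = FALSE]
    if (nrow(bad) == 0) break
    id <- edge_ids(bad)[which.max(bad$p)]
    struct <- remove_edge(struct, id)
    audit[[length(audit) + 1]] <- audit_row("individual", "prune", id,
                                            "lost significance (final pass)")
    fit <- estimate_model(matrix, struct, hrfs, warn_ratio = FALSE)
  }
  list(structure = struct, fit = fit, indices = fit_indices(fit),
       audit = if (length(audit)) do.call(rbind, audit) else
         audit_row(character(0), character(0), character(0), character(0)))
}

#' Full group + individual model search
#'
#' @param matrices list of `subject_matrix` objects.
#' @param hrfs list of per-subject HRF sets, or NULL.
#' @param config a [search_config()].
#' @return object of class `search_result`: `group` (structure),
#'   `subjects` (per-subject structure/fit/indices), `fit_table`
#'   (per-subject RMSEA/SRMR/CFI/NNFI), `audit`.
#' @export
gimme_search <- function(matrices, hrfs = NULL, config = search_config()) {
  n_sub <- length(matrices)
  hrfs <- hrfs %||% vector("list", n_sub)
  grp <- run_group_search(matrices, hrfs, config)
  subjects <- lapply(seq_len(n_sub), function(s) {
    res <- run_individual_search(matrices[[s]], hrfs[[s]], grp$structure, config)
    res$audit$stage <- paste0("sub", s, ":", res$audit$stage)
    res
  })
  group_ids <- edge_ids(grp$structure$edges)
  for (s in seq_len(n_sub)) {
    if (!all(group_ids %in% edge_ids(subjects[[s]]$structure$edges))) {
      stopf("internal error: group edge missing from subject %d's final structure", s)
    }
  }
  fit_table <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
    fi <- subjects[[s]]$indices
    data.frame(participant = s, rmsea = fi$rmsea, srmr = fi$srmr,
               cfi = fi$cfi, nnfi = fi$nnfi, excellent = fi$excellent)
  }))
  audit <- rbind(grp$audit, do.call(rbind, lapply(subjects, `[[`, "audit")))
  structure(list(group = grp$structure, subjects = subjects,
                 fit_table = fit_table, audit = audit, config = config),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  ng <- sum(x$group$edges$type != "ar")
  cat(sprintf("search result: %d subjects, %d group paths (+%d AR), mean CFI %.3f\n",
              length(x$subjects), ng, sum(x$group$edges$type == "ar"),
              mean(x$fit_table$cfi)))
  invisible(x)
}

#' Presence precision/recall of a search result against a known truth
#'
#' Compares the recovered non-autoregressive edges (group and individual
#' pooled across subjects, each subject contributing one edge set) with
#' the generating network. Precision = true recovered / all recovered
#' (defined as 1 when nothing was claimed); recall = true recovered / true
#' edges. Direction accuracy is the proportion of recovered ROI-pair edges
#' matching a true edge when direction is ignored that also match its
#' direction. Beta RMSE pools the estimation error of correctly recovered
#' edges.
#'
#' @param result a `search_result`.
#' @param truth a [true_network()] over the same node set.
#' @return list with `precision`, `recall`, `direction_accuracy`,
#'   `beta_rmse`, and the underlying counts.
#' @export
evaluate_recovery <- function(result, truth) {
  if (!setequal(truth$roi_names, result$group$roi_names)) {
    stopf("node mismatch between truth and result")
  }
  tr <- true_edge_table(truth)
  tr_ids <- ifelse(tr$type == "bilinear",
                   paste0(tr$type, ":", tr$source, "*", tr$input, "->", tr$target),
                   paste0(tr$type, ":", tr$source, "->", tr$target))
  undirected <- function(type, a, b) paste0(type, ":", pmin(a, b), "~", pmax(a, b))
  tp <- fp <- fn_units <- 0
  dir_ok <- dir_tot <- 0
  sq_err <- numeric(0)
  for (sub in result$subjects) {
    ed <- sub$fit$edges
    ed <- ed[ed$type != "ar", , drop = FALSE]
    ids <- edge_ids(ed)
    hit <- ids %in% tr_ids
    tp <- tp + sum(hit)
    fp <- fp + sum(!hit)
    fn_units <- fn_units + sum(!tr_ids %in% ids)
    roi_edges <- ed$type %in% c("contemporaneous", "lagged")
    und <- undirected(ed$type[roi_edges], ed$source[roi_edges], ed$target[roi_edges])
    tr_roi <- tr$type %in% c("contemporaneous", "lagged")
    und_true <- undirected(tr$type[tr_roi], tr$source[tr_roi], tr$target[tr_roi])
    matched <- und %in% und_true
    dir_tot <- dir_tot + sum(matched)
    dir_ok <- dir_ok + sum(ids[roi_edges][matched] %in% tr_ids)
    for (i in which(hit)) {
      sq_err <- c(sq_err, (ed$beta[i] - tr$beta[match(ids[i], tr_ids)])^2)
    }
  }
  claimed <- tp + fp
  list(precision = if (claimed == 0) 1 else tp / claimed,
       recall = if (nrow(tr) == 0) 1 else
         tp / (nrow(tr) * length(result$subjects)),
       direction_accuracy = if (dir_tot == 0) NA_real_ else dir_ok / dir_tot,
       beta_rmse = if (length(sq_err)) sqrt(mean(sq_err)) else NA_real_,
       true_recovered = tp, claimed = claimed,
       true_total = nrow(tr) * length(result$subjects))
}
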