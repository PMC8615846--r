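fast_cfg <- function(...) search_config(classes = c("contemporaneous", "lagged"), ...)

test_that("the 75% cutoff rounds up to whole subjects", {
  expect_equal(ceiling(0.75 * 11), 9)  # 8/11 (72.7%) misses, 9/11 (81.8%) passes
  expect_equal(ceiling(0.75 * 10), 8)
  expect_error(search_config(group_cutoff = 0.3), "cutoff")
})

test_that("a shared extra path is recovered at the group level and only it", {
  truth <- single_path_truth("contemporaneous", beta = 0.6)
  for (r in 1:5) {
    mats <- simulate_bold(truth, NULL, task_config(n_trs = 200),
                          seed = derive_seed(50, "homog", r), n_subjects = 10)
    grp <- run_group_search(mats, NULL, fast_cfg())
    got <- grp$structure$edges[grp$structure$edges$type != "ar", ]
    expect_equal(nrow(got), 1)
    expect_equal(got[, c("type", "source", "target")],
                 data.frame(type = "contemporaneous", source = "roi1",
                            target = "roi2", stringsAsFactors = FALSE),
                 ignore_attr = TRUE)
  }
})

test_that("pure-noise cohorts keep the null group model", {
  truth <- single_path_truth("contemporaneous", beta = 0)
  clean <- vapply(1:5, function(r) {
    mats <- simulate_bold(truth, NULL, task_config(n_trs = 200),
                          seed = derive_seed(51, "null", r), n_subjects = 10)
    grp <- run_group_search(mats, NULL, fast_cfg())
    sum(grp$structure$edges$type != "ar") == 0
  }, logical(1))
  expect_gte(mean(clean), 0.8)
})

test_that("private individual paths are found on top of the group model", {
  group_truth <- single_path_truth("contemporaneous", beta = 0.6)
  private <- group_truth
  private$Phi[4, 1] <- 0.5  # one subject also has lagged roi1 -> roi4
  hits <- vapply(1:5, function(r) {
    mats <- simulate_bold(group_truth, NULL, task_config(n_trs = 540),
                          seed = derive_seed(52, "grp", r), n_subjects = 9)
    mats[[10]] <- simulate_bold(private, NULL, task_config(n_trs = 540),
                                seed = derive_seed(52, "priv", r),
                                n_subjects = 1)[[1]]
    grp <- run_group_search(mats, NULL, fast_cfg())
    res <- run_individual_search(mats[[10]], NULL, grp$structure, fast_cfg())
    ind <- res$structure$edges[res$structure$edges$level == "individual", ]
    any(ind$type == "lagged" & ind$source == "roi1" & ind$target == "roi4")
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("a subject matching the group truth gains no individual paths", {
  truth <- single_path_truth("contemporaneous", beta = 0.6)
  extras <- vapply(1:10, function(r) {
    mats <- simulate_bold(truth, NULL, task_config(n_trs = 540),
                          seed = derive_seed(53, "p9", r), n_subjects = 10)
    grp <- run_group_search(mats, NULL, fast_cfg())
    res <- run_individual_search(mats[[1]], NULL, grp$structure, fast_cfg())
    sum(res$structure$edges$level == "individual")
  }, numeric(1))
  expect_gte(mean(extras == 0), 0.9)
})

test_that("a zero individual cap returns the group model verbatim", {
  truth <- single_path_truth("contemporaneous", beta = 0.6)
  mats <- simulate_bold(truth, NULL, task_config(n_trs = 200), seed = 54,
                        n_subjects = 4)
  grp <- run_group_search(mats, NULL, fast_cfg())
  res <- run_individual_search(mats[[2]], NULL, grp$structure,
                               fast_cfg(max_individual_paths = 0))
  expect_identical(res$structure$edges, grp$structure$edges)
})

test_that("search results are deterministic and contain every group edge", {
  truth <- network_preset("benchmark")
  mats <- simulate_bold(truth, NULL, task_config(n_trs = 200), seed = 55,
                        n_subjects = 6)
  a <- gimme_search(mats, NULL, fast_cfg())
  b <- gimme_search(mats, NULL, fast_cfg())
  expect_identical(a$group$edges, b$group$edges)
  expect_identical(a$audit, b$audit)
  expect_identical(a$fit_table, b$fit_table)
  gid <- pitconnect:::edge_ids(a$group$edges)
  for (s in seq_along(a$subjects)) {
    expect_true(all(gid %in% pitconnect:::edge_ids(a$subjects[[s]]$structure$edges)))
  }
})

test_that("recovery metrics count hits, misses and the empty-claim convention", {
  truth <- network_preset("benchmark")
  fake <- function(edges) {
    structure(list(
      group = network_structure(truth$roi_names, character(0)),
      subjects = list(list(fit = list(edges = edges)))),
      class = "search_result")
  }
  perfect <- true_edge_table(truth)
  perfect$level <- "group"
  ar <- data.frame(type = "ar", source = "roi1", target = "roi1",
                   input = NA_character_, beta = 0.5, level = "group",
                   stringsAsFactors = FALSE)
  ev <- evaluate_recovery(fake(rbind(perfect[, names(ar)], ar)), truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)

  spur <- rbind(perfect[, names(ar)],
                data.frame(type = "lagged", source = "roi2", target = "roi1",
                           input = NA_character_, beta = 0.1, level = "individual",
                           stringsAsFactors = FALSE))
  ev2 <- evaluate_recovery(fake(spur), truth)
  expect_equal(ev2$precision, 4 / 5)
  expect_equal(ev2$recall, 1)

  ev3 <- evaluate_recovery(fake(perfect[0, names(ar)]), truth)
  expect_equal(ev3$precision, 1)  # nothing claimed
  expect_equal(ev3$recall, 0)
})

test_that("recall of an input-driven path degrades as dynamic noise grows", {
  recalls <- vapply(c(1, 6, 20), function(ns) {
    G <- matrix(0, 5, 2); G[1, 1] <- 0.5
    truth <- true_network(matrix(0, 5, 5), diag(0.5, 5), Gamma = G,
                          noise_sd = ns, roi_names = paste0("roi", 1:5))
    mean(vapply(1:3, function(r) {
      cfgt <- task_config(n_trs = 200)
      scheds <- lapply(1:6, function(s)
        gen_transfer_schedule(cfgt, derive_seed(56, "sched", r, s)))
      mats <- simulate_bold(truth, scheds, cfgt,
                            seed = derive_seed(56, "noise", r))
      hrfs <- lapply(mats, estimate_subject_hrfs, mode = "mean")
      res <- gimme_search(mats, hrfs,
                          search_config(classes = c("contemporaneous",
                                                    "lagged", "direct")))
      evaluate_recovery(res, truth)$recall
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1e-9))
  expect_gt(recalls[1], recalls[3])
})
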