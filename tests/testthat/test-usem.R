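rois5 <- paste0("roi", 1:5)
edge_ids_test <- function(e) paste0(e$type, ":", e$source, "->", e$target)

test_that("structures enforce edge rules and carry the AR base", {
  ns <- network_structure(rois5, c("specific", "general"))
  expect_equal(sum(ns$edges$type == "ar"), 5)
  expect_error(add_edge(ns, "contemporaneous", "roi1", "roi1"), "forbidden")
  ns2 <- add_edge(ns, "contemporaneous", "roi1", "roi2")
  expect_error(add_edge(ns2, "contemporaneous", "roi1", "roi2"), "already")
  expect_error(add_edge(ns, "direct", "nope", "roi1"), "unknown input")
  expect_error(remove_edge(ns, "contemporaneous:roi9->roi1"), "not present")
  cands <- candidate_edges(ns2, c("contemporaneous", "lagged"))
  # the present edge and its cycle-creating reverse are both excluded
  expect_equal(nrow(cands), 20 + 20 - 2)
  expect_false(any(cands$type == "contemporaneous" & cands$source == "roi2" &
                     cands$target == "roi1"))
  all_c <- candidate_edges(ns2, c("contemporaneous", "lagged"),
                           acyclic_only = FALSE)
  expect_equal(nrow(all_c), 20 + 20 - 1)
})

test_that("AR-only fits recover autoregressive weights without bias", {
  truth <- single_path_truth("contemporaneous", beta = 0)
  ns <- network_structure(rois5, c("specific", "general"))
  m <- simulate_bold(truth, NULL, task_config(n_trs = 540), seed = 31,
                     n_subjects = 1)[[1]]
  fit <- estimate_model(m, ns, warn_ratio = FALSE)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$edges$beta - 0.5)), 0.08)
})

test_that("an omitted contemporaneous path shows up in the residuals", {
  truth <- single_path_truth("contemporaneous", beta = 0.6)
  ns <- network_structure(rois5, c("specific", "general"))
  m <- simulate_bold(truth, NULL, task_config(n_trs = 540), seed = 32,
                     n_subjects = 1)[[1]]
  fit <- estimate_model(m, ns, warn_ratio = FALSE)
  expect_gt(abs(cor(fit$resid[, "roi1"], fit$resid[, "roi2"])), 0.3)
  # equations untouched by the omitted path keep unbiased AR estimates
  clean <- fit$edges$target != "roi2"
  expect_lt(max(abs(fit$edges$beta[clean] - 0.5)), 0.1)
})

test_that("equation-wise estimates equal the lm() oracle on acyclic models", {
  set.seed(33)
  truth <- network_preset("benchmark")
  m <- simulate_bold(truth, NULL, task_config(n_trs = 300), seed = 33,
                     n_subjects = 1)[[1]]
  ns <- network_structure(rois5, c("specific", "general"),
    edges = data.frame(type = c("contemporaneous", "lagged"),
                       source = c("roi1", "roi4"),
                       target = c("roi2", "roi5"),
                       stringsAsFactors = FALSE))
  fit <- estimate_model(m, ns, warn_ratio = FALSE)
  y <- m[2:300, ]; ylag <- m[1:299, ]
  ref <- coef(lm(y[, "roi2"] ~ ylag[, "roi2"] + y[, "roi1"]))
  got <- fit$edges[fit$edges$target == "roi2", ]
  expect_equal(got$beta[got$type == "ar"], unname(ref[2]), tolerance = 1e-6)
  expect_equal(got$beta[got$type == "contemporaneous"], unname(ref[3]),
               tolerance = 1e-6)
  ref5 <- coef(lm(y[, "roi5"] ~ ylag[, "roi5"] + ylag[, "roi4"]))
  got5 <- fit$edges[fit$edges$target == "roi5", ]
  expect_equal(got5$beta[got5$type == "lagged"], unname(ref5[3]),
               tolerance = 1e-6)
})

test_that("freeing a path never decreases the log-likelihood", {
  truth <- network_preset("benchmark")
  m <- simulate_bold(truth, NULL, task_config(n_trs = 200), seed = 34,
                     n_subjects = 1)[[1]]
  ns <- network_structure(rois5, c("specific", "general"))
  ll <- estimate_model(m, ns, warn_ratio = FALSE)$loglik
  for (edge in list(c("contemporaneous", "roi1", "roi2"),
                    c("lagged", "roi3", "roi1"))) {
    ns <- add_edge(ns, edge[1], edge[2], edge[3])
    ll2 <- estimate_model(m, ns, warn_ratio = FALSE)$loglik
    expect_gte(ll2, ll - 1e-8)
    ll <- ll2
  }
})

test_that("a reciprocal pair without instruments is flagged unidentified", {
  m <- simulate_bold(single_path_truth("contemporaneous", 0.3), NULL,
                     task_config(n_trs = 100), seed = 35, n_subjects = 1)[[1]]
  ns <- network_structure(rois5, character(0), include_ar = FALSE,
    edges = data.frame(type = c("contemporaneous", "contemporaneous"),
                       source = c("roi1", "roi2"),
                       target = c("roi2", "roi1"),
                       stringsAsFactors = FALSE))
  expect_error(estimate_model(m, ns, warn_ratio = FALSE), "identification")
})

test_that("an instrumented reciprocal pair is estimated by full-information ML", {
  A <- matrix(0, 5, 5); A[2, 1] <- 0.4; A[1, 2] <- 0.3
  truth <- true_network(A, diag(0.5, 5), noise_sd = 1, roi_names = rois5)
  m <- simulate_bold(truth, NULL, task_config(n_trs = 540), seed = 36,
                     n_subjects = 1)[[1]]
  ns <- network_structure(rois5, c("specific", "general"),
    edges = data.frame(type = c("contemporaneous", "contemporaneous"),
                       source = c("roi1", "roi2"),
                       target = c("roi2", "roi1"),
                       stringsAsFactors = FALSE))
  fit <- estimate_model(m, ns, warn_ratio = FALSE)
  expect_true(fit$converged)
  got <- fit$edges[fit$edges$type == "contemporaneous", ]
  expect_lt(abs(got$beta[got$source == "roi1"] - 0.4), 0.2)
  expect_lt(abs(got$beta[got$source == "roi2"] - 0.3), 0.2)
})

test_that("modification indices flag true omitted paths and ignore dead inputs", {
  truth <- single_path_truth("contemporaneous", beta = 0.6)
  ns <- network_structure(rois5, c("specific", "general"))
  hits <- vapply(1:20, function(r) {
    m <- simulate_bold(truth, NULL, task_config(n_trs = 540),
                       seed = derive_seed(37, "mi", r), n_subjects = 1)[[1]]
    fit <- estimate_model(m, ns, warn_ratio = FALSE)
    cand <- data.frame(type = "contemporaneous", source = "roi1",
                       target = "roi2", input = NA_character_,
                       level = "candidate", stringsAsFactors = FALSE)
    modification_indices(fit, cand)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  m <- simulate_bold(truth, NULL, task_config(n_trs = 200), seed = 38,
                     n_subjects = 1)[[1]]
  fit <- estimate_model(m, ns, warn_ratio = FALSE)
  dead <- data.frame(type = "direct", source = "specific", target = "roi1",
                     input = NA_character_, level = "candidate",
                     stringsAsFactors = FALSE)
  expect_equal(modification_indices(fit, dead)$mi, 0) # no onsets anywhere
  expect_error(modification_indices(fit, fit$structure$edges[1, ]), "present")
})

test_that("score tests on truly-zero paths reject near the nominal rate", {
  truth <- single_path_truth("contemporaneous", beta = 0)
  ns <- network_structure(rois5, c("specific", "general"))
  cand <- data.frame(type = c("contemporaneous", "lagged"),
                     source = c("roi4", "roi5"), target = c("roi5", "roi3"),
                     input = NA_character_, level = "candidate",
                     stringsAsFactors = FALSE)
  rej <- vapply(1:60, function(r) {
    m <- simulate_bold(truth, NULL, task_config(n_trs = 300),
                       seed = derive_seed(39, "cal", r), n_subjects = 1)[[1]]
    fit <- estimate_model(m, ns, warn_ratio = FALSE)
    modification_indices(fit, cand)$significant
  }, logical(2))
  expect_lt(mean(rej), 0.15)
})

test_that("pruning returns exactly the non-significant paths", {
  truth <- network_preset("benchmark")
  m <- simulate_bold(truth, NULL, task_config(n_trs = 540), seed = 40,
                     n_subjects = 1)[[1]]
  ns <- network_structure(rois5, c("specific", "general"),
    edges = data.frame(type = c("contemporaneous", "contemporaneous"),
                       source = c("roi1", "roi5"),
                       target = c("roi2", "roi1"),  # second path is truly zero
                       stringsAsFactors = FALSE))
  fit <- estimate_model(m, ns, warn_ratio = FALSE)
  bad <- prune_check(fit, alpha = 0.05)
  expect_true(all(bad$p >= 0.05))
  strong <- fit$edges[abs(fit$edges$z) > 10, ]
  expect_false(any(edge_ids_test(strong) %in% edge_ids_test(bad)))
})

test_that("fit indices hit their limits and the two-of-four verdict", {
  truth <- network_preset("benchmark")
  m <- simulate_bold(truth, NULL, task_config(n_trs = 300), seed = 41,
                     n_subjects = 1)[[1]]
  # saturated: full lower-triangular A, full Phi, full Gamma
  pairs <- expand.grid(source = rois5, target = rois5, stringsAsFactors = FALSE)
  lower <- pairs[match(pairs$source, rois5) < match(pairs$target, rois5), ]
  lagged <- pairs[pairs$source != pairs$target, ]
  ed <- rbind(
    data.frame(type = "contemporaneous", source = lower$source,
               target = lower$target, stringsAsFactors = FALSE),
    data.frame(type = "lagged", source = lagged$source,
               target = lagged$target, stringsAsFactors = FALSE))
  ns <- network_structure(rois5, character(0), edges = ed)
  fit <- estimate_model(m, ns, warn_ratio = FALSE)
  fi <- fit_indices(fit)
  expect_equal(fi$df, 0)
  expect_equal(fi$cfi, 1)
  expect_equal(fi$rmsea, 0)
  expect_true(fi$excellent)

  expect_true(excellent_fit(cfi = 0.96, nnfi = 0.91, rmsea = 0.07, srmr = 0.04))
  expect_false(excellent_fit(cfi = 0.90, nnfi = 0.90, rmsea = 0.10, srmr = 0.10))

  bad <- estimate_model(m, network_structure(rois5, character(0)),
                        warn_ratio = FALSE)
  bad$converged <- FALSE
  expect_error(fit_indices(bad), "converge")
})

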