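test_that("Pavlovian schedules have exact trial counts and jittered ITIs", {
  cfg <- task_config()
  for (seed in c(1, 77, 2024)) {
    sch <- gen_pavlovian_schedule(cfg, seed)
    cs <- sch[grepl("^CS", sch$trial_type), ]
    expect_equal(nrow(cs), 45)
    expect_true(all(table(cs$trial_type) == 9))
    itis <- sch$duration[sch$trial_type == "fixation"]
    expect_true(all(itis %in% c(7, 9, 11)))
    expect_false(is.unsorted(sch$onset, strictly = TRUE))
  }
  one <- gen_pavlovian_schedule(task_config(pav_reps_per_pairing = 1), 3)
  expect_equal(sum(grepl("^CS", one$trial_type)), 5)
})

test_that("transfer schedules have exact counts and bounded recharge screens", {
  cfg <- task_config()
  for (seed in c(2, 31)) {
    sch <- gen_transfer_schedule(cfg, seed)
    cs <- sch[grepl("^CS", sch$trial_type), ]
    expect_equal(nrow(cs), 60)
    expect_true(all(table(cs$trial_type) == 12))
    expect_true(all(cs$duration == cfg$cs_duration_s))
    rch <- sch$duration[sch$trial_type == "recharge"]
    expect_true(all(rch >= 2 & rch <= 12))
  }
  expect_equal(nrow(gen_transfer_schedule(task_config(transfer_reps_per_cs = 0), 1)), 0)
})

test_that("schedules are seed-deterministic with seed-independent margins", {
  cfg <- task_config()
  a <- gen_transfer_schedule(cfg, 5)
  b <- gen_transfer_schedule(cfg, 5)
  c <- gen_transfer_schedule(cfg, 6)
  expect_identical(a, b)
  expect_false(identical(a$trial_type, c$trial_type))
  expect_equal(table(a$trial_type), table(c$trial_type))
})

test_that("instrumental attack clock honors press coverage and deferral", {
  cfg <- task_config()
  always <- agent_params(learn_start_p = 1, learn_end_p = 1)
  never <- agent_params(learn_start_p = 0, learn_end_p = 0)
  expect_length(gen_instrumental_run(cfg, always, 1)$attacks, 0)
  expect_length(gen_instrumental_run(cfg, never, 1)$attacks, 180)
  expect_error(gen_instrumental_run(task_config(session_length_s = -1), always, 1))
})

test_that("a learning agent's attacks decline from first to last 30-s bin", {
  cfg <- task_config()
  ag <- agent_params()
  bins <- t(vapply(1:200, function(r)
    bin_attacks(gen_instrumental_run(cfg, ag, r)$attacks), numeric(6)))
  expect_gt(mean(bins[, 1]), mean(bins[, 6]))
})

test_that("transfer behavior is a congruent-gain Poisson stream", {
  cfg <- task_config()
  sch <- gen_transfer_schedule(cfg, 9)
  expect_equal(nrow(gen_transfer_behavior(sch, agent_params(baseline_rate = 0), 1)), 0)
  pav <- gen_pavlovian_schedule(cfg, 9)
  expect_error(gen_transfer_behavior(pav, agent_params(), 1), "phase")
  # no presses land inside recharge windows
  rec <- gen_transfer_behavior(sch, agent_params(baseline_rate = 2), 4)
  rch <- sch[sch$trial_type == "recharge", ]
  for (i in seq_len(nrow(rch))) {
    expect_false(any(rec$timestamp >= rch$onset[i] &
                     rec$timestamp < rch$onset[i] + rch$duration[i]))
  }
})

test_that("CS1/R1 press counts match the closed-form Poisson mean", {
  cfg <- task_config()
  ag <- agent_params(baseline_rate = 0.1, specific_gain = 5)
  counts <- vapply(1:500, function(r) {
    sch <- gen_transfer_schedule(cfg, derive_seed(3, "s", r))
    rec <- gen_transfer_behavior(sch, ag, derive_seed(3, "b", r))
    rt <- transfer_rates(rec, sch)
    rt$rate[rt$stimulus == "CS1" & rt$interval == "stim" & rt$response == "R1"]
  }, numeric(1))
  # 0.1/s x gain 5 x 4 s = 2.0 expected presses per presentation
  expect_equal(mean(counts), 2.0, tolerance = 0.03)
})

test_that("euSEM simulation reproduces white noise, AR(1) and direct effects", {
  cfg <- task_config(n_trs = 540)
  p5 <- paste0("roi", 1:5)
  null_truth <- true_network(matrix(0, 5, 5), matrix(0, 5, 5),
                             noise_sd = 1.5, roi_names = p5)
  m <- simulate_bold(null_truth, NULL, cfg, seed = 4, n_subjects = 1)[[1]]
  expect_equal(unname(apply(m[, p5], 2, sd)), rep(1.5, 5), tolerance = 0.12)

  Phi <- matrix(0, 5, 5); Phi[1, 1] <- 0.6
  ar_truth <- true_network(matrix(0, 5, 5), Phi, roi_names = p5)
  m <- simulate_bold(ar_truth, NULL, cfg, seed = 8, n_subjects = 1)[[1]]
  y <- m[, "roi1"]
  expect_equal(cor(y[-1], y[-540]), 0.6, tolerance = 0.1)

  G <- matrix(0, 5, 2); G[1, 1] <- 0.5
  g_truth <- true_network(matrix(0, 5, 5), matrix(0, 5, 5), Gamma = G,
                          roi_names = p5)
  sch <- gen_transfer_schedule(cfg, 2)
  m <- simulate_bold(g_truth, list(sch), cfg, seed = 12)[[1]]
  u <- pitconnect:::convolve_onsets_hrf(
    sch$onset[sch$trial_type %in% c("CS1", "CS2")], 540, 2,
    function(t) canonical_hrf(t, 6, 1))
  expect_lt(abs(coef(lm(m[, "roi1"] ~ u))[2] - 0.5), 0.06)
})

test_that("input-free simulation converges to the stationary VAR covariance", {
  truth <- network_preset("benchmark")
  m <- simulate_bold(truth, NULL, task_config(n_trs = 5000), seed = 21,
                     n_subjects = 1, burn_in = 200)[[1]]
  y <- m[, truth$roi_names]
  IA <- solve(diag(5) - truth$A)
  B <- IA %*% truth$Phi
  Q <- IA %*% diag(truth$noise_sd^2) %*% t(IA)
  Sigma <- matrix(solve(diag(25) - kronecker(B, B), as.vector(Q)), 5, 5)
  expect_equal(unname(cov(y)), unname(Sigma), tolerance = 0.12)
})

test_that("voxel volumes embed, sum and round-trip ROI series", {
  rois <- roi_table(radius_mm = 2)[1:2, ]
  rois$x <- c(3, 5); rois$y <- c(3, 3); rois$z <- c(3, 3)
  gs <- grid_spec(c(10, 10, 10))
  series <- matrix(rnorm(40), 20, 2)
  vol <- make_voxel_volume(series, rois, gs, noise_sd = 0, seed = 1)
  only_roi1 <- matrix(c(2, 4, 4), 1)  # mm point (1,3,3): inside sphere 1 only
  expect_equal(mean_timeseries(vol, only_roi1), series[, 1])
  # overlapping spheres: mm point (4,3,3) is within 2 mm of both centers
  overlap <- matrix(c(5, 4, 4), 1)
  expect_equal(mean_timeseries(vol, overlap), series[, 1] + series[, 2])
  empty <- make_voxel_volume(series[, 0, drop = FALSE], rois[0, ], gs,
                             noise_sd = 0.7, seed = 2)
  expect_equal(sd(empty$data), 0.7, tolerance = 0.05)
})
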