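# shared fixture builders; everything is generated in code at test time

null_agent <- function() agent_params(specific_gain = 1, general_gain = 1)

# one simulated cohort from a preset truth, no task inputs
bench_cohort <- function(n_subjects = 10, n_trs = 200, seed = 1) {
  simulate_bold(network_preset("benchmark"), NULL,
                task_config(n_trs = n_trs), seed = seed,
                n_subjects = n_subjects)
}

# response-rate tables for n simulated subjects under one agent
rate_tables <- function(n, agent, master_seed, cfg = task_config()) {
  do.call(rbind, lapply(seq_len(n), function(s) {
    sch <- gen_transfer_schedule(cfg, derive_seed(master_seed, "sched", s))
    rec <- gen_transfer_behavior(sch, agent, derive_seed(master_seed, "beh", s),
                                 subject_id = paste0("s", s))
    transfer_rates(rec, sch)
  }))
}

# independent 3-way RM-ANOVA oracle via base aov() with an Error() stratum
aov_oracle <- function(table) {
  df <- table
  df$subject <- factor(df$subject)
  df$stimulus <- factor(df$stimulus)
  df$interval <- factor(df$interval)
  df$response <- factor(df$response)
  fit <- stats::aov(rate ~ interval * stimulus * response +
                      Error(subject / (interval * stimulus * response)),
                    data = df)
  sm <- summary(fit)
  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    for (i in seq_len(nrow(tab))) {
      nm <- trimws(rownames(tab)[i])
      if (nm == "Residuals") next
      out[[nm]] <- c(F = tab[i, "F value"], df1 = tab[i, "Df"],
                     ss = tab[i, "Sum Sq"])
    }
  }
  out
}

# truth with a single non-AR path (for targeted recovery tests)
single_path_truth <- function(type = c("contemporaneous", "lagged"),
                              beta = 0.6, ar = 0.5) {
  type <- match.arg(type)
  A <- matrix(0, 5, 5)
  Phi <- diag(ar, 5)
  if (type == "contemporaneous") A[2, 1] <- beta else Phi[2, 1] <- beta
  true_network(A, Phi, noise_sd = 1, roi_names = paste0("roi", 1:5))
}
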