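roi_default_names <- function(n = 5) {
  if (n == 5) c("putamen_L", "putamen_R", "insula_L", "insula_R", "cingulate_R")
  else paste0("roi", seq_len(n))
}

new_schedule <- function(phase, trial_type, onset, duration) {
  data.frame(phase = phase, trial_type = trial_type,
             onset = onset, duration = duration,
             stringsAsFactors = FALSE)
}

empty_schedule <- function(phase) {
  new_schedule(character(0), character(0), numeric(0), numeric(0))
}

check_schedule <- function(schedule) {
  if (nrow(schedule) < 2) return(invisible(schedule))
  if (is.unsorted(schedule$onset, strictly = TRUE)) {
    stopf("schedule onsets must be strictly increasing within a run")
  }
  ends <- schedule$onset + schedule$duration
  if (any(schedule$onset[-1] < ends[-length(ends)] - 1e-9)) {
    stopf("schedule events overlap")
  }
  invisible(schedule)
}

#' Simulate one instrumental avoidance session
#'
#' The aversive creature is scheduled on a discrete 1-s clock: each 1-s
#' window in which the agent does not make the correct press ends with one
#' attack; a correct press inside the window defers the next scheduled
#' attack by an additional `correct_press_delay_s`. At most one press per
#' window counts. The agent's per-window correct-press probability
#' interpolates linearly from `learn_start_p` to `learn_end_p` over the
#' session, so an always-correct agent suffers zero attacks and a
#' never-correct agent suffers one attack per second.
#'
#' @param config a [task_config()].
#' @param agent an [agent_params()].
#' @param seed integer seed.
#' @param response which response/outcome contingency this session trains
#'   ("R1" or "R2"); one response-outcome pairing per run.
#' @return a list with `schedule` (attack events), `record` (press
#'   timestamps), and `attacks` (numeric vector of attack onset times, s).
#' @export
gen_instrumental_run <- function(config, agent, seed, response = "R1") {
  if (config$session_length_s <= 0) stopf("non-positive session length")
  set.seed(seed)
  len <- config$session_length_s
  step <- config$attack_interval_s
  delay <- config$correct_press_delay_s
  p_at <- function(t) {
    frac <- min(max(t / len, 0), 1)
    agent$learn_start_p + frac * (agent$learn_end_p - agent$learn_start_p)
  }
  attacks <- numeric(0)
  presses <- numeric(0)
  next_attack <- step
  while (next_attack <= len) {
    win_start <- next_attack - step
    if (stats::runif(1) < p_at(win_start + step / 2)) {
      presses <- c(presses, win_start + stats::runif(1) * step)
      next_attack <- next_attack + delay
    } else {
      attacks <- c(attacks, next_attack)
      next_attack <- next_attack + step
    }
  }
  record <- data.frame(subject_id = rep(NA_character_, length(presses)),
                       timestamp = presses,
                       response = rep(response, length(presses)),
                       phase = rep("instrumental", length(presses)),
                       stringsAsFactors = FALSE)
  schedule <- new_schedule(rep("instrumental", length(attacks)),
                           rep("attack", length(attacks)),
                           attacks,
                           rep(config$outcome_duration_s, length(attacks)))
  list(schedule = schedule, record = record, attacks = attacks)
}

#' Generate a Pavlovian conditioning schedule
#'
#' 45 trials by default: each of the five CS-O pairings appears exactly
#' `pav_reps_per_pairing` times in seeded-random order. Each trial is a 4-s
#' CS, a 1-s outcome, then a fixation ITI drawn uniformly from {7, 9, 11} s.
#'
#' @inheritParams gen_instrumental_run
#' @return an event schedule data frame (phase, trial_type, onset, duration).
#' @export
gen_pavlovian_schedule <- function(config, seed) {
  set.seed(seed)
  reps <- config$pav_reps_per_pairing
  if (reps == 0) return(empty_schedule("pavlovian"))
  order <- sample(rep(seq_len(5), reps))
  n <- length(order)
  itis <- sample(config$pav_iti_choices_s, n, replace = TRUE)
  durs <- as.vector(rbind(config$cs_duration_s, config$outcome_duration_s, itis))
  onsets <- cumsum(c(0, durs[-length(durs)]))
  types <- as.vector(rbind(paste0("CS", order), paste0("O", order), "fixation"))
  check_schedule(new_schedule(rep("pavlovian", 3 * n), types, onsets, durs))
}

#' Generate a transfer-phase schedule
#'
#' 60 trials by default: each CS1-CS5 appears exactly
#' `transfer_reps_per_cs` times in seeded-random order. Each trial is a
#' pre-stimulus fixation, the 4-s CS, then a recharge screen whose duration
#' is drawn uniformly from `recharge_range_s`.
#'
#' @inheritParams gen_instrumental_run
#' @return an event schedule data frame.
#' @export
gen_transfer_schedule <- function(config, seed) {
  set.seed(seed)
  reps <- config$transfer_reps_per_cs
  if (reps == 0) return(empty_schedule("transfer"))
  order <- sample(rep(seq_len(5), reps))
  n <- length(order)
  recharge <- stats::runif(n, config$recharge_range_s[1], config$recharge_range_s[2])
  durs <- as.vector(rbind(config$prestim_duration_s, config$cs_duration_s, recharge))
  onsets <- cumsum(c(0, durs[-length(durs)]))
  types <- as.vector(rbind("fixation", paste0("CS", order), "recharge"))
  check_schedule(new_schedule(rep("transfer", 3 * n), types, onsets, durs))
}

#' Simulate free-operant responding during the transfer phase
#'
#' Presses form an inhomogeneous Poisson process. The rate is
#' `baseline_rate` during fixation windows and under CS4/CS5, multiplied by
#' `specific_gain` for the congruent response only (R1 under CS1, R2 under
#' CS2) and by `general_gain` for both responses under CS3. No presses are
#' emitted during recharge screens.
#'
#' @param schedule a transfer-phase schedule from [gen_transfer_schedule()].
#' @param agent an [agent_params()].
#' @param seed integer seed.
#' @param subject_id optional subject label carried in the record.
#' @return a behavioral record data frame
#'   (subject_id, timestamp, response, phase).
#' @export
gen_transfer_behavior <- function(schedule, agent, seed, subject_id = "s1") {
  if (nrow(schedule) > 0 && any(schedule$phase != "transfer")) {
    stopf("phase mismatch: gen_transfer_behavior needs a transfer-phase schedule")
  }
  set.seed(seed)
  active <- schedule[schedule$trial_type != "recharge", , drop = FALSE]
  ts <- numeric(0)
  resp <- character(0)
  for (r in c("R1", "R2")) {
    gain <- rep(1, nrow(active))
    gain[active$trial_type == if (r == "R1") "CS1" else "CS2"] <- agent$specific_gain
    gain[active$trial_type == "CS3"] <- agent$general_gain
    n <- stats::rpois(nrow(active), agent$baseline_rate * gain * active$duration)
    if (sum(n) > 0) {
      ts <- c(ts, rep(active$onset, n) + stats::runif(sum(n)) * rep(active$duration, n))
      resp <- c(resp, rep(r, sum(n)))
    }
  }
  ord <- order(ts)
  data.frame(subject_id = rep(subject_id, length(ts)),
             timestamp = ts[ord], response = resp[ord],
             phase = rep("transfer", length(ts)),
             stringsAsFactors = FALSE)
}
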