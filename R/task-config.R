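#' Task configuration for the avoidance PIT paradigm
#'
#' Timing constants of the three-phase task: 180-s instrumental sessions with
#' a 1-s attack clock and a 3-s deferral per correct press; a Pavlovian phase
#' of 9 repetitions of each of 5 CS-O pairings (4-s CS, 1-s outcome, ITI
#' jittered over 7/9/11 s); a transfer phase of 12 presentations of each CS
#' (pre-stimulus fixation, 4-s CS, 2-12-s recharge screen). BOLD sampling is
#' at TR = 2 s over 5 regions of interest.
#'
#' @param session_length_s instrumental session length, seconds.
#' @param attack_interval_s attack clock increment, seconds.
#' @param correct_press_delay_s deferral earned by a correct press, seconds.
#' @param cs_duration_s conditioned-stimulus duration, seconds.
#' @param outcome_duration_s outcome display duration, seconds.
#' @param pav_iti_choices_s jittered Pavlovian inter-trial intervals, seconds.
#' @param pav_reps_per_pairing Pavlovian repetitions of each CS-O pairing.
#' @param transfer_reps_per_cs transfer presentations of each CS.
#' @param recharge_range_s min/max of the transfer recharge screen, seconds.
#' @param prestim_duration_s pre-stimulus fixation before each transfer CS,
#'   seconds. Matches the CS duration so pre vs. stimulus response rates are
#'   compared over equal windows.
#' @param tr_s repetition time of the BOLD sampling, seconds.
#' @param n_rois number of regions of interest.
#' @param n_trs per-subject BOLD series length, TRs.
#' @return an object of class `task_config`.
#' @export
task_config <- function(session_length_s = 180,
                        attack_interval_s = 1,
                        correct_press_delay_s = 3,
                        cs_duration_s = 4,
                        outcome_duration_s = 1,
                        pav_iti_choices_s = c(7, 9, 11),
                        pav_reps_per_pairing = 9,
                        transfer_reps_per_cs = 12,
                        recharge_range_s = c(2, 12),
                        prestim_duration_s = 4,
                        tr_s = 2,
                        n_rois = 5,
                        n_trs = 540) {
  cfg <- list(
    session_length_s = session_length_s,
    attack_interval_s = attack_interval_s,
    correct_press_delay_s = correct_press_delay_s,
    cs_duration_s = cs_duration_s,
    outcome_duration_s = outcome_duration_s,
    pav_iti_choices_s = pav_iti_choices_s,
    pav_reps_per_pairing = pav_reps_per_pairing,
    transfer_reps_per_cs = transfer_reps_per_cs,
    recharge_range_s = recharge_range_s,
    prestim_duration_s = prestim_duration_s,
    tr_s = tr_s,
    n_rois = n_rois,
    n_trs = n_trs
  )
  durs <- c(session_length_s, attack_interval_s, correct_press_delay_s,
            cs_duration_s, outcome_duration_s, prestim_duration_s, tr_s)
  if (any(durs <= 0)) {
    stopf("all task durations must be positive")
  }
  if (pav_reps_per_pairing < 0 || transfer_reps_per_cs < 0) {
    stopf("repetition counts must be non-negative")
  }
  if (length(recharge_range_s) != 2 || diff(recharge_range_s) < 0 ||
      any(recharge_range_s < 0)) {
    stopf("recharge_range_s must be a non-negative interval [lo, hi]")
  }
  if (any(pav_iti_choices_s <= 0)) stopf("Pavlovian ITIs must be positive")
  if (n_rois < 1 || n_trs < 1) stopf("n_rois and n_trs must be positive")
  structure(cfg, class = "task_config")
}

#' Behavioral agent parameters
#'
#' A stochastic agent for the instrumental and transfer phases. In the
#' instrumental phase the probability of a correct avoidance press per 1-s
#' window interpolates linearly from `learn_start_p` to `learn_end_p` over
#' the session. In the transfer phase button presses form an inhomogeneous
#' Poisson stream: `baseline_rate` presses/s everywhere outside recharge
#' screens, multiplied by `specific_gain` for the congruent response under
#' CS1/CS2 and by `general_gain` for both responses under CS3.
#'
#' Defaults describe an agent that learns the avoidance contingency
#' (expected first/last 30-s-bin attack counts near the 6.8 / 2.6 typically
#' observed with this task) and shows a specific- but no general-transfer
#' effect.
#'
#' @param baseline_rate presses per second outside stimulus-modulated windows.
#' @param specific_gain multiplicative rate gain for the congruent response
#'   under CS1 (R1) and CS2 (R2).
#' @param general_gain multiplicative rate gain for both responses under CS3.
#' @param learn_start_p,learn_end_p correct-press probability at session
#'   start / end (instrumental phase).
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(baseline_rate = 0.1,
                         specific_gain = 5,
                         general_gain = 1,
                         learn_start_p = 0.55,
                         learn_end_p = 0.80) {
  if (baseline_rate < 0 || specific_gain < 0 || general_gain < 0) {
    stopf("rates and gains must be non-negative")
  }
  p <- c(learn_start_p, learn_end_p)
  if (any(p < 0 | p > 1)) stopf("learning probabilities must lie in [0, 1]")
  structure(list(baseline_rate = baseline_rate,
                 specific_gain = specific_gain,
                 general_gain = general_gain,
                 learn_start_p = learn_start_p,
                 learn_end_p = learn_end_p),
            class = "agent_params")
}
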