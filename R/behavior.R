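#' Bin attack times into fixed-width bins
#'
#' Splits an instrumental session into consecutive `bin_s`-second bins
#' (six 30-s bins for the default 180-s session) and counts attacks per
#' bin. A trailing partial bin is dropped with a warning.
#'
#' @param attacks numeric vector of attack onset times, seconds.
#' @param session_length_s session length, seconds.
#' @param bin_s bin width, seconds.
#' @return integer vector of counts, one per complete bin.
#' @export
bin_attacks <- function(attacks, session_length_s = 180, bin_s = 30) {
  n_bins <- session_length_s %/% bin_s
  if (session_length_s %% bin_s != 0) {
    warning(sprintf("session length %g s not divisible by %g s; dropping the partial last bin",
                    session_length_s, bin_s), call. = FALSE)
  }
  counts <- integer(n_bins)
  if (length(attacks) > 0) {
    b <- floor(attacks / bin_s) + 1
    b <- b[b >= 1 & b <= n_bins]
    tab <- tabulate(b, nbins = n_bins)
    counts <- as.integer(tab)
  }
  counts
}

#' Paired t test of first-bin vs last-bin attack counts
#'
#' Classical paired t on (first - last) with df = n - 1, two-sided p.
#' When the differences have zero variance the test is degenerate: a zero
#' mean difference returns t = 0, p = 1; a nonzero mean difference is
#' surfaced as an explicit degenerate-variance condition rather than an
#' infinite statistic.
#'
#' @param first,last equal-length paired count vectors across subjects.
#' @return list with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
learning_test <- function(first, last) {
  if (length(first) != length(last)) stopf("paired vectors differ in length")
  n <- length(first)
  if (n < 2) stopf("need at least 2 paired observations")
  d <- first - last
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, degenerate = FALSE))
    }
    stopf("degenerate-variance condition: differences are constant and nonzero (mean = %g)",
          mean(d))
  }
  ht <- stats::t.test(first, last, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate), degenerate = FALSE)
}

#' Instrumental-learning exclusion rule from shield-effectiveness ratings
#'
#' After the instrumental phase, each response-outcome pair is rated 1-10.
#' For each outcome the incorrect-response rating is subtracted from the
#' correct-response rating (correct pairings: R1-O1, R2-O2); subjects with
#' a score of 0 or less for either outcome are excluded as non-learners.
#'
#' @param ratings named list or vector with elements `r1_o1`, `r1_o2`,
#'   `r2_o1`, `r2_o2`, each in 1-10.
#' @return list with `keep` (logical) and `scores` (named, per outcome).
#' @export
instrumental_exclusion <- function(ratings) {
  need <- c("r1_o1", "r1_o2", "r2_o1", "r2_o2")
  ratings <- as.list(ratings)
  if (!all(need %in% names(ratings)) || any(vapply(ratings[need], function(x)
    is.null(x) || is.na(x), logical(1)))) {
    stopf("missing rating: need all of %s", paste(need, collapse = ", "))
  }
  r <- vapply(ratings[need], as.numeric, numeric(1))
  if (any(r < 1 | r > 10)) stopf("ratings must lie in [1, 10]")
  scores <- c(O1 = unname(r["r1_o1"] - r["r2_o1"]),
              O2 = unname(r["r2_o2"] - r["r1_o2"]))
  list(keep = all(scores > 0), scores = scores)
}

#' Per-stimulus response rates in the transfer phase
#'
#' Assigns each press to the (stimulus, interval) window containing it:
#' `pre` is the fixation window immediately preceding each CS, `stim` the
#' CS window itself. Presses during recharge screens are ignored. Counts
#' are divided by the number of presentations per CS to give the mean
#' responses per presentation, yielding the full 5 x 2 x 2
#' (stimulus x interval x response) cell table per subject.
#'
#' @param record behavioral record from [gen_transfer_behavior()].
#' @param schedule the matching transfer schedule.
#' @param reps_per_cs presentations of each CS (the rate denominator).
#' @return long data frame: subject, stimulus, interval, response, rate.
#' @export
transfer_rates <- function(record, schedule, reps_per_cs = 12) {
  run_end <- if (nrow(schedule)) max(schedule$onset + schedule$duration) else 0
  if (nrow(record) > 0 &&
      (any(record$timestamp < 0) || any(record$timestamp > run_end + 1e-9))) {
    stopf("press timestamps fall outside the run span [0, %.1f]", run_end)
  }
  subject <- if (nrow(record) > 0) record$subject_id[1] else "s1"
  grid <- expand.grid(stimulus = paste0("CS", 1:5),
                      interval = c("pre", "stim"),
                      response = c("R1", "R2"),
                      stringsAsFactors = FALSE)
  grid$count <- 0
  cs_rows <- which(grepl("^CS", schedule$trial_type))
  # window table: each CS window plus the fixation window directly before it
  w_start <- schedule$onset[cs_rows]
  w_end <- w_start + schedule$duration[cs_rows]
  w_stim <- schedule$trial_type[cs_rows]
  w_int <- rep("stim", length(cs_rows))
  pre_ok <- cs_rows > 1 & schedule$trial_type[pmax(cs_rows - 1, 1)] == "fixation"
  pr <- cs_rows[pre_ok] - 1
  w_start <- c(w_start, schedule$onset[pr])
  w_end <- c(w_end, schedule$onset[pr] + schedule$duration[pr])
  w_stim <- c(w_stim, schedule$trial_type[cs_rows[pre_ok]])
  w_int <- c(w_int, rep("pre", length(pr)))
  ord <- order(w_start)
  w_start <- w_start[ord]; w_end <- w_end[ord]
  w_stim <- w_stim[ord]; w_int <- w_int[ord]
  if (nrow(record) > 0 && length(w_start) > 0) {
    idx <- findInterval(record$timestamp, w_start)
    hit <- idx >= 1 & record$timestamp < w_end[pmax(idx, 1)]
    if (any(hit)) {
      keys <- paste(w_stim[idx[hit]], w_int[idx[hit]], record$response[hit])
      tab <- table(keys)
      gkeys <- paste(grid$stimulus, grid$interval, grid$response)
      hit_counts <- as.integer(tab[match(gkeys, names(tab))])
      hit_counts[is.na(hit_counts)] <- 0L
      grid$count <- hit_counts
    }
  }
  data.frame(subject = subject, stimulus = grid$stimulus,
             interval = grid$interval, response = grid$response,
             rate = grid$count / reps_per_cs, stringsAsFactors = FALSE)
}
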