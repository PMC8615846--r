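#' Canonical two-gamma hemodynamic response
#'
#' Difference of two gamma densities, parameterized by the time-to-peak and
#' dispersion of the positive lobe; the undershoot lobe peaks at
#' `undershoot_delay` and is scaled by `undershoot_ratio`. Normalized to a
#' peak amplitude of 1. This is the generative HRF family whose parameters
#' vary across simulated subjects; the estimator ([estimate_sfir()]) makes
#' no use of it.
#'
#' @param t time points, seconds.
#' @param peak_delay time to peak of the positive lobe, seconds.
#' @param dispersion scale of the positive lobe, seconds.
#' @param undershoot_delay,undershoot_dispersion,undershoot_ratio undershoot
#'   lobe parameters.
#' @return numeric vector of HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak_delay = 6, dispersion = 1,
                          undershoot_delay = 16, undershoot_dispersion = 1,
                          undershoot_ratio = 1 / 6) {
  pos <- stats::dgamma(t, shape = peak_delay / dispersion + 1, scale = dispersion)
  und <- stats::dgamma(t, shape = undershoot_delay / undershoot_dispersion + 1,
                       scale = undershoot_dispersion)
  h <- pos - undershoot_ratio * und
  peak <- max(h)
  if (peak > 0) h / peak else h
}

# Convolve event onsets (seconds) with an HRF sampled on a 16x-upsampled
# microtime grid, then decimate to TR resolution. Avoids +-1-TR onset
# aliasing from direct TR-grid binning.
convolve_onsets_hrf <- function(onsets_s, n_trs, tr_s, hrf_fun,
                                upsample = 16, hrf_span_s = 32) {
  dt <- tr_s / upsample
  n_micro <- n_trs * upsample
  sticks <- numeric(n_micro)
  keep <- onsets_s >= 0 & onsets_s < n_trs * tr_s
  idx <- floor(onsets_s[keep] / dt) + 1
  for (i in idx) sticks[i] <- sticks[i] + 1
  h <- hrf_fun(seq(0, hrf_span_s, by = dt))
  u <- stats::convolve(sticks, rev(h), type = "open")[seq_len(n_micro)]
  u[seq(1, n_micro, by = upsample)]
}

# specific = CS1 u CS2 onsets, general = CS3 onsets (seconds)
schedule_input_onsets <- function(schedule) {
  if (is.null(schedule) || nrow(schedule) == 0) {
    return(list(specific = numeric(0), general = numeric(0)))
  }
  list(specific = schedule$onset[schedule$trial_type %in% c("CS1", "CS2")],
       general = schedule$onset[schedule$trial_type == "CS3"])
}

new_subject_matrix <- function(mat, tr_s, subject_id, n_inputs = 2) {
  structure(mat, tr_s = tr_s, subject_id = subject_id,
            n_inputs = n_inputs, class = c("subject_matrix", "matrix", "array"))
}

#' @export
print.subject_matrix <- function(x, ...) {
  cat(sprintf("subject_matrix '%s': %d TRs x %d columns (TR = %g s)\n",
              attr(x, "subject_id"), nrow(x), ncol(x), attr(x, "tr_s")))
  cat("columns:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate ROI BOLD series from a ground-truth euSEM
#'
#' For each subject, task inputs are built from the schedule (specific =
#' CS1/CS2 onsets, general = CS3 onsets), convolved with that subject's
#' generative HRF on a 16x microtime grid, and fed through
#' \deqn{y_t = (I - A - T u_t)^{-1} (\Phi y_{t-1} + \Gamma u_t + \zeta_t)}
#' with white Gaussian dynamic noise. A burn-in period (with inputs off) is
#' discarded so the series start near the stationary regime.
#'
#' @param truth a [true_network()].
#' @param schedules list of transfer-phase event schedules, one per subject;
#'   `NULL` for input-free (resting-style) simulation of `n_subjects`
#'   subjects.
#' @param config a [task_config()]; supplies TR and series length.
#' @param seed master seed; each subject draws from a derived substream.
#' @param n_subjects number of subjects when `schedules` is `NULL`.
#' @param burn_in TRs simulated and discarded before the recorded series.
#' @return a list of `subject_matrix` objects, each `n_trs` x (p + 2)
#'   (ROI columns plus binary `specific`/`general` onset indicator columns).
#' @export
simulate_bold <- function(truth, schedules = NULL, config = task_config(),
                          seed = 1, n_subjects = NULL, burn_in = 50) {
  if (is.null(schedules)) {
    if (is.null(n_subjects)) stopf("give schedules or n_subjects")
    schedules <- vector("list", n_subjects)
  }
  n_sub <- length(schedules)
  p <- length(truth$roi_names)
  n_trs <- config$n_trs
  tr <- config$tr_s
  hrf_tab <- truth$hrf_params[rep_len(seq_len(nrow(truth$hrf_params)), n_sub), ,
                              drop = FALSE]
  lapply(seq_len(n_sub), function(s) {
    set.seed(derive_seed(seed, "bold", s))
    ons <- schedule_input_onsets(schedules[[s]])
    hf <- function(t) canonical_hrf(t, hrf_tab$peak_delay[s], hrf_tab$dispersion[s])
    u_conv <- cbind(
      specific = convolve_onsets_hrf(ons$specific, n_trs, tr, hf),
      general = convolve_onsets_hrf(ons$general, n_trs, tr, hf))
    u_all <- rbind(matrix(0, burn_in, 2), u_conv)
    total <- burn_in + n_trs
    y <- matrix(0, total, p)
    zeta <- matrix(stats::rnorm(total * p, sd = rep(truth$noise_sd, each = total)),
                   total, p)
    has_inputs <- length(truth$input_names) > 0
    y_prev <- numeric(p)
    for (t in seq_len(total)) {
      ut <- if (has_inputs) u_all[t, ] else numeric(0)
      W <- diag(p) - truth$A
      drive <- truth$Phi %*% y_prev + zeta[t, ]
      if (has_inputs) {
        for (j in seq_along(ut)) {
          if (ut[j] != 0) W <- W - ut[j] * truth$Tau[, j, ]
        }
        drive <- drive + truth$Gamma %*% ut
      }
      if (abs(det(W)) < 1e-10) {
        stopf("simulation error: (I - A - Tau u_t) singular at t = %d", t - burn_in)
      }
      y[t, ] <- solve(W, drive)
      y_prev <- y[t, ]
    }
    y <- y[(burn_in + 1):total, , drop = FALSE]
    bins <- function(o) {
      v <- numeric(n_trs)
      b <- floor(o / tr) + 1
      b <- b[b >= 1 & b <= n_trs]
      v[b] <- 1
      v
    }
    mat <- cbind(y, specific = bins(ons$specific), general = bins(ons$general))
    colnames(mat) <- c(truth$roi_names, "specific", "general")
    new_subject_matrix(mat, tr, paste0("sub", s))
  })
}

#' Embed ROI time series into a synthetic 4D voxel volume
#'
#' Every voxel inside an ROI sphere carries that ROI's time series plus
#' independent Gaussian noise; all other voxels carry pure noise. Voxels
#' covered by overlapping spheres carry the sum of the overlapping ROI
#' signals. A fixture generator for testing sphere-mask extraction.
#'
#' @param series a `subject_matrix` (only ROI columns are used) or T x p
#'   matrix.
#' @param roi_specs data frame as from [roi_table()] (name, hemisphere,
#'   x, y, z, radius_mm).
#' @param grid_spec list with `dim` (length-3 voxel counts) and `affine`
#'   (4 x 4 voxel-index -> MNI-mm matrix, 0-based indices).
#' @param noise_sd voxel noise standard deviation.
#' @param seed integer seed.
#' @return list with `data` (4D array) and `affine`.
#' @export
make_voxel_volume <- function(series, roi_specs, grid_spec, noise_sd = 0.5,
                              seed = 1) {
  set.seed(seed)
  p <- nrow(roi_specs)
  y <- unclass(series)[, seq_len(p), drop = FALSE]
  n_t <- nrow(y)
  d <- grid_spec$dim
  vol <- array(stats::rnorm(prod(d) * n_t, sd = noise_sd), c(d, n_t))
  if (noise_sd == 0) vol[] <- 0
  for (k in seq_len(p)) {
    mask <- sphere_mask(roi_spec_row(roi_specs, k), grid_spec)
    for (v in seq_len(nrow(mask))) {
      vol[mask[v, 1], mask[v, 2], mask[v, 3], ] <-
        vol[mask[v, 1], mask[v, 2], mask[v, 3], ] + y[, k]
    }
  }
  list(data = vol, affine = grid_spec$affine)
}
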