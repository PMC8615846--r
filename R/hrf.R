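#' Smoothed finite impulse response (sFIR) estimate of the HRF
#'
#' Estimates a shape-free, TR-spaced impulse response of length `L` from
#' one ROI series and a binary onset vector, by penalized least squares:
#' minimize ||y - X h||^2 + lambda ||D h||^2, where X is the lagged-onset
#' (Toeplitz) design and D the second-difference operator. The roughness
#' penalty shrinks the estimate toward a straight line as lambda grows and
#' reduces to ordinary FIR least squares at lambda = 0. An unpenalized
#' intercept absorbs the series mean. lambda = "gcv" selects the penalty by
#' generalized cross-validation over a log-spaced grid.
#'
#' @param y numeric ROI time series (length T).
#' @param onsets binary onset vector (length T, TR-spaced).
#' @param L impulse-response length in TRs (default 16, i.e. 32 s at
#'   TR = 2 s).
#' @param lambda non-negative penalty, or "gcv".
#' @param tr_s TR, seconds.
#' @return object of class `hrf_estimate`: `coefficients` (length L),
#'   `lambda`, `window_s`, `tr_s`, `gcv` (grid, when selected).
#' @export
estimate_sfir <- function(y, onsets, L = 16, lambda = "gcv", tr_s = 2) {
  T_ <- length(y)
  if (length(onsets) != T_) stopf("y and onsets differ in length")
  if (sum(onsets != 0) == 0) stopf("zero onsets: cannot estimate an HRF")
  if (T_ <= L) stopf("series too short: need T > L")
  X <- matrix(0, T_, L)
  for (l in seq_len(L)) {
    X[l:T_, l] <- onsets[1:(T_ - l + 1)]
  }
  Xa <- cbind(1, X) # unpenalized intercept
  D <- matrix(0, L - 2, L)
  for (i in seq_len(L - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  Da <- cbind(0, D)
  XtX <- crossprod(Xa)
  Xty <- crossprod(Xa, y)
  DtD <- crossprod(Da)
  solve_at <- function(lam) {
    M <- XtX + lam * DtD
    h <- tryCatch(solve(M, Xty), error = function(e)
      stopf("singular penalized normal equations at lambda = %g; try a larger lambda", lam))
    drop(h)
  }
  gcv_grid <- NULL
  if (identical(lambda, "gcv")) {
    grid <- 10^seq(-2, 4, length.out = 25)
    scores <- vapply(grid, function(lam) {
      M <- XtX + lam * DtD
      Minv <- tryCatch(solve(M), error = function(e) NULL)
      if (is.null(Minv)) return(Inf)
      h <- drop(Minv %*% Xty)
      fit <- drop(Xa %*% h)
      edf <- sum(diag(Minv %*% XtX))
      T_ * sum((y - fit)^2) / (T_ - edf)^2
    }, numeric(1))
    lambda <- grid[which.min(scores)]
    gcv_grid <- data.frame(lambda = grid, gcv = scores)
  }
  h <- solve_at(lambda)
  structure(list(coefficients = h[-1], intercept = h[1], lambda = lambda,
                 window_s = L * tr_s, tr_s = tr_s, gcv = gcv_grid),
            class = "hrf_estimate")
}

#' Time-to-peak of an estimated HRF
#'
#' Sub-TR precision: a quadratic is interpolated through the maximum
#' coefficient and its two neighbors, removing the up-to-half-TR
#' discretization bias of the raw argmax.
#'
#' @param hrf an `hrf_estimate`.
#' @return seconds from event onset to the (interpolated) peak.
#' @export
hrf_peak_time <- function(hrf) {
  h <- hrf$coefficients
  k <- which.max(h)
  off <- 0
  if (k > 1 && k < length(h)) {
    denom <- h[k - 1] - 2 * h[k] + h[k + 1]
    if (denom < 0) off <- 0.5 * (h[k - 1] - h[k + 1]) / denom
    off <- max(-0.5, min(0.5, off))
  }
  (k - 1 + off) * hrf$tr_s
}

#' Convolve a binary onset vector with an estimated HRF
#'
#' Discrete causal convolution truncated to the input length; linear in the
#' onsets, so a single onset at bin k copies the HRF coefficients starting
#' at bin k.
#'
#' @param onsets binary (or weighted) onset vector.
#' @param hrf an `hrf_estimate`, or a numeric coefficient vector.
#' @return numeric vector, same length as `onsets`.
#' @export
convolve_input <- function(onsets, hrf) {
  h <- if (inherits(hrf, "hrf_estimate")) hrf$coefficients else as.numeric(hrf)
  T_ <- length(onsets)
  u <- numeric(T_)
  for (l in seq_len(min(length(h), T_))) {
    idx <- l:T_
    u[idx] <- u[idx] + h[l] * onsets[idx - l + 1]
  }
  u
}

#' Estimate per-subject HRFs for each task input
#'
#' Runs [estimate_sfir()] once per input, either against each ROI's series
#' (`mode = "target"`, giving one HRF per input x ROI so each direct effect
#' uses the HRF of the ROI it targets) or against the mean over all ROIs
#' (`mode = "mean"`). Estimated once, before any model search, and held
#' fixed thereafter. Inputs with no onsets get a NULL entry.
#'
#' @param mat a `subject_matrix` (binary input columns).
#' @param mode "target" or "mean".
#' @param L,lambda passed to [estimate_sfir()].
#' @return nested list: `hrfs[[input]][[roi]]` for "target",
#'   `hrfs[[input]]` for "mean"; carries attribute `mode`.
#' @export
estimate_subject_hrfs <- function(mat, mode = c("target", "mean"),
                                  L = 16, lambda = "gcv") {
  mode <- match.arg(mode)
  tr <- attr(mat, "tr_s")
  n_in <- attr(mat, "n_inputs") %||% 2
  p <- ncol(mat) - n_in
  rois <- colnames(mat)[seq_len(p)]
  inputs <- colnames(mat)[p + seq_len(n_in)]
  out <- list()
  for (u in inputs) {
    ons <- mat[, u]
    if (sum(ons != 0) == 0) {
      out[u] <- list(NULL)
      next
    }
    if (mode == "mean") {
      out[[u]] <- estimate_sfir(rowMeans(mat[, rois, drop = FALSE]), ons,
                                L = L, lambda = lambda, tr_s = tr)
    } else {
      out[[u]] <- lapply(stats::setNames(rois, rois), function(r)
        estimate_sfir(mat[, r], ons, L = L, lambda = lambda, tr_s = tr))
    }
  }
  attr(out, "mode") <- mode
  out
}
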