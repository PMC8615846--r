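#' SEM fit indices for a euSEM fit
#'
#' Computes RMSEA, SRMR, CFI and NNFI from the model, saturated and
#' baseline discrepancies over the joint covariance of the ROI series and
#' their exogenous predictors (lagged series, convolved inputs, bilinear
#' terms). Exogenous covariances are saturated, so the modeled moments are
#' the ROI covariance block plus the ROI-by-predictor block; degrees of
#' freedom count the freed paths plus the p residual variances against
#' those moments. The baseline is the independence model with free
#' variances (distinct from the search's AR-only null model). Exogenous
#' columns with zero variance (e.g. inputs with no onsets) are dropped.
#'
#' The excellent-fit verdict follows the two-of-four rule:
#' CFI > 0.95, NNFI > 0.95, RMSEA < 0.05, SRMR < 0.05.
#'
#' @param fit a converged `model_fit`.
#' @param data ignored (the fit carries its model data); kept for call-site
#'   symmetry.
#' @return list with `rmsea`, `srmr`, `cfi`, `nnfi`, `chisq`, `df`,
#'   `chisq_baseline`, `df_baseline`, `excellent`.
#' @export
fit_indices <- function(fit, data = NULL) {
  if (!fit$converged) {
    stopf("fit indices refused: model fit did not converge")
  }
  md <- fit$md
  e <- fit$edges
  n <- md$n
  p <- md$p
  rois <- fit$structure$roi_names

  lag_cols <- md$ylag
  colnames(lag_cols) <- paste0("lag:", rois)
  extra <- md$xcols
  bil <- e[e$type == "bilinear", , drop = FALSE]
  for (i in seq_len(nrow(bil))) {
    key <- paste0("bil:", bil$source[i], "*", bil$input[i], "@", bil$target[i])
    extra[[key]] <- edge_regressor(md, "bilinear", bil$source[i],
                                   bil$target[i], bil$input[i])
  }
  xmat <- cbind(lag_cols, do.call(cbind, extra))
  if (!is.null(xmat)) {
    keep <- apply(xmat, 2, stats::sd) > 1e-12
    xmat <- xmat[, keep, drop = FALSE]
  }
  k <- ncol(xmat)
  xnames <- colnames(xmat)

  joint <- cbind(md$y, xmat)
  jc <- sweep(joint, 2, colMeans(joint))
  S <- crossprod(jc) / n
  Syy <- S[seq_len(p), seq_len(p), drop = FALSE]
  Sxx <- S[p + seq_len(k), p + seq_len(k), drop = FALSE]

  A <- matrix(0, p, p, dimnames = list(rois, rois))
  B <- matrix(0, p, k, dimnames = list(rois, xnames))
  for (i in seq_len(nrow(e))) {
    b <- e$beta[i]
    tgt <- e$target[i]
    key <- switch(e$type[i],
      ar = paste0("lag:", e$source[i]),
      lagged = paste0("lag:", e$source[i]),
      contemporaneous = NA,
      direct = if (md$mode == "target" && md$has_hrfs)
        paste0("in:", e$source[i], "@", tgt) else paste0("in:", e$source[i]),
      bilinear = paste0("bil:", e$source[i], "*", e$input[i], "@", tgt))
    if (e$type[i] == "contemporaneous") {
      A[tgt, e$source[i]] <- b
    } else if (!is.na(key) && key %in% xnames) {
      B[tgt, key] <- b
    }
    # edges whose regressor was dropped (zero variance) contribute nothing
  }
  Psi <- diag(fit$sigma2, p)
  IAinv <- solve(diag(p) - A)

  implied <- function(Ai, Bi, Psii) {
    Syy_i <- Ai %*% (Bi %*% Sxx %*% t(Bi) + Psii) %*% t(Ai)
    Syx_i <- Ai %*% Bi %*% Sxx
    Sig <- rbind(cbind(Syy_i, Syx_i), cbind(t(Syx_i), Sxx))
    dimnames(Sig) <- dimnames(S)
    Sig
  }
  fml <- function(Sig) {
    m <- nrow(S)
    val <- determinant(Sig, logarithm = TRUE)$modulus -
      determinant(S, logarithm = TRUE)$modulus +
      sum(diag(S %*% solve(Sig))) - m
    max(0, as.numeric(val))
  }

  Sigma <- implied(IAinv, B, Psi)
  n_moments <- p * (p + 1) / 2 + p * k
  n_par <- nrow(e) + p
  df <- n_moments - n_par
  chisq <- n * fml(Sigma)

  Sigma_b <- implied(diag(p), matrix(0, p, k), diag(diag(Syy), p))
  df_b <- n_moments - p
  chisq_b <- n * fml(Sigma_b)

  rmsea <- if (df > 0) sqrt(max(0, (chisq - df) / (df * (n - 1)))) else 0
  denom <- max(chisq - df, chisq_b - df_b, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chisq - df, 0) / denom
  nnfi <- if (df > 0 && df_b > 0 && chisq_b / df_b > 1) {
    (chisq_b / df_b - chisq / df) / (chisq_b / df_b - 1)
  } else 1

  sd_all <- sqrt(diag(S))
  resid_std <- (S - Sigma) / outer(sd_all, sd_all)
  ut <- upper.tri(resid_std, diag = TRUE)
  modeled <- ut
  modeled[p + seq_len(k), p + seq_len(k)] <- FALSE # x-block saturated
  srmr <- sqrt(mean(resid_std[modeled]^2))

  passes <- c(cfi = cfi > 0.95, nnfi = nnfi > 0.95,
              rmsea = rmsea < 0.05, srmr = srmr < 0.05)
  list(rmsea = rmsea, srmr = srmr, cfi = cfi, nnfi = nnfi,
       chisq = chisq, df = df, chisq_baseline = chisq_b, df_baseline = df_b,
       excellent = sum(passes) >= 2, passes = passes)
}

#' Two-of-four excellent-fit verdict from index values
#'
#' @param cfi,nnfi,rmsea,srmr index values.
#' @return TRUE iff at least two of CFI > 0.95, NNFI > 0.95, RMSEA < 0.05,
#'   SRMR < 0.05 hold.
#' @export
excellent_fit <- function(cfi, nnfi, rmsea, srmr) {
  sum(c(cfi > 0.95, nnfi > 0.95, rmsea < 0.05, srmr < 0.05)) >= 2
}
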