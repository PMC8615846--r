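# ---- model-data preparation -------------------------------------------
# Aligns y_t (t = 2..T) with y_{t-1} and the task inputs, convolving the
# binary input columns with the supplied HRF estimates. `hrfs` may be NULL
# (input columns used as-is), a per-input list of hrf_estimates ("mean"
# mode), or a nested per-input-per-ROI list ("target" mode, each direct or
# bilinear effect using the HRF of the ROI it targets).
build_model_data <- function(data, hrfs = NULL) {
  mat <- unclass(data)
  n_in <- attr(data, "n_inputs") %||% 2
  p <- ncol(mat) - n_in
  rois <- colnames(mat)[seq_len(p)]
  inputs <- if (n_in > 0) colnames(mat)[p + seq_len(n_in)] else character(0)
  T_ <- nrow(mat)
  y <- mat[2:T_, rois, drop = FALSE]
  ylag <- mat[1:(T_ - 1), rois, drop = FALSE]
  n <- T_ - 1
  mode <- attr(hrfs, "mode") %||% "mean"
  xcols <- list()
  ucol_key <- function(u, r = NULL) {
    if (mode == "target" && !is.null(hrfs)) paste0("in:", u, "@", r)
    else paste0("in:", u)
  }
  for (u in inputs) {
    raw <- mat[, u]
    if (is.null(hrfs) || is.null(hrfs[[u]])) {
      xcols[[paste0("in:", u)]] <- raw[2:T_]
    } else if (mode == "mean") {
      xcols[[paste0("in:", u)]] <- convolve_input(raw, hrfs[[u]])[2:T_]
    } else {
      for (r in rois) {
        xcols[[paste0("in:", u, "@", r)]] <-
          convolve_input(raw, hrfs[[u]][[r]])[2:T_]
      }
    }
  }
  ycen <- sweep(y, 2, colMeans(y))
  list(y = y, ylag = ylag, ycen = ycen, xcols = xcols, n = n, p = p,
       rois = rois, inputs = inputs, mode = mode,
       has_hrfs = !is.null(hrfs))
}

edge_regressor <- function(md, type, source, target, input) {
  if (type %in% c("ar", "lagged")) return(md$ylag[, source])
  if (type == "contemporaneous") return(md$y[, source])
  if (type == "direct") {
    key <- if (md$mode == "target" && md$has_hrfs)
      paste0("in:", source, "@", target) else paste0("in:", source)
    col <- md$xcols[[key]]
    if (is.null(col)) stopf("input '%s' has no onsets", source)
    return(col)
  }
  if (type == "bilinear") {
    key <- if (md$mode == "target" && md$has_hrfs)
      paste0("in:", input, "@", target) else paste0("in:", input)
    col <- md$xcols[[key]]
    if (is.null(col)) stopf("input '%s' has no onsets", input)
    return(col * md$ycen[, source])
  }
  stopf("unknown edge type '%s'", type)
}

# order-condition identification check for equations with endogenous
# (contemporaneous) right-hand sides: the number of system exogenous
# variables excluded from an equation must be at least the number of its
# endogenous regressors. Bilinear terms count as endogenous (they contain a
# contemporaneous ROI series).
check_identification <- function(structure, md) {
  # recursive (acyclic) systems with diagonal noise are identified outright;
  # the order condition is needed only when contemporaneous cycles exist
  if (isTRUE(contemporaneous_acyclic(structure))) return(invisible(TRUE))
  e <- structure$edges
  exog_id <- function(rows) {
    ifelse(rows$type %in% c("ar", "lagged"), paste0("lag:", rows$source),
           ifelse(rows$type == "direct", paste0("in:", rows$source), NA))
  }
  sys_exog <- unique(stats::na.omit(exog_id(e)))
  for (r in structure$roi_names) {
    eq <- e[e$target == r, , drop = FALSE]
    endo <- sum(eq$type %in% c("contemporaneous", "bilinear"))
    if (endo == 0) next
    eq_exog <- unique(stats::na.omit(exog_id(eq)))
    excluded <- length(setdiff(sys_exog, eq_exog))
    if (excluded < endo) {
      acyc <- contemporaneous_acyclic(structure)
      cyc <- attr(acyc, "cycle")
      stopf(paste0("identification error: equation for '%s' has %d endogenous ",
                   "regressor(s) but only %d excluded instrument(s)%s"),
            r, endo, excluded,
            if (length(cyc)) paste0(" (cycle among: ",
                                    paste(cyc, collapse = ", "), ")") else "")
    }
  }
  invisible(TRUE)
}

#' Fit a euSEM with a fixed path structure to one subject
#'
#' Maximum-likelihood estimation of
#' \deqn{y_t = A y_t + \Phi y_{t-1} + \Gamma u_t + (T u_t) y_t + \zeta_t}
#' with diagonal noise covariance. Lagged series and HRF-convolved inputs
#' are exogenous regressors; contemporaneous effects make the equations
#' simultaneous. When the contemporaneous dependency graph is acyclic the
#' ML solution is the equation-wise least-squares fit (unit Jacobian,
#' independent equations); cyclic but order-identified structures are fit
#' by full-information ML over the simultaneous system (quasi-Newton, with
#' the log-Jacobian term), flagged `converged = FALSE` if the optimizer
#' does not converge - never silently downgraded. Each equation carries an
#' unpenalized intercept that is not counted as a path.
#'
#' @param data a `subject_matrix`.
#' @param structure a [network_structure()].
#' @param hrfs HRF estimates from [estimate_subject_hrfs()], or NULL to use
#'   the input columns as-is.
#' @param warn_ratio warn when T < 10 x free parameters.
#' @return object of class `model_fit`: `edges` (with beta, se, z, p),
#'   `sigma2`, `loglik`, `converged`, `n`, plus internals reused by
#'   [modification_indices()] and [fit_indices()].
#' @export
estimate_model <- function(data, structure, hrfs = NULL, warn_ratio = TRUE) {
  md <- build_model_data(data, hrfs)
  e <- structure$edges
  if (anyDuplicated(edge_ids(e))) stopf("duplicate edges in structure")
  if (warn_ratio && md$n < 10 * nrow(e)) {
    warning(sprintf("only %d time points for %d free paths (< 10 per path)",
                    md$n, nrow(e)), call. = FALSE)
  }
  check_identification(structure, md)
  acyc <- contemporaneous_acyclic(structure)

  designs <- lapply(stats::setNames(structure$roi_names, structure$roi_names),
                    function(r) {
    eq <- e[e$target == r, , drop = FALSE]
    Z <- matrix(1, md$n, 1)
    colnames(Z) <- "(intercept)"
    if (nrow(eq)) {
      X <- vapply(seq_len(nrow(eq)), function(i)
        edge_regressor(md, eq$type[i], eq$source[i], eq$target[i], eq$input[i]),
        numeric(md$n))
      colnames(X) <- edge_ids(eq)
      Z <- cbind(Z, X)
    }
    list(Z = Z, edge_rows = which(e$target == r))
  })

  est <- e
  est$beta <- est$se <- est$z <- est$p <- NA_real_
  sigma2 <- stats::setNames(numeric(md$p), structure$roi_names)
  resid <- matrix(0, md$n, md$p, dimnames = list(NULL, structure$roi_names))
  qr_list <- list()
  converged <- TRUE

  if (isTRUE(acyc)) {
    for (r in structure$roi_names) {
      d <- designs[[r]]
      qz <- qr(d$Z)
      if (qz$rank < ncol(d$Z)) {
        stopf("rank-deficient design for equation '%s'", r)
      }
      beta <- qr.coef(qz, md$y[, r])
      res <- md$y[, r] - d$Z %*% beta
      s2 <- sum(res^2) / md$n
      XtXinv <- chol2inv(qr.R(qz))
      se <- sqrt(s2 * diag(XtXinv))
      if (length(d$edge_rows)) {
        est$beta[d$edge_rows] <- beta[-1]
        est$se[d$edge_rows] <- se[-1]
      }
      sigma2[r] <- s2
      resid[, r] <- res
      qr_list[[r]] <- qz
    }
    loglik <- -md$n / 2 * sum(log(2 * pi * sigma2) + 1)
  } else {
    fiml <- fit_fiml(md, structure, designs, e)
    est$beta <- fiml$beta
    est$se <- fiml$se
    sigma2 <- fiml$sigma2
    resid <- fiml$resid
    loglik <- fiml$loglik
    converged <- fiml$converged
    qr_list <- lapply(designs, function(d) qr(d$Z))
  }

  est$z <- est$beta / est$se
  est$p <- 2 * stats::pnorm(-abs(est$z))
  out <- list(edges = est, sigma2 = sigma2, loglik = loglik,
              converged = converged, n = md$n,
              structure = structure, md = md, resid = resid,
              qr_list = qr_list)
  class(out) <- "model_fit"
  out
}

# full-information ML for cyclic (but identified) contemporaneous graphs:
# minimize -sum log|det(I - A)| + n/2 sum_i log(RSS_i/n) over all edge
# weights, intercepts concentrated out by centering.
fit_fiml <- function(md, structure, designs, e) {
  p <- md$p
  rois <- structure$roi_names
  ycen <- sweep(md$y, 2, colMeans(md$y))
  Zc <- lapply(designs, function(d) {
    Z <- d$Z[, -1, drop = FALSE]
    if (ncol(Z)) sweep(Z, 2, colMeans(Z)) else Z
  })
  con_rows <- which(e$type == "contemporaneous")
  resid_mat <- function(theta) {
    R <- ycen
    for (r in rois) {
      rows <- designs[[r]]$edge_rows
      if (length(rows)) {
        R[, r] <- R[, r] - Zc[[r]] %*% theta[rows]
      }
    }
    R
  }
  # contemporaneous regressors are centered y columns inside Zc, so the
  # Jacobian of zeta -> y is (I - A)
  a_mat <- function(theta) {
    A <- matrix(0, p, p, dimnames = list(rois, rois))
    for (i in con_rows) A[e$target[i], e$source[i]] <- theta[i]
    A
  }
  nll <- function(theta) {
    A <- a_mat(theta)
    dt <- det(diag(p) - A)
    if (!is.finite(dt) || abs(dt) < 1e-12) return(1e10)
    R <- resid_mat(theta)
    rss <- colSums(R^2)
    if (any(rss <= 0)) return(1e10)
    -md$n * log(abs(dt)) + md$n / 2 * sum(log(rss / md$n))
  }
  theta0 <- numeric(nrow(e))
  for (r in rois) {
    rows <- designs[[r]]$edge_rows
    if (length(rows)) {
      theta0[rows] <- stats::lm.fit(designs[[r]]$Z, md$y[, r])$coefficients[-1]
    }
  }
  opt <- stats::optim(theta0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  theta <- opt$par
  R <- resid_mat(theta)
  sigma2 <- stats::setNames(colSums(R^2) / md$n, rois)
  # observed information over (theta, log sigma2)
  nll_full <- function(par) {
    th <- par[seq_along(theta)]
    ls <- par[-seq_along(theta)]
    A <- a_mat(th)
    dt <- det(diag(p) - A)
    if (!is.finite(dt) || abs(dt) < 1e-12) return(1e10)
    Rm <- resid_mat(th)
    -md$n * log(abs(dt)) +
      sum(md$n / 2 * ls + colSums(Rm^2) / (2 * exp(ls)))
  }
  par_hat <- c(theta, log(sigma2))
  H <- tryCatch(stats::optimHess(par_hat, nll_full), error = function(e) NULL)
  se <- rep(NA_real_, length(theta))
  ok <- FALSE
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)[seq_along(theta)]
      se <- ifelse(dv > 0, sqrt(dv), NA_real_)
      ok <- TRUE
    }
  }
  loglik <- -(nll(theta) + md$n * md$p / 2 * (log(2 * pi) + 1))
  list(beta = theta, se = se, sigma2 = sigma2, resid = R, loglik = loglik,
       converged = opt$convergence == 0 && ok)
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("euSEM fit: %d paths, n = %d, loglik = %.2f, converged = %s\n",
              nrow(x$edges), x$n, x$loglik, x$converged))
  print(x$edges[, c("type", "source", "target", "input", "level",
                    "beta", "se", "z", "p")])
  invisible(x)
}

#' Score tests (modification indices) for candidate paths
#'
#' One-degree-of-freedom Lagrange multiplier statistic for each absent
#' candidate edge: with e the fitted residual of the target equation and
#' x the candidate regressor orthogonalized against that equation's current
#' design, MI = n (e'x)^2 / (e'e x'x). The statistic is calibrated only for
#' candidates whose source series does not itself depend (contemporaneously,
#' possibly through other paths) on the target - for cycle-creating
#' candidates the source contains the target equation's own shock and the
#' plain score test is simultaneity-biased. [candidate_edges()] therefore
#' keeps the candidate universe recursive (acyclic) by default, which is
#' also what makes the search resolve path direction. A candidate whose
#' regressor is constant (e.g. an input with no onsets) gets MI = 0.
#' Significance is judged against the chi-square(1) critical value at
#' `alpha`, optionally Bonferroni-divided by the candidate count.
#'
#' @param fit a `model_fit`.
#' @param candidates edge data frame (e.g. [candidate_edges()]).
#' @param alpha significance level.
#' @param bonferroni divide alpha by the number of candidates.
#' @return candidates with columns mi, p, significant appended.
#' @export
modification_indices <- function(fit, candidates, alpha = 0.05,
                                 bonferroni = FALSE) {
  present <- edge_ids(fit$structure$edges)
  ids <- edge_ids(candidates)
  if (any(ids %in% present)) {
    stopf("candidate already present in structure: %s",
          ids[ids %in% present][1])
  }
  md <- fit$md
  n <- md$n
  mi <- numeric(nrow(candidates))
  for (r in unique(candidates$target)) {
    rows <- which(candidates$target == r)
    X <- vapply(rows, function(i)
      edge_regressor(md, candidates$type[i], candidates$source[i],
                     candidates$target[i], candidates$input[i]),
      numeric(n))
    XP <- qr.resid(fit$qr_list[[r]], X)
    sxx <- colSums(XP^2)
    e <- fit$resid[, r]
    see <- sum(e^2)
    vals <- if (see <= 0) numeric(length(rows)) else
      n * drop(crossprod(XP, e))^2 / (see * sxx)
    vals[sxx < 1e-12 * pmax(1, colSums(X^2))] <- 0
    mi[rows] <- vals
  }
  alpha_eff <- if (bonferroni) alpha / max(1, nrow(candidates)) else alpha
  out <- candidates
  out$mi <- mi
  out$p <- stats::pchisq(mi, df = 1, lower.tail = FALSE)
  out$significant <- mi > stats::qchisq(1 - alpha_eff, df = 1)
  out
}

#' Paths failing the significance check
#'
#' @param fit a converged `model_fit`.
#' @param alpha significance level.
#' @param exclude_ar keep autoregressive base paths out of the result
#'   (they are never pruned by the search).
#' @return the edge rows with two-sided p >= alpha.
#' @export
prune_check <- function(fit, alpha = 0.05, exclude_ar = TRUE) {
  e <- fit$edges
  bad <- !is.na(e$p) & e$p >= alpha
  if (exclude_ar) bad <- bad & e$type != "ar"
  e[bad, , drop = FALSE]
}
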