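# ---- balanced within-subject sums-of-squares machinery -----------------
# Y is a 4-d array (subject, interval, stimulus, response). Effect and
# error sums of squares come from inclusion-exclusion over marginal means,
# which is exact for complete balanced designs.

all_subsets <- function(D) {
  out <- list(integer(0))
  for (d in D) out <- c(out, lapply(out, function(s) c(s, d)))
  out
}

marg_mean <- function(Y, D) {
  if (length(D) == 0) return(mean(Y))
  apply(Y, sort(D), mean)
}

broadcast_dims <- function(mS, S, D, full_dim) {
  D <- sort(D)
  S <- sort(S)
  if (length(S) == 0) return(array(mS, full_dim[D]))
  rest <- setdiff(D, S)
  a <- array(mS, c(full_dim[S], full_dim[rest]))
  aperm(a, order(c(S, rest)))
}

effect_ss <- function(Y, D) {
  full_dim <- dim(Y)
  D <- sort(D)
  out <- array(0, if (length(D)) full_dim[D] else 1)
  for (S in all_subsets(D)) {
    sgn <- (-1)^(length(D) - length(S))
    out <- out + sgn * broadcast_dims(marg_mean(Y, S), S, D, full_dim)
  }
  prod(full_dim[setdiff(seq_along(full_dim), D)]) * sum(out^2)
}

orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C <- apply(C, 2, function(v) v / sqrt(sum(v^2)))
  t(C) # (k-1) x k, orthonormal mean-zero rows
}

# Greenhouse-Geisser epsilon for one within-subject effect. C is the
# orthonormal contrast matrix of the effect applied to the per-subject
# cell vector; eps = tr(CSC')^2 / (df * tr((CSC')^2)).
gg_epsilon <- function(cell_mat, C) {
  S <- stats::cov(cell_mat)
  M <- C %*% S %*% t(C)
  df <- nrow(C)
  tr <- sum(diag(M))
  denom <- df * sum(M^2)
  if (denom <= 0) return(1)
  min(1, tr^2 / denom)
}

#' Three-way repeated-measures ANOVA on transfer response rates
#'
#' Fully within-subject interval (pre/stim) x stimulus (CS1-CS5) x
#' response (R1/R2) ANOVA on the per-presentation response rates.
#' Each within effect is tested against its effect-by-subject interaction;
#' degrees of freedom are Greenhouse-Geisser corrected (the correction that
#' yields fractional dfs such as 1.67, 16.73 on this design), and effect
#' sizes are generalized eta squared,
#' SS_effect / (SS_effect + SS_subjects + sum of all error SS).
#'
#' @param table long data frame with columns subject, stimulus, interval,
#'   response, rate: one row per cell per subject (5 x 2 x 2 cells).
#' @return data frame with one row per effect: effect, df1, df2
#'   (uncorrected), eps (GG epsilon), df1_corr, df2_corr, F, p
#'   (GG-corrected), ges.
#' @export
rm_anova_3way <- function(table) {
  req <- c("subject", "stimulus", "interval", "response", "rate")
  if (!all(req %in% names(table))) {
    stopf("table must have columns %s", paste(req, collapse = ", "))
  }
  subjects <- unique(table$subject)
  n <- length(subjects)
  if (n < 2) stopf("need at least 2 subjects")
  lev <- list(interval = c("pre", "stim"),
              stimulus = paste0("CS", 1:5),
              response = c("R1", "R2"))
  Y <- array(NA_real_, c(n, 2, 5, 2))
  for (r in seq_len(nrow(table))) {
    i <- match(table$subject[r], subjects)
    a <- match(table$interval[r], lev$interval)
    b <- match(table$stimulus[r], lev$stimulus)
    c_ <- match(table$response[r], lev$response)
    if (anyNA(c(i, a, b, c_))) stopf("unknown factor level in row %d", r)
    Y[i, a, b, c_] <- table$rate[r]
  }
  if (anyNA(Y)) {
    miss <- which(is.na(Y), arr.ind = TRUE)
    stopf("incomplete design: %d missing cell(s), first at subject %s, %s, %s, %s",
          nrow(miss), subjects[miss[1, 1]], lev$interval[miss[1, 2]],
          lev$stimulus[miss[1, 3]], lev$response[miss[1, 4]])
  }

  effects <- list(interval = 2, stimulus = 3, response = 4,
                  `interval:stimulus` = c(2, 3),
                  `interval:response` = c(2, 4),
                  `stimulus:response` = c(3, 4),
                  `interval:stimulus:response` = c(2, 3, 4))
  k <- c(1, 2, 5, 2) # dim sizes incl. subject
  ss_subj <- effect_ss(Y, 1)
  ss_eff <- vapply(effects, function(D) effect_ss(Y, D), numeric(1))
  ss_err <- vapply(effects, function(D) effect_ss(Y, c(1, D)), numeric(1))

  # per-subject cell vectors ordered interval-slowest, response-fastest to
  # match the Kronecker ordering of the contrast matrices
  cell_mat <- t(apply(Y, 1, function(x) as.vector(aperm(x, c(3, 2, 1)))))
  ones <- function(kk) matrix(1 / sqrt(kk), 1, kk)
  base <- list(`2` = orthonormal_contrasts(2), `3` = orthonormal_contrasts(5),
               `4` = orthonormal_contrasts(2))
  onesm <- list(`2` = ones(2), `3` = ones(5), `4` = ones(2))

  rows <- lapply(names(effects), function(nm) {
    D <- effects[[nm]]
    df1 <- prod(k[D] - 1)
    df2 <- (n - 1) * df1
    tol <- 1e-12 * max(1, sum(Y^2))
    Fv <- if (ss_eff[nm] < tol && ss_err[nm] < tol) 0 else
      (ss_eff[nm] / df1) / (ss_err[nm] / df2)
    C <- Reduce(kronecker, lapply(c(2, 3, 4), function(d) {
      if (d %in% D) base[[as.character(d)]] else onesm[[as.character(d)]]
    }))
    eps <- if (df1 == 1) 1 else gg_epsilon(cell_mat, C)
    ges <- ss_eff[nm] / (ss_eff[nm] + ss_subj + sum(ss_err))
    data.frame(effect = nm, df1 = df1, df2 = df2, eps = eps,
               df1_corr = eps * df1, df2_corr = eps * df2, F = Fv,
               p = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
               ges = ges, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

paired_t_guarded <- function(x, y) {
  d <- x - y
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1, degenerate = FALSE))
    return(list(t = NA_real_, df = n - 1, p = NA_real_, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       degenerate = FALSE)
}

#' Default pairwise comparison family for the transfer probes
#'
#' Per conditioned stimulus: R1 pre vs stim, R2 pre vs stim, R1 vs R2
#' within pre, and R1 vs R2 within stim - 20 comparisons in all, corrected
#' as one Bonferroni family.
#'
#' @return data frame of comparisons usable by [pairwise_probes()].
#' @export
default_probe_family <- function() {
  rows <- list()
  for (cs in paste0("CS", 1:5)) {
    rows[[length(rows) + 1]] <- data.frame(
      stimulus = cs,
      interval1 = c("pre", "pre", "pre", "stim"),
      response1 = c("R1", "R2", "R1", "R1"),
      interval2 = c("stim", "stim", "pre", "stim"),
      response2 = c("R1", "R2", "R2", "R2"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Bonferroni-corrected pairwise probes of the transfer cell means
#'
#' Paired t tests between two cells of the within-subject design for each
#' comparison in the family; adjusted p = min(1, raw p x family size).
#'
#' @param table long response-rate table (as for [rm_anova_3way()]),
#'   stacked across subjects.
#' @param family comparison data frame (see [default_probe_family()]).
#' @param alpha significance level applied to adjusted p values.
#' @return data frame with one row per comparison: the two cells, t, df,
#'   p, p_adj, significant, degenerate.
#' @export
pairwise_probes <- function(table, family = default_probe_family(),
                            alpha = 0.05) {
  key <- with(family, paste(stimulus, interval1, response1, interval2, response2))
  if (anyDuplicated(key)) stopf("duplicate comparisons in the family")
  subjects <- unique(table$subject)
  cell <- function(stim, int, resp) {
    v <- numeric(length(subjects))
    for (i in seq_along(subjects)) {
      k <- table$subject == subjects[i] & table$stimulus == stim &
        table$interval == int & table$response == resp
      if (sum(k) != 1) stopf("cell (%s, %s, %s) not unique for subject %s",
                             stim, int, resp, subjects[i])
      v[i] <- table$rate[k]
    }
    v
  }
  m <- nrow(family)
  rows <- lapply(seq_len(m), function(j) {
    f <- family[j, ]
    res <- paired_t_guarded(cell(f$stimulus, f$interval1, f$response1),
                            cell(f$stimulus, f$interval2, f$response2))
    p_adj <- if (is.na(res$p)) NA_real_ else min(1, res$p * m)
    cbind(f, data.frame(t = res$t, df = res$df, p = res$p, p_adj = p_adj,
                        significant = !is.na(p_adj) && p_adj < alpha,
                        degenerate = res$degenerate))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
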