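#' Ground-truth euSEM generating network
#'
#' Encodes the data-generating process
#' \deqn{y_t = A y_t + \Phi y_{t-1} + \Gamma u_t + (T u_t) y_t + \zeta_t}
#' over `p` ROIs and `q` task inputs: `A` holds contemporaneous weights
#' (zero diagonal), `Phi` lag-1 weights (its diagonal is the autoregressive
#' paths), `Gamma` direct effects of the HRF-convolved inputs, and `Tau` the
#' bilinear (input-modulated) weights, dimension target x input x source.
#' `zeta` is white Gaussian noise with per-ROI standard deviation
#' `noise_sd`.
#'
#' @param A p x p contemporaneous weight matrix, zero diagonal.
#' @param Phi p x p lag-1 weight matrix.
#' @param Gamma p x q direct-input weight matrix (NULL for no inputs).
#' @param Tau p x q x p bilinear weight array (target, input, source).
#' @param noise_sd scalar or length-p dynamic-noise standard deviation.
#' @param roi_names,input_names variable names.
#' @param hrf_params data frame with columns `peak_delay`, `dispersion`
#'   (seconds), one row per subject; recycled when more subjects are
#'   simulated than rows provided.
#' @return an object of class `true_network`.
#' @export
true_network <- function(A, Phi, Gamma = NULL, Tau = NULL, noise_sd = 1,
                         roi_names = NULL, input_names = NULL,
                         hrf_params = NULL) {
  p <- nrow(A)
  if (!all(dim(A) == c(p, p)) || !all(dim(Phi) == c(p, p))) {
    stopf("A and Phi must both be p x p")
  }
  if (any(diag(A) != 0)) stopf("A must have a zero diagonal")
  if (is.null(Gamma)) Gamma <- matrix(0, p, 0)
  q <- ncol(Gamma)
  if (nrow(Gamma) != p) stopf("Gamma must have p rows")
  if (is.null(Tau)) Tau <- array(0, c(p, q, p))
  if (!all(dim(Tau) == c(p, q, p))) stopf("Tau must be p x q x p")
  noise_sd <- rep_len(noise_sd, p)
  if (any(noise_sd <= 0)) stopf("noise_sd must be positive")
  IA <- diag(p) - A
  if (abs(det(IA)) < 1e-10) stopf("(I - A) must be invertible")
  rho <- max(Mod(eigen(solve(IA, Phi), only.values = TRUE)$values))
  if (rho >= 1) {
    stopf("non-stationary network: spectral radius of (I-A)^-1 Phi is %.3f", rho)
  }
  roi_names <- roi_names %||% roi_default_names(p)
  input_names <- input_names %||% (if (q == 2) c("specific", "general") else
    if (q > 0) paste0("u", seq_len(q)) else character(0))
  dimnames(A) <- dimnames(Phi) <- list(roi_names, roi_names)
  dimnames(Gamma) <- list(roi_names, input_names)
  dimnames(Tau) <- list(roi_names, input_names, roi_names)
  if (is.null(hrf_params)) {
    hrf_params <- data.frame(peak_delay = 6, dispersion = 1)
  }
  structure(list(A = A, Phi = Phi, Gamma = Gamma, Tau = Tau,
                 noise_sd = noise_sd, roi_names = roi_names,
                 input_names = input_names, hrf_params = hrf_params),
            class = "true_network")
}

#' Named ground-truth network presets
#'
#' * `"benchmark"`: 5 nodes, the 5 autoregressive paths at 0.5 plus 4
#'   non-autoregressive paths (two contemporaneous at 0.6/0.55, two lagged
#'   at 0.5/0.6), unit noise, no task inputs. Used for the desk-scale
#'   precision/recall benchmark.
#' * `"pit_study"`: the 5 PIT ROIs with 4 contemporaneous paths from
#'   bilateral putamen into bilateral insula / right cingulate, one lagged
#'   path left insula -> right cingulate, and a direct effect of the
#'   specific-PIT input on the left putamen; subject HRF peak delays spread
#'   over 4.5-7.5 s.
#'
#' @param name preset name.
#' @param n_subjects number of subjects the preset should carry HRF
#'   parameters for.
#' @return a [true_network()].
#' @export
network_preset <- function(name = c("benchmark", "pit_study"),
                           n_subjects = 11) {
  name <- match.arg(name)
  if (name == "benchmark") {
    p <- 5
    A <- matrix(0, p, p)
    Phi <- diag(0.5, p)
    A[2, 1] <- 0.6   # node1 -> node2, contemporaneous
    A[4, 3] <- 0.55  # node3 -> node4, contemporaneous
    Phi[3, 1] <- 0.5 # node1 -> node3, lagged
    Phi[5, 4] <- 0.6 # node4 -> node5, lagged
    return(true_network(A, Phi, noise_sd = 1,
                        roi_names = paste0("roi", 1:5)))
  }
  p <- 5
  rois <- roi_default_names(5)
  A <- matrix(0, p, p, dimnames = list(rois, rois))
  Phi <- diag(0.5, p)
  dimnames(Phi) <- list(rois, rois)
  A["insula_R", "putamen_L"] <- 0.45
  A["cingulate_R", "putamen_R"] <- 0.45
  A["insula_L", "putamen_L"] <- 0.40
  A["insula_R", "putamen_R"] <- 0.35
  Phi["cingulate_R", "insula_L"] <- 0.35
  Gamma <- matrix(0, p, 2, dimnames = list(rois, c("specific", "general")))
  Gamma["putamen_L", "specific"] <- 0.5
  hrf <- data.frame(peak_delay = seq(4.5, 7.5, length.out = n_subjects),
                    dispersion = rep_len(c(0.9, 1, 1.1), n_subjects))
  true_network(A, Phi, Gamma, noise_sd = 1, roi_names = rois,
               hrf_params = hrf)
}

#' Serialize / deserialize a ground-truth network as JSON
#'
#' @param truth a [true_network()].
#' @param path file path.
#' @return `read_true_network` returns the network; `write_true_network`
#'   returns `path` invisibly.
#' @export
write_true_network <- function(truth, path) {
  obj <- list(A = truth$A, Phi = truth$Phi, Gamma = truth$Gamma,
              Tau = as.vector(truth$Tau), tau_dim = dim(truth$Tau),
              noise_sd = truth$noise_sd, roi_names = truth$roi_names,
              input_names = truth$input_names, hrf_params = truth$hrf_params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_true_network
#' @export
read_true_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  q <- length(obj$input_names)
  p <- length(obj$roi_names)
  true_network(matrix(unlist(obj$A), p, p), matrix(unlist(obj$Phi), p, p),
               Gamma = if (q > 0) matrix(unlist(obj$Gamma), p, q) else NULL,
               Tau = array(unlist(obj$Tau) %||% numeric(0),
                           unlist(obj$tau_dim)),
               noise_sd = obj$noise_sd, roi_names = obj$roi_names,
               input_names = as.character(obj$input_names),
               hrf_params = as.data.frame(obj$hrf_params))
}

# non-autoregressive true edge set as an edge data frame (see structures)
true_edge_table <- function(truth) {
  rois <- truth$roi_names
  ins <- truth$input_names
  rows <- list()
  idx <- which(truth$A != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    rows[[length(rows) + 1]] <- data.frame(
      type = "contemporaneous", source = rois[idx[i, 2]],
      target = rois[idx[i, 1]], input = NA_character_,
      beta = truth$A[idx[i, 1], idx[i, 2]], stringsAsFactors = FALSE)
  }
  Phi_off <- truth$Phi
  diag(Phi_off) <- 0
  idx <- which(Phi_off != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    rows[[length(rows) + 1]] <- data.frame(
      type = "lagged", source = rois[idx[i, 2]], target = rois[idx[i, 1]],
      input = NA_character_, beta = Phi_off[idx[i, 1], idx[i, 2]],
      stringsAsFactors = FALSE)
  }
  idx <- which(truth$Gamma != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    rows[[length(rows) + 1]] <- data.frame(
      type = "direct", source = ins[idx[i, 2]], target = rois[idx[i, 1]],
      input = NA_character_, beta = truth$Gamma[idx[i, 1], idx[i, 2]],
      stringsAsFactors = FALSE)
  }
  if (length(ins) > 0) {
    for (j in seq_along(ins)) {
      idx <- which(truth$Tau[, j, , drop = FALSE] != 0, arr.ind = TRUE)
      for (i in seq_len(nrow(idx))) {
        rows[[length(rows) + 1]] <- data.frame(
          type = "bilinear", source = rois[idx[i, 3]],
          target = rois[idx[i, 1]], input = ins[j],
          beta = truth$Tau[idx[i, 1], j, idx[i, 3]], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(type = character(0), source = character(0),
                      target = character(0), input = character(0),
                      beta = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
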