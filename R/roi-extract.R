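#' Regions of interest for the PIT connectivity analysis
#'
#' The five corticostriatal ROIs (bilateral putamen, bilateral insula,
#' right cingulate) with their MNI-mm centers, and the default 10-mm
#' diameter (5-mm radius) sphere used for mask extraction.
#'
#' @param radius_mm sphere radius in mm. The masks are described in the
#'   field both by diameter and by radius; `diameter_convention = TRUE`
#'   halves nothing and treats `radius_mm` as a diameter instead.
#' @param diameter_convention interpret `radius_mm` as a diameter.
#' @return data frame with columns name, hemisphere, x, y, z, radius_mm.
#' @export
roi_table <- function(radius_mm = 5, diameter_convention = FALSE) {
  r <- if (diameter_convention) radius_mm / 2 else radius_mm
  data.frame(
    name = roi_default_names(5),
    hemisphere = c("L", "R", "L", "R", "R"),
    x = c(-23, 18, -42, 37, 2),
    y = c(7, 10, 6, 4, 11),
    z = c(4, 0, 0, 3, 46),
    radius_mm = r,
    stringsAsFactors = FALSE)
}

roi_spec_row <- function(roi_specs, k) {
  list(name = roi_specs$name[k],
       center_mni = c(roi_specs$x[k], roi_specs$y[k], roi_specs$z[k]),
       radius_mm = roi_specs$radius_mm[k])
}

#' Regular voxel grid specification
#'
#' @param dim length-3 voxel counts.
#' @param voxel_mm length-3 voxel sizes in mm.
#' @param origin_mni MNI-mm coordinate of voxel (0, 0, 0).
#' @return list with `dim` and a 4 x 4 `affine` (0-based voxel index ->
#'   MNI mm).
#' @export
grid_spec <- function(dim, voxel_mm = c(1, 1, 1), origin_mni = c(0, 0, 0)) {
  affine <- diag(4)
  diag(affine)[1:3] <- voxel_mm
  affine[1:3, 4] <- origin_mni
  list(dim = dim, affine = affine)
}

#' Voxels within a sphere around an MNI-mm center
#'
#' A voxel is included iff the Euclidean distance from its center to the
#' sphere center is at most the radius (boundary ties included). Returns
#' 1-based voxel indices into the grid.
#'
#' @param spec list with `center_mni` (length-3 mm) and `radius_mm`; rows of
#'   [roi_table()] can be converted via their x/y/z columns.
#' @param grid a [grid_spec()].
#' @return integer matrix, one row per voxel, columns i, j, k (1-based).
#' @export
sphere_mask <- function(spec, grid) {
  aff <- grid$affine
  center <- spec$center_mni
  r <- spec$radius_mm
  # invert affine to find the voxel-space bounding box of the sphere
  inv <- solve(aff)
  cvox <- (inv %*% c(center, 1))[1:3]
  vox_mm <- sqrt(colSums(aff[1:3, 1:3]^2))
  lo <- floor(cvox - r / vox_mm - 1)
  hi <- ceiling(cvox + r / vox_mm + 1)
  lo_c <- pmax(lo, 0)
  hi_c <- pmin(hi, grid$dim - 1)
  if (any(lo_c > hi_c)) stopf("empty mask: sphere entirely outside the grid")
  if (any(cvox - r / vox_mm < 0 | cvox + r / vox_mm > grid$dim - 1)) {
    warning(sprintf("sphere '%s' extends outside the grid; mask truncated",
                    spec$name %||% "roi"), call. = FALSE)
  }
  g <- expand.grid(i = lo_c[1]:hi_c[1], j = lo_c[2]:hi_c[2], k = lo_c[3]:hi_c[3])
  mm <- t(aff[1:3, 1:3] %*% t(as.matrix(g)) + aff[1:3, 4])
  d2 <- rowSums(sweep(mm, 2, center)^2)
  keep <- d2 <= r^2 + 1e-9
  if (!any(keep)) {
    stopf("empty mask: radius %.2f mm captures no voxel center near (%g, %g, %g)",
          r, center[1], center[2], center[3])
  }
  m <- as.matrix(g[keep, , drop = FALSE]) + 1L
  storage.mode(m) <- "integer"
  colnames(m) <- c("i", "j", "k")
  rownames(m) <- NULL
  m
}

#' Mean time series over a voxel mask
#'
#' @param volume list with `data` (4D array) as from [make_voxel_volume()]
#'   or [read_volume()].
#' @param mask integer matrix of 1-based voxel indices from [sphere_mask()].
#' @return numeric vector of length T (unweighted mean across mask voxels
#'   per TR).
#' @export
mean_timeseries <- function(volume, mask) {
  if (nrow(mask) == 0) stopf("empty mask")
  d <- dim(volume$data)
  bad <- mask[, 1] < 1 | mask[, 1] > d[1] | mask[, 2] < 1 | mask[, 2] > d[2] |
    mask[, 3] < 1 | mask[, 3] > d[3]
  if (any(bad)) {
    v <- mask[which(bad)[1], ]
    stopf("mask voxel (%d, %d, %d) lies outside the volume", v[1], v[2], v[3])
  }
  out <- matrix(0, d[4], nrow(mask))
  for (v in seq_len(nrow(mask))) {
    out[, v] <- volume$data[mask[v, 1], mask[v, 2], mask[v, 3], ]
  }
  rowMeans(out)
}

#' Write / read a 4D volume as NIfTI-1
#'
#' @param volume list with `data` and `affine`.
#' @param path file path (.nii or .nii.gz).
#' @return `read_volume` returns a list with `data` and `affine`.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::sform(img) <- structure(volume$affine, code = 4L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       affine = unclass(RNifti::xform(img)))
}

#' Binary PIT input vectors from a transfer schedule
#'
#' Marks the TR bin containing each qualifying stimulus onset: CS1 and CS2
#' onsets feed the `specific` vector, CS3 onsets the `general` vector;
#' CS4/CS5 contribute to neither. An onset at `t` seconds lands in 0-based
#' bin `floor(t / tr_s)`.
#'
#' @param schedule a transfer-phase event schedule.
#' @param tr_s TR, seconds.
#' @param n_trs series length, TRs.
#' @return T x 2 matrix with columns `specific`, `general`.
#' @export
build_inputs <- function(schedule, tr_s, n_trs) {
  if (nrow(schedule) > 0 && any(schedule$phase != "transfer")) {
    stopf("build_inputs needs a transfer-phase schedule")
  }
  ons <- schedule_input_onsets(schedule)
  mark <- function(o) {
    if (any(o >= n_trs * tr_s)) {
      stopf("onset at %.1f s exceeds the series span of %g s",
            max(o), n_trs * tr_s)
    }
    v <- numeric(n_trs)
    v[floor(o / tr_s) + 1] <- 1
    v
  }
  cbind(specific = mark(ons$specific), general = mark(ons$general))
}

#' Assemble the per-subject analysis matrix
#'
#' Fixed column order: left putamen, right putamen, left insula, right
#' insula, right cingulate, then the `specific` and `general` input
#' columns.
#'
#' @param roi_series list of 5 equal-length numeric vectors (order above) or
#'   a T x 5 matrix.
#' @param inputs T x 2 matrix from [build_inputs()].
#' @param tr_s TR, seconds.
#' @param subject_id subject label.
#' @return a `subject_matrix`.
#' @export
assemble_matrix <- function(roi_series, inputs, tr_s = 2, subject_id = "s1") {
  y <- if (is.list(roi_series)) do.call(cbind, roi_series) else as.matrix(roi_series)
  if (nrow(y) == 0) stopf("empty matrix: zero time points")
  if (nrow(y) != nrow(inputs)) stopf("ROI series and inputs differ in length")
  if (anyNA(y) || anyNA(inputs)) stopf("missing values in assembled matrix")
  if (any(inputs < 0)) stopf("input columns must be non-negative")
  mat <- cbind(y, inputs)
  colnames(mat) <- c(roi_default_names(ncol(y)), colnames(inputs))
  new_subject_matrix(mat, tr_s, subject_id)
}

#' Write / read a subject matrix as TSV
#'
#' One row per TR; five ROI columns plus the two input columns.
#'
#' @param mat a `subject_matrix`.
#' @param path file path.
#' @param tr_s,subject_id metadata restored on read.
#' @return `read_subject_matrix` returns a `subject_matrix`.
#' @export
write_subject_matrix <- function(mat, path) {
  utils::write.table(as.data.frame(unclass(mat)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_matrix
#' @export
read_subject_matrix <- function(path, tr_s = 2, subject_id = "s1") {
  df <- utils::read.delim(path)
  new_subject_matrix(as.matrix(df), tr_s, subject_id)
}
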