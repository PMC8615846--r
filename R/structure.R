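edge_frame <- function(type = character(0), source = character(0),
                       target = character(0), input = character(0),
                       level = character(0)) {
  data.frame(type = type, source = source, target = target,
             input = input, level = level, stringsAsFactors = FALSE)
}

edge_ids <- function(edges) {
  ifelse(edges$type == "bilinear",
         paste0(edges$type, ":", edges$source, "*", edges$input, "->", edges$target),
         paste0(edges$type, ":", edges$source, "->", edges$target))
}

#' euSEM path structure
#'
#' The free-path set of an extended unified SEM over `p` ROIs and `q` task
#' inputs. Edge types: `ar` (the lag-1 autoregressive path of each ROI -
#' the null-model base, always present), `contemporaneous` (A, no
#' self-loops), `lagged` (off-diagonal Phi), `direct` (input -> ROI, Gamma)
#' and `bilinear` (input x source-ROI -> target-ROI, Tau). Each edge is
#' flagged `group` or `individual`.
#'
#' @param roi_names ROI names.
#' @param input_names task input names.
#' @param edges optional edge data frame (type, source, target, input,
#'   level) appended to the autoregressive base.
#' @param include_ar include the p autoregressive base paths (default).
#' @return object of class `network_structure`.
#' @export
network_structure <- function(roi_names, input_names = character(0),
                              edges = NULL, include_ar = TRUE) {
  base <- if (include_ar) {
    edge_frame(type = rep("ar", length(roi_names)), source = roi_names,
               target = roi_names, input = rep(NA_character_, length(roi_names)),
               level = rep("group", length(roi_names)))
  } else edge_frame()
  s <- structure(list(roi_names = roi_names, input_names = input_names,
                      edges = base),
                 class = "network_structure")
  if (!is.null(edges)) {
    for (i in seq_len(nrow(edges))) {
      s <- add_edge(s, edges$type[i], edges$source[i], edges$target[i],
                    input = if ("input" %in% names(edges)) edges$input[i] else NA,
                    level = if ("level" %in% names(edges)) edges$level[i] else "group")
    }
  }
  s
}

validate_edge <- function(structure, type, source, target, input) {
  rois <- structure$roi_names
  if (!target %in% rois) stopf("unknown target ROI '%s'", target)
  if (type %in% c("ar", "contemporaneous", "lagged", "bilinear") &&
      !source %in% rois) stopf("unknown source ROI '%s'", source)
  if (type == "direct" && !source %in% structure$input_names) {
    stopf("unknown input '%s' for direct edge", source)
  }
  if (type == "bilinear" && !input %in% structure$input_names) {
    stopf("unknown input '%s' for bilinear edge", input)
  }
  if (type == "contemporaneous" && source == target) {
    stopf("self-contemporaneous edge %s -> %s forbidden", source, target)
  }
  if (type == "bilinear" && source == target) {
    stopf("bilinear self-modulation %s -> %s not supported", source, target)
  }
  if (type == "ar" && source != target) stopf("ar edges are self-loops")
  invisible(TRUE)
}

#' Add or remove an edge
#'
#' @param structure a [network_structure()].
#' @param type one of ar, contemporaneous, lagged, direct, bilinear.
#' @param source source ROI (or input name, for direct edges).
#' @param target target ROI.
#' @param input modulating input (bilinear edges only).
#' @param level "group" or "individual".
#' @return the modified structure.
#' @export
add_edge <- function(structure, type, source, target, input = NA,
                     level = "group") {
  validate_edge(structure, type, source, target, input)
  new <- edge_frame(type, source, target, as.character(input), level)
  if (edge_ids(new) %in% edge_ids(structure$edges)) {
    stopf("edge %s already present", edge_ids(new))
  }
  structure$edges <- rbind(structure$edges, new)
  structure
}

#' @rdname add_edge
#' @param id edge id string as produced internally
#'   (`type:source->target` / `type:source*input->target`).
#' @export
remove_edge <- function(structure, id) {
  keep <- edge_ids(structure$edges) != id
  if (all(keep)) stopf("edge %s not present", id)
  structure$edges <- structure$edges[keep, , drop = FALSE]
  structure
}

#' @export
print.network_structure <- function(x, ...) {
  cat(sprintf("euSEM structure: %d ROIs, %d inputs, %d edges\n",
              length(x$roi_names), length(x$input_names), nrow(x$edges)))
  tab <- table(x$edges$type, x$edges$level)
  print(tab)
  invisible(x)
}

# contemporaneous dependency graph (A edges plus bilinear source -> target);
# returns TRUE when acyclic, with a topological order attribute
contemporaneous_acyclic <- function(structure) {
  rois <- structure$roi_names
  e <- structure$edges
  dep <- e[e$type %in% c("contemporaneous", "bilinear"), c("source", "target")]
  adj <- lapply(stats::setNames(rois, rois), function(r)
    unique(dep$target[dep$source == r]))
  indeg <- stats::setNames(numeric(length(rois)), rois)
  for (t in dep$target) indeg[t] <- indeg[t] + 1
  order <- character(0)
  queue <- names(indeg)[indeg == 0]
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in adj[[v]]) {
      indeg2[w] <- indeg2[w] - 1
      if (indeg2[w] == 0) queue <- c(queue, w)
    }
  }
  ok <- length(order) == length(rois)
  res <- ok
  attr(res, "order") <- order
  attr(res, "cycle") <- if (!ok) setdiff(rois, order) else character(0)
  res
}

#' Candidate edges absent from a structure
#'
#' The search universe: all absent contemporaneous and lagged ROI-pair
#' edges, direct edges input -> ROI, and bilinear edges
#' input x source -> target, filtered by the enabled classes. By default
#' candidates that would put a cycle into the contemporaneous dependency
#' graph (including the reverse of an existing contemporaneous path) are
#' excluded: the search explores recursive structures, where the score
#' tests of [modification_indices()] are calibrated and path direction is
#' resolved.
#'
#' @param structure a [network_structure()].
#' @param classes character subset of
#'   c("contemporaneous", "lagged", "direct", "bilinear").
#' @param acyclic_only drop cycle-creating contemporaneous/bilinear
#'   candidates.
#' @return edge data frame (level unset).
#' @export
candidate_edges <- function(structure,
                            classes = c("contemporaneous", "lagged",
                                        "direct", "bilinear"),
                            acyclic_only = TRUE) {
  rois <- structure$roi_names
  ins <- structure$input_names
  cand <- list()
  pairs <- expand.grid(source = rois, target = rois, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  if ("contemporaneous" %in% classes) {
    cand$con <- edge_frame("contemporaneous", pairs$source, pairs$target,
                           NA_character_, "candidate")
  }
  if ("lagged" %in% classes) {
    cand$lag <- edge_frame("lagged", pairs$source, pairs$target,
                           NA_character_, "candidate")
  }
  if ("direct" %in% classes && length(ins)) {
    g <- expand.grid(source = ins, target = rois, stringsAsFactors = FALSE)
    cand$dir <- edge_frame("direct", g$source, g$target, NA_character_,
                           "candidate")
  }
  if ("bilinear" %in% classes && length(ins)) {
    g <- expand.grid(input = ins, source = rois, target = rois,
                     stringsAsFactors = FALSE)
    g <- g[g$source != g$target, ]
    cand$bil <- edge_frame("bilinear", g$source, g$target, g$input,
                           "candidate")
  }
  out <- do.call(rbind, cand)
  if (is.null(out)) return(edge_frame())
  out <- out[!edge_ids(out) %in% edge_ids(structure$edges), , drop = FALSE]
  if (acyclic_only && nrow(out)) {
    reach <- contemporaneous_reachability(structure)
    endo <- out$type %in% c("contemporaneous", "bilinear")
    cyclic <- endo & reach[cbind(match(out$target, rois),
                                 match(out$source, rois))]
    out <- out[!cyclic, , drop = FALSE]
  }
  out <- out[order(edge_ids(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# boolean reachability over the contemporaneous dependency graph
# (A edges plus bilinear source -> target); reach[i, j] is TRUE when roi_i
# reaches roi_j through one or more edges
contemporaneous_reachability <- function(structure) {
  rois <- structure$roi_names
  p <- length(rois)
  e <- structure$edges
  dep <- e[e$type %in% c("contemporaneous", "bilinear"), , drop = FALSE]
  R <- matrix(FALSE, p, p, dimnames = list(rois, rois))
  R[cbind(match(dep$source, rois), match(dep$target, rois))] <- TRUE
  for (k in seq_len(p)) R <- R | (R[, k] %o% R[k, ])
  R
}
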