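#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Folds the master seed and any number of string/integer tags into a single
#' 31-bit integer. Each (subject, stage) pair gets its own stream, so adding
#' subjects or stages never perturbs the draws of earlier ones.
#'
#' @param master integer master seed.
#' @param ... character or integer tags (e.g. subject id, stage name).
#' @return an integer in [0, 2^31 - 1), usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  parts <- unlist(list(...), use.names = FALSE)
  h <- as.double(master) %% 2147483647
  for (p in parts) {
    codes <- if (is.character(p)) utf8ToInt(p) else as.integer(p)
    for (k in codes) h <- (h * 31 + as.double(k)) %% 2147483647
  }
  as.integer(h)
}

# cheap deterministic fingerprint of an R object (provenance only, not crypto)
fold_fingerprint <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  h <- 0
  for (k in utf8ToInt(txt)) h <- (h * 131 + k) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Write / read a tab-separated event table (BIDS events dialect)
#'
#' Columns `onset`, `duration`, `trial_type` (plus `phase` when present);
#' onsets in seconds, 0-based from run start.
#'
#' @param schedule an event schedule data frame.
#' @param path file path.
#' @return `read_events` returns the data frame; `write_events` returns
#'   `path` invisibly.
#' @export
write_events <- function(schedule, path) {
  utils::write.table(schedule, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
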