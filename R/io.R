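#' Write / read a frame stack container
#'
#' Serializes a frame stack (and optionally its ground truth) to the
#' package's single-file container: a `frames` dataset with `fps`/`t0`
#' attributes and an optional `truth` group. Reading validates the schema
#' and names any missing field.
#'
#' @param stack A `frame_stack`.
#' @param path Output file path.
#' @param truth Optional `ground_truth` stored alongside the frames.
#' @return `write_frames()` returns `path` invisibly; `read_frames()`
#'   returns a list with `stack` and (possibly NULL) `truth`.
#' @export
write_frames <- function(stack, path, truth = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  obj <- list(frames = stack$counts, fps = stack$fps, t0 = stack$t0,
              truth = truth)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  obj <- readRDS(path)
  for (field in c("frames", "fps", "t0")) {
    if (is.null(obj[[field]]))
      stop("frame container schema error: missing field '", field, "'")
  }
  if (length(dim(obj$frames)) != 3L)
    stop("frame container schema error: 'frames' is not a 3D array")
  stack <- structure(list(counts = obj$frames, fps = obj$fps, t0 = obj$t0),
                     class = "frame_stack")
  list(stack = stack, truth = obj$truth)
}

#' Write an extracted pulse signal to CSV
#'
#' Columns: `t_seconds`, `raw_signal`, `mask_pixels`, `held_flag`.
#'
#' @param sig A `pulse_signal` from [extract_pulse_signal()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(sig, path) {
  stopifnot(inherits(sig, "pulse_signal"))
  df <- data.frame(t_seconds = sig$t, raw_signal = sig$samples,
                   mask_pixels = sig$mask_pixels,
                   held_flag = as.integer(sig$held))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  for (field in c("t_seconds", "raw_signal", "mask_pixels", "held_flag")) {
    if (is.null(df[[field]]))
      stop("signal CSV schema error: missing column '", field, "'")
  }
  structure(list(samples = df$raw_signal, t = df$t_seconds,
                 fs = 1 / stats::median(diff(df$t_seconds)),
                 mask_pixels = df$mask_pixels,
                 held = as.logical(df$held_flag),
                 capacity = length(df$raw_signal)),
            class = "pulse_signal")
}
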