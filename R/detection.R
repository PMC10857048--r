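#' Mean raw-frame temperature (A1)
#'
#' The detector's first statistic: the arithmetic mean of the 64 raw
#' pixel temperatures, \eqn{A_1 = \sum_n pt(n) / px} with \eqn{px = 64}.
#'
#' @param frame a [thermal_frame()].
#' @return Mean pixel temperature in degrees Celsius.
#' @export
average_raw <- function(frame) {
  stopifnot(inherits(frame, "thermal_frame"))
  mean(frame$pixels)
}

#' Difference factor (df)
#'
#' Ratio of mean frame temperature to ambient temperature,
#' \eqn{df = A_1 / t}. Its trend over successive frames encodes motion:
#' a warm body entering the field of view raises the frame mean relative
#' to the unchanged ambient reading, so df rises on approach and falls
#' on recession.
#'
#' @param a1 mean raw-frame temperature in degrees Celsius.
#' @param t ambient (thermistor) temperature in degrees Celsius; must be
#'   non-zero. The ratio is undefined at 0 degrees C, consistent with the
#'   sensor's loss of discrimination near freezing.
#' @return The dimensionless difference factor.
#' @export
difference_factor <- function(a1, t) {
  if (t == 0) {
    stop("ambient temperature is 0 degrees C: difference factor undefined",
         call. = FALSE)
  }
  a1 / t
}

#' Normalized mean of the interpolated grid (A2)
#'
#' The detector's second statistic, computed from the bilinearly
#' upsampled silhouette map. Two normalizations are provided:
#'
#' * `"alg1"` (canonical): \eqn{A_2 = (\sum z) / \mathrm{side} \cdot df},
#'   the grid's total divided by its row count (`8 * ipf`), scaled by the
#'   difference factor. Equivalently `side * mean(grid) * df`. Under this
#'   form the posture rule `A2 > px * t * df` reduces to a df-free
#'   threshold on the interpolated mean (see [classify_posture()]).
#' * `"eq6"`: \eqn{A_2 = (\sum z) / (px \cdot ipf)}, i.e.
#'   `ipf * mean(grid)` for an 8x8 source. Retained for reference; with
#'   this normalization the standing condition is unreachable for
#'   realistic indoor temperatures, so it is not the default.
#'
#' @param grid interpolated grid from [bilinear_interpolate()] on an 8x8
#'   source.
#' @param df difference factor from [difference_factor()].
#' @param mode `"alg1"` (default) or `"eq6"`.
#' @param ipf interpolation factor used to produce `grid`; taken from the
#'   grid's `ipf` attribute when omitted.
#' @return The A2 statistic.
#' @export
average_interpolated <- function(grid, df, mode = c("alg1", "eq6"),
                                 ipf = attr(grid, "ipf")) {
  mode <- match.arg(mode)
  if (is.null(ipf)) stop("'ipf' is required when the grid carries no attribute",
                         call. = FALSE)
  ipf <- check_ipf(ipf)
  switch(mode,
    alg1 = sum(grid) / nrow(grid) * df,
    eq6  = sum(grid) / (64 * ipf)
  )
}

#' Posture decision rule
#'
#' Standing if and only if \eqn{A_2 > px \cdot t \cdot df}; otherwise
#' sitting. The tie (exact equality) falls to sitting, since only the
#' strict inequalities are defined. With the canonical `"alg1"` A2 the
#' df factors cancel and the rule is equivalent to
#' `mean(interpolated grid) > (px / (8 * ipf)) * t`
#' (e.g. mean above `0.8 * t` at `ipf = 10`).
#'
#' @param a2 the A2 statistic.
#' @param t ambient temperature in degrees Celsius.
#' @param px number of raw pixels (64 for the 8x8 sensor).
#' @param df difference factor.
#' @return `"standing"` or `"sitting"`.
#' @export
classify_posture <- function(a2, t, px = 64, df) {
  stopifnot(is.finite(a2), is.finite(t), is.finite(df))
  if (a2 > px * t * df) "standing" else "sitting"
}

#' Motion decision rule
#'
#' Compares the current difference factor with the previous one:
#' approaching if it increased by more than `epsilon`, receding
#' otherwise; `"unknown"` when no previous value exists (first frame).
#' The default `epsilon = 0` reproduces the strict comparison of the
#' real-time loop, under which an unchanged df labels as receding; a
#' positive `epsilon` adds hysteresis against noise-driven flapping.
#'
#' @param previous_df previous difference factor, or `NA` before the
#'   first processed frame.
#' @param df_current current difference factor.
#' @param epsilon non-negative hysteresis threshold on the df increase.
#' @return `"approaching"`, `"receding"` or `"unknown"`.
#' @export
classify_motion <- function(previous_df, df_current, epsilon = 0) {
  stopifnot(epsilon >= 0)
  if (is.null(previous_df) || is.na(previous_df)) return("unknown")
  if (df_current > previous_df + epsilon) "approaching" else "receding"
}

#' Create a detector state
#'
#' Running state for the frame-by-frame detector: the previous difference
#' factor (unset before the first frame) plus configuration.
#'
#' @param ipf interpolation factor (default 10, the factor found optimal
#'   for real-time operation).
#' @param a2_mode A2 normalization, `"alg1"` (canonical) or `"eq6"`.
#' @param epsilon motion hysteresis (default 0, strict comparison).
#' @param sample_period nominal sampling period in seconds (default
#'   0.625); informational — the detector itself is timestamp-agnostic.
#' @return An object of class `detector_state`.
#' @seealso [detect_step()], [detect_frames()]
#' @export
detector_state <- function(ipf = 10, a2_mode = c("alg1", "eq6"),
                           epsilon = 0, sample_period = 0.625) {
  structure(
    list(previous_df = NA_real_, ipf = check_ipf(ipf),
         a2_mode = match.arg(a2_mode), epsilon = epsilon,
         sample_period = sample_period),
    class = "detector_state"
  )
}

#' @export
print.detector_state <- function(x, ...) {
  cat("<detector_state> ipf ", x$ipf, ", mode ", x$a2_mode,
      ", epsilon ", format(x$epsilon),
      if (is.na(x$previous_df)) ", no frame seen yet"
      else paste0(", previous df ", format(x$previous_df)), "\n", sep = "")
  invisible(x)
}

#' One detector step
#'
#' Processes a single thermal frame through the full closed-form
#' pipeline: raw mean (A1), difference factor (df), bilinear upsampling,
#' normalized interpolated mean (A2), then the posture and motion
#' decision rules. Deterministic given inputs.
#'
#' @param state a [detector_state()].
#' @param frame a [thermal_frame()].
#' @return A list with elements `state` (updated: `previous_df` advanced
#'   to the current df) and `result`, a one-row data frame with columns
#'   `timestamp`, `A1`, `df`, `A2`, `threshold` (the compared quantity
#'   `px * t * df`), `posture` and `motion`.
#' @examples
#' st <- detector_state(ipf = 10)
#' out <- detect_step(st, thermal_frame(matrix(20, 8, 8), thermistor = 18))
#' out$result$posture
#' @export
detect_step <- function(state, frame) {
  stopifnot(inherits(state, "detector_state"),
            inherits(frame, "thermal_frame"))
  a1 <- average_raw(frame)
  t <- frame$thermistor
  df <- difference_factor(a1, t)
  grid <- bilinear_interpolate(frame$pixels, state$ipf)
  a2 <- average_interpolated(grid, df, mode = state$a2_mode)
  posture <- classify_posture(a2, t, px = 64, df = df)
  motion <- classify_motion(state$previous_df, df, epsilon = state$epsilon)
  state$previous_df <- df
  result <- data.frame(
    timestamp = frame$timestamp, A1 = a1, df = df, A2 = a2,
    threshold = 64 * t * df, posture = posture, motion = motion,
    stringsAsFactors = FALSE
  )
  list(state = state, result = result)
}

#' Run the detector over a frame sequence
#'
#' Applies [detect_step()] to each frame in order, threading the running
#' state, and collects the per-frame results. Malformed entries (anything
#' that is not a `thermal_frame`) are skipped, mirroring the real-time
#' loop's null-status guard.
#'
#' @param frames a list of [thermal_frame()] objects.
#' @param state a [detector_state()]; defaults to a fresh one at
#'   `ipf = 10`.
#' @param ... passed to [detector_state()] when `state` is missing.
#' @return A data frame of class `detection_log`, one row per processed
#'   frame, with the columns of [detect_step()]'s result.
#' @export
detect_frames <- function(frames, state = detector_state(...), ...) {
  frames <- Filter(function(f) inherits(f, "thermal_frame"), frames)
  if (length(frames) == 0L) {
    stop("no valid frames to process", call. = FALSE)
  }
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    out <- detect_step(state, frames[[i]])
    state <- out$state
    rows[[i]] <- out$result
  }
  log <- do.call(rbind, rows)
  class(log) <- c("detection_log", "data.frame")
  attr(log, "ipf") <- state$ipf
  attr(log, "a2_mode") <- state$a2_mode
  log
}

#' @export
print.detection_log <- function(x, ...) {
  cat("<detection_log> ", nrow(x), " frames, ipf ", attr(x, "ipf"),
      ", mode ", attr(x, "a2_mode"), "\n", sep = "")
  cat("  posture: ", paste(sprintf("%s %d", names(table(x$posture)),
                                   as.integer(table(x$posture))),
                           collapse = ", "), "\n", sep = "")
  cat("  motion:  ", paste(sprintf("%s %d", names(table(x$motion)),
                                   as.integer(table(x$motion))),
                           collapse = ", "), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' Posture accuracy across interpolation factors
#'
#' Runs the full detector over a labeled frame set once per candidate
#' interpolation factor and reports the fraction of frames whose posture
#' decision matches the ground-truth label — the design of the
#' interpolation-factor sweep used to pick the operating factor.
#'
#' @param frames list of [thermal_frame()] objects.
#' @param labels character vector of ground-truth postures
#'   (`"standing"`/`"sitting"`), one per frame.
#' @param ipf_values integer vector of interpolation factors to try.
#' @param a2_mode A2 normalization passed to the detector.
#' @return A data frame with columns `ipf`, `accuracy` (fraction correct
#'   in \[0, 1\]) and `n_frames`, ordered by `ipf`.
#' @export
sweep_ipf <- function(frames, labels, ipf_values, a2_mode = "alg1") {
  if (length(frames) == 0L) stop("empty frame set", call. = FALSE)
  stopifnot(length(labels) == length(frames))
  ipf_values <- sort(unique(vapply(ipf_values, check_ipf, integer(1))))
  acc <- vapply(ipf_values, function(ipf) {
    log <- detect_frames(frames, detector_state(ipf = ipf, a2_mode = a2_mode))
    mean(log$posture == labels)
  }, numeric(1))
  data.frame(ipf = ipf_values, accuracy = acc, n_frames = length(frames))
}
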