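# Cleaning and windowing: envelope-based artifact masking (a deterministic
# replacement for manual inspection of corrupted epochs), segmentation into
# protocol-aligned 30-s run windows, trimmed-mean heart rate per window.

#' Envelope-based artifact mask
#'
#' Flags high-frequency motion artifacts from the signal envelope. Per
#' axis, the residual `|signal - moving median|` is computed over a
#' `win_s`-second window, its moving maximum over the same window forms
#' the envelope, and samples where any axis envelope exceeds `k` times
#' that axis's trace-wide median envelope are flagged. Flagged samples are
#' dilated to whole 1-s epochs, mirroring epoch-wise removal of corrupted
#' data.
#'
#' @param trace An [accel_trace()].
#' @param win_s Envelope window, s.
#' @param k Threshold multiple of the median envelope.
#' @return Logical vector (class `artifact_mask`), `TRUE` = artifact, with
#'   attribute `fraction` (fraction flagged).
#' @export
envelope_mask <- function(trace, win_s = 0.5, k = 6) {
  stopifnot(inherits(trace, "accel_trace"))
  check_number(win_s, "win_s", lower = 0, allow_equal_lower = FALSE)
  check_number(k, "k", lower = 0, allow_equal_lower = FALSE)
  rate <- attr(trace, "sampling_rate")
  n <- nrow(trace)
  if (n == 0L) stop_invalid("trace must be non-empty")
  width <- max(3L, as.integer(round(win_s * rate)))

  flagged <- rep(FALSE, n)
  for (col in c("x_g", "y_g", "z_g")) {
    sig <- trace[[col]]
    resid <- abs(sig - moving_median(sig, width))
    env <- moving_max(resid, width)
    thr <- k * stats::median(env)
    flagged <- flagged | (env > thr)
  }

  # dilate to whole 1-s epochs on the session clock
  if (any(flagged)) {
    epoch <- floor(trace$time_s)
    bad_epochs <- unique(epoch[flagged])
    flagged <- epoch %in% bad_epochs
  }

  attr(flagged, "fraction") <- mean(flagged)
  class(flagged) <- c("artifact_mask", class(flagged))
  flagged
}

#' Segment traces into protocol-aligned run windows
#'
#' Cuts the session into one window per run phase (recoveries are never
#' windowed). Windows whose masked fraction exceeds `max_masked_frac` are
#' marked invalid and excluded downstream. Stages extending past the end
#' of either trace are dropped with a warning.
#'
#' @param accel An [accel_trace()].
#' @param hr An [hr_trace()] on the same session clock.
#' @param schedule An [build_schedule()] schedule.
#' @param mask Optional [envelope_mask()] result (default: nothing masked).
#' @param max_masked_frac Maximum tolerated masked fraction per window.
#' @param subject_id Subject label carried into the windows.
#' @return List of `ift_window` objects: `subject_id`, `stage`, `velocity`,
#'   `accel` (data frame slice `x_g,y_g,z_g`), `mask` (per-sample flags),
#'   `hr` (1-Hz samples in the run phase), `masked_frac`, `valid`.
#' @export
segment_windows <- function(accel, hr, schedule, mask = NULL,
                            max_masked_frac = 0.2, subject_id = "S01") {
  stopifnot(inherits(accel, "accel_trace"), inherits(hr, "hr_trace"),
            inherits(schedule, "ift_schedule"))
  check_number(max_masked_frac, "max_masked_frac", lower = 0, upper = 1)
  if (is.null(mask)) mask <- rep(FALSE, nrow(accel))
  if (length(mask) != nrow(accel)) {
    stop_invalid("mask length (%d) must match the accelerometer trace (%d)",
                 length(mask), nrow(accel))
  }

  accel_end <- max(accel$time_s) + 1 / attr(accel, "sampling_rate")
  hr_end <- max(hr$time_s) + 1 / attr(hr, "sampling_rate")
  covered <- schedule$run_end_s <= accel_end + 1e-9 &
    schedule$run_end_s <= hr_end + 1e-9
  if (!all(covered)) {
    warning(sprintf("dropping %d stage(s) not covered by the traces",
                    sum(!covered)), call. = FALSE)
  }

  windows <- list()
  for (kk in which(covered)) {
    ai <- which(accel$time_s >= schedule$run_start_s[kk] &
                accel$time_s < schedule$run_end_s[kk])
    hi <- which(hr$time_s >= schedule$run_start_s[kk] &
                hr$time_s < schedule$run_end_s[kk])
    wmask <- mask[ai]
    mfrac <- mean(wmask)
    win <- structure(
      list(subject_id = subject_id, stage = schedule$stage[kk],
           velocity = schedule$velocity_kmh[kk],
           accel = accel[ai, c("x_g", "y_g", "z_g")],
           mask = as.logical(wmask), hr = hr$hr_bpm[hi],
           masked_frac = mfrac, valid = mfrac <= max_masked_frac),
      class = "ift_window"
    )
    windows[[length(windows) + 1L]] <- win
  }
  windows
}

#' Trimmed-mean heart rate of a window
#'
#' Discards `trim_percent / 2` percent of samples from each tail (rounded
#' down to whole samples) and averages the rest; an outlier-robust window
#' mean.
#'
#' @param hr_segment Numeric HR samples, bpm.
#' @param trim_percent Total percentage trimmed (half per tail), in
#'   `[0, 100)`.
#' @return Trimmed mean, bpm.
#' @export
#' @examples
#' trimmed_mean_hr(c(rep(100, 9), 200), trim_percent = 20) # 100
trimmed_mean_hr <- function(hr_segment, trim_percent = 20) {
  if (length(hr_segment) == 0L) stop_invalid("hr_segment must be non-empty")
  if (!is.numeric(trim_percent) || trim_percent < 0 || trim_percent >= 100) {
    stop_invalid("trim_percent must be in [0, 100)")
  }
  n <- length(hr_segment)
  drop <- floor(n * trim_percent / 200)
  if (2 * drop >= n) return(stats::median(hr_segment))
  s <- sort(hr_segment)
  mean(s[(drop + 1):(n - drop)])
}
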