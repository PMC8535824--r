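# Accelerometry load metrics per window and the model-ready feature table.
#
# Conventions: raw axes are in g and include gravity; VMU operates on the
# raw axes. Net force converts VMU to SI acceleration (x 9.80665) before
# multiplying by body mass, so AvNetForce is in newtons and carries a
# ~1-g body-weight floor. Player Load differences out any constant offset,
# so gravity does not contribute to it.

#' Vector magnitude units
#'
#' Euclidean norm of the three raw accelerometer axes,
#' `sqrt(x^2 + y^2 + z^2)`, in g.
#'
#' @param x,y,z Per-axis acceleration, g. Vectorised.
#' @return VMU, g.
#' @export
#' @examples
#' vmu(3, 4, 0) # 5
vmu <- function(x, y, z) {
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z))) {
    stop_invalid("vmu inputs must be finite")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Instantaneous net force series
#'
#' Body mass times VMU, with VMU converted from g to m s^-2 so the result
#' is in newtons. A raw-g mode (`convert_g = FALSE`) multiplies mass by
#' VMU in g directly, for parity with device exports that skip the unit
#' conversion.
#'
#' @param vmu_series VMU samples, g.
#' @param mass Body mass, kg.
#' @param convert_g Convert VMU to m s^-2 before multiplying (default).
#' @return Per-sample net force (N, or kg g in raw-g mode).
#' @export
#' @examples
#' instantaneous_net_force(1, 70) # 686.4655 N
instantaneous_net_force <- function(vmu_series, mass, convert_g = TRUE) {
  check_number(mass, "mass", lower = 0, allow_equal_lower = FALSE)
  g0 <- if (convert_g) 9.80665 else 1
  mass * vmu_series * g0
}

#' Average net force of a window
#'
#' Arithmetic mean of the window's instantaneous net force over unmasked
#' samples.
#'
#' @param window An `ift_window` from [segment_windows()].
#' @param mass Body mass, kg.
#' @param convert_g See [instantaneous_net_force()].
#' @return Average net force, N.
#' @export
av_net_force <- function(window, mass, convert_g = TRUE) {
  stopifnot(inherits(window, "ift_window"))
  keep <- !window$mask
  if (!any(keep)) stop_invalid("all samples masked in stage %d window", window$stage)
  v <- vmu(window$accel$x_g[keep], window$accel$y_g[keep], window$accel$z_g[keep])
  mean(instantaneous_net_force(v, mass, convert_g = convert_g))
}

#' Player Load of a window
#'
#' Accumulated per-sample magnitude of successive-sample axis differences,
#' scaled by 1/100 (axes in g):
#' `PL = sum_t sqrt((dx_t)^2 + (dy_t)^2 + (dz_t)^2) / 100`.
#' Differences that span a masked gap are skipped rather than bridged, so
#' artifact removal cannot create spurious spikes. `per_sample_mean = TRUE`
#' divides by the number of contributing differences instead of
#' accumulating (the windowed-average reading of the formula).
#'
#' @param window An `ift_window`.
#' @param per_sample_mean Average instead of accumulate.
#' @return Player Load, arbitrary units.
#' @export
player_load <- function(window, per_sample_mean = FALSE) {
  stopifnot(inherits(window, "ift_window"))
  keep <- which(!window$mask)
  if (length(keep) < 2L) {
    stop_invalid("stage %d window has fewer than 2 unmasked samples", window$stage)
  }
  consecutive <- diff(keep) == 1L
  i2 <- keep[-1L][consecutive]
  i1 <- keep[-length(keep)][consecutive]
  if (length(i1) == 0L) {
    stop_invalid("stage %d window has no consecutive unmasked samples", window$stage)
  }
  dx <- window$accel$x_g[i2] - window$accel$x_g[i1]
  dy <- window$accel$y_g[i2] - window$accel$y_g[i1]
  dz <- window$accel$z_g[i2] - window$accel$z_g[i1]
  total <- sum(sqrt(dx^2 + dy^2 + dz^2)) / 100
  if (per_sample_mean) total / length(dx) else total
}

#' Assemble the model-ready feature table
#'
#' One row per valid window: Player Load, Average Net Force, trimmed-mean
#' HR, and the stage-velocity label.
#'
#' @param windows List of `ift_window` objects (possibly across subjects).
#' @param profiles Data frame with at least `subject_id` and `mass`.
#' @param trim_percent Passed to [trimmed_mean_hr()].
#' @param per_sample_mean,convert_g Metric conventions, see
#'   [player_load()] and [instantaneous_net_force()].
#' @return Data frame with columns
#'   `subject_id,stage,velocity_kmh,pl_au,avnetforce_N,hr_bpm`.
#' @export
build_feature_table <- function(windows, profiles, trim_percent = 20,
                                per_sample_mean = FALSE, convert_g = TRUE) {
  rows <- lapply(windows, function(w) {
    if (!w$valid) return(NULL)
    m <- profiles$mass[match(w$subject_id, profiles$subject_id)]
    if (length(m) != 1L || is.na(m)) {
      stop_invalid("no profile with a mass for subject '%s'", w$subject_id)
    }
    data.frame(
      subject_id = w$subject_id, stage = w$stage, velocity_kmh = w$velocity,
      pl_au = player_load(w, per_sample_mean = per_sample_mean),
      avnetforce_N = av_net_force(w, m, convert_g = convert_g),
      hr_bpm = trimmed_mean_hr(w$hr, trim_percent)
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(subject_id = character(), stage = integer(),
                      velocity_kmh = numeric(), pl_au = numeric(),
                      avnetforce_N = numeric(), hr_bpm = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
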