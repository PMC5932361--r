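interp_crossing <- function(t1, t2, v1, v2, target) {
  # linear interpolation of the time at which v crosses `target`
  if (v2 == v1) return(t1)
  t1 + (target - v1) / (v2 - v1) * (t2 - t1)
}

#' Response metrics of a TIR1:IAA trajectory
#'
#' Reduces a simulated trajectory to the descriptors of the auxin-signaling
#' response: the baseline TIR1:IAA level, the transient drop (amplitude and
#' fold-decrease, from the global post-onset minimum), the recovery time,
#' the post-recovery overshoot, and the final state.
#'
#' Recovery is declared when the deficit `baseline - value` first falls
#' below `recovery_fraction` of the peak deficit (default 5%), located by
#' linear interpolation between output grid points. The overshoot is
#' searched only after the recovery point, so solver wiggle near the
#' minimum is never labelled an overshoot. If the trajectory is too short
#' to bracket recovery, `recovery_time` is `NA` (unresolved), never
#' extrapolated.
#'
#' @param traj An `i3g_trajectory` from [simulate_scenario()].
#' @param recovery_fraction Deficit fraction below which the drop counts as
#'   recovered (default 0.05).
#' @return An object of class `i3g_metrics`; see [tidy.i3g_metrics()] for
#'   the tabular form. Fields: `baseline`, `min_value`, `min_time`,
#'   `drop_amplitude`, `fold_decrease`, `recovery_time`, `overshoot_peak`,
#'   `overshoot_time`, `final_value`, `final_fold_vs_baseline`.
#' @export
compute_metrics <- function(traj, recovery_fraction = 0.05) {
  stopifnot(is.data.frame(traj), all(c("time", "tir1_iaa") %in% names(traj)))
  recovery_fraction <- ensure_scalar(recovery_fraction, "recovery_fraction",
                                     positive = TRUE)
  df <- traj[traj$time >= 0, c("time", "tir1_iaa")]
  if (nrow(df) < 2L) abort("Trajectory must cover t >= 0 with >= 2 points.")
  tt <- df$time
  vv <- df$tir1_iaa
  base <- attr(traj, "baseline")
  baseline <- if (!is.null(base)) base[["tir1_iaa"]] else vv[1L]

  post <- tt > 0
  imin <- which(post)[which.min(vv[post])]
  min_value <- vv[imin]
  min_time <- tt[imin]
  drop_amplitude <- baseline - min_value
  fold_decrease <- baseline / min_value

  # flat (or rising-only) trajectory: no drop to recover from
  flat <- drop_amplitude <= 1e-9 * baseline
  if (flat) {
    drop_amplitude <- max(drop_amplitude, 0)
    fold_decrease <- max(fold_decrease, 1)
    recovery_time <- 0
  } else {
    thr <- recovery_fraction * drop_amplitude
    deficit <- baseline - vv
    idx <- which(tt > min_time & deficit < thr)
    if (length(idx) == 0L) {
      recovery_time <- NA_real_
    } else {
      i2 <- idx[1L]
      i1 <- i2 - 1L
      recovery_time <- interp_crossing(tt[i1], tt[i2],
                                       deficit[i1], deficit[i2], thr)
    }
  }

  after <- if (flat) tt > 0 else !is.na(recovery_time) & tt > recovery_time
  if (any(after)) {
    excess <- vv[after] - baseline
    ipk <- which.max(excess)
    overshoot_peak <- max(excess[ipk], 0)
    overshoot_time <- if (excess[ipk] > 0) tt[after][ipk] else NA_real_
  } else {
    overshoot_peak <- if (is.na(recovery_time)) NA_real_ else 0
    overshoot_time <- NA_real_
  }

  final_value <- vv[length(vv)]
  structure(
    list(
      baseline = baseline, min_value = min_value, min_time = min_time,
      drop_amplitude = drop_amplitude, fold_decrease = fold_decrease,
      recovery_time = recovery_time, recovery_fraction = recovery_fraction,
      overshoot_peak = overshoot_peak, overshoot_time = overshoot_time,
      final_value = final_value,
      final_fold_vs_baseline = final_value / baseline
    ),
    class = "i3g_metrics"
  )
}

#' @export
print.i3g_metrics <- function(x, ...) {
  cat("<i3g_metrics>\n")
  cat(sprintf("  baseline TIR1:IAA: %.6g uM\n", x$baseline))
  cat(sprintf("  drop: %.6g uM (%.3g-fold) at t = %.4g min\n",
              x$drop_amplitude, x$fold_decrease, x$min_time))
  cat(sprintf("  recovery (deficit < %g%% of peak): %s min\n",
              100 * x$recovery_fraction,
              if (is.na(x$recovery_time)) "unresolved"
              else sprintf("%.4g", x$recovery_time)))
  cat(sprintf("  overshoot: %s\n",
              if (is.na(x$overshoot_peak)) "unresolved"
              else if (x$overshoot_peak == 0) "none"
              else sprintf("+%.4g uM at t = %.4g min",
                           x$overshoot_peak, x$overshoot_time)))
  cat(sprintf("  final: %.6g uM (%.4g x baseline)\n",
              x$final_value, x$final_fold_vs_baseline))
  invisible(x)
}

#' @export
tidy.i3g_metrics <- function(x, ...) {
  as_tibble(x[c("baseline", "min_value", "min_time", "drop_amplitude",
                "fold_decrease", "recovery_time", "overshoot_peak",
                "overshoot_time", "final_value", "final_fold_vs_baseline")])
}

#' Time of first return to the pre-hydrolysis baseline
#'
#' For sustained-hydrolysis trajectories the natural notion of recovery is
#' the first time (after the trajectory minimum) at which TIR1:IAA climbs
#' back to its pre-hydrolysis baseline, found by linear interpolation. A
#' trajectory that never drops below baseline returns 0; one that never
#' crosses back (strong antagonist, weak nitrilase: the drop is maintained
#' at a new lower level) returns `NA` (unresolved), which is a value, not
#' an error.
#'
#' @param traj An `i3g_trajectory`.
#' @return Crossing time in minutes, 0, or `NA`.
#' @export
baseline_crossing_time <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("time", "tir1_iaa") %in% names(traj)))
  df <- traj[traj$time >= 0, c("time", "tir1_iaa")]
  tt <- df$time
  vv <- df$tir1_iaa
  base <- attr(traj, "baseline")
  baseline <- if (!is.null(base)) base[["tir1_iaa"]] else vv[1L]

  post <- tt > 0
  if (all(vv[post] >= baseline * (1 - 1e-9))) return(0)
  imin <- which(post)[which.min(vv[post])]
  idx <- which(tt > tt[imin] & vv >= baseline)
  if (length(idx) == 0L) return(NA_real_)
  i2 <- idx[1L]
  interp_crossing(tt[i2 - 1L], tt[i2], vv[i2 - 1L], vv[i2], baseline)
}
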