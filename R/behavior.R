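# Behavioral quantification: stop-period masks, delay periods, poke
# performance curves and maze performance.

#' Detect stopping periods from the position series
#'
#' Maximal intervals during which speed stays below `v_thresh` continuously
#' for more than `min_dur` seconds. These periods are excluded from all
#' maze running-rate computations.
#'
#' @param position position data frame with `t` and `speed` (speed derived
#'   from `x`/`y` if absent).
#' @param v_thresh speed threshold, cm/s (default 5).
#' @param min_dur minimal duration, s (default 3; strict `>`).
#' @return an [interval_set()] of stop periods.
#' @export
stop_mask <- function(position, v_thresh = 5, min_dur = 3) {
  if (!nrow(position)) return(interval_set())
  if (!"speed" %in% names(position)) position$speed <- derive_speed(position)
  slow <- position$speed < v_thresh
  r <- rle(slow)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  dt <- stats::median(diff(position$t))
  ss <- ee <- numeric(0)
  for (j in which(r$values)) {
    t0 <- position$t[starts_i[j]]
    t1 <- if (ends_i[j] < nrow(position)) position$t[ends_i[j] + 1L]
          else position$t[ends_i[j]] + dt
    if (t1 - t0 > min_dur) { ss <- c(ss, t0); ee <- c(ee, t1) }
  }
  interval_set(ss, ee)
}

#' Delay period of a trial
#'
#' The fixed-length window before the observer's first correct (rewarded)
#' poke in the box: `[t_ob_poke - duration, t_ob_poke)`.
#'
#' @param trial one-row data frame (or list) with `t_ob_poke`.
#' @param duration window length, s (default 2).
#' @return numeric length-2 vector `c(start, end)`.
#' @export
delay_period <- function(trial, duration = 2.0) {
  if (duration <= 0) stop("delay_period: 'duration' must be > 0")
  poke <- trial$t_ob_poke
  if (is.null(poke) || length(poke) != 1L || is.na(poke))
    stop("delay_period: trial has no t_ob_poke")
  c(poke - duration, poke)
}

#' Delay periods of all trials as an interval set
#' @param trials trial table.
#' @param duration window length, s.
#' @return an [interval_set()], one interval per trial in trial order.
#' @export
delay_intervals <- function(trials, duration = 2.0) {
  if (duration <= 0) stop("delay_intervals: 'duration' must be > 0")
  interval_set(trials$t_ob_poke - duration, trials$t_ob_poke)
}

#' Poke performance curve
#'
#' Histogram of observer poke times relative to the corresponding
#' demonstrator poke (time 0) in each trial, in 0.25 s bins, normalized.
#'
#' Normalization modes: `"total"` (default) divides bin counts by the total
#' number of pokes in the window so the curve sums to 1; `"per_trial"`
#' normalizes each trial's histogram first and averages across trials with
#' pokes.
#'
#' @param ob_pokes list (one element per trial) of observer poke times, s.
#' @param demo_poke_times numeric vector of demonstrator poke times, one per
#'   trial.
#' @param bin bin width, s (default 0.25).
#' @param window length-2 window around time 0, s (default `c(-10, 10)`,
#'   covering the 10 s response deadline).
#' @param normalize `"total"` or `"per_trial"`.
#' @return list of class `poke_curve` with `bin_centers`, `rate`,
#'   `n_trials`, `n_pokes`.
#' @export
poke_performance_curve <- function(ob_pokes, demo_poke_times, bin = 0.25,
                                   window = c(-10, 10),
                                   normalize = c("total", "per_trial")) {
  normalize <- match.arg(normalize)
  n_trials <- length(demo_poke_times)
  if (n_trials < 1L) stop("poke_performance_curve: need >= 1 trial")
  if (length(ob_pokes) != n_trials)
    stop("poke_performance_curve: ob_pokes and demo_poke_times lengths differ")
  edges <- seq(window[1L], window[2L], by = bin)
  nb <- length(edges) - 1L
  centers <- edges[-length(edges)] + bin / 2
  per_trial <- matrix(0, n_trials, nb)
  for (k in seq_len(n_trials)) {
    rel <- ob_pokes[[k]] - demo_poke_times[k]
    rel <- rel[rel >= window[1L] & rel < window[2L]]
    if (length(rel))
      per_trial[k, ] <- tabulate(findInterval(rel, edges), nbins = nb)
  }
  total <- sum(per_trial)
  if (total == 0) {
    warning("poke_performance_curve: no pokes in window; returning zeros")
    rate <- rep(0, nb)
  } else if (normalize == "total") {
    rate <- colSums(per_trial) / total
  } else {
    rows <- rowSums(per_trial)
    use <- rows > 0
    rate <- colMeans(per_trial[use, , drop = FALSE] / rows[use])
  }
  structure(list(bin_centers = centers, rate = rate, n_trials = n_trials,
                 n_pokes = total), class = "poke_curve")
}

#' @export
print.poke_curve <- function(x, ...) {
  cat("poke_curve:", length(x$bin_centers), "bins,", x$n_pokes,
      "pokes over", x$n_trials, "trials; peak at",
      x$bin_centers[which.max(x$rate)], "s\n")
  invisible(x)
}

#' Maze performance: fraction of correct trials
#' @param trials trial table with logical `correct`.
#' @return fraction in `[0, 1]`.
#' @export
maze_performance <- function(trials) {
  if (!nrow(trials)) stop("maze_performance: need >= 1 trial")
  mean(trials$correct)
}
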