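# Sharp-wave-ripple detection as population burst events (PBEs) from CA1
# multiunit activity: 10 ms spike-count bins, Gaussian smoothing (sigma =
# 2 bins), min-max standardization to [0, 1], threshold crossing (peak >=
# 0.35 with event edges at the outermost bins still >= 0.15), and merging
# of events separated by < 30 ms.

#' Bin CA1 multiunit activity
#'
#' Total CA1 spike counts in fixed-width time bins over the session span.
#' Bins are half-open `[edge, edge + bin)`; a spike exactly on an edge goes
#' to the later bin.
#'
#' @param session an `oswm_session` (all CA1 units are pooled), or a numeric
#'   vector of pooled CA1 spike times.
#' @param bin bin width, s (default 0.010).
#' @param t_range optional length-2 span; defaults to `[0, last spike or
#'   position sample]`.
#' @return object of class `mua_trace` with `time` (bin centers), `counts`,
#'   `bin`; `values` is added by [smooth_standardize()].
#' @export
bin_mua <- function(session, bin = 0.010, t_range = NULL) {
  if (inherits(session, "oswm_session")) {
    spikes <- sort(unlist(lapply(region_units(session, "CA1"), `[[`, "t")))
    if (is.null(t_range))
      t_range <- c(0, max(session$position$t, spikes, 0) + bin)
  } else {
    spikes <- sort(as.numeric(session))
    if (is.null(t_range)) t_range <- c(0, max(spikes, 0) + bin)
  }
  edges <- seq(t_range[1L], t_range[2L], by = bin)
  if (length(edges) < 2L) stop("bin_mua: span shorter than one bin")
  nb <- length(edges) - 1L
  if (!length(spikes)) {
    warning("bin_mua: no CA1 spikes; returning all-zero trace")
    counts <- integer(nb)
  } else {
    spikes <- spikes[spikes >= edges[1L] & spikes < edges[nb + 1L]]
    counts <- tabulate(findInterval(spikes, edges), nbins = nb)
  }
  structure(list(time = edges[-length(edges)] + bin / 2, counts = counts,
                 bin = bin), class = "mua_trace")
}

#' @export
print.mua_trace <- function(x, ...) {
  cat("mua_trace:", length(x$counts), "bins of", x$bin * 1000, "ms;",
      sum(x$counts), "spikes",
      if (!is.null(x$values)) "(smoothed+standardized)" else "", "\n")
  invisible(x)
}

#' Smooth and standardize a multiunit trace
#'
#' Gaussian smoothing (kernel truncated at +/- 4 sigma and renormalized at
#' the edges) followed by min-max scaling to `[0, 1]` over the whole trace
#' (the standardization window; a per-interval variant can be had by slicing
#' the trace first).
#'
#' @param trace a `mua_trace` from [bin_mua()].
#' @param sigma_bins Gaussian sigma in bins (default 2).
#' @return the trace with a `values` component in `[0, 1]`.
#' @export
smooth_standardize <- function(trace, sigma_bins = 2) {
  if (!length(trace$counts)) stop("smooth_standardize: empty trace")
  sm <- gauss_smooth(as.numeric(trace$counts), sigma_bins)
  rng <- range(sm)
  if (rng[2L] == rng[1L]) {
    warning("smooth_standardize: constant trace; standardized values all 0")
    trace$values <- rep(0, length(sm))
  } else {
    trace$values <- (sm - rng[1L]) / (rng[2L] - rng[1L])
  }
  trace$smoothed <- sm
  trace
}

#' Detect population burst events
#'
#' A PBE is a maximal run of bins with standardized MUA `>= edge_thr`
#' containing at least one bin `>= peak_thr`; events separated by less than
#' `merge_gap` are combined (the merged event's peak is the members' max).
#' Threshold comparisons are inclusive (`>=`) to avoid float-equality
#' flakiness.
#'
#' @param trace standardized `mua_trace` (after [smooth_standardize()]).
#' @param peak_thr peak threshold in standardized units (0.35).
#' @param edge_thr start/end threshold (0.15).
#' @param merge_gap merge events with gaps strictly smaller than this, s
#'   (0.030).
#' @return data frame of events: `event_id`, `start`, `end`, `peak_time`,
#'   `peak_value` (event spans cover their bins, half-open).
#' @export
detect_pbes <- function(trace, peak_thr = 0.35, edge_thr = 0.15,
                        merge_gap = 0.030) {
  v <- trace$values
  if (is.null(v)) stop("detect_pbes: trace is not standardized; ",
                       "run smooth_standardize() first")
  empty <- data.frame(event_id = integer(), start = numeric(),
                      end = numeric(), peak_time = numeric(),
                      peak_value = numeric())
  above <- v >= edge_thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values
  segs <- cbind(starts_i[keep], ends_i[keep])
  half <- trace$bin / 2
  ev <- list()
  for (i in seq_len(nrow(segs))) {
    a <- segs[i, 1L]; b <- segs[i, 2L]
    pk <- which.max(v[a:b]) + a - 1L
    if (v[pk] >= peak_thr)
      ev[[length(ev) + 1L]] <- c(trace$time[a] - half, trace$time[b] + half,
                                 trace$time[pk], v[pk])
  }
  if (!length(ev)) return(empty)
  m <- do.call(rbind, ev)
  ## merge adjacent events with gap < merge_gap
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) for (i in 2L:nrow(m)) {
    last <- nrow(out)
    if (m[i, 1L] - out[last, 2L] < merge_gap) {
      out[last, 2L] <- m[i, 2L]
      if (m[i, 4L] > out[last, 4L]) out[last, 3:4] <- m[i, 3:4]
    } else out <- rbind(out, m[i, , drop = FALSE])
  }
  data.frame(event_id = seq_len(nrow(out)), start = out[, 1L],
             end = out[, 2L], peak_time = out[, 3L], peak_value = out[, 4L])
}

#' Restrict events to an interval set
#'
#' Keeps the events whose peak time falls inside the intervals (half-open:
#' a peak exactly at an interval end is excluded).
#'
#' @param events event table from [detect_pbes()].
#' @param intervals an [interval_set()].
#' @return the retained rows of `events`.
#' @export
restrict_events <- function(events, intervals) {
  if (!nrow(events)) return(events)
  events[iv_contains(events$peak_time, intervals), , drop = FALSE]
}
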