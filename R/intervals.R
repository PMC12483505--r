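# Interval sets: ordered, pairwise-disjoint half-open [start, end) time
# intervals. All masking, restriction and rate computations in the package
# run on these. The half-open convention avoids double counting at shared
# boundaries in binning and interval arithmetic.

#' Construct an interval set
#'
#' An interval set is an ordered collection of pairwise-disjoint half-open
#' time intervals `[start, end)`, in seconds. Used throughout the package for
#' masking (stop periods), restriction (delay, water, lap windows) and
#' duration bookkeeping.
#'
#' @param start,end numeric vectors of equal length; each `start < end`.
#' @return an object of class `interval_set` (a data frame with columns
#'   `start`, `end`, sorted by `start`).
#' @examples
#' iv <- interval_set(c(0, 10), c(5, 12))
#' iv_total(iv)  # 7
#' @export
interval_set <- function(start = numeric(), end = numeric()) {
  if (length(start) != length(end))
    stop("interval_set: 'start' and 'end' must have equal length")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("interval_set: non-finite interval bounds")
  if (any(end <= start))
    stop("interval_set: every interval must satisfy start < end")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1L] < end[-length(end)]))
    stop("interval_set: intervals overlap")
  structure(data.frame(start = start, end = end),
            class = c("interval_set", "data.frame"))
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set with", nrow(x), "interval(s), total",
      format(iv_total(x)), "s\n")
  if (nrow(x)) print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Total duration of an interval set
#' @param x an `interval_set`.
#' @return total length in seconds.
#' @export
iv_total <- function(x) {
  if (!nrow(x)) return(0)
  sum(x$end - x$start)
}

#' Membership of time points in an interval set
#'
#' @param t numeric vector of time points.
#' @param x an `interval_set`.
#' @return logical vector: is `t` inside some `[start, end)`?
#' @export
iv_contains <- function(t, x) {
  if (!nrow(x)) return(rep(FALSE, length(t)))
  bounds <- as.numeric(t(cbind(x$start, x$end)))
  findInterval(t, bounds) %% 2L == 1L
}

#' Count sorted event times falling in an interval set
#'
#' @param t sorted numeric vector of event (spike) times.
#' @param x an `interval_set`.
#' @return integer count of events inside the set (half-open intervals).
#' @export
iv_count <- function(t, x) {
  if (!nrow(x) || !length(t)) return(0L)
  lo <- findInterval(x$start, t, left.open = TRUE)  # #{t < start}
  hi <- findInterval(x$end,   t, left.open = TRUE)  # #{t < end}
  as.integer(sum(hi - lo))
}

#' Restrict event times to an interval set
#' @param t numeric vector of times.
#' @param x an `interval_set`.
#' @return the subset of `t` inside the set, original order preserved.
#' @export
iv_restrict <- function(t, x) t[iv_contains(t, x)]

#' Intersect two interval sets
#' @param x,y `interval_set` objects.
#' @return their intersection as an `interval_set`.
#' @export
iv_intersect <- function(x, y) {
  if (!nrow(x) || !nrow(y)) return(interval_set())
  ss <- numeric(0); ee <- numeric(0)
  for (i in seq_len(nrow(x))) {
    j <- which(y$start < x$end[i] & y$end > x$start[i])
    if (length(j)) {
      ss <- c(ss, pmax(x$start[i], y$start[j]))
      ee <- c(ee, pmin(x$end[i], y$end[j]))
    }
  }
  interval_set(ss, ee)
}

#' Subtract one interval set from another
#' @param x,y `interval_set` objects.
#' @return `x` minus `y`, as an `interval_set`.
#' @export
iv_subtract <- function(x, y) {
  if (!nrow(x) || !nrow(y)) return(x)
  ss <- numeric(0); ee <- numeric(0)
  for (i in seq_len(nrow(x))) {
    cur <- x$start[i]
    j <- which(y$start < x$end[i] & y$end > x$start[i])
    for (k in j) {
      if (y$start[k] > cur) { ss <- c(ss, cur); ee <- c(ee, y$start[k]) }
      cur <- max(cur, y$end[k])
    }
    if (cur < x$end[i]) { ss <- c(ss, cur); ee <- c(ee, x$end[i]) }
  }
  interval_set(ss, ee)
}

#' Merge intervals separated by less than a gap
#'
#' Combines consecutive intervals whose gap is strictly smaller than
#' `gap` seconds (used by the PBE detector's < 30 ms merge rule).
#'
#' @param x an `interval_set`.
#' @param gap merge threshold in seconds (strict `<`).
#' @return merged `interval_set`.
#' @export
iv_merge_gaps <- function(x, gap) {
  if (nrow(x) < 2L) return(x)
  ss <- x$start[1L]; ee <- x$end[1L]
  for (i in 2L:nrow(x)) {
    if (x$start[i] - ee[length(ee)] < gap) {
      ee[length(ee)] <- max(ee[length(ee)], x$end[i])
    } else {
      ss <- c(ss, x$start[i]); ee <- c(ee, x$end[i])
    }
  }
  interval_set(ss, ee)
}
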