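# Replay decoding: linearized spatial firing-rate curves, place-cell
# templates and left/right ensembles, memoryless Poisson Bayesian decoding
# of candidate population burst events in overlapping 20 ms windows, time-
# bin-shuffle significance, and per-trial replay counting.

#' Linearized firing-rate curve on one trajectory
#'
#' Spike counts per spatial bin divided by occupancy time per bin, during
#' active running only (stop periods excluded), then Gaussian-smoothed
#' (counts and occupancy smoothed with the same kernel before the ratio).
#' Bins never occupied are marked invalid and excluded from the curve's
#' peak/mean/sd summary.
#'
#' @param spike_times sorted spike times of one unit.
#' @param position position data frame (`t`, `traj_id`, `lin_pos`).
#' @param traj trajectory id (`left_out`, `left_in`, `right_out`,
#'   `right_in`).
#' @param bin_size spatial bin, cm (default 2).
#' @param sigma_bins smoothing sigma in spatial bins (default 2).
#' @param stops optional stop-period [interval_set()] to exclude.
#' @param traj_length trajectory length, cm (default: observed maximum
#'   rounded up to a bin).
#' @return object of class `rate_curve`: `x` (bin centers), `rate` (Hz, NA
#'   at invalid bins), `occupancy` (s), `peak`, `mean`, `sd`, `valid`.
#' @export
linearized_rate_curve <- function(spike_times, position, traj,
                                  bin_size = 2, sigma_bins = 2,
                                  stops = NULL, traj_length = NULL) {
  sel <- position$traj_id == traj & !is.na(position$lin_pos)
  if (!is.null(stops) && nrow(stops))
    sel <- sel & !iv_contains(position$t, stops)
  if (!any(sel))
    stop("linearized_rate_curve: no traversal of trajectory ", traj)
  dt <- stats::median(diff(position$t))
  lin <- position$lin_pos[sel]
  if (is.null(traj_length))
    traj_length <- ceiling(max(lin) / bin_size) * bin_size
  edges <- seq(0, traj_length, by = bin_size)
  nb <- length(edges) - 1L
  x <- edges[-length(edges)] + bin_size / 2
  occ_raw <- tabulate(findInterval(pmin(lin, traj_length - 1e-9), edges),
                      nbins = nb) * dt
  ## assign each spike to the position sample at or before it
  idx <- findInterval(spike_times, position$t)
  ok <- idx >= 1L & sel[pmax(idx, 1L)]
  spk_lin <- position$lin_pos[idx[ok]]
  cnt_raw <- tabulate(findInterval(pmin(spk_lin, traj_length - 1e-9), edges),
                      nbins = nb)
  valid <- occ_raw > 0
  s_cnt <- gauss_smooth(cnt_raw, sigma_bins)
  s_occ <- gauss_smooth(occ_raw, sigma_bins)
  rate <- rep(NA_real_, nb)
  rate[valid] <- s_cnt[valid] / s_occ[valid]
  vr <- rate[valid]
  structure(list(traj = traj, x = x, rate = rate, occupancy = occ_raw,
                 valid = valid, n_spikes = sum(cnt_raw),
                 peak = if (length(vr)) max(vr) else NA_real_,
                 mean = if (length(vr)) mean(vr) else NA_real_,
                 sd = if (length(vr)) stats::sd(vr) else NA_real_),
            class = "rate_curve")
}

#' @export
print.rate_curve <- function(x, ...) {
  cat("rate_curve [", x$traj, "]: ", sum(x$valid), "/", length(x$x),
      " valid bins, peak ", format(x$peak, digits = 3), " Hz, mean ",
      format(x$mean, digits = 3), " Hz\n", sep = "")
  invisible(x)
}

#' Construct a rate curve directly from values
#'
#' Convenience constructor for analytically specified curves (tests,
#' simulations): uniform bins, all valid.
#'
#' @param traj trajectory id.
#' @param x uniform spatial bin centers, cm.
#' @param rate rates at `x`, Hz (>= 0).
#' @return a `rate_curve`.
#' @export
rate_curve <- function(traj, x, rate) {
  stopifnot(length(x) == length(rate), all(rate >= 0))
  structure(list(traj = traj, x = x, rate = rate,
                 occupancy = rep(1, length(x)),
                 valid = rep(TRUE, length(x)), n_spikes = NA_integer_,
                 peak = max(rate), mean = mean(rate), sd = stats::sd(rate)),
            class = "rate_curve")
}

#' Build a place-cell template for one trajectory
#'
#' A unit enters the template iff its rate curve's peak is at least
#' `n_sd` standard deviations above the curve's mean (statistics over the
#' curve's valid spatial bins) and strictly above the mean — so constant
#' curves (sd = 0) are excluded.
#'
#' @param curves named list of `rate_curve`s (names = unit ids), all on the
#'   same trajectory.
#' @param n_sd inclusion threshold in curve SDs (default 3).
#' @return object of class `replay_template`: `traj`, `unit_ids`, `x`
#'   (common valid bin centers), `rates` (members x bins matrix); possibly
#'   empty.
#' @export
build_template <- function(curves, n_sd = 3) {
  if (!length(curves))
    return(structure(list(traj = NA_character_, unit_ids = character(),
                          x = numeric(), rates = NULL),
                     class = "replay_template"))
  traj <- curves[[1L]]$traj
  keep <- vapply(curves, function(cv)
    is.finite(cv$peak) && is.finite(cv$sd) &&
      cv$peak > cv$mean && cv$peak >= cv$mean + n_sd * cv$sd, logical(1))
  members <- curves[keep]
  if (!length(members))
    return(structure(list(traj = traj, unit_ids = character(),
                          x = numeric(), rates = NULL),
                     class = "replay_template"))
  valid <- Reduce(`&`, lapply(members, `[[`, "valid"))
  x <- members[[1L]]$x[valid]
  rates <- do.call(rbind, lapply(members, function(cv) cv$rate[valid]))
  rownames(rates) <- names(members)
  structure(list(traj = traj, unit_ids = names(members), x = x,
                 rates = rates), class = "replay_template")
}

#' @export
print.replay_template <- function(x, ...) {
  cat("replay_template [", x$traj, "]: ", length(x$unit_ids),
      " member(s), ", length(x$x), " spatial bins\n", sep = "")
  invisible(x)
}

#' Left/right CA1 ensembles from the four templates
#'
#' Each side's ensemble is the union of that side's inbound and outbound
#' template members; a unit may belong to both ensembles.
#'
#' @param templates named list of `replay_template`s for `left_out`,
#'   `left_in`, `right_out`, `right_in` (missing entries treated as empty).
#' @return list with `left` and `right` character vectors of unit ids.
#' @export
build_ensembles <- function(templates) {
  get_ids <- function(nm) {
    t <- templates[[nm]]
    if (is.null(t)) character() else t$unit_ids
  }
  list(left = union(get_ids("left_out"), get_ids("left_in")),
       right = union(get_ids("right_out"), get_ids("right_in")))
}

#' Candidate events for a template
#'
#' PBEs in which at least `min_active` distinct template members fire at
#' least one spike (spikes within the event span only).
#'
#' @param pbes event table from [detect_pbes()].
#' @param template a `replay_template`.
#' @param spikes named list of sorted spike-time vectors (unit id -> times).
#' @param min_active minimum active member count (default 4).
#' @return the candidate rows of `pbes`, with an `n_active` column.
#' @export
find_candidates <- function(pbes, template, spikes, min_active = 4) {
  if (!nrow(pbes) || !length(template$unit_ids)) {
    pbes$n_active <- integer(nrow(pbes))
    return(pbes[integer(0), , drop = FALSE])
  }
  n_active <- integer(nrow(pbes))
  for (u in template$unit_ids) {
    tt <- spikes[[u]]
    lo <- findInterval(pbes$start, tt, left.open = TRUE)
    hi <- findInterval(pbes$end, tt, left.open = TRUE)
    n_active <- n_active + as.integer(hi > lo)
  }
  pbes$n_active <- n_active
  pbes[n_active >= min_active, , drop = FALSE]
}

#' Poisson posterior over template positions for a spike-count matrix
#'
#' The memoryless decoder core: for each window with counts `n_i` and
#' length tau, `P(x | n) ~ prod_i (tau f_i(x))^(n_i) exp(-tau f_i(x))`
#' under a uniform spatial prior, computed in the log domain and normalized
#' per window.
#'
#' @param counts members x windows spike-count matrix (rows ordered as the
#'   template's unit ids).
#' @param template a `replay_template`.
#' @param tau_w window length(s), s (scalar or one per window).
#' @param rate_floor lower clamp on template rates, Hz.
#' @return list with `posterior` (positions x windows, columns sum to 1)
#'   and `decoded` (argmax position per window; ties take the lowest
#'   position).
#' @export
poisson_posterior <- function(counts, template, tau_w, rate_floor = 1e-3) {
  W <- ncol(counts)
  if (length(tau_w) == 1L) tau_w <- rep(tau_w, W)
  Fq <- pmax(template$rates, rate_floor)
  logF <- log(Fq)
  sumF <- colSums(Fq)
  ## B x W log-likelihood (uniform prior): sum_i n_i log f_i(x) - tau sum f
  ll <- t(logF) %*% counts - outer(sumF, tau_w)
  post <- apply(ll, 2L, function(col) exp(col - logsumexp(col)))
  post <- matrix(post, nrow = length(template$x))
  list(posterior = post, decoded = template$x[apply(ll, 2L, which.max)])
}

#' Bayesian decoding of one candidate event
#'
#' Memoryless Poisson decoder: in each window of length tau (sliding by
#' `step`, a trailing partial window kept if at least tau/2 long), the
#' posterior over template positions under a uniform spatial prior is
#' `P(x | n) ~ prod_i (tau f_i(x))^(n_i) exp(-tau f_i(x))`, computed in the
#' log domain and normalized per window. The decoded position of a window
#' is the template position with maximum posterior (ties: lowest position).
#' Windows with zero spikes are excluded from the decoded-position series
#' by default (their posterior reflects only the exp(-tau f) factor).
#'
#' @param pbe one event: list/row with `start`, `end` (and optionally
#'   `event_id`).
#' @param template a `replay_template`.
#' @param spikes named list of sorted spike-time vectors.
#' @param tau window length, s (0.020).
#' @param step window step, s (0.010).
#' @param rate_floor lower clamp on template rates, Hz, so zero-rate bins
#'   keep a finite log-likelihood (1e-3).
#' @param include_empty include zero-spike windows in the decoded series.
#' @return object of class `decoded_event`: window table, spike-count
#'   matrix, posterior matrix (columns sum to 1), decoded positions,
#'   `included` mask, `undecodable` flag.
#' @export
decode_event <- function(pbe, template, spikes, tau = 0.020, step = 0.010,
                         rate_floor = 1e-3, include_empty = FALSE) {
  if (!length(template$unit_ids)) stop("decode_event: empty template")
  ws <- seq(pbe$start, pbe$end, by = step)
  ws <- ws[ws < pbe$end]
  we <- pmin(ws + tau, pbe$end)
  keep <- (we - ws) >= tau / 2
  ws <- ws[keep]; we <- we[keep]
  W <- length(ws)
  m <- length(template$unit_ids)
  counts <- matrix(0L, m, W, dimnames = list(template$unit_ids, NULL))
  for (i in seq_len(m)) {
    tt <- spikes[[template$unit_ids[i]]]
    lo <- findInterval(ws, tt, left.open = TRUE)
    hi <- findInterval(we, tt, left.open = TRUE)
    counts[i, ] <- hi - lo
  }
  tau_w <- we - ws
  pp <- poisson_posterior(counts, template, tau_w, rate_floor)
  post <- pp$posterior
  decoded <- pp$decoded
  included <- if (include_empty) rep(TRUE, W) else colSums(counts) > 0
  structure(list(event_id = pbe$event_id %||% NA_integer_,
                 traj = template$traj, start = pbe$start, end = pbe$end,
                 window_start = ws, window_len = tau_w, counts = counts,
                 posterior = post, decoded = decoded, included = included,
                 n_windows = sum(included),
                 undecodable = !any(included)),
            class = "decoded_event")
}

#' @export
print.decoded_event <- function(x, ...) {
  cat("decoded_event [", x$traj, "]: ", length(x$window_start),
      " windows (", x$n_windows, " with spikes)",
      if (!is.null(x$r)) paste0(", r = ", format(x$r, digits = 3),
                                ", p = ", format(x$p, digits = 3),
                                if (isTRUE(x$is_replay)) " *replay*" else ""),
      "\n", sep = "")
  invisible(x)
}

#' Shuffle significance of a decoded event
#'
#' Pearson correlation `r` of decoded positions against window indices,
#' compared with `n_shuffles` coefficients obtained by permuting the window
#' indices. Default convention is two-sided on `|r|` (forward and reverse
#' replays are both of interest); `sided = "one.sided"` uses the
#' greater-than-actual convention on signed `r`. The `+1/(n+1)` correction
#' keeps p in `(0, 1]`.
#'
#' @param decoded a `decoded_event`.
#' @param n_shuffles number of index permutations (1000).
#' @param seed optional RNG seed.
#' @param sided `"two.sided"` (default) or `"one.sided"`.
#' @param alpha replay call threshold (0.05).
#' @return the event with `r`, `p`, `is_replay`, `direction`, `flag` added.
#' @export
replay_significance <- function(decoded, n_shuffles = 1000, seed = NULL,
                                sided = c("two.sided", "one.sided"),
                                alpha = 0.05) {
  sided <- match.arg(sided)
  if (!is.null(seed)) set.seed(seed)
  y <- decoded$decoded[decoded$included]
  decoded$r <- NA_real_; decoded$p <- NA_real_
  decoded$is_replay <- FALSE; decoded$direction <- NA_character_
  decoded$flag <- NA_character_
  if (length(y) < 4L) {
    decoded$flag <- "insufficient_windows"
    return(decoded)
  }
  if (stats::sd(y) == 0) {
    decoded$flag <- "constant_positions"
    return(decoded)
  }
  r <- stats::cor(seq_along(y), y)
  null <- perm_index_cors(y, n_shuffles)
  p <- if (sided == "two.sided")
    (1 + sum(abs(null) >= abs(r) - 1e-12)) / (n_shuffles + 1)
  else (1 + sum(null >= r - 1e-12)) / (n_shuffles + 1)
  decoded$r <- r
  decoded$p <- p
  decoded$is_replay <- p < alpha
  decoded$direction <- if (r > 0) "forward" else "reverse"
  decoded
}

#' Decode and test all candidate events against all templates
#'
#' @param pbes event table (typically already restricted to water periods).
#' @param templates named list of the four `replay_template`s.
#' @param spikes named list of sorted spike-time vectors.
#' @param min_active candidate threshold (4).
#' @param tau,step,rate_floor decoding parameters.
#' @param n_shuffles,sided,alpha significance parameters.
#' @param seed optional RNG seed.
#' @return data frame, one row per (candidate event x template):
#'   `event_id`, `template`, `peak_time`, `n_active`, `n_windows`, `r`,
#'   `p`, `is_replay`, `direction`, `flag`.
#' @export
decode_session_replays <- function(pbes, templates, spikes, min_active = 4,
                                   tau = 0.020, step = 0.010,
                                   rate_floor = 1e-3, n_shuffles = 1000,
                                   sided = c("two.sided", "one.sided"),
                                   alpha = 0.05, seed = NULL) {
  sided <- match.arg(sided)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (nm in names(templates)) {
    tmpl <- templates[[nm]]
    if (is.null(tmpl) || !length(tmpl$unit_ids)) next
    cand <- find_candidates(pbes, tmpl, spikes, min_active)
    for (j in seq_len(nrow(cand))) {
      de <- decode_event(cand[j, ], tmpl, spikes, tau, step, rate_floor)
      de <- replay_significance(de, n_shuffles, sided = sided, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = cand$event_id[j], template = nm,
        peak_time = cand$peak_time[j], n_active = cand$n_active[j],
        n_windows = de$n_windows, r = de$r, p = de$p,
        is_replay = de$is_replay,
        direction = de$direction %||% NA_character_,
        flag = de$flag %||% NA_character_)
    }
  }
  if (!length(rows))
    return(data.frame(event_id = integer(), template = character(),
                      peak_time = numeric(), n_active = integer(),
                      n_windows = integer(), r = numeric(), p = numeric(),
                      is_replay = logical(), direction = character(),
                      flag = character()))
  do.call(rbind, rows)
}

#' Per-trial replay counts for each template
#'
#' Counts, for each trial and each of the four templates, the significant
#' replay events whose peak time lies in that trial's water-consumption
#' interval. An event significant for several templates increments each.
#'
#' @param trials trial table (`trial_id`, `water_start`, `water_end`).
#' @param decoded output of [decode_session_replays()].
#' @return integer matrix, trials x templates (`left_out`, `left_in`,
#'   `right_out`, `right_in`).
#' @export
replay_counts_per_trial <- function(trials, decoded) {
  tmpls <- c("left_out", "left_in", "right_out", "right_in")
  counts <- matrix(0L, nrow(trials), 4L,
                   dimnames = list(trials$trial_id, tmpls))
  sig <- decoded[which(decoded$is_replay), , drop = FALSE]
  if (!nrow(sig)) return(counts)
  for (k in seq_len(nrow(trials))) {
    inw <- sig$peak_time >= trials$water_start[k] &
      sig$peak_time < trials$water_end[k]
    if (any(inw))
      counts[k, ] <- vapply(tmpls, function(tm)
        sum(inw & sig$template == tm), integer(1))
  }
  counts
}
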