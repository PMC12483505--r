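# ACC-CA1 coupling statistics: lag-resolved cross-correlation of 200 ms
# binned delay-period rates, trial-by-trial rate correlations within SWRs
# during water consumption, delay-to-water and delay-to-replay-count
# correlations, and their same- vs opposite-side population tests.

#' Spike counts in fixed bins over one interval
#'
#' Half-open bins tiled from the interval start; a trailing partial bin is
#' dropped. For an ensemble, pass the pooled (aggregated) spike times of
#' all member cells.
#'
#' @param spike_times sorted spike times (a unit's, or an ensemble's pooled
#'   spikes).
#' @param interval length-2 `c(start, end)`, with `end - start >= bin`.
#' @param bin bin width, s (default 0.200).
#' @return integer vector of per-bin counts.
#' @export
binned_rates <- function(spike_times, interval, bin = 0.200) {
  len <- interval[2L] - interval[1L]
  if (len < bin)
    stop("binned_rates: interval shorter than one bin")
  nb <- floor(len / bin + 1e-9)
  edges <- interval[1L] + bin * (0:nb)
  tt <- spike_times[spike_times >= edges[1L] & spike_times < edges[nb + 1L]]
  tabulate(findInterval(tt, edges), nbins = nb)
}

#' Lag-resolved delay-period cross-correlation
#'
#' Per trial, Pearson correlation between an ACC cell's and a CA1 ensemble's
#' binned delay-period rates at each lag (vectors shifted, overlap region
#' used, at least 3 overlapping bins), averaged across trials; the lag-0
#' value is the cell's coupling statistic. A positive lag means the ensemble
#' trace is shifted later relative to the ACC trace.
#'
#' @param acc_spikes sorted ACC spike times.
#' @param ens_spikes pooled sorted ensemble spike times.
#' @param delays an [interval_set()] of delay periods (one per trial).
#' @param bin bin width, s (0.200).
#' @param max_lag_bins maximal lag in bins (5, i.e. +/- 1 s at 200 ms).
#' @param mode `"per_trial"` (average of per-trial correlations, default) or
#'   `"pooled"` (bin pairs pooled across trials before one correlation per
#'   lag).
#' @return list with `lags` (bins), `curve` (mean correlation per lag),
#'   `lag0`, `n_trials` (per-lag trial counts for per-trial mode).
#' @export
delay_crosscorr <- function(acc_spikes, ens_spikes, delays, bin = 0.200,
                            max_lag_bins = 5,
                            mode = c("per_trial", "pooled")) {
  mode <- match.arg(mode)
  lags <- -max_lag_bins:max_lag_bins
  nt <- nrow(delays)
  if (nt < 1L) stop("delay_crosscorr: no delay intervals")
  a_list <- e_list <- vector("list", nt)
  for (k in seq_len(nt)) {
    ivk <- c(delays$start[k], delays$end[k])
    a_list[[k]] <- binned_rates(acc_spikes, ivk, bin)
    e_list[[k]] <- binned_rates(ens_spikes, ivk, bin)
  }
  lag_pairs <- function(a, e, lag) {
    nbin <- length(a)
    if (lag >= 0) {
      ia <- seq_len(nbin - lag); ie <- ia + lag
    } else {
      ie <- seq_len(nbin + lag); ia <- ie - lag
    }
    list(a = a[ia], e = e[ie])
  }
  curve <- numeric(length(lags))
  n_used <- integer(length(lags))
  if (mode == "per_trial") {
    for (li in seq_along(lags)) {
      vals <- numeric(0)
      for (k in seq_len(nt)) {
        pr <- lag_pairs(a_list[[k]], e_list[[k]], lags[li])
        if (length(pr$a) >= 3L && stats::sd(pr$a) > 0 && stats::sd(pr$e) > 0)
          vals <- c(vals, stats::cor(pr$a, pr$e))
      }
      curve[li] <- if (length(vals)) mean(vals) else NA_real_
      n_used[li] <- length(vals)
    }
  } else {
    for (li in seq_along(lags)) {
      aa <- ee <- numeric(0)
      for (k in seq_len(nt)) {
        pr <- lag_pairs(a_list[[k]], e_list[[k]], lags[li])
        if (length(pr$a) >= 3L) { aa <- c(aa, pr$a); ee <- c(ee, pr$e) }
      }
      curve[li] <- if (length(aa) >= 3L && stats::sd(aa) > 0 &&
                         stats::sd(ee) > 0) stats::cor(aa, ee) else NA_real_
      n_used[li] <- length(aa)
    }
  }
  list(lags = lags, curve = curve, lag0 = curve[lags == 0],
       n_trials = n_used)
}

#' Ensemble in-SWR firing rate per trial
#'
#' Total pooled ensemble spikes inside the trial's PBEs (those with peak
#' time in the trial's water interval) divided by the total PBE duration;
#' `NA` for trials without PBEs (excluded pairwise from correlations).
#'
#' @param ens_spikes pooled sorted ensemble spike times.
#' @param pbes PBE table from [detect_pbes()].
#' @param trials trial table with `water_start`, `water_end`.
#' @return numeric vector, one rate (Hz) per trial.
#' @export
swr_rate_per_trial <- function(ens_spikes, pbes, trials) {
  out <- rep(NA_real_, nrow(trials))
  for (k in seq_len(nrow(trials))) {
    inw <- pbes$peak_time >= trials$water_start[k] &
      pbes$peak_time < trials$water_end[k]
    if (!any(inw)) next
    iv <- interval_set(pbes$start[inw], pbes$end[inw])
    out[k] <- iv_count(ens_spikes, iv) / iv_total(iv)
  }
  out
}

#' Trial-by-trial Pearson correlation
#'
#' Pairwise-complete Pearson correlation of two per-trial quantities with a
#' one- or two-sided p-value; requires at least 3 complete pairs and
#' nondegenerate variance.
#'
#' @param x,y numeric vectors, one value per trial (NAs allowed).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `r`, `p`, `n` (complete pairs), `flag`.
#' @export
trial_correlation <- function(x, y,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L)
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "too_few_pairs"))
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "zero_variance"))
  ct <- stats::cor.test(x[ok], y[ok], alternative = alternative,
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, flag = NA_character_)
}

#' Battery of ACC-CA1 coupling analyses for a session
#'
#' For every ACC cell selective in the maze, computes against its same- and
#' opposite-side CA1 ensembles:
#' \itemize{
#'   \item `delay_xcorr_lag0` — lag-0 value of the 200 ms delay-period
#'     cross-correlation;
#'   \item `water_swr_trial_corr` — trial-by-trial correlation between the
#'     ACC rate over the whole water period and the ensemble in-SWR rate;
#'   \item `delay_to_swr_trial_corr` — trial-by-trial correlation between
#'     the ACC delay rate and the ensemble in-SWR rate;
#'   \item `delay_to_replay_count_inbound` / `_outbound` — trial-by-trial
#'     correlation between the ACC delay rate and the per-trial replay
#'     counts of the same/opposite inbound or outbound template (if
#'     `replay_counts` supplied);
#'   \item `delay_to_water_self` — the ACC cell's delay rate vs its own
#'     water-period rate (relation `"self"`).
#' }
#' Population summaries per analysis: one-sample t-tests of the same- and
#' opposite-side mean statistic against 0 and a paired t-test same vs
#' opposite, with the per-analysis sidedness recorded as metadata
#' (two-sided for the delay cross-correlation and delay-to-SWR-rate
#' analyses; one-sided for the water-period and replay-count analyses).
#'
#' @param session an `oswm_session`.
#' @param maze_results [session_selectivity()] output for the maze context.
#' @param ensembles [build_ensembles()] output.
#' @param pbes PBE table.
#' @param replay_counts optional matrix from [replay_counts_per_trial()].
#' @param bin cross-correlation bin, s (0.200).
#' @param max_lag_bins lag range in bins (5).
#' @param delay_duration delay length, s (2).
#' @param xcorr_mode per-trial or pooled cross-correlation.
#' @param analyses subset of analysis families to run: any of `"xcorr"`,
#'   `"swr"` (the two in-SWR trial-correlation analyses), `"replay"` (the
#'   replay-count correlations) and `"self"`; default all.
#' @return list with `cells` (long per-cell table: `acc_unit_id`,
#'   `relation`, `analysis`, `r`, `n`) and `population` (per-analysis
#'   summary table).
#' @export
coupling_battery <- function(session, maze_results, ensembles, pbes,
                             replay_counts = NULL, bin = 0.200,
                             max_lag_bins = 5, delay_duration = 2.0,
                             xcorr_mode = c("per_trial", "pooled"),
                             analyses = c("xcorr", "swr", "replay",
                                          "self")) {
  xcorr_mode <- match.arg(xcorr_mode)
  analyses <- match.arg(analyses, several.ok = TRUE)
  trials <- session$trials
  delays <- delay_intervals(trials, delay_duration)
  waters <- water_intervals(session)
  sel <- maze_results[maze_results$label != "nonselective", , drop = FALSE]
  pooled <- function(ids)
    sort(unlist(lapply(ids, function(u) unit_spikes(session, u))))
  ens_spk <- list(left = pooled(ensembles$left),
                  right = pooled(ensembles$right))
  ens_swr <- list(
    left = if (length(ensembles$left))
      swr_rate_per_trial(ens_spk$left, pbes, trials) else NULL,
    right = if (length(ensembles$right))
      swr_rate_per_trial(ens_spk$right, pbes, trials) else NULL)
  sided_of <- c(delay_xcorr_lag0 = "two.sided",
                water_swr_trial_corr = "greater",
                delay_to_swr_trial_corr = "two.sided",
                delay_to_replay_count_inbound = "greater",
                delay_to_replay_count_outbound = "greater",
                delay_to_water_self = "greater")
  rows <- list()
  add <- function(uid, rel, an, r, n)
    rows[[length(rows) + 1L]] <<- data.frame(acc_unit_id = uid,
                                             relation = rel, analysis = an,
                                             r = r, n = n)
  for (j in seq_len(nrow(sel))) {
    uid <- sel$unit_id[j]
    pref <- sel$label[j]
    opp <- if (pref == "left") "right" else "left"
    acc <- unit_spikes(session, uid)
    acc_delay <- vapply(seq_len(nrow(trials)), function(k)
      iv_count(acc, interval_set(delays$start[k], delays$end[k])) /
        (delays$end[k] - delays$start[k]), numeric(1))
    acc_water <- vapply(seq_len(nrow(trials)), function(k)
      iv_count(acc, interval_set(waters$start[k], waters$end[k])) /
        (waters$end[k] - waters$start[k]), numeric(1))
    for (rel in c("same", "opposite")) {
      side <- if (rel == "same") pref else opp
      if (!length(ensembles[[side]])) next
      if ("xcorr" %in% analyses) {
        xc <- delay_crosscorr(acc, ens_spk[[side]], delays, bin,
                              max_lag_bins, xcorr_mode)
        add(uid, rel, "delay_xcorr_lag0", xc$lag0,
            xc$n_trials[xc$lags == 0])
      }
      if ("swr" %in% analyses) {
        tc <- trial_correlation(acc_water, ens_swr[[side]], "greater")
        add(uid, rel, "water_swr_trial_corr", tc$r, tc$n)
        tc <- trial_correlation(acc_delay, ens_swr[[side]], "two.sided")
        add(uid, rel, "delay_to_swr_trial_corr", tc$r, tc$n)
      }
      if ("replay" %in% analyses && !is.null(replay_counts)) {
        tc <- trial_correlation(acc_delay,
                                replay_counts[, paste0(side, "_in")],
                                "greater")
        add(uid, rel, "delay_to_replay_count_inbound", tc$r, tc$n)
        tc <- trial_correlation(acc_delay,
                                replay_counts[, paste0(side, "_out")],
                                "greater")
        add(uid, rel, "delay_to_replay_count_outbound", tc$r, tc$n)
      }
    }
    if ("self" %in% analyses) {
      tc <- trial_correlation(acc_delay, acc_water, "greater")
      add(uid, "self", "delay_to_water_self", tc$r, tc$n)
    }
  }
  cells <- if (length(rows)) do.call(rbind, rows)
  else data.frame(acc_unit_id = character(), relation = character(),
                  analysis = character(), r = numeric(), n = integer())
  ## population summaries
  pop <- list()
  one_t <- function(v, alt) {
    v <- v[!is.na(v)]
    if (length(v) < 3L || stats::sd(v) == 0)
      return(list(mean = if (length(v)) mean(v) else NA_real_,
                  sem = NA_real_, t = NA_real_, p = NA_real_,
                  n = length(v)))
    tt <- stats::t.test(v, mu = 0, alternative = alt)
    list(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
         t = unname(tt$statistic), p = tt$p.value, n = length(v))
  }
  for (an in unique(cells$analysis)) {
    alt <- unname(sided_of[an])
    sub <- cells[cells$analysis == an, , drop = FALSE]
    if (an == "delay_to_water_self") {
      s <- one_t(sub$r, alt)
      pop[[length(pop) + 1L]] <- data.frame(
        analysis = an, relation = "self", mean = s$mean, sem = s$sem,
        t = s$t, p = s$p, n = s$n, sidedness = alt, test = "one_sample_t")
      next
    }
    same <- sub$r[sub$relation == "same"]
    oppo <- sub$r[sub$relation == "opposite"]
    for (rel in c("same", "opposite")) {
      v <- if (rel == "same") same else oppo
      s <- one_t(v, alt)
      pop[[length(pop) + 1L]] <- data.frame(
        analysis = an, relation = rel, mean = s$mean, sem = s$sem,
        t = s$t, p = s$p, n = s$n, sidedness = alt, test = "one_sample_t")
    }
    ## paired same vs opposite over cells with both values
    ids <- intersect(sub$acc_unit_id[sub$relation == "same"],
                     sub$acc_unit_id[sub$relation == "opposite"])
    sv <- sub$r[sub$relation == "same"][match(ids,
            sub$acc_unit_id[sub$relation == "same"])]
    ov <- sub$r[sub$relation == "opposite"][match(ids,
            sub$acc_unit_id[sub$relation == "opposite"])]
    ok <- !is.na(sv) & !is.na(ov)
    if (sum(ok) >= 3L && stats::sd(sv[ok] - ov[ok]) > 0) {
      alt_p <- if (alt == "two.sided") "two.sided" else "greater"
      pt <- stats::t.test(sv[ok], ov[ok], paired = TRUE,
                          alternative = alt_p)
      pop[[length(pop) + 1L]] <- data.frame(
        analysis = an, relation = "same_vs_opposite",
        mean = mean(sv[ok] - ov[ok]),
        sem = stats::sd(sv[ok] - ov[ok]) / sqrt(sum(ok)),
        t = unname(pt$statistic), p = pt$p.value, n = sum(ok),
        sidedness = alt_p, test = "paired_t")
    }
  }
  population <- if (length(pop)) do.call(rbind, pop)
  else data.frame(analysis = character(), relation = character(),
                  mean = numeric(), sem = numeric(), t = numeric(),
                  p = numeric(), n = integer(), sidedness = character(),
                  test = character())
  list(cells = cells, population = population)
}
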