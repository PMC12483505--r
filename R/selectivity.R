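# Trajectory selectivity: per-lap and per-delay firing rates, the
# selectivity index SI = (FR_right - FR_left) / (FR_right + FR_left),
# selective-cell classification by two-sample t-test, same/opposite-side
# population statistics with 1000-fold permutation nulls, and the
# correct-vs-error difference index DI of the same functional form.

#' Running firing rate over lap intervals
#'
#' Spike count during active running (lap intervals minus stop periods)
#' divided by the total running time.
#'
#' @param spike_times sorted numeric spike times.
#' @param laps an [interval_set()] of lap intervals.
#' @param stops optional [interval_set()] of stop periods to exclude.
#' @return rate in Hz.
#' @export
lap_rate <- function(spike_times, laps, stops = NULL) {
  if (!nrow(laps)) stop("lap_rate: empty lap set")
  run <- if (is.null(stops) || !nrow(stops)) laps else iv_subtract(laps, stops)
  dur <- iv_total(run)
  if (dur <= 0) stop("lap_rate: zero running time after stop subtraction")
  iv_count(spike_times, run) / dur
}

#' Selectivity index
#'
#' `SI = (FR_right - FR_left) / (FR_right + FR_left)`, in `[-1, 1]`;
#' -1 is fully left-selective, +1 fully right-selective. `NaN` when both
#' rates are zero (such cells are excluded and logged by callers).
#'
#' @param fr_left,fr_right mean rates, Hz (>= 0). Vectorized.
#' @return SI value(s).
#' @export
selectivity_index <- function(fr_left, fr_right) {
  if (any(fr_left < 0, na.rm = TRUE) || any(fr_right < 0, na.rm = TRUE))
    stop("selectivity_index: rates must be >= 0")
  s <- fr_left + fr_right
  ifelse(s == 0, NaN, (fr_right - fr_left) / s)
}

#' Difference index
#'
#' Same functional form as the selectivity index, applied to correct- vs
#' error-trial rates: `DI = (rate_correct - rate_error) /
#' (rate_correct + rate_error)`. Positive DI means higher rate in correct
#' trials.
#'
#' @param rate_correct,rate_error mean rates, Hz (>= 0). Vectorized.
#' @return DI value(s); `NaN` when both rates are zero.
#' @export
difference_index <- function(rate_correct, rate_error) {
  if (any(rate_correct < 0, na.rm = TRUE) || any(rate_error < 0, na.rm = TRUE))
    stop("difference_index: rates must be >= 0")
  s <- rate_correct + rate_error
  ifelse(s == 0, NaN, (rate_correct - rate_error) / s)
}

#' Classify a cell's side selectivity from per-trial rates
#'
#' Two-sided two-sample t-test (Student's equal-variance by default) on the
#' per-trial rates; the cell is labelled with the higher-rate side when
#' `p < alpha`, otherwise `"nonselective"`.
#'
#' @param left_rates,right_rates per-trial rates, Hz.
#' @param alpha significance level (0.05).
#' @param var_equal Student (TRUE, default) or Welch (FALSE) test.
#' @return list with `fr_left`, `fr_right`, `si`, `t`, `p`, `label`,
#'   `n_left`, `n_right`, `flag` (NA or reason the test was not run).
#' @export
classify_selectivity <- function(left_rates, right_rates, alpha = 0.05,
                                 var_equal = TRUE) {
  nl <- length(left_rates); nr <- length(right_rates)
  fr_l <- if (nl) mean(left_rates) else NA_real_
  fr_r <- if (nr) mean(right_rates) else NA_real_
  si <- if (nl && nr) selectivity_index(fr_l, fr_r) else NA_real_
  out <- list(fr_left = fr_l, fr_right = fr_r, si = si,
              t = NA_real_, p = NA_real_, label = "nonselective",
              n_left = nl, n_right = nr, flag = NA_character_)
  if (nl < 2L || nr < 2L) {
    out$flag <- "insufficient_trials"
    return(out)
  }
  tt <- student_t2(right_rates, left_rates, var_equal = var_equal)
  out$t <- tt$t; out$p <- tt$p
  if (is.na(tt$p)) {
    out$flag <- "degenerate_variance"
  } else if (tt$p < alpha) {
    out$label <- if (fr_r > fr_l) "right" else "left"
  }
  out
}

# Per-trial delay-period rates for a set of units: matrix units x trials.
delay_rate_matrix <- function(session, unit_ids, trials,
                              duration = 2.0) {
  dl <- delay_intervals(trials, duration)
  m <- matrix(NA_real_, length(unit_ids), nrow(trials),
              dimnames = list(unit_ids, NULL))
  for (i in seq_along(unit_ids)) {
    tt <- unit_spikes(session, unit_ids[i])
    lo <- findInterval(dl$start, tt, left.open = TRUE)
    hi <- findInterval(dl$end, tt, left.open = TRUE)
    m[i, ] <- (hi - lo) / (dl$end - dl$start)
  }
  m
}

#' Per-session side-selectivity of all units of a region
#'
#' Computes, for every unit, per-trial firing rates in the requested context
#' and classifies left/right selectivity. Maze rates are lap rates during
#' active running (stop periods excluded, outbound and inbound combined);
#' box rates are delay-period rates. Correct trials only by default,
#' mirroring the maze definition.
#'
#' @param session an `oswm_session`.
#' @param context `"maze"` or `"box"`.
#' @param region unit region to analyze (default `"ACC"`).
#' @param alpha significance level.
#' @param correct_only use correct trials only (default TRUE).
#' @param delay_duration delay-period length, s.
#' @param var_equal Student (TRUE) or Welch t-test.
#' @param v_thresh,min_dur stop-mask parameters (maze context).
#' @return data frame with one row per unit: rates, SI, t, p, label.
#' @export
session_selectivity <- function(session, context = c("maze", "box"),
                                region = "ACC", alpha = 0.05,
                                correct_only = TRUE, delay_duration = 2.0,
                                var_equal = TRUE, v_thresh = 5, min_dur = 3) {
  context <- match.arg(context)
  units <- region_units(session, region)
  trials <- session$trials
  if (correct_only) trials <- trials[trials$correct, , drop = FALSE]
  sides <- trials$side
  if (context == "maze") {
    stops <- stop_mask(session$position, v_thresh, min_dur)
    rates <- matrix(NA_real_, length(units), nrow(trials))
    for (k in seq_len(nrow(trials))) {
      ivk <- session$intervals[
        session$intervals$trial_id == trials$trial_id[k] &
          session$intervals$kind %in% TRAJ_LEVELS[1:4], , drop = FALSE]
      if (!nrow(ivk)) next
      laps <- interval_set(ivk$start, ivk$end)
      run <- if (nrow(stops)) iv_subtract(laps, stops) else laps
      dur <- iv_total(run)
      if (dur <= 0) next
      for (i in seq_along(units))
        rates[i, k] <- iv_count(units[[i]]$t, run) / dur
    }
  } else {
    rates <- delay_rate_matrix(session,
                               vapply(units, `[[`, "", "unit_id"),
                               trials, delay_duration)
  }
  res <- lapply(seq_along(units), function(i) {
    ok <- !is.na(rates[i, ])
    cl <- classify_selectivity(rates[i, ok & sides == "left"],
                               rates[i, ok & sides == "right"],
                               alpha = alpha, var_equal = var_equal)
    data.frame(unit_id = units[[i]]$unit_id, region = region,
               context = context, n_left = cl$n_left, n_right = cl$n_right,
               fr_left = cl$fr_left, fr_right = cl$fr_right, si = cl$si,
               t = cl$t, p = cl$p, label = cl$label,
               flag = cl$flag %||% NA_character_)
  })
  do.call(rbind, res)
}

#' Same-side / opposite-side selectivity fractions and SI correlation
#'
#' Over the maze-selective cells: the fraction whose box selectivity is
#' significant and on the same (or opposite) side as their maze label, plus
#' the Pearson correlation of maze vs box SIs.
#'
#' @param maze_results,box_results outputs of [session_selectivity()] for the
#'   two contexts (matched by `unit_id`).
#' @return list with counts, fractions, and SI correlation `r`, `p`, `n`.
#' @export
same_side_fraction <- function(maze_results, box_results) {
  m <- maze_results[maze_results$label != "nonselective", , drop = FALSE]
  b <- box_results[match(m$unit_id, box_results$unit_id), , drop = FALSE]
  if (any(is.na(b$unit_id)))
    stop("same_side_fraction: box results missing for some maze-selective cells")
  n_sel <- nrow(m)
  same <- b$label != "nonselective" & b$label == m$label
  opp <- b$label != "nonselective" & b$label != m$label
  r <- p <- NA_real_
  if (n_sel >= 3L && stats::sd(m$si) > 0 && stats::sd(b$si) > 0) {
    ct <- stats::cor.test(m$si, b$si, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  } else if (n_sel) {
    warning("same_side_fraction: < 3 selective cells (or degenerate SIs); ",
            "SI correlation skipped")
  }
  list(n_selective = n_sel, n_same = sum(same), n_opposite = sum(opp),
       frac_same = if (n_sel) sum(same) / n_sel else NA_real_,
       frac_opposite = if (n_sel) sum(opp) / n_sel else NA_real_,
       si_r = r, si_p = p)
}

# Vectorized box classification of many cells for one rate matrix
# (rows = cells, cols = trials): Student t by side, returns labels.
box_labels_fast <- function(rates, is_left, alpha = 0.05) {
  nl <- sum(is_left); nr <- sum(!is_left)
  xl <- rates[, is_left, drop = FALSE]
  xr <- rates[, !is_left, drop = FALSE]
  ml <- rowMeans(xl); mr <- rowMeans(xr)
  vl <- rowSums((xl - ml)^2) / (nl - 1)
  vr <- rowSums((xr - mr)^2) / (nr - 1)
  df <- nl + nr - 2
  se <- sqrt((((nl - 1) * vl + (nr - 1) * vr) / df) * (1 / nl + 1 / nr))
  tt <- (mr - ml) / se
  p <- 2 * stats::pt(-abs(tt), df)
  lab <- rep("nonselective", nrow(rates))
  sig <- is.finite(p) & p < alpha
  lab[sig & mr > ml] <- "right"
  lab[sig & mr <= ml] <- "left"
  lab
}

#' Permutation null for the same-side (or opposite-side) fraction
#'
#' Each cell's delay-period rates are permuted across the pooled left+right
#' trials, box selectivity is re-classified, and the same-side fraction is
#' recounted; repeated `n_shuffles` times. The observed fraction is z-scored
#' against this chance-level distribution and converted to a one-sided
#' normal-tail p-value.
#'
#' @param rates matrix of per-trial delay rates, one row per (maze-selective)
#'   cell, columns aligned with `sides`.
#' @param sides character vector of trial sides (`"left"`/`"right"`).
#' @param maze_labels per-cell maze selectivity labels (`"left"`/`"right"`).
#' @param relation count cells whose box label matches (`"same"`) or opposes
#'   (`"opposite"`) the maze label.
#' @param n_shuffles number of permutations (1000).
#' @param alpha box-classification significance level.
#' @param alternative tail for the Z-test (`"greater"` default; use
#'   `"less"` for the opposite-side deficit).
#' @param seed optional RNG seed.
#' @return list of class `perm_null`: `observed`, `null`, `z`, `p`.
#' @export
shuffle_selectivity_null <- function(rates, sides, maze_labels,
                                     relation = c("same", "opposite"),
                                     n_shuffles = 1000, alpha = 0.05,
                                     alternative = c("greater", "less"),
                                     seed = NULL) {
  relation <- match.arg(relation)
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  rates <- as.matrix(rates)
  is_left <- sides == "left"
  nt <- ncol(rates)
  frac_fn <- function(r) {
    lab <- box_labels_fast(r, is_left, alpha)
    sel <- lab != "nonselective"
    if (relation == "same") mean(sel & lab == maze_labels)
    else mean(sel & lab != maze_labels)
  }
  observed <- frac_fn(rates)
  null <- numeric(n_shuffles)
  rp <- rates
  for (s in seq_len(n_shuffles)) {
    for (i in seq_len(nrow(rates))) rp[i, ] <- rates[i, sample.int(nt)]
    null[s] <- frac_fn(rp)
  }
  sd0 <- stats::sd(null)
  if (sd0 == 0) {
    warning("shuffle_selectivity_null: degenerate null; ",
            "using empirical rank p-value")
    z <- NA_real_
    p <- if (alternative == "greater")
      (1 + sum(null >= observed)) / (n_shuffles + 1)
    else (1 + sum(null <= observed)) / (n_shuffles + 1)
  } else {
    z <- (observed - mean(null)) / sd0
    p <- z_to_p(z, alternative)
  }
  structure(list(observed = observed, null = null, z = z, p = p,
                 alternative = alternative, n_shuffles = n_shuffles,
                 relation = relation),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat("perm_null (", x$relation, "-side): observed ",
      format(x$observed, digits = 3), ", null ",
      format(mean(x$null), digits = 3), " +/- ",
      format(stats::sd(x$null), digits = 3), ", Z = ",
      format(x$z, digits = 3), ", p = ", format(x$p, digits = 3),
      " (", x$alternative, ")\n", sep = "")
  invisible(x)
}

#' Correct-vs-error difference-index analysis
#'
#' For every cell with same-side selectivity (maze-selective and box-
#' selective on the same side), compares delay-period rates between correct
#' and error trials on its preferred side (or non-preferred side), provided
#' the session has at least `min_errors` error trials on that side. Reports
#' per-cell DIs, the population mean DI with a two-sided one-sample t-test
#' against 0, and the fraction of cells with an individually significant
#' positive DI against a correct/error label-permutation null.
#'
#' @param session an `oswm_session`.
#' @param maze_results,box_results [session_selectivity()] outputs.
#' @param side `"preferred"` (default) or `"nonpreferred"`.
#' @param min_errors minimal error-trial count per side (3).
#' @param alpha per-cell significance level.
#' @param n_shuffles label permutations for the fraction null (1000).
#' @param delay_duration delay length, s.
#' @param seed optional RNG seed.
#' @return list with `cells` (per-cell table), population statistics and the
#'   permutation null of the significant fraction.
#' @export
correct_error_analysis <- function(session, maze_results, box_results,
                                   side = c("preferred", "nonpreferred"),
                                   min_errors = 3, alpha = 0.05,
                                   n_shuffles = 1000, delay_duration = 2.0,
                                   seed = NULL) {
  side <- match.arg(side)
  if (!is.null(seed)) set.seed(seed)
  m <- maze_results[maze_results$label != "nonselective", , drop = FALSE]
  b <- box_results[match(m$unit_id, box_results$unit_id), , drop = FALSE]
  ss_cells <- m$unit_id[b$label == m$label & b$label != "nonselective"]
  pref <- m$label[match(ss_cells, m$unit_id)]
  if (side == "nonpreferred")
    pref <- ifelse(pref == "left", "right", "left")
  trials <- session$trials
  cells <- list(); rate_store <- list()
  for (j in seq_along(ss_cells)) {
    tsel <- trials$side == pref[j]
    n_err <- sum(tsel & !trials$correct)
    if (n_err < min_errors) next
    tr <- trials[tsel, , drop = FALSE]
    rates <- delay_rate_matrix(session, ss_cells[j], tr, delay_duration)[1L, ]
    rc <- rates[tr$correct]; re <- rates[!tr$correct]
    di <- difference_index(mean(rc), mean(re))
    if (is.nan(di)) next
    tt <- student_t2(rc, re)
    p_one <- if (is.na(tt$p)) NA_real_
             else if (tt$t > 0) tt$p / 2 else 1 - tt$p / 2
    cells[[length(cells) + 1L]] <- data.frame(
      unit_id = ss_cells[j], pref_side = pref[j], n_correct = length(rc),
      n_error = length(re), rate_correct = mean(rc), rate_error = mean(re),
      di = di, p = p_one, sig_positive = !is.na(p_one) && p_one < alpha)
    rate_store[[length(rate_store) + 1L]] <-
      list(rates = rates, is_correct = tr$correct)
  }
  if (!length(cells))
    return(list(cells = data.frame(), n_cells = 0L, mean_di = NA_real_,
                sem_di = NA_real_, t = NA_real_, p = NA_real_,
                frac_sig = NA_real_, null = NULL, z = NA_real_,
                p_frac = NA_real_,
                note = "no eligible cells (>= min_errors error trials)"))
  cells <- do.call(rbind, cells)
  pop <- stats::t.test(cells$di, mu = 0)
  frac_sig <- mean(cells$sig_positive)
  ## permutation null of the significant fraction
  null <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    sig <- vapply(rate_store, function(rs) {
      lab <- sample(rs$is_correct)
      tt <- student_t2(rs$rates[lab], rs$rates[!lab])
      !is.na(tt$p) && tt$t > 0 && tt$p / 2 < alpha
    }, logical(1))
    null[s] <- mean(sig)
  }
  sd0 <- stats::sd(null)
  z <- if (sd0 > 0) (frac_sig - mean(null)) / sd0 else NA_real_
  p_frac <- if (sd0 > 0) z_to_p(z, "greater")
            else (1 + sum(null >= frac_sig)) / (n_shuffles + 1)
  list(cells = cells, n_cells = nrow(cells), mean_di = mean(cells$di),
       sem_di = stats::sd(cells$di) / sqrt(nrow(cells)),
       t = unname(pop$statistic), p = pop$p.value, frac_sig = frac_sig,
       null = null, z = z, p_frac = p_frac)
}
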