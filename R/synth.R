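# Synthetic oSWM session generator with ground truth.
#
# Emulates the structure of an observational spatial working memory session:
# ~40 left/right trials with occasional errors, a delay window whose duration
# peaks near 2 s, CA1 place cells with Gaussian fields on the four linearized
# maze trajectories, ACC cells with side-selective rate steps during delay /
# water / maze running, sharp-wave-ripple population bursts during water
# consumption carrying time-compressed forward or reverse replay sequences,
# and a planted trial-wise lognormal gain that couples each ACC cell to its
# same-side CA1 ensemble. Spiking is inhomogeneous Poisson; replay spikes are
# injected on top of a concurrent multiunit surge so the population-burst
# detector sees the event.

#' Synthetic session parameters
#'
#' Defaults are the study conditions the generator emulates: ~40 trials per
#' session, ~11% error trials, a 2 s delay, ~64 s of maze running per trial,
#' CA1 maze rates inside the 0.4-10 Hz inclusion band.
#'
#' @param n_trials number of trials (default 40).
#' @param p_left probability that the demonstrator chooses left (0.5).
#' @param p_error probability of an error trial (0.11).
#' @param delay_duration analysis delay-period length in s (2.0). The
#'   generated delay window (choice-point crossing to first rewarded poke)
#'   is `delay_duration` plus exponential jitter, so its mode is at 2 s.
#' @param delay_jitter_mean mean of the exponential jitter on the delay
#'   window (0.5 s).
#' @param lap_duration total maze running time per trial, outbound plus
#'   inbound (64 s).
#' @param traj_length linearized trajectory length in cm (200).
#' @param water_duration water-consumption period per trial in s (10).
#' @param n_ca1,n_acc unit counts (32 CA1, 12 ACC; 32 CA1 cells give
#'   8-member templates on each of the four trajectories).
#' @param field_width_sigma CA1 place-field Gaussian width in cm (10).
#' @param field_peak_rate CA1 in-field peak rate above baseline, Hz (8).
#' @param ca1_baseline_rate CA1 background rate, Hz (0.5).
#' @param acc_baseline_rate ACC background rate, Hz (3).
#' @param acc_selectivity_ratio preferred/non-preferred ACC rate ratio in
#'   maze and box (2).
#' @param acc_error_attenuation multiplicative drop of the preferred-side
#'   delay rate in error trials (0.75; 1 = no error effect).
#' @param swr_per_water_period mean number of population bursts per water
#'   period (3).
#' @param mua_burst_gain multiplicative rate surge of non-template CA1
#'   units inside a burst (15), so the population-burst detector sees a
#'   concurrent multiunit surge.
#' @param replay_spikes_extra expected extra field-locked spikes per
#'   template member per replay, on top of the one ordered anchor spike
#'   (2.5). Extras follow the time-compressed virtual traversal of the
#'   trajectory, so member spiking is position-locked. Sequence spikes are
#'   stereotyped (not scaled by the trial gain); the trial-wise excitability
#'   gain rides on the diffuse non-member surge.
#' @param replay_bias probability that an embedded replay uses the current
#'   trial's same-side template (0.7; 0.5 = unbiased).
#' @param replay_duration embedded replay/burst duration in s (0.15).
#' @param replay_jitter_sd timing jitter of replay member spikes in s (0.005).
#' @param coupling_strength correlation of the trial-wise latent gains of
#'   an ACC cell and its same-side CA1 ensemble (0.4; 0 = uncoupled). One
#'   latent excitability series per side drives that side's CA1 in-burst
#'   rates; each ACC cell draws its own gain series correlated with its
#'   preferred side's latent series (applied to the cell's delay and water
#'   rates on every trial), so cells stay conditionally independent given
#'   the ensembles.
#' @param coupling_gain_sd log-scale SD of the trial-wise lognormal gain
#'   (0.35, i.e. roughly +/-35% trial-to-trial rate modulation). Gains are
#'   normalized to mean 1 so they shift no side's mean rate.
#' @param seed RNG seed (integer).
#' @return validated list of class `synth_params`.
#' @export
synth_params <- function(n_trials = 40, p_left = 0.5, p_error = 0.11,
                         delay_duration = 2.0, delay_jitter_mean = 0.5,
                         lap_duration = 64, traj_length = 200,
                         water_duration = 10,
                         n_ca1 = 32, n_acc = 12,
                         field_width_sigma = 10, field_peak_rate = 8,
                         ca1_baseline_rate = 0.5, acc_baseline_rate = 3,
                         acc_selectivity_ratio = 2,
                         acc_error_attenuation = 0.75,
                         swr_per_water_period = 3, mua_burst_gain = 15,
                         replay_spikes_extra = 2.5,
                         replay_bias = 0.7, replay_duration = 0.15,
                         replay_jitter_sd = 0.005,
                         coupling_strength = 0.4, coupling_gain_sd = 0.35,
                         seed = 1L) {
  p <- list(n_trials = n_trials, p_left = p_left, p_error = p_error,
            delay_duration = delay_duration,
            delay_jitter_mean = delay_jitter_mean,
            lap_duration = lap_duration, traj_length = traj_length,
            water_duration = water_duration, n_ca1 = n_ca1, n_acc = n_acc,
            field_width_sigma = field_width_sigma,
            field_peak_rate = field_peak_rate,
            ca1_baseline_rate = ca1_baseline_rate,
            acc_baseline_rate = acc_baseline_rate,
            acc_selectivity_ratio = acc_selectivity_ratio,
            acc_error_attenuation = acc_error_attenuation,
            swr_per_water_period = swr_per_water_period,
            mua_burst_gain = mua_burst_gain,
            replay_spikes_extra = replay_spikes_extra,
            replay_bias = replay_bias,
            replay_duration = replay_duration,
            replay_jitter_sd = replay_jitter_sd,
            coupling_strength = coupling_strength,
            coupling_gain_sd = coupling_gain_sd, seed = seed)
  for (f in c("p_left", "p_error", "replay_bias"))
    if (p[[f]] < 0 || p[[f]] > 1)
      stop("synth_params: '", f, "' must be a probability in [0, 1]")
  for (f in c("field_peak_rate", "ca1_baseline_rate", "acc_baseline_rate",
              "swr_per_water_period", "mua_burst_gain",
              "replay_spikes_extra", "coupling_gain_sd"))
    if (p[[f]] < 0) stop("synth_params: '", f, "' must be >= 0")
  for (f in c("n_trials", "n_ca1", "n_acc"))
    if (p[[f]] < 1 || p[[f]] != round(p[[f]]))
      stop("synth_params: '", f, "' must be a positive integer")
  for (f in c("delay_duration", "lap_duration", "traj_length",
              "water_duration", "field_width_sigma", "replay_duration",
              "acc_selectivity_ratio"))
    if (p[[f]] <= 0) stop("synth_params: '", f, "' must be > 0")
  if (p$acc_error_attenuation < 0 || p$acc_error_attenuation > 1)
    stop("synth_params: 'acc_error_attenuation' must be in [0, 1]")
  if (abs(p$coupling_strength) > 1)
    stop("synth_params: 'coupling_strength' must be a correlation in [-1, 1]")
  structure(p, class = "synth_params")
}

#' Gaussian place-field rate
#'
#' `rate = baseline + peak * exp(-(lin_pos - center)^2 / (2 sigma^2))`.
#'
#' @param lin_pos linearized position(s), cm.
#' @param center field center, cm.
#' @param sigma field width, cm (> 0).
#' @param peak in-field peak rate above baseline, Hz.
#' @param baseline background rate, Hz.
#' @return firing rate(s), Hz; `>= baseline` everywhere.
#' @export
place_field_rate <- function(lin_pos, center, sigma, peak, baseline) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("place_field_rate: 'sigma' must be > 0")
  baseline + peak * exp(-(lin_pos - center)^2 / (2 * sigma^2))
}

#' Simulate an inhomogeneous Poisson spike train by thinning
#'
#' @param rate_fn vectorized function of time returning the rate in Hz.
#' @param interval length-2 numeric, half-open `[start, end)`.
#' @param rate_max a stated upper bound of `rate_fn` on the interval; the
#'   function errors if `rate_fn` exceeds it.
#' @param seed optional seed set before drawing.
#' @return sorted spike times inside the interval.
#' @export
simulate_inhomogeneous_poisson <- function(rate_fn, interval, rate_max,
                                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.finite(rate_max) || rate_max < 0)
    stop("simulate_inhomogeneous_poisson: 'rate_max' must be finite and >= 0")
  len <- interval[2L] - interval[1L]
  if (len <= 0 || rate_max == 0) return(numeric(0))
  n <- stats::rpois(1L, rate_max * len)
  if (n == 0L) return(numeric(0))
  tt <- stats::runif(n, interval[1L], interval[2L])
  r <- rate_fn(tt)
  if (any(r > rate_max * (1 + 1e-8)))
    stop("simulate_inhomogeneous_poisson: rate_fn exceeds 'rate_max'")
  sort(tt[stats::runif(n) < r / rate_max])
}

#' Embed a time-compressed replay sequence
#'
#' Places one spike per template member at times ordered along (forward) or
#' against (reverse) the template position order, compressed into
#' `duration` seconds and jittered.
#'
#' @param template_order character vector of member unit ids in template
#'   position order (>= 4 members, the candidate-event minimum).
#' @param t0 event start, s.
#' @param duration event duration, s (> 0).
#' @param direction `"forward"` or `"reverse"`.
#' @param jitter_sd Gaussian jitter SD on each spike time, s.
#' @param seed optional seed.
#' @return list with `spikes` (data frame `unit_id`, `t`) and `interval`
#'   (the half-open burst interval, for ground-truth bookkeeping).
#' @export
embed_replay <- function(template_order, t0, duration,
                         direction = c("forward", "reverse"),
                         jitter_sd = 0, seed = NULL) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  if (duration <= 0) stop("embed_replay: 'duration' must be > 0")
  m <- length(template_order)
  if (m < 4L) stop("embed_replay: need >= 4 template members")
  ranks <- seq_len(m)
  if (direction == "reverse") ranks <- rev(ranks)
  tt <- t0 + duration * (ranks - 0.5) / m
  if (jitter_sd > 0) tt <- tt + stats::rnorm(m, 0, jitter_sd)
  tt <- pmin(pmax(tt, t0), t0 + duration - 1e-6)
  list(spikes = data.frame(unit_id = template_order, t = tt,
                           stringsAsFactors = FALSE),
       interval = c(t0, t0 + duration))
}

# Piecewise-constant Poisson sampler: one spike burst per (start,end,rate)
# segment, vectorized across segments.
sim_piecewise_spikes <- function(start, end, rate) {
  len <- end - start
  n <- stats::rpois(length(start), rate * len)
  if (!sum(n)) return(numeric(0))
  stats::runif(sum(n)) * rep.int(len, n) + rep.int(start, n)
}

#' Generate a synthetic oSWM session with ground truth
#'
#' @param params a [synth_params()] object.
#' @return list with `session` (an [oswm_session()]) and `truth` (ground
#'   truth: per-unit planted selectivity/fields, per-burst embedded template
#'   and direction, per-trial planted coupling gains).
#' @export
generate_session <- function(params = synth_params()) {
  if (!inherits(params, "synth_params")) params <- do.call(synth_params, params)
  p <- params
  set.seed(p$seed)
  L <- p$traj_length
  half_lap <- p$lap_duration / 2
  v <- L / half_lap  # running speed, cm/s

  ## ---- trial scaffold ------------------------------------------------------
  side <- ifelse(stats::runif(p$n_trials) < p$p_left, "left", "right")
  correct <- stats::runif(p$n_trials) >= p$p_error
  window <- p$delay_duration + stats::rexp(p$n_trials, 1 / p$delay_jitter_mean)
  t_demo_cp <- t_ob_poke <- demo_poke <- w0 <- w1 <-
    out0 <- out1 <- in0 <- in1 <- numeric(p$n_trials)
  cur <- 0
  for (k in seq_len(p$n_trials)) {
    t_demo_cp[k] <- cur + 1
    t_ob_poke[k] <- t_demo_cp[k] + window[k]
    demo_poke[k] <- t_demo_cp[k] + 0.5
    w0[k] <- t_ob_poke[k]
    w1[k] <- w0[k] + p$water_duration
    out0[k] <- w1[k] + 4
    out1[k] <- out0[k] + half_lap
    in0[k] <- out1[k]
    in1[k] <- in0[k] + half_lap
    cur <- in1[k] + 4
  }
  t_end <- cur
  run_side <- ifelse(correct, side, ifelse(side == "left", "right", "left"))
  trials <- data.frame(trial_id = seq_len(p$n_trials), side = side,
                       correct = correct, t_demo_cp = t_demo_cp,
                       t_ob_poke = t_ob_poke, demo_poke_time = demo_poke,
                       water_start = w0, water_end = w1)

  ## ---- coupling gains (trial-wise, mean-1 lognormal) -----------------------
  ## One latent excitability series per side drives that side's CA1
  ## ensemble in-burst rates; each ACC cell gets its own gain series
  ## correlated (coupling_strength) with its preferred side's latent
  ## series, so cells are conditionally independent given the ensembles —
  ## a session-level shared gain would make every population test
  ## anticonservative by construction.
  sdg <- p$coupling_gain_sd
  z_ca1 <- list(left = stats::rnorm(p$n_trials),
                right = stats::rnorm(p$n_trials))
  g_ca1 <- lapply(z_ca1, function(z) exp(sdg * z - sdg^2 / 2))
  rho <- p$coupling_strength
  acc_gain_for <- function(pref) {
    zi <- rho * z_ca1[[pref]] +
      sqrt(max(0, 1 - rho^2)) * stats::rnorm(p$n_trials)
    exp(sdg * zi - sdg^2 / 2)
  }

  ## ---- embedded bursts/replays during water periods ------------------------
  trajs <- c("left_out", "left_in", "right_out", "right_in")
  ca1_traj <- rep_len(trajs, p$n_ca1)
  ca1_center <- stats::runif(p$n_ca1, 0.1 * L, 0.9 * L)
  ca1_ids <- sprintf("ca1_%02d", seq_len(p$n_ca1))
  acc_ids <- sprintf("acc_%02d", seq_len(p$n_acc))
  acc_pref <- rep_len(c("left", "right"), p$n_acc)

  template_members <- lapply(trajs, function(tr) {
    i <- which(ca1_traj == tr)
    i[order(ca1_center[i])]   # indices in template position order
  })
  names(template_members) <- trajs

  ev <- list()
  eid <- 0L
  for (k in seq_len(p$n_trials)) {
    n_e <- stats::rpois(1L, p$swr_per_water_period)
    if (!n_e) next
    slack <- p$water_duration - p$replay_duration - 0.4
    if (slack <= 0) next
    starts <- sort(stats::runif(n_e, w0[k] + 0.2,
                                w0[k] + 0.2 + slack))
    keep <- rep(TRUE, n_e)
    if (n_e > 1L) for (i in 2:n_e)
      if (starts[i] < starts[max(which(keep[1:(i - 1)]))] +
            p$replay_duration + 0.3) keep[i] <- FALSE
    starts <- starts[keep]
    for (s in starts) {
      eid <- eid + 1L
      tside <- if (stats::runif(1) < p$replay_bias) side[k] else
        setdiff(c("left", "right"), side[k])
      tmpl <- paste0(tside, sample(c("_out", "_in"), 1L))
      dirn <- sample(c("forward", "reverse"), 1L)
      ev[[eid]] <- list(event_id = eid, trial_id = k, template = tmpl,
                        direction = dirn, start = s,
                        end = s + p$replay_duration)
    }
  }

  ## ---- CA1 spikes ----------------------------------------------------------
  ## Spike pieces are accumulated in per-unit lists and concatenated once.
  ca1_side <- ifelse(grepl("^left", ca1_traj), "left", "right")
  pieces <- lapply(seq_len(p$n_ca1), function(i) list())
  push <- function(i, x) {
    if (length(x)) pieces[[i]][[length(pieces[[i]]) + 1L]] <<- x
  }
  for (i in seq_len(p$n_ca1)) {
    push(i, sim_piecewise_spikes(0, t_end, p$ca1_baseline_rate))
    ## place-field spikes on this unit's trajectory
    dir_out <- grepl("_out$", ca1_traj[i])
    lap_sel <- if (dir_out) cbind(out0, out1) else cbind(in0, in1)
    for (k in which(run_side == ca1_side[i])) {
      a <- lap_sel[k, 1L]; b <- lap_sel[k, 2L]
      rate_fn <- function(t)
        p$field_peak_rate *
          exp(-(v * (t - a) - ca1_center[i])^2 / (2 * p$field_width_sigma^2))
      push(i, simulate_inhomogeneous_poisson(rate_fn, c(a, b),
                                             p$field_peak_rate))
    }
  }
  ## embedded bursts: template members replay a time-compressed virtual
  ## traversal (one ordered anchor spike each plus field-locked Poisson
  ## extras); non-member CA1 units get an unordered multiunit surge.
  dur <- p$replay_duration
  sigma_t <- p$field_width_sigma / L * dur  # field passage time in a replay
  for (e in ev) {
    k <- e$trial_id
    mem <- template_members[[e$template]]
    if (length(mem) >= 4L) {
      rs <- embed_replay(ca1_ids[mem], e$start, dur, e$direction,
                         p$replay_jitter_sd)
      for (j in seq_along(mem)) {
        i <- mem[j]
        push(i, rs$spikes$t[rs$spikes$unit_id == ca1_ids[i]])
        n_x <- stats::rpois(1L, p$replay_spikes_extra)
        if (n_x) {
          frac <- ca1_center[i] / L
          if (e$direction == "reverse") frac <- 1 - frac
          tx <- stats::rnorm(n_x, e$start + frac * dur, sigma_t)
          push(i, pmin(pmax(tx, e$start), e$end - 1e-6))
        }
      }
    }
    for (i in setdiff(seq_len(p$n_ca1), mem)) {
      gk <- g_ca1[[ca1_side[i]]][k]
      surge <- p$ca1_baseline_rate * p$mua_burst_gain * gk
      push(i, sim_piecewise_spikes(e$start, e$end, surge))
    }
  }
  ca1_units <- lapply(pieces, function(ps) unlist(ps, use.names = FALSE))

  ## ---- ACC spikes ----------------------------------------------------------
  acc_units <- vector("list", p$n_acc)
  base <- p$acc_baseline_rate
  acc_gains <- matrix(NA_real_, p$n_acc, p$n_trials,
                      dimnames = list(acc_ids, NULL))
  for (i in seq_len(p$n_acc)) {
    pref <- acc_pref[i]
    gk <- acc_gain_for(pref)
    acc_gains[i, ] <- gk
    d_rate <- gk * ifelse(side == pref,
                          base * p$acc_selectivity_ratio *
                            ifelse(correct, 1, p$acc_error_attenuation),
                          base)
    w_rate <- gk * ifelse(side == pref,
                          base * p$acc_selectivity_ratio, base)
    lap_rate_out <- ifelse(run_side == pref,
                           base * p$acc_selectivity_ratio, base)
    seg_s <- c(t_ob_poke - p$delay_duration, w0, out0, in0)
    seg_e <- c(t_ob_poke, w1, out1, in1)
    seg_r <- c(d_rate, w_rate, lap_rate_out, lap_rate_out)
    tt <- sim_piecewise_spikes(seg_s, seg_e, seg_r)
    ## baseline in the complement of the override segments
    ov <- interval_set(seg_s, seg_e)
    comp <- iv_subtract(interval_set(0, t_end), ov)
    tt <- c(tt, sim_piecewise_spikes(comp$start, comp$end, base))
    acc_units[[i]] <- tt
  }

  ## ---- position series -----------------------------------------------------
  tp <- seq(0, t_end, by = 1 / 30)
  np <- length(tp)
  traj_id <- rep("none", np)
  lin <- rep(NA_real_, np)
  x <- -30 + cumsum(stats::rnorm(np, 0, 0.03))
  y <- cumsum(stats::rnorm(np, 0, 0.03))
  for (k in seq_len(p$n_trials)) {
    io <- which(tp >= out0[k] & tp < out1[k])
    ii <- which(tp >= in0[k] & tp < in1[k])
    traj_id[io] <- paste0(run_side[k], "_out")
    traj_id[ii] <- paste0(run_side[k], "_in")
    lin[io] <- v * (tp[io] - out0[k])
    lin[ii] <- v * (tp[ii] - in0[k])
    ys <- if (run_side[k] == "left") 15 else -15
    x[io] <- lin[io]
    x[ii] <- L - lin[ii]
    y[c(io, ii)] <- ys
  }
  position <- data.frame(t = tp, x = x, y = y, traj_id = traj_id,
                         lin_pos = lin)

  ## ---- intervals table -----------------------------------------------------
  iv <- rbind(
    data.frame(trial_id = seq_len(p$n_trials), kind = "delay",
               start = t_ob_poke - p$delay_duration, end = t_ob_poke),
    data.frame(trial_id = seq_len(p$n_trials), kind = "water",
               start = w0, end = w1),
    data.frame(trial_id = seq_len(p$n_trials),
               kind = paste0(run_side, "_out"), start = out0, end = out1),
    data.frame(trial_id = seq_len(p$n_trials),
               kind = paste0(run_side, "_in"), start = in0, end = in1))

  ## ---- assemble ------------------------------------------------------------
  units <- c(
    lapply(seq_len(p$n_acc), function(i)
      spike_train(acc_ids[i], "ACC", unique(sort(acc_units[[i]])))),
    lapply(seq_len(p$n_ca1), function(i)
      spike_train(ca1_ids[i], "CA1", unique(sort(ca1_units[[i]])))))
  session <- oswm_session("Demo", units, position, trials, iv,
                          meta = list(generator = "oswm synthetic",
                                      seed = p$seed))

  si_mag <- (p$acc_selectivity_ratio - 1) / (p$acc_selectivity_ratio + 1)
  truth_units <- rbind(
    data.frame(unit_id = acc_ids, region = "ACC", pref_side = acc_pref,
               traj_id = NA_character_, field_center = NA_real_,
               expected_si = ifelse(acc_pref == "right", si_mag, -si_mag)),
    data.frame(unit_id = ca1_ids, region = "CA1",
               pref_side = ca1_side, traj_id = ca1_traj,
               field_center = ca1_center, expected_si = NA_real_))
  truth_replays <- if (length(ev)) do.call(rbind, lapply(ev, function(e)
    data.frame(event_id = e$event_id, trial_id = e$trial_id,
               template = e$template, direction = e$direction,
               start = e$start, end = e$end,
               n_members = length(template_members[[e$template]]),
               member_order = paste(
                 ca1_ids[template_members[[e$template]]], collapse = ";"))))
  else data.frame(event_id = integer(), trial_id = integer(),
                  template = character(), direction = character(),
                  start = numeric(), end = numeric(),
                  n_members = integer(), member_order = character())
  truth_trials <- data.frame(trial_id = seq_len(p$n_trials), side = side,
                             correct = correct,
                             g_ca1_left = g_ca1$left,
                             g_ca1_right = g_ca1$right)
  truth <- structure(list(units = truth_units, replays = truth_replays,
                          trials = truth_trials, acc_gains = acc_gains,
                          params = p,
                          replay_compression =
                            (L / p$replay_duration) / v),
                     class = "oswm_truth")
  list(session = session, truth = truth)
}

#' @export
print.oswm_truth <- function(x, ...) {
  cat("oswm_truth:", nrow(x$units), "units,", nrow(x$replays),
      "embedded replays,", nrow(x$trials), "trials\n")
  invisible(x)
}

#' Write a synthetic bundle (session plus ground truth) to disk
#'
#' @param params a [synth_params()] object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(params, dir) {
  gs <- generate_session(params)
  write_session(gs$session, dir)
  tu <- gs$truth$units
  tu$field_center <- fmt_num(tu$field_center)
  tu$expected_si <- fmt_num(tu$expected_si)
  write_table_stable(tu, file.path(dir, "groundtruth_units.csv"))
  tr <- gs$truth$replays
  tr$start <- fmt_num(tr$start); tr$end <- fmt_num(tr$end)
  write_table_stable(tr, file.path(dir, "groundtruth_replays.csv"))
  tt <- gs$truth$trials
  for (cn in c("g_ca1_left", "g_ca1_right"))
    tt[[cn]] <- fmt_num(tt[[cn]])
  tt$correct <- as.integer(tt$correct)
  write_table_stable(tt, file.path(dir, "groundtruth_trials.csv"))
  ag <- gs$truth$acc_gains
  write_table_stable(
    data.frame(unit_id = rep(rownames(ag), each = ncol(ag)),
               trial_id = rep(seq_len(ncol(ag)), times = nrow(ag)),
               gain = fmt_num(as.numeric(t(ag)))),
    file.path(dir, "groundtruth_acc_gains.csv"))
  invisible(dir)
}
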