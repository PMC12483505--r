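test_that("binned rates tile the interval half-open and conserve spikes", {
  expect_length(binned_rates(numeric(0), c(0, 2), 0.2), 10L)
  spk <- c(0.05, 0.1, 0.25, 1.99)
  b <- binned_rates(spk, c(0, 2), 0.2)
  expect_equal(sum(b), 4L)
  expect_equal(b[1], 2L)
  expect_error(binned_rates(1, c(0, 0.1), 0.2), "shorter than one bin")
  ## ensemble aggregation is plain pooling
  ens <- sort(c(runif(3, 0, 0.2), runif(4, 0, 0.2)))
  expect_equal(sum(binned_rates(ens, c(0, 0.2), 0.2)), 7L)
})

test_that("cross-correlation peaks at the planted lag", {
  set.seed(71)
  delays <- interval_set(seq(0, by = 10, length.out = 20),
                         seq(2, by = 10, length.out = 20))
  ## identical spike trains: lag-0 correlation 1
  acc <- sort(unlist(lapply(delays$start, function(s)
    s + c(0.05, 0.35, 0.41, 1.13, 1.62, runif(3, 0, 2)))))
  xc <- delay_crosscorr(acc, acc, delays)
  expect_equal(xc$lag0, 1)
  ## ensemble shifted by +1 bin: curve peak at lag +1, not 0
  ens <- sort(acc + 0.2)
  xc2 <- delay_crosscorr(acc, ens, delays)
  expect_equal(xc2$lags[which.max(xc2$curve)], 1)
  ## independent Poisson trains decorrelate
  acc3 <- sort(runif(400, 0, 200))
  ens3 <- sort(runif(400, 0, 200))
  xc3 <- delay_crosscorr(acc3, ens3, delays)
  expect_lt(abs(xc3$lag0), 3 / sqrt(20 * 10))
  ## pooled mode agrees qualitatively
  xcp <- delay_crosscorr(acc, acc, delays, mode = "pooled")
  expect_equal(xcp$lag0, 1)
})

test_that("in-SWR ensemble rates divide pooled spikes by PBE time", {
  trials <- data.frame(trial_id = 1:2, water_start = c(0, 100),
                       water_end = c(10, 110))
  pbes <- data.frame(event_id = 1:3, start = c(1, 3, 200),
                     end = c(1.3, 3.2, 200.5),
                     peak_time = c(1.1, 3.1, 200.2), peak_value = 1)
  ens <- c(seq(1.01, 1.29, length.out = 6), seq(3.01, 3.19, length.out = 4))
  r <- swr_rate_per_trial(ens, pbes, trials)
  expect_equal(r[1], 10 / 0.5)
  expect_true(is.na(r[2]))   # no PBEs in trial 2's water period
  expect_equal(swr_rate_per_trial(numeric(0), pbes, trials)[1], 0)
})

test_that("trial correlations are pairwise-complete with sidedness", {
  x <- c(1, 2, 3, 4, NA, 6)
  expect_equal(trial_correlation(x, x)$r, 1)
  expect_equal(trial_correlation(x, -x)$r, -1)
  expect_equal(trial_correlation(x, x)$n, 5L)
  expect_equal(trial_correlation(c(1, 2, NA), c(1, 2, 3))$flag,
               "too_few_pairs")
  expect_equal(trial_correlation(rep(1, 5), 1:5)$flag, "zero_variance")
  set.seed(81)
  ## bivariate normal rho = 0.5: mean estimate near 0.5
  rs <- replicate(400, {
    z <- rnorm(40); w <- 0.5 * z + sqrt(0.75) * rnorm(40)
    trial_correlation(z, w)$r
  })
  expect_lt(abs(mean(rs) - 0.5), 3 * sd(rs) / sqrt(400))
  ## one-sided p is half the two-sided p for a positive r
  a <- rnorm(30); b <- a + rnorm(30)
  expect_equal(trial_correlation(a, b, "greater")$p,
               cor.test(a, b, alternative = "greater")$p.value)
})

test_that("coupling battery reports an identity ensemble at lag-0 r = 1", {
  ## tiny hand-built session: one ACC cell and a CA1 'ensemble' firing
  ## identically during delays
  nt <- 6
  poke <- seq(10, by = 20, length.out = nt)
  trials <- data.frame(trial_id = 1:nt,
                       side = rep(c("left", "right"), 3),
                       correct = TRUE, t_demo_cp = poke - 3,
                       t_ob_poke = poke, demo_poke_time = poke - 2.5,
                       water_start = poke, water_end = poke + 5)
  spk <- sort(unlist(lapply(poke, function(pk)
    pk - 2 + c(0.01, 0.1, 0.32, 0.55, 0.61, 1.15, 1.22, 1.74, 1.91))))
  units <- list(spike_train("acc_1", "ACC", spk),
                spike_train("ca1_1", "CA1", spk + 1e-4))
  pos <- data.frame(t = seq(0, 130, by = 1 / 30), x = 0, y = 0,
                    traj_id = "none", lin_pos = NA_real_, speed = 0)
  iv <- data.frame(trial_id = rep(1:nt, 2),
                   kind = rep(c("delay", "water"), each = nt),
                   start = c(poke - 2, poke), end = c(poke, poke + 5))
  s <- oswm_session("Demo", units, pos, trials, iv)
  maze_df <- data.frame(unit_id = "acc_1", label = "left")
  ens <- list(left = "ca1_1", right = character())
  cb <- coupling_battery(s, maze_df, ens,
                         pbes = data.frame(event_id = integer(),
                                           start = numeric(),
                                           end = numeric(),
                                           peak_time = numeric(),
                                           peak_value = numeric()))
  lag0 <- cb$cells[cb$cells$analysis == "delay_xcorr_lag0" &
                     cb$cells$relation == "same", ]
  expect_equal(lag0$r, 1)
  ## self-continuation is defined even without PBEs
  self <- cb$cells[cb$cells$analysis == "delay_to_water_self", ]
  expect_equal(nrow(self), 1L)
})

test_that("planted trial-wise coupling separates same from opposite side", {
  ## neutral grid (no side rate asymmetry, ground-truth labels) so the
  ## planted gain correlation is the only same/opposite difference
  gs <- generate_session(synth_params(n_trials = 40, p_error = 0,
                                      n_acc = 10, n_ca1 = 16,
                                      lap_duration = 12,
                                      water_duration = 10,
                                      swr_per_water_period = 4,
                                      acc_baseline_rate = 12,
                                      mua_burst_gain = 45,
                                      acc_selectivity_ratio = 1,
                                      replay_bias = 0.5,
                                      coupling_strength = 0.6, seed = 91L))
  s <- gs$session
  stops <- stop_mask(s$position)
  st <- smooth_standardize(bin_mua(s))
  pbes <- detect_pbes(st)
  templates <- lapply(stats::setNames(nm = c("left_out", "left_in",
                                             "right_out", "right_in")),
                      function(tr) {
    curves <- list()
    for (u in region_units(s, "CA1")) {
      cv <- tryCatch(linearized_rate_curve(u$t, s$position, tr,
                                           stops = stops),
                     error = function(e) NULL)
      if (!is.null(cv)) curves[[u$unit_id]] <- cv
    }
    build_template(curves)
  })
  ens <- build_ensembles(templates)
  tu <- gs$truth$units
  labels <- data.frame(unit_id = tu$unit_id[tu$region == "ACC"],
                       label = tu$pref_side[tu$region == "ACC"])
  cb <- coupling_battery(s, labels, ens, pbes, analyses = "swr")
  pop <- cb$population
  same <- pop$mean[pop$analysis == "delay_to_swr_trial_corr" &
                     pop$relation == "same"]
  opp <- pop$mean[pop$analysis == "delay_to_swr_trial_corr" &
                    pop$relation == "opposite"]
  expect_gt(same, opp)
  expect_gt(same, 0.1)
})

test_that("same/opposite statistics are invariant to a global side swap", {
  gs <- generate_session(light_params(n_ca1 = 16, seed = 101L))
  s <- gs$session
  swap <- function(x) ifelse(x == "left", "right",
                             ifelse(x == "right", "left", x))
  swap_traj <- function(x) {
    out <- x
    out[x == "left_out"] <- "right_out"; out[x == "right_out"] <- "left_out"
    out[x == "left_in"] <- "right_in"; out[x == "right_in"] <- "left_in"
    out
  }
  s2 <- s
  s2$trials$side <- swap(s2$trials$side)
  s2$position$traj_id <- swap_traj(s2$position$traj_id)
  s2$intervals$kind <- swap_traj(s2$intervals$kind)
  cfg <- pipeline_config(n_shuffles = 50, seed = 7L)
  r1 <- run_analysis(s, cfg, withr::local_tempdir())
  r2 <- run_analysis(s2, cfg, withr::local_tempdir())
  ## replay-count analyses depend on shuffle draws whose RNG alignment
  ## changes under relabeling; the deterministic analyses must be bitwise
  ## label-symmetric.
  det <- c("delay_xcorr_lag0", "water_swr_trial_corr",
           "delay_to_swr_trial_corr", "delay_to_water_self")
  key <- function(m) {
    m <- m[m$analysis %in% det, ]
    m[order(m$acc_unit_id, m$analysis, m$relation), ]
  }
  m1 <- key(r1$coupling$cells); m2 <- key(r2$coupling$cells)
  expect_equal(m1$relation, m2$relation)
  expect_equal(m1$r, m2$r, tolerance = 1e-9)
})
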