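# Position series helper: repeated traversals of one trajectory at constant
# speed, 30 Hz sampling.
mk_traversals <- function(n_laps = 10, L = 100, lap_dur = 20, gap = 5,
                          traj = "left_out") {
  t <- x <- numeric(0); id <- character(0)
  cur <- 0
  for (k in seq_len(n_laps)) {
    tk <- seq(cur, cur + lap_dur - 1e-9, by = 1 / 30)
    t <- c(t, tk)
    x <- c(x, L * (tk - cur) / lap_dur)
    id <- c(id, rep(traj, length(tk)))
    cur <- cur + lap_dur + gap
  }
  data.frame(t = t, x = x, y = 0, traj_id = id, lin_pos = x,
             speed = L / lap_dur)
}

test_that("rate curves are flat for constant-rate units and localized for fields", {
  set.seed(51)
  pos <- mk_traversals(n_laps = 30)
  ## constant 4 Hz during traversals
  laps <- interval_set(seq(0, by = 25, length.out = 30),
                       seq(20, by = 25, length.out = 30))
  spk <- sort(unlist(lapply(seq_len(nrow(laps)), function(k)
    runif(rpois(1, 4 * 20), laps$start[k], laps$end[k]))))
  cv <- linearized_rate_curve(spk, pos, "left_out")
  expect_true(all(cv$valid))
  expect_lt(max(abs(cv$rate - 4)), 1.5)   # sampling error bound
  expect_lt(cv$peak, cv$mean + 3 * cv$sd) # flat curves never pass 3 SD
  ## a Gaussian field at 50 cm decodes its center within one bin
  rate_fn <- function(t) {
    xx <- approx(pos$t, pos$lin_pos, t, rule = 2)$y
    place_field_rate(xx, 50, 8, 10, 0.2)
  }
  spk2 <- sort(unlist(lapply(seq_len(nrow(laps)), function(k)
    simulate_inhomogeneous_poisson(rate_fn,
                                   c(laps$start[k], laps$end[k]), 10.2))))
  cv2 <- linearized_rate_curve(spk2, pos, "left_out")
  expect_lt(abs(cv2$x[which.max(cv2$rate)] - 50), 4)
  expect_gt(cv2$peak, 3 * cv2$mean)
  ## no spikes: all-zero curve
  cv0 <- linearized_rate_curve(numeric(0), pos, "left_out")
  expect_true(all(cv0$rate[cv0$valid] == 0))
  expect_error(linearized_rate_curve(1, pos, "right_in"), "no traversal")
})

test_that("template inclusion follows the 3 SD peak criterion", {
  flat <- rate_curve("left_out", seq(1, 99, 2), rep(5, 50))
  zero <- rate_curve("left_out", seq(1, 99, 2), rep(0, 50))
  field <- rate_curve("left_out", seq(1, 99, 2),
                      0.5 + 10 * exp(-(seq(1, 99, 2) - 40)^2 / 50))
  tm <- build_template(list(a = flat, b = zero, c = field))
  expect_equal(tm$unit_ids, "c")
  expect_equal(nrow(tm$rates), 1L)
  empty <- build_template(list(a = flat, b = zero))
  expect_length(empty$unit_ids, 0L)
})

test_that("ensembles are set unions of inbound and outbound members", {
  mk <- function(ids) list(traj = "x", unit_ids = ids)
  ens <- build_ensembles(list(left_out = mk(c("a", "b")),
                              left_in = mk(c("b", "c")),
                              right_out = mk(character()),
                              right_in = mk(c("b", "d"))))
  expect_setequal(ens$left, c("a", "b", "c"))
  expect_setequal(ens$right, c("b", "d"))
  expect_length(build_ensembles(list())$left, 0L)
})

test_that("candidate events need at least four active template members", {
  tmpl <- list(traj = "left_out", unit_ids = paste0("u", 1:6),
               x = seq(1, 99, 2),
               rates = matrix(1, 6, 50))
  pbes <- data.frame(event_id = 1:2, start = c(0, 10), end = c(1, 11),
                     peak_time = c(0.5, 10.5), peak_value = 0.5)
  spikes <- list(u1 = c(0.1, 10.1), u2 = c(0.2, 10.2), u3 = c(0.3, 10.3),
                 u4 = c(10.4), u5 = numeric(0), u6 = numeric(0))
  cand <- find_candidates(pbes, tmpl, spikes, min_active = 4)
  expect_equal(cand$event_id, 2L)   # event 1 has 3 active members
  expect_equal(cand$n_active, 4L)
})

test_that("the Poisson decoder normalizes posteriors and matches a direct product", {
  x <- seq(1, 99, 2)
  set.seed(61)
  for (rep in 1:10) {
    m <- sample(4:7, 1)
    rates <- matrix(runif(m * length(x), 0.1, 15), m)
    tmpl <- list(traj = "left_out", unit_ids = paste0("u", 1:m), x = x,
                 rates = rates)
    spikes <- lapply(seq_len(m), function(i) sort(runif(rpois(1, 6), 0, 0.2)))
    names(spikes) <- tmpl$unit_ids
    de <- decode_event(list(event_id = 1L, start = 0, end = 0.2), tmpl,
                       spikes)
    expect_true(all(abs(colSums(de$posterior) - 1) < 1e-9))
    ## direct-product oracle on each window
    for (w in seq_along(de$window_start)) {
      tau_w <- de$window_len[w]
      n <- de$counts[, w]
      lik <- vapply(seq_along(x), function(b) {
        f <- pmax(rates[, b], 1e-3)
        prod((tau_w * f)^n * exp(-tau_w * f))
      }, numeric(1))
      expect_equal(de$posterior[, w], lik / sum(lik), tolerance = 1e-9)
    }
  }
})

test_that("degenerate templates decode to the forced answer", {
  x <- seq(1, 99, 2)
  ## constant rates: posterior uniform over positions in spiking windows
  tmpl <- list(traj = "left_out", unit_ids = "u1", x = x,
               rates = matrix(3, 1, 50))
  de <- decode_event(list(start = 0, end = 0.1), tmpl,
                     list(u1 = c(0.01, 0.05)))
  expect_true(all(abs(de$posterior - 1 / 50) < 1e-12))
  ## near-delta field: a lone spike decodes to the field position
  r <- rep(1e-3, 50); r[25] <- 50
  tmpl2 <- list(traj = "left_out", unit_ids = "u1", x = x,
                rates = matrix(r, 1, 50))
  de2 <- decode_event(list(start = 0, end = 0.04), tmpl2,
                      list(u1 = 0.01))
  expect_equal(unique(de2$decoded[de2$included]), x[25])
})

test_that("shuffle significance flags monotone sequences and not noise", {
  de <- list(decoded = seq(10, 100, by = 10), included = rep(TRUE, 10),
             n_windows = 10L)
  class(de) <- "decoded_event"
  rs <- replay_significance(de, n_shuffles = 1000, seed = 3L)
  expect_equal(rs$r, 1)
  expect_lt(rs$p, 0.01)
  expect_true(rs$is_replay)
  expect_equal(rs$direction, "forward")
  ## the reversed sequence has the same two-sided p and reverse direction
  de$decoded <- rev(de$decoded)
  rv <- replay_significance(de, n_shuffles = 1000, seed = 3L)
  expect_equal(rv$r, -1)
  expect_equal(rv$p, rs$p)
  expect_equal(rv$direction, "reverse")
  ## constant positions are flagged, never significant
  de$decoded <- rep(5, 10)
  rc <- replay_significance(de, n_shuffles = 100, seed = 1L)
  expect_false(rc$is_replay)
  expect_equal(rc$flag, "constant_positions")
  ## fewer than 4 windows is insufficient
  de$decoded <- c(1, 2, 3); de$included <- rep(TRUE, 3)
  ri <- replay_significance(de, n_shuffles = 100, seed = 1L)
  expect_equal(ri$flag, "insufficient_windows")
  ## p can never be 0 or exceed 1
  expect_true(rs$p > 0 && rs$p <= 1)
})

test_that("one-sided significance follows the greater-than-actual convention", {
  de <- list(decoded = seq(10, 100, by = 10), included = rep(TRUE, 10),
             n_windows = 10L)
  class(de) <- "decoded_event"
  fw <- replay_significance(de, n_shuffles = 500, seed = 5L,
                            sided = "one.sided")
  expect_lt(fw$p, 0.05)
  de$decoded <- rev(de$decoded)
  rv <- replay_significance(de, n_shuffles = 500, seed = 5L,
                            sided = "one.sided")
  expect_gt(rv$p, 0.95)   # reverse sequences sit in the far tail
})

test_that("per-trial replay counts are keyed by water interval and template", {
  trials <- data.frame(trial_id = 1:8,
                       water_start = seq(0, by = 100, length.out = 8),
                       water_end = seq(10, by = 100, length.out = 8))
  dec <- data.frame(event_id = 1:3, template = c("left_in", "left_in",
                                                 "right_out"),
                    peak_time = c(605, 303, 304), is_replay = c(TRUE, FALSE,
                                                                TRUE))
  cnt <- replay_counts_per_trial(trials, dec)
  expect_equal(sum(cnt), 2L)
  expect_equal(unname(cnt[7, "left_in"]), 1L)
  expect_equal(unname(cnt[4, "right_out"]), 1L)
  expect_true(all(replay_counts_per_trial(trials, dec[dec$is_replay == FALSE,
                                                      ]) == 0L))
})

test_that("embedded replays are recovered with the correct direction", {
  gs <- replay_session()
  s <- gs$session
  stops <- stop_mask(s$position)
  spikes <- stats::setNames(lapply(s$units, `[[`, "t"),
                            vapply(s$units, `[[`, "", "unit_id"))
  st <- smooth_standardize(bin_mua(s))
  pbes <- restrict_events(detect_pbes(st), water_intervals(s))
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
  dec <- decode_session_replays(pbes, templates, spikes, n_shuffles = 500,
                                seed = 7L)
  tr <- gs$truth$replays
  own <- merge(dec, tr, by = "template")
  own <- own[own$peak_time >= own$start & own$peak_time <= own$end, ]
  expect_gt(nrow(own), 10)
  expect_gte(mean(own$is_replay), 0.9)
  sig <- own[own$is_replay, ]
  expect_gte(mean(sig$direction.x == sig$direction.y), 0.95)
})
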