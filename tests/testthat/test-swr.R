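test_that("MUA binning is half-open and conserves spikes", {
  tr <- bin_mua(c(0.001, 0.002, 0.003, 0.025), bin = 0.01,
                t_range = c(0, 0.05))
  expect_equal(tr$counts, c(3L, 0L, 1L, 0L, 0L))
  ## a spike exactly on a bin edge goes to the later bin
  tr2 <- bin_mua(c(0.02), bin = 0.01, t_range = c(0, 0.05))
  expect_equal(which(tr2$counts == 1L), 3L)
  set.seed(5)
  spk <- sort(runif(500, 0, 3))
  tr3 <- bin_mua(spk, bin = 0.01, t_range = c(0, 3.2))
  expect_equal(sum(tr3$counts), 500L)
  expect_warning(bin_mua(numeric(0), t_range = c(0, 1)), "no CA1 spikes")
})

test_that("Gaussian smoothing matches a direct truncated-kernel sum", {
  direct <- function(x, sigma) {
    half <- ceiling(4 * sigma)
    k <- dnorm(-half:half, sd = sigma); k <- k / sum(k)
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      js <- max(1, i - half):min(n, i + half)
      w <- k[js - i + half + 1]
      out[i] <- sum(x[js] * w) / sum(w)
    }
    out
  }
  set.seed(6)
  for (sigma in c(1, 2, 3.5)) {
    x <- rpois(200, 2)
    expect_equal(gauss_smooth(x, sigma), direct(x, sigma),
                 tolerance = 1e-12)
  }
  ## constants are preserved exactly, including at the edges
  expect_equal(gauss_smooth(rep(4, 50), 2), rep(4, 50))
  ## a single impulse becomes a Gaussian bump peaking at the impulse
  x <- numeric(101); x[51] <- 1
  sm <- gauss_smooth(x, 2)
  expect_equal(which.max(sm), 51L)
  expect_equal(sm[51 + 0:8] / sm[51], dnorm(0:8, sd = 2) / dnorm(0, sd = 2),
               tolerance = 1e-9)
})

test_that("standardization maps the trace onto [0, 1]", {
  tr <- bin_mua(c(0.005, 0.015, 0.015), bin = 0.01, t_range = c(0, 0.2))
  st <- smooth_standardize(tr)
  expect_equal(min(st$values), 0)
  expect_equal(max(st$values), 1)
  flat <- bin_mua(0.005, bin = 0.01, t_range = c(0, 0.1))
  flat$counts <- rep(2L, length(flat$counts))
  expect_warning(st2 <- smooth_standardize(flat), "constant")
  expect_true(all(st2$values == 0))
})

test_that("PBE detection finds thresholded bumps and merges close ones", {
  mk_trace <- function(values, bin = 0.01)
    structure(list(time = (seq_along(values) - 0.5) * bin,
                   counts = values, bin = bin, values = values),
              class = "mua_trace")
  expect_equal(nrow(detect_pbes(mk_trace(rep(0, 100)))), 0L)
  ## one bump with known edge bins
  v <- rep(0, 60)
  v[20:30] <- c(0.16, 0.2, 0.3, 0.4, 0.5, 0.45, 0.35, 0.25, 0.18, 0.16, 0.15)
  ev <- detect_pbes(mk_trace(v))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, (20 - 1) * 0.01)
  expect_equal(ev$end, 30 * 0.01)
  expect_equal(ev$peak_value, 0.5)
  expect_equal(ev$peak_time, (24 - 0.5) * 0.01)
  ## sub-peak bumps above the edge threshold alone are not events
  v2 <- rep(0, 50); v2[10:14] <- 0.2
  expect_equal(nrow(detect_pbes(mk_trace(v2))), 0L)
  ## two supra-threshold bumps separated by 20 ms merge into one
  v3 <- rep(0, 80)
  v3[20:24] <- 0.5
  v3[27:31] <- 0.6   # gap of 2 bins = 20 ms < 30 ms
  ev3 <- detect_pbes(mk_trace(v3))
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$peak_value, 0.6)
  ## a 40 ms gap stays two events
  v4 <- rep(0, 80)
  v4[20:24] <- 0.5
  v4[29:33] <- 0.6
  expect_equal(nrow(detect_pbes(mk_trace(v4))), 2L)
})

test_that("event restriction keeps peaks inside half-open intervals", {
  ev <- data.frame(event_id = 1:3, start = c(0, 5, 9), end = c(1, 6, 10),
                   peak_time = c(0.5, 5.5, 10), peak_value = 1)
  expect_equal(nrow(restrict_events(ev, interval_set())), 0L)
  keep <- restrict_events(ev, interval_set(c(0, 5), c(2, 10)))
  expect_equal(keep$event_id, 1:2)   # peak at 10 = interval end is excluded
  all_in <- restrict_events(ev, interval_set(0, 100))
  expect_equal(nrow(all_in), 3L)
})

test_that("detected events on synthetic sessions cover the embedded bursts", {
  gs <- replay_session()
  st <- smooth_standardize(bin_mua(gs$session))
  ev <- detect_pbes(st)
  expect_true(all(ev$peak_value >= 0.35))
  ## no overlap after merging
  if (nrow(ev) > 1L)
    expect_true(all(ev$start[-1] >= ev$end[-nrow(ev)]))
  tr <- gs$truth$replays
  hit <- vapply(seq_len(nrow(tr)), function(i)
    any(ev$start < tr$end[i] & ev$end > tr$start[i]), logical(1))
  expect_gte(mean(hit), 0.9)
})
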