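test_that("lap rate divides spikes by running time after stop subtraction", {
  laps <- interval_set(0, 5)
  expect_equal(lap_rate(seq(0.25, 4.75, by = 0.5), laps), 2)
  ## all spikes inside stops contribute nothing
  expect_equal(lap_rate(c(1, 2), interval_set(0, 10),
                        interval_set(0.5, 2.5)), 0)
  ## two 10 s laps, a stop covering 5 s of lap 1, 30 spikes outside stops
  laps2 <- interval_set(c(0, 20), c(10, 30))
  stops <- interval_set(2, 7)
  spk <- c(seq(7.5, 9.9, length.out = 10), seq(20.5, 29.5, length.out = 20))
  expect_equal(lap_rate(spk, laps2, stops), 30 / 15)
  expect_error(lap_rate(1, interval_set(0, 5), interval_set(-1, 6)),
               "zero running time")
})

test_that("SI and DI have the index closed form and its symmetries", {
  expect_equal(selectivity_index(2, 2), 0)
  expect_equal(selectivity_index(0, 3), 1)
  expect_equal(selectivity_index(3, 1), -0.5)
  expect_true(is.nan(selectivity_index(0, 0)))
  expect_error(selectivity_index(-1, 2), ">= 0")
  expect_equal(difference_index(4, 4), 0)
  expect_equal(difference_index(4, 0), 1)
  expect_equal(difference_index(1, 3), -0.5)
  expect_equal(difference_index(2, 1), 1 / 3)
  ## antisymmetry and scale invariance on a random sweep
  set.seed(21)
  a <- runif(500, 0, 20); b <- runif(500, 0, 20); c <- runif(500, 0.01, 50)
  expect_equal(selectivity_index(a, b), -selectivity_index(b, a))
  expect_equal(selectivity_index(c * a, c * b), selectivity_index(a, b))
})

test_that("classification agrees with stats::t.test and labels the winner", {
  set.seed(31)
  for (i in 1:30) {
    nl <- sample(3:12, 1); nr <- sample(3:12, 1)
    l <- rnorm(nl, 5, 2); r <- rnorm(nr, 5 + sample(c(0, 3), 1), 2)
    cl <- classify_selectivity(l, r)
    tt <- t.test(r, l, var.equal = TRUE)
    expect_equal(cl$p, tt$p.value, tolerance = 1e-12)
    expect_equal(cl$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(cl$label,
                 if (tt$p.value < 0.05) {
                   if (mean(r) > mean(l)) "right" else "left"
                 } else "nonselective")
  }
  ## Welch variant agrees with Welch t.test
  l <- rnorm(8, 2, 1); r <- rnorm(15, 6, 4)
  cw <- classify_selectivity(l, r, var_equal = FALSE)
  tw <- t.test(r, l)
  expect_equal(cw$p, tw$p.value, tolerance = 1e-12)
  ## strongly separated populations are classified with the correct side
  cl <- classify_selectivity(rnorm(20, 1, 0.1), rnorm(20, 5, 0.1))
  expect_equal(cl$label, "right")
  expect_lt(cl$p, 1e-10)
  ## insufficient trials are flagged, never classified
  expect_equal(classify_selectivity(1, c(2, 3))$flag, "insufficient_trials")
  expect_equal(classify_selectivity(c(5, 5), c(5, 5))$label, "nonselective")
})

test_that("session selectivity recovers the planted ACC sides", {
  gs <- generate_session(light_params(acc_selectivity_ratio = 3,
                                      n_trials = 40, n_acc = 6, seed = 17L))
  maze <- session_selectivity(gs$session, "maze")
  box <- session_selectivity(gs$session, "box")
  truth <- gs$truth$units
  pref <- truth$pref_side[match(maze$unit_id, truth$unit_id)]
  expect_true(all(maze$label == pref))
  expect_true(all(abs(maze$si - truth$expected_si[match(
    maze$unit_id, truth$unit_id)]) < 0.25))
  ss <- same_side_fraction(maze, box)
  expect_equal(ss$n_selective, 6L)
  expect_gt(ss$frac_same, 0.5)
  expect_equal(ss$frac_same + ss$frac_opposite <= 1, TRUE)
})

test_that("same_side_fraction handles the degenerate label layouts", {
  mk <- function(labels, si = seq_along(labels))
    data.frame(unit_id = paste0("u", seq_along(labels)), si = si,
               label = labels)
  both <- same_side_fraction(mk(c("left", "right", "left")),
                             mk(c("left", "right", "left")))
  expect_equal(both$frac_same, 1)
  expect_equal(both$frac_opposite, 0)
  none <- suppressWarnings(same_side_fraction(
    mk(c("left", "right", "left")),
    mk(rep("nonselective", 3))))
  expect_equal(none$frac_same, 0)
  expect_equal(none$frac_opposite, 0)
})

test_that("the shuffle null matches a hand-computed observed fraction", {
  set.seed(41)
  n_cells <- 12; n_trials <- 30
  sides <- rep(c("left", "right"), length.out = n_trials)
  maze_labels <- rep(c("left", "right"), length.out = n_cells)
  rates <- matrix(rpois(n_cells * n_trials, 8), n_cells)
  ## plant box selectivity matching the maze label for half the cells
  for (i in 1:6) rates[i, sides == maze_labels[i]] <-
    rates[i, sides == maze_labels[i]] + 14
  ## independent recomputation of the observed fraction
  obs <- mean(vapply(seq_len(n_cells), function(i) {
    cl <- classify_selectivity(rates[i, sides == "left"],
                               rates[i, sides == "right"])
    cl$label != "nonselective" && cl$label == maze_labels[i]
  }, logical(1)))
  pn <- shuffle_selectivity_null(rates, sides, maze_labels,
                                 n_shuffles = 200, seed = 1L)
  expect_equal(pn$observed, obs)
  expect_length(pn$null, 200L)
  expect_gt(pn$z, 2)
  expect_true(pn$p > 0 && pn$p <= 1)
})

test_that("correct-error analysis recovers the planted attenuation", {
  gs <- generate_session(light_params(acc_error_attenuation = 0.5,
                                      p_error = 0.3, n_trials = 40,
                                      n_acc = 8, acc_selectivity_ratio = 3,
                                      seed = 23L))
  maze <- session_selectivity(gs$session, "maze")
  box <- session_selectivity(gs$session, "box")
  ce <- correct_error_analysis(gs$session, maze, box, n_shuffles = 200,
                               seed = 2L)
  expect_gt(ce$n_cells, 2)
  expect_gt(ce$mean_di, 0)
  expect_lt(ce$p, 0.05)
  expect_true(all(ce$cells$n_error >= 3))
})
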