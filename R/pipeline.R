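# Pipeline orchestration: configuration, structured logging, running all
# analysis stages on a session bundle, and the synthetic validation harness.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default: 2 s delay, alpha 0.05,
#' 10 ms MUA bins with sigma 2 bins and 0.35/0.15 thresholds and 30 ms
#' merge, 3 SD template criterion with 4 active cells for candidates,
#' 20 ms/10 ms decoding windows, 1000 shuffles, 200 ms coupling bins,
#' minimum 3 error trials.
#'
#' @param delay_duration s (2).
#' @param alpha significance level (0.05).
#' @param correct_only classify selectivity on correct trials only (TRUE).
#' @param var_equal Student (TRUE) vs Welch t-tests.
#' @param v_thresh,min_stop_dur stop-mask parameters (5 cm/s, 3 s).
#' @param mua_bin,mua_sigma_bins MUA binning (0.010 s, 2 bins).
#' @param peak_thr,edge_thr,merge_gap PBE thresholds (0.35, 0.15, 0.030 s).
#' @param spatial_bin,curve_sigma_bins rate-curve binning (2 cm, 2 bins).
#' @param template_n_sd template inclusion criterion (3).
#' @param min_active candidate threshold (4).
#' @param tau,step decoding windows (0.020, 0.010 s).
#' @param rate_floor decoder rate clamp, Hz (1e-3).
#' @param replay_sided shuffle convention (`"two.sided"` default).
#' @param n_shuffles permutation count (1000).
#' @param coupling_bin coupling bin, s (0.200).
#' @param max_lag_bins cross-correlation lag range (5).
#' @param xcorr_mode `"per_trial"` or `"pooled"`.
#' @param min_errors error-trial minimum (3).
#' @param seed RNG seed for all stochastic stages.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(delay_duration = 2.0, alpha = 0.05,
                            correct_only = TRUE, var_equal = TRUE,
                            v_thresh = 5, min_stop_dur = 3,
                            mua_bin = 0.010, mua_sigma_bins = 2,
                            peak_thr = 0.35, edge_thr = 0.15,
                            merge_gap = 0.030, spatial_bin = 2,
                            curve_sigma_bins = 2, template_n_sd = 3,
                            min_active = 4, tau = 0.020, step = 0.010,
                            rate_floor = 1e-3,
                            replay_sided = "two.sided", n_shuffles = 1000,
                            coupling_bin = 0.200, max_lag_bins = 5,
                            xcorr_mode = "per_trial", min_errors = 3,
                            seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("delay_duration", "mua_bin", "tau", "step", "coupling_bin",
              "spatial_bin"))
    if (cfg[[f]] <= 0) stop("pipeline_config: '", f, "' must be > 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("pipeline_config: 'alpha' must be in (0, 1)")
  if (cfg$n_shuffles < 1) stop("pipeline_config: 'n_shuffles' must be >= 1")
  if (!cfg$replay_sided %in% c("two.sided", "one.sided"))
    stop("pipeline_config: 'replay_sided' must be two.sided or one.sided")
  if (!cfg$xcorr_mode %in% c("per_trial", "pooled"))
    stop("pipeline_config: 'xcorr_mode' must be per_trial or pooled")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a session
#'
#' Executes behavior -> selectivity -> SWR detection -> replay decoding ->
#' coupling, writing all result tables, a structured run log and the
#' resolved configuration to `out_dir`. Stages whose preconditions fail are
#' skipped with a log entry; downstream stages that depend on them are
#' skipped too. Deterministic for a fixed seed and bundle.
#'
#' @param session an `oswm_session` or a path to a session bundle.
#' @param config a [pipeline_config()].
#' @param out_dir results directory (created).
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_analysis <- function(session, config = pipeline_config(), out_dir) {
  if (is.character(session)) session <- load_session(session)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("run_analysis: cannot create ", out_dir)
  set.seed(config$seed)
  log_lines <- character()
  logit <- function(stage, msg) {
    log_lines <<- c(log_lines, paste0(stage, "\t", msg))
  }
  res <- list()
  trials <- session$trials
  logit("input", paste0("condition=", session$condition,
                        " units=", length(session$units),
                        " trials=", nrow(trials)))

  ## behavior ----------------------------------------------------------------
  res$maze_performance <- maze_performance(trials)
  pokes <- lapply(seq_len(nrow(trials)), function(k) trials$t_ob_poke[k])
  res$poke_curve <- poke_performance_curve(pokes, trials$demo_poke_time)
  logit("behavior", paste0("maze_performance=",
                           format(res$maze_performance, digits = 4)))
  write_table_stable(
    data.frame(bin_center = res$poke_curve$bin_centers,
               rate = res$poke_curve$rate),
    file.path(out_dir, "poke_curve.csv"))

  ## selectivity -------------------------------------------------------------
  maze_df <- session_selectivity(session, "maze", "ACC",
                                 alpha = config$alpha,
                                 correct_only = config$correct_only,
                                 delay_duration = config$delay_duration,
                                 var_equal = config$var_equal,
                                 v_thresh = config$v_thresh,
                                 min_dur = config$min_stop_dur)
  box_df <- session_selectivity(session, "box", "ACC",
                                alpha = config$alpha,
                                correct_only = config$correct_only,
                                delay_duration = config$delay_duration,
                                var_equal = config$var_equal)
  res$maze_selectivity <- maze_df
  res$box_selectivity <- box_df
  write_table_stable(maze_df, file.path(out_dir, "selectivity_maze.csv"))
  write_table_stable(box_df, file.path(out_dir, "selectivity_box.csv"))
  res$same_side <- same_side_fraction(maze_df, box_df)
  logit("selectivity",
        paste0("n_selective=", res$same_side$n_selective,
               " frac_same=", format(res$same_side$frac_same, digits = 3)))

  sel_ids <- maze_df$unit_id[maze_df$label != "nonselective"]
  if (length(sel_ids) >= 2L) {
    tr_used <- if (config$correct_only)
      trials[trials$correct, , drop = FALSE] else trials
    rates <- delay_rate_matrix(session, sel_ids, tr_used,
                               config$delay_duration)
    res$shuffle_null <- shuffle_selectivity_null(
      rates, tr_used$side,
      maze_df$label[match(sel_ids, maze_df$unit_id)],
      relation = "same", n_shuffles = config$n_shuffles,
      alpha = config$alpha)
    write_table_stable(
      data.frame(shuffle = seq_along(res$shuffle_null$null),
                 frac_same = res$shuffle_null$null),
      file.path(out_dir, "nulls.csv"))
    logit("shuffle_null", paste0("observed=",
                                 format(res$shuffle_null$observed,
                                        digits = 3),
                                 " z=", format(res$shuffle_null$z,
                                               digits = 3)))
  } else logit("shuffle_null", "skipped: < 2 maze-selective cells")

  ## error-trial DI ----------------------------------------------------------
  n_err <- sum(!trials$correct)
  if (n_err >= config$min_errors) {
    res$di_error <- correct_error_analysis(
      session, maze_df, box_df, min_errors = config$min_errors,
      alpha = config$alpha, n_shuffles = config$n_shuffles,
      delay_duration = config$delay_duration)
    write_table_stable(res$di_error$cells %||% data.frame(),
                       file.path(out_dir, "di_error.csv"))
    logit("di_error", paste0("n_cells=", res$di_error$n_cells,
                             " mean_di=", format(res$di_error$mean_di,
                                                 digits = 3)))
  } else {
    write_table_stable(data.frame(), file.path(out_dir, "di_error.csv"))
    logit("di_error", paste0("skipped: only ", n_err, " error trials"))
  }

  ## SWR detection -----------------------------------------------------------
  mua <- smooth_standardize(bin_mua(session, config$mua_bin),
                            config$mua_sigma_bins)
  pbes <- detect_pbes(mua, config$peak_thr, config$edge_thr,
                      config$merge_gap)
  waters <- water_intervals(session)
  pbes$in_water <- iv_contains(pbes$peak_time, waters)
  res$pbes <- pbes
  write_table_stable(pbes, file.path(out_dir, "pbes.csv"))
  logit("swr", paste0("n_pbes=", nrow(pbes), " in_water=",
                      sum(pbes$in_water)))

  ## replay decoding ---------------------------------------------------------
  stops <- stop_mask(session$position, config$v_thresh,
                     config$min_stop_dur)
  ca1 <- region_units(session, "CA1")
  spikes <- stats::setNames(lapply(session$units, `[[`, "t"),
                            vapply(session$units, `[[`, "", "unit_id"))
  templates <- list()
  for (tr in c("left_out", "left_in", "right_out", "right_in")) {
    curves <- list()
    for (u in ca1) {
      cv <- tryCatch(linearized_rate_curve(u$t, session$position, tr,
                                           config$spatial_bin,
                                           config$curve_sigma_bins, stops),
                     error = function(e) NULL)
      if (!is.null(cv)) curves[[u$unit_id]] <- cv
    }
    templates[[tr]] <- build_template(curves, config$template_n_sd)
  }
  res$templates <- templates
  res$ensembles <- build_ensembles(templates)
  logit("templates", paste0(
    paste(vapply(templates, function(t) length(t$unit_ids), integer(1)),
          collapse = "/"), " members (lo/li/ro/ri)"))

  pbes_w <- restrict_events(pbes, waters)
  res$decoded <- decode_session_replays(
    pbes_w, templates, spikes, config$min_active, config$tau,
    config$step, config$rate_floor, config$n_shuffles,
    config$replay_sided, config$alpha)
  write_table_stable(res$decoded, file.path(out_dir, "decoded_events.csv"))
  res$replay_counts <- replay_counts_per_trial(trials, res$decoded)
  write_table_stable(
    cbind(data.frame(trial_id = trials$trial_id), res$replay_counts),
    file.path(out_dir, "replay_counts.csv"))
  logit("replay", paste0("candidates=", nrow(res$decoded), " replays=",
                         sum(res$decoded$is_replay)))

  ## coupling ----------------------------------------------------------------
  if (length(res$ensembles$left) || length(res$ensembles$right)) {
    res$coupling <- coupling_battery(
      session, maze_df, res$ensembles, pbes,
      replay_counts = res$replay_counts, bin = config$coupling_bin,
      max_lag_bins = config$max_lag_bins,
      delay_duration = config$delay_duration,
      xcorr_mode = config$xcorr_mode)
    write_table_stable(res$coupling$cells,
                       file.path(out_dir, "coupling.csv"))
    ## supplementary BH-adjusted column (never used for the headline counts)
    popu <- res$coupling$population
    popu$p_bh <- stats::p.adjust(popu$p, method = "BH")
    write_table_stable(popu, file.path(out_dir, "population_tests.csv"))
    logit("coupling", paste0("n_rows=", nrow(res$coupling$cells)))
  } else logit("coupling", "skipped: empty ensembles")

  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run_log.tsv"))
  invisible(res)
}

#' Synthetic validation harness
#'
#' Generates sessions under a null condition (no selectivity, unbiased
#' replay, no coupling) and an effect condition (planted selectivity, error
#' attenuation, replay bias and coupling), runs the pipeline stages, and
#' reports recovery statistics against the generator's ground truth:
#' selectivity type-I rate and power with side accuracy, PBE recall against
#' embedded bursts, replay detection recall, and same- vs opposite-side
#' coupling.
#'
#' @param config a [pipeline_config()].
#' @param null_params,effect_params [synth_params()] for the two grid
#'   conditions (sensible small defaults are used when NULL).
#' @param seed seed for the harness.
#' @return data frame report with one row per metric (`condition`,
#'   `metric`, `value`, `n`, `seed`).
#' @export
run_synthetic_validation <- function(config = pipeline_config(),
                                     null_params = NULL,
                                     effect_params = NULL, seed = 1L) {
  if (is.null(null_params))
    null_params <- synth_params(acc_selectivity_ratio = 1,
                                acc_error_attenuation = 1,
                                replay_bias = 0.5, coupling_strength = 0,
                                n_acc = 20, n_ca1 = 16, lap_duration = 16,
                                water_duration = 6, seed = seed)
  if (is.null(effect_params))
    effect_params <- synth_params(acc_selectivity_ratio = 3,
                                  acc_error_attenuation = 0.5,
                                  p_error = 0.2, replay_bias = 0.8,
                                  coupling_strength = 0.4, n_acc = 20,
                                  n_ca1 = 16, lap_duration = 16,
                                  water_duration = 6, seed = seed + 1L)
  report <- list()
  add <- function(cond, metric, value, n)
    report[[length(report) + 1L]] <<- data.frame(
      condition = cond, metric = metric, value = value, n = n, seed = seed)
  for (cond in c("null", "effect")) {
    p <- if (cond == "null") null_params else effect_params
    gs <- generate_session(p)
    s <- gs$session; tru <- gs$truth
    out <- file.path(tempdir(), paste0("oswm_val_", cond, "_", seed))
    res <- run_analysis(s, config, out)
    md <- res$maze_selectivity
    frac_sel <- mean(md$label != "nonselective")
    add(cond, "frac_acc_selective", frac_sel, nrow(md))
    if (cond == "effect") {
      truth_pref <- tru$units$pref_side[match(md$unit_id,
                                              tru$units$unit_id)]
      add(cond, "selectivity_side_accuracy",
          mean(md$label == truth_pref), nrow(md))
    }
    ## PBE recall against embedded bursts
    if (nrow(tru$replays)) {
      hit <- vapply(seq_len(nrow(tru$replays)), function(i)
        any(res$pbes$start < tru$replays$end[i] &
              res$pbes$end > tru$replays$start[i]), logical(1))
      add(cond, "pbe_recall", mean(hit), nrow(tru$replays))
      ## replay recall: embedded replay significant for its own template
      dec <- res$decoded
      rec <- vapply(seq_len(nrow(tru$replays)), function(i) {
        j <- which(dec$template == tru$replays$template[i] &
                     dec$peak_time >= tru$replays$start[i] - 0.05 &
                     dec$peak_time <= tru$replays$end[i] + 0.05)
        any(dec$is_replay[j])
      }, logical(1))
      add(cond, "replay_recall", mean(rec), nrow(tru$replays))
    }
    if (!is.null(res$coupling)) {
      popu <- res$coupling$population
      g <- function(an, rel) {
        v <- popu$mean[popu$analysis == an & popu$relation == rel]
        if (length(v)) v else NA_real_
      }
      add(cond, "coupling_same_mean",
          g("delay_to_swr_trial_corr", "same"), nrow(s$trials))
      add(cond, "coupling_opposite_mean",
          g("delay_to_swr_trial_corr", "opposite"), nrow(s$trials))
    }
    if (!is.null(res$di_error))
      add(cond, "mean_di", res$di_error$mean_di, res$di_error$n_cells)
  }
  do.call(rbind, report)
}
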