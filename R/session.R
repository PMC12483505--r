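# Session data model and plain-text bundle I/O.
#
# A session holds: sorted units (spike times + region), a 30 Hz position
# series with linearized trajectory coordinates, a trial table, and a long
# table of named per-trial intervals (delay, water, lap and stop windows).
# Bundles are UTF-8 CSV files plus a small YAML manifest, so they are
# inspectable and diffable.

TRAJ_LEVELS <- c("left_out", "left_in", "right_out", "right_in", "none")
INTERVAL_KINDS <- c("delay", "water", "left_out", "left_in",
                    "right_out", "right_in", "stop")

#' Construct a spike train
#'
#' One sorted unit: a region label (ACC or CA1) and strictly ascending spike
#' times in session-relative seconds.
#'
#' @param unit_id character scalar.
#' @param region `"ACC"` or `"CA1"`.
#' @param t numeric vector of spike times, strictly ascending, finite, >= 0.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(unit_id, region, t) {
  region <- match.arg(region, c("ACC", "CA1"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("spike_train '", unit_id, "': spike times must be finite and >= 0")
  if (is.unsorted(t, strictly = TRUE))
    stop("spike_train '", unit_id, "': spike times must be strictly ascending")
  structure(list(unit_id = as.character(unit_id), region = region, t = t),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("spike_train", x$unit_id, "(", x$region, "):", length(x$t), "spikes\n")
  invisible(x)
}

#' Assemble a session object
#'
#' @param condition behavioral condition: `"Demo"`, `"Object"` or `"Empty"`.
#' @param units list of [spike_train()] objects.
#' @param position data frame with columns `t`, `x`, `y`, `traj_id`,
#'   `lin_pos` (speed is derived on construction if absent).
#' @param trials data frame with one row per trial: `trial_id`, `side`
#'   (left/right, the demonstrator's choice), `correct` (logical),
#'   `t_demo_cp`, `t_ob_poke`, `demo_poke_time`, `water_start`, `water_end`.
#' @param intervals data frame of named per-trial intervals: `trial_id`,
#'   `kind` (one of delay, water, left_out, left_in, right_out, right_in,
#'   stop), `start`, `end`.
#' @param meta free-form list of key/values.
#' @return object of class `oswm_session`.
#' @export
oswm_session <- function(condition, units, position, trials, intervals,
                         meta = list()) {
  condition <- match.arg(condition, c("Demo", "Object", "Empty"))
  if (!"speed" %in% names(position) && nrow(position))
    position$speed <- derive_speed(position)
  s <- structure(list(condition = condition, units = units,
                      position = position, trials = trials,
                      intervals = intervals, meta = meta),
                 class = "oswm_session")
  s
}

#' @export
print.oswm_session <- function(x, ...) {
  reg <- vapply(x$units, `[[`, "", "region")
  cat("oswm_session [", x$condition, "]: ",
      sum(reg == "ACC"), " ACC + ", sum(reg == "CA1"), " CA1 units, ",
      nrow(x$trials), " trials, ",
      nrow(x$position), " position samples\n", sep = "")
  invisible(x)
}

# Speed from consecutive x/y samples; the last sample inherits the previous
# value so the vector has the series' length.
derive_speed <- function(position) {
  n <- nrow(position)
  if (n < 2L) return(rep(0, n))
  d <- sqrt(diff(position$x)^2 + diff(position$y)^2)
  dt <- diff(position$t)
  v <- d / dt
  c(v, v[n - 1L])
}

#' Validate a session against the data-model invariants
#'
#' Always returns (never throws). Each violation carries the offending
#' record's id and the rule name.
#'
#' @param session an `oswm_session`.
#' @return data frame with columns `record`, `rule`, `detail`; zero rows iff
#'   all invariants hold.
#' @export
validate_session <- function(session) {
  v <- list()
  add <- function(record, rule, detail)
    v[[length(v) + 1L]] <<- data.frame(record = record, rule = rule,
                                       detail = detail)
  ## units
  for (u in session$units) {
    if (length(u$t) && is.unsorted(u$t, strictly = TRUE))
      add(u$unit_id, "spikes_sorted", "spike times not strictly ascending")
    if (length(u$t) && (any(!is.finite(u$t)) || any(u$t < 0)))
      add(u$unit_id, "spikes_finite", "non-finite or negative spike times")
    if (!u$region %in% c("ACC", "CA1"))
      add(u$unit_id, "region", paste("unknown region", u$region))
  }
  reg <- vapply(session$units, `[[`, "", "region")
  if (!any(reg == "ACC") || !any(reg == "CA1"))
    add("session", "regions", "full pipeline needs >= 1 ACC and >= 1 CA1 unit")
  ## position
  p <- session$position
  if (nrow(p)) {
    if (is.unsorted(p$t, strictly = TRUE))
      add("position", "position_sorted", "t not strictly ascending")
    bad <- (p$traj_id != "none") != !is.na(p$lin_pos)
    if (any(bad))
      add("position", "lin_pos_defined",
          paste0(sum(bad), " samples where lin_pos presence does not match traj_id"))
    if (any(p$speed < 0, na.rm = TRUE))
      add("position", "speed_nonneg", "negative speed values")
    if (!all(p$traj_id %in% TRAJ_LEVELS))
      add("position", "traj_levels", "unknown traj_id levels")
  }
  ## trials
  tr <- session$trials
  if (nrow(tr)) {
    if (is.unsorted(tr$t_ob_poke))
      add("trials", "trials_ordered", "trials not ordered by t_ob_poke")
    bad <- !is.na(tr$t_demo_cp) & tr$t_demo_cp > tr$t_ob_poke
    for (i in which(bad))
      add(tr$trial_id[i], "demo_before_poke", "t_demo_cp > t_ob_poke")
    bad <- !is.na(tr$water_start) & tr$water_start < tr$t_ob_poke
    for (i in which(bad))
      add(tr$trial_id[i], "water_after_poke", "water interval starts before t_ob_poke")
  }
  ## intervals
  iv <- session$intervals
  if (nrow(iv)) {
    bad <- iv$end <= iv$start
    for (i in which(bad))
      add(paste0("interval:", iv$trial_id[i], ":", iv$kind[i]),
          "interval_positive", "end <= start")
    if (!all(iv$kind %in% INTERVAL_KINDS))
      add("intervals", "interval_kinds", "unknown interval kind")
    # pairwise overlap within each kind (one violation per overlapping pair)
    for (k in unique(iv$kind)) {
      sub <- iv[iv$kind == k & iv$end > iv$start, , drop = FALSE]
      if (nrow(sub) > 1L) {
        o <- order(sub$start)
        sub <- sub[o, ]
        ov <- which(sub$start[-1L] < sub$end[-nrow(sub)])
        for (i in ov)
          add(paste0("interval:", k), "intervals_disjoint",
              paste0("overlap between trials ", sub$trial_id[i], " and ",
                     sub$trial_id[i + 1L]))
      }
    }
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(record = character(), rule = character(),
                  detail = character())
}

# ---- bundle I/O -------------------------------------------------------------

fmt_num <- function(x, digits = 6) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- ""
  out
}

#' Write a session bundle to a directory
#'
#' Writes `spikes.csv`, `position.csv`, `trials.csv`, `intervals.csv` and
#' `manifest.yaml` with a fixed column order and fixed float formatting
#' (six decimals, i.e. microsecond time resolution), so the output is
#' byte-stable for a given session.
#'
#' @param session an `oswm_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("write_session: cannot create directory ", dir)
  spikes <- do.call(rbind, lapply(session$units, function(u)
    if (length(u$t)) data.frame(unit_id = u$unit_id, region = u$region,
                                t = fmt_num(u$t)) else NULL))
  if (is.null(spikes))
    spikes <- data.frame(unit_id = character(), region = character(),
                         t = character())
  write_table_stable(spikes, file.path(dir, "spikes.csv"))
  p <- session$position
  pos <- data.frame(t = fmt_num(p$t), x = fmt_num(p$x), y = fmt_num(p$y),
                    traj_id = p$traj_id, lin_pos = fmt_num(p$lin_pos))
  write_table_stable(pos, file.path(dir, "position.csv"))
  tr <- session$trials
  trials <- data.frame(trial_id = tr$trial_id, side = tr$side,
                       correct = as.integer(tr$correct),
                       t_demo_cp = fmt_num(tr$t_demo_cp),
                       t_ob_poke = fmt_num(tr$t_ob_poke),
                       demo_poke_time = fmt_num(tr$demo_poke_time),
                       water_start = fmt_num(tr$water_start),
                       water_end = fmt_num(tr$water_end))
  write_table_stable(trials, file.path(dir, "trials.csv"))
  iv <- session$intervals
  ivd <- data.frame(trial_id = iv$trial_id, kind = iv$kind,
                    start = fmt_num(iv$start), end = fmt_num(iv$end))
  write_table_stable(ivd, file.path(dir, "intervals.csv"))
  units_meta <- data.frame(
    unit_id = vapply(session$units, `[[`, "", "unit_id"),
    region = vapply(session$units, `[[`, "", "region"))
  write_table_stable(units_meta, file.path(dir, "units.csv"))
  manifest <- list(condition = session$condition,
                   files = list(spikes = "spikes.csv",
                                units = "units.csv",
                                position = "position.csv",
                                trials = "trials.csv",
                                intervals = "intervals.csv"),
                   n_units = length(session$units),
                   n_trials = nrow(session$trials))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

read_bundle_csv <- function(dir, fname, what) {
  path <- file.path(dir, fname)
  if (!file.exists(path))
    stop("load_session: missing ", what, " file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load a session bundle
#'
#' Reads a bundle written by [write_session()] (or assembled by hand in the
#' same dialect) and validates it; a validation failure lists the offending
#' records.
#'
#' @param manifest_path path to the bundle's `manifest.yaml`, or to the
#'   bundle directory itself.
#' @param validate stop on invariant violations (default TRUE).
#' @return an `oswm_session`.
#' @export
load_session <- function(manifest_path, validate = TRUE) {
  if (dir.exists(manifest_path))
    manifest_path <- file.path(manifest_path, "manifest.yaml")
  if (!file.exists(manifest_path))
    stop("load_session: missing manifest file: ", manifest_path)
  manifest <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  f <- manifest$files
  spikes <- read_bundle_csv(dir, f$spikes %||% "spikes.csv", "spikes")
  units_meta <- read_bundle_csv(dir, f$units %||% "units.csv", "units")
  pos <- read_bundle_csv(dir, f$position %||% "position.csv", "position")
  trials <- read_bundle_csv(dir, f$trials %||% "trials.csv", "trials")
  iv <- read_bundle_csv(dir, f$intervals %||% "intervals.csv", "intervals")

  units <- lapply(seq_len(nrow(units_meta)), function(i) {
    id <- units_meta$unit_id[i]
    tt <- spikes$t[spikes$unit_id == id]
    tr <- spikes$region[spikes$unit_id == id]
    if (length(tr) && any(tr != units_meta$region[i]))
      stop("load_session: unit ", id, " has inconsistent region labels")
    if (length(tt) && is.unsorted(tt, strictly = TRUE))
      stop("load_session: unit ", id, " spike times not strictly ascending")
    spike_train(id, units_meta$region[i], tt)
  })
  pos$traj_id <- as.character(pos$traj_id)
  pos$lin_pos <- as.numeric(pos$lin_pos)
  trials$correct <- as.logical(trials$correct)
  trials$side <- as.character(trials$side)
  session <- oswm_session(manifest$condition %||% "Demo", units, pos,
                          trials, iv)
  if (validate) {
    viol <- validate_session(session)
    if (nrow(viol))
      stop("load_session: session fails validation:\n",
           paste(sprintf("  [%s] %s: %s", viol$rule, viol$record,
                         viol$detail), collapse = "\n"))
  }
  session
}

# ---- convenience accessors --------------------------------------------------

#' Spike times of a unit
#' @param session an `oswm_session`.
#' @param unit_id unit identifier.
#' @return numeric vector of spike times.
#' @export
unit_spikes <- function(session, unit_id) {
  for (u in session$units) if (u$unit_id == unit_id) return(u$t)
  stop("unknown unit: ", unit_id)
}

#' Units of a region
#' @param session an `oswm_session`.
#' @param region `"ACC"` or `"CA1"`.
#' @return list of `spike_train`s.
#' @export
region_units <- function(session, region) {
  Filter(function(u) u$region == region, session$units)
}

#' Per-trial intervals of a given kind
#' @param session an `oswm_session`.
#' @param kind one of the interval kinds (delay, water, lap kinds, stop).
#' @param trial_id optional trial filter.
#' @return an `interval_set`.
#' @export
session_intervals <- function(session, kind, trial_id = NULL) {
  iv <- session$intervals
  sel <- iv$kind %in% kind
  if (!is.null(trial_id)) sel <- sel & iv$trial_id %in% trial_id
  interval_set(iv$start[sel], iv$end[sel])
}

#' Water-consumption interval of each trial
#' @param session an `oswm_session`.
#' @return an `interval_set`, one interval per trial (trial order).
#' @export
water_intervals <- function(session) {
  tr <- session$trials
  interval_set(tr$water_start, tr$water_end)
}
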