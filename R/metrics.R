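#' @title Per-trial behavioral metrics
#'
#' @description
#' Derived parameters for one trial: signaling economy (duty cycle, signal
#' counts and composition), path metrics on the arena tree (total and
#' searching distance, approach to the target, path efficiency, search
#' ratio, latencies), and the composite overall-efficiency score
#' `eff = (1 - duty cycle) / log10(distance / approach)`, which is 1 for a
#' male that walks straight to the target without signaling.
#'
#' @name trial_metrics
NULL

#' Construct a trial record
#'
#' @param trajectory data.frame of movement events with columns `time`
#'   (seconds), `section`, `subsection`, `class` (`"walk"` or `"search"`),
#'   sorted by time; each row is a move to a new subsection.
#' @param sections [signal_sections()] table of the male's annotated signal
#'   sections.
#' @param schedules named list of `vib_schedule`s (`noise`, `reply`,
#'   `masking`), any subset.
#' @param treatment treatment name or [treatment_spec()].
#' @param trial_duration trial length, seconds.
#' @param male_id,plant_id,operator,repetition identifiers for the stats
#'   layer.
#' @param ground_truth optional list of generating parameters (synthetic
#'   trials).
#' @return an object of class `vib_trial`.
#' @export
trial_record <- function(trajectory, sections, schedules = list(),
                         treatment = "control_plus", trial_duration,
                         male_id = NA, plant_id = NA, operator = NA,
                         repetition = NA, ground_truth = NULL) {
  if (inherits(treatment, "vib_treatment")) treatment <- treatment$name
  treatment <- match.arg(treatment, .TREATMENTS)
  if (!is.finite(trial_duration) || trial_duration <= 0)
    stop("trial_duration must be positive")
  req <- c("time", "section", "subsection", "class")
  if (nrow(trajectory) && !all(req %in% names(trajectory)))
    stop("trajectory needs columns: ", paste(req, collapse = ", "))
  if (!nrow(trajectory))
    trajectory <- data.frame(time = numeric(0), section = character(0),
                             subsection = integer(0), class = character(0))
  if (is.unsorted(trajectory$time)) stop("trajectory events must be sorted by time")
  if (any(trajectory$time < 0)) stop("event times must be >= 0")
  if (!all(trajectory$class %in% c("walk", "search")))
    stop("movement class must be 'walk' or 'search'")
  # searching is reply-associated: no search events before the first reply
  reply <- schedules$reply
  if (!is.null(reply) && any(trajectory$class == "search")) {
    first_reply <- if (nrow(reply$intervals)) min(reply$intervals[, 1L]) else Inf
    if (any(trajectory$time[trajectory$class == "search"] < first_reply))
      stop("search-class movement before the first female reply")
  }
  structure(list(trajectory = trajectory,
                 sections = signal_sections(sections),
                 schedules = schedules, treatment = treatment,
                 trial_duration = trial_duration,
                 male_id = male_id, plant_id = plant_id,
                 operator = operator, repetition = repetition,
                 ground_truth = ground_truth),
            class = "vib_trial")
}

#' @export
print.vib_trial <- function(x, ...) {
  cat("<trial ", x$treatment, ", male ", x$male_id, ", rep ", x$repetition,
      ": ", nrow(x$trajectory), " moves, ", nrow(x$sections),
      " signal sections, ", x$trial_duration, " s>\n", sep = "")
  invisible(x)
}

#' Total traversed distance of a trajectory
#'
#' Sums the path distances between consecutive positions, starting from
#' `start`. With a `class_filter`, only steps whose destination event
#' carries that movement class contribute.
#'
#' @param trajectory movement-event data.frame (see [trial_record()]).
#' @param arena a [build_arena()] result.
#' @param start starting [location()] (default the arena's start).
#' @param class_filter optional `"walk"` or `"search"`.
#' @return distance in mm.
#' @export
traverse_distance <- function(trajectory, arena, start = arena$start,
                              class_filter = NULL) {
  if (!nrow(trajectory)) return(0)
  if (is.unsorted(trajectory$time)) stop("trajectory events must be sorted by time")
  sec <- c(start$section, trajectory$section)
  sub <- c(start$subsection, trajectory$subsection)
  n <- length(sec)
  d <- .path_dist_vec(arena, sec[-n], sub[-n], sec[-1L], sub[-1L])
  if (!is.null(class_filter)) d <- d[trajectory$class == class_filter]
  sum(d)
}

#' Approach ratio
#'
#' Fraction of the starting distance to the target covered at the trial's
#' closest point: `1 - d_min / d_start`, clipped to `[0, 1]`. Remaining at
#' the start (or only moving farther) gives 0; reaching the target gives 1.
#'
#' @param d_min closest distance to the target attained, mm.
#' @param d_start starting distance to the target, mm (> 0).
#' @return value in `[0, 1]`.
#' @export
approach_ratio <- function(d_min, d_start) {
  if (!is.finite(d_start) || d_start <= 0) stop("d_start must be positive")
  if (d_min < 0) stop("d_min must be >= 0")
  min(1, max(0, 1 - d_min / d_start))
}

#' Path metrics of one trial
#'
#' @param trial a [trial_record()].
#' @param arena a [build_arena()] result.
#' @return named list: `total_distance`, `search_distance`, `d_start`,
#'   `d_min` (mm), `approach`, `path_efficiency`, `search_ratio`,
#'   `moving_latency`, `searching_latency`, `time_to_closest` (s),
#'   `found_target`. Latencies are relative to the first reply onset and
#'   `NA` when undefined.
#' @export
path_metrics <- function(trial, arena) {
  stopifnot(inherits(trial, "vib_trial"))
  tr <- trial$trajectory
  if (!nrow(tr)) stop("excluded trial: male did not move")
  total <- traverse_distance(tr, arena)
  if (total <= 0) stop("excluded trial: total traversed distance is zero")
  search_d <- traverse_distance(tr, arena, class_filter = "search")

  d_start <- start_distance(arena)
  d_events <- .path_dist_vec(arena, tr$section, tr$subsection,
                             rep(arena$target$section, nrow(tr)),
                             rep(arena$target$subsection, nrow(tr)))
  d_min <- min(d_start, d_events)
  time_to_closest <- if (any(d_events <= d_min + 1e-9))
    tr$time[which(d_events <= d_min + 1e-9)[1L]] else 0

  reply <- trial$schedules$reply
  first_reply <- if (!is.null(reply) && nrow(reply$intervals))
    min(reply$intervals[, 1L]) else NA_real_
  search_times <- tr$time[tr$class == "search"]

  list(total_distance = total,
       search_distance = search_d,
       d_start = d_start,
       d_min = d_min,
       approach = approach_ratio(d_min, d_start),
       path_efficiency = d_start / total,
       search_ratio = search_d / total,
       moving_latency = if (is.na(first_reply)) NA_real_
         else tr$time[1L] - first_reply,
       searching_latency = if (is.na(first_reply) || !length(search_times))
         NA_real_ else search_times[1L] - first_reply,
       time_to_closest = time_to_closest,
       found_target = d_min <= arena$sub_len[[arena$target$section]])
}

#' Overall efficiency
#'
#' `eff = (1 - duty_cycle) / log10(distance / approach)`, where `distance`
#' is the total traversed distance expressed in formula units via
#' `unit_scale` and `approach` is the approach ratio. With the arena-based
#' unit scale ([eff_unit_scale()]), a straight silent walk to the target
#' scores `eff = 1`. `approach = 0` gives `eff = 0` (the limit as the
#' denominator grows); very short walks are kept finite and positive by
#' flooring the denominator at `eps_floor`.
#'
#' @param duty_cycle signaling duty cycle in `[0, 1]`.
#' @param total_distance total traversed distance, mm (> 0).
#' @param approach approach ratio in `[0, 1]`.
#' @param unit_scale multiplier converting mm to the formula's distance
#'   unit; 1 evaluates the formula on raw mm.
#' @param eps_floor lower bound on the log10 denominator (default 0.1).
#' @return dimensionless efficiency score.
#' @export
overall_efficiency <- function(duty_cycle, total_distance, approach,
                               unit_scale = 1, eps_floor = 0.1) {
  if (!is.finite(total_distance) || total_distance <= 0)
    stop("total_distance must be positive")
  stopifnot(duty_cycle >= 0, duty_cycle <= 1, approach >= 0, approach <= 1)
  if (approach == 0) return(0)
  denom <- log10(total_distance * unit_scale / approach)
  if (denom <= eps_floor) denom <- eps_floor
  (1 - duty_cycle) / denom
}

#' Distance unit scale that anchors eff = 1 at a straight walk
#'
#' Returns the multiplier that maps the arena's starting distance to 10
#' formula units, so a straight, silent walk to the target has
#' `log10(distance/approach) = 1` and overall efficiency exactly 1.
#'
#' @param arena a [build_arena()] result.
#' @return scalar unit scale (per mm).
#' @export
eff_unit_scale <- function(arena) 10 / start_distance(arena)

#' All metrics of one trial
#'
#' Combines [signal_summary()], [path_metrics()] and
#' [overall_efficiency()] into one row. Trials without movement are
#' returned with `excluded = TRUE` and `NA` path metrics, mirroring the
#' exclusion of males that never started moving.
#'
#' @param trial a [trial_record()].
#' @param arena a [build_arena()] result.
#' @param distance_unit `"normalized"` (straight walk = 10 units, the
#'   default) or `"mm"` (literal formula on mm).
#' @return one-row data.frame of identifiers and metrics.
#' @export
compute_trial_metrics <- function(trial, arena,
                                  distance_unit = c("normalized", "mm")) {
  stopifnot(inherits(trial, "vib_trial"))
  distance_unit <- match.arg(distance_unit)
  ss <- signal_summary(trial$sections, trial_duration = trial$trial_duration)
  ids <- data.frame(male_id = trial$male_id, plant_id = trial$plant_id,
                    operator = trial$operator, repetition = trial$repetition,
                    treatment = trial$treatment,
                    stringsAsFactors = FALSE)
  sig <- data.frame(trial_duration = ss$trial_duration,
                    total_signal_duration = ss$total_signal_duration,
                    n_signals = ss$n_signals, duty_cycle = ss$duty_cycle,
                    mean_signal_duration = ss$mean_signal_duration,
                    me0_ratio = ss$me_ratio[["Me0"]],
                    me1_ratio = ss$me_ratio[["Me1"]],
                    me2_ratio = ss$me_ratio[["Me2"]],
                    me3_ratio = ss$me_ratio[["Me3"]],
                    masking_ratio = ss$masking_ratio,
                    interrupted_ratio = ss$interrupted_ratio)
  pm_cols <- c("total_distance", "search_distance", "d_start", "d_min",
               "approach", "path_efficiency", "search_ratio",
               "moving_latency", "searching_latency", "time_to_closest")
  excluded <- !nrow(trial$trajectory) ||
    traverse_distance(trial$trajectory, arena) <= 0
  if (excluded) {
    pm <- as.data.frame(as.list(stats::setNames(rep(NA_real_, length(pm_cols)),
                                                pm_cols)))
    pm$found_target <- NA
    pm$eff <- NA_real_
  } else {
    p <- path_metrics(trial, arena)
    pm <- as.data.frame(p[pm_cols])
    pm$found_target <- p$found_target
    us <- if (distance_unit == "normalized") eff_unit_scale(arena) else 1
    pm$eff <- overall_efficiency(ss$duty_cycle, p$total_distance,
                                 p$approach, unit_scale = us)
  }
  cbind(ids, sig, pm, data.frame(excluded = excluded))
}

#' Metrics table for a set of trials
#'
#' @param trials list of [trial_record()]s.
#' @param arena a [build_arena()] result.
#' @param ... passed to [compute_trial_metrics()].
#' @return data.frame, one row per trial.
#' @export
metrics_table <- function(trials, arena, ...) {
  do.call(rbind, lapply(trials, compute_trial_metrics, arena = arena, ...))
}
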