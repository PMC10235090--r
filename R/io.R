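#' @title Interchange formats
#'
#' @description
#' Readers and writers for the pipeline's text formats: Raven-style
#' tab-separated selection tables (and a plain CSV dialect) for annotated
#' signal sections, movement-event CSVs, playback-schedule CSVs, the tidy
#' metrics CSV, and the YAML run configuration. All times are seconds from
#' trial start (t = 0 at the first male signal for playback treatments).
#'
#' @name io_formats
NULL

.RAVEN_COLS <- c("Selection", "Begin Time (s)", "End Time (s)",
                 "Low Freq (Hz)", "High Freq (Hz)", "Annotation")

#' Read a selection table of annotated signal sections
#'
#' @param path file path.
#' @param dialect `"raven"` (tab-separated, Raven column names) or `"csv"`
#'   (plain CSV with columns `label`, `begin`, `end`).
#' @return a sorted, validated [signal_sections()] table.
#' @export
read_selection_table <- function(path, dialect = c("raven", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "raven") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    need <- c("Begin Time (s)", "End Time (s)", "Annotation")
    if (!all(need %in% names(df)))
      stop("selection table lacks columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    out <- data.frame(label = df[["Annotation"]],
                      begin = df[["Begin Time (s)"]],
                      end = df[["End Time (s)"]],
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  signal_sections(out)
}

#' Write a selection table
#'
#' @param sections a [signal_sections()] table.
#' @param path output path.
#' @param dialect `"raven"` or `"csv"`.
#' @param low_hz,high_hz frequency bounds recorded in the Raven dialect
#'   (annotation metadata only).
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(sections, path, dialect = c("raven", "csv"),
                                  low_hz = 0, high_hz = 2000) {
  dialect <- match.arg(dialect)
  sections <- signal_sections(sections)
  if (dialect == "raven") {
    df <- data.frame(seq_len(nrow(sections)), sections$begin, sections$end,
                     low_hz, high_hz, sections$label, check.names = FALSE)
    names(df) <- .RAVEN_COLS
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.csv(sections, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a movement-event CSV
#'
#' Columns: `trial_id`, `time_s`, `section`, `subsection`,
#' `movement_class`.
#'
#' @param path file path.
#' @return data.frame with one trajectory data.frame per trial in a list
#'   column-free form: a named list of trajectories keyed by `trial_id`.
#' @export
read_movement_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "time_s", "section", "subsection", "movement_class")
  if (!all(need %in% names(df)))
    stop("movement CSV lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lapply(split(df, df$trial_id), function(g) {
    g <- g[order(g$time_s), ]
    data.frame(time = g$time_s, section = g$section,
               subsection = as.integer(g$subsection), class = g$movement_class,
               stringsAsFactors = FALSE)
  })
}

#' Write movement events of one or more trials
#'
#' @param trajectories named list of trajectory data.frames (names are
#'   trial ids), or a single trajectory.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_movement_csv <- function(trajectories, path) {
  if (is.data.frame(trajectories)) trajectories <- list(trial1 = trajectories)
  rows <- do.call(rbind, lapply(names(trajectories), function(id) {
    g <- trajectories[[id]]
    if (!nrow(g)) return(NULL)
    data.frame(trial_id = id, time_s = g$time, section = g$section,
               subsection = g$subsection, movement_class = g$class)
  }))
  if (is.null(rows))
    rows <- data.frame(trial_id = character(0), time_s = numeric(0),
                       section = character(0), subsection = integer(0),
                       movement_class = character(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a playback schedule CSV
#'
#' Columns: `channel`, `begin_s`, `end_s`; trial duration in a `#` header
#' comment.
#'
#' @param schedule a `vib_schedule`.
#' @param path file path.
#' @return [read_schedule_csv()]: a `vib_schedule`; the writer returns
#'   `path` invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "vib_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# trial_duration_s=", schedule$trial_duration), con)
  df <- data.frame(channel = schedule$channel,
                   begin_s = schedule$intervals[, 1L],
                   end_s = schedule$intervals[, 2L])
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  dur <- as.numeric(sub("# trial_duration_s=", "", first, fixed = TRUE))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  channel <- if (nrow(df)) df$channel[1L] else "noise"
  .schedule(channel, .iv(df$begin_s, df$end_s), dur)
}

#' Read the YAML run configuration
#'
#' Top-level blocks: `arena` (section lengths and `subsections`),
#' `simulation` (any [simulation_params()] argument), `treatments`
#' (treatment names to simulate), `stats` (list of `response`/`family`
#' model specs), `seed`, `n_males_per_treatment`.
#'
#' @param path YAML file path.
#' @return validated config list with an `arena_spec` element.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("arena", "simulation", "treatments", "stats", "seed",
             "n_males_per_treatment")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg$arena_spec <- arena_spec_from_config(cfg$arena %||% list())
  cfg$params <- do.call(simulation_params, cfg$simulation %||% list())
  cfg$treatments <- unlist(cfg$treatments) %||% .TREATMENTS
  bad <- setdiff(cfg$treatments, .TREATMENTS)
  if (length(bad)) stop("unknown treatment(s): ", paste(bad, collapse = ", "))
  cfg$seed <- cfg$seed %||% 1L
  cfg$n_males_per_treatment <- cfg$n_males_per_treatment %||% 14L
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the tidy metrics CSV
#'
#' @param metrics data.frame from [metrics_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
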