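#' @title Signal trains: grouping annotated sections into signals
#'
#' @description
#' Male advertisement signals are composed of up to four named sections
#' (Me0--Me3); some males also emit rapid masking "clicks". Annotation
#' yields a train of labeled, non-overlapping sections with begin/end
#' times. A maximal run of Me sections separated by silent gaps shorter
#' than 2 s counts as one signal if it includes Me3 (which triggers the
#' female reply) plus at least one other section; a run lacking Me3 -- or a
#' lone Me3 -- is an interrupted fragment. Click runs are merged into
#' masking bouts independently of the Me runs.
#'
#' @name signal_grouping
NULL

.LABELS <- c("Me0", "Me1", "Me2", "Me3", "click")

#' Validate and sort a table of annotated signal sections
#'
#' @param df data.frame with columns `label`, `begin`, `end` (seconds).
#' @return the validated table, sorted by begin time.
#' @export
signal_sections <- function(df) {
  req <- c("label", "begin", "end")
  if (!all(req %in% names(df)))
    stop("signal sections need columns: ", paste(req, collapse = ", "))
  df <- df[req]
  bad <- setdiff(unique(df$label), .LABELS)
  if (length(bad))
    stop("unknown section label(s): ", paste(bad, collapse = ", "))
  if (any(df$end <= df$begin)) {
    k <- which(df$end <= df$begin)
    stop("section end must exceed begin (row ", paste(k, collapse = ", "), ")")
  }
  df <- df[order(df$begin, df$end), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L && any(df$begin[-1L] < df$end[-nrow(df)])) {
    k <- which(df$begin[-1L] < df$end[-nrow(df)])
    stop("overlapping sections at sorted row(s): ",
         paste(k + 1L, collapse = ", "))
  }
  df
}

.make_signal <- function(sections) {
  complete <- any(sections$label == "Me3") && nrow(sections) >= 2L
  structure(list(sections = sections,
                 begin = min(sections$begin), end = max(sections$end),
                 duration = sum(sections$end - sections$begin),
                 complete = complete),
            class = "vib_signal")
}

#' @export
print.vib_signal <- function(x, ...) {
  cat("<", if (x$complete) "signal" else "fragment", " [",
      signif(x$begin, 5), ", ", signif(x$end, 5), ") s: ",
      paste(x$sections$label, collapse = "+"), ">\n", sep = "")
  invisible(x)
}

#' Group annotated sections into signals, fragments and masking bouts
#'
#' @param sections a [signal_sections()] table (sorted, non-overlapping).
#' @param max_gap_s silent-gap threshold separating signals; gaps strictly
#'   shorter than this merge consecutive sections into one run (default 2 s).
#' @return list with `signals` (complete signals), `fragments` (interrupted
#'   runs), and `bouts` (masking-click bouts as a `[begin, end)` matrix).
#' @export
group_signals <- function(sections, max_gap_s = 2.0) {
  sections <- signal_sections(sections)
  me <- sections[sections$label != "click", , drop = FALSE]
  cl <- sections[sections$label == "click", , drop = FALSE]

  runs_of <- function(df) {
    if (!nrow(df)) return(list())
    gap <- df$begin[-1L] - df$end[-nrow(df)]
    grp <- cumsum(c(1L, as.integer(gap >= max_gap_s)))
    lapply(split(df, grp), identity)
  }

  me_runs <- lapply(runs_of(me), .make_signal)
  complete <- vapply(me_runs, `[[`, logical(1), "complete")

  bouts <- .iv_empty()
  for (run in runs_of(cl))
    bouts <- rbind(bouts, .iv(min(run$begin), max(run$end)))

  list(signals = unname(me_runs[complete]),
       fragments = unname(me_runs[!complete]),
       bouts = bouts)
}

#' Per-trial signal summary metrics
#'
#' Total signal duration adds the durations of all marked sections, Me
#' sections and masking-click bouts alike; the duty cycle divides it by the
#' trial duration. Per-label ratios (`me_ratio`) are means over complete
#' signals of the label's share in that signal's summed section duration.
#' The interrupted ratio is fragments / (signals + fragments), and the
#' masking ratio is the click-bout share of total signal duration.
#'
#' @param sections a [signal_sections()] table.
#' @param grouped result of [group_signals()] on the same table (computed if
#'   missing).
#' @param trial_duration trial length, seconds (> 0).
#' @return named list of summary metrics; ratios are `NA` when their
#'   denominator is empty.
#' @export
signal_summary <- function(sections, grouped = NULL, trial_duration) {
  if (!is.finite(trial_duration) || trial_duration <= 0)
    stop("trial_duration must be positive")
  sections <- signal_sections(sections)
  if (is.null(grouped)) grouped <- group_signals(sections)
  sig <- grouped$signals; frag <- grouped$fragments

  me_dur <- sum(with(sections[sections$label != "click", , drop = FALSE],
                     end - begin))
  bout_dur <- .iv_total(grouped$bouts)
  total <- me_dur + bout_dur

  ratio_of <- function(lab) {
    if (!length(sig)) return(NA_real_)
    mean(vapply(sig, function(s)
      sum(with(s$sections[s$sections$label == lab, , drop = FALSE],
               end - begin)) / s$duration, numeric(1)))
  }

  list(trial_duration = trial_duration,
       total_signal_duration = total,
       n_signals = length(sig),
       duty_cycle = total / trial_duration,
       mean_signal_duration = if (length(sig))
         mean(vapply(sig, `[[`, numeric(1), "duration")) else NA_real_,
       me_ratio = stats::setNames(
         vapply(c("Me0", "Me1", "Me2", "Me3"), ratio_of, numeric(1)),
         c("Me0", "Me1", "Me2", "Me3")),
       masking_ratio = if (total > 0) bout_dur / total else NA_real_,
       interrupted_ratio = if (length(sig) + length(frag) > 0)
         length(frag) / (length(sig) + length(frag)) else NA_real_)
}
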