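#' @title Playback schedules and temporal masking statistics
#'
#' @description
#' Each trial exposes the male to playback on up to three channels: a
#' female-reply channel triggered by the male's own Me3 section, and for
#' noise treatments a contralateral channel looping a masking stimulus.
#' Schedules are lists of half-open on-intervals `[begin, end)` in seconds
#' from trial start. Overlap ("masking") statistics are purely temporal.
#'
#' @name masking_analysis
NULL

.TREATMENTS <- c("control_plus", "rival", "duet", "bionoise",
                 "anthronoise", "control_minus")

#' Treatment specification
#'
#' Encodes the playback design of the six treatment groups: the stimulus
#' durations (female reply 10.0 s, male advertisement signal 17.9 s, rival
#' masking signal 5.5 s, heterospecific noise signal 14.9 s, anthropogenic
#' noise 28.0 s looped continuously), the loop pauses (10 s between
#' heterospecific signals, 12.1 s between duet male signals) and the reply /
#' masking trigger rules relative to the end of the male's signal.
#'
#' @param name treatment name.
#' @param manual_offset_s anticipation of the manually triggered reply: the
#'   operator triggers the reply this many seconds before the end of Me3
#'   (the anticipation is not quantified in the protocol; default 1.0 s,
#'   configurable).
#' @param noise_phase_s phase offset of the noise loop relative to trial
#'   start (the loop phase was uncontrolled in the experiment; default 0).
#' @param durations optional named overrides of the stimulus durations
#'   (`reply`, `male_signal`, `masking`, `heterospecific`, `anthropogenic`),
#'   seconds.
#' @return an object of class `vib_treatment`.
#' @export
treatment_spec <- function(name = .TREATMENTS, manual_offset_s = 1.0,
                           noise_phase_s = 0, durations = list()) {
  name <- match.arg(name)
  dur <- list(reply = 10.0, male_signal = 17.9, masking = 5.5,
              heterospecific = 14.9, anthropogenic = 28.0)
  unknown <- setdiff(names(durations), names(dur))
  if (length(unknown))
    stop("unknown duration keys: ", paste(unknown, collapse = ", "))
  dur[names(durations)] <- durations
  structure(list(name = name, durations = dur,
                 loop_pause = list(bionoise = 10.0, duet_male = 12.1),
                 trigger = list(rival = c(pre = 4.1, post = 1.4),
                                duet  = c(pre = 1.5, post = 8.5)),
                 manual_offset_s = manual_offset_s,
                 noise_phase_s = noise_phase_s),
            class = "vib_treatment")
}

.schedule <- function(channel, iv, trial_duration) {
  iv <- .iv_clip(.iv_merge(iv), 0, trial_duration)
  structure(list(channel = channel, intervals = iv,
                 trial_duration = trial_duration),
            class = "vib_schedule")
}

#' @export
print.vib_schedule <- function(x, ...) {
  cat("<schedule ", x$channel, ": ", nrow(x$intervals), " on-intervals, ",
      signif(.iv_total(x$intervals), 4), " s on / ", x$trial_duration,
      " s trial>\n", sep = "")
  invisible(x)
}

#' Build the looped noise schedule of a treatment
#'
#' Heterospecific noise ("bionoise") loops a 14.9 s signal with a 10 s
#' pause; anthropogenic noise plays continuously; the duet treatment's male
#' channel loops the 17.9 s male signal with a 12.1 s pause. The controls
#' have no looped channel, and the rival treatment's masking channel is
#' triggered by the male's signals (see [build_triggered_schedule()]), so
#' these return an empty schedule.
#'
#' @param spec a [treatment_spec()].
#' @param trial_duration trial length in seconds.
#' @return a `vib_schedule` for channel `"noise"` (or `"male_playback"` for
#'   the duet treatment).
#' @export
build_noise_schedule <- function(spec, trial_duration) {
  stopifnot(inherits(spec, "vib_treatment"))
  if (!is.finite(trial_duration) || trial_duration <= 0)
    stop("trial_duration must be positive")
  ph <- spec$noise_phase_s
  loop <- function(on, pause) {
    period <- on + pause
    k <- seq(floor(-ph / period) - 1, ceiling(trial_duration / period) + 1)
    .iv(k * period + ph, k * period + ph + on)
  }
  switch(spec$name,
    bionoise = .schedule("noise",
      loop(spec$durations$heterospecific, spec$loop_pause$bionoise),
      trial_duration),
    anthronoise = .schedule("noise", .iv(0, trial_duration), trial_duration),
    duet = .schedule("male_playback",
      loop(spec$durations$male_signal, spec$loop_pause$duet_male),
      trial_duration),
    control_plus = ,
    control_minus = ,
    rival = .schedule("noise", .iv_empty(), trial_duration)
  )
}

#' Build a reply or masking schedule triggered by the male's signals
#'
#' For each complete signal's Me3 end time `t`: the rival masking signal
#' plays on `[t - 4.1, t + 1.4)` (5.5 s); the duet reply plays on
#' `[t - 1.5, t + 8.5)` (10 s); the manually triggered reply of the other
#' playback treatments plays for 10 s starting `manual_offset_s` before the
#' Me3 end. Signals lacking Me3 are skipped with a warning.
#'
#' @param signals list of `vib_signal` objects from [group_signals()], or a
#'   numeric vector of Me3 end times.
#' @param spec a [treatment_spec()].
#' @param channel `"reply"` or `"masking"` (masking only meaningful for the
#'   rival treatment).
#' @param trial_duration trial length in seconds.
#' @return a `vib_schedule`.
#' @export
build_triggered_schedule <- function(signals, spec,
                                     channel = c("reply", "masking"),
                                     trial_duration) {
  stopifnot(inherits(spec, "vib_treatment"))
  channel <- match.arg(channel)
  if (is.numeric(signals)) {
    ends <- signals
  } else {
    ends <- vapply(signals, function(s) {
      me3 <- s$sections[s$sections$label == "Me3", , drop = FALSE]
      if (!nrow(me3)) NA_real_ else max(me3$end)
    }, numeric(1))
    if (anyNA(ends)) {
      warning(sum(is.na(ends)), " signal(s) without Me3 skipped")
      ends <- ends[!is.na(ends)]
    }
  }
  if (spec$name == "control_minus" ||
      (channel == "masking" && spec$name != "rival") || !length(ends))
    return(.schedule(channel, .iv_empty(), trial_duration))
  iv <- if (channel == "masking") {
    tr <- spec$trigger$rival
    .iv(ends - tr[["pre"]], ends + tr[["post"]])
  } else if (spec$name == "duet") {
    tr <- spec$trigger$duet
    .iv(ends - tr[["pre"]], ends + tr[["post"]])
  } else {
    t0 <- ends - spec$manual_offset_s
    .iv(t0, t0 + spec$durations$reply)
  }
  .schedule(channel, iv, trial_duration)
}

#' Fraction of onsets falling inside noise playback
#'
#' An onset exactly at a noise offset counts as outside (half-open
#' convention).
#'
#' @param onsets numeric vector of onset times, seconds.
#' @param noise a `vib_schedule`.
#' @return fraction in `[0, 1]`, or `NA` for an empty onset list.
#' @export
onset_in_noise_fraction <- function(onsets, noise) {
  stopifnot(inherits(noise, "vib_schedule"))
  if (!length(onsets)) return(NA_real_)
  mean(.iv_contains(noise$intervals, onsets))
}

#' Expected onset-in-noise fraction under random onset timing
#'
#' The noise schedule's duty cycle: total on-time divided by trial
#' duration. This is the fraction of onsets expected to fall in noise if
#' onset timing were independent of the playback.
#'
#' @param noise a `vib_schedule`.
#' @return fraction in `[0, 1]`.
#' @export
expected_onset_fraction <- function(noise) {
  stopifnot(inherits(noise, "vib_schedule"))
  .iv_total(noise$intervals) / noise$trial_duration
}

#' Fraction of target intervals covered by noise
#'
#' For each target interval, the fraction of its duration overlapped by the
#' noise schedule's on-intervals. With `per_trial_mean = TRUE` (the
#' trial-averaging used for reply masking) the unweighted mean over
#' intervals is returned; otherwise the duration-weighted pooled fraction.
#'
#' @param targets two-column matrix or data.frame of `[begin, end)` times,
#'   seconds.
#' @param noise a `vib_schedule`.
#' @param per_trial_mean average per-interval fractions (default) or pool.
#' @return fraction in `[0, 1]`, `NA` if there are no target intervals.
#' @export
coverage_fraction <- function(targets, noise, per_trial_mean = TRUE) {
  stopifnot(inherits(noise, "vib_schedule"))
  targets <- as.matrix(targets)
  if (!nrow(targets)) return(NA_real_)
  if (any(targets[, 2L] <= targets[, 1L]))
    stop("zero-length or inverted target interval")
  ov <- vapply(seq_len(nrow(targets)), function(k)
    .iv_overlap1(targets[k, 1L], targets[k, 2L], noise$intervals), numeric(1))
  dur <- targets[, 2L] - targets[, 1L]
  if (per_trial_mean) mean(ov / dur) else sum(ov) / sum(dur)
}
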