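#' @title Synthetic trials with known ground truth
#'
#' @description
#' Event-driven continuous-time simulation of a playback trial: a male on
#' the arena tree emits advertisement signals from a renewal process whose
#' onset hazard is thinned by a gap-avoidance factor while masking noise
#' plays, each complete signal's Me3 end triggers the treatment's female
#' reply, replies trigger fast directed search bouts, and ordinary walking
#' is a persistent random walk over the subsection graph. A trial ends at
#' the cutoff, when the male reaches the target, or when it leaves the
#' plant, whichever comes first. Identical seeds give identical records.
#'
#' @name synthetic_trials
NULL

#' Simulation parameters
#'
#' Movement, signaling and trial-protocol parameters with defaults chosen
#' to emulate the annotated trials. Anchored values: signal duration 17.9 s
#' mean, 900 s cutoff, 5 trials per male, junction correctness 0.5,
#' gap-avoidance factor 0.23 (calibrated so that with the heterospecific
#' noise loop about a quarter of signal onsets fall in noise). Quantities
#' the protocol does not constrain (inter-signal interval distribution,
#' movement rates, bout lengths, random-effect SDs) are free parameters
#' documented in the methods vignette.
#'
#' @param move_hazard walking-step hazard, steps/s.
#' @param p_correct probability of taking the branch toward the target at
#'   the crossing during search.
#' @param reversal_prob per-step probability of turning back while walking
#'   away from the crossing on a non-target chain.
#' @param search_trigger_prob probability a female reply triggers a search
#'   bout.
#' @param search_bout_len mean number of steps per search bout.
#' @param search_rate step hazard during search bouts, steps/s.
#' @param isi_meanlog,isi_sdlog lognormal inter-signal interval (silent gap
#'   between signals), log-seconds.
#' @param signal_mean,signal_sd normal signal duration, s (truncated below
#'   at 5 s).
#' @param me_prop section composition: proportions of signal duration in
#'   Me0--Me3, summing to 1.
#' @param gamma gap-avoidance factor in `[0, 1]` multiplying the onset
#'   hazard while noise plays (1 = no avoidance, 0 = complete avoidance).
#' @param p_interrupt probability a signal is interrupted before Me3
#'   (yielding a fragment that triggers no reply).
#' @param cutoff trial cutoff, s.
#' @param stop_on_target end the trial when the male reaches the target.
#' @param leave_hazard hazard of leaving the plant, events/s.
#' @param trials_per_male trials per male in a cohort.
#' @param n_plants plant pool size per cohort.
#' @param n_operators number of operators.
#' @param sd_male,sd_plant,sd_operator SDs of lognormal random intercepts
#'   applied to the movement and signaling rates.
#' @param treatment_effects named list: treatment name -> list of
#'   multipliers among `isi_mult` (inter-signal interval), `duration_mult`
#'   (signal duration), `search_trigger_mult`, `move_hazard_mult`.
#' @return object of class `vib_sim_params`.
#' @export
simulation_params <- function(move_hazard = 0.04, p_correct = 0.5,
                              reversal_prob = 0.3,
                              search_trigger_prob = 0.8,
                              search_bout_len = 8, search_rate = 1.0,
                              isi_meanlog = log(35), isi_sdlog = 0.6,
                              signal_mean = 17.9, signal_sd = 2.5,
                              me_prop = c(Me0 = 0.05, Me1 = 0.25,
                                          Me2 = 0.30, Me3 = 0.40),
                              gamma = 0.23, p_interrupt = 0.05,
                              cutoff = 900, stop_on_target = TRUE,
                              leave_hazard = 1 / 3600,
                              trials_per_male = 5L, n_plants = 12L,
                              n_operators = 3L,
                              sd_male = 0.2, sd_plant = 0.2,
                              sd_operator = 0,
                              treatment_effects = list()) {
  stopifnot(move_hazard >= 0, p_correct >= 0, p_correct <= 1,
            reversal_prob >= 0, reversal_prob <= 1,
            search_trigger_prob >= 0, search_trigger_prob <= 1,
            gamma >= 0, gamma <= 1, p_interrupt >= 0, p_interrupt <= 1,
            cutoff > 0, leave_hazard >= 0,
            abs(sum(me_prop) - 1) < 1e-8)
  p <- as.list(environment())
  structure(p, class = "vib_sim_params")
}

# chain layout helpers: positions along a chain indexed 1..K from crossing
.chain_sections <- function(n) list(
  apex = data.frame(section = "stem_upper", subsection = seq_len(n)),
  base = data.frame(section = "stem_lower", subsection = seq_len(n)),
  ipsi = rbind(data.frame(section = "stalk_ipsi", subsection = seq_len(n)),
               data.frame(section = "leaf_ipsi", subsection = seq_len(n))),
  contra = rbind(data.frame(section = "stalk_contra", subsection = seq_len(n)),
                 data.frame(section = "leaf_contra", subsection = seq_len(n))))

# generate the signal train: list(sections = data.frame, me3_ends = numeric)
.sim_signals <- function(p, thin_iv, t_max) {
  lab4 <- c("Me0", "Me1", "Me2", "Me3")
  rows <- list(); me3_ends <- numeric(0)
  t_cursor <- stats::runif(1, 0, 10)  # settling time before first attempt
  repeat {
    onset <- t_cursor + stats::rlnorm(1, p$isi_meanlog, p$isi_sdlog)
    if (onset >= t_max) break
    if (.iv_contains(thin_iv, onset) && stats::runif(1) > p$gamma) {
      t_cursor <- onset  # onset suppressed by gap avoidance
      next
    }
    dur <- max(5, stats::rnorm(1, p$signal_mean, p$signal_sd))
    props <- p$me_prop[p$me_prop > 0]
    labs <- names(props)
    ends <- onset + cumsum(dur * props / sum(props))
    begins <- c(onset, ends[-length(ends)])
    if (stats::runif(1) < p$p_interrupt && length(labs) > 1) {
      keep <- seq_len(sample(length(labs) - 1L, 1L))  # truncated before Me3
      labs <- labs[keep]; begins <- begins[keep]; ends <- ends[keep]
    }
    rows[[length(rows) + 1L]] <-
      data.frame(label = labs, begin = begins, end = unname(ends))
    if ("Me3" %in% labs) me3_ends <- c(me3_ends, ends[[length(ends)]])
    t_cursor <- ends[[length(ends)]]
  }
  sections <- if (length(rows)) do.call(rbind, rows)
    else data.frame(label = character(0), begin = numeric(0), end = numeric(0))
  rownames(sections) <- NULL
  list(sections = sections, me3_ends = me3_ends)
}

#' Simulate one trial
#'
#' @param params a [simulation_params()].
#' @param treatment a [treatment_spec()] or treatment name.
#' @param arena a [build_arena()] result.
#' @param seed optional integer seed (omit inside [simulate_cohort()] to
#'   inherit the RNG stream).
#' @return a [trial_record()] with `ground_truth` holding the generating
#'   parameters.
#' @export
simulate_trial <- function(params, treatment, arena, seed = NULL) {
  stopifnot(inherits(params, "vib_sim_params"), inherits(arena, "vib_arena"))
  if (!is.null(seed)) set.seed(seed)
  trt <- if (inherits(treatment, "vib_treatment")) treatment
         else treatment_spec(treatment)
  p <- params
  n <- arena$spec$subsections
  chains <- .chain_sections(n)
  cutoff <- p$cutoff

  loop_sched <- build_noise_schedule(trt, cutoff)
  thin_iv <- loop_sched$intervals

  sig <- .sim_signals(p, thin_iv, cutoff)

  # replies: duet replies follow the looped male playback; other playback
  # treatments reply to the focal male's Me3
  reply <- if (trt$name == "duet") {
    build_triggered_schedule(loop_sched$intervals[, 2L], trt, "reply", cutoff)
  } else {
    build_triggered_schedule(sig$me3_ends, trt, "reply", cutoff)
  }
  masking <- build_triggered_schedule(sig$me3_ends, trt, "masking", cutoff)

  # reply onsets that trigger search bouts
  reply_onsets <- if (nrow(reply$intervals)) reply$intervals[, 1L] else numeric(0)
  triggers <- reply_onsets[stats::runif(length(reply_onsets)) <
                             p$search_trigger_prob]
  triggers <- sort(triggers[triggers >= 0 & triggers < cutoff])

  t_leave <- if (p$leave_hazard > 0) stats::rexp(1, p$leave_hazard) else Inf
  t_limit <- min(cutoff, t_leave)

  # start: chain position of the arena start (apex chain, distal index)
  start_chain <- "apex"; start_idx <- arena$start$subsection
  target_chain <- "ipsi"; target_idx <- n + arena$target$subsection

  chain_len <- vapply(chains, nrow, integer(1))
  pos_chain <- start_chain; pos_idx <- start_idx
  heading <- -1L  # males tend to walk down from the apex first
  bout_left <- 0L; trig_i <- 1L
  t <- 0
  ev_t <- numeric(0); ev_sec <- character(0); ev_sub <- integer(0)
  ev_cl <- character(0)
  t_found <- Inf

  repeat {
    rate <- if (bout_left > 0L) p$search_rate else p$move_hazard
    dt <- if (rate > 0) stats::rexp(1, rate) else Inf
    te <- t + dt
    # a pending triggered reply interrupts the wait and starts a bout
    if (trig_i <= length(triggers) && triggers[trig_i] < te) {
      t <- triggers[trig_i]; trig_i <- trig_i + 1L
      if (t >= t_limit) break
      bout_left <- max(1L, stats::rpois(1, p$search_bout_len))
      next
    }
    if (te >= t_limit) break
    t <- te
    searching <- bout_left > 0L
    if (searching) {
      heading <- if (pos_chain == target_chain) 1L else -1L
      bout_left <- bout_left - 1L
    } else if (pos_chain != target_chain && heading == 1L &&
               stats::runif(1) < p$reversal_prob) {
      heading <- -1L
    }
    if (pos_idx == 1L && heading == -1L) {
      # step across the zero-length crossing into another chain
      if (searching) {
        if (stats::runif(1) < p$p_correct) {
          new_chain <- target_chain
        } else {
          new_chain <- sample(setdiff(names(chains),
                                      c(target_chain, pos_chain)), 1L)
        }
      } else {
        new_chain <- sample(setdiff(names(chains), pos_chain), 1L)
      }
      pos_chain <- new_chain; pos_idx <- 1L; heading <- 1L
    } else {
      if (pos_idx == chain_len[[pos_chain]] && heading == 1L) heading <- -1L
      pos_idx <- pos_idx + heading
    }
    here <- chains[[pos_chain]][pos_idx, ]
    ev_t <- c(ev_t, t); ev_sec <- c(ev_sec, here$section)
    ev_sub <- c(ev_sub, here$subsection)
    ev_cl <- c(ev_cl, if (searching) "search" else "walk")
    if (pos_chain == target_chain && pos_idx == target_idx &&
        p$stop_on_target) { t_found <- t; break }
  }

  t_end <- min(t_limit, t_found)
  keep <- ev_t <= t_end
  trajectory <- data.frame(time = ev_t[keep], section = ev_sec[keep],
                           subsection = ev_sub[keep], class = ev_cl[keep],
                           stringsAsFactors = FALSE)
  sections <- sig$sections[sig$sections$begin < t_end, , drop = FALSE]
  sections$end <- pmin(sections$end, t_end)
  sections <- sections[sections$end > sections$begin, , drop = FALSE]

  clip_sched <- function(s) .schedule(s$channel, .iv_clip(s$intervals, 0, t_end),
                                      t_end)
  schedules <- list(noise = clip_sched(loop_sched),
                    reply = clip_sched(reply),
                    masking = clip_sched(masking))

  trial_record(trajectory = trajectory, sections = sections,
               schedules = schedules, treatment = trt$name,
               trial_duration = t_end,
               ground_truth = list(params = p, treatment = trt$name,
                                   found = is.finite(t_found),
                                   left_plant = t_leave < min(cutoff, t_found),
                                   me3_ends = sig$me3_ends))
}

#' Simulate a cohort of males across treatments
#'
#' Males are assigned to treatments in equal groups; male-, plant- and
#' operator-level lognormal random intercepts perturb the movement and
#' signaling rates, and per-treatment fixed effects (multipliers in
#' `params$treatment_effects`) are applied on top. Each male is tested
#' `trials_per_male` times.
#'
#' @param params a [simulation_params()].
#' @param treatments character vector of treatment names.
#' @param n_males_per_treatment males per treatment (>= 2).
#' @param arena a [build_arena()] result.
#' @param seed integer seed.
#' @return list with `trials` (records), `metrics` (tidy metrics table via
#'   [metrics_table()]), and `ground_truth` (per-male effects and the
#'   injected treatment effects).
#' @export
simulate_cohort <- function(params, treatments = .TREATMENTS,
                            n_males_per_treatment = 14L, arena, seed = 1L) {
  stopifnot(n_males_per_treatment >= 2)
  set.seed(seed)
  p <- params
  males <- expand.grid(treatment = treatments,
                       male_in_group = seq_len(n_males_per_treatment),
                       stringsAsFactors = FALSE)
  males$male_id <- sprintf("m%03d", seq_len(nrow(males)))
  males$operator <- sprintf("op%d", 1 + (seq_len(nrow(males)) %% p$n_operators))
  males$male_eff <- stats::rnorm(nrow(males), 0, p$sd_male)
  plant_eff <- stats::setNames(stats::rnorm(p$n_plants, 0, p$sd_plant),
                               sprintf("p%02d", seq_len(p$n_plants)))
  op_eff <- stats::setNames(stats::rnorm(p$n_operators, 0, p$sd_operator),
                            sprintf("op%d", seq_len(p$n_operators)))
  trials <- vector("list", nrow(males) * p$trials_per_male)
  k <- 0L
  for (i in seq_len(nrow(males))) {
    m <- males[i, ]
    eff <- p$treatment_effects[[m$treatment]]
    mult <- function(key) if (!is.null(eff[[key]])) eff[[key]] else 1
    for (rep_i in seq_len(p$trials_per_male)) {
      plant <- sample(names(plant_eff), 1L)
      ri <- m$male_eff + plant_eff[[plant]] + op_eff[[m$operator]]
      pi <- p
      pi$move_hazard <- p$move_hazard * exp(ri) * mult("move_hazard_mult")
      pi$isi_meanlog <- p$isi_meanlog - ri + log(mult("isi_mult"))
      pi$signal_mean <- p$signal_mean * mult("duration_mult")
      pi$search_trigger_prob <- min(1, p$search_trigger_prob *
                                      mult("search_trigger_mult"))
      rec <- simulate_trial(pi, m$treatment, arena)
      rec$male_id <- m$male_id; rec$plant_id <- plant
      rec$operator <- m$operator; rec$repetition <- rep_i
      k <- k + 1L
      trials[[k]] <- rec
    }
  }
  list(trials = trials,
       metrics = metrics_table(trials, arena),
       ground_truth = list(males = males, plant_eff = plant_eff,
                           op_eff = op_eff,
                           treatment_effects = p$treatment_effects,
                           seed = seed))
}
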