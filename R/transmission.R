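#' @title Two-axis vibration transmission analysis
#'
#' @description
#' At a single analysis frequency (the playback's 430 Hz dominant
#' frequency by default), a point on the stem or a stalk traces an ellipse
#' in the plane perpendicular to the rod. From the complex amplitudes of
#' the two perpendicular velocity channels, the semi-major and semi-minor
#' axes of that motion ellipse are computed; the semi-major amplitude in dB
#' relative to a reference point summarizes local transmission, averaged
#' across plants into an amplitude map of the arena.
#'
#' @name transmission
NULL

#' Single-frequency complex amplitude
#'
#' Amplitude (peak) and phase of the `f0` component via a discrete Fourier
#' projection over the largest integer number of cycles that fits in the
#' series, with a flat window -- exact for noiseless sinusoids.
#'
#' @param series numeric samples (velocity, arbitrary consistent units).
#' @param sample_rate sampling rate, Hz.
#' @param f0 analysis frequency, Hz (default 430); must be below Nyquist.
#' @return list with `amplitude` (peak, input units) and `phase` (radians,
#'   of a cosine convention: the signal `A*cos(2*pi*f0*t + phase)`).
#' @export
complex_amplitude <- function(series, sample_rate, f0 = 430) {
  if (f0 >= sample_rate / 2) stop("f0 must be below the Nyquist frequency")
  n_cycles <- floor(length(series) * f0 / sample_rate)
  if (n_cycles < 2) stop("series must span at least 2 cycles of f0")
  n <- floor(n_cycles * sample_rate / f0)
  t <- (seq_len(n) - 1) / sample_rate
  z <- sum(series[seq_len(n)] * exp(-2i * pi * f0 * t)) * 2 / n
  list(amplitude = Mod(z), phase = Arg(z))
}

#' Motion-ellipse semi-axes from two-channel amplitudes and phases
#'
#' For channel motions `Ax*cos(wt + phix)` and `Ay*cos(wt + phiy)` the
#' traced ellipse has semi-axes `a >= b` with `a^2 + b^2 = Ax^2 + Ay^2` and
#' `a*b = Ax*Ay*|sin(dphi)|`, and orientation
#' `theta = atan2(2*Ax*Ay*cos(dphi), Ax^2 - Ay^2) / 2`, where
#' `dphi = phiy - phix`.
#'
#' @param Ax,Ay channel amplitudes (>= 0).
#' @param phix,phiy channel phases, radians.
#' @return list with `a` (semi-major), `b` (semi-minor), `theta`
#'   (orientation in `(-pi/2, pi/2]`).
#' @export
ellipse_axes <- function(Ax, phix, Ay, phiy) {
  if (Ax < 0 || Ay < 0) stop("amplitudes must be non-negative")
  dphi <- phiy - phix
  S <- Ax^2 + Ay^2
  P <- Ax * Ay * abs(sin(dphi))
  disc <- sqrt(max(0, S^2 - 4 * P^2))
  a <- sqrt((S + disc) / 2)
  b <- sqrt(max(0, (S - disc) / 2))
  theta <- atan2(2 * Ax * Ay * cos(dphi), Ax^2 - Ay^2) / 2
  list(a = a, b = b, theta = theta)
}

#' Amplitude ratio in decibels
#'
#' @param amplitude amplitude (same units as the reference).
#' @param reference_amplitude reference amplitude (> 0).
#' @return `20*log10(amplitude/reference)`; `-Inf` for zero amplitude.
#' @export
to_db <- function(amplitude, reference_amplitude) {
  if (any(reference_amplitude <= 0)) stop("reference amplitude must be positive")
  if (any(amplitude < 0)) stop("amplitude must be non-negative")
  ifelse(amplitude == 0, -Inf, 20 * log10(amplitude / reference_amplitude))
}

#' Build a two-axis (or single-axis leaf) recording
#'
#' @param x,y numeric sample vectors; `y = NULL` for single-plane leaf
#'   measurements.
#' @param sample_rate Hz.
#' @param section,subsection the measurement [location()].
#' @param plant_id plant identifier.
#' @return an object of class `vib_recording`.
#' @export
two_axis_recording <- function(x, y = NULL, sample_rate, section, subsection,
                               plant_id = 1L) {
  if (!is.null(y) && length(x) != length(y))
    stop("x and y series must have equal length")
  structure(list(x = as.numeric(x), y = if (is.null(y)) NULL else as.numeric(y),
                 sample_rate = sample_rate,
                 location = location(section, subsection),
                 plant_id = plant_id),
            class = "vib_recording")
}

# semi-major amplitude of one recording at f0 (single-axis: plain amplitude)
.rec_amplitude <- function(rec, f0) {
  cx <- complex_amplitude(rec$x, rec$sample_rate, f0)
  if (is.null(rec$y)) return(cx$amplitude)
  cy <- complex_amplitude(rec$y, rec$sample_rate, f0)
  ellipse_axes(cx$amplitude, cx$phase, cy$amplitude, cy$phase)$a
}

#' Amplitude map of the arena
#'
#' For every recording the semi-major motion-ellipse amplitude at `f0` is
#' computed (single-axis leaf recordings use the plain channel amplitude),
#' expressed in dB relative to the same plant's reference-location
#' recording, and averaged arithmetically in the dB domain across plants at
#' equivalent locations.
#'
#' @param recordings list of [two_axis_recording()]s; each plant must
#'   include a recording at the reference location.
#' @param f0 analysis frequency, Hz.
#' @param reference reference [location()] (0 dB by construction).
#' @param average `"db"` (mean of dB values, default) or `"linear"` (dB of
#'   the mean linear amplitude ratio).
#' @return object of class `vib_amplitude_map`: data.frame with `section`,
#'   `subsection`, `db`, `n_plants`, plus the reference location.
#' @export
amplitude_map <- function(recordings, f0 = 430, reference,
                          average = c("db", "linear")) {
  average <- match.arg(average)
  stopifnot(inherits(reference, "vib_location"))
  plants <- unique(vapply(recordings, function(r) as.character(r$plant_id),
                          character(1)))
  rows <- list()
  for (p in plants) {
    recs <- Filter(function(r) as.character(r$plant_id) == p, recordings)
    locs <- vapply(recs, function(r) format(r$location), character(1))
    ref_k <- which(locs == format(reference))
    if (!length(ref_k))
      stop("plant ", p, " has no recording at the reference location ",
           format(reference))
    amps <- vapply(recs, .rec_amplitude, numeric(1), f0 = f0)
    ref_amp <- amps[ref_k[1L]]
    if (ref_amp <= 0) stop("plant ", p, ": zero amplitude at the reference")
    rows[[p]] <- data.frame(
      plant_id = p,
      section = vapply(recs, function(r) r$location$section, character(1)),
      subsection = vapply(recs, function(r) r$location$subsection, integer(1)),
      ratio = amps / ref_amp,
      db = to_db(amps, ref_amp))
  }
  all <- do.call(rbind, rows)
  key <- interaction(all$section, all$subsection, drop = TRUE)
  agg <- do.call(rbind, lapply(split(all, key), function(g) {
    data.frame(section = g$section[1L], subsection = g$subsection[1L],
               db = if (average == "db") mean(g$db)
                    else to_db(mean(g$ratio), 1),
               n_plants = nrow(g))
  }))
  agg <- agg[order(agg$section, agg$subsection), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(map = agg, reference = reference, f0 = f0,
                 average = average),
            class = "vib_amplitude_map")
}

#' @export
print.vib_amplitude_map <- function(x, ...) {
  cat("<amplitude map: ", nrow(x$map), " locations, ", x$f0,
      " Hz, dB re ", format(x$reference), ">\n", sep = "")
  print(utils::head(x$map, 10))
  if (nrow(x$map) > 10) cat("...\n")
  invisible(x)
}

#' Amplitude-gradient diagnostics along the arena
#'
#' Tests whether the mapped amplitude provides a usable gradient toward
#' the playback source: for each tip-to-source path, whether amplitude
#' increases strictly at every mapped step toward the source, and the
#' Pearson correlation between dB amplitude and path distance to the
#' source over all mapped locations.
#'
#' @param map a [amplitude_map()] result (>= 3 mapped locations).
#' @param arena a [build_arena()] result.
#' @param source source [location()] (e.g. the arena target).
#' @return list: `paths` data.frame (tip chain, `n_points`, `monotone`),
#'   `correlation` (`r`, `p`; `NA` for a constant map).
#' @export
gradient_diagnostics <- function(map, arena, source = arena$target) {
  stopifnot(inherits(map, "vib_amplitude_map"))
  m <- map$map
  if (nrow(m) < 3) stop("amplitude map must cover at least 3 locations")
  d_src <- .path_dist_vec(arena, m$section, m$subsection,
                          rep(source$section, nrow(m)),
                          rep(source$subsection, nrow(m)))
  tips <- list(apex = "stem_upper", base = "stem_lower",
               ipsi = c("stalk_ipsi", "leaf_ipsi"),
               contra = c("stalk_contra", "leaf_contra"))
  paths <- do.call(rbind, lapply(names(tips), function(nm) {
    sel <- m$section %in% tips[[nm]]
    if (sum(sel) < 2)
      return(data.frame(path = nm, n_points = sum(sel), monotone = NA))
    ord <- order(d_src[sel], decreasing = TRUE)  # from tip toward source
    db_path <- m$db[sel][ord]
    data.frame(path = nm, n_points = sum(sel),
               monotone = all(diff(db_path) > 0))
  }))
  corr <- if (stats::sd(m$db) == 0 || stats::sd(d_src) == 0) {
    list(r = NA_real_, p = NA_real_)
  } else {
    ct <- stats::cor.test(m$db, d_src)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  list(paths = paths, correlation = corr)
}
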