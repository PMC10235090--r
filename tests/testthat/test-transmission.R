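make_sine <- function(A, phase, f0 = 430, fs = 8000, dur = 0.5) {
  t <- seq(0, dur, by = 1 / fs)
  A * cos(2 * pi * f0 * t + phase)
}

test_that("single-bin projection recovers amplitude and phase exactly", {
  x <- make_sine(1.0, 0.7)
  ca <- complex_amplitude(x, 8000, 430)
  expect_equal(ca$amplitude, 1.0, tolerance = 1e-9)
  expect_equal(ca$phase, 0.7, tolerance = 1e-9)
  expect_equal(complex_amplitude(rep(0, 4000), 8000, 430)$amplitude, 0)
  expect_error(complex_amplitude(x, 800, 430), "Nyquist")
  expect_error(complex_amplitude(x[1:10], 8000, 430), "2 cycles")
})

test_that("projection amplitude is robust to 20 dB SNR white noise", {
  set.seed(71)
  for (k in 1:10) {
    A <- runif(1, 0.5, 2)
    x <- make_sine(A, runif(1, -pi, pi), dur = 1)
    x <- x + rnorm(length(x), 0, A / 10 / sqrt(2))  # ~20 dB SNR
    expect_equal(complex_amplitude(x, 8000, 430)$amplitude, A,
                 tolerance = 0.05)
  }
})

test_that("ellipse axes handle circular and degenerate motion", {
  circ <- ellipse_axes(1, 0, 1, pi / 2)
  expect_equal(circ$a, 1)
  expect_equal(circ$b, 1)
  lin <- ellipse_axes(3, 0, 4, 0)  # in-phase: straight line of length 5
  expect_equal(lin$a, 5)
  expect_equal(lin$b, 0)
  expect_error(ellipse_axes(-1, 0, 1, 0), "non-negative")
})

test_that("ellipse axes match the dense parametric-sampling oracle", {
  ax <- ellipse_axes(2, 0, 1, pi / 3)
  orc <- oracle_ellipse(2, 0, 1, pi / 3)
  expect_equal(ax$a, orc$a, tolerance = 1e-6)
  expect_equal(ax$b, orc$b, tolerance = 1e-6)
  # algebraic identities a^2 + b^2 = S, a*b = P
  expect_equal(ax$a^2 + ax$b^2, 2^2 + 1^2)
  expect_equal(ax$a * ax$b, 2 * 1 * abs(sin(pi / 3)))
})

test_that("ellipse axes are invariant to common phase and channel swap", {
  set.seed(81)
  for (k in 1:50) {
    Ax <- runif(1, 0, 3); Ay <- runif(1, 0, 3)
    px <- runif(1, -pi, pi); py <- runif(1, -pi, pi); c0 <- runif(1, -pi, pi)
    e1 <- ellipse_axes(Ax, px, Ay, py)
    e2 <- ellipse_axes(Ax, px + c0, Ay, py + c0)
    e3 <- ellipse_axes(Ay, py, Ax, px)
    expect_equal(e1$a, e2$a, tolerance = 1e-10)
    expect_equal(e1$b, e2$b, tolerance = 1e-10)
    expect_equal(e1$a, e3$a, tolerance = 1e-10)
    expect_gte(e1$a + 1e-12, max(Ax, Ay))
    expect_gte(e1$b, 0)
    expect_true(e1$theta > -pi / 2 - 1e-12 && e1$theta <= pi / 2 + 1e-12)
  }
})

test_that("dB conversion is a 20 log10 ratio", {
  expect_equal(to_db(1, 1), 0)
  expect_equal(to_db(2, 1), 20 * log10(2))
  expect_equal(to_db(10, 1), 20)
  expect_equal(to_db(0, 1), -Inf)
  expect_error(to_db(1, 0), "positive")
})

# y channel in quadrature at 0.4x amplitude: the ellipse semi-major equals
# the x amplitude exactly, so two-axis and single-axis (leaf) points share
# one constructed dB scale
make_plant <- function(plant_id, db_by_loc, ref_loc, f0 = 430, fs = 8000,
                       noise_phase = pi / 2) {
  lapply(seq_len(nrow(db_by_loc)), function(k) {
    amp <- 10^(db_by_loc$db[k] / 20)
    leaf <- startsWith(db_by_loc$section[k], "leaf")
    two_axis_recording(
      x = make_sine(amp, 0.2, f0, fs),
      y = if (leaf) NULL else make_sine(amp * 0.4, 0.2 + noise_phase, f0, fs),
      sample_rate = fs, section = db_by_loc$section[k],
      subsection = db_by_loc$subsection[k], plant_id = plant_id)
  })
}

test_that("amplitude map recovers a constructed dB field", {
  locs <- data.frame(section = c("stem_upper", "stem_upper", "stalk_ipsi",
                                 "leaf_ipsi"),
                     subsection = c(1L, 5L, 5L, 9L))
  ref <- location("stem_upper", 1)
  # plant A: flat field; all points at the reference amplitude
  flat <- transform(locs, db = 0)
  mapA <- amplitude_map(make_plant("A", flat, ref), reference = ref)
  expect_true(all(abs(mapA$map$db) < 1e-6))

  # two plants with mirrored fields average to 0 dB under dB-domain averaging
  grad <- transform(locs, db = c(0, -3, -6, -9))
  mirr <- transform(locs, db = c(0, 3, 6, 9))
  map2 <- amplitude_map(c(make_plant("A", grad, ref),
                          make_plant("B", mirr, ref)), reference = ref)
  expect_true(all(abs(map2$map$db) < 1e-6))
  expect_equal(unique(map2$map$n_plants), 2L)

  # a known decay law is recovered within numeric tolerance
  map1 <- amplitude_map(make_plant("A", grad, ref), reference = ref)
  got <- merge(map1$map, grad, by = c("section", "subsection"))
  expect_equal(got$db.x, got$db.y, tolerance = 1e-6)

  expect_error(amplitude_map(make_plant("A", flat, ref),
                             reference = location("stem_lower", 9)),
               "reference")
})

test_that("gradient diagnostics detect monotone fields and flat maps", {
  a <- default_arena()
  ref <- location("stem_upper", 1)
  locs <- expand.grid(section = c("stem_upper", "stalk_ipsi", "leaf_ipsi",
                                  "stalk_contra", "leaf_contra"),
                      subsection = c(2L, 7L), stringsAsFactors = FALSE)
  d_src <- vapply(seq_len(nrow(locs)), function(k)
    path_distance(a, location(locs$section[k], locs$subsection[k]),
                  a$target), numeric(1))
  dec <- transform(locs, db = -0.1 * d_src)
  map_dec <- amplitude_map(make_plant("A", dec, location("stem_upper", 2)),
                           reference = location("stem_upper", 2))
  gd <- gradient_diagnostics(map_dec, a, source = a$target)
  expect_true(all(gd$paths$monotone[!is.na(gd$paths$monotone)]))
  expect_equal(gd$correlation$r, -1, tolerance = 1e-6)

  flat_map <- amplitude_map(make_plant("A", transform(locs, db = 0),
                                       location("stem_upper", 2)),
                            reference = location("stem_upper", 2))
  gd_flat <- gradient_diagnostics(flat_map, a, source = a$target)
  expect_true(is.na(gd_flat$correlation$r))
  expect_error(gradient_diagnostics(
    amplitude_map(make_plant("A", dec[1:2, ], location("stem_upper", 2)),
                  reference = location("stem_upper", 2)), a), "3 locations")
})

test_that("monotonicity flags agree with a pairwise comparison oracle", {
  a <- default_arena()
  set.seed(91)
  for (k in 1:10) {
    locs <- data.frame(section = c(rep("stem_upper", 4), rep("stalk_ipsi", 2),
                                   rep("leaf_ipsi", 3)),
                       subsection = c(1L, 3L, 6L, 9L, 2L, 8L, 2L, 5L, 9L))
    fld <- transform(locs, db = round(rnorm(nrow(locs), 0, 4), 2))
    fld$db[1] <- 0
    mp <- amplitude_map(make_plant("A", fld, location("stem_upper", 1)),
                        reference = location("stem_upper", 1))
    gd <- gradient_diagnostics(mp, a, source = a$target)
    m <- mp$map
    d_src <- vapply(seq_len(nrow(m)), function(i)
      path_distance(a, location(m$section[i], m$subsection[i]), a$target),
      numeric(1))
    for (nm in c("apex", "ipsi")) {
      secs <- if (nm == "apex") "stem_upper" else c("stalk_ipsi", "leaf_ipsi")
      sel <- m$section %in% secs
      ord <- order(d_src[sel], decreasing = TRUE)
      vals <- m$db[sel][ord]
      oracle_mono <- all(outer(seq_along(vals), seq_along(vals),
                               function(i, j) ifelse(i < j, vals[i] < vals[j],
                                                     TRUE)))
      expect_equal(gd$paths$monotone[gd$paths$path == nm], oracle_mono)
    }
  }
})

test_that("end-to-end: generated ellipse recovered through the projection", {
  set.seed(101)
  for (k in 1:10) {
    Ax <- runif(1, 0.2, 2); Ay <- runif(1, 0.2, 2)
    px <- runif(1, -pi, pi); py <- runif(1, -pi, pi)
    cx <- complex_amplitude(make_sine(Ax, px, dur = 0.25), 8000, 430)
    cy <- complex_amplitude(make_sine(Ay, py, dur = 0.25), 8000, 430)
    got <- ellipse_axes(cx$amplitude, cx$phase, cy$amplitude, cy$phase)
    want <- oracle_ellipse(Ax, px, Ay, py)
    # projection windows that are not exact cycle multiples leak slightly
    expect_lt(abs(got$a - want$a), 5e-3)
    expect_lt(abs(got$b - want$b), 5e-3)
  }
})

test_that("WAV and CSV sample files round-trip", {
  fs <- 8000
  x <- cbind(make_sine(0.5, 0, dur = 0.1), make_sine(0.25, 1, dur = 0.1))
  wav <- file.path(tempdir(), "two_axis.wav")
  write_wav(x, fs, wav)
  rt <- read_wav(wav)
  expect_equal(rt$sample_rate, fs)
  expect_equal(dim(rt$samples), dim(x))
  expect_equal(rt$samples, x, tolerance = 1e-6)

  csv <- file.path(tempdir(), "two_axis.csv")
  write.csv(as.data.frame(x), csv, row.names = FALSE)
  rc <- read_samples_csv(csv, fs)
  expect_equal(unname(rc$samples), unname(x), tolerance = 1e-12)
})
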