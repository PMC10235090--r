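# Shared fixtures and independent oracles. Each oracle recomputes a
# quantity by a different route than the implementation (graph search,
# rasterization, dense parametric sampling, explicit sums of squares).

default_arena <- function(...) build_arena(arena_spec(...))

SECTIONS <- c("stem_upper", "stem_lower", "stalk_ipsi", "stalk_contra",
              "leaf_ipsi", "leaf_contra")

random_location <- function(arena) {
  location(sample(SECTIONS, 1), sample(arena$spec$subsections, 1))
}

# --- tree-distance oracle: weighted shortest path over an explicitly
# constructed midpoint graph (igraph), independent of the chain arithmetic
oracle_midpoint_graph <- function(arena) {
  n <- arena$spec$subsections
  w <- arena$sub_len
  edges <- character(0); wts <- numeric(0)
  add <- function(a, b, len) {
    edges <<- c(edges, a, b); wts <<- c(wts, len)
  }
  for (s in SECTIONS) {
    if (n > 1)
      for (k in seq_len(n - 1))
        add(paste0(s, ".", k), paste0(s, ".", k + 1), w[[s]])
  }
  for (s in c("stem_upper", "stem_lower", "stalk_ipsi", "stalk_contra"))
    add("crossing", paste0(s, ".1"), w[[s]] / 2)
  for (side in c("ipsi", "contra"))
    add(paste0("stalk_", side, ".", n), paste0("leaf_", side, ".1"),
        w[[paste0("stalk_", side)]] / 2 + w[[paste0("leaf_", side)]] / 2)
  g <- igraph::make_graph(edges, directed = FALSE)
  igraph::E(g)$weight <- wts
  g
}

oracle_path_distance <- function(g, a, b) {
  igraph::distances(g, v = paste0(a$section, ".", a$subsection),
                    to = paste0(b$section, ".", b$subsection))[1, 1]
}

# full midpoint-to-midpoint distance matrix from the graph oracle
oracle_dist_matrix <- function(g) igraph::distances(g)

# --- replay oracle: event-by-event rasterization of a trajectory using the
# graph-search distance matrix only
oracle_replay <- function(arena, D, trial) {
  tr <- trial$trajectory
  id <- function(loc) paste0(loc$section, ".", loc$subsection)
  pos <- id(arena$start)
  target <- id(arena$target)
  total <- 0; search_d <- 0
  d_start <- D[pos, target]
  d_min <- d_start; t_closest <- 0
  for (k in seq_len(nrow(tr))) {
    nxt <- paste0(tr$section[k], ".", tr$subsection[k])
    step <- D[pos, nxt]
    total <- total + step
    if (tr$class[k] == "search") search_d <- search_d + step
    d_here <- D[nxt, target]
    if (d_here < d_min - 1e-9) { d_min <- d_here; t_closest <- tr$time[k] }
    pos <- nxt
  }
  list(total_distance = total, search_distance = search_d,
       d_start = d_start, d_min = d_min,
       approach = min(1, max(0, 1 - d_min / d_start)),
       path_efficiency = d_start / total,
       search_ratio = search_d / total,
       time_to_closest = t_closest,
       found_target = d_min <= arena$sub_len[[arena$target$section]])
}

# --- 1 ms rasterization oracle for interval overlap quantities; cell
# midpoints are sampled so boundary error stays below half a cell
raster_cells <- function(b, e, iv, dt = 1e-3) {
  ts <- seq(b + dt / 2, e, by = dt)
  on <- rep(FALSE, length(ts))
  if (nrow(iv))
    for (k in seq_len(nrow(iv)))
      on <- on | (ts >= iv[k, 1] & ts < iv[k, 2])
  on
}

raster_overlap <- function(b, e, iv, dt = 1e-3) {
  sum(raster_cells(b, e, iv, dt)) * dt
}

raster_fraction <- function(b, e, iv, dt = 1e-3) {
  mean(raster_cells(b, e, iv, dt))
}

# --- parametric-sampling oracle for the motion ellipse: dense sweep of the
# traced curve plus local refinement of the extreme radii
oracle_ellipse <- function(Ax, phix, Ay, phiy, n = 4000L, refine = TRUE) {
  radius <- function(wt) sqrt((Ax * cos(wt + phix))^2 +
                                (Ay * cos(wt + phiy))^2)
  wt <- seq(0, 2 * pi, length.out = n)
  r <- radius(wt)
  if (!refine) return(list(a = max(r), b = min(r)))
  h <- 2 * pi / (n - 1)
  sharpen <- function(k, maximize) {
    stats::optimize(radius, interval = c(wt[k] - h, wt[k] + h),
                    maximum = maximize, tol = 1e-12)[[2]]
  }
  list(a = sharpen(which.max(r), TRUE), b = sharpen(which.min(r), FALSE))
}

# --- explicit sums-of-squares oracle for the within-subject correlation:
# subject-wise centering, no lm()
oracle_rm_corr <- function(subject, x, y) {
  subject <- factor(subject)
  xc <- x - ave(x, subject)
  yc <- y - ave(y, subject)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  r <- sxy / sqrt(sxx * syy)
  df <- length(x) - nlevels(subject) - 1L
  list(r = r, df = df)
}

# random signal-section train (possibly with clicks), non-overlapping
random_train <- function(n = 10, t_max = 300, click_prob = 0.2) {
  begins <- sort(runif(n, 0, t_max))
  durs <- runif(n, 0.2, 4)
  ends <- begins + durs
  # push overlapping sections apart
  for (k in seq_len(n)[-1]) {
    if (begins[k] < ends[k - 1]) {
      begins[k] <- ends[k - 1] + runif(1, 0.01, 0.5)
      ends[k] <- begins[k] + durs[k]
    }
  }
  lab <- ifelse(runif(n) < click_prob, "click",
                sample(c("Me0", "Me1", "Me2", "Me3"), n, replace = TRUE))
  data.frame(label = lab, begin = begins, end = ends,
             stringsAsFactors = FALSE)
}
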