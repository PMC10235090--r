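#' @title Arena model: the experimental plant as a metric tree
#'
#' @description
#' The experimental arena is a plant cutting with a stem, two opposite
#' stalks and two leaves, meeting at a single stem--stalk crossing. Each of
#' the six sections is divided into a fixed number of subsections of equal
#' length (default 10) and the male's position is recorded at subsection
#' resolution. Locations are identified with subsection midpoints and all
#' distances are path distances along the tree between midpoints.
#'
#' @name arena_model
NULL

.SECTIONS <- c("stem_upper", "stem_lower", "stalk_ipsi", "stalk_contra",
               "leaf_ipsi", "leaf_contra")

# chain = maximal path from the crossing outward that a section belongs to
.CHAIN <- c(stem_upper = "apex", stem_lower = "base",
            stalk_ipsi = "ipsi", leaf_ipsi = "ipsi",
            stalk_contra = "contra", leaf_contra = "contra")

#' Specify arena geometry
#'
#' @param stem_upper,stem_lower,stalk_ipsi,stalk_contra,leaf_ipsi,leaf_contra
#'   section lengths in mm. Defaults follow the nominal cutting used in the
#'   behavioral trials: 10 cm of stem above and below the crossing, 3 cm
#'   stalks, 8 cm leaves.
#' @param subsections number of equal-length subsections per section (>= 1).
#' @param start,target optional [location()]s. Default start is the
#'   apical-most subsection of the upper stem (the male is placed on top of
#'   the cutting); default target is the distal-most subsection of the
#'   ipsilateral leaf (the shaker just below the leaf tip).
#' @return an object of class `vib_arena_spec`.
#' @export
arena_spec <- function(stem_upper = 100, stem_lower = 100,
                       stalk_ipsi = 30, stalk_contra = 30,
                       leaf_ipsi = 80, leaf_contra = 80,
                       subsections = 10L,
                       start = NULL, target = NULL) {
  lengths <- c(stem_upper = stem_upper, stem_lower = stem_lower,
               stalk_ipsi = stalk_ipsi, stalk_contra = stalk_contra,
               leaf_ipsi = leaf_ipsi, leaf_contra = leaf_contra)
  bad <- names(lengths)[!is.finite(lengths) | lengths <= 0]
  if (length(bad))
    stop("section length must be positive: ", paste(bad, collapse = ", "))
  subsections <- as.integer(subsections)
  if (is.na(subsections) || subsections < 1L)
    stop("subsections must be an integer >= 1")
  if (is.null(start))  start  <- location("stem_upper", subsections)
  if (is.null(target)) target <- location("leaf_ipsi", subsections)
  structure(list(lengths = lengths, subsections = subsections,
                 start = start, target = target),
            class = "vib_arena_spec")
}

#' A location on the arena
#'
#' @param section one of `stem_upper`, `stem_lower`, `stalk_ipsi`,
#'   `stalk_contra`, `leaf_ipsi`, `leaf_contra`.
#' @param subsection integer subsection index; 1 is proximal to the crossing
#'   (for leaves: proximal to the stalk attachment), the maximum index is
#'   distal.
#' @return an object of class `vib_location`.
#' @export
location <- function(section, subsection) {
  section <- match.arg(section, .SECTIONS)
  subsection <- as.integer(subsection)
  if (is.na(subsection) || subsection < 1L)
    stop("subsection must be a positive integer")
  structure(list(section = section, subsection = subsection),
            class = "vib_location")
}

#' @export
format.vib_location <- function(x, ...) paste0(x$section, ":", x$subsection)

#' @export
print.vib_location <- function(x, ...) {
  cat("<location ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Build the arena graph
#'
#' Constructs the metric tree: a zero-length crossing junction joining the
#' upper stem, lower stem and both stalks, with each leaf chained onto its
#' stalk's distal end. Vertices of the returned edge table are subsection
#' boundaries, so each subsection is one arc and the arc lengths sum to the
#' total plant length; the `nodes` table lists the subsection midpoints used
#' for all distance computations.
#'
#' @param spec an [arena_spec()].
#' @return an object of class `vib_arena` with elements `spec`, `nodes`
#'   (section, subsection, chain, `d_cross` = midpoint distance to the
#'   crossing in mm), `edges` (boundary graph with arc lengths), `sub_len`
#'   (per-section subsection length, mm), `start`, `target`.
#' @export
build_arena <- function(spec) {
  stopifnot(inherits(spec, "vib_arena_spec"))
  n <- spec$subsections
  len <- spec$lengths
  sub_len <- len / n

  nodes <- do.call(rbind, lapply(.SECTIONS, function(s) {
    data.frame(section = s, subsection = seq_len(n),
               chain = .CHAIN[[s]], stringsAsFactors = FALSE)
  }))
  # midpoint distance to the crossing along the chain
  offs <- ifelse(startsWith(nodes$section, "leaf"),
                 len[paste0("stalk_", sub("leaf_", "", nodes$section))], 0)
  nodes$d_cross <- offs + (nodes$subsection - 0.5) * sub_len[nodes$section]
  nodes$node_id <- paste0(nodes$section, ".", nodes$subsection)

  # boundary-vertex edge list: one arc per subsection
  edges <- do.call(rbind, lapply(.SECTIONS, function(s) {
    v0 <- if (startsWith(s, "stalk")) "crossing"
          else if (startsWith(s, "leaf")) paste0("stalk_", sub("leaf_", "", s), ".b", n)
          else "crossing"
    from <- c(v0, paste0(s, ".b", seq_len(n - 1)))[seq_len(n)]
    to <- paste0(s, ".b", seq_len(n))
    data.frame(from = from, to = to, length = sub_len[[s]],
               stringsAsFactors = FALSE)
  }))

  arena <- structure(list(spec = spec, nodes = nodes, edges = edges,
                          sub_len = sub_len,
                          start = spec$start, target = spec$target),
                     class = "vib_arena")
  .validate_location(arena, spec$start)
  .validate_location(arena, spec$target)
  arena
}

#' @export
print.vib_arena <- function(x, ...) {
  cat("<arena: ", nrow(x$nodes), " subsection nodes, total length ",
      sum(x$spec$lengths), " mm; start ", format(x$start),
      ", target ", format(x$target), ">\n", sep = "")
  invisible(x)
}

.validate_location <- function(arena, loc) {
  if (!inherits(loc, "vib_location")) stop("not a location")
  if (!loc$section %in% .SECTIONS) stop("unknown section: ", loc$section)
  if (loc$subsection > arena$spec$subsections)
    stop("subsection out of range for ", loc$section)
  invisible(loc)
}

# vectorized midpoint distance to crossing + chain, from parallel vectors
.loc_coords <- function(arena, section, subsection) {
  if (!all(section %in% .SECTIONS))
    stop("unknown section: ", paste(setdiff(section, .SECTIONS), collapse = ", "))
  n <- arena$spec$subsections
  if (any(subsection < 1L | subsection > n))
    stop("subsection out of range")
  len <- arena$spec$lengths
  offs <- ifelse(startsWith(section, "leaf"),
                 len[paste0("stalk_", sub("leaf_", "", section))], 0)
  list(chain = unname(.CHAIN[section]),
       d = unname(offs + (subsection - 0.5) * arena$sub_len[section]))
}

#' Path distance between two locations
#'
#' Distance in mm along the unique tree path between the midpoints of the
#' two subsections. Locations on the same chain (same side of the crossing)
#' are at distance `|d1 - d2|`; otherwise the path passes the crossing and
#' the distances to the crossing add.
#'
#' @param arena a [build_arena()] result.
#' @param a,b [location()]s.
#' @return distance in mm.
#' @export
path_distance <- function(arena, a, b) {
  .validate_location(arena, a); .validate_location(arena, b)
  ca <- .loc_coords(arena, a$section, a$subsection)
  cb <- .loc_coords(arena, b$section, b$subsection)
  if (ca$chain == cb$chain) abs(ca$d - cb$d) else ca$d + cb$d
}

# vectorized pairwise distance between consecutive positions; used by the
# metrics layer (sections/subsections are parallel vectors)
.path_dist_vec <- function(arena, sec1, sub1, sec2, sub2) {
  c1 <- .loc_coords(arena, sec1, sub1)
  c2 <- .loc_coords(arena, sec2, sub2)
  ifelse(c1$chain == c2$chain, abs(c1$d - c2$d), c1$d + c2$d)
}

#' Snap a within-section position to the nearest subsection
#'
#' Returns the subsection whose midpoint is nearest to `position_mm`
#' measured from the proximal end of the section; exact boundary ties are
#' broken toward the distal subsection.
#'
#' @param arena a [build_arena()] result.
#' @param section section id.
#' @param position_mm position along the section, in `[0, section length]`.
#' @return a [location()].
#' @export
nearest_subsection <- function(arena, section, position_mm) {
  section <- match.arg(section, .SECTIONS)
  len <- arena$spec$lengths[[section]]
  if (!is.finite(position_mm) || position_mm < 0 || position_mm > len)
    stop("position ", position_mm, " outside section ", section,
         " [0, ", len, "]")
  w <- arena$sub_len[[section]]
  idx <- min(arena$spec$subsections, floor(position_mm / w) + 1L)
  location(section, idx)
}

#' Starting distance to the target
#'
#' @param arena a [build_arena()] result.
#' @return distance in mm from the arena's start to its target location.
#' @export
start_distance <- function(arena) path_distance(arena, arena$start, arena$target)

#' Read an arena specification from a config list
#'
#' Accepts the `arena:` block of a run configuration: six section lengths in
#' mm plus `subsections`.
#'
#' @param cfg a named list, e.g. from [yaml::read_yaml()].
#' @return an [arena_spec()].
#' @export
arena_spec_from_config <- function(cfg) {
  known <- c(.SECTIONS, "subsections")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown arena config keys: ", paste(unknown, collapse = ", "))
  args <- cfg[intersect(names(cfg), known)]
  do.call(arena_spec, args)
}
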