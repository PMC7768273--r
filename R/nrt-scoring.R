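# NRt scoring: state-space cluster boundaries from trajectory intersections,
# the transition-trajectory (NRt) space, and the six-rule 4-stage scorer.
#
# Rationale: within NREM and REM sleep the state-space trajectory is bounded
# and reverses direction, so it self-intersects over short spans; in the
# intervening transitionary space it is directed and rarely loops. Points
# bounding short-window self-intersections therefore pick out the state
# clusters, and convex envelopes around them define the state boundaries.

#' Find trajectory self-intersections within a moving window
#'
#' Every pair of non-adjacent trajectory segments that fits inside a
#' `window`-epoch wide span is tested for a proper crossing. Each crossing
#' segment pair is reported once, even though overlapping windows revisit
#' it. Segments touching invalid (NA) epochs, and degenerate (zero-length)
#' segments, are skipped and counted in the `skipped` attribute.
#'
#' @param traj Trajectory tibble from [compute_trajectory()] (columns
#'   `epoch_index`, `x`, `y`, `valid`).
#' @param window Moving-window width in epochs (default 5).
#' @return Tibble with crossing coordinates (`x`, `y`) and the four bounding
#'   epoch indices `e1`..`e4` (segment endpoints).
#' @export
find_intersections <- function(traj, window = 5) {
  n <- nrow(traj)
  if (n < 4) abort("trajectory shorter than the moving window")
  ep <- traj$epoch_index
  X <- traj$x; Y <- traj$y
  ok_seg <- function(i) {
    all(is.finite(c(X[i], Y[i], X[i + 1], Y[i + 1])))
  }
  degen <- function(i) X[i] == X[i + 1] && Y[i] == Y[i + 1]
  rows <- list(); skipped <- 0L
  # segments i span epochs i..i+1; a pair (i, j), j >= i+2, fits in a
  # window of `window` epochs iff (j+1) - i <= window - 1
  for (i in seq_len(n - 3L)) {
    for (j in (i + 2L):min(n - 1L, i + window - 2L)) {
      if (!ok_seg(i) || !ok_seg(j)) { skipped <- skipped + 1L; next }
      if (degen(i) || degen(j)) { skipped <- skipped + 1L; next }
      pt <- segment_crossing(c(X[i], Y[i]), c(X[i + 1], Y[i + 1]),
                             c(X[j], Y[j]), c(X[j + 1], Y[j + 1]))
      if (!is.null(pt))
        rows[[length(rows) + 1L]] <-
          c(pt[1], pt[2], ep[i], ep[i + 1L], ep[j], ep[j + 1L])
    }
  }
  out <- if (length(rows)) {
    m <- do.call(rbind, rows)
    tibble::tibble(x = m[, 1], y = m[, 2],
                   e1 = as.integer(m[, 3]), e2 = as.integer(m[, 4]),
                   e3 = as.integer(m[, 5]), e4 = as.integer(m[, 6]))
  } else {
    tibble::tibble(x = double(), y = double(),
                   e1 = integer(), e2 = integer(), e3 = integer(), e4 = integer())
  }
  attr(out, "skipped") <- skipped
  out
}

check_hypnogram <- function(hyp, stages = c("W", "N", "R")) {
  stopifnot(all(c("epoch_index", "label") %in% names(hyp)))
  bad <- setdiff(unique(hyp$label), stages)
  if (length(bad)) abort(paste("unexpected hypnogram labels:", paste(bad, collapse = ", ")))
  hyp
}

#' Fit convex state boundaries to intersection-bounding points
#'
#' The four epochs bounding each intersection are pooled, assigned to the
#' NREM or REM cluster by their manual 3-stage label (wake-labelled points
#' are discarded), trimmed once of points farther than
#' `mean + outlier_sd * sd` of the centroid distance, and wrapped in a
#' convex envelope.
#'
#' @param events Intersection tibble from [find_intersections()].
#' @param traj Trajectory the events were computed on.
#' @param hypnogram 3-stage hypnogram tibble (`epoch_index`, `label` in
#'   W/N/R) covering the control period.
#' @param outlier_sd Centroid-distance exclusion threshold in standard
#'   deviations (default 5).
#' @return An object of class `state_boundaries`: list with elements `N` and
#'   `R`, each holding `polygon` (vertex tibble), `centroid`,
#'   `excluded_points`, and `points` (retained cluster points).
#' @export
fit_state_boundaries <- function(events, traj, hypnogram, outlier_sd = 5) {
  hypnogram <- check_hypnogram(hypnogram)
  lab <- setNames(hypnogram$label, hypnogram$epoch_index)
  eps <- unique(c(events$e1, events$e2, events$e3, events$e4))
  idx <- match(eps, traj$epoch_index)
  pts <- tibble::tibble(epoch = eps, x = traj$x[idx], y = traj$y[idx],
                        label = unname(lab[as.character(eps)]))
  pts <- pts[!is.na(pts$label) & pts$label != "W" & is.finite(pts$x) & is.finite(pts$y), ]
  fit_one <- function(state) {
    p <- pts[pts$label == state, ]
    if (nrow(p) < 3) abort(sprintf(
      "insufficient control sleep: <3 %s-labelled intersection points", state))
    cx <- mean(p$x); cy <- mean(p$y)
    d <- sqrt((p$x - cx)^2 + (p$y - cy)^2)
    keep <- if (length(d) < 4 || sd(d) == 0) rep(TRUE, length(d))
            else d <= mean(d) + outlier_sd * sd(d)
    excluded <- sum(!keep)
    p <- p[keep, , drop = FALSE]
    if (nrow(p) < 3) abort(sprintf(
      "insufficient control sleep: <3 surviving %s points after outlier trim", state))
    poly <- convex_polygon(p$x, p$y)
    list(polygon = poly, centroid = polygon_centroid(poly),
         excluded_points = excluded, points = p)
  }
  out <- list(N = fit_one("N"), R = fit_one("R"), outlier_sd = outlier_sd)
  if (polygons_overlap(out$N$polygon, out$R$polygon))
    abort("NREM and REM state polygons overlap; control-period clusters are not separable")
  class(out) <- "state_boundaries"
  out
}

#' @export
print.state_boundaries <- function(x, ...) {
  cat("State-space boundaries (convex envelopes)\n")
  for (s in c("N", "R"))
    cat(sprintf("  %s: %d vertices, centroid (%.3f, %.3f), %d outliers excluded\n",
                s, nrow(x[[s]]$polygon), x[[s]]$centroid["x"], x[[s]]$centroid["y"],
                x[[s]]$excluded_points))
  invisible(x)
}

#' @export
tidy.state_boundaries <- function(x, ...) {
  dplyr::bind_rows(lapply(c("N", "R"), function(s) {
    poly <- x[[s]]$polygon
    tibble::tibble(state = s, vertex = seq_len(nrow(poly)),
                   x = poly$x, y = poly$y)
  }))
}

# classify each epoch's position: "N", "R", "out", or NA for invalid coords
region_of <- function(traj, bounds) {
  reg <- rep(NA_character_, nrow(traj))
  ok <- is.finite(traj$x) & is.finite(traj$y)
  inN <- ok & point_in_polygon(traj$x, traj$y, bounds$N$polygon)
  inR <- ok & point_in_polygon(traj$x, traj$y, bounds$R$polygon)
  reg[ok] <- "out"
  reg[inN] <- "N"
  reg[inR] <- "R"
  reg
}

# Effective region: wake-labelled epochs are barriers ("W"); an epoch only
# counts as being inside a state polygon when it is part of a run of at
# least two consecutive in-polygon epochs (rule 2: a single in-boundary
# epoch neither starts nor ends a state), otherwise it is "out".
effective_region <- function(region, label3) {
  eff <- region
  eff[label3 == "W"] <- "W"
  r <- run_lengths(ifelse(is.na(eff), "NA", eff))
  for (k in seq_len(nrow(r))) {
    if (r$value[k] %in% c("N", "R") && r$length[k] < 2L)
      eff[r$start[k]:r$end[k]] <- "out"
  }
  eff
}

# maximal excursions: runs of sleep epochs outside both state polygons
# (isolated single in-polygon epochs included), with origin and
# termination context; shared by define_nrt_space() and score_4stage()
excursion_runs <- function(region, label3) {
  n <- length(region)
  eff <- effective_region(region, label3)
  r <- run_lengths(ifelse(is.na(eff), "NA", eff))
  r <- r[r$value == "out", , drop = FALSE]
  if (!nrow(r)) return(tibble::tibble(start = integer(), end = integer(),
                                      origin = character(), ending = character()))
  origin <- character(nrow(r)); ending <- character(nrow(r))
  for (k in seq_len(nrow(r))) {
    a <- r$start[k]; b <- r$end[k]
    # rule 1: preceded by two consecutive in-boundary sleep epochs (an
    # in-state effective region implies a run of >= 2 epochs)
    org <- if (a >= 3 && eff[a - 1L] %in% c("N", "R")) eff[a - 1L]
           else NA_character_
    origin[k] <- org
    ending[k] <- if (b >= n) "truncated"
      else if (is.na(eff[b + 1L]) || eff[b + 1L] == "NA") "invalid"
      else if (eff[b + 1L] == "W") "arousal"
      else if (!is.na(org) && eff[b + 1L] == org) "return"
      else "transition"   # entered the other state for >= 2 epochs (rule 2)
  }
  tibble::tibble(start = r$start, end = r$end, origin = origin, ending = ending)
}

#' Demarcate NRt space from complete NREM-to-REM transition trajectories
#'
#' Complete transitions are excursions that leave the NREM polygon and reach
#' the REM polygon (two consecutive in-boundary epochs) with no intervening
#' wake. The union of their between-boundary points, wrapped in a convex
#' envelope and minus the state-polygon interiors, is the region through
#' which valid NRt bouts must travel (scoring rule 6).
#'
#' @inheritParams fit_state_boundaries
#' @param bounds `state_boundaries` object.
#' @return An object of class `nrt_space`: list with the transition-point
#'   `hull`, the contributing `points`, and the state polygons.
#' @export
define_nrt_space <- function(traj, hypnogram, bounds) {
  hypnogram <- check_hypnogram(hypnogram)
  stopifnot(nrow(traj) == nrow(hypnogram))
  region <- region_of(traj, bounds)
  runs <- excursion_runs(region, hypnogram$label)
  tr <- runs[!is.na(runs$origin) & runs$origin == "N" & runs$ending == "transition", ]
  if (!nrow(tr))
    abort(paste("no complete NREM-to-REM transitions found in the control period;",
                "extend the control period"))
  idx <- unlist(mapply(seq, tr$start, tr$end, SIMPLIFY = FALSE))
  pts <- tibble::tibble(x = traj$x[idx], y = traj$y[idx])
  pts <- pts[is.finite(pts$x) & is.finite(pts$y), ]
  hull <- if (nrow(pts) >= 3) convex_polygon(pts$x, pts$y) else pts
  out <- list(hull = hull, points = pts,
              n_polygon = bounds$N$polygon, r_polygon = bounds$R$polygon,
              n_transitions = nrow(tr))
  class(out) <- "nrt_space"
  out
}

#' @export
print.nrt_space <- function(x, ...) {
  cat(sprintf("NRt space: hull of %d points from %d complete N-to-R transitions\n",
              nrow(x$points), x$n_transitions))
  invisible(x)
}

# membership in NRt space: inside the transition hull, outside both
# state-polygon interiors
in_nrt_space <- function(px, py, space) {
  if (nrow(space$hull) < 3) {
    # degenerate hull (collinear path): accept points within a tolerance of
    # the segment set -- handled by bounding-box + distance test
    ok <- rep(FALSE, length(px))
    for (i in seq_len(nrow(space$points))) {
      ok <- ok | (abs(px - space$points$x[i]) < 1e-9 &
                  abs(py - space$points$y[i]) < 1e-9)
    }
    return(ok)
  }
  point_in_polygon(px, py, space$hull) &
    !point_in_polygon(px, py, space$n_polygon, strict = TRUE) &
    !point_in_polygon(px, py, space$r_polygon, strict = TRUE)
}

#' Score a 4-stage hypnogram (W/N/R/t) from a 3-stage hypnogram
#'
#' Sleep epochs whose trajectory point leaves the state polygons are
#' relabelled `t` when the excursion satisfies all six scoring rules:
#' (1) preceded by two consecutive in-boundary sleep epochs; (2) a switch to
#' the other sleep state counts only after two consecutive in-boundary
#' epochs there; (3) excursions ending in arousal or returning to the origin
#' must last at least `min_excursion` epochs; (4) t-bouts separated by
#' manual arousals of at most `arousal_merge` epochs are one bout (applied
#' in [bout_stats()]); (5) excursions from NREM count only when the
#' trajectory moves toward the REM polygon; (6) every excursion point lies
#' in NRt space. Wake epochs are never relabelled; epochs with invalid
#' coordinates keep their 3-stage label.
#'
#' @inheritParams define_nrt_space
#' @param nrt_space `nrt_space` object from [define_nrt_space()].
#' @param min_excursion Minimum length (epochs) of excursions ending in
#'   arousal or return-to-origin (rule 3; default 2).
#' @param toward_r_sign Direction that counts as "toward REM" along x for
#'   rule 5: `NULL` (default) derives it from the sign of
#'   `x_centroid(R) - x_centroid(N)`; otherwise +1 or -1.
#' @return Tibble `epoch_index`, `label3`, `label` (4-stage), `region`.
#' @export
score_4stage <- function(traj, hypnogram, bounds, nrt_space,
                         min_excursion = 2, toward_r_sign = NULL) {
  hypnogram <- check_hypnogram(hypnogram)
  stopifnot(nrow(traj) == nrow(hypnogram))
  region <- region_of(traj, bounds)
  label3 <- hypnogram$label
  label4 <- label3
  dir_sign <- toward_r_sign %||%
    sign(bounds$R$centroid[["x"]] - bounds$N$centroid[["x"]])
  runs <- excursion_runs(region, label3)
  for (k in seq_len(nrow(runs))) {
    a <- runs$start[k]; b <- runs$end[k]
    if (is.na(runs$origin[k])) next                       # rule 1
    if (runs$ending[k] %in% c("blip", "truncated", "invalid")) next  # rule 2
    if (runs$ending[k] %in% c("arousal", "return") &&
        (b - a + 1L) < min_excursion) next                # rule 3
    # rule 6: the excursion must pass through NRt space -- at least two
    # consecutive epochs inside the transition-trajectory region (the
    # two-epoch persistence convention of the other rules)
    xs <- traj$x[a:b]; ys <- traj$y[a:b]
    inside <- in_nrt_space(xs, ys, nrt_space)
    pass6 <- if (length(inside) == 1L) inside
             else any(inside[-length(inside)] & inside[-1])
    if (!pass6) next
    if (runs$origin[k] == "N") {                          # rule 5
      # the traversal of transitionary space must head toward the REM
      # polygon: mean x over the excursion's in-NRt-space epochs lies on
      # the REM side of the last in-boundary epoch
      trav_x <- mean(xs[inside])
      last_in <- traj$x[a - 1L]
      if (!is.finite(trav_x) || !is.finite(last_in)) next
      if (sign(trav_x - last_in) != dir_sign) next
    }
    label4[a:b] <- "t"
  }
  tibble::tibble(epoch_index = hypnogram$epoch_index,
                 label3 = label3, label = label4, region = region)
}
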