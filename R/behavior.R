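# Open-field behavioral analysis: inactivity-bout classification,
# activity percentage, center-zone occupancy, and the across-condition
# repeated-measures comparison.

#' Classify inactivity bouts in a trajectory
#'
#' Inactivity is movement confined to a tiny fraction of the arena for
#' longer than a minimum duration: a time interval is an inactivity bout
#' when the positions within it stay inside a region of at most
#' `area_fraction` of the arena area (default 0.01%) and the interval
#' lasts strictly longer than `min_duration` seconds (default 0.5 s).
#' With `method = "box"` the region is a square of the threshold area that
#' must contain the axis-aligned bounding box (so degenerate collinear
#' paths are still measured by their extent); with `method = "disc"` it is
#' a disc of the threshold area that must contain the bounding-box
#' diagonal, making the test rotation invariant.  Intervals are grown
#' greedily frame by frame; when adding a frame would exceed the bound the
#' interval is closed and a new one starts there.  Gaps in tracking longer
#' than `max_gap` split candidate bouts.
#'
#' @param traj A `flicker_trajectory`.
#' @param area_fraction Bounding-region area bound as a fraction of arena
#'   area.
#' @param min_duration Strict lower bound on bout duration, s.
#' @param method `"box"` (axis-aligned bounding box) or `"disc"` (minimal
#'   bounding circle via diameter, rotation invariant).
#' @param max_gap Largest inter-frame gap (s) allowed inside a bout;
#'   default 2.5 median frame intervals.
#' @return Data frame of bouts: `start`, `end`, `duration` (s).
#' @export
classify_inactivity <- function(traj, area_fraction = 1e-4,
                                min_duration = 0.5,
                                method = c("box", "disc"), max_gap = NULL) {
  stopifnot(inherits(traj, "flicker_trajectory"))
  method <- match.arg(method)
  d <- traj$data
  n <- nrow(d)
  if (n < 2) stopf("trajectory needs at least 2 frames")
  if (is.null(max_gap)) max_gap <- 2.5 * median(diff(d$t))
  thr <- area_fraction * prod(traj$arena)
  # admissible extent: side of the threshold-area square (box) or diameter
  # of the threshold-area disc (disc)
  ext_max <- if (method == "box") sqrt(thr) else 2 * sqrt(thr / pi)

  bouts <- list()
  i <- 1L
  while (i < n) {
    xmin <- xmax <- d$x[i]
    ymin <- ymax <- d$y[i]
    j <- i
    while (j < n) {
      if (d$t[j + 1L] - d$t[j] > max_gap) break
      nx_min <- min(xmin, d$x[j + 1L]); nx_max <- max(xmax, d$x[j + 1L])
      ny_min <- min(ymin, d$y[j + 1L]); ny_max <- max(ymax, d$y[j + 1L])
      ext <- if (method == "box") {
        max(nx_max - nx_min, ny_max - ny_min)
      } else {
        sqrt((nx_max - nx_min)^2 + (ny_max - ny_min)^2)
      }
      if (ext > ext_max) break
      xmin <- nx_min; xmax <- nx_max; ymin <- ny_min; ymax <- ny_max
      j <- j + 1L
    }
    if (d$t[j] - d$t[i] > min_duration)
      bouts[[length(bouts) + 1L]] <- c(start = d$t[i], end = d$t[j])
    i <- max(j, i + 1L)
  }
  if (!length(bouts))
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0)))
  out <- as.data.frame(do.call(rbind, bouts))
  out$duration <- out$end - out$start
  out
}

#' Percent of session time spent active
#'
#' `100 * (1 - total inactivity-bout time / record time)`.
#'
#' @param traj A `flicker_trajectory`.
#' @param bouts Bout table from [classify_inactivity()]; computed if
#'   missing.
#' @param ... Passed to [classify_inactivity()] when `bouts` is missing.
#' @export
percent_time_active <- function(traj, bouts = NULL, ...) {
  if (is.null(bouts)) bouts <- classify_inactivity(traj, ...)
  span <- diff(range(traj$data$t))
  100 * (1 - sum(bouts$duration) / span)
}

#' Percent of frames spent in a zone
#'
#' Fraction of frames whose position falls inside the rectangle (boundary
#' inclusive), times 100.  The default zone is the trajectory's center
#' zone, the standard inverse index of anxiety-like behavior.
#'
#' @param traj A `flicker_trajectory`.
#' @param zone `c(x0, y0, x1, y1)` in cm; default `traj$center_zone`.
#' @export
percent_time_in_zone <- function(traj, zone = NULL) {
  stopifnot(inherits(traj, "flicker_trajectory"))
  if (is.null(zone)) zone <- traj$center_zone
  if (zone[3] <= zone[1] || zone[4] <= zone[2]) stopf("degenerate zone")
  if (zone[1] < 0 || zone[2] < 0 || zone[3] > traj$arena[1] ||
      zone[4] > traj$arena[2]) stopf("zone extends outside the arena")
  d <- traj$data
  inside <- d$x >= zone[1] & d$x <= zone[3] &
            d$y >= zone[2] & d$y <= zone[4]
  100 * mean(inside)
}

#' Behavioral summary of one session
#'
#' @param traj A `flicker_trajectory`.
#' @param area_fraction,min_duration Inactivity parameters, see
#'   [classify_inactivity()].
#' @return A `behavior_report`: percent time active, percent time in the
#'   center zone, the bout table, and the parameters used.
#' @export
behavior_report <- function(traj, area_fraction = 1e-4, min_duration = 0.5) {
  bouts <- classify_inactivity(traj, area_fraction, min_duration)
  structure(list(
    percent_time_active = percent_time_active(traj, bouts),
    percent_time_in_center = percent_time_in_zone(traj),
    bouts = bouts,
    params = list(area_fraction = area_fraction,
                  min_duration = min_duration)),
    class = "behavior_report")
}

#' @export
print.behavior_report <- function(x, ...) {
  cat(sprintf("<behavior_report> active %.1f%%, center zone %.1f%%, %d inactivity bouts\n",
              x$percent_time_active, x$percent_time_in_center, nrow(x$bouts)))
  invisible(x)
}

#' Repeated-measures comparison across stimulation conditions
#'
#' One-way repeated-measures ANOVA of a behavioral measure across
#' conditions, each subject observed under every condition (balanced
#' within-subject design).  The F statistic uses the subject-by-condition
#' interaction as its error term.
#'
#' @param values Numeric measure, one per (subject, condition) cell.
#' @param subject Subject identifier, same length.
#' @param condition Condition label, same length.
#' @return List: `F`, `df` (numerator, denominator), `p`.
#' @export
compare_conditions <- function(values, subject, condition) {
  subject <- factor(subject); condition <- factor(condition)
  if (length(values) != length(subject) || length(values) != length(condition))
    stopf("values, subject, condition must have equal length")
  tab <- table(subject, condition)
  if (any(tab != 1))
    stopf("design must be balanced: one observation per subject x condition")
  fit <- aov(values ~ condition + Error(subject))
  s <- summary(fit)[["Error: Within"]][[1]]
  rn <- trimws(rownames(s))
  ic <- match("condition", rn); ir <- match("Residuals", rn)
  Fval <- s[ic, "F value"]
  if (isTRUE(all.equal(s[ic, "Sum Sq"], 0))) Fval <- 0  # 0/0 guard
  list(F = unname(Fval),
       df = c(unname(s[ic, "Df"]), unname(s[ir, "Df"])),
       p = unname(s[ic, "Pr(>F)"]))
}
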