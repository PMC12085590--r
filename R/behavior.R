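label_cols <- function(traces, label) {
  cx <- paste0(label, "_x"); cy <- paste0(label, "_y")
  if (!all(c(cx, cy) %in% names(traces)))
    stop("unknown pose label: ", label)
  list(x = traces[[cx]], y = traces[[cy]])
}

excluded_mask <- function(traces) {
  if ("excluded" %in% names(traces)) as.logical(traces$excluded)
  else rep(FALSE, nrow(traces))
}

#' Motion energy of a pose label
#'
#' Euclidean displacement of the marker between frame t and frame t-2 (the
#' two-frame-lag convention for pose-label motion energy). The first two
#' frames are 0; frames involving an excluded frame are NA, not interpolated.
#'
#' @param traces pose-trace data.frame (see \code{\link{generate_behavior_traces}}).
#' @param label label name, e.g. \code{"whisker1"}.
#' @return numeric vector of motion energy per frame (pixels / 2 frames).
#' @export
label_motion_energy <- function(traces, label) {
  p <- label_cols(traces, label)
  n <- length(p$x)
  e <- rep(0, n)
  if (n > 2) {
    i <- 3:n
    e[i] <- sqrt((p$x[i] - p$x[i - 2])^2 + (p$y[i] - p$y[i - 2])^2)
  }
  m <- excluded_mask(traces)
  if (any(m)) {
    bad <- m
    if (n > 2) bad[3:n] <- bad[3:n] | m[1:(n - 2)]
    e[bad] <- NA_real_
  }
  e
}

#' Eye area from the eye-outline labels
#'
#' Shoelace (polygon) area of the eye-outline labels per frame, in pixel^2.
#' Labels are taken in their listed order, assumed to trace the outline.
#'
#' @param traces pose-trace data.frame.
#' @param eye_labels outline label names in polygon order, default
#'   \code{paste0("eye", 1:6)}.
#' @return numeric vector of areas; NA on excluded frames.
#' @export
eye_area_trace <- function(traces, eye_labels = paste0("eye", 1:6)) {
  if (length(eye_labels) < 3) stop("need at least 3 eye-outline labels")
  xs <- sapply(eye_labels, function(l) label_cols(traces, l)$x)
  ys <- sapply(eye_labels, function(l) label_cols(traces, l)$y)
  if (is.null(dim(xs))) { xs <- matrix(xs, nrow = 1); ys <- matrix(ys, nrow = 1) }
  k <- length(eye_labels)
  nxt <- c(2:k, 1)
  area <- abs(rowSums(xs * ys[, nxt, drop = FALSE] -
                      xs[, nxt, drop = FALSE] * ys)) / 2
  area[excluded_mask(traces)] <- NA_real_
  area
}

#' Detect saccades along the temporal-nasal axis
#'
#' A saccade is a frame where the pupil-centroid x-velocity exceeds
#' \code{velocity_threshold} in magnitude; contiguous supra-threshold frames
#' are one event. Direction is \code{"temporal"} for negative x displacement
#' and \code{"nasal"} for positive (the synthetic face has the nose at
#' larger x than the eye). Pure y-axis movement never triggers an event.
#'
#' @param traces pose-trace data.frame.
#' @param velocity_threshold pixels/s, default 200.
#' @param pupil_labels labels averaged into the pupil centroid.
#' @return data.frame: \code{t_on_s}, \code{t_off_s}, \code{direction}.
#' @export
detect_saccades <- function(traces, velocity_threshold = 200,
                            pupil_labels = paste0("pupil", 1:4)) {
  xs <- rowMeans(sapply(pupil_labels, function(l) label_cols(traces, l)$x))
  tt <- traces$time_s
  n <- length(tt)
  if (n < 2)
    return(data.frame(t_on_s = numeric(0), t_off_s = numeric(0),
                      direction = character(0)))
  dt <- tt[2] - tt[1]
  vx <- c(0, diff(xs)) / dt
  vx[excluded_mask(traces)] <- NA_real_
  supra <- !is.na(vx) & abs(vx) > velocity_threshold
  runs <- rle(supra)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  on <- starts[runs$values]; off <- ends[runs$values]
  if (!length(on))
    return(data.frame(t_on_s = numeric(0), t_off_s = numeric(0),
                      direction = character(0)))
  dir <- vapply(seq_along(on), function(i) {
    if (mean(vx[on[i]:off[i]]) < 0) "temporal" else "nasal"
  }, character(1))
  data.frame(t_on_s = tt[on], t_off_s = tt[off], direction = dir,
             stringsAsFactors = FALSE)
}

#' Detect aversive-facial-expression bouts in a feature series
#'
#' A bout is a contiguous epoch in which the feature crosses the aversive
#' threshold for at least \code{min_duration}; epochs separated by less than
#' \code{merge_gap} are merged before the duration test. For
#' \code{"whisker_protraction"} the feature is supra-threshold when above
#' the threshold (forward displacement); for \code{"orbital_tightening"} when
#' below it (eye-area contraction). NA (excluded) frames are sub-threshold.
#'
#' @param time_s frame times (uniform spacing).
#' @param feature feature series (protraction proxy or eye area).
#' @param kind \code{"whisker_protraction"} or \code{"orbital_tightening"}.
#' @param threshold aversive threshold in feature units. Defaults: for
#'   protraction, baseline median + 4 baseline MAD; for tightening,
#'   \code{(1 - kappa)} times the baseline median with \code{kappa = 0.3}.
#' @param min_duration minimum bout length in seconds, default 0.5.
#' @param merge_gap maximum sub-threshold gap merged into a bout, default 0.25.
#' @param baseline optional logical mask of baseline (no-touch) frames used
#'   for the default threshold; defaults to all frames.
#' @return list: \code{bouts} (data.frame \code{t_on_s}, \code{t_off_s}),
#'   \code{n_bouts}, \code{occupancy} (supra-threshold fraction of frames).
#' @export
detect_afe_bouts <- function(time_s, feature,
                             kind = c("whisker_protraction",
                                      "orbital_tightening"),
                             threshold = NULL,
                             min_duration = 0.5, merge_gap = 0.25,
                             baseline = NULL) {
  kind <- match.arg(kind)
  n <- length(feature)
  stopifnot(length(time_s) == n)
  if (is.null(baseline)) baseline <- rep(TRUE, n)
  base <- feature[baseline & !is.na(feature)]
  if (is.null(threshold)) {
    threshold <- if (kind == "whisker_protraction")
      stats::median(base) + 4 * stats::mad(base)
    else 0.7 * stats::median(base)
  }
  supra <- if (kind == "whisker_protraction") feature > threshold
           else feature < threshold
  supra[is.na(supra)] <- FALSE
  if (n < 2 || !any(supra))
    return(list(bouts = data.frame(t_on_s = numeric(0), t_off_s = numeric(0)),
                n_bouts = 0L, occupancy = 0))
  dt <- time_s[2] - time_s[1]
  runs <- rle(supra)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  on <- starts[runs$values]; off <- ends[runs$values]
  # merge epochs separated by < merge_gap
  if (length(on) > 1) {
    keep_on <- on[1]; merged_on <- c(); merged_off <- c()
    cur_off <- off[1]
    for (i in 2:length(on)) {
      gap <- (on[i] - cur_off - 1) * dt
      if (gap < merge_gap) {
        cur_off <- off[i]
      } else {
        merged_on <- c(merged_on, keep_on); merged_off <- c(merged_off, cur_off)
        keep_on <- on[i]; cur_off <- off[i]
      }
    }
    merged_on <- c(merged_on, keep_on); merged_off <- c(merged_off, cur_off)
    on <- merged_on; off <- merged_off
  }
  dur <- (off - on + 1) * dt
  sel <- dur >= min_duration
  bouts <- data.frame(t_on_s = time_s[on[sel]], t_off_s = time_s[off[sel]] + dt)
  list(bouts = bouts, n_bouts = nrow(bouts), occupancy = mean(supra))
}

#' Fraction of running time spent in the avoidance direction
#'
#' Within a trial window, the fraction of running frames (ball motion above
#' \code{run_threshold}) whose direction channel is negative, i.e. running
#' away from the stimulus. With no running at all the fraction is undefined
#' and NA is returned.
#'
#' @param traces pose-trace data.frame with \code{ball_motion} and
#'   \code{ball_direction} columns.
#' @param window \code{c(start, end)} in session seconds.
#' @param run_threshold motion-energy threshold defining "running", default 1.
#' @return scalar in [0,1], or NA when the animal never ran in the window.
#' @export
running_avoidance_fraction <- function(traces, window, run_threshold = 1) {
  if (!all(c("ball_motion", "ball_direction") %in% names(traces)))
    stop("traces lack ball_motion/ball_direction channels")
  sel <- traces$time_s >= window[1] & traces$time_s < window[2] &
    !excluded_mask(traces)
  running <- sel & traces$ball_motion > run_threshold
  n_run <- sum(running)
  if (n_run == 0) return(NA_real_)
  sum(traces$ball_direction[running] < 0) / n_run
}

#' Add frames to the exclusion mask
#'
#' OR-combines \code{mask} with the existing per-frame exclusion flag
#' (blinking, grooming, occlusion). All downstream features honor the mask:
#' excluded frames yield NA, never interpolation.
#'
#' @param traces pose-trace data.frame.
#' @param mask logical vector, one entry per frame.
#' @return traces with updated \code{excluded} column.
#' @export
exclude_frames <- function(traces, mask) {
  if (length(mask) != nrow(traces))
    stop("mask length (", length(mask), ") != number of frames (",
         nrow(traces), ")")
  traces$excluded <- excluded_mask(traces) | as.logical(mask)
  traces
}

#' Whisker-protraction proxy feature
#'
#' Mean forward (+x, toward the stimulus side of the face) displacement of
#' the whisker-follicle labels relative to their session median position —
#' a scalar protraction proxy suitable for \code{\link{detect_afe_bouts}}.
#'
#' @param traces pose-trace data.frame.
#' @param whisker_labels follicle labels, default \code{paste0("whisker", 1:6)}.
#' @return numeric vector per frame; NA on excluded frames.
#' @export
whisker_protraction_trace <- function(traces,
                                      whisker_labels = paste0("whisker", 1:6)) {
  xs <- sapply(whisker_labels, function(l) label_cols(traces, l)$x)
  if (is.null(dim(xs))) xs <- matrix(xs, nrow = 1)
  med <- apply(xs, 2, stats::median, na.rm = TRUE)
  out <- rowMeans(sweep(xs, 2, med))
  out[excluded_mask(traces)] <- NA_real_
  out
}
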