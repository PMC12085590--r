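#' Build the bout schedule for a touch session
#'
#' A session consists of repeated presentation bouts: the motorized platform
#' carrying the stimulus (stranger mouse or object) stops within whisker or
#' snout reach for \code{stim_dur} seconds, then withdraws for an
#' interstimulus interval (ISI) of \code{isi_dur} seconds. Time 0 of every
#' trial is the platform stop, so the i-th stop falls at
#' \code{t0 + (i-1) * (stim_dur + isi_dur)}.
#'
#' @param n_bouts number of presentation bouts (>= 0).
#' @param stim_dur stimulus (platform stopped) duration in seconds, default 5.
#' @param isi_dur interstimulus interval in seconds, default 5.
#' @param t0 session time of the first platform stop, seconds.
#' @param platform_speed platform travel speed in cm/s, default 1.65.
#' @param withdraw_dist withdrawal distance during the ISI in cm, default 1.
#' @return an object of class \code{bout_schedule}: a list with fields
#'   \code{n_bouts}, \code{stim_dur}, \code{isi_dur}, \code{platform_speed},
#'   \code{withdraw_dist} and \code{stop_times} (seconds, one per bout).
#' @export
build_bout_schedule <- function(n_bouts, stim_dur = 5, isi_dur = 5, t0 = 0,
                                platform_speed = 1.65, withdraw_dist = 1) {
  if (n_bouts < 0) stop("n_bouts must be >= 0")
  if (stim_dur <= 0 || isi_dur <= 0) stop("stim_dur and isi_dur must be > 0")
  if (platform_speed <= 0) stop("platform_speed must be > 0")
  if (withdraw_dist < 0) stop("withdraw_dist must be >= 0")
  stops <- if (n_bouts == 0) numeric(0) else
    t0 + (seq_len(n_bouts) - 1) * (stim_dur + isi_dur)
  structure(
    list(n_bouts = as.integer(n_bouts), stim_dur = stim_dur, isi_dur = isi_dur,
         platform_speed = platform_speed, withdraw_dist = withdraw_dist,
         stop_times = stops),
    class = "bout_schedule"
  )
}

#' Number of bouts that fit in a session
#'
#' @param session_dur session duration in seconds (>= 0).
#' @param stim_dur,isi_dur bout cycle components in seconds (> 0).
#' @return integer count, \code{floor(session_dur / (stim_dur + isi_dur))}.
#' @export
count_bouts_in_session <- function(session_dur, stim_dur = 5, isi_dur = 5) {
  if (session_dur < 0) stop("session_dur must be >= 0")
  if (stim_dur <= 0 || isi_dur <= 0) stop("durations must be > 0")
  as.integer(floor(session_dur / (stim_dur + isi_dur)))
}

#' Round-trip platform travel time
#'
#' Out-and-back travel over \code{withdraw_dist} at constant speed.
#'
#' @param withdraw_dist withdrawal distance in cm (>= 0).
#' @param speed platform speed in cm/s (> 0).
#' @return travel time in seconds, \code{2 * withdraw_dist / speed}.
#' @export
travel_time <- function(withdraw_dist, speed) {
  if (speed <= 0) stop("speed must be > 0")
  if (withdraw_dist < 0) stop("withdraw_dist must be >= 0")
  2 * withdraw_dist / speed
}

#' Platform displacement trace for a bout schedule
#'
#' Piecewise-linear distance of the platform from the touch position:
#' 0 while the platform is stopped (stimulus on), and a triangular excursion
#' to \code{withdraw_dist} at the start of each ISI with slopes of
#' \code{+/- platform_speed}, so that the time spent away from the touch
#' position per ISI equals \code{\link{travel_time}}.
#'
#' @param schedule a \code{\link{build_bout_schedule}} object.
#' @param dt sample spacing in seconds (> 0).
#' @return data.frame with columns \code{time_s} and \code{distance_cm},
#'   covering the schedule from the first stop to the end of the last ISI.
#' @export
platform_position_trace <- function(schedule, dt) {
  stopifnot(inherits(schedule, "bout_schedule"))
  if (dt <= 0) stop("dt must be > 0")
  if (schedule$n_bouts == 0)
    return(data.frame(time_s = numeric(0), distance_cm = numeric(0)))
  cyc <- schedule$stim_dur + schedule$isi_dur
  t_end <- schedule$stop_times[schedule$n_bouts] + cyc
  tt <- seq(schedule$stop_times[1], t_end, by = dt)
  # phase within the bout cycle, 0 at platform stop
  ph <- (tt - schedule$stop_times[1]) %% cyc
  half <- schedule$withdraw_dist / schedule$platform_speed
  e <- ph - schedule$stim_dur            # time into the ISI (< 0 during stim)
  d <- ifelse(e < 0, 0,
       ifelse(e < half, e * schedule$platform_speed,
       ifelse(e < 2 * half, (2 * half - e) * schedule$platform_speed, 0)))
  data.frame(time_s = tt, distance_cm = d)
}
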