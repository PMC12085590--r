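#' Modulation index of stimulus vs baseline firing
#'
#' MI = (FR_stim - FR_isi) / (FR_stim + FR_isi), bounded in [-1, 1]: +1 for a
#' unit silent during the ISI, -1 for one silenced by the stimulus, 0 for no
#' change. Both rates zero gives NA (degenerate, flagged by callers).
#'
#' @param fr_stim,fr_isi mean firing rates in Hz (>= 0), vectorized.
#' @return MI values in [-1, 1], NA where both rates are 0.
#' @export
modulation_index <- function(fr_stim, fr_isi) {
  if (any(fr_stim < 0, na.rm = TRUE) || any(fr_isi < 0, na.rm = TRUE))
    stop("firing rates must be >= 0")
  out <- (fr_stim - fr_isi) / (fr_stim + fr_isi)
  out[fr_stim + fr_isi == 0] <- NA_real_
  out
}

#' Stimulus/ISI window pairs for the modulation-index variants
#'
#' Three variants, in seconds relative to the platform stop (presentation
#' onset): \code{STIM} compares the full 5 s stimulus against the 5 s ISI of
#' the same bout cycle (the following ISI by default; set
#' \code{isi_side = "preceding"} for [-5, 0]); \code{SHORTSTIM} compares the
#' first 3 s of the presentation against the 3 s before onset; \code{PLATFORM}
#' compares [-1, 1] around onset (platform moving in) against [-3, -1].
#'
#' @param variant one of \code{"STIM"}, \code{"SHORTSTIM"}, \code{"PLATFORM"}.
#' @param isi_side for \code{STIM}: \code{"following"} (default) or
#'   \code{"preceding"}.
#' @return list with \code{stim} and \code{isi} windows (\code{c(start, end)}).
#' @export
mi_windows <- function(variant = c("STIM", "SHORTSTIM", "PLATFORM"),
                       isi_side = c("following", "preceding")) {
  variant <- match.arg(variant)
  isi_side <- match.arg(isi_side)
  switch(variant,
    STIM = list(stim = c(0, 5),
                isi = if (isi_side == "following") c(5, 10) else c(-5, 0)),
    SHORTSTIM = list(stim = c(0, 3), isi = c(-3, 0)),
    PLATFORM = list(stim = c(-1, 1), isi = c(-3, -1)))
}

#' Per-unit modulation index from an aligned PSTH
#'
#' Computes MI from the trial-averaged rates in the variant's stimulus and
#' ISI windows (the index of mean rates, not the mean of per-trial indices).
#'
#' @param aligned output of \code{\link{trial_align_psth}} (window must cover
#'   the variant's windows; use \code{c(-3, 10)} for the STIM variant with a
#'   following ISI).
#' @param variant see \code{\link{mi_windows}}.
#' @param isi_side see \code{\link{mi_windows}}.
#' @return scalar MI (NA when both window rates are zero).
#' @export
psth_modulation_index <- function(aligned, variant = "STIM",
                                  isi_side = "following") {
  w <- mi_windows(variant, isi_side)
  mean_in <- function(win) {
    sel <- aligned$time_s >= win[1] & aligned$time_s < win[2]
    if (!any(sel)) stop("aligned window does not cover [", win[1], ", ",
                        win[2], ") for variant ", variant)
    mean(aligned$average[sel])
  }
  modulation_index(mean_in(w$stim), mean_in(w$isi))
}

#' Difference in modulation between social and object touch
#'
#' @param mi_social,mi_object modulation indices (vectorized).
#' @return \code{mi_social - mi_object}; NA propagates.
#' @export
delta_modulation <- function(mi_social, mi_object) mi_social - mi_object

#' Modulation index split by aversion epochs
#'
#' Computes the MI separately over presentations flagged as aversive and
#' non-aversive (e.g. forced object bouts with vs without aversive facial
#' expressions). Each class's MI uses the trial-averaged rates over that
#' class; an empty class yields NA for that entry.
#'
#' @param aligned output of \code{\link{trial_align_psth}}; rownames of
#'   \code{trial_mat} are trial ids.
#' @param aversion_flags named logical vector (trial_id -> aversive).
#' @param variant,isi_side see \code{\link{mi_windows}}.
#' @return named numeric vector \code{c(aversive = , nonaversive = )}.
#' @export
aversion_split_modulation <- function(aligned, aversion_flags,
                                      variant = "STIM",
                                      isi_side = "following") {
  w <- mi_windows(variant, isi_side)
  ids <- rownames(aligned$trial_mat)
  fl <- aversion_flags[ids]
  mi_for <- function(rows) {
    if (!length(rows) || !any(rows)) return(NA_real_)
    avg <- colMeans(aligned$trial_mat[rows, , drop = FALSE])
    sel_s <- aligned$time_s >= w$stim[1] & aligned$time_s < w$stim[2]
    sel_i <- aligned$time_s >= w$isi[1] & aligned$time_s < w$isi[2]
    modulation_index(mean(avg[sel_s]), mean(avg[sel_i]))
  }
  c(aversive = mi_for(!is.na(fl) & fl),
    nonaversive = mi_for(!is.na(fl) & !fl))
}

#' Pick the MI variant for a response cluster
#'
#' Onset-transient clusters use \code{PLATFORM}, sustained clusters
#' \code{STIM}, and mixed (onset plus sustained) clusters \code{SHORTSTIM}.
#' The decision is keyed off the centroid: peak latency within the first
#' second with little sustained change selects PLATFORM; a sustained change
#' without an early peak selects STIM; both features select SHORTSTIM.
#'
#' @param centroid numeric z-score centroid over time.
#' @param time_s matching time axis (seconds, relative to platform stop).
#' @param sustained_theta |mean z| over [1, 5] s counting as sustained,
#'   default 0.25.
#' @param onset_theta |z| peak over [-1, 1] s counting as an onset transient,
#'   default 1.
#' @return one of \code{"PLATFORM"}, \code{"STIM"}, \code{"SHORTSTIM"}.
#' @export
select_mi_variant <- function(centroid, time_s, sustained_theta = 0.25,
                              onset_theta = 1) {
  onset <- max(abs(centroid[time_s >= -1 & time_s < 1]))
  sustained <- abs(mean(centroid[time_s >= 1 & time_s < 5]))
  has_onset <- onset > onset_theta
  has_sustained <- sustained > sustained_theta
  if (has_onset && has_sustained) "SHORTSTIM"
  else if (has_onset) "PLATFORM"
  else "STIM"
}
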