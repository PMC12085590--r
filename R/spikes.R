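#' Quality-control filter for sorted units
#'
#' Keeps units that satisfy the standard curation thresholds: inter-spike
#' interval (refractory) violation fraction below \code{max_isi_violation},
#' amplitude cutoff (estimated fraction of missed spikes) below
#' \code{max_amplitude_cutoff}, and median spike amplitude above
#' \code{min_median_amplitude}. A unit with any metric missing is rejected
#' with reason \code{"missing"}.
#'
#' @param units data.frame with columns \code{unit_id}, \code{isi_violation},
#'   \code{amplitude_cutoff}, \code{median_amplitude_uv}.
#' @param max_isi_violation strict upper bound, default 0.10.
#' @param max_amplitude_cutoff strict upper bound, default 0.10.
#' @param min_median_amplitude strict lower bound in microvolts, default 50.
#' @return list with \code{kept} (data.frame of passing units) and
#'   \code{rejected} (data.frame: unit_id, reasons as a comma-joined string).
#' @export
qc_filter_units <- function(units,
                            max_isi_violation = 0.10,
                            max_amplitude_cutoff = 0.10,
                            min_median_amplitude = 50) {
  stopifnot(is.data.frame(units))
  need <- c("unit_id", "isi_violation", "amplitude_cutoff", "median_amplitude_uv")
  miss <- setdiff(need, names(units))
  if (length(miss)) stop("units table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(units) == 0)
    return(list(kept = units, rejected = data.frame(unit_id = units$unit_id[0],
                                                    reasons = character(0))))
  reasons <- vapply(seq_len(nrow(units)), function(i) {
    r <- character(0)
    v <- units$isi_violation[i]; a <- units$amplitude_cutoff[i]
    m <- units$median_amplitude_uv[i]
    if (any(is.na(c(v, a, m)))) return("missing")
    if (!(v < max_isi_violation)) r <- c(r, "isi_violation")
    if (!(a < max_amplitude_cutoff)) r <- c(r, "amplitude_cutoff")
    if (!(m > min_median_amplitude)) r <- c(r, "median_amplitude")
    paste(r, collapse = ",")
  }, character(1))
  keep <- reasons == ""
  list(kept = units[keep, , drop = FALSE],
       rejected = data.frame(unit_id = units$unit_id[!keep],
                             reasons = reasons[!keep],
                             stringsAsFactors = FALSE))
}

#' Classify units as regular-spiking by waveform width
#'
#' Regular-spiking (RS, putative excitatory) units have broad waveforms:
#' peak-to-trough duration >= 400 microseconds (inclusive).
#'
#' @param units data.frame with \code{unit_id} and \code{peak_to_trough_us}.
#' @param rs_min_us inclusive RS boundary, default 400.
#' @return named character vector, unit_id -> "RS" or "other".
#' @export
classify_unit_types <- function(units, rs_min_us = 400) {
  stopifnot(is.data.frame(units), "peak_to_trough_us" %in% names(units))
  out <- ifelse(units$peak_to_trough_us >= rs_min_us, "RS", "other")
  names(out) <- as.character(units$unit_id)
  out
}

#' Assign units to brain regions by recording depth
#'
#' Probe depth intervals are half-open \code{[min, max)} in micrometers below
#' the pia, ordered dorsal to ventral (e.g. vS1, then tSTR, then BLA). Depths
#' outside every interval return \code{"unassigned"}.
#'
#' @param units data.frame with \code{unit_id} and \code{depth_um}.
#' @param boundaries named list of \code{c(min, max)} depth intervals.
#' @return named character vector, unit_id -> region or "unassigned".
#' @export
assign_regions_by_depth <- function(units, boundaries) {
  stopifnot(is.data.frame(units), "depth_um" %in% names(units))
  b <- do.call(rbind, boundaries)
  if (any(b[, 1] >= b[, 2])) stop("each boundary must satisfy min < max")
  ord <- order(b[, 1])
  if (length(boundaries) > 1 && any(b[ord, 2][-nrow(b)] > b[ord, 1][-1]))
    stop("region depth boundaries overlap")
  out <- rep("unassigned", nrow(units))
  for (r in names(boundaries)) {
    iv <- boundaries[[r]]
    out[units$depth_um >= iv[1] & units$depth_um < iv[2]] <- r
  }
  names(out) <- as.character(units$unit_id)
  out
}

#' Bin a spike train into a firing-rate series
#'
#' Counts spikes in half-open bins \code{[t, t + bin_width)} and divides by
#' the bin width, so the rate series conserves total spike count:
#' \code{sum(rate) * bin_width} equals the number of spikes in
#' \code{[t_start, t_end)}. A spike falling exactly on a bin edge is counted
#' in the later bin.
#'
#' @param spike_times numeric vector of spike times (seconds).
#' @param bin_width bin width in seconds (> 0), default 0.05.
#' @param t_start,t_end series extent in seconds; \code{t_end} is rounded up
#'   to a whole number of bins.
#' @return data.frame with \code{time_s} (left bin edges) and \code{rate_hz}.
#' @export
bin_firing_rates <- function(spike_times, bin_width = 0.05, t_start = 0, t_end) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (missing(t_end)) t_end <- if (length(spike_times)) max(spike_times) + bin_width else t_start
  n_bins <- max(0L, as.integer(ceiling((t_end - t_start) / bin_width - 1e-9)))
  edges <- t_start + bin_width * (0:n_bins)
  if (n_bins == 0L)
    return(data.frame(time_s = numeric(0), rate_hz = numeric(0)))
  s <- spike_times[spike_times >= t_start & spike_times < edges[n_bins + 1]]
  idx <- floor((s - t_start) / bin_width) + 1
  idx <- pmin(idx, n_bins)  # numeric guard at the last edge
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(time_s = edges[seq_len(n_bins)], rate_hz = counts / bin_width)
}

#' Smooth a rate series with a centered moving average
#'
#' @param rates data.frame from \code{\link{bin_firing_rates}} (or any frame
#'   with \code{time_s} and \code{rate_hz} at constant spacing).
#' @param window smoothing window in seconds, a positive multiple of the bin
#'   width, default 0.25. At the series edges the window shrinks (no padding),
#'   so a constant series is left unchanged everywhere.
#' @return data.frame of the same shape with smoothed \code{rate_hz}.
#' @export
smooth_rates <- function(rates, window = 0.25) {
  stopifnot(is.data.frame(rates), all(c("time_s", "rate_hz") %in% names(rates)))
  n <- nrow(rates)
  if (n < 2) return(rates)
  bw <- rates$time_s[2] - rates$time_s[1]
  if (window < bw - 1e-12) stop("window must be >= bin width")
  k <- as.integer(round(window / bw))
  if (abs(k * bw - window) > 1e-9) stop("window must be a multiple of the bin width")
  if (k <= 1) return(rates)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  x <- rates$rate_hz
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  rates$rate_hz <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  rates
}

#' Align a rate series to platform-stop times
#'
#' Slices the session rate series into per-trial windows relative to each
#' trial's platform stop (trial time 0) and averages across trials. Trials
#' whose window extends past the recorded series are dropped and reported.
#'
#' @param rates data.frame with \code{time_s}, \code{rate_hz} at constant bin
#'   width covering the session.
#' @param trials data.frame with \code{trial_id} and \code{t_stop_s}.
#' @param window alignment window in seconds relative to the stop,
#'   default \code{c(-2, 7)} (2 s before touch onset to 2 s after touch end).
#' @return list with \code{time_s} (relative left bin edges), \code{trial_mat}
#'   (trial x bin matrix, rownames trial_id), \code{average} (mean over
#'   trials) and \code{dropped} (trial_ids outside the recording).
#' @export
trial_align_psth <- function(rates, trials, window = c(-2, 7)) {
  stopifnot(is.data.frame(rates), nrow(rates) >= 2)
  if (window[1] >= window[2]) stop("window start must precede end")
  bw <- rates$time_s[2] - rates$time_s[1]
  n_rel <- as.integer(round((window[2] - window[1]) / bw))
  rel_time <- window[1] + bw * (seq_len(n_rel) - 1)
  t0 <- rates$time_s[1]
  n <- nrow(rates)
  rows <- list(); kept_ids <- c(); dropped <- c()
  for (i in seq_len(nrow(trials))) {
    start_idx <- as.integer(round((trials$t_stop_s[i] + window[1] - t0) / bw)) + 1L
    idx <- start_idx + seq_len(n_rel) - 1L
    if (idx[1] < 1L || idx[n_rel] > n) {
      dropped <- c(dropped, trials$trial_id[i])
      next
    }
    rows[[length(rows) + 1L]] <- rates$rate_hz[idx]
    kept_ids <- c(kept_ids, trials$trial_id[i])
  }
  if (!length(rows)) stop("no trial fits within the recorded series")
  mat <- do.call(rbind, rows)
  rownames(mat) <- as.character(kept_ids)
  list(time_s = rel_time, trial_mat = mat, average = colMeans(mat),
       dropped = dropped)
}

#' z-score an aligned PSTH to its ISI baseline
#'
#' Baseline mean and SD are pooled over all ISI-window bins across trials
#' (every bin of \code{trial_mat} whose relative time falls in
#' \code{isi_window}); the trial-averaged trace is then z-scored against that
#' baseline. A zero baseline SD is replaced by \code{sd_floor} and flagged.
#'
#' @param aligned output of \code{\link{trial_align_psth}}.
#' @param isi_window baseline window in relative seconds, default
#'   \code{c(-2, 0)} (the pre-touch ISI portion of the aligned window).
#' @param sd_floor substitute SD when the baseline is constant, default 0.1.
#' @return list with \code{time_s}, \code{z} (z-scored trial average),
#'   \code{baseline_mean}, \code{baseline_sd}, \code{flagged} (TRUE when the
#'   floor was applied).
#' @export
zscore_to_isi <- function(aligned, isi_window = c(-2, 0), sd_floor = 0.1) {
  if (isi_window[1] >= isi_window[2]) stop("empty ISI window")
  if (isi_window[2] > 1e-9)
    stop("ISI window must lie before the platform stop")
  sel <- aligned$time_s >= isi_window[1] & aligned$time_s < isi_window[2]
  if (!any(sel)) stop("ISI window contains no bins of the aligned window")
  base <- as.vector(aligned$trial_mat[, sel, drop = FALSE])
  m <- mean(base)
  s <- stats::sd(base)
  flagged <- FALSE
  if (!is.finite(s) || s == 0) { s <- sd_floor; flagged <- TRUE }
  list(time_s = aligned$time_s, z = (aligned$average - m) / s,
       baseline_mean = m, baseline_sd = s, flagged = flagged)
}
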