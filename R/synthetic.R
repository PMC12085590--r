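#' Configuration for a synthetic touch session
#'
#' Defines the study conditions emulated by the generator: 40 presentation
#' bouts per context/choice block (5 s stimulus, 5 s ISI), Poisson units in
#' three regions drawn from four temporal response archetypes with
#' context-dependent gain, and correlated behavioral channels sampled at
#' 120 frames per second (running, orbital area, whisker protraction,
#' saccades).
#'
#' @param n_units named integer vector of units per region,
#'   default \code{c(vS1 = 20, tSTR = 12, BLA = 8)}.
#' @param archetype_props named proportions over the four archetypes
#'   \code{transient_excited}, \code{sustained_excited}, \code{suppressed},
#'   \code{unmodulated}; allocation is deterministic (largest remainder).
#' @param n_bouts bouts per context x choice block, default 40.
#' @param stim_dur,isi_dur bout cycle in seconds, defaults 5 and 5.
#' @param contexts,choices condition vocabularies.
#' @param baseline_range units' baseline rates are drawn uniformly from this
#'   range in Hz, default \code{c(2, 10)}.
#' @param social_gain,object_gain multiplicative stimulus gain per context
#'   applied during the stimulus window, defaults 2 and 1.2 (social-preferring
#'   population on average).
#' @param frame_rate behavioral sampling rate in Hz, default 120.
#' @param behavior_noise_sd pixel noise SD on pose labels, default 0.5.
#' @param afe_prob named per-context probability that a bout carries an
#'   aversive facial expression / avoidance epoch, default
#'   \code{c(social = 0.2, object = 0.6)} (object touch is the aversive one).
#' @param qc_fail_frac fraction of units generated with failing QC metrics,
#'   default 0.
#' @param behavior_betas named list unit-archetype -> named numeric vector of
#'   log-linear couplings from standardized behavioral regressors to firing;
#'   default no coupling.
#' @param seed integer seed governing all randomness (spikes and behavior use
#'   independent sub-streams derived from it).
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_units = c(vS1 = 20, tSTR = 12, BLA = 8),
                             archetype_props = c(transient_excited = 0.25,
                                                 sustained_excited = 0.25,
                                                 suppressed = 0.25,
                                                 unmodulated = 0.25),
                             n_bouts = 40, stim_dur = 5, isi_dur = 5,
                             contexts = c("social", "object"),
                             choices = c("voluntary", "forced"),
                             baseline_range = c(2, 10),
                             social_gain = 2, object_gain = 1.2,
                             frame_rate = 120,
                             behavior_noise_sd = 0.5,
                             afe_prob = c(social = 0.2, object = 0.6),
                             qc_fail_frac = 0,
                             behavior_betas = NULL,
                             seed = 1L) {
  stopifnot(all(n_units >= 0), n_bouts >= 0, stim_dur > 0, isi_dur > 0,
            abs(sum(archetype_props) - 1) < 1e-9,
            social_gain > 0, object_gain > 0, frame_rate > 0,
            qc_fail_frac >= 0, qc_fail_frac <= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

ARCHETYPES <- c("transient_excited", "sustained_excited", "suppressed",
                "unmodulated")

# Temporal gain profile of an archetype within one trial; 1 outside the
# stimulus window. `t` is time relative to the platform stop.
archetype_profile <- function(archetype, t, stim_dur = 5) {
  in_stim <- t >= 0 & t < stim_dur
  p <- rep(1, length(t))
  p[in_stim] <- switch(archetype,
    transient_excited = 1 + 4 * exp(-((t[in_stim] - 0.4)^2) / (2 * 0.25^2)),
    sustained_excited = 3,
    suppressed        = 0.25,
    unmodulated       = 1)
  p
}

# Largest-remainder deterministic allocation of n items to proportions p.
allocate_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate ground-truth unit definitions
#'
#' Draws per-region unit populations with deterministic archetype allocation,
#' uniform baseline rates, the configured context gains, and QC metrics that
#' pass (or fail, for a configured fraction) the curation thresholds.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return data.frame with one row per unit: \code{unit_id}, \code{region},
#'   \code{archetype}, \code{baseline_hz}, \code{social_gain},
#'   \code{object_gain}, \code{depth_um}, \code{peak_to_trough_us},
#'   \code{isi_violation}, \code{amplitude_cutoff}, \code{median_amplitude_uv},
#'   \code{qc_should_fail}.
#' @export
generate_units <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  depth_iv <- list(vS1 = c(0, 1200), tSTR = c(1400, 2600), BLA = c(3000, 4200))
  rows <- list()
  uid <- 0L
  for (region in names(config$n_units)) {
    n <- config$n_units[[region]]
    if (n == 0) next
    counts <- allocate_counts(n, config$archetype_props)
    arche <- rep(ARCHETYPES, counts)
    iv <- depth_iv[[region]]
    if (is.null(iv)) iv <- c(0, 4000)
    for (j in seq_len(n)) {
      uid <- uid + 1L
      rows[[uid]] <- data.frame(
        unit_id = uid, region = region, archetype = arche[j],
        baseline_hz = stats::runif(1, config$baseline_range[1],
                                   config$baseline_range[2]),
        social_gain = config$social_gain, object_gain = config$object_gain,
        depth_um = stats::runif(1, iv[1], iv[2] - 1e-6),
        peak_to_trough_us = sample(c(450, 550, 650, 300), 1,
                                   prob = c(0.3, 0.3, 0.2, 0.2)),
        isi_violation = stats::runif(1, 0, 0.08),
        amplitude_cutoff = stats::runif(1, 0, 0.08),
        median_amplitude_uv = stats::runif(1, 60, 200),
        qc_should_fail = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  units <- if (uid > 0) do.call(rbind, rows) else
    data.frame(unit_id = integer(0), region = character(0),
               archetype = character(0), baseline_hz = numeric(0),
               social_gain = numeric(0), object_gain = numeric(0),
               depth_um = numeric(0), peak_to_trough_us = numeric(0),
               isi_violation = numeric(0), amplitude_cutoff = numeric(0),
               median_amplitude_uv = numeric(0), qc_should_fail = logical(0))
  n_fail <- round(config$qc_fail_frac * nrow(units))
  if (n_fail > 0) {
    idx <- sample(nrow(units), n_fail)
    units$qc_should_fail[idx] <- TRUE
    # each failing unit violates one criterion, cycling through the three
    crit <- rep_len(1:3, n_fail)
    units$isi_violation[idx[crit == 1]] <- 0.25
    units$amplitude_cutoff[idx[crit == 2]] <- 0.3
    units$median_amplitude_uv[idx[crit == 3]] <- 30
  }
  units
}

#' Build the trial table for a synthetic session
#'
#' Blocks of \code{n_bouts} bouts are laid out sequentially, one block per
#' choice x context combination, with a 20 s gap between blocks.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return data.frame: \code{trial_id}, \code{context}, \code{choice},
#'   \code{t_stop_s}.
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cyc <- config$stim_dur + config$isi_dur
  block_len <- config$n_bouts * cyc
  gap <- 20
  rows <- list()
  t0 <- 5  # leave room for the pre-touch analysis window of the first trial
  k <- 0L
  for (choice in config$choices) for (context in config$contexts) {
    sched <- build_bout_schedule(config$n_bouts, config$stim_dur,
                                 config$isi_dur, t0 = t0)
    if (config$n_bouts > 0) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        trial_id = seq_along(sched$stop_times),
        context = context, choice = choice,
        t_stop_s = sched$stop_times, stringsAsFactors = FALSE)
    }
    t0 <- t0 + block_len + gap
  }
  if (!length(rows))
    return(data.frame(trial_id = integer(0), context = character(0),
                      choice = character(0), t_stop_s = numeric(0)))
  out <- do.call(rbind, rows)
  out$trial_id <- seq_len(nrow(out))
  out
}

# Per-unit rate on a fine time grid for the whole session.
unit_rate_trace <- function(unit, trials, tt, stim_dur, coupling = NULL) {
  rate <- rep(unit$baseline_hz, length(tt))
  for (i in seq_len(nrow(trials))) {
    rel <- tt - trials$t_stop_s[i]
    sel <- rel >= 0 & rel < stim_dur
    if (!any(sel)) next
    gain <- if (trials$context[i] == "social") unit$social_gain else unit$object_gain
    rate[sel] <- unit$baseline_hz *
      archetype_profile(unit$archetype, rel[sel], stim_dur) * gain
  }
  if (!is.null(coupling)) rate <- rate * exp(coupling)
  pmax(rate, 0)
}

#' Generate inhomogeneous Poisson spike trains
#'
#' Each unit fires as an inhomogeneous Poisson process whose rate is its
#' baseline outside stimulation and
#' \code{baseline * archetype_profile(t) * context_gain} during the 5 s
#' stimulus window, optionally modulated log-linearly by standardized
#' behavioral regressors (\code{exp(sum(beta * regressor))}) so rates stay
#' positive. Spikes are drawn per 1 ms sub-bin (thinning at the grid
#' resolution) with uniform jitter within the sub-bin.
#'
#' @param units data.frame from \code{\link{generate_units}}.
#' @param trials data.frame from \code{\link{generate_trials}}.
#' @param config a \code{\link{synthetic_config}}.
#' @param regressors optional list: \code{time_s} plus named standardized
#'   regressor traces used when \code{config$behavior_betas} is set.
#' @return data.frame with \code{unit_id} and \code{spike_time_s}, sorted.
#' @export
generate_spike_trains <- function(units, trials, config, regressors = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  if (nrow(trials) == 0 || nrow(units) == 0)
    return(data.frame(unit_id = integer(0), spike_time_s = numeric(0)))
  dt <- 0.001
  t_end <- max(trials$t_stop_s) + config$stim_dur + config$isi_dur
  tt <- seq(0, t_end, by = dt)
  out_id <- list(); out_t <- list()
  for (j in seq_len(nrow(units))) {
    u <- units[j, ]
    coupling <- NULL
    if (!is.null(config$behavior_betas) && !is.null(regressors)) {
      bet <- config$behavior_betas[[u$archetype]]
      if (!is.null(bet)) {
        coupling <- rep(0, length(tt))
        for (nm in names(bet)) {
          tr <- stats::approx(regressors$time_s, regressors[[nm]], xout = tt,
                              rule = 2)$y
          coupling <- coupling + bet[[nm]] * tr
        }
      }
    }
    rate <- unit_rate_trace(u, trials, tt, config$stim_dur, coupling)
    n <- stats::rpois(length(tt), rate * dt)
    idx <- rep.int(seq_along(tt), n)
    if (length(idx)) {
      st <- tt[idx] + stats::runif(length(idx), 0, dt)
      out_id[[length(out_id) + 1L]] <- rep.int(u$unit_id, length(st))
      out_t[[length(out_t) + 1L]] <- st
    }
  }
  if (!length(out_t))
    return(data.frame(unit_id = integer(0), spike_time_s = numeric(0)))
  sp <- data.frame(unit_id = unlist(out_id), spike_time_s = unlist(out_t))
  sp[order(sp$unit_id, sp$spike_time_s), , drop = FALSE]
}

# 23 face labels: 6 whisker follicles, 6 eye outline, 4 pupil, 3 mouth, 4 nose
FACE_LABELS <- c(paste0("whisker", 1:6), paste0("eye", 1:6),
                 paste0("pupil", 1:4), paste0("mouth", 1:3),
                 paste0("nose", 1:4))

# resting geometry (pixels) of the labels, roughly a mouse face profile
label_rest_positions <- function() {
  pos <- rbind(
    cbind(x = c(200, 220, 240, 205, 225, 245), y = c(120, 118, 116, 140, 138, 136)),   # whiskers
    cbind(x = 60 + 20 * cos(seq(0, 2 * pi, length.out = 7)[-7]),
          y = 60 + 12 * sin(seq(0, 2 * pi, length.out = 7)[-7])),                      # eye outline
    cbind(x = 60 + 5 * cos(seq(0, 2 * pi, length.out = 5)[-5]),
          y = 60 + 5 * sin(seq(0, 2 * pi, length.out = 5)[-5])),                       # pupil
    cbind(x = c(150, 160, 170), y = c(200, 205, 200)),                                 # mouth
    cbind(x = c(110, 120, 115, 125), y = c(170, 170, 180, 180))                        # nose
  )
  rownames(pos) <- FACE_LABELS
  pos
}

#' Generate synthetic behavioral traces with a planted event log
#'
#' Emits, at the configured frame rate, x/y pixel coordinates for the 23 face
#' labels (whisker follicles, eye outline, pupil, mouth, nose), ball motion
#' energy with a signed running-direction channel, and an all-FALSE frame
#' exclusion flag. Aversive events are planted per bout with context-dependent
#' probability \code{config$afe_prob}: an avoidance epoch couples backward
#' running, orbital tightening (eye-area contraction), aversive whisker
#' protraction (forward whisker-label displacement) and a temporal saccade.
#' The returned \code{events} log is the ground truth for detector tests.
#'
#' @param trials trial table.
#' @param config a \code{\link{synthetic_config}}.
#' @return list with \code{traces} (data.frame: \code{time_s}, one
#'   \code{<label>_x}/\code{<label>_y} pair per label, \code{ball_motion},
#'   \code{ball_direction}, \code{excluded}) and \code{events} (data.frame:
#'   \code{trial_id}, \code{kind}, \code{t_on_s}, \code{t_off_s}).
#' @export
generate_behavior_traces <- function(trials, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  fr <- config$frame_rate
  t_end <- if (nrow(trials)) max(trials$t_stop_s) + config$stim_dur +
    config$isi_dur else 10
  tt <- seq(0, t_end, by = 1 / fr)
  nf <- length(tt)
  rest <- label_rest_positions()
  noise <- function() stats::rnorm(nf, 0, config$behavior_noise_sd)
  traces <- data.frame(time_s = tt)
  # slow common facial motion so motion-energy channels are non-degenerate
  sway_x <- 1.5 * sin(2 * pi * 0.5 * tt)
  sway_y <- 1.0 * sin(2 * pi * 0.3 * tt + 1)
  for (lab in FACE_LABELS) {
    traces[[paste0(lab, "_x")]] <- rest[lab, "x"] + sway_x + noise()
    traces[[paste0(lab, "_y")]] <- rest[lab, "y"] + sway_y + noise()
  }
  # baseline running: positive direction = toward the stimulus
  ball <- pmax(stats::rnorm(nf, 2, 0.5), 0)
  dir <- rep(1, nf)
  events <- list()
  for (i in seq_len(nrow(trials))) {
    p <- config$afe_prob[[trials$context[i]]]
    if (is.null(p) || stats::runif(1) > p) next
    t_on <- trials$t_stop_s[i] + stats::runif(1, 0.2, 1)
    dur <- stats::runif(1, 1.5, 3)
    t_off <- min(t_on + dur, trials$t_stop_s[i] + config$stim_dur)
    sel <- tt >= t_on & tt < t_off
    if (!any(sel)) next
    # avoidance running: high ball motion, backward direction
    ball[sel] <- ball[sel] + 8
    dir[sel] <- -1
    # orbital tightening: contract eye outline toward its centroid by 40%
    exy <- paste0("eye", 1:6)
    cx <- mean(rest[exy, "x"]); cy <- mean(rest[exy, "y"])
    for (lab in exy) {
      traces[[paste0(lab, "_x")]][sel] <- cx +
        0.6 * (traces[[paste0(lab, "_x")]][sel] - cx)
      traces[[paste0(lab, "_y")]][sel] <- cy +
        0.6 * (traces[[paste0(lab, "_y")]][sel] - cy)
    }
    # aversive whisker protraction: forward (+x) displacement of follicles
    for (lab in paste0("whisker", 1:6))
      traces[[paste0(lab, "_x")]][sel] <- traces[[paste0(lab, "_x")]][sel] + 12
    # one temporal saccade at event onset (pupil jumps -x and drifts back)
    psel <- which(sel)
    jump <- 6 * exp(-(seq_along(psel) - 1) / (0.2 * fr))
    for (lab in paste0("pupil", 1:4))
      traces[[paste0(lab, "_x")]][psel] <- traces[[paste0(lab, "_x")]][psel] - jump
    events[[length(events) + 1L]] <- data.frame(
      trial_id = trials$trial_id[i], kind = "aversive_epoch",
      t_on_s = t_on, t_off_s = t_off)
  }
  traces$ball_motion <- ball
  traces$ball_direction <- dir
  traces$excluded <- FALSE
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(trial_id = integer(0), kind = character(0),
               t_on_s = numeric(0), t_off_s = numeric(0))
  list(traces = traces, events = ev)
}

#' Generate a full synthetic session with ground truth
#'
#' Bundles schedule, trials, units (with QC metrics), Poisson spike trains and
#' behavioral traces, all reproducible under \code{config$seed}. Spikes and
#' behavior use independent sub-streams of the seed, so either can be
#' regenerated without perturbing the other.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list of class \code{touch_session}: \code{trials}, \code{units},
#'   \code{spikes}, \code{behavior} (traces), \code{ground_truth} (unit table
#'   plus planted behavioral \code{events}), \code{meta} (frame rate, seed,
#'   stim/ISI durations).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  trials <- generate_trials(config)
  units <- generate_units(config)
  beh <- generate_behavior_traces(trials, config)
  spikes <- generate_spike_trains(units, trials, config)
  structure(list(
    trials = trials,
    units = units[, c("unit_id", "region", "depth_um", "peak_to_trough_us",
                      "isi_violation", "amplitude_cutoff",
                      "median_amplitude_uv")],
    spikes = spikes,
    behavior = beh$traces,
    ground_truth = list(units = units, events = beh$events),
    meta = list(frame_rate = config$frame_rate, seed = config$seed,
                stim_dur = config$stim_dur, isi_dur = config$isi_dur)
  ), class = "touch_session")
}
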