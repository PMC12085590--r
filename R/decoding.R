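#' Decoder configuration
#'
#' Fixed-hyperparameter soft-margin classifier with a radial-basis-function
#' kernel and box constraint (cost) 1, 10-fold cross-validation on the
#' training split, stratified 80/20 train/test splits, and 100 random
#' iterations of unit subsampling and splitting.
#'
#' @param n_units_subsample units drawn per iteration (NULL = all available).
#' @param n_iterations random iterations, default 100.
#' @param train_fraction training fraction per class, default 0.8.
#' @param cv_folds internal cross-validation folds, default 10.
#' @param cost box constraint, default 1.
#' @param seed RNG seed.
#' @return list of class \code{decoder_config}.
#' @export
decoder_config <- function(n_units_subsample = NULL, n_iterations = 100,
                           train_fraction = 0.8, cv_folds = 10, cost = 1,
                           seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2,
            n_iterations >= 1)
  structure(list(n_units_subsample = n_units_subsample,
                 n_iterations = n_iterations,
                 train_fraction = train_fraction, cv_folds = cv_folds,
                 cost = cost, seed = seed), class = "decoder_config")
}

#' Trial x feature matrix for decoding
#'
#' Neural source: one column per unit, each trial's mean firing rate over
#' \code{window} (or, with \code{bin_width} set, one column per unit per bin
#' across the window). Behavioral sources: per-label motion energies
#' (all 23 face labels) or the aversive set (running avoidance, eye area,
#' saccade direction, whisker protraction), trial-averaged per bin.
#'
#' @param session a \code{touch_session}.
#' @param source \code{"neural"}, \code{"behavior_all_labels"} or
#'   \code{"behavior_aversive"}.
#' @param trials subset of \code{session$trials} to use.
#' @param window seconds relative to platform stop, default \code{c(0, 5)}.
#' @param bin_width NULL for window-averaged features, or a width in seconds
#'   (50 ms neural, 100 ms behavioral conventions) for time-binned features.
#' @param unit_ids neural units to include (default: all in the session).
#' @return list: \code{x} (trial x feature matrix), \code{labels} (context
#'   factor), \code{trial_id}, and for binned neural features
#'   \code{bin_time_s} plus \code{feature_unit}/\code{feature_bin} maps.
#' @export
make_feature_matrix <- function(session, source = c("neural",
                                                    "behavior_all_labels",
                                                    "behavior_aversive"),
                                trials = session$trials, window = c(0, 5),
                                bin_width = NULL, unit_ids = NULL) {
  source <- match.arg(source)
  if (!nrow(trials)) stop("empty trial list")
  if (source == "neural") {
    if (is.null(session$spikes) || !nrow(session$spikes))
      stop("session has no spike data")
    if (is.null(unit_ids)) unit_ids <- sort(unique(session$units$unit_id))
    if (is.null(bin_width)) {
      x <- sapply(unit_ids, function(u) {
        st <- session$spikes$spike_time_s[session$spikes$unit_id == u]
        vapply(seq_len(nrow(trials)), function(i) {
          t0 <- trials$t_stop_s[i]
          sum(st >= t0 + window[1] & st < t0 + window[2]) /
            (window[2] - window[1])
        }, numeric(1))
      })
      if (is.null(dim(x))) x <- matrix(x, nrow = nrow(trials))
      colnames(x) <- paste0("u", unit_ids)
      fu <- unit_ids; fb <- NULL; bt <- NULL
    } else {
      n_bins <- as.integer(round((window[2] - window[1]) / bin_width))
      bt <- window[1] + bin_width * (seq_len(n_bins) - 1)
      cols <- list()
      fu <- integer(0); fb <- integer(0)
      for (u in unit_ids) {
        st <- session$spikes$spike_time_s[session$spikes$unit_id == u]
        m <- sapply(seq_len(nrow(trials)), function(i) {
          rel <- st - trials$t_stop_s[i]
          rel <- rel[rel >= window[1] & rel < window[2]]
          tabulate(pmin(floor((rel - window[1]) / bin_width) + 1, n_bins),
                   nbins = n_bins) / bin_width
        })
        cols[[length(cols) + 1L]] <- t(m)
        fu <- c(fu, rep(u, n_bins)); fb <- c(fb, seq_len(n_bins))
      }
      x <- do.call(cbind, cols)
      colnames(x) <- paste0("u", fu, "_b", fb)
    }
    out <- list(x = x, labels = factor(trials$context),
                trial_id = trials$trial_id, bin_time_s = bt,
                feature_unit = fu, feature_bin = fb)
    return(out)
  }
  # behavioral sources
  if (is.null(session$behavior)) stop("session has no behavior data")
  tr <- session$behavior
  if (is.null(bin_width)) bin_width <- 0.1
  n_bins <- as.integer(round((window[2] - window[1]) / bin_width))
  bt <- window[1] + bin_width * (seq_len(n_bins) - 1)
  series <- if (source == "behavior_all_labels") {
    s <- lapply(FACE_LABELS, function(l) label_motion_energy(tr, l))
    names(s) <- FACE_LABELS
    s
  } else {
    pup <- detect_saccades(tr)
    sacc <- rep(0, nrow(tr))
    for (i in seq_len(nrow(pup))) {
      sel <- tr$time_s >= pup$t_on_s[i] & tr$time_s <= pup$t_off_s[i]
      sacc[sel] <- if (pup$direction[i] == "temporal") -1 else 1
    }
    list(running_avoidance = as.numeric(tr$ball_motion > 1 &
                                          tr$ball_direction < 0),
         eye_area = eye_area_trace(tr),
         saccade_direction = sacc,
         whisker_protraction = whisker_protraction_trace(tr))
  }
  bin_one <- function(v, t0) {
    vapply(seq_len(n_bins), function(b) {
      sel <- tr$time_s >= t0 + bt[b] & tr$time_s < t0 + bt[b] + bin_width
      mean(v[sel], na.rm = TRUE)
    }, numeric(1))
  }
  x <- do.call(cbind, lapply(names(series), function(nm) {
    m <- t(sapply(seq_len(nrow(trials)),
                  function(i) bin_one(series[[nm]], trials$t_stop_s[i])))
    colnames(m) <- paste0(nm, "_b", seq_len(n_bins))
    m
  }))
  x[is.nan(x)] <- 0
  list(x = x, labels = factor(trials$context), trial_id = trials$trial_id,
       bin_time_s = bt)
}

# one stratified train/test split; returns train/test row indices
stratified_split <- function(labels, train_fraction) {
  tr <- unlist(lapply(levels(labels), function(l) {
    idx <- which(labels == l)
    sample(idx, floor(length(idx) * train_fraction))
  }))
  list(train = tr, test = setdiff(seq_along(labels), tr))
}

fit_predict_svm <- function(x_train, y_train, x_test, cost, cv_folds) {
  keep <- apply(x_train, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) return(factor(rep(levels(y_train)[1], nrow(x_test)),
                                levels = levels(y_train)))
  fit <- e1071::svm(x_train[, keep, drop = FALSE], y_train,
                    kernel = "radial", cost = cost, scale = TRUE,
                    cross = min(cv_folds, length(y_train)))
  stats::predict(fit, x_test[, keep, drop = FALSE])
}

#' Decode touch context from a feature matrix
#'
#' Per iteration: draw a random unit subsample (neural features) or use all
#' features, make a stratified train/test split, fit the RBF classifier
#' (cost 1, 10-fold cross-validation on the training split) and score the
#' held-out trials. Reports the mean and SE of accuracy over iterations.
#'
#' @param features output of \code{\link{make_feature_matrix}}.
#' @param config a \code{\link{decoder_config}}.
#' @return list of class \code{decode_result}: \code{accuracy_mean},
#'   \code{accuracy_se}, \code{accuracies} (per iteration), \code{n_trials},
#'   \code{n_features}.
#' @export
decode_context <- function(features, config = decoder_config()) {
  y <- features$labels
  if (nlevels(droplevels(y)) < 2) stop("need both classes present")
  x <- features$x
  set.seed(config$seed)
  acc <- vapply(seq_len(config$n_iterations), function(it) {
    xi <- x
    if (!is.null(config$n_units_subsample) && !is.null(features$feature_unit)) {
      units <- unique(features$feature_unit)
      pick <- sample(units, min(config$n_units_subsample, length(units)))
      xi <- x[, features$feature_unit %in% pick, drop = FALSE]
    } else if (!is.null(config$n_units_subsample)) {
      pick <- sample(ncol(x), min(config$n_units_subsample, ncol(x)))
      xi <- x[, pick, drop = FALSE]
    }
    sp <- stratified_split(y, config$train_fraction)
    pred <- fit_predict_svm(xi[sp$train, , drop = FALSE], y[sp$train],
                            xi[sp$test, , drop = FALSE],
                            config$cost, config$cv_folds)
    mean(pred == y[sp$test])
  }, numeric(1))
  structure(list(accuracy_mean = mean(acc),
                 accuracy_se = stats::sd(acc) / sqrt(length(acc)),
                 accuracies = acc, n_trials = length(y),
                 n_features = ncol(x)),
            class = "decode_result")
}

#' Time-resolved context decoding
#'
#' Fits an independent decoder per time bin of a binned feature matrix
#' (e.g. 50 ms neural bins over [-1, +2] s, 10 units per iteration) and
#' returns the accuracy curve.
#'
#' @param features binned output of \code{\link{make_feature_matrix}} (must
#'   carry \code{feature_bin}).
#' @param config a \code{\link{decoder_config}}.
#' @return data.frame: \code{time_s}, \code{accuracy_mean},
#'   \code{accuracy_se}.
#' @export
decode_timecourse <- function(features, config = decoder_config()) {
  if (is.null(features$feature_bin)) stop("features are not time-binned")
  bins <- sort(unique(features$feature_bin))
  out <- lapply(bins, function(b) {
    sel <- features$feature_bin == b
    f <- list(x = features$x[, sel, drop = FALSE], labels = features$labels,
              feature_unit = features$feature_unit[sel])
    cfg <- config; cfg$seed <- config$seed + b
    r <- decode_context(f, cfg)
    data.frame(time_s = features$bin_time_s[b],
               accuracy_mean = r$accuracy_mean, accuracy_se = r$accuracy_se)
  })
  do.call(rbind, out)
}

#' Shuffle controls for the context decoder
#'
#' \code{"test_labels"}: labels of the held-out trials are shuffled after the
#' split (decoder trained normally; tests that accuracy is label-driven).
#' \code{"partial_80pct"}: context labels of a random \code{fraction} of
#' presentations (default 0.8) are shuffled before splitting.
#' \code{"time_shuffle_neural"}: each neural feature column is independently
#' permuted across trials, destroying the trial-label association of neural
#' activity while any behavioral columns stay aligned.
#'
#' @param features output of \code{\link{make_feature_matrix}}.
#' @param config a \code{\link{decoder_config}}.
#' @param mode control mode.
#' @param fraction shuffled fraction for \code{"partial_80pct"}, default 0.8.
#' @param neural_cols columns treated as neural for
#'   \code{"time_shuffle_neural"}; defaults to all columns.
#' @return \code{decode_result}.
#' @export
shuffle_controls <- function(features, config = decoder_config(),
                             mode = c("test_labels", "partial_80pct",
                                      "time_shuffle_neural"),
                             fraction = 0.8, neural_cols = NULL) {
  mode <- match.arg(mode)
  set.seed(config$seed + 7919L)
  y <- features$labels
  n <- length(y)
  if (mode == "partial_80pct") {
    if (fraction > 0) {
      idx <- sample(n, round(fraction * n))
      y[idx] <- sample(y[idx])
    }
    f <- features; f$labels <- y
    return(decode_context(f, config))
  }
  if (mode == "time_shuffle_neural") {
    x <- features$x
    if (is.null(neural_cols)) neural_cols <- seq_len(ncol(x))
    for (j in neural_cols) x[, j] <- x[sample(n), j]
    f <- features; f$x <- x
    return(decode_context(f, config))
  }
  # test_labels: shuffle held-out labels inside the iteration loop
  x <- features$x
  set.seed(config$seed)
  acc <- vapply(seq_len(config$n_iterations), function(it) {
    xi <- x
    if (!is.null(config$n_units_subsample) && !is.null(features$feature_unit)) {
      units <- unique(features$feature_unit)
      pick <- sample(units, min(config$n_units_subsample, length(units)))
      xi <- x[, features$feature_unit %in% pick, drop = FALSE]
    }
    sp <- stratified_split(y, config$train_fraction)
    pred <- fit_predict_svm(xi[sp$train, , drop = FALSE], y[sp$train],
                            xi[sp$test, , drop = FALSE],
                            config$cost, config$cv_folds)
    mean(pred == sample(y[sp$test]))
  }, numeric(1))
  structure(list(accuracy_mean = mean(acc),
                 accuracy_se = stats::sd(acc) / sqrt(length(acc)),
                 accuracies = acc, n_trials = n, n_features = ncol(x)),
            class = "decode_result")
}

#' Exclude units with baseline drift between sessions
#'
#' A unit is excluded when its second-session baseline firing differs from
#' the first session's mean baseline by strictly more than \code{k} standard
#' deviations of the first session's per-trial baseline rates. Units whose
#' first-session SD is undefined (a single trial) are kept and flagged.
#'
#' @param baseline1 matrix or data.frame of per-trial baseline rates in
#'   session 1 (trials x units) or a list of per-unit vectors.
#' @param baseline2 named numeric vector of session-2 mean baseline per unit.
#' @param k SD multiple, default 1.5.
#' @return list: \code{kept} (unit names), \code{excluded}, \code{flagged}.
#' @export
exclude_baseline_drift <- function(baseline1, baseline2, k = 1.5) {
  if (is.matrix(baseline1) || is.data.frame(baseline1))
    baseline1 <- as.list(as.data.frame(baseline1))
  units <- names(baseline2)
  kept <- character(0); excl <- character(0); flag <- character(0)
  for (u in units) {
    b1 <- baseline1[[u]]
    m <- mean(b1); s <- stats::sd(b1)
    if (!is.finite(s)) { kept <- c(kept, u); flag <- c(flag, u); next }
    if (abs(baseline2[[u]] - m) > k * s) excl <- c(excl, u)
    else kept <- c(kept, u)
  }
  list(kept = kept, excluded = excl, flagged = flag)
}

#' Context decoding with locomotion in the feature space
#'
#' Augments neural features with trial-binned running motion energy
#' (50 ms bins by convention); with \code{shuffle_neural = TRUE} the neural
#' columns are permuted across trials while the locomotion columns stay
#' aligned, isolating what locomotion alone contributes.
#'
#' @param features neural output of \code{\link{make_feature_matrix}}.
#' @param locomotion trial x bin matrix of running motion energy.
#' @param config a \code{\link{decoder_config}}.
#' @param shuffle_neural permute neural columns across trials, default FALSE.
#' @return \code{decode_result}.
#' @export
decode_with_locomotion <- function(features, locomotion,
                                   config = decoder_config(),
                                   shuffle_neural = FALSE) {
  stopifnot(nrow(locomotion) == nrow(features$x))
  x <- features$x
  if (shuffle_neural) {
    set.seed(config$seed + 104729L)
    for (j in seq_len(ncol(x))) x[, j] <- x[sample(nrow(x)), j]
  }
  loco <- as.matrix(locomotion)
  colnames(loco) <- paste0("loco_b", seq_len(ncol(loco)))
  f <- features
  f$x <- cbind(x, loco)
  # locomotion columns are not unit features; keep unit subsampling over
  # neural columns only
  if (!is.null(features$feature_unit))
    f$feature_unit <- c(features$feature_unit, rep(NA_integer_, ncol(loco)))
  cfg <- config
  if (!is.null(cfg$n_units_subsample) && !is.null(f$feature_unit)) {
    # subsample units but always retain locomotion columns
    y <- f$labels
    set.seed(cfg$seed)
    acc <- vapply(seq_len(cfg$n_iterations), function(it) {
      units <- unique(stats::na.omit(f$feature_unit))
      pick <- sample(units, min(cfg$n_units_subsample, length(units)))
      keep <- is.na(f$feature_unit) | f$feature_unit %in% pick
      xi <- f$x[, keep, drop = FALSE]
      sp <- stratified_split(y, cfg$train_fraction)
      pred <- fit_predict_svm(xi[sp$train, , drop = FALSE], y[sp$train],
                              xi[sp$test, , drop = FALSE],
                              cfg$cost, cfg$cv_folds)
      mean(pred == y[sp$test])
    }, numeric(1))
    return(structure(list(accuracy_mean = mean(acc),
                          accuracy_se = stats::sd(acc) / sqrt(length(acc)),
                          accuracies = acc, n_trials = length(y),
                          n_features = ncol(f$x)),
                     class = "decode_result"))
  }
  decode_context(f, cfg)
}
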