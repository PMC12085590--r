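#' Write a session to a directory of delimited text files
#'
#' Writes \code{trials.tsv}, \code{spikes.tsv}, \code{units.tsv},
#' \code{behavior.tsv} (when present) and, for synthetic sessions,
#' \code{ground_truth.json}.
#'
#' @param session a \code{touch_session}.
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(path, f), sep = "\t", row.names = FALSE, quote = FALSE)
  w(session$trials, "trials.tsv")
  w(session$spikes, "spikes.tsv")
  w(session$units, "units.tsv")
  if (!is.null(session$behavior)) w(session$behavior, "behavior.tsv")
  if (!is.null(session$ground_truth)) {
    gt <- list(units = session$ground_truth$units,
               events = session$ground_truth$events,
               meta = session$meta)
    jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(session$meta))
    jsonlite::write_json(session$meta, file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a session from a directory of delimited text files
#'
#' Requires \code{trials.tsv}, \code{spikes.tsv} and \code{units.tsv};
#' \code{behavior.tsv} is optional (behavioral analyses then error clearly).
#' Validates referential integrity (every spike's unit id must exist) and
#' time monotonicity of the trial table.
#'
#' @param path session directory.
#' @return a \code{touch_session}.
#' @export
load_session <- function(path) {
  need <- c("trials.tsv", "spikes.tsv", "units.tsv")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop("missing session file: ", f)
  r <- function(f) utils::read.table(file.path(path, f), sep = "\t",
                                     header = TRUE, stringsAsFactors = FALSE)
  trials <- r("trials.tsv"); spikes <- r("spikes.tsv"); units <- r("units.tsv")
  bad <- setdiff(unique(spikes$unit_id), units$unit_id)
  if (length(bad))
    stop("spikes reference unknown unit_id(s): ", paste(bad, collapse = ", "))
  for (ch in unique(paste(trials$context, trials$choice))) {
    sel <- paste(trials$context, trials$choice) == ch
    ts <- trials$t_stop_s[sel]
    if (is.unsorted(ts, strictly = TRUE))
      stop("non-monotone platform-stop times within block: ", ch)
  }
  behavior <- if (file.exists(file.path(path, "behavior.tsv")))
    r("behavior.tsv") else NULL
  meta <- if (file.exists(file.path(path, "meta.json")))
    jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  else NULL
  structure(list(trials = trials, units = units, spikes = spikes,
                 behavior = behavior, ground_truth = NULL, meta = meta),
            class = "touch_session")
}

#' Per-unit z-scored PSTHs for a set of trials
#'
#' Convenience wrapper running bin -> smooth -> align -> z-score for each
#' unit: 50 ms bins, 250 ms moving average, alignment window relative to each
#' platform stop, z-scored to the pre-touch ISI.
#'
#' @param session a \code{touch_session}.
#' @param trials trial subset (default all trials).
#' @param unit_ids units to process (default all).
#' @param window alignment window, default \code{c(-2, 7)} s.
#' @param bin_width seconds, default 0.05.
#' @param smooth_window seconds, default 0.25.
#' @return named list unit_id -> \code{\link{zscore_to_isi}} output, each
#'   also carrying the \code{aligned} matrices.
#' @export
session_psths <- function(session, trials = session$trials,
                          unit_ids = NULL, window = c(-2, 7),
                          bin_width = 0.05, smooth_window = 0.25) {
  if (is.null(unit_ids)) unit_ids <- sort(unique(session$units$unit_id))
  t_end <- max(session$trials$t_stop_s) + max(window[2], 10) + 1
  out <- lapply(unit_ids, function(u) {
    st <- session$spikes$spike_time_s[session$spikes$unit_id == u]
    rates <- bin_firing_rates(st, bin_width, t_start = 0, t_end = t_end)
    rates <- smooth_rates(rates, smooth_window)
    aligned <- trial_align_psth(rates, trials, window)
    z <- zscore_to_isi(aligned)
    z$aligned <- aligned
    z
  })
  names(out) <- as.character(unit_ids)
  out
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Simulate -> QC -> PSTH -> cluster -> modulation -> preference -> decode ->
#' encode -> report, writing each stage's tables (csv/json) and a log with
#' the seed to \code{out_dir}.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param out_dir results directory.
#' @param n_restarts k-means restarts, default 100.
#' @param n_boot preference permutation draws, default 200.
#' @param n_iterations decoder iterations, default 50.
#' @return list with the stage results, invisibly; tables on disk.
#' @export
run_pipeline <- function(config, out_dir, n_restarts = 100, n_boot = 200,
                         n_iterations = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  logln <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ...,
                             "\n", file = logf, append = TRUE)
  logln("pipeline start, seed =", config$seed)
  session <- generate_session(config)
  write_session(session, file.path(out_dir, "session"))
  logln("stage simulate: units =", nrow(session$units),
        "trials =", nrow(session$trials))

  qc <- qc_filter_units(session$units)
  utils::write.csv(qc$kept, file.path(out_dir, "units_kept.csv"),
                   row.names = FALSE)
  logln("stage qc: kept", nrow(qc$kept), "rejected", nrow(qc$rejected))

  kept_ids <- qc$kept$unit_id
  results <- list(session = session, qc = qc)
  for (cond in unique(session$trials$choice)) {
    trl <- session$trials[session$trials$choice == cond, , drop = FALSE]
    psths <- session_psths(session, trl, kept_ids, window = c(-3, 10))
    m <- build_psth_matrix(psths)
    red <- pca_reduce(m)
    K <- select_k_gap(red$scores, k_range = 1:6, seed = config$seed)
    cm <- kmeans_consensus(red$scores, K, n_restarts = n_restarts,
                           psth_matrix = m, seed = config$seed)
    classes <- group_response_classes(cm)
    logln("stage cluster (", cond, "): K =", K)

    # per-unit MI and preference over this condition's trials
    rows <- lapply(kept_ids, function(u) {
      al <- psths[[as.character(u)]]$aligned
      mi_s <- {
        s_tr <- trl[trl$context == "social", ]
        al_s <- trial_align_psth_from(al, s_tr)
        psth_modulation_index_safe(al_s)
      }
      mi_o <- {
        o_tr <- trl[trl$context == "object", ]
        al_o <- trial_align_psth_from(al, o_tr)
        psth_modulation_index_safe(al_o)
      }
      data.frame(unit_id = u, condition = cond,
                 response_class = unname(classes$unit_class[as.character(u)]),
                 cluster = unname(cm$assignments[as.character(u)]),
                 mi_social = mi_s, mi_object = mi_o,
                 delta_mi = delta_modulation(mi_s, mi_o))
    })
    mi_tab <- do.call(rbind, rows)
    utils::write.csv(mi_tab, file.path(out_dir,
                                       paste0("modulation_", cond, ".csv")),
                     row.names = FALSE)

    pref <- lapply(kept_ids, function(u) {
      fx <- make_feature_matrix(session, "neural", trl, unit_ids = u)
      rs <- fx$x[trl$context == "social", 1]
      ro <- fx$x[trl$context == "object", 1]
      cls <- classes$unit_class[as.character(u)]
      if (!cls %in% c("excited", "suppressed")) cls <- "excited"
      bt <- bootstrap_preference_test(rs, ro, n_boot = n_boot,
                                      seed = config$seed + u)
      data.frame(unit_id = u, condition = cond, auroc = bt$auroc,
                 p_boot = bt$p_boot,
                 label = classify_preference(bt$auroc, bt$p_boot, cls))
    })
    pref_tab <- do.call(rbind, pref)
    utils::write.csv(pref_tab, file.path(out_dir,
                                         paste0("preference_", cond, ".csv")),
                     row.names = FALSE)
    logln("stage roc (", cond, "): social =",
          sum(pref_tab$label == "social"), "object =",
          sum(pref_tab$label == "object"))

    fx <- make_feature_matrix(session, "neural", trl, unit_ids = kept_ids)
    dec <- decode_context(fx, decoder_config(
      n_units_subsample = min(10, length(kept_ids)),
      n_iterations = n_iterations, seed = config$seed))
    logln("stage decode (", cond, "): accuracy =",
          round(dec$accuracy_mean, 3))
    results[[cond]] <- list(clusters = cm, classes = classes, mi = mi_tab,
                            preference = pref_tab, decode = dec)
  }

  forced <- session$trials[session$trials$choice == "forced", , drop = FALSE]
  if (nrow(forced) && !is.null(session$behavior)) {
    design <- build_design_matrix(session, forced)
    fxf <- make_feature_matrix(session, "neural", forced, unit_ids = kept_ids)
    fits <- lapply(seq_along(kept_ids), function(i)
      fit_ridge_cv(design, fxf$x[, i], seed = config$seed))
    names(fits) <- kept_ids
    enc <- data.frame(unit_id = kept_ids,
                      lambda = vapply(fits, `[[`, numeric(1), "lambda"),
                      cv_r2 = vapply(fits, `[[`, numeric(1), "cv_r2"))
    enc <- cbind(enc, t(vapply(fits, `[[`, numeric(13), "beta_norm")))
    utils::write.csv(enc, file.path(out_dir, "encoding.csv"),
                     row.names = FALSE)
    results$encoding <- fits
    logln("stage encode: mean cvR2 =",
          round(mean(enc$cv_r2, na.rm = TRUE), 3))
  }

  report <- list(
    seed = config$seed,
    n_units_kept = length(kept_ids),
    counts = lapply(results[intersect(names(results),
                                      unique(session$trials$choice))],
                    function(r) list(
                      excited = sum(r$classes$unit_class == "excited"),
                      suppressed = sum(r$classes$unit_class == "suppressed"),
                      social_pref = sum(r$preference$label == "social"),
                      object_pref = sum(r$preference$label == "object"))))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  logln("pipeline done")
  invisible(results)
}

# subset an aligned PSTH to a set of trials (rows by trial_id)
trial_align_psth_from <- function(aligned, trials) {
  ids <- as.character(trials$trial_id)
  ids <- ids[ids %in% rownames(aligned$trial_mat)]
  mat <- aligned$trial_mat[ids, , drop = FALSE]
  list(time_s = aligned$time_s, trial_mat = mat, average = colMeans(mat),
       dropped = character(0))
}

psth_modulation_index_safe <- function(aligned) {
  # STIM variant needs [0,10); fall back to SHORTSTIM if window is narrower
  if (max(aligned$time_s) >= 10 - 1e-9)
    psth_modulation_index(aligned, "STIM")
  else psth_modulation_index(aligned, "SHORTSTIM")
}
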