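#' Assemble the time x unit PSTH matrix for clustering
#'
#' Columns are z-scored, trial-averaged PSTHs, one per unit, pooled over
#' contexts within the given choice condition (clustering is run once per
#' choice condition and brain region; units from different genotypes are
#' pooled in the same matrix).
#'
#' @param psths named list (unit_id -> list with \code{time_s} and \code{z},
#'   as produced by \code{\link{zscore_to_isi}}).
#' @return numeric matrix (time bins x units) with unit ids as colnames and
#'   the shared relative time in \code{attr(, "time_s")}.
#' @export
build_psth_matrix <- function(psths) {
  if (!length(psths)) stop("no PSTHs supplied")
  t0 <- psths[[1]]$time_s
  for (p in psths)
    if (length(p$time_s) != length(t0) || any(abs(p$time_s - t0) > 1e-9))
      stop("PSTHs do not share a common window/binning")
  m <- sapply(psths, function(p) p$z)
  if (is.null(dim(m))) m <- matrix(m, ncol = length(psths))
  colnames(m) <- names(psths)
  attr(m, "time_s") <- t0
  m
}

#' PCA reduction of unit response shapes
#'
#' Treats each unit (column of the PSTH matrix) as an observation and keeps
#' the smallest number of principal components whose cumulative explained
#' variance exceeds \code{variance_target}.
#'
#' @param psth_matrix time x unit matrix from \code{\link{build_psth_matrix}}.
#' @param variance_target cumulative explained-variance threshold, default 0.95.
#' @return list: \code{scores} (unit x component matrix), \code{n_components},
#'   \code{explained} (per-component variance fractions).
#' @export
pca_reduce <- function(psth_matrix, variance_target = 0.95) {
  x <- t(psth_matrix)  # units as observations
  if (nrow(x) < 2) stop("need at least 2 units for PCA")
  if (all(apply(x, 2, stats::var) == 0)) stop("zero-variance PSTH matrix")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) > variance_target)[1]
  if (is.na(k)) k <- length(ev)
  k <- max(1L, k)
  list(scores = pc$x[, seq_len(k), drop = FALSE], n_components = k,
       explained = ev)
}

#' Choose the number of clusters by the gap statistic
#'
#' Standard gap criterion against a uniform reference over the bounding box
#' of the scores: the chosen K is the smallest k with
#' \code{Gap(k) >= Gap(k+1) - SE(k+1)}.
#'
#' @param scores unit x component matrix.
#' @param k_range candidate cluster counts, default \code{1:8} (clipped to
#'   \code{n_units - 1}).
#' @param B reference draws, default 50.
#' @param seed RNG seed for the reference draws and k-means inits.
#' @return selected K (integer).
#' @export
select_k_gap <- function(scores, k_range = 1:8, B = 50, seed = 1L) {
  if (!length(k_range)) stop("k_range is empty")
  k_range <- sort(unique(as.integer(k_range)))
  k_max <- min(max(k_range), nrow(scores) - 1L)
  if (k_max < min(k_range)) stop("k_range exceeds n_units - 1")
  set.seed(seed)
  gap <- cluster::clusGap(scores,
                          FUN = function(x, k) stats::kmeans(x, k, nstart = 10,
                                                             iter.max = 50),
                          K.max = k_max, B = B, spaceH0 = "original",
                          verbose = FALSE)
  tab <- gap$Tab[k_range[k_range <= k_max], , drop = FALSE]
  k_sel <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                          method = "Tibs2001SEmax")
  as.integer(k_range[k_range <= k_max][k_sel])
}

#' Consensus k-means over random restarts
#'
#' Runs \code{n_restarts} k-means fits, each from a fresh random centroid
#' initialization; the reported assignment is the restart with the lowest
#' within-cluster sum of squares, and the co-assignment matrix records the
#' fraction of restarts in which each unit pair shared a cluster (the
#' stability evidence for the final assignment). Cluster labels are
#' canonicalized by descending mean stimulus-window z of the centroid.
#'
#' @param scores unit x component matrix (rownames = unit ids).
#' @param K number of clusters.
#' @param n_restarts number of random initializations, default 10000
#'   (validation suites typically use 100).
#' @param psth_matrix optional time x unit matrix used to compute centroid
#'   response shapes and the canonical ordering; when omitted, clusters are
#'   ordered by first-score mean.
#' @param stim_window stimulus window in seconds for centroid ordering,
#'   default \code{c(0, 5)}.
#' @param seed RNG seed.
#' @return list of class \code{cluster_model}: \code{assignments} (named
#'   integer vector), \code{co_assignment} (unit x unit), \code{centroids}
#'   (cluster x time, when \code{psth_matrix} given), \code{K},
#'   \code{withinss}, \code{time_s}.
#' @export
kmeans_consensus <- function(scores, K, n_restarts = 10000,
                             psth_matrix = NULL, stim_window = c(0, 5),
                             seed = 1L) {
  n <- nrow(scores)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of units")
  set.seed(seed)
  best <- NULL; best_ss <- Inf
  co <- matrix(0, n, n)
  for (r in seq_len(n_restarts)) {
    km <- suppressWarnings(stats::kmeans(scores, K, nstart = 1, iter.max = 50))
    same <- outer(km$cluster, km$cluster, "==")
    co <- co + same
    if (km$tot.withinss < best_ss) { best_ss <- km$tot.withinss; best <- km }
  }
  co <- co / n_restarts
  assign <- best$cluster
  # canonical order: descending mean stim-window z of the cluster centroid
  if (!is.null(psth_matrix)) {
    tt <- attr(psth_matrix, "time_s")
    cent <- t(sapply(seq_len(K), function(k) {
      rowMeans(psth_matrix[, assign == k, drop = FALSE])
    }))
    sel <- tt >= stim_window[1] & tt < stim_window[2]
    ord <- order(rowMeans(cent[, sel, drop = FALSE]), decreasing = TRUE)
  } else {
    ord <- order(tapply(scores[, 1], assign, mean), decreasing = TRUE)
    cent <- NULL
    tt <- NULL
  }
  relabel <- match(seq_len(K), ord)
  assign <- relabel[assign]
  if (!is.null(cent)) cent <- cent[ord, , drop = FALSE]
  ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  names(assign) <- ids
  dimnames(co) <- list(ids, ids)
  structure(list(assignments = assign, co_assignment = co, centroids = cent,
                 K = as.integer(K), withinss = best_ss, time_s = tt),
            class = "cluster_model")
}

#' Merge clusters into excited / suppressed / weak response classes
#'
#' A cluster is excited when the mean z-score of its centroid over the
#' stimulus window exceeds \code{+theta}, suppressed below \code{-theta},
#' weak otherwise. Units inherit their cluster's class.
#'
#' @param model a \code{\link{kmeans_consensus}} result with centroids.
#' @param stim_window seconds, default \code{c(0, 5)}.
#' @param theta class threshold in z units, default 0.25.
#' @return list: \code{cluster_class} (per cluster) and \code{unit_class}
#'   (named per unit).
#' @export
group_response_classes <- function(model, stim_window = c(0, 5), theta = 0.25) {
  if (is.null(model$centroids)) stop("model lacks centroids")
  sel <- model$time_s >= stim_window[1] & model$time_s < stim_window[2]
  mz <- rowMeans(model$centroids[, sel, drop = FALSE])
  cls <- ifelse(mz > theta, "excited", ifelse(mz < -theta, "suppressed", "weak"))
  unit_cls <- cls[model$assignments]
  names(unit_cls) <- names(model$assignments)
  list(cluster_class = cls, unit_class = unit_cls)
}
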