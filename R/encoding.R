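REGRESSOR_NAMES <- c("context", "running_avoidance", "orbital_area",
                     "whisker_protraction", "whisker_motion", "eye_motion",
                     "pupil_motion", "mouth_motion", "nose_motion",
                     "pupil_size", "running_motion", "saccades", "locomotion")
BINARY_REGRESSORS <- c("running_avoidance", "whisker_protraction", "locomotion")

#' Build the 13-regressor design matrix for the encoding model
#'
#' One column per forced-touch presentation, 13 rows: context (social = 1,
#' object = 0), running avoidance (binary), orbital (eye) area, whisker
#' protraction (binary), mean motion energy of the whisker / eye / pupil /
#' mouth / nose labels, pupil size, running (ball) motion energy, signed
#' saccade count, and locomotion (binary). Every regressor is the mean over
#' the 5 s presentation window of its trial. Continuous regressors are
#' standardized across trials (zero mean, unit variance); binary regressors
#' stay \{0, 1\}. A constant continuous regressor is kept as a zero row and
#' flagged.
#'
#' @param session a \code{touch_session} with behavior traces.
#' @param trials trials to include; default all forced trials of the session.
#' @param window presentation window, default \code{c(0, 5)} s.
#' @return list of class \code{design_matrix}: \code{x} (13 x n_trials),
#'   \code{regressors}, \code{trial_id}, \code{constant_flagged}.
#' @export
build_design_matrix <- function(session, trials = NULL, window = c(0, 5)) {
  if (is.null(session$behavior)) stop("session has no behavior traces")
  if (is.null(trials))
    trials <- session$trials[session$trials$choice == "forced", , drop = FALSE]
  if (!nrow(trials)) stop("no trials to build a design from")
  tr <- session$behavior
  me <- function(labels) {
    m <- sapply(labels, function(l) label_motion_energy(tr, l))
    rowMeans(m, na.rm = TRUE)
  }
  eye_area <- eye_area_trace(tr)
  whisk_prot <- whisker_protraction_trace(tr)
  pupil_x <- rowMeans(sapply(paste0("pupil", 1:4),
                             function(l) label_cols(tr, l)$x))
  pupil_y <- rowMeans(sapply(paste0("pupil", 1:4),
                             function(l) label_cols(tr, l)$y))
  # pupil size: mean distance of pupil labels from their centroid
  pup_d <- rowMeans(sapply(paste0("pupil", 1:4), function(l) {
    p <- label_cols(tr, l)
    sqrt((p$x - pupil_x)^2 + (p$y - pupil_y)^2)
  }))
  series <- list(
    orbital_area = eye_area,
    whisker_motion = me(paste0("whisker", 1:6)),
    eye_motion = me(paste0("eye", 1:6)),
    pupil_motion = me(paste0("pupil", 1:4)),
    mouth_motion = me(paste0("mouth", 1:3)),
    nose_motion = me(paste0("nose", 1:4)),
    pupil_size = pup_d,
    running_motion = tr$ball_motion
  )
  sacc <- detect_saccades(tr)
  prot_thr <- stats::median(whisk_prot, na.rm = TRUE) +
    4 * stats::mad(whisk_prot, na.rm = TRUE)
  n_t <- nrow(trials)
  x <- matrix(NA_real_, length(REGRESSOR_NAMES), n_t,
              dimnames = list(REGRESSOR_NAMES, NULL))
  for (i in seq_len(n_t)) {
    t0 <- trials$t_stop_s[i]
    sel <- tr$time_s >= t0 + window[1] & tr$time_s < t0 + window[2]
    x["context", i] <- as.numeric(trials$context[i] == "social")
    rav <- running_avoidance_fraction(tr, t0 + window)
    x["running_avoidance", i] <- as.numeric(!is.na(rav) && rav > 0.5)
    for (nm in names(series)) x[nm, i] <- mean(series[[nm]][sel], na.rm = TRUE)
    x["whisker_protraction", i] <-
      as.numeric(mean(whisk_prot[sel] > prot_thr, na.rm = TRUE) > 0.1)
    in_win <- sacc$t_on_s >= t0 + window[1] & sacc$t_on_s < t0 + window[2]
    x["saccades", i] <- sum(in_win & sacc$direction == "nasal") -
      sum(in_win & sacc$direction == "temporal")
    x["locomotion", i] <- as.numeric(mean(tr$ball_motion[sel] > 1,
                                          na.rm = TRUE) > 0.5)
  }
  flagged <- character(0)
  cont <- setdiff(REGRESSOR_NAMES, c(BINARY_REGRESSORS, "context"))
  for (nm in cont) {
    s <- stats::sd(x[nm, ])
    if (!is.finite(s) || s == 0) {
      x[nm, ] <- 0
      flagged <- c(flagged, nm)
    } else {
      x[nm, ] <- (x[nm, ] - mean(x[nm, ])) / s
    }
  }
  structure(list(x = x, regressors = REGRESSOR_NAMES,
                 trial_id = trials$trial_id, constant_flagged = flagged),
            class = "design_matrix")
}

# closed-form ridge on centered data; lambda penalizes all predictors,
# intercept unpenalized via centering
ridge_solve <- function(X, y, lambda) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  A <- crossprod(Xc) + diag(lambda, ncol(X))
  beta <- solve(A, crossprod(Xc, y - ym))
  list(beta = drop(beta), intercept = ym - sum(xm * beta))
}

#' Ridge encoding fit with cross-validated penalty
#'
#' Predicts a unit's per-trial mean firing rate from the design matrix by
#' ridge regression. The penalty is chosen from \code{lambda_grid} by k-fold
#' cross-validated squared error; \code{cv_r2 = 1 - SS_cv / SS_tot} may be
#' negative (worse than the mean predictor), which marks the fit for
#' exclusion. At \code{lambda = 0} on a full-rank design the fit equals
#' ordinary least squares.
#'
#' @param design a \code{\link{build_design_matrix}} result (or a plain
#'   regressors x trials matrix).
#' @param rates per-trial response vector (mean rate or z-score per trial).
#' @param lambda_grid penalty grid; default logarithmic over
#'   \code{10^seq(-3, 3)} scaled by \code{mean(diag(X'X))}.
#' @param folds cross-validation folds, default 5.
#' @param seed RNG seed for fold assignment.
#' @return list of class \code{encoding_fit}: \code{beta} (named),
#'   \code{beta_norm}, \code{lambda}, \code{cv_r2}, \code{included},
#'   \code{intercept}.
#' @export
fit_ridge_cv <- function(design, rates, lambda_grid = NULL, folds = 5,
                         seed = 1L) {
  X <- if (inherits(design, "design_matrix")) t(design$x) else t(design)
  n <- nrow(X)
  stopifnot(length(rates) == n)
  if (n <= folds || folds < 2) stop("need n_trials > folds >= 2")
  if (stats::var(rates) == 0) {
    b <- stats::setNames(rep(0, ncol(X)), colnames(X))
    return(structure(list(beta = b, beta_norm = rep(NA_real_, ncol(X)),
                          lambda = NA_real_, cv_r2 = NA_real_,
                          included = FALSE, intercept = mean(rates),
                          degenerate = TRUE),
                     class = "encoding_fit"))
  }
  if (is.null(lambda_grid)) {
    Xc <- sweep(X, 2, colMeans(X))
    scale <- mean(diag(crossprod(Xc)))
    if (scale == 0) scale <- 1
    lambda_grid <- scale * 10^seq(-3, 3, length.out = 13)
  }
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  cv_sse <- sapply(lambda_grid, function(l) {
    sum(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- ridge_solve(X[tr, , drop = FALSE], rates[tr], l)
      pred <- X[!tr, , drop = FALSE] %*% fit$beta + fit$intercept
      sum((rates[!tr] - pred)^2)
    }, numeric(1)))
  })
  l_best <- lambda_grid[which.min(cv_sse)]
  cv_r2 <- 1 - min(cv_sse) / sum((rates - mean(rates))^2)
  fit <- ridge_solve(X, rates, l_best)
  beta <- stats::setNames(fit$beta, colnames(X))
  structure(list(beta = beta, beta_norm = normalize_weights(beta),
                 lambda = l_best, cv_r2 = cv_r2, included = cv_r2 >= 0,
                 intercept = fit$intercept, degenerate = FALSE),
            class = "encoding_fit")
}

#' Sign-preserving normalization of encoding weights
#'
#' Divides each weight by the sum of absolute weights, so the normalized
#' weights keep their signs and satisfy \code{sum(abs(beta_norm)) == 1}.
#' An all-zero weight vector returns NA (flagged degenerate).
#'
#' @param beta numeric weight vector (one entry per regressor).
#' @return normalized weights, or all-NA when beta is all zero.
#' @export
normalize_weights <- function(beta) {
  s <- sum(abs(beta))
  if (s == 0) return(stats::setNames(rep(NA_real_, length(beta)), names(beta)))
  beta / s
}

#' Correlation between two regressors' normalized weights across units
#'
#' @param fits list of \code{encoding_fit} objects (one per unit).
#' @param regressor_a,regressor_b regressor names.
#' @return list: \code{r} (Pearson correlation), \code{slope_sign},
#'   \code{n}; all NA with fewer than 3 usable units.
#' @export
weight_correlation <- function(fits, regressor_a, regressor_b) {
  a <- vapply(fits, function(f) f$beta_norm[[regressor_a]], numeric(1))
  b <- vapply(fits, function(f) f$beta_norm[[regressor_b]], numeric(1))
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) return(list(r = NA_real_, slope_sign = NA_real_, n = sum(ok)))
  r <- stats::cor(a[ok], b[ok])
  list(r = r, slope_sign = sign(r), n = sum(ok))
}

#' Per-group summary of normalized encoding weights
#'
#' Averages normalized weights over units within each animal, then over
#' animals within each group, keeping the 10 reported regressors (binary
#' regressors dropped, except context). Animals whose session-level cvR2 is
#' negative are excluded and listed in the report.
#'
#' @param fits_by_animal named list: animal id -> list of \code{encoding_fit}.
#' @param groups named character vector animal id -> group (e.g. genotype);
#'   default one group, "all".
#' @return list: \code{summary} (data.frame group x regressor means),
#'   \code{excluded_animals}, \code{session_cv_r2} (per animal).
#' @export
model_qc_and_summary <- function(fits_by_animal, groups = NULL) {
  animals <- names(fits_by_animal)
  if (is.null(groups)) groups <- stats::setNames(rep("all", length(animals)),
                                                 animals)
  keep_reg <- setdiff(REGRESSOR_NAMES, BINARY_REGRESSORS)
  cv <- vapply(fits_by_animal, function(fl) {
    mean(vapply(fl, function(f) f$cv_r2, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  excluded <- animals[!is.na(cv) & cv < 0]
  kept <- setdiff(animals, excluded)
  if (!length(kept))
    return(list(summary = data.frame(), excluded_animals = excluded,
                session_cv_r2 = cv))
  per_animal <- t(vapply(kept, function(a) {
    m <- t(vapply(fits_by_animal[[a]], function(f) f$beta_norm[keep_reg],
                  numeric(length(keep_reg))))
    colMeans(m, na.rm = TRUE)
  }, numeric(length(keep_reg))))
  rows <- lapply(unique(groups[kept]), function(g) {
    sel <- kept[groups[kept] == g]
    data.frame(group = g, regressor = keep_reg,
               mean_beta_norm = colMeans(per_animal[sel, , drop = FALSE],
                                         na.rm = TRUE),
               n_animals = length(sel), stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows), excluded_animals = excluded,
       session_cv_r2 = cv)
}
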