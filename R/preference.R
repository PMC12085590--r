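#' Leave-one-out decision variables for context preference
#'
#' Each trial i receives a scalar decision variable built from its
#' presentation-period firing rate t_i and the leave-one-out context means:
#' for a social trial, \code{DV = t_i * (mean(other social trials) -
#' mean(object trials))}; for an object trial, \code{DV = t_i * (mean(social
#' trials) - mean(other object trials))}. The multiplicative form is applied
#' literally, including its sign behavior when the mean difference is
#' negative.
#'
#' @param rates_social,rates_object per-trial mean firing rates (Hz) over the
#'   presentation window [0, 5] s; at least 2 trials per context.
#' @return list with \code{dv_social} and \code{dv_object}.
#' @export
decision_variables <- function(rates_social, rates_object) {
  ns <- length(rates_social); no <- length(rates_object)
  if (ns < 2 || no < 2)
    stop("leave-one-out decision variables need >= 2 trials per context")
  sum_s <- sum(rates_social); sum_o <- sum(rates_object)
  mean_o <- sum_o / no; mean_s <- sum_s / ns
  dv_s <- rates_social * ((sum_s - rates_social) / (ns - 1) - mean_o)
  dv_o <- rates_object * (mean_s - (sum_o - rates_object) / (no - 1))
  list(dv_social = dv_s, dv_object = dv_o)
}

#' Area under the ROC curve for decision variables
#'
#' Sweeps the criterion over all observed DV values and integrates the
#' (false-positive rate, true-positive rate) curve with the trapezoidal rule.
#' Ties are handled so that the area equals
#' \code{P(DV_social > DV_object) + 0.5 * P(DV_social = DV_object)}:
#' identical distributions give exactly 0.5, perfect separation gives 1.
#'
#' @param dv_social,dv_object decision-variable vectors (social = positive
#'   class).
#' @return auROC in [0, 1].
#' @export
roc_auc <- function(dv_social, dv_object) {
  if (!length(dv_social) || !length(dv_object))
    stop("both DV vectors must be non-empty")
  thr <- sort(unique(c(dv_social, dv_object, Inf)), decreasing = TRUE)
  ns <- length(dv_social); no <- length(dv_object)
  # classify "social" when DV >= criterion; sweep criterion high -> low
  tpr <- c(0, vapply(thr, function(c) sum(dv_social >= c) / ns, numeric(1)))
  fpr <- c(0, vapply(thr, function(c) sum(dv_object >= c) / no, numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Permutation test for the preference auROC
#'
#' Builds the null distribution by permuting context labels across trials
#' (resampling without replacement by default; set \code{replace = TRUE} for
#' a with-replacement variant), recomputing the leave-one-out decision
#' variables and auROC for each draw. The p-value is the two-sided tail
#' fraction with add-one correction: \code{(r + 1) / (n_boot + 1)} where r
#' counts null draws at least as far from 0.5 as the observed auROC.
#'
#' @param rates_social,rates_object per-trial presentation-window rates (Hz).
#' @param n_boot resampling draws, default 1000.
#' @param seed RNG seed.
#' @param replace resample labels with replacement, default FALSE.
#' @return list: \code{auroc}, \code{p_boot}, \code{null_auroc}.
#' @export
bootstrap_preference_test <- function(rates_social, rates_object,
                                      n_boot = 1000, seed = 1L,
                                      replace = FALSE) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  dv <- decision_variables(rates_social, rates_object)
  obs <- roc_auc(dv$dv_social, dv$dv_object)
  ns <- length(rates_social)
  pooled <- c(rates_social, rates_object)
  n <- length(pooled)
  set.seed(seed)
  null_auroc <- vapply(seq_len(n_boot), function(b) {
    idx <- if (replace) sample.int(n, n, replace = TRUE) else sample.int(n)
    perm <- pooled[idx]
    dvb <- decision_variables(perm[seq_len(ns)], perm[(ns + 1):n])
    roc_auc(dvb$dv_social, dvb$dv_object)
  }, numeric(1))
  r <- sum(abs(null_auroc - 0.5) >= abs(obs - 0.5))
  list(auroc = obs, p_boot = (r + 1) / (n_boot + 1), null_auroc = null_auroc)
}

#' Preference label from auROC, significance and response class
#'
#' Excited units: significant auROC above 0.5 is social-preferring, below 0.5
#' object-preferring. Suppressed units: the mapping reverses (a significant
#' auROC below 0.5 marks a social cell). Non-significant units are
#' \code{"none"}; a significant auROC of exactly 0.5 (excluded by the tie
#' rule, guarded anyway) is also \code{"none"}.
#'
#' @param auroc auROC in [0, 1].
#' @param p_boot permutation p-value.
#' @param response_class \code{"excited"} or \code{"suppressed"}.
#' @param alpha significance level, default 0.05.
#' @return \code{"social"}, \code{"object"}, or \code{"none"}.
#' @export
classify_preference <- function(auroc, p_boot, response_class, alpha = 0.05) {
  response_class <- match.arg(response_class, c("excited", "suppressed"))
  if (p_boot >= alpha || auroc == 0.5) return("none")
  above <- auroc > 0.5
  if (response_class == "suppressed") above <- !above
  if (above) "social" else "object"
}
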