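forced_session <- function(seed = 31, n_bouts = 20) {
  cfg <- synthetic_config(n_units = c(vS1 = 4), n_bouts = n_bouts,
                          choices = "forced", frame_rate = 60,
                          afe_prob = c(social = 0.15, object = 0.7),
                          seed = seed)
  generate_session(cfg)
}

test_that("the design matrix is 13 regressors by forced trials", {
  sess <- forced_session()
  d <- build_design_matrix(sess)
  expect_equal(dim(d$x), c(13, 40))
  expect_equal(d$regressors[1], "context")
  expect_setequal(unique(d$x["context", ]), c(0, 1))
  expect_true(all(d$x["running_avoidance", ] %in% c(0, 1)))
  expect_true(all(d$x["locomotion", ] %in% c(0, 1)))
  # continuous regressors are standardized
  for (nm in c("orbital_area", "running_motion", "whisker_motion")) {
    expect_equal(mean(d$x[nm, ]), 0, tolerance = 1e-12)
    expect_equal(sd(d$x[nm, ]), 1, tolerance = 1e-12)
  }
  # object touch is the aversive context: more avoidance on object trials
  obj <- d$x["context", ] == 0
  expect_gt(mean(d$x["running_avoidance", obj]),
            mean(d$x["running_avoidance", !obj]))
})

test_that("ridge at lambda -> 0 reproduces least squares on noiseless data", {
  set.seed(3)
  X <- matrix(rnorm(13 * 80), 13, 80, dimnames = list(paste0("r", 1:13), NULL))
  w <- rnorm(13)
  y <- drop(t(X) %*% w) + 2
  f <- fit_ridge_cv(X, y, lambda_grid = c(1e-10, 1, 100), seed = 1)
  expect_lt(max(abs(f$beta - w)), 1e-6)
  expect_gt(f$cv_r2, 0.999)
  expect_true(f$included)
})

test_that("planted dominant couplings surface as the top normalized weights", {
  sess <- forced_session(seed = 33)
  d <- build_design_matrix(sess)
  set.seed(9)
  w <- stats::setNames(rep(0, 13), d$regressors)
  w["context"] <- 3; w["orbital_area"] <- -2.5
  w[setdiff(names(w), c("context", "orbital_area"))] <- rnorm(11, 0, 0.2)
  fits <- lapply(1:12, function(i) {
    y <- drop(t(d$x) %*% w) + rnorm(ncol(d$x), 0, 1)
    fit_ridge_cv(d, y, seed = i)
  })
  mean_abs <- colMeans(do.call(rbind, lapply(fits, function(f) abs(f$beta_norm))))
  top2 <- names(sort(mean_abs, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("context", "orbital_area"))
  # sign agreement of the dominant weights
  signs <- sapply(fits, function(f) sign(f$beta_norm[c("context", "orbital_area")]))
  expect_gte(mean(signs["context", ] == 1), 0.9)
  expect_gte(mean(signs["orbital_area", ] == -1), 0.9)
})

test_that("pure-noise responses produce non-positive cvR2 and exclusion", {
  set.seed(10)
  X <- matrix(rnorm(13 * 80), 13, 80, dimnames = list(paste0("r", 1:13), NULL))
  f <- fit_ridge_cv(X, rnorm(80), seed = 1)
  expect_lte(f$cv_r2, 0)
  expect_false(f$included)
  # degenerate constant response is flagged, not fit
  fd <- fit_ridge_cv(X, rep(2, 80), seed = 1)
  expect_true(fd$degenerate)
  expect_true(is.na(fd$cv_r2))
})

test_that("weight normalization is sign-preserving with unit L1 norm", {
  b <- c(2, -1, 1, rep(0, 10))
  bn <- normalize_weights(b)
  expect_equal(bn[1:3], c(0.5, -0.25, 0.25))
  expect_equal(sum(abs(bn)), 1)
  # invariant to uniform positive rescaling
  expect_equal(normalize_weights(7 * b), bn)
  expect_true(all(is.na(normalize_weights(rep(0, 13)))))
  set.seed(11)
  for (i in 1:5) {
    v <- rnorm(13)
    expect_equal(sum(abs(normalize_weights(v))), 1)
  }
})

test_that("weight correlations recover planted couplings across units", {
  set.seed(12)
  mk_fit <- function(ctx, orb) {
    beta <- stats::setNames(rnorm(13, 0, 0.1), socialtouch:::REGRESSOR_NAMES)
    beta["context"] <- ctx; beta["orbital_area"] <- orb
    list(beta = beta, beta_norm = normalize_weights(beta))
  }
  ctx <- rnorm(30)
  coupled <- lapply(seq_along(ctx), function(i)
    mk_fit(ctx[i], 0.8 * ctx[i] + rnorm(1, 0, 0.2)))
  wc <- weight_correlation(coupled, "context", "orbital_area")
  expect_gt(wc$r, 0.5)
  expect_equal(wc$slope_sign, 1)
  indep <- lapply(1:30, function(i) mk_fit(rnorm(1), rnorm(1)))
  wi <- weight_correlation(indep, "context", "orbital_area")
  expect_lt(abs(wi$r), 0.5)
  self <- weight_correlation(coupled, "context", "context")
  expect_equal(self$r, 1)
  expect_true(is.na(weight_correlation(coupled[1:2], "context",
                                       "orbital_area")$r))
})

test_that("the group summary keeps 10 regressors and excludes negative-cvR2 animals", {
  mk <- function(cv) {
    b <- stats::setNames(rnorm(13), socialtouch:::REGRESSOR_NAMES)
    list(beta = b, beta_norm = normalize_weights(b), cv_r2 = cv)
  }
  fits <- list(m1 = lapply(1:5, function(i) mk(0.3)),
               m2 = lapply(1:5, function(i) mk(-0.2)),
               m3 = lapply(1:5, function(i) mk(0.1)))
  out <- model_qc_and_summary(fits, groups = c(m1 = "WT", m2 = "WT", m3 = "KO"))
  expect_equal(out$excluded_animals, "m2")
  expect_equal(length(unique(out$summary$regressor)), 10)
  expect_true("context" %in% out$summary$regressor)
  expect_false(any(c("running_avoidance", "locomotion",
                     "whisker_protraction") %in% out$summary$regressor))
  all_neg <- model_qc_and_summary(list(m1 = lapply(1:3, function(i) mk(-1))))
  expect_equal(nrow(all_neg$summary), 0)
  expect_equal(all_neg$excluded_animals, "m1")
})
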