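fake_psths <- function(zs) {
  tm <- seq(-2, 6.95, 0.05)
  out <- lapply(seq_len(nrow(zs)), function(i) list(time_s = tm, z = zs[i, ]))
  names(out) <- seq_len(nrow(zs))
  out
}

test_that("the PSTH matrix pools units column-wise on a shared time base", {
  z <- matrix(rnorm(3 * 180), 3, 180)
  m <- build_psth_matrix(fake_psths(z))
  expect_equal(dim(m), c(180, 3))
  expect_equal(m[, 2], z[2, ])
  one <- build_psth_matrix(fake_psths(z[1, , drop = FALSE]))
  expect_equal(ncol(one), 1)
  # pooling two sets is just more columns
  both <- build_psth_matrix(c(fake_psths(z), stats::setNames(fake_psths(z), 4:6)))
  expect_equal(ncol(both), 6)
  bad <- fake_psths(z)
  bad[[2]]$time_s <- bad[[2]]$time_s + 1
  expect_error(build_psth_matrix(bad), "window")
})

test_that("PCA keeps the smallest component count above the variance target", {
  tm <- 180
  base <- sin(seq(0, 4 * pi, length.out = tm))
  z <- t(sapply(seq(0.5, 5, length.out = 12), function(a) a * base))
  m <- build_psth_matrix(fake_psths(z))
  red <- pca_reduce(m)
  expect_equal(red$n_components, 1)
  expect_equal(pca_reduce(m, variance_target = 0)$n_components, 1)
  set.seed(1)
  iso <- matrix(rnorm(30 * 10), 30, 10)  # isotropic: needs nearly all dims
  rownames(iso) <- 1:30
  pc_iso <- stats::prcomp(iso)
  ev <- pc_iso$sdev^2 / sum(pc_iso$sdev^2)
  expect_gte(which(cumsum(ev) > 0.95)[1], 8)
  expect_error(pca_reduce(m[, 1, drop = FALSE]), "2 units")
})

test_that("gap statistic finds K=1 on one blob and K=3 on three blobs", {
  set.seed(9)
  blob <- matrix(rnorm(60 * 2), 60, 2)
  expect_equal(select_k_gap(blob, 1:5, seed = 2), 1L)
  three <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
                 matrix(rnorm(40, 8, 0.3), 20, 2),
                 cbind(rnorm(20, 0, 0.3), rnorm(20, 8, 0.3)))
  expect_equal(select_k_gap(three, 1:6, seed = 2), 3L)
  k <- select_k_gap(three, 2:4, seed = 2)
  expect_true(k %in% 2:4)
  expect_error(select_k_gap(blob, integer(0)), "empty")
})

test_that("consensus k-means is stable on separated blobs and canonicalizes labels", {
  set.seed(4)
  scores <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2),
                  matrix(rnorm(30, 6, 0.2), 15, 2))
  rownames(scores) <- 1:30
  cm <- kmeans_consensus(scores, 2, n_restarts = 100, seed = 3)
  expect_equal(length(unique(cm$assignments[1:15])), 1)
  expect_equal(length(unique(cm$assignments[16:30])), 1)
  within <- c(cm$co_assignment[1:15, 1:15], cm$co_assignment[16:30, 16:30])
  expect_true(all(within > 0.99))
  # duplicate columns are always co-assigned
  dup <- rbind(scores, scores[1, , drop = FALSE])
  rownames(dup) <- 1:31
  cmd <- kmeans_consensus(dup, 2, n_restarts = 50, seed = 3)
  expect_equal(cmd$co_assignment["1", "31"], 1)
  # K = 1: everything together
  cm1 <- kmeans_consensus(scores, 1, n_restarts = 5, seed = 1)
  expect_true(all(cm1$co_assignment == 1))
  expect_error(kmeans_consensus(scores, 31), "exceeds")
})

test_that("clustering is invariant to unit column order", {
  s <- archetype_session(n_units = 24, n_bouts = 12, seed = 31)
  p <- session_psths(s)
  m <- build_psth_matrix(p)
  red <- pca_reduce(m)
  cm <- kmeans_consensus(red$scores, 4, n_restarts = 60, psth_matrix = m,
                         seed = 5)
  perm <- sample(ncol(m))
  m2 <- m[, perm, drop = FALSE]
  attr(m2, "time_s") <- attr(m, "time_s")
  red2 <- pca_reduce(m2)
  cm2 <- kmeans_consensus(red2$scores, 4, n_restarts = 60, psth_matrix = m2,
                          seed = 5)
  ids <- names(cm$assignments)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(cm$assignments[ids],
                                       cm2$assignments[ids]), 0.999)
})

test_that("planted archetypes are recovered and classed correctly", {
  skip_if_not_installed("mclust")
  s <- archetype_session(n_units = 40, n_bouts = 20, seed = 42)
  p <- session_psths(s)
  m <- build_psth_matrix(p)
  red <- pca_reduce(m)
  cm <- kmeans_consensus(red$scores, 4, n_restarts = 100, psth_matrix = m,
                         seed = 1)
  gt <- s$ground_truth$units$archetype[
    match(as.integer(names(cm$assignments)), s$ground_truth$units$unit_id)]
  expect_gte(mclust::adjustedRandIndex(cm$assignments, gt), 0.9)
  cls <- group_response_classes(cm)
  expect_true(all(cls$unit_class[gt == "suppressed"] == "suppressed"))
  expect_true(all(cls$unit_class[gt == "sustained_excited"] == "excited"))
})

test_that("response-class grouping thresholds behave at the limits", {
  tm <- seq(-2, 6.95, 0.05)
  cent <- rbind(rep(0, 180),
                ifelse(tm >= 0 & tm < 5, 2, 0),
                ifelse(tm >= 0 & tm < 5, -2, 0))
  model <- list(centroids = cent, time_s = tm,
                assignments = stats::setNames(c(1, 2, 3), 1:3))
  cls <- group_response_classes(model)
  expect_equal(unname(cls$cluster_class), c("weak", "excited", "suppressed"))
  all_weak <- group_response_classes(model, theta = Inf)
  expect_true(all(all_weak$cluster_class == "weak"))
})
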