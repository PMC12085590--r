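units_fixture <- function() {
  data.frame(unit_id = 1:4,
             depth_um = c(500, 1500, 3500, 4500),
             peak_to_trough_us = c(450, 300, 400, 500),
             isi_violation = c(0.12, 0.05, 0.05, NA),
             amplitude_cutoff = c(0.05, 0.05, 0.2, 0.05),
             median_amplitude_uv = c(80, 60, 60, 70))
}

test_that("QC filter applies strict thresholds with per-unit reasons", {
  u <- units_fixture()
  out <- qc_filter_units(u)
  expect_equal(out$kept$unit_id, 2L)
  expect_equal(out$rejected$reasons[out$rejected$unit_id == 1], "isi_violation")
  expect_equal(out$rejected$reasons[out$rejected$unit_id == 3], "amplitude_cutoff")
  expect_equal(out$rejected$reasons[out$rejected$unit_id == 4], "missing")

  # boundary values fail the strict comparisons
  b <- data.frame(unit_id = 1, isi_violation = 0.10, amplitude_cutoff = 0.05,
                  median_amplitude_uv = 50)
  r <- qc_filter_units(b)
  expect_equal(nrow(r$kept), 0)
  expect_equal(r$rejected$reasons, "isi_violation,median_amplitude")

  empty <- qc_filter_units(u[0, ])
  expect_equal(nrow(empty$kept), 0)
})

test_that("QC filter is monotone in its thresholds", {
  set.seed(1)
  u <- data.frame(unit_id = 1:50, isi_violation = runif(50, 0, 0.2),
                  amplitude_cutoff = runif(50, 0, 0.2),
                  median_amplitude_uv = runif(50, 30, 90))
  tight <- qc_filter_units(u)$kept$unit_id
  loose <- qc_filter_units(u, 0.15, 0.15, 40)$kept$unit_id
  expect_true(all(tight %in% loose))
})

test_that("RS classification is inclusive at 400 us", {
  u <- units_fixture()
  cls <- classify_unit_types(u)
  expect_equal(unname(cls), c("RS", "other", "RS", "RS"))
})

test_that("region assignment uses half-open depth intervals", {
  u <- units_fixture()
  b <- list(vS1 = c(0, 1200), tSTR = c(1200, 2600), BLA = c(3000, 4200))
  r <- assign_regions_by_depth(u, b)
  expect_equal(unname(r), c("vS1", "tSTR", "BLA", "unassigned"))
  # boundary depth belongs to the deeper region
  r2 <- assign_regions_by_depth(data.frame(unit_id = 1, depth_um = 1200), b)
  expect_equal(unname(r2), "tSTR")
  expect_error(assign_regions_by_depth(u, list(a = c(0, 100), b = c(50, 200))),
               "overlap")
})

test_that("rate binning conserves spike count with half-open bins", {
  set.seed(2)
  st <- sort(runif(100, 0, 10))
  r <- bin_firing_rates(st, 0.05, 0, 10)
  expect_equal(sum(r$rate_hz) * 0.05, 100)
  # a spike exactly on an edge lands in the later bin
  r2 <- bin_firing_rates(c(0.05), 0.05, 0, 0.2)
  expect_equal(r2$rate_hz, c(0, 20, 0, 0))
  expect_equal(bin_firing_rates(numeric(0), 0.05, 0, 1)$rate_hz, rep(0, 20))
})

test_that("moving-average smoothing preserves constants and spreads impulses", {
  const <- data.frame(time_s = seq(0, 1, 0.05)[1:20], rate_hz = rep(4, 20))
  expect_equal(smooth_rates(const, 0.25)$rate_hz, rep(4, 20))
  imp <- data.frame(time_s = seq(0, 1, 0.05)[1:20],
                    rate_hz = c(rep(0, 10), 20, rep(0, 9)))
  sm <- smooth_rates(imp, 0.25)
  expect_equal(sum(sm$rate_hz > 0), 5)
  expect_equal(max(sm$rate_hz), 4)
  expect_equal(smooth_rates(imp, 0.05)$rate_hz, imp$rate_hz)
  expect_error(smooth_rates(imp, 0.01), "window")
})

test_that("trial alignment averages trials and drops out-of-range ones", {
  r <- bin_firing_rates(c(2.11, 2.22, 12.11, 12.22), 0.05, 0, 16)
  trials <- data.frame(trial_id = 1:3, t_stop_s = c(2, 12, 100))
  al <- trial_align_psth(r, trials, c(-2, 4))
  expect_equal(al$dropped, 3)
  expect_equal(nrow(al$trial_mat), 2)
  # identical spike patterns relative to the stop: average equals either trial
  expect_equal(al$average, unname(al$trial_mat[1, ]))
})

test_that("bin->smooth->align is linear in the spike train", {
  set.seed(3)
  a <- sort(runif(200, 0, 20)); b <- sort(runif(150, 0, 20))
  trials <- data.frame(trial_id = 1, t_stop_s = 10)
  f <- function(st) {
    r <- smooth_rates(bin_firing_rates(st, 0.05, 0, 20), 0.25)
    trial_align_psth(r, trials, c(-2, 7))$average
  }
  expect_equal(f(c(a, b)), f(a) + f(b))
})

test_that("ISI z-scoring centers the baseline and guards zero SD", {
  tm <- seq(-2, 6.95, 0.05)
  mat <- rbind(rep(c(2, 5), c(40, 140)), rep(c(2, 5), c(40, 140)))
  mat[1, 1:40] <- 1; mat[2, 1:40] <- 3  # baseline mean 2, sd 1 pooled
  rownames(mat) <- 1:2
  al <- list(time_s = tm, trial_mat = mat, average = colMeans(mat))
  z <- zscore_to_isi(al, c(-2, 0))
  expect_equal(z$baseline_mean, 2)
  expect_equal(z$baseline_sd, 1, tolerance = 0.01)
  expect_equal(z$z[100], (5 - 2) / z$baseline_sd)

  const <- list(time_s = tm, trial_mat = matrix(2, 2, 180, dimnames =
                  list(1:2, NULL)), average = rep(2, 180))
  zc <- zscore_to_isi(const)
  expect_true(zc$flagged)
  expect_equal(zc$z, rep(0, 180))
  expect_error(zscore_to_isi(al, c(0, 2)), "before")
  expect_error(zscore_to_isi(al, c(-1, -1)), "empty")
})

test_that("planted transient archetype peaks within the first second", {
  s <- archetype_session(n_units = 8, n_bouts = 15, seed = 9)
  tid <- s$ground_truth$units$unit_id[
    s$ground_truth$units$archetype == "transient_excited"][1]
  p <- session_psths(s, unit_ids = tid)
  peak_t <- p[[1]]$time_s[which.max(p[[1]]$z)]
  expect_gte(peak_t, 0)
  expect_lte(peak_t, 1)
})
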