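make_map <- function(per_trial, labels) spatial_activity_map(per_trial, labels)

test_that("spatial maps average per-trial bin activity correctly", {
  s <- make_session(seed = 5)
  det <- detect_arm_entries(s$traj)
  tr <- segment_trials(s$traj, det)
  bins <- bin_trials(tr, s$traj)
  # neuron active only during bin-10 frames
  nf <- length(s$traj$time_s)
  dff <- matrix(0, 2, nf)
  for (k in seq_along(bins))
    dff[1, bins[[k]]$frame[bins[[k]]$bin == 10]] <- 1
  dff[2, ] <- 0.3
  map <- build_spatial_map(trace_set(dff, 30), tr, bins)
  nz <- which(map$mean_map[1, ] > 1e-9)
  expect_equal(nz, 10)
  expect_equal(unname(map$mean_map[2, ]), rep(0.3, 20))
  # two identical trials give identical per-trial slices equal to the mean
  pt <- array(rep(matrix(runif(3 * 20), 3), each = 1), c(1, 3, 20))
  pt2 <- array(c(pt[1, , ], pt[1, , ]), c(2, 3, 20))
  pt2[1, , ] <- pt[1, , ]; pt2[2, , ] <- pt[1, , ]
  m2 <- make_map(pt2, c(TRUE, FALSE))
  expect_equal(m2$per_trial[1, , ], m2$per_trial[2, , ])
  expect_equal(m2$mean_map, m2$per_trial[1, , ])
  expect_error(build_spatial_map(trace_set(dff, 30), tr[0, ], list()), "no trials")
})

test_that("empty bins are interpolated from neighbours and flagged", {
  pt <- array(1, c(2, 1, 20))
  pt[1, 1, ] <- seq(0, 1.9, by = 0.1)
  pt[1, 1, 5] <- NA
  m <- make_map(pt, c(TRUE, FALSE))
  expect_true(m$empty_bins[1, 5])
  expect_false(any(m$empty_bins[2, ]))
  expect_equal(m$per_trial[1, 1, 5], (0.3 + 0.5) / 2)
})

test_that("tuning centres are recovered from simulated populations", {
  cfg <- behavior_sim_config(p_alternate = 0.6, session_duration = 1440, seed = 3)
  traj <- simulate_trajectory(simulate_arm_entries(cfg), cfg)
  # sharply tuned population, interior centres (terminal bins overlap the
  # dwell period and are contaminated by anticipatory transients)
  tc <- trace_sim_config(n_neurons = 100, tuning_center = NULL,
                         tuning_width = 1, peak_rate = 3, baseline_rate = 0.1,
                         noise_sd = 0.05, seed = 8)
  tc$tuning_center <- sample(3:18, 100, replace = TRUE)
  sim <- simulate_trace_set(traj, tc)
  map <- build_spatial_map(sim$traces, sim$trials, sim$bins)
  pd <- peak_position_distribution(map)
  expect_gte(mean(pd$peak_bin == sim$ground_truth$tuning_center), 0.9)
  expect_gte(mean(abs(pd$peak_bin - sim$ground_truth$tuning_center) <= 1), 0.99)
})

test_that("peak-position distributions are proportions with Wilson intervals", {
  pt <- array(0, c(4, 30, 20))
  pt[, , 10] <- 1
  pt <- pt + array(runif(prod(dim(pt)), 0, 1e-3), dim(pt))
  m <- make_map(pt, c(TRUE, TRUE, FALSE, FALSE))
  pd <- peak_position_distribution(m)
  expect_equal(pd$table$proportion[10], 1)
  expect_equal(sum(pd$table$proportion), 1)
  expect_true(all(pd$table$ci_low >= 0 & pd$table$ci_high <= 1))
  # invariant to per-neuron positive rescaling
  pt_scaled <- pt
  for (i in 1:30) pt_scaled[, i, ] <- pt[, i, ] * runif(1, 0.1, 10)
  expect_equal(peak_position_distribution(make_map(pt_scaled, c(TRUE, TRUE, FALSE, FALSE)))$peak_bin,
               pd$peak_bin)
  # constant neurons are excluded and counted
  pt[, 1, ] <- 2
  pd2 <- peak_position_distribution(make_map(pt, c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(pd2$n_excluded, 1)
  expect_equal(pd2$n_neurons, 29)
})

test_that("selectivity flags positions whose difference stands out", {
  # identical alternating and non-alternating maps: nothing selective
  base <- matrix(runif(5 * 20), 5)
  pt <- array(0, c(4, 5, 20))
  for (t in 1:4) pt[t, , ] <- base
  sel0 <- alternation_selectivity(make_map(pt, c(TRUE, TRUE, FALSE, FALSE)))
  expect_false(any(sel0$selective & !sel0$degenerate))
  # a difference spike at bin 9 with tiny jitter elsewhere
  set.seed(9)
  pt2 <- array(rnorm(4 * 1 * 20, 0, 0.01), c(4, 1, 20))
  pt2[1:2, 1, 9] <- pt2[1:2, 1, 9] + 1
  sel <- alternation_selectivity(make_map(pt2, c(TRUE, TRUE, FALSE, FALSE)))
  expect_true(sel$selective[1, 9])
  expect_equal(sum(sel$selective[1, ]), 1)
  expect_error(alternation_selectivity(make_map(pt2, c(TRUE, NA, FALSE, FALSE))),
               "at least 2")
})

test_that("vectorized selectivity equals direct enumeration", {
  set.seed(14)
  sm <- simulate_spatial_map_cohort(10, n_alt = 6, n_nonalt = 6,
                                    frac_selective = 0.3, seed = 15)
  sel <- alternation_selectivity(sm$map)
  expect_equal(sel$selective, oracle_selectivity(sel$difference))
})

test_that("selectivity rule is calibrated on null cohorts and powered on gain-2 cohorts", {
  alpha0 <- selectivity_chance_rate()
  expect_equal(alpha0, 2 * pt(-2, 18))
  n_neur <- 150
  ub <- wilson_ci(alpha0 * n_neur, n_neur, conf.level = 1 - 0.05 / 20)$upper
  clean <- logical(40)
  for (i in seq_along(clean)) {
    sm <- simulate_spatial_map_cohort(n_neur, amp = 0, frac_selective = 0,
                                      seed = 5000 + i)
    sel <- alternation_selectivity(sm$map)
    clean[i] <- all(sel$table$proportion <= ub)
  }
  expect_gte(mean(clean), 0.95)
  # injected selectivity recovered at the neuron level
  sm <- simulate_spatial_map_cohort(200, frac_selective = 0.2, gain = 2, seed = 77)
  sel <- alternation_selectivity(sm$map)
  pred <- which(sel$selective_at_peak)
  truth <- sm$ground_truth$selective_ids
  tp <- length(intersect(pred, truth))
  f1 <- 2 * tp / (length(pred) + length(truth))
  expect_gte(f1, 0.8)
})

test_that("group proportion comparisons reproduce hand-computed chi-squares", {
  mk_pd <- function(center_count, total) {
    counts <- c(rep(0, 9), center_count, rep(0, 9), total - center_count)
    structure(list(table = data.frame(bin = 1:20, count = counts,
                                      proportion = counts / total),
                   n_neurons = total), class = "mf_peak_dist")
  }
  a <- mk_pd(50, 100); b <- mk_pd(10, 100)
  res <- compare_peak_proportions(a, b, center_bins = 8:12)
  expect_equal(res$statistic, 200 * (50 * 90 - 50 * 10)^2 /
                 (100 * 100 * 60 * 140))
  expect_equal(res$df, 1)
  # identical groups: statistic ~ 0, p ~ 1
  same <- compare_peak_proportions(a, a, center_bins = 8:12)
  expect_lt(same$statistic, 1e-9)
  expect_gt(same$p, 0.999)
  # doubling all counts doubles the statistic, proportions unchanged
  a2 <- mk_pd(100, 200); b2 <- mk_pd(20, 200)
  res2 <- compare_peak_proportions(a2, b2, center_bins = 8:12)
  expect_gt(res2$statistic, res$statistic)
  expect_equal(res2$table["A", "center"] / 200, res$table["A", "center"] / 100)
})

test_that("raster normalization sorts neurons by peak and scales rows to 1", {
  sm <- simulate_spatial_map_cohort(25, seed = 31)
  rm_ <- raster_matrix(sm$map)
  expect_equal(dim(rm_), c(25, 20))
  expect_true(all(abs(apply(rm_, 1, max) - 1) < 1e-12))
  expect_true(!is.unsorted(apply(rm_, 1, which.max)))
})
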