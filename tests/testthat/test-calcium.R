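test_that("dF/F0 follows hand-computed values for both baseline modes", {
  expect_equal(compute_dff(matrix(5, 1, 10))$dff, matrix(0, 1, 10))
  raw <- matrix(c(10, 10, 20, 10), 1)
  expect_equal(compute_dff(raw)$dff[1, ], c(-0.2, -0.2, 0.6, -0.2))
  # a frame at twice baseline reads 1
  r2 <- c(rep(100, 450), 200, rep(100, 49))
  d2 <- compute_dff(matrix(r2, 1), f0_mode = "first_15s", frame_rate = 30)
  expect_equal(d2$dff[1, 451], 1)
  expect_equal(mean(d2$dff[1, 1:450]), 0)
  expect_error(compute_dff(matrix(c(0, 0, 0, 1, 2, 3), 2, byrow = TRUE)),
               "trace\\(s\\): 1")
})

test_that("annulus subtraction recovers a soma signal on structured background", {
  h <- 11; w <- 11; nf <- 300
  yy <- matrix(rep(1:h, w), h); xx <- matrix(rep(1:w, each = h), h)
  d <- sqrt((yy - 6)^2 + (xx - 6)^2)
  soma <- d <= 2; ann <- d >= 3 & d <= 5
  # uniform movie -> zero trace; constant offset -> constant trace
  mov <- array(3, c(h, w, nf))
  expect_equal(extract_trace_with_annulus(mov, soma, ann), rep(0, nf))
  mov_c <- mov; mov_c[rep(soma, nf)] <- 3 + 0.7
  expect_equal(extract_trace_with_annulus(mov_c, soma, ann), rep(0.7, nf))
  # flashing cell over shared noisy background drift
  set.seed(4)
  sig <- as.numeric(stats::filter(rbinom(nf, 1, 0.05) * 2, 0.9^(0:30), sides = 1))
  sig[is.na(sig)] <- 0
  drift <- cumsum(rnorm(nf, 0, 0.05))
  mov_n <- array(rnorm(h * w * nf, 0, 0.1), c(h, w, nf)) +
    rep(drift, each = h * w) + 1
  for (f in seq_len(nf)) mov_n[, , f][soma] <- mov_n[, , f][soma] + sig[f]
  rec <- extract_trace_with_annulus(mov_n, soma, ann)
  expect_gt(cor(rec, sig), 0.99)
  expect_error(extract_trace_with_annulus(mov, soma, soma), "overlap")
  expect_error(extract_trace_with_annulus(mov, soma & FALSE, ann), "nonempty")
})

test_that("component selection rejects low skewness and vessel overlap", {
  set.seed(2)
  nf <- 2000
  sym <- rnorm(nf)                                   # skewness ~ 0
  ev <- numeric(nf); ev[sample(nf, 20)] <- 3
  skewed <- as.numeric(stats::filter(ev, 0.93^(0:50), sides = 1))
  skewed[is.na(skewed)] <- 0
  skewed <- skewed + rnorm(nf, 0, 0.05)
  np <- 400
  filt_clear <- runif(np); filt_vessel <- runif(np)
  vessel <- rep(FALSE, np); vessel[1:80] <- TRUE
  # put the brightest 5% of the second filter half inside the vessel mask
  top <- order(filt_vessel, decreasing = TRUE)[1:20]
  vessel[] <- FALSE; vessel[top[1:10]] <- TRUE
  keep <- select_components(rbind(sym, skewed, skewed),
                            rbind(filt_clear, filt_clear, filt_vessel),
                            vessel)
  expect_equal(as.integer(keep), 2L)
  det <- attr(keep, "details")
  expect_lt(det$skewness[1], 1)
  expect_gt(det$skewness[2], 1)
  expect_equal(det$vessel_overlap[3], 0.5)
})

test_that("event detection obeys the rise and peak rules", {
  fs <- 30
  expect_equal(nrow(detect_events(rep(0.2, 600), fs)), 0)
  kern <- mesoframe:::calcium_kernel(0.1, 1, fs)
  set.seed(7)
  noise <- rnorm(900, 0, 0.05)
  tr <- noise
  tr[300:(299 + length(kern))] <- tr[300:(299 + length(kern))] + 0.5 * kern
  st <- baseline_stats(tr, fs)
  ev <- detect_events(tr, fs, st)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$start_frame - 300), 8)
  # magnitude accuracy, assessed where trace noise does not dominate the
  # start/end difference itself
  trq <- rnorm(900, 0, 0.01)
  trq[300:(299 + length(kern))] <- trq[300:(299 + length(kern))] + 0.5 * kern
  evq <- detect_events(trq, fs)
  expect_equal(nrow(evq), 1)
  expect_lt(abs(evq$magnitude - 0.5) / 0.5, 0.1)
  # a 2-SD bump fails the 3-SD peak rule
  tr2 <- noise
  tr2[300:(299 + length(kern))] <- tr2[300:(299 + length(kern))] + 2 * st$sd_baseline * kern
  expect_equal(nrow(detect_events(tr2, fs, st)), 0)
  # detection is invariant to adding a constant
  ev_shift <- detect_events(tr + 5, fs)
  expect_equal(ev_shift$start_frame, ev$start_frame)
  expect_equal(ev_shift$magnitude, ev$magnitude)
  expect_error(detect_events(tr, fs, deriv_window = 0.01), "2 frames")
})

test_that("streaming detector matches the exhaustive crossing-pair oracle", {
  fs <- 30
  kern <- mesoframe:::calcium_kernel(0.1, 1, fs)
  set.seed(11)
  for (rep in 1:50) {
    tr <- rnorm(200, 0, 0.05)
    n_ev <- sample(0:2, 1)
    for (f in sample(20:140, n_ev)) {
      idx <- f:min(200, f + length(kern) - 1)
      tr[idx] <- tr[idx] + runif(1, 0.3, 0.7) * kern[seq_along(idx)]
    }
    got <- detect_events(tr, fs)
    want <- oracle_detect_events(tr, fs)
    expect_equal(got$start_frame, want$start_frame)
    expect_equal(got$end_frame, want$end_frame)
  }
})

test_that("event detector is accurate on a large simulated population", {
  s <- make_session(seed = 21)
  tc <- trace_sim_config(n_neurons = 60, noise_sd = 0.05, event_amplitude = 0.5,
                         peak_rate = 0.3, baseline_rate = 0.05, seed = 22)
  sim <- simulate_trace_set(s$traj, tc)
  tp <- fp <- fn <- 0
  for (i in seq_len(60)) {
    ev <- detect_events(sim$traces$dff[i, ], 30)
    truth <- merge_truth(sim$ground_truth$events[[i]]$frame)
    m <- match_events(ev$start_frame, truth)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  expect_gt(tp / (tp + fn), 0.95)
  expect_gt(tp / (tp + fp), 0.95)
})

test_that("activity summaries behave under scaling and rebaselining", {
  expect_equal(activity_sd(rep(2, 100)), 0)
  sq <- rep(c(-1, 1), 500)
  expect_equal(activity_sd(sq), sd(sq))
  expect_lt(abs(activity_sd(sq) - 1), 0.01)
  x <- rnorm(200)
  expect_equal(activity_sd(3 * x), 3 * activity_sd(x))
  expect_equal(activity_change(1, 1), 0)
  expect_equal(activity_change(1, 1.5), 0.5)
  expect_equal(activity_change(2, 1), -0.5)
  expect_error(activity_change(0, 1), "sd1")
  # pure gain on raw fluorescence leaves dF/F (and its SD) unchanged
  raw <- 100 + 20 * abs(sin(seq_len(600) / 20)) + rnorm(600, 0, 1)
  sd1 <- activity_sd(compute_dff(raw)$dff[1, ])
  sd2 <- activity_sd(compute_dff(raw * 7)$dff[1, ])
  expect_equal(sd1, sd2)
})

test_that("stimulation time courses are baseline-referenced with onset at 20 s", {
  expect_equal(stim_onset_frame(20, 0.351) - 1L, round(20 / 0.351))
  expect_equal(stim_onset_frame(20, 0.351) - 1L, 57)
  flat <- simulate_stim_response(n_pulses = 0, amplitude = 0.5)
  tc0 <- stim_timecourse(flat$raw)
  expect_equal(max(abs(tc0$mean_dff)), 0)
  resp <- simulate_stim_response(n_pulses = 10, amplitude = 0.5)
  tc <- stim_timecourse(resp$raw)
  expect_equal(length(tc$mean_dff), 115)
  expect_equal(mean(tc$mean_dff[seq_len(resp$onset_frame - 1)]), 0)
  expect_equal(max(tc$mean_dff), 0.5)
  expect_equal(which.max(tc$mean_dff), resp$onset_frame)
  # amplitude scales monotonically with pulse count
  peaks <- vapply(c(1, 5, 10), function(np)
    max(stim_timecourse(simulate_stim_response(np, 0.5)$raw)$mean_dff), numeric(1))
  expect_true(all(diff(peaks) > 0))
  # two identical animals -> SEM identically zero
  two <- rbind(resp$raw, resp$raw)
  expect_equal(stim_timecourse(two)$sem_dff, rep(0, 115))
  expect_error(stim_timecourse(resp$raw[1:30]), "baseline|onset")
})
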