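test_that("alternation scoring matches hand-enumerated triplets", {
  expect_equal(score_alternation(strsplit("ABCABC", "")[[1]])$percent, 100)
  expect_equal(score_alternation(c("A", "B", "A", "B"))$percent, 0)
  # ABCB: ABC alternates, BCB does not
  expect_equal(score_alternation(c("A", "B", "C", "B"))$percent, 50)
  s <- score_alternation(c("A", "B"))
  expect_true(s$insufficient)
  expect_true(is.na(s$percent))
  expect_equal(s$n_entries, 2)
  expect_error(score_alternation(c("A", "A", "B")), "repeat")
})

test_that("alternation score is invariant to relabelling arms", {
  e <- simulate_arm_entries(behavior_sim_config(p_alternate = 0.6, seed = 12),
                            n_entries = 200)
  relabel <- c(A = "B", B = "C", C = "A")
  expect_equal(score_alternation(unname(relabel[e$arms]))$percent,
               score_alternation(e$arms)$percent)
})

test_that("a uniform-random agent scores at the 50% chance level", {
  e <- simulate_arm_entries(behavior_sim_config(p_alternate = 0.5, seed = 301),
                            n_entries = 10000)
  expect_lt(abs(score_alternation(e)$percent - 50), 1.5)  # 3 binomial SEs
})

test_that("entry detection requires penetration past the entry fraction", {
  g <- maze_geometry()
  # animal leaves A, pokes 5% into B, retreats, then enters C fully
  path_r <- c(seq(45, 5, by = -2), seq(5, 45 * 0.05, by = -1),
              seq(45 * 0.05, 5, by = 1), seq(5, 45, by = 2))
  arms <- rep(c(1, 2, 2, 3), c(21, 3, 3, 21))
  th <- c(90, 210, 330)[arms] * pi / 180
  traj <- trajectory(seq_along(path_r) / 30, path_r * cos(th), path_r * sin(th), g)
  det <- detect_arm_entries(traj, entry_fraction = 0.2)
  expect_equal(det$arm, c("A", "C"))
  expect_error(detect_arm_entries(traj, entry_fraction = 1.2), "entry_fraction")
})

test_that("a trajectory confined to the centre yields no entries", {
  g <- maze_geometry()
  traj <- trajectory(seq_len(50) / 30, runif(50, -2, 2), runif(50, -2, 2), g)
  expect_equal(nrow(detect_arm_entries(traj)), 0)
})

test_that("trial segmentation labels alternation by the triplet rule", {
  s <- make_session(seed = 5)
  det <- detect_arm_entries(s$traj)
  tr <- segment_trials(s$traj, det)
  expect_equal(nrow(tr), nrow(det) - 1)
  expect_true(is.na(tr$is_alternation[1]))
  # label k (trial k: entry k -> k+1) is the ground-truth flag of entry k+1
  expect_equal(tr$is_alternation[-1],
               s$entries$is_alternation[3:length(s$entries$arms)])
  expect_true(all(tr$end_s > tr$start_s))
  expect_true(all(tr$start_frame[-1] >= tr$end_frame[-nrow(tr)]))
  expect_equal(attr(tr, "n_aborted"), 0)
  # origin/destination follow the entry sequence
  expect_equal(tr$origin, s$entries$arms[-length(s$entries$arms)])
  expect_equal(tr$destination, s$entries$arms[-1])
})

test_that("position binning maps the travel path onto 1..20", {
  s <- make_session(seed = 5)
  det <- detect_arm_entries(s$traj)
  tr <- segment_trials(s$traj, det)
  bins <- bin_trials(tr, s$traj)
  allb <- unlist(lapply(bins, `[[`, "bin"))
  expect_true(all(allb >= 1 & allb <= 20))
  # every trial frame gets exactly one bin
  expect_equal(vapply(bins, nrow, integer(1)),
               tr$end_frame - tr$start_frame + 1L)
  # by the half-open convention a frame at the centre falls in bin 11
  g <- s$traj$geometry
  onetrial <- data.frame(origin = "A", destination = "B",
                         start_frame = 1L, end_frame = 3L)
  tt <- trajectory(1:3 / 30,
                   c(g$unit_x[1] * 45, 0, g$unit_x[2] * 45),
                   c(g$unit_y[1] * 45, 0, g$unit_y[2] * 45), g)
  expect_equal(bin_position(onetrial, tt), c(1L, 11L, 20L))
  # uniform-speed traversal spreads frames evenly across bins
  nfr <- 200
  u <- seq(0, 1, length.out = nfr)
  xs <- ifelse(u < 0.5, (1 - 2 * u), 0) * 45 * g$unit_x[1] +
        ifelse(u < 0.5, 0, (2 * u - 1)) * 45 * g$unit_x[2]
  ys <- ifelse(u < 0.5, (1 - 2 * u), 0) * 45 * g$unit_y[1] +
        ifelse(u < 0.5, 0, (2 * u - 1)) * 45 * g$unit_y[2]
  tu <- trajectory(seq_len(nfr) / 30, xs, ys, g)
  bu <- bin_position(data.frame(origin = "A", destination = "B",
                                start_frame = 1L, end_frame = nfr), tu)
  expect_lte(diff(range(table(bu))), 1)
  expect_error(bin_position(data.frame(origin = "A", destination = "B",
                                       start_frame = 5L, end_frame = 5L), tu),
               "zero-length")
})
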