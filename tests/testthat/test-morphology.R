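test_that("image simulator records ground truth exactly as drawn", {
  # blank plus noise
  blank <- simulate_morphology_image(image_sim_config(n_axons = 0,
                                                      boutons_per_100um = 0,
                                                      seed = 4))
  expect_equal(blank$ground_truth$total_axon_um, 0)
  expect_equal(blank$ground_truth$n_boutons, 0)
  expect_equal(sd(blank$ground_truth$axon_lengths_um), NA_real_)
  # bouton count is exact for a known length and density
  one <- simulate_morphology_image(image_sim_config(n_axons = 1,
                                                    axon_length_um = 200,
                                                    axon_length_jitter = 0,
                                                    curvature = 0.05,
                                                    image_shape = c(512, 512),
                                                    boutons_per_100um = 5,
                                                    seed = 6))
  expect_equal(one$ground_truth$n_boutons,
               round(one$ground_truth$total_axon_um * 5 / 100))
  expect_equal(one$ground_truth$n_boutons, 10)
  # recorded length equals the resummed polyline length
  p <- mesoframe:::random_axon_path(c(256, 256), 240, 0.25)
  expect_equal(p$length_px, sum(sqrt(diff(p$y)^2 + diff(p$x)^2)), tolerance = 1e-8)
  expect_lt(abs(p$length_px - 240) / 240, 0.05)
})

test_that("bouton detection counts well-separated puncta and ignores dim ones", {
  blank <- simulate_morphology_image(image_sim_config(n_axons = 0,
                                                      boutons_per_100um = 0,
                                                      seed = 4))
  expect_equal(detect_boutons(blank)$count, 0)
  img <- simulate_morphology_image(image_sim_config(seed = 2))
  b <- detect_boutons(img)
  expect_equal(b$count, img$ground_truth$n_boutons)
  # puncta at ~2 background SD are rejected by the 5-SD rule
  dim_img <- simulate_morphology_image(image_sim_config(bouton_amplitude = 0.1,
                                                        seed = 5))
  expect_equal(detect_boutons(dim_img)$count, 0)
  expect_error(detect_boutons(section_image(green = matrix(0, 8, 8),
                                            pixel_size = 0.5,
                                            roi_mask = matrix(FALSE, 8, 8))),
               "ROI")
})

test_that("axon detection recovers skeleton length with stated conventions", {
  # straight 200-px line at 0.5 um/px reads 100 +/- 2 um
  m <- matrix(0, 64, 256)
  for (o in -2:2) m[32 + o, 20:219] <- exp(-o^2 / 2 / 0.8^2)
  straight <- detect_axons(section_image(red = m, pixel_size = 0.5))
  expect_lt(abs(straight$length_um - 100), 2)
  # step conventions: horizontal counts 1, diagonal sqrt(2)
  horiz <- matrix(FALSE, 20, 120); horiz[10, 10:109] <- TRUE
  expect_equal(mesoframe:::skeleton_length(horiz), 99)
  diag_m <- matrix(FALSE, 120, 120)
  for (i in 1:100) diag_m[9 + i, 9 + i] <- TRUE
  expect_equal(mesoframe:::skeleton_length(diag_m), 99 * sqrt(2))
  # corner shortcut is not double counted: L of 3 pixels = 2 steps
  ell <- matrix(FALSE, 5, 5); ell[2, 2] <- ell[2, 3] <- ell[3, 3] <- TRUE
  expect_equal(mesoframe:::skeleton_length(ell), 2)
  # blank image yields zero length
  blank <- simulate_morphology_image(image_sim_config(n_axons = 0,
                                                      boutons_per_100um = 0,
                                                      seed = 4))
  expect_equal(detect_axons(blank)$length_um, 0)
})

test_that("axon length is recovered within 10% on simulated sections", {
  for (seed in c(3, 9, 16)) {
    img <- simulate_morphology_image(image_sim_config(seed = seed))
    a <- detect_axons(img)
    expect_lt(abs(a$length_um - img$ground_truth$total_axon_um) /
                img$ground_truth$total_axon_um, 0.10)
  }
})

test_that("thinning reduces shapes to unit-width connected skeletons", {
  thick <- matrix(FALSE, 30, 80)
  thick[12:18, 10:70] <- TRUE
  sk <- mesoframe:::zhang_suen_thin(thick)
  expect_true(all(rowSums(sk)[13:17] <= 1) || all(colSums(sk)[15:65] <= 1))
  expect_equal(oracle_count_blobs(sk), 1)  # stays connected
  expect_true(all(sk[!thick] == FALSE))    # skeleton inside the shape
})

test_that("cell counting merges touching somata and ignores blanks", {
  ccfg <- image_sim_config(n_axons = 0, boutons_per_100um = 0, n_cells = 25,
                           seed = 3)
  cimg <- simulate_morphology_image(ccfg)
  cc <- count_cells(cimg, sigma_um = 4)
  expect_lte(abs(cc$count - 25), 1)
  blank <- simulate_morphology_image(image_sim_config(n_axons = 0,
                                                      boutons_per_100um = 0,
                                                      seed = 4))
  expect_equal(count_cells(blank, sigma_um = 4)$count, 0)
  # two somata closer than one radius merge to a single detection
  two <- matrix(0, 128, 128)
  two <- mesoframe:::stamp_gaussian(two, 60, 60, 8, 1)
  two <- mesoframe:::stamp_gaussian(two, 60, 66, 8, 1)
  set.seed(1); two <- two + matrix(rnorm(128^2, 0, 0.02), 128)
  expect_equal(count_cells(section_image(red = two, pixel_size = 0.5),
                           sigma_um = 4)$count, 1)
})

test_that("detection counts are invariant to a constant intensity offset", {
  img <- simulate_morphology_image(image_sim_config(seed = 7))
  b0 <- detect_boutons(img)$count
  a0 <- detect_axons(img)$length_um
  img_off <- img
  img_off$channels$red <- img$channels$red + 3
  img_off$channels$green <- img$channels$green + 3
  expect_equal(detect_boutons(img_off)$count, b0)
  expect_equal(detect_axons(img_off)$length_um, a0)
})

test_that("detector counts agree with brute-force blob labelling on small images", {
  set.seed(23)
  small <- matrix(rnorm(64 * 64, 0, 0.05), 64)
  pts <- cbind(c(15, 15, 40, 52), c(12, 45, 30, 55))
  for (i in seq_len(nrow(pts)))
    small <- mesoframe:::stamp_gaussian(small, pts[i, 1], pts[i, 2], 1.0, 1)
  si <- section_image(green = small, red = small, pixel_size = 0.5)
  det <- detect_boutons(si, sigma_um = 0.5)
  expect_equal(det$count, oracle_count_blobs(small > 0.5))
  expect_equal(det$count, 4)
})

test_that("per-animal normalization uses ratios of sums and control percentages", {
  sections <- data.frame(
    animal = rep(c("m1", "m2", "m3", "m4"), each = 2),
    group = rep(c("ctrl", "ctrl", "ctrl", "treat"), each = 2),
    bouton_count = c(60, 40, 50, 50, 70, 50, 40, 40),
    axon_length_um = c(600, 400, 550, 450, 700, 500, 500, 500),
    cell_count = c(10, NA, 12, NA, 11, NA, 9, NA))
  res <- normalize_metrics(sections, control_group = "ctrl")
  m1 <- res$per_animal[res$per_animal$animal == "m1", ]
  expect_equal(m1$bouton_density, 100 / 1000)
  expect_equal(m1$axon_per_cell, 1000 / 10)
  ctrl <- res$per_animal$group == "ctrl"
  expect_equal(mean(res$per_animal$bouton_density_pct[ctrl]), 100)
  # hand-checked percent-of-control values
  expect_equal(normalize_metrics(data.frame(
    animal = c("a", "b", "c"), group = "ctrl",
    bouton_count = c(8, 10, 12), axon_length_um = c(100, 100, 100),
    cell_count = c(1, 1, 1)))$per_animal$bouton_density_pct,
    c(80, 100, 120))
  # zero denominators flag and exclude the animal
  bad <- rbind(sections, data.frame(animal = "m5", group = "treat",
                                    bouton_count = 10, axon_length_um = 0,
                                    cell_count = 5))
  res_bad <- normalize_metrics(bad, control_group = "ctrl")
  expect_equal(res_bad$excluded, "m5")
  expect_false("m5" %in% res_bad$per_animal$animal)
})

test_that("bouton density is invariant to co-doubling boutons and axons", {
  base <- image_sim_config(seed = 12)
  dbl <- image_sim_config(n_axons = 6, seed = 12)
  d1 <- simulate_morphology_image(base)
  d2 <- simulate_morphology_image(dbl)
  dens <- function(img) detect_boutons(img)$count / detect_axons(img)$length_um
  expect_lt(abs(dens(d2) / dens(d1) - 1), 0.1)
})
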