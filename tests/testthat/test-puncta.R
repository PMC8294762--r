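test_that("axon simulation plants the exact configured counts and classes", {
  cfg <- sim_axon_config(axon_length_um = 500, puncta_per_100um = 10, seed = 2)
  sim <- simulate_axon_image(cfg)
  ch1 <- sim$truth[sim$truth$channel == "ch1", ]
  expect_equal(nrow(ch1), 50)
  expect_equal(sum(ch1$class == "full"), round(0.2 * 50))
  expect_equal(sum(ch1$class == "partial"), round(0.4 * 50))
  # determinism
  again <- simulate_axon_image(cfg)
  expect_identical(sim$image$channels, again$image$channels)
  expect_identical(sim$truth, again$truth)
  # oversized puncta rejected at configuration time
  expect_error(sim_axon_config(punctum_area_um2_range = c(0.5, 4),
                               corridor_width_um = 2), "corridor")
})

test_that("overlap_full_frac = 1 leaves every channel-1 punctum inside the ch2 mask", {
  sim <- simulate_axon_image(sim_axon_config(axon_length_um = 100,
                                             puncta_per_100um = 15,
                                             overlap_full_frac = 1,
                                             overlap_partial_frac = 0,
                                             noise_sd = 0, seed = 3))
  mask2 <- sim$image$channels$ch2 > 0.5
  px <- sim$image$pixel_size_um
  ch1 <- sim$truth[sim$truth$channel == "ch1", ]
  for (i in seq_len(nrow(ch1))) {
    off <- riboshift:::disk_offsets(ch1$radius_um[i] / px)
    expect_true(all(mask2[cbind(ch1$center_row_px[i] + off$dr,
                                ch1$center_col_px[i] + off$dc)]))
  }
})

test_that("puncta detection recovers the planted count and is scale-invariant", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_axon_image(sim_axon_config(axon_length_um = 500,
                                               puncta_per_100um = 10,
                                               noise_sd = 0.02, seed = s))
    nrow(detect_puncta(sim$image$channels$ch1, sim$image$pixel_size_um))
  }, numeric(1))
  expect_true(all(abs(hits - 50) <= 2))
  # doubling intensities leaves the detection count unchanged
  sim <- simulate_axon_image(sim_axon_config(seed = 30))
  a <- detect_puncta(sim$image$channels$ch1, 0.1)
  b <- detect_puncta(sim$image$channels$ch1 * 2, 0.1)
  expect_equal(nrow(a), nrow(b))
  # empty field: isolated hot pixels below the minimum area leave no puncta
  empty <- matrix(0.05, 100, 100)
  empty[cbind(seq(5, 95, 10), seq(5, 95, 10))] <- 1
  expect_equal(nrow(detect_puncta(empty, 0.1, min_area_um2 = 0.05)), 0)
  expect_error(detect_puncta(matrix(1, 5, 5), 0.1), "constant")
})

test_that("the PLA size gate keeps [0.05, 3.00] um2 inclusively and is idempotent", {
  puncta <- data.frame(label = 1:5,
                       area_um2 = c(0.04, 0.05, 1.0, 3.00, 3.01))
  gated <- size_gate(puncta)
  expect_equal(gated$area_um2, c(0.05, 1.0, 3.00))
  expect_equal(size_gate(gated)$area_um2, gated$area_um2)
  expect_equal(size_gate(puncta, 0, Inf)$area_um2, puncta$area_um2)
  expect_error(size_gate(puncta, 2, 1), "lo_um2")
})

test_that("linear density counts corridor puncta per 100 um and is additive", {
  axon <- axon_trace(data.frame(x_um = c(0, 500), y_um = c(0, 0)))
  puncta <- data.frame(centroid_row = rep(0, 50), centroid_col = seq(5, 4995, 100))
  expect_equal(linear_density(puncta, axon, corridor_um = 1,
                              pixel_size_um = 0.1), 10)
  none <- puncta[0, ]
  expect_equal(linear_density(none, axon, pixel_size_um = 0.1), 0)
  # additivity over segments: a two-segment polyline of the same total length
  bent <- axon_trace(data.frame(x_um = c(0, 250, 250), y_um = c(0, 0, 250)))
  on_first <- data.frame(centroid_row = rep(0, 10), centroid_col = seq(10, 2400, length.out = 10))
  d_full <- linear_density(on_first, bent, pixel_size_um = 0.1)
  expect_equal(d_full, 10 * 100 / 500)
  # off-corridor puncta are not counted
  far <- data.frame(centroid_row = rep(100, 5), centroid_col = seq(100, 500, 100))
  expect_equal(linear_density(far, axon, corridor_um = 1, pixel_size_um = 0.1), 0)
})

test_that("planted density is recovered across simulated axons", {
  dens <- vapply(1:10, function(s) {
    sim <- simulate_axon_image(sim_axon_config(axon_length_um = 300,
                                               puncta_per_100um = 12, seed = s))
    p <- detect_puncta(sim$image$channels$ch1, sim$image$pixel_size_um)
    linear_density(p, sim$axon, corridor_um = 1.2)
  }, numeric(1))
  expect_lt(abs(mean(dens) - 12), 1)
})

test_that("overlap classification thresholds behave at the extremes and midpoint", {
  m <- matrix(FALSE, 20, 60)
  lab <- matrix(0L, 20, 60)
  lab[8:12, 5:9] <- 1L                    # fully inside mask
  lab[8:12, 25:29] <- 2L                  # fully outside
  lab[8:13, 45:50] <- 3L                  # half inside
  m[, 1:15] <- TRUE
  m[8:13, 45:47] <- TRUE
  puncta <- data.frame(label = 1:3, area_um2 = rep(0.25, 3))
  attr(puncta, "labels") <- lab
  out <- classify_overlap(puncta, m)
  expect_equal(out$class, c("full", "negative", "partial"))
  expect_equal(out$overlap_fraction, c(1, 0, 0.5))
})

test_that("planted overlap composition is recovered from detected puncta", {
  fracs <- t(vapply(1:10, function(s) {
    sim <- simulate_axon_image(sim_axon_config(axon_length_um = 400,
                                               puncta_per_100um = 12,
                                               overlap_full_frac = 0.2,
                                               overlap_partial_frac = 0.4,
                                               seed = 100 + s))
    p <- detect_puncta(sim$image$channels$ch1, sim$image$pixel_size_um)
    mask2 <- otsu_mask(sim$image$channels$ch2)
    cls <- classify_overlap(p, mask2)$class
    c(full = mean(cls == "full"), partial = mean(cls == "partial"),
      negative = mean(cls == "negative"))
  }, numeric(3)))
  avg <- colMeans(fracs)
  expect_lt(abs(avg[["full"]] - 0.2), 0.07)
  expect_lt(abs(avg[["partial"]] - 0.4), 0.07)
  expect_lt(abs(avg[["negative"]] - 0.4), 0.07)
})

test_that("group summaries normalize the control mean to 100", {
  d <- data.frame(group = c(rep("control", 3), rep("mutant", 3)),
                  density = c(10, 10, 10, 18, 18, 18))
  smry <- summarize_by_group(d)
  expect_equal(smry$mean_normalized[smry$group == "control"], 100)
  expect_equal(smry$sem[smry$group == "control"], 0)
  expect_equal(smry$mean_normalized[smry$group == "mutant"], 180)
  # idempotent on already-normalized values
  d2 <- data.frame(group = d$group, density = attr(smry, "per_axon")$normalized)
  expect_equal(summarize_by_group(d2)$mean_normalized,
               smry$mean_normalized)
  expect_true(is.numeric(attr(smry, "kruskal_p")))
  expect_error(summarize_by_group(d, control = "wt"), "not found")
})
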