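test_that("Skaggs information matches hand-evaluated cases", {
  # two equal-occupancy bins with rates (2, 0): I = 1 bit/spike
  nb <- 2
  m <- structure(list(rate = matrix(c(2, 0), 1, 2),
                      occupancy = matrix(c(1, 1), 1, 2),
                      valid = matrix(TRUE, 1, 2),
                      peak_rate = 2, peak_bin = c(1, 1),
                      bin_cm = 5, origin = c(-5, -5)),
                 class = "gs_ratemap")
  expect_equal(spatial_information(m), 1.0)
  # flat map: zero information
  flat <- toy_ratemap(c(0, 0), peak = 3, sigma_cm = 1e6)
  expect_equal(spatial_information(flat), 0, tolerance = 1e-9)
  # invariance under uniform rate scaling
  g <- toy_ratemap(c(10, -20), peak = 4)
  g2 <- g; g2$rate <- g$rate * 7; g2$peak_rate <- g$peak_rate * 7
  expect_equal(spatial_information(g), spatial_information(g2),
               tolerance = 1e-12)
  # masking the zero-rate half renormalizes occupancy probabilities
  half <- m
  half$valid[1, 2] <- FALSE
  expect_equal(spatial_information(half), 0)  # single bin left, r == rbar
})

test_that("occupancy masking and rate recovery behave as specified", {
  # serpentine sweep gives near-uniform sampling above the speed gate
  tr <- serpentine_track(speed = 25, n_sweeps = 3)
  dur <- max(tr$times)
  set.seed(7)
  u <- gs_unit("hom", "dCA1", rpoisson_train(2, dur), 0.5, 3, dur)
  m <- compute_rate_map(u, tr)
  expect_true(m$peak_rate > 0)
  # homogeneous 2-Hz firing: valid-bin rates near 2 Hz
  expect_equal(mean(m$rate[m$valid]), 2, tolerance = 0.3)
  # a bin occupied for < 200 ms is masked: the still corner is never
  # visited long enough in a short window
  short <- goalsync:::window_track(tr, 0, 3)
  short <- gs_track(short$times - short$times[1], short$x, short$y)
  m2 <- compute_rate_map(u, short)
  expect_true(any(!m2$valid))
  expect_true(all(is.na(m2$rate[!m2$valid])))
  # no spikes: all-zero map
  u0 <- gs_unit("none", "dCA1", numeric(0), 0.5, 3, dur)
  m0 <- compute_rate_map(u0, tr)
  expect_equal(m0$peak_rate, 0)
  expect_true(all(m0$rate[m0$valid] == 0))
})

test_that("peak region keeps ties and honors the 1-Hz inclusion rule", {
  g <- toy_ratemap(c(20, 20), peak = 5)
  pr <- peak_region(g)
  expect_true(nrow(pr) >= 1)
  # contains the peak bin
  expect_true(any(pr[, 1] == g$peak_bin[1] & pr[, 2] == g$peak_bin[2]))
  # brute-force size oracle
  oracle <- sum(g$rate >= 0.8 * g$peak_rate)
  expect_equal(attr(pr, "size"), oracle)
  # two equal peaks both kept
  tw <- toy_ratemap(c(30, 30), peak = 5)
  tw$rate <- pmax(tw$rate, toy_ratemap(c(-30, -30), peak = 5)$rate)
  tw$peak_rate <- max(tw$rate)
  pr2 <- peak_region(tw)
  ctrs <- tw$origin[1] + (pr2[, 1] - 0.5) * tw$bin_cm
  expect_true(any(ctrs > 0) && any(ctrs < 0))
  # peak at or below 1 Hz: excluded
  low <- toy_ratemap(c(0, 0), peak = 0.9)
  expect_null(peak_region(low))
})

test_that("goal windows are 3x3 bins and overlap counts are bounded", {
  g <- toy_ratemap(c(20, 20), peak = 5, sigma_cm = 4)
  m <- g
  # peak region equal to exactly the goal bin
  gb <- goalsync:::goal_bin(c(20, 20), m)
  pb <- matrix(gb, 1, 2)
  expect_equal(goal_overlap(pb, c(20, 20), m), 1L)
  expect_equal(goal_overlap(pb, c(-50, -50), m), 0L)
  # full 3x3 window inside the peak region
  full <- as.matrix(expand.grid(gb[1] + (-1:1), gb[2] + (-1:1)))
  expect_equal(goal_overlap(full, c(20, 20), m), 9L)
  expect_error(goal_overlap(pb, c(500, 0), m), "outside")
})

test_that("goal classification applies the pre/post overlap rules", {
  goals_prev <- rbind(c(-40, 30), c(25, -40))
  goals_curr <- rbind(c(40, 20), c(-30, -35))
  # remapping cell: field at a previous goal pre, at a current goal post
  remap <- classify_goal_cells(toy_ratemap(goals_prev[1, ]),
                               toy_ratemap(goals_curr[1, ]),
                               goals_prev, goals_curr)
  expect_true(remap$goal_related)
  expect_true(remap$reorganization)
  # far-from-goal cell in both probes
  far <- classify_goal_cells(toy_ratemap(c(0, 60)), toy_ratemap(c(0, 60)),
                             goals_prev, goals_curr)
  expect_false(far$goal_related)
  expect_false(far$reorganization)
  # current-goal-only cell: goal-related, non-reorganization
  curr_only <- classify_goal_cells(toy_ratemap(c(0, 60)),
                                   toy_ratemap(goals_curr[2, ]),
                                   goals_prev, goals_curr)
  expect_true(curr_only$goal_related)
  expect_false(curr_only$reorganization)
  expect_true(curr_only$non_reorganization)
  # low-peak unit excluded with a reason
  ex <- classify_goal_cells(toy_ratemap(c(0, 0), peak = 0.5),
                            toy_ratemap(c(0, 0)), goals_prev, goals_curr)
  expect_true(ex$excluded)
  # reorganization implies goal-related over random field placements
  set.seed(3)
  for (i in 1:20) {
    ctr1 <- runif(2, -50, 50); ctr2 <- runif(2, -50, 50)
    cl <- classify_goal_cells(toy_ratemap(ctr1), toy_ratemap(ctr2),
                              goals_prev, goals_curr)
    if (isTRUE(cl$reorganization)) expect_true(cl$goal_related)
  }
})

test_that("session fractions are labeled/eligible within strata", {
  labs <- data.frame(
    session_id = "s1",
    region = rep(c("dCA1", "mOFC"), c(10, 4)),
    cell_type = "pyramidal",
    labeled = c(rep(TRUE, 3), rep(FALSE, 7), rep(TRUE, 4)))
  fr <- session_fractions(labs)
  expect_equal(fr$fraction[fr$region == "dCA1"], 0.3)
  expect_equal(fr$fraction[fr$region == "mOFC"], 1.0)
})

test_that("generated remapping goal cells classify as reorganization", {
  cfg <- synth_config(seed = 21, pre_probe_s = 300, post_probe_s = 300,
                      path_floor = 250, path_pre_slope = -20,
                      run_speed = 30, n_place = c(dCA1 = 1, mOFC = 0),
                      n_goal = c(dCA1 = 0, mOFC = 4),
                      n_interneuron = c(dCA1 = 1, mOFC = 0),
                      goal_remap_fraction = 1, theta_locked_fraction = 0)
  s <- generate_session(cfg)
  gt <- attr(s, "ground_truth")$units
  idx <- which(gt$kind == "goal" & gt$remap)
  got <- vapply(idx, function(k) {
    pre <- compute_rate_map(s$units[[k]], s$track, window = s$probes$pre)
    post <- compute_rate_map(s$units[[k]], s$track, window = s$probes$post)
    cl <- classify_goal_cells(pre, post, s$goals_previous, s$goals_current)
    isTRUE(cl$reorganization)
  }, logical(1))
  expect_gte(mean(got), 0.75)
})
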