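test_that("Rayleigh test separates uniform from concentrated phases", {
  set.seed(21)
  expect_gt(rayleigh_test(runif(200, -pi, pi))$p, 0.05)
  expect_lt(rayleigh_test(rvonmises(200, 0, 2))$p, 1e-6)
})

test_that("von Mises kappa recovers the generating concentration", {
  set.seed(22)
  ks <- replicate(20, vonmises_fit(rvonmises(500, 1, 2))$kappa)
  expect_gte(median(ks), 1.6)
  expect_lte(median(ks), 2.4)
})

test_that("theta phase locking gates on spike count and significance", {
  # one long block of cycles covering 60 s of an 8-Hz phase series
  n <- 60000
  phase <- ((2 * pi * 8 * (0:(n - 1)) / 1000 + pi) %% (2 * pi)) - pi
  cycles <- data.frame(start_s = seq(0, 59, by = 1),
                       end_s = seq(0.999, 59.999, by = 1))
  set.seed(23)
  # locked unit: spikes near phase 0 (phase = 0 at times k/8)
  st_locked <- sort(sample(0:479, 400) / 8 + rnorm(400, sd = 0.004))
  u1 <- gs_unit("l", "dCA1", st_locked[st_locked >= 0], 0.5, 3, 60)
  pl <- theta_phase_locking(u1, cycles, phase)
  expect_lt(pl$rayleigh_p, 0.001)
  expect_false(is.na(pl$kappa))
  expect_gte(pl$preferred_phase_deg, 0)
  expect_lt(pl$preferred_phase_deg, 360)
  # uniform unit: not significant, kappa not estimated
  u2 <- gs_unit("u", "dCA1", sort(runif(400, 0, 60)), 0.5, 3, 60)
  pl2 <- theta_phase_locking(u2, cycles, phase)
  expect_gt(pl2$rayleigh_p, 0.01)
  expect_true(is.na(pl2$kappa))
  # 49 in-cycle spikes: excluded
  u3 <- gs_unit("few", "dCA1", sort(runif(49, 0, 60)), 0.5, 3, 60)
  expect_null(theta_phase_locking(u3, cycles, phase))
})

test_that("normalized CCG matches the hand-counted example", {
  p <- ccg_excess(c(0, 0.1, 0.2), c(0.002, 0.102, 0.202), c(0, 0.3))
  expect_equal(p$ccg_norm[p$lags == 2], 1.0)
  expect_equal(p$baseline, 0)
  expect_equal(p$strength, 1.0)
  expect_equal(p$n_ref, 3L)
  # target shifted to -2 ms: all mass on the negative lag, positive-window
  # strength at baseline level
  m <- ccg_excess(c(0.1, 0.2, 0.3), c(0.098, 0.198, 0.298), c(0, 0.4))
  expect_equal(m$ccg_norm[m$lags == -2], 1.0)
  expect_lte(m$strength, 0)
})

test_that("CCG is invariant to global time translation of both trains", {
  set.seed(24)
  a <- sort(runif(200, 0, 60)); b <- sort(runif(200, 0, 60))
  c1 <- ccg_excess(a, b, c(0, 60))
  c2 <- ccg_excess(a + 12, b + 12, c(12, 72))
  expect_equal(c1$ccg_norm, c2$ccg_norm)
  # binarized mass identity: sum of the CCG equals in-window coincidences
  # per reference spike
  expect_equal(sum(c1$ccg_norm) * c1$n_ref,
               sum(vapply(round(a * 1000), function(r)
                 sum(abs(unique(round(b * 1000)) - r) <= 50), numeric(1))))
})

test_that("jittered-surrogate p follows the add-one empirical formula", {
  set.seed(25)
  dur <- 300
  ref <- rpoisson_train(2, dur)
  tgt <- rpoisson_train(2, dur)
  # planted pair: clearly significant at the resolution floor
  tgt2 <- sort(unique(c(tgt, ref[runif(length(ref)) < 0.3] + 0.002)))
  pp <- ccg_excess(ref, tgt2, c(0, dur))
  jp <- jitter_null(pp, n_surr = 1000, seed = 1)
  expect_equal(jp$p_emp, 1 / 1001, tolerance = 1e-12)
  expect_length(jp$null, 1000)
  # observed strength below every surrogate would give p = 1; emulate by
  # testing the formula directly on the returned null
  fake <- pp; fake$strength <- -Inf
  expect_equal(jitter_null(fake, n_surr = 100, seed = 2)$p_emp, 1)
  # independent pair: not at the floor
  pn <- ccg_excess(ref, tgt, c(0, dur))
  jn <- jitter_null(pn, n_surr = 200, seed = 3)
  expect_gt(jn$p_emp, 1 / 201)
})

test_that("BH correction within reference families matches hand step-up", {
  sig <- fdr_by_reference(c(0.001, 0.02, 0.04, 0.9), rep("A", 4))
  expect_equal(sig, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(fdr_by_reference(rep(1, 5), rep("A", 5))))
  expect_true(fdr_by_reference(0.04, "A"))
  # families are corrected independently
  two <- fdr_by_reference(c(0.04, 0.04, 0.9), c("A", "B", "B"))
  expect_true(two[1])
  expect_false(two[2])
})

test_that("trend classification requires consistent slope and net change", {
  expect_equal(classify_trend(c(1, 2, 3, 4))$trend, "increased")
  expect_equal(classify_trend(c(4, 3, 2, 1))$trend, "decreased")
  tr <- classify_trend(c(1, 3, 2, 1))
  expect_equal(tr$trend, "unclassified")
  expect_equal(tr$beta, -0.1, tolerance = 1e-9)
  expect_equal(tr$delta, 0)
  expect_equal(classify_trend(c(1, 2, NA, 4))$trend, "unclassified")
})

test_that("pair counts follow the reference neuron's label", {
  pairs <- data.frame(
    ref_id = c("a", "b", "c", "d"), target_id = c("b", "a", "d", "c"),
    ref_region = c("dCA1", "mOFC", "dCA1", "dCA1"),
    target_region = c("mOFC", "dCA1", "mOFC", "dCA1"),
    trend = c("increased", "decreased", "increased", "unclassified"),
    significant = c(TRUE, TRUE, FALSE, TRUE))
  labels <- data.frame(unit_id = c("a", "b", "d"),
                       reorganization = c(TRUE, FALSE, TRUE))
  ct <- reorganization_pair_counts(pairs, labels)
  inc <- ct$n[ct$direction == "dCA1->mOFC" & ct$trend == "increased" &
                ct$label == "reorganization"]
  expect_equal(inc, 1L)
  dec <- ct$n[ct$direction == "mOFC->dCA1" & ct$trend == "decreased" &
                ct$label == "non_reorganization"]
  expect_equal(dec, 1L)
  # pair c->d not significant, pair d->c unclassified: neither counted
  expect_equal(sum(ct$n), 2L)
  none <- reorganization_pair_counts(pairs[pairs$significant == FALSE, ],
                                     labels)
  expect_equal(sum(none$n), 0L)
})

test_that("planted 2-ms pairs pass the full per-block pipeline", {
  s <- fix_session()
  blocks <- block_windows(s$trials)
  res <- pair_coordination(s$units[1:3], blocks, n_surr = 200,
                           master_seed = 7)
  row <- res[res$ref_id == s$units[[1]]$unit_id &
               res$target_id == s$units[[2]]$unit_id, ]
  expect_true(row$significant)
  expect_true(all(row[paste0("p_b", 1:4)] < 0.05))
})
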