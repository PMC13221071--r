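# fabricated epochs: 8 trials, each with the four stage labels, 2 s per
# epoch, trials assigned to blocks 1..4
toy_epochs <- function(n_trials = 8, epoch_s = 2) {
  rows <- list()
  t0 <- 0
  for (ti in seq_len(n_trials)) {
    for (lb in c("Navigation1", "Goal1", "Navigation2", "Goal2")) {
      rows[[length(rows) + 1]] <- data.frame(
        label = lb, trial = ti, block = ceiling(ti / 2),
        start_s = t0, end_s = t0 + epoch_s)
      t0 <- t0 + epoch_s
    }
  }
  do.call(rbind, rows)
}

toy_units <- function(n = 4, dur = 64, seed = 41) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    gs_unit(paste0("u", i), if (i %% 2) "dCA1" else "mOFC",
            rpoisson_train(5, dur), 0.5, 3, dur))
}

test_that("decoding samples are balanced windows inside labeled epochs", {
  ep <- toy_epochs()
  us <- toy_units()
  s <- build_samples(us, ep, "stage")
  expect_equal(length(unique(table(s$y))), 1L)  # balanced classes
  expect_equal(ncol(s$x), length(us) * 20)      # 20 bins of 20 ms per unit
  expect_setequal(levels(s$y), c("Goal1", "Goal2", "Navigation1",
                                 "Navigation2"))
  # stage task only uses block 4
  expect_true(all(s$trial %in% ep$trial[ep$block == 4]))
  sb <- build_samples(us, ep, "block_goal")
  expect_setequal(levels(sb$y), paste0("Block", 1:4))
  expect_equal(length(unique(table(sb$y))), 1L)
})

test_that("leave-one-trial-out folds partition samples without leakage", {
  trial <- rep(c(3, 5, 9), c(4, 6, 2))
  folds <- loto_cv(trial)
  expect_length(folds, 3)
  test_idx <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_idx, seq_along(trial))
  for (f in folds) {
    expect_length(intersect(trial[f$train], trial[f$test]), 0)
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_error(loto_cv(rep(1, 5)), "at least 2")
})

test_that("Gaussian naive Bayes equals a hand-rolled density product", {
  set.seed(42)
  x_train <- rbind(matrix(rnorm(40, 0), 20, 2),
                   matrix(rnorm(40, 3), 20, 2))
  y_train <- rep(c("a", "b"), each = 20)
  x_test <- rbind(c(0.5, -0.2), c(2.8, 3.3), c(1.5, 1.5))
  post <- gnb_fit_predict(x_train, y_train, x_test)
  # oracle: same z-scoring, explicit normal densities
  mu0 <- colMeans(x_train); sd0 <- apply(x_train, 2, sd)
  zt <- sweep(sweep(x_train, 2, mu0), 2, sd0, "/")
  zs <- sweep(sweep(x_test, 2, mu0), 2, sd0, "/")
  lik <- sapply(c("a", "b"), function(cl) {
    m <- colMeans(zt[y_train == cl, ]); v <- apply(zt[y_train == cl, ], 2, var)
    apply(zs, 1, function(r) prod(dnorm(r, m, sqrt(v))) * 0.5)
  })
  oracle <- lik / rowSums(lik)
  expect_equal(unname(post), unname(oracle), tolerance = 1e-9)
  # separable classes give near-certain posteriors
  expect_gt(post[1, "a"], 0.99)
  expect_gt(post[2, "b"], 0.99)
  # uninformative features: posteriors fall back to priors
  set.seed(43)
  xs <- matrix(rnorm(300), 150, 2)
  ys <- rep(c("a", "b", "b"), 50)
  p2 <- gnb_fit_predict(xs, ys, matrix(rnorm(20), 10, 2))
  expect_equal(mean(p2[, "b"]), 2 / 3, tolerance = 0.15)
})

test_that("naive Bayes posteriors agree with an independent library fit", {
  skip_if_not_installed("e1071")
  set.seed(44)
  x <- rbind(matrix(rnorm(60, 0, 1.3), 30, 2), matrix(rnorm(60, 2), 30, 2))
  y <- factor(rep(c("p", "q"), each = 30))
  xt <- matrix(rnorm(10, 1), 5, 2)
  # compare on pre-standardized features so both models see the same input
  mu <- colMeans(x); sdv <- apply(x, 2, sd)
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  xts <- sweep(sweep(xt, 2, mu), 2, sdv, "/")
  ours <- gnb_fit_predict(xs, y, xts)
  ref <- predict(e1071::naiveBayes(xs, y), xts, type = "raw")
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("micro-average AUC matches oracles and hits its bounds", {
  y <- factor(c("a", "a", "b", "b"))
  perfect <- rbind(c(1, 0), c(0.9, 0.1), c(0.2, 0.8), c(0, 1))
  expect_equal(micro_roc_auc(y, perfect), 1)
  # brute-force concordance oracle on flattened pairs
  set.seed(45)
  y2 <- factor(sample(c("a", "b", "c"), 20, replace = TRUE))
  post <- matrix(runif(60), 20, 3)
  post <- post / rowSums(post)
  onehot <- outer(as.integer(y2), 1:3, "==") * 1
  lab <- as.vector(onehot); sc <- as.vector(post)
  pos <- which(lab == 1); neg <- which(lab == 0)
  conc <- outer(sc[pos], sc[neg], ">") + 0.5 * outer(sc[pos], sc[neg], "==")
  expect_equal(micro_roc_auc(y2, post), mean(conc), tolerance = 1e-12)
  expect_error(micro_roc_auc(factor(rep("a", 4)), perfect), "single class")
})

test_that("micro-average AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(46)
  y <- factor(sample(c("a", "b"), 40, replace = TRUE))
  post <- matrix(runif(80), 40, 2); post <- post / rowSums(post)
  onehot <- outer(as.integer(y), 1:2, "==") * 1
  ref <- as.numeric(pROC::auc(as.vector(onehot), as.vector(post),
                              quiet = TRUE, direction = "<"))
  expect_equal(micro_roc_auc(y, post), ref, tolerance = 1e-9)
})

test_that("full decode separates constructed codes and stays at chance on noise", {
  set.seed(47)
  n <- 400
  y <- factor(rep(c("A", "B", "C", "D"), n / 4))
  trial <- rep(1:10, each = n / 10)
  x0 <- matrix(rnorm(n * 12), n, 12)
  expect_equal(decode_auc(list(x = x0, y = y, trial = trial))$auc, 0.5,
               tolerance = 0.05)
  x1 <- x0 + model.matrix(~ y - 1) %*% matrix(rnorm(4 * 12, sd = 2), 4, 12)
  expect_gt(decode_auc(list(x = x1, y = y, trial = trial))$auc, 0.9)
})

test_that("region-complementary codes decode better jointly than alone", {
  # dCA1 units carry Goal1 information, mOFC units carry Navigation1
  # information; only the combined population sees both distinctions
  mk <- function(seed, n_trials = 8, epoch_s = 2) {
    set.seed(seed)
    ep <- toy_epochs(n_trials, epoch_s)
    dur <- max(ep$end_s)
    gen_unit <- function(id, region, hot_label) {
      st <- unlist(lapply(seq_len(nrow(ep)), function(i) {
        r <- if (ep$label[i] == hot_label) 25 else 5
        sort(runif(rpois(1, r * epoch_s), ep$start_s[i], ep$end_s[i]))
      }))
      gs_unit(id, region, sort(st), 0.5, 3, dur)
    }
    us <- c(lapply(1:4, function(i) gen_unit(paste0("d", i), "dCA1",
                                             "Goal1")),
            lapply(1:4, function(i) gen_unit(paste0("m", i), "mOFC",
                                             "Navigation1")))
    list(units = us, epochs = ep)
  }
  res <- vapply(1:5, function(sd) {
    cc <- mk(sd)
    reg <- vapply(cc$units, `[[`, "", "region")
    auc_of <- function(us)
      decode_auc(build_samples(us, cc$epochs, "stage", seed = sd))$auc
    c(auc_of(cc$units), auc_of(cc$units[reg == "dCA1"]),
      auc_of(cc$units[reg == "mOFC"]))
  }, numeric(3))
  expect_gt(median(res[1, ]), median(pmax(res[2, ], res[3, ])))
})

test_that("fixed-N replacement keeps population size and reduces at 0", {
  ep <- toy_epochs()
  us <- toy_units(8, seed = 48)
  base <- fixed_n_replacement(us, ep, "stage", "dCA1", fraction = 0,
                              seed = 5)
  expect_equal(base$n_population, 4)
  # fraction 0 is exactly the single-region decode under the same seed
  src <- which(vapply(us, `[[`, "", "region") == "dCA1")
  s0 <- build_samples(us[src], ep, "stage", seed = (5 * 131L + 1L))
  expect_equal(base$mean_auc, decode_auc(s0)$auc, tolerance = 1e-12)
  mix <- fixed_n_replacement(us, ep, "stage", "dCA1", fraction = 0.5,
                             n_resamples = 3, seed = 5)
  expect_equal(mix$n_population, 4)
  expect_length(mix$aucs, 3)
  # four source neurons but a single donor: fraction 0.5 needs two
  scarce <- us[c(1, 3, 5, 7, 2)]
  expect_error(fixed_n_replacement(scarce, ep, "stage", "dCA1",
                                   fraction = 0.5),
               "insufficient donor")
})
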