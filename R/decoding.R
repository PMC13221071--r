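#' Build decoding samples from labeled epochs
#'
#' Every labeled epoch is cut into consecutive non-overlapping 400-ms
#' windows (partial trailing windows dropped); within a window, each
#' neuron's spikes are counted in 20-ms bins and converted to rates, and
#' the per-neuron bins are concatenated into the feature vector
#' (`n_neurons x 20` features). Tasks: `stage` uses the four Block-4
#' epoch labels (Goal1/Goal2/Navigation1/Navigation2); `block_goal` /
#' `block_nav` use Goal-only / Navigation-only samples labeled by learning
#' block (1..4). Classes are balanced by randomly subsampling each class to
#' the smallest class (once per task).
#'
#' @param units List of [gs_unit()]s forming the decoding population.
#' @param epochs Epoch data frame from [segment_epochs()].
#' @param task One of `"stage"`, `"block_goal"`, `"block_nav"`.
#' @param window_s,bin_s Window and bin lengths, s.
#' @param balance Subsample classes to the smallest class.
#' @param seed Seed for the balancing draw.
#' @return List with `x` (samples x features), `y` (factor labels),
#'   `trial` (trial index per sample).
#' @export
build_samples <- function(units, epochs, task = c("stage", "block_goal",
                                                  "block_nav"),
                          window_s = 0.4, bin_s = 0.02, balance = TRUE,
                          seed = 1) {
  task <- match.arg(task)
  ep <- switch(task,
    stage = epochs[epochs$block == 4, , drop = FALSE],
    block_goal = epochs[grepl("^Goal", epochs$label), , drop = FALSE],
    block_nav = epochs[grepl("^Navigation", epochs$label), , drop = FALSE])
  if (nrow(ep) == 0) stop("no epochs available for task ", task)
  label_of <- function(row) if (task == "stage") row$label else
    paste0("Block", row$block)
  nb <- round(window_s / bin_s)
  feats <- list(); labs <- character(0); trials <- integer(0)
  for (i in seq_len(nrow(ep))) {
    row <- ep[i, ]
    n_win <- floor((row$end_s - row$start_s) / window_s)
    if (n_win < 1) next
    for (w in seq_len(n_win)) {
      w0 <- row$start_s + (w - 1) * window_s
      edges <- seq(w0, w0 + window_s, by = bin_s)
      f <- unlist(lapply(units, function(u) {
        st <- u$spike_times
        st <- st[st >= w0 & st < w0 + window_s]
        tabulate(findInterval(st, edges, rightmost.closed = FALSE), nb) / bin_s
      }))
      feats[[length(feats) + 1]] <- f
      labs <- c(labs, label_of(row))
      trials <- c(trials, row$trial)
    }
  }
  if (!length(feats)) stop("no decoding samples could be built")
  x <- do.call(rbind, feats)
  y <- factor(labs)
  if (length(levels(y)) < 2 || any(table(y) == 0))
    stop("task ", task, ": a class has no samples")
  trial <- trials
  if (balance) {
    set.seed(seed)
    n_min <- min(table(y))
    keep <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sort(sample(idx, n_min))
    }))
    keep <- sort(keep)
    x <- x[keep, , drop = FALSE]; y <- droplevels(y[keep])
    trial <- trial[keep]
  }
  list(x = x, y = y, trial = trial)
}

#' Leave-one-trial-out fold assignment
#'
#' One fold per distinct trial; all windows of the held-out trial form the
#' test set, so no window of a test trial ever appears in training.
#'
#' @param trial Trial index per sample.
#' @return List of folds, each with `train` and `test` index vectors.
#' @export
loto_cv <- function(trial) {
  trials <- sort(unique(trial))
  if (length(trials) < 2) stop("leave-one-trial-out needs at least 2 trials")
  lapply(trials, function(tt)
    list(train = which(trial != tt), test = which(trial == tt)))
}

#' Gaussian naive Bayes: fit on training samples, predict posteriors
#'
#' Feature-wise Gaussian class-conditional likelihoods with class priors
#' estimated from the training fold; features are z-scored with training-
#' fold statistics before fitting (the same transform is applied to the
#' test fold). Zero-variance features have their variance floored at a
#' small epsilon.
#'
#' @param x_train,y_train Training samples and labels.
#' @param x_test Test samples.
#' @param var_floor Variance floor.
#' @return Posterior matrix (test samples x classes), rows summing to 1.
#' @export
gnb_fit_predict <- function(x_train, y_train, x_test, var_floor = 1e-9) {
  y_train <- factor(y_train)
  mu0 <- colMeans(x_train)
  sd0 <- apply(x_train, 2, sd); sd0[sd0 == 0] <- 1
  xt <- sweep(sweep(x_train, 2, mu0), 2, sd0, "/")
  xs <- sweep(sweep(x_test, 2, mu0), 2, sd0, "/")
  classes <- levels(y_train)
  loglik <- sapply(classes, function(cl) {
    xc <- xt[y_train == cl, , drop = FALSE]
    m <- colMeans(xc)
    v <- pmax(apply(xc, 2, var), var_floor)
    prior <- mean(y_train == cl)
    rowSums(-0.5 * log(2 * pi * v)[col(xs)] -
              0.5 * sweep(xs, 2, m)^2 / v[col(xs)]) + log(prior)
  })
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = 1)
  mx <- apply(loglik, 1, max)
  post <- exp(loglik - mx)
  post / rowSums(post)
}

#' Micro-average ROC-AUC for multiclass posteriors
#'
#' One-hot encodes the true labels, flattens the one-hot and posterior
#' matrices across classes, and computes the trapezoidal ROC AUC on the
#' flattened (label, score) pairs (rank/Mann-Whitney formulation with tie
#' correction).
#'
#' @param y True labels (factor).
#' @param post Posterior matrix with one column per class, in
#'   `levels(y)` order.
#' @return Scalar AUC in `[0, 1]`.
#' @export
micro_roc_auc <- function(y, post) {
  y <- factor(y)
  if (length(levels(y)) < 2) stop("AUC undefined with a single class")
  onehot <- outer(as.integer(y), seq_along(levels(y)), "==") * 1
  lab <- as.vector(onehot)
  sc <- as.vector(post)
  n_pos <- sum(lab == 1); n_neg <- sum(lab == 0)
  r <- rank(sc)
  (sum(r[lab == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Leave-one-trial-out decoding with micro-average ROC-AUC
#'
#' Runs [gnb_fit_predict()] over [loto_cv()] folds, accumulates held-out
#' posteriors, and summarizes performance as the micro-average ROC-AUC
#' over all held-out samples.
#'
#' @param samples List from [build_samples()] (fields `x`, `y`, `trial`).
#' @return List with `auc`, `posteriors`, `y`.
#' @export
decode_auc <- function(samples) {
  folds <- loto_cv(samples$trial)
  post <- matrix(NA_real_, nrow(samples$x), length(levels(samples$y)))
  for (f in folds) {
    if (length(unique(samples$y[f$train])) < length(levels(samples$y)))
      next  # fold missing a class in training: skip its predictions
    post[f$test, ] <- gnb_fit_predict(samples$x[f$train, , drop = FALSE],
                                      samples$y[f$train],
                                      samples$x[f$test, , drop = FALSE])
  }
  ok <- complete.cases(post)
  list(auc = micro_roc_auc(samples$y[ok], post[ok, , drop = FALSE]),
       posteriors = post, y = samples$y)
}

#' Fixed-N replacement decoding control
#'
#' Holds the decoding population size constant while a fraction of
#' source-region neurons is replaced by randomly drawn other-region
#' neurons; the full decode is re-run for each of `n_resamples` random
#' replacements and the AUC averaged. `fraction = 0` reduces to the
#' single-region decode.
#'
#' @param units All units.
#' @param epochs Epoch data frame.
#' @param task Decoding task (see [build_samples()]).
#' @param source_region Region forming the baseline population.
#' @param fraction Fraction of source neurons replaced (0-0.5).
#' @param n_resamples Random resamples per fraction.
#' @param seed Master seed; per-resample seeds are derived from it.
#' @return List with `mean_auc`, `aucs`, `n_population`.
#' @export
fixed_n_replacement <- function(units, epochs, task = "stage",
                                source_region = "dCA1", fraction = 0,
                                n_resamples = 200, seed = 1) {
  regions <- vapply(units, `[[`, "", "region")
  src <- which(regions == source_region)
  oth <- which(regions != source_region)
  n_pop <- length(src)
  n_rep <- floor(fraction * n_pop)
  if (n_rep > length(oth))
    stop("insufficient donor neurons for fraction ", fraction)
  if (n_rep == 0) n_resamples <- 1
  aucs <- vapply(seq_len(n_resamples), function(k) {
    set.seed((seed * 7919L + k) %% .Machine$integer.max)
    pop <- src
    if (n_rep > 0) {
      drop_idx <- sample(seq_along(src), n_rep)
      pop <- c(src[-drop_idx], sample(oth, n_rep))
    }
    stopifnot(length(pop) == n_pop)
    s <- build_samples(units[pop], epochs, task,
                       seed = (seed * 131L + k) %% .Machine$integer.max)
    decode_auc(s)$auc
  }, numeric(1))
  list(mean_auc = mean(aucs), aucs = aucs, n_population = n_pop)
}
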