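#' Time-delay embedding of an epoch window
#'
#' Builds the feature matrix for one time point: all samples in a window of
#' `2 * half_width_samples + 1` samples (25 samples = 50 ms at the 500 Hz
#' analysis rate) around the time point, per channel, concatenated into one
#' feature vector of length `window * n_channels` per epoch. Each feature
#' column is z-scored across epochs, which puts channels with different
#' units (fT vs fT/cm) on a common scale for the margin classifier. The
#' embedding buys resilience to activation-latency differences across
#' participants compared with single-sample features.
#'
#' @param epochs an [epoch_set()].
#' @param t_index index of the center sample on the epoch time axis.
#' @param half_width_samples half-width of the window in samples (12 gives
#'   the 25-sample window).
#' @return numeric matrix, epochs x (window * channels); features are
#'   ordered window-sample-major, channel-minor.
#' @examples
#' es <- simulate_epochs(20, 4, effects = list(), seed = 1)
#' dim(embed_window(es, t_index = 251)) # 20 x 100
#' @export
embed_window <- function(epochs, t_index, half_width_samples = 12) {
  d <- dim(epochs$data)
  w <- half_width_samples
  if (t_index - w < 1 || t_index + w > d[3]) {
    stop("the full ", 2 * w + 1, "-sample window does not fit at t_index = ",
         t_index)
  }
  x <- matrix(epochs$data[, , (t_index - w):(t_index + w)],
              nrow = d[1])
  zscore_cols(x)
}

zscore_cols <- function(x) {
  m <- colMeans(x)
  s <- sqrt(pmax(colMeans(x^2) - m^2, 0) * nrow(x) / max(1, nrow(x) - 1))
  s[s == 0] <- 1
  sweep(sweep(x, 2, m), 2, s, "/")
}

#' Average trials into super-trials
#'
#' Randomly partitions the epochs of each class into groups of `k` (without
#' replacement) and averages each group, boosting the signal-to-noise ratio
#' before classification. Leftover epochs (fewer than `k`) are discarded for
#' the current repetition; a fresh partition is drawn per repetition inside
#' the decoder so all epochs are used in expectation.
#'
#' @param x numeric matrix, epochs x features.
#' @param labels class label per epoch.
#' @param k trials averaged per super-trial; `k = 1` returns the input
#'   (reordered).
#' @param seed optional seed.
#' @return list with `x` (super-trials x features) and `labels`.
#' @export
make_super_trials <- function(x, labels, k = 10, seed = NULL) {
  with_seed(seed, {
    labels <- as.character(labels)
    counts <- table(labels)
    if (any(counts < k)) {
      bad <- names(counts)[counts < k][1]
      stop("insufficient data: class '", bad, "' has ", counts[[bad]],
           " epochs, fewer than k = ", k)
    }
    grp <- super_groups(labels, k)
    list(
      x = rowsum(x[grp$row, , drop = FALSE], grp$id, reorder = TRUE) / k,
      labels = grp$label[!duplicated(grp$id)][order(unique(grp$id))]
    )
  })
}

# Random partition of each class into groups of k; returns row indices,
# group ids and group labels (one label per group id, ids sorted).
super_groups <- function(labels, k) {
  rows <- integer(0)
  ids <- integer(0)
  labs <- character(0)
  next_id <- 1L
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    n_g <- floor(length(idx) / k)
    if (n_g == 0) { # use all epochs as one (smaller) group
      n_g <- 1L
      k_eff <- length(idx)
    } else {
      k_eff <- k
    }
    use <- idx[seq_len(n_g * k_eff)]
    id <- rep(next_id:(next_id + n_g - 1L), each = k_eff)
    rows <- c(rows, use)
    ids <- c(ids, id)
    labs <- c(labs, rep(cl, length(use)))
    next_id <- next_id + n_g
  }
  list(row = rows, id = ids, label = labs)
}

#' Split an epoch set into outcome-balanced halves
#'
#' Subsamples the larger outcome (without replacement) to the size of the
#' smaller one, so correct and incorrect trials enter decoding in equal
#' numbers.
#'
#' @param epochs an [epoch_set()] whose labels contain `outcome`.
#' @param seed optional seed.
#' @return named list of two `epoch_set`s, `correct` and `incorrect`, of
#'   equal size.
#' @export
balance_by_outcome <- function(epochs, seed = NULL) {
  with_seed(seed, {
    out <- epochs$labels$outcome
    if (is.null(out)) stop("labels have no outcome column")
    idx_c <- which(out == "correct")
    idx_i <- which(out == "incorrect")
    if (length(idx_c) == 0 || length(idx_i) == 0) {
      stop("both outcomes must be present to balance")
    }
    m <- min(length(idx_c), length(idx_i))
    list(
      correct = epochs[sort(sample(idx_c, m))],
      incorrect = epochs[sort(sample(idx_i, m))]
    )
  })
}

#' Sliding-window decoding of a stimulus dimension
#'
#' Time-resolved multivariate classification of one epoch set (one
#' participant): at each time point the 25-sample window is embedded
#' ([embed_window()]), epochs are split into stratified cross-validation
#' folds, super-trials are built independently within the training and test
#' sides ([make_super_trials()]), a linear max-margin classifier
#' ([linsvm()]) is fit on the training super-trials, and performance is the
#' AUC of the signed decision values on the test super-trials, averaged over
#' folds and `n_reps` repetitions (fresh super-trial partitions each).
#' Classes are balanced by subsampling the majority class per repetition.
#' The three-class category problem is decoded as the unweighted mean of the
#' three pairwise binary AUCs (animal/food, animal/object, food/object).
#' Fold assignments are fixed across time points within a repetition, so the
#' curve is smooth and matches the temporal-generalization diagonal.
#'
#' @param epochs an [epoch_set()].
#' @param problem `"color"` (gray vs color) or `"category"` (3-class).
#' @param labels optional explicit label vector overriding the labels column
#'   (`color_scale` or `category`) selected by `problem`.
#' @param n_folds cross-validation folds.
#' @param n_reps repetitions of the super-trial construction.
#' @param k_super trials per super-trial.
#' @param half_width_samples embedding half-width (12 = 25-sample window).
#' @param time_window analysis window in seconds (statistics are restricted
#'   to -250..+250 ms around fixation onset).
#' @param time_step evaluate every `time_step`-th sample (1 = every 2 ms).
#' @param cost SVM cost parameter.
#' @param seed optional seed; fixes balancing, folds and partitions.
#' @return a `decoding_curve` tibble with columns `time_s`, `auc` and
#'   attributes `problem`, `n_epochs`, and `pairwise` (the per-pair AUC
#'   matrix whose row means are the reported curve).
#' @export
decode_sliding <- function(epochs, problem = c("color", "category"),
                           labels = NULL, n_folds = 10, n_reps = 10,
                           k_super = 10, half_width_samples = 12,
                           time_window = c(-0.25, 0.25), time_step = 1,
                           cost = 1, seed = NULL) {
  problem <- match.arg(problem)
  res <- .decode_core(epochs, problem, labels, n_folds, n_reps, k_super,
                      half_width_samples, time_window, time_step, cost, seed,
                      tg = FALSE)
  out <- tibble(time_s = res$times, auc = res$auc)
  attr(out, "problem") <- problem
  attr(out, "n_epochs") <- res$n_epochs
  attr(out, "pairwise") <- res$pairwise
  class(out) <- c("decoding_curve", class(out))
  out
}

#' Temporal generalization decoding
#'
#' Trains the classifier at each time point and tests it at every time
#' point, yielding a train x test matrix of AUC. With the same seed, its
#' diagonal equals the [decode_sliding()] curve exactly. Transient neural
#' codes give above-chance values confined near the diagonal; sustained
#' codes generalize off-diagonal into a square region.
#'
#' @inheritParams decode_sliding
#' @return a `tg_matrix` object: list with `train_times`, `test_times`,
#'   `auc` (matrix), `problem`.
#' @export
decode_generalization <- function(epochs, problem = c("color", "category"),
                                  labels = NULL, n_folds = 10, n_reps = 10,
                                  k_super = 10, half_width_samples = 12,
                                  time_window = c(-0.25, 0.25), time_step = 1,
                                  cost = 1, seed = NULL) {
  problem <- match.arg(problem)
  res <- .decode_core(epochs, problem, labels, n_folds, n_reps, k_super,
                      half_width_samples, time_window, time_step, cost, seed,
                      tg = TRUE)
  structure(
    list(train_times = res$times, test_times = res$times, auc = res$tg,
         problem = problem, n_epochs = res$n_epochs),
    class = "tg_matrix"
  )
}

#' @export
print.tg_matrix <- function(x, ...) {
  cat(sprintf("<tg_matrix> %s, %d x %d time points (%.3f..%.3f s)\n",
              x$problem, length(x$train_times), length(x$test_times),
              min(x$train_times), max(x$train_times)))
  invisible(x)
}

#' @method tidy tg_matrix
#' @export
tidy.tg_matrix <- function(x, ...) {
  out <- tidyr::expand_grid(train_time_s = x$train_times,
                            test_time_s = x$test_times)
  out$auc <- as.vector(t(x$auc))
  out
}

# Shared engine for sliding and temporal-generalization decoding. Handles
# label selection and pairwise averaging for the 3-class category problem.
.decode_core <- function(epochs, problem, labels, n_folds, n_reps, k_super,
                         hw, time_window, time_step, cost, seed, tg) {
  y <- labels %||% switch(problem,
    color = epochs$labels$color_scale,
    category = epochs$labels$category
  )
  if (is.null(y)) stop("no labels found for problem '", problem, "'")
  y <- as.character(y)
  keep <- !is.na(y)
  y <- y[keep]
  d <- dim(epochs$data)
  nt <- d[3]
  nch <- d[2]
  x <- matrix(epochs$data[keep, , , drop = FALSE], nrow = sum(keep))

  times <- epochs$times
  valid <- which(times >= time_window[1] - 1e-9 & times <= time_window[2] + 1e-9 &
                   seq_along(times) > hw & seq_along(times) <= nt - hw)
  times_idx <- valid[seq(1, length(valid), by = time_step)]

  classes <- sort(unique(y))
  pairs <- if (length(classes) == 2) {
    list(classes)
  } else if (length(classes) == 3) {
    utils::combn(classes, 2, simplify = FALSE)
  } else {
    stop("expected 2 or 3 classes, got ", length(classes))
  }

  acc_tg <- NULL
  pair_auc <- matrix(0, length(times_idx), length(pairs))
  colnames(pair_auc) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    sel <- y %in% pr
    r <- .decode_binary(x[sel, , drop = FALSE], y[sel], nch, times_idx, hw,
                        n_folds, n_reps, k_super, cost,
                        seed = derive_seed(seed, pi), tg = tg)
    pair_auc[, pi] <- r$auc
    if (tg) acc_tg <- if (is.null(acc_tg)) r$tg else acc_tg + r$tg
  }

  list(times = times[times_idx], auc = rowMeans(pair_auc),
       pairwise = pair_auc,
       tg = if (tg) acc_tg / length(pairs), n_epochs = sum(keep))
}

# Binary decoding over time on a pre-z-scored feature matrix whose columns
# are (channel within sample) blocks; the embedding window at time index t
# is the contiguous column slab (t - hw - 1) * nch + 1 .. (t + hw) * nch.
.decode_binary <- function(x, y, nch, times_idx, hw, n_folds, n_reps, k, cost,
                           seed, tg) {
  with_seed(seed, {
    ntp <- length(times_idx)
    auc_sum <- numeric(ntp)
    tg_sum <- if (tg) matrix(0, ntp, ntp)
    n_eval <- 0L
    lev <- sort(unique(y))

    slab <- function(t) ((t - hw - 1) * nch + 1):((t + hw) * nch)

    for (rep_i in seq_len(n_reps)) {
      # balance classes by subsampling the majority class
      idx1 <- which(y == lev[1])
      idx2 <- which(y == lev[2])
      m <- min(length(idx1), length(idx2))
      if (m < n_folds) {
        stop("insufficient data: class '", lev[which.min(c(length(idx1), length(idx2)))],
             "' has fewer epochs (", m, ") than folds (", n_folds, ")")
      }
      use <- c(sample(idx1, m), sample(idx2, m))
      yb <- y[use]

      # stratified folds, fixed across time points within this repetition
      fold <- integer(length(use))
      for (cl in lev) {
        w <- which(yb == cl)
        fold[w] <- rep_len(seq_len(n_folds), length(w))[sample.int(length(w))]
      }

      for (f in seq_len(n_folds)) {
        tr <- use[fold != f]
        te <- use[fold == f]
        ytr <- y[tr]
        yte <- y[te]
        if (any(table(factor(ytr, levels = lev)) < k)) {
          stop("insufficient data: a training fold has a class with fewer ",
               "than k = ", k, " epochs")
        }
        g_tr <- super_groups(ytr, k)
        g_te <- super_groups(yte, min(k, min(table(factor(yte, levels = lev)))))
        s_tr <- rowsum(x[tr[g_tr$row], , drop = FALSE], g_tr$id, reorder = TRUE)
        s_tr <- s_tr / as.vector(table(g_tr$id))
        s_te <- rowsum(x[te[g_te$row], , drop = FALSE], g_te$id, reorder = TRUE)
        s_te <- s_te / as.vector(table(g_te$id))
        yl_tr <- g_tr$label[!duplicated(g_tr$id)]
        yl_te <- g_te$label[!duplicated(g_te$id)]

        # per-feature standardization from training-fold epochs, applied to
        # both sides: unit-free features without train/test coupling.
        # z-scoring is affine, so applying it to the averaged super-trials
        # equals averaging z-scored epochs.
        mu <- colMeans(x[tr, , drop = FALSE])
        sdev <- sqrt(pmax(colMeans(x[tr, , drop = FALSE]^2) - mu^2, 0))
        sdev[sdev == 0] <- 1
        s_tr <- sweep(sweep(s_tr, 2, mu), 2, sdev, "/")
        s_te <- sweep(sweep(s_te, 2, mu), 2, sdev, "/")

        for (ti in seq_len(ntp)) {
          cols <- slab(times_idx[ti])
          fit <- linsvm(s_tr[, cols, drop = FALSE], yl_tr, cost = cost)
          if (tg) {
            for (tj in seq_len(ntp)) {
              sc <- s_te[, slab(times_idx[tj]), drop = FALSE] %*% fit$w - fit$rho
              tg_sum[ti, tj] <- tg_sum[ti, tj] + auc_score(drop(sc), yl_te, positive = lev[1])
            }
            auc_sum[ti] <- auc_sum[ti] +
              auc_score(drop(s_te[, cols, drop = FALSE] %*% fit$w - fit$rho),
                        yl_te, positive = lev[1])
          } else {
            sc <- s_te[, cols, drop = FALSE] %*% fit$w - fit$rho
            auc_sum[ti] <- auc_sum[ti] + auc_score(drop(sc), yl_te, positive = lev[1])
          }
        }
        n_eval <- n_eval + 1L
      }
    }
    list(auc = auc_sum / n_eval, tg = if (tg) tg_sum / n_eval)
  })
}
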