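#' Sign-flip max-t permutation test against chance
#'
#' Group-level test of decoding performance against chance with family-wise
#' error control over time points (or train x test cells). For each of
#' `n_perm` permutations, the chance-subtracted curve of each participant is
#' multiplied by a random sign — one sign per participant applied to the
#' whole curve, preserving its temporal autocorrelation under the null — and
#' a one-sample t statistic against zero is computed at each point. The
#' maximum t over points is collected per permutation, and the observed t
#' field is thresholded at the `(1 - alpha)` quantile of that max-t
#' distribution. Consecutive supra-threshold points form the reported
#' temporal clusters (descriptive maximal runs; significance is pointwise at
#' the corrected threshold). The test is one-sided (above chance) by
#' default, as only above-chance decoding is interpretable.
#'
#' @param curves numeric matrix participants x time, a 3-D array
#'   participants x train x test, or a tibble with `participant`, `time_s`
#'   and `auc` columns.
#' @param chance chance level subtracted before testing (0.5 for AUC).
#' @param n_perm number of sign-flip permutations (1,500 by default).
#' @param alpha significance level of the max-t threshold.
#' @param tail `"greater"` (one-sided, above chance) or `"two.sided"`.
#' @param times optional time axis (seconds), one per column; taken from the
#'   tibble when `curves` is tidy.
#' @param seed optional seed for the sign flips.
#' @return a `cluster_test` object: `t_obs`, `threshold_t`, `clusters`
#'   (tibble with onset/offset in seconds for curves, or cell lists for
#'   matrices), `alpha`, `n_perm`, `chance`, `times`.
#' @export
signflip_maxt <- function(curves, chance = 0.5, n_perm = 1500, alpha = 0.05,
                          tail = c("greater", "two.sided"), times = NULL,
                          seed = NULL) {
  tail <- match.arg(tail)
  if (n_perm < 100) {
    warning("n_perm = ", n_perm, " is too small for stable thresholds")
  }
  if (is.data.frame(curves)) {
    wide <- tidyr::pivot_wider(curves[, c("participant", "time_s", "auc")],
                               names_from = "time_s", values_from = "auc")
    times <- as.numeric(names(wide)[-1])
    curves <- as.matrix(wide[, -1])
  }
  dims <- dim(curves)
  is2d <- length(dims) == 3
  P <- dims[1]
  if (P < 3) stop("need at least 3 participants")
  X <- matrix(curves, nrow = P) - chance
  if (any(!is.finite(X))) stop("curves contain non-finite values")

  vzero <- apply(X, 2, function(c) all(c == c[1]))
  if (all(vzero) && any(X != 0)) {
    stop("undefined t statistic (zero variance across participants)")
  }
  tfield <- .one_sample_t(X)

  maxs <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * P, replace = TRUE), n_perm, P)
    M <- S %*% X / P
    # sign flips leave per-point sums of squares unchanged, so the permuted
    # t field needs only the permuted means
    ss <- colSums(X^2)
    V <- sweep(-(M^2) * P, 2, ss, "+") / (P - 1)
    Tm <- M / sqrt(pmax(V, 1e-300) / P)
    if (tail == "two.sided") Tm <- abs(Tm)
    m <- Tm[, 1]
    for (j in seq_len(ncol(Tm))[-1]) m <- pmax(m, Tm[, j])
    m
  })
  threshold <- sort(maxs)[ceiling((1 - alpha) * n_perm)]

  obs <- if (tail == "two.sided") abs(tfield) else tfield
  sig <- obs > threshold

  if (is2d) {
    t_obs <- matrix(tfield, dims[2], dims[3])
    sig_m <- matrix(sig, dims[2], dims[3])
    clusters <- .components_2d(sig_m, t_obs)
  } else {
    t_obs <- drop(tfield)
    runs <- logical_runs(sig)
    tt <- times %||% seq_along(t_obs)
    clusters <- tibble(
      cluster = seq_along(runs$start),
      onset = tt[runs$start], offset = tt[runs$end],
      n_points = runs$end - runs$start + 1L,
      peak_t = vapply(seq_along(runs$start),
                      function(k) max(obs[runs$start[k]:runs$end[k]]), numeric(1))
    )
  }

  structure(
    list(t_obs = t_obs, threshold_t = threshold, clusters = clusters,
         alpha = alpha, n_perm = n_perm, chance = chance, tail = tail,
         times = times, n_participants = P),
    class = "cluster_test"
  )
}

# One-sample t per column; a zero-variance column gives t = 0 when its mean
# is zero (e.g. all curves exactly at chance) and +/-Inf otherwise (e.g.
# every participant saturated at the same AUC).
.one_sample_t <- function(X) {
  P <- nrow(X)
  m <- colMeans(X)
  v <- pmax((colSums(X^2) - P * m^2) / (P - 1), 0)
  t <- ifelse(v == 0, sign(m) * Inf, m / sqrt(v / P))
  t[v == 0 & m == 0] <- 0
  t
}

# 4-connected components of a logical matrix; returns a tibble with one row
# per component and the member cells as a list column.
.components_2d <- function(sig, t_obs) {
  lab <- matrix(0L, nrow(sig), ncol(sig))
  cur <- 0L
  for (s0 in which(sig & lab == 0)) {
    if (lab[s0] != 0L) next
    cur <- cur + 1L
    queue <- s0
    lab[s0] <- cur
    nr <- nrow(sig)
    while (length(queue)) {
      cell <- queue[[1]]
      queue <- queue[-1]
      i <- (cell - 1L) %% nr + 1L
      j <- (cell - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]
        jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= ncol(sig)) {
          c2 <- (jj - 1L) * nr + ii
          if (sig[c2] && lab[c2] == 0L) {
            lab[c2] <- cur
            queue <- c(queue, c2)
          }
        }
      }
    }
  }
  if (cur == 0L) {
    return(tibble(cluster = integer(0), n_cells = integer(0),
                  peak_t = numeric(0), cells = list()))
  }
  tibble(
    cluster = seq_len(cur),
    n_cells = vapply(seq_len(cur), function(k) sum(lab == k), integer(1)),
    peak_t = vapply(seq_len(cur), function(k) max(abs(t_obs[lab == k])), numeric(1)),
    cells = lapply(seq_len(cur), function(k) which(lab == k, arr.ind = TRUE))
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "<cluster_test> %d participants, %d permutations, alpha = %g (%s)\n",
    x$n_participants, x$n_perm, x$alpha, x$tail))
  cat(sprintf("threshold t = %.3f; %d cluster(s)\n", x$threshold_t,
              nrow(x$clusters)))
  invisible(x)
}

#' @method tidy cluster_test
#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' @method glance cluster_test
#' @export
glance.cluster_test <- function(x, ...) {
  tibble(threshold_t = x$threshold_t, n_clusters = nrow(x$clusters),
         alpha = x$alpha, n_perm = x$n_perm,
         n_participants = x$n_participants)
}

#' Two-condition permutation test on paired decoding curves
#'
#' Compares two within-participant conditions (e.g. correct vs incorrect
#' trials) with the same max-t machinery as [signflip_maxt()]: condition
#' labels are swapped per participant with probability 1/2 at each
#' permutation — equivalent to flipping the sign of the paired difference —
#' and the two-sided max |t| distribution thresholds the observed
#' difference t field. Optionally the comparison is restricted to time
#' points where both conditions exceed chance (`mask`), as condition
#' differences are only interpretable where there is decodable signal.
#'
#' @param curves_a,curves_b matrices participants x time, paired by row.
#' @param mask optional logical vector over time points; `FALSE` points are
#'   excluded from the test.
#' @inheritParams signflip_maxt
#' @return a `cluster_test` object for the A - B difference.
#' @export
two_condition_perm <- function(curves_a, curves_b, n_perm = 1500,
                               alpha = 0.05, mask = NULL, times = NULL,
                               seed = NULL) {
  if (!all(dim(curves_a) == dim(curves_b))) {
    stop("condition curve shapes differ")
  }
  D <- curves_a - curves_b
  if (!is.null(mask)) {
    if (length(mask) != ncol(D)) stop("mask length must match time points")
    keep <- which(mask)
    res <- signflip_maxt(D[, keep, drop = FALSE], chance = 0, n_perm = n_perm,
                         alpha = alpha, tail = "two.sided",
                         times = (times %||% seq_len(ncol(D)))[keep], seed = seed)
  } else {
    res <- signflip_maxt(D, chance = 0, n_perm = n_perm, alpha = alpha,
                         tail = "two.sided", times = times, seed = seed)
  }
  res
}

#' Per-participant peak latency of a decoding curve
#'
#' The latency of each participant's maximum within a window (the intervals
#' where group decoding exceeds chance: 60-235 ms for color, 160-200 ms for
#' category in the reference analysis). Ties are broken to the earliest
#' time.
#'
#' @param curves matrix participants x time, or tidy tibble (`participant`,
#'   `time_s`, `auc`).
#' @param window numeric length-2 window in the units of `times`.
#' @param times time axis, one value per column (required for matrices).
#' @return tibble with `participant` and `peak_time`.
#' @export
peak_latencies <- function(curves, window, times = NULL) {
  if (is.data.frame(curves)) {
    wide <- tidyr::pivot_wider(curves[, c("participant", "time_s", "auc")],
                               names_from = "time_s", values_from = "auc")
    times <- as.numeric(names(wide)[-1])
    participants <- wide$participant
    curves <- as.matrix(wide[, -1])
  } else {
    participants <- seq_len(nrow(curves))
    if (is.null(times)) times <- seq_len(ncol(curves))
  }
  sel <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(sel) == 0) stop("empty peak window")
  tibble(
    participant = participants,
    peak_time = times[sel][apply(curves[, sel, drop = FALSE], 1, which.max)]
  )
}

#' Paired t test with effect size and confidence interval
#'
#' Two-tailed paired t test computed from first principles:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = a - b`, p from the Student t
#' distribution with `n - 1` degrees of freedom, Cohen's d as
#' `mean(d) / sd(d)`, and the 95% CI of the mean difference.
#'
#' @param a,b paired numeric vectors (`n >= 3`).
#' @param conf confidence level for the CI.
#' @return one-row tibble: `n`, `mean_diff`, `sd_diff`, `t`, `df`, `p`,
#'   `cohen_d`, `ci_lo`, `ci_hi`.
#' @export
paired_ttest <- function(a, b, conf = 0.95) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) stop("need at least 3 complete pairs")
  s <- sd(d)
  if (s == 0) stop("undefined t statistic: zero variance of differences")
  m <- mean(d)
  t <- m / (s / sqrt(n))
  df <- n - 1
  p <- 2 * pt(-abs(t), df)
  ci <- m + c(-1, 1) * qt(1 - (1 - conf) / 2, df) * s / sqrt(n)
  tibble(n = n, mean_diff = m, sd_diff = s, t = t, df = df, p = p,
         cohen_d = m / s, ci_lo = ci[1], ci_hi = ci[2])
}

#' JZS Bayes factor for a one-sample / paired t statistic
#'
#' Jeffreys-Zellner-Siow Bayes factor BF10 for a (paired) t test, with a
#' Cauchy prior of scale `prior_scale` on the standardized effect size,
#' computed by numerical integration of the non-central t likelihood over
#' the prior:
#' `BF10 = [integral dt(t; df, ncp = delta * sqrt(n)) Cauchy(delta; 0, r) d delta] / dt(t; df, 0)`.
#' Values above 1 favor the alternative; below 1 the null.
#'
#' @param t observed t statistic.
#' @param n number of (pairs of) observations (`df = n - 1`).
#' @param prior_scale Cauchy prior scale r (0.707 = sqrt(2)/2, the
#'   conventional default).
#' @return the Bayes factor BF10 (scalar).
#' @examples
#' jzs_bf10(5.12, 36) # ~1.85e3: decisive evidence
#' jzs_bf10(1.33, 36) # ~0.4: anecdotal evidence for the null
#' @export
jzs_bf10 <- function(t, n, prior_scale = 0.707) {
  stopifnot(is.finite(t), n >= 2)
  df <- n - 1
  f <- function(delta) {
    dt(t, df = df, ncp = delta * sqrt(n)) * dcauchy(delta, 0, prior_scale)
  }
  # dt(ncp) warns about precision in the far tails; harmless at these scales
  num <- suppressWarnings(integrate(f, 0, Inf, rel.tol = 1e-9,
                                    stop.on.error = FALSE))
  num2 <- suppressWarnings(integrate(f, -Inf, 0, rel.tol = 1e-9,
                                     stop.on.error = FALSE))
  if (num$message != "OK" && num2$message != "OK") {
    stop("Bayes factor integral did not converge")
  }
  (num$value + num2$value) / dt(t, df = df)
}

#' Peak-latency contrast between two conditions
#'
#' Pairs each participant's peak latency in condition A with condition B,
#' tests the differences against zero with [paired_ttest()], and quantifies
#' the evidence with the JZS Bayes factor ([jzs_bf10()]).
#'
#' @param lat_a,lat_b numeric vectors of per-participant latencies (same
#'   participants, same order), or tibbles from [peak_latencies()].
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @return one-row tibble: the [paired_ttest()] columns plus `bf10`.
#' @export
latency_contrast <- function(lat_a, lat_b, prior_scale = 0.707) {
  if (is.data.frame(lat_a)) lat_a <- lat_a$peak_time
  if (is.data.frame(lat_b)) lat_b <- lat_b$peak_time
  res <- paired_ttest(lat_a, lat_b)
  res$bf10 <- jzs_bf10(res$t, res$n, prior_scale)
  res
}
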