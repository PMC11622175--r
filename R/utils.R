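# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child seed derivation (Lehmer step), kept under 2^31.
derive_seed <- function(seed, i) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.double(seed) * 48271 + 11 * as.double(i)) %% 2147483647)
}

# Merge spans (two-column matrix / data.frame onset, offset) closer than `gap`.
merge_spans <- function(onset, offset, gap = 0) {
  if (length(onset) == 0L) {
    return(list(onset = numeric(0), offset = numeric(0)))
  }
  o <- order(onset)
  onset <- onset[o]
  offset <- offset[o]
  keep_on <- onset[1]
  keep_off <- offset[1]
  res_on <- numeric(0)
  res_off <- numeric(0)
  for (i in seq_along(onset)[-1]) {
    if (onset[i] - keep_off <= gap) {
      keep_off <- max(keep_off, offset[i])
    } else {
      res_on <- c(res_on, keep_on)
      res_off <- c(res_off, keep_off)
      keep_on <- onset[i]
      keep_off <- offset[i]
    }
  }
  list(onset = c(res_on, keep_on), offset = c(res_off, keep_off))
}

# Contiguous runs of TRUE in a logical vector -> start/end indices.
logical_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(start = starts[keep], end = ends[keep])
}

# Gaussian bump / smoothed plateau temporal kernels on a time axis in ms,
# unit peak amplitude.
temporal_kernel <- function(t_ms, latency_ms, width_ms, sustained = FALSE) {
  if (sustained) {
    edge <- 10 # ms, softness of the plateau edges
    k <- plogis((t_ms - latency_ms) / edge) *
      plogis(-(t_ms - latency_ms - width_ms) / edge)
    pmin(k / plogis(width_ms / (2 * edge))^2, 1)
  } else {
    sd <- width_ms / 2.355 # width taken as FWHM
    exp(-0.5 * ((t_ms - latency_ms) / sd)^2)
  }
}
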