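# Internal numeric helpers shared by the ethogram and photometry code.

# Centered moving average of width `w` (odd); windows shrink at the edges so
# the output has the same length as the input and no NA padding.
moving_average <- function(x, w) {
  stopifnot(w >= 1L, w %% 2L == 1L)
  n <- length(x)
  if (w == 1L || n == 1L) return(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Central-difference derivative scaled to per-second units; one-sided
# differences at the two endpoints.
central_diff <- function(x, fs) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  v <- numeric(n)
  v[1L] <- (x[2L] - x[1L]) * fs
  v[n] <- (x[n] - x[n - 1L]) * fs
  if (n > 2L) {
    idx <- 2:(n - 1L)
    v[idx] <- (x[idx + 1L] - x[idx - 1L]) * fs / 2
  }
  v
}

# Linearly interpolate samples whose confidence falls below `min_conf`;
# constant extrapolation at the ends.  Returns x unchanged when nothing is
# below threshold.
interp_low_confidence <- function(x, conf, min_conf) {
  bad <- conf < min_conf
  if (!any(bad)) return(x)
  good <- which(!bad)
  if (length(good) == 0L) {
    abort("all samples below the confidence threshold; track unusable")
  }
  out <- x
  out[bad] <- approx(good, x[good], xout = which(bad), rule = 2)$y
  out
}

# Longest run of TRUE in a logical vector, in elements.
longest_run <- function(mask) {
  if (!any(mask)) return(0L)
  r <- rle(mask)
  max(r$lengths[r$values])
}

# Run-length intervals of TRUE frames as half-open [start, end) 0-based
# frame spans.
mask_to_intervals <- function(mask) {
  n <- length(mask)
  if (n == 0L || !any(mask)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

# Merge intervals whose gap (next start minus previous end, frames) is
# strictly below `max_gap` frames.
merge_intervals <- function(iv, max_gap) {
  if (nrow(iv) <= 1L) return(iv)
  start <- iv$start
  end <- iv$end
  out_s <- start[1L]
  out_e <- end[1L]
  for (i in 2:nrow(iv)) {
    if (start[i] - out_e[length(out_e)] < max_gap) {
      out_e[length(out_e)] <- end[i]
    } else {
      out_s <- c(out_s, start[i])
      out_e <- c(out_e, end[i])
    }
  }
  tibble::tibble(start = out_s, end = out_e)
}

# Sample z-score (n-1 denominator); errors on zero variance.
zscore <- function(x, what = "component") {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort(paste0("zero variance in ", what, "; z-score undefined"))
  }
  (x - mean(x)) / s
}

# Draw a 31-bit sub-seed stream deterministically from the current RNG state.
derive_seeds <- function(n) {
  sample.int(.Machine$integer.max, n)
}
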