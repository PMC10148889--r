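# Independent reference implementations used to check the package's
# vectorized code paths.  Everything here is written with plain loops and
# first-principles formulas, deliberately sharing no code with R/.

# --- frame-wise ethogram oracle ------------------------------------------

oracle_smooth <- function(x, w) {
  n <- length(x)
  half <- (w - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

oracle_velocity <- function(x, fs) {
  n <- length(x)
  v <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1) v[i] <- (x[2] - x[1]) * fs
    else if (i == n) v[i] <- (x[n] - x[n - 1]) * fs
    else v[i] <- (x[i + 1] - x[i - 1]) * fs / 2
  }
  v
}

oracle_runs <- function(mask) {
  runs <- list()
  i <- 1; n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(start = i - 1, end = j) # half-open 0-based
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

oracle_merge <- function(runs, max_gap) {
  if (length(runs) <= 1) return(runs)
  out <- list(runs[[1]])
  for (k in 2:length(runs)) {
    last <- out[[length(out)]]
    if (runs[[k]]["start"] - last["end"] < max_gap) {
      last["end"] <- runs[[k]]["end"]
      out[[length(out)]] <- last
    } else out[[length(out) + 1]] <- runs[[k]]
  }
  out
}

# Full loop-based reimplementation of the interval classifier: per-frame
# predicate evaluation, run-length encoding, merging, duration and
# displacement filters, in the same staged order as the spec of the rules.
oracle_classify <- function(bout, config = ethogram_config()) {
  fps <- bout$fps
  mice <- bout$mice
  tracks <- lapply(mice, function(m) {
    tr <- bout$tracks[bout$tracks$mouse == m, ]
    tr <- tr[order(tr$frame), ]
    nose <- oracle_smooth(tr$nose_x, config$smooth_frames)
    tail <- oracle_smooth(tr$tail_x, config$smooth_frames)
    f <- unname(bout$facing[m])
    list(nose = nose, tail = tail,
         v_nose = f * oracle_velocity(nose, fps),
         v_tail = f * oracle_velocity(tail, fps),
         s_tail = f * tail)
  })
  names(tracks) <- mice
  n <- bout$n_frames
  min_frames_ok <- function(r) (r["end"] - r["start"]) / fps >= config$min_event_s - 1e-9
  gap <- config$merge_gap_s * fps

  retreat_runs <- list(); retreat_mask <- list()
  for (m in mice) {
    tk <- tracks[[m]]
    runs <- oracle_merge(oracle_runs(tk$v_tail <= config$v_retreat_cm_s), gap)
    keep <- list()
    for (r in runs) {
      disp <- tk$s_tail[r["start"] + 1] - tk$s_tail[r["end"]]
      if (disp >= config$d_min_retreat_cm - 1e-9 && min_frames_ok(r)) {
        keep[[length(keep) + 1]] <- r
      }
    }
    retreat_runs[[m]] <- keep
    msk <- rep(FALSE, n)
    for (r in keep) msk[(r["start"] + 1):r["end"]] <- TRUE
    retreat_mask[[m]] <- msk
  }

  overlap <- abs(tracks[[mice[1]]]$nose - tracks[[mice[2]]]$nose) <=
    config$nose_overlap_cm

  ev <- list()
  push_runs <- list()
  for (m in mice) {
    p <- setdiff(mice, m)
    tk <- tracks[[m]]
    body <- logical(n); nose <- logical(n)
    for (i in seq_len(n)) {
      body[i] <- tk$v_nose[i] >= config$v_push_cm_s &&
        tk$v_tail[i] >= config$v_push_cm_s && overlap[i] && !retreat_mask[[p]][i]
      nose[i] <- tk$v_nose[i] >= config$v_push_cm_s && overlap[i] &&
        !retreat_mask[[p]][i] && !body[i]
    }
    b_runs <- Filter(min_frames_ok, oracle_merge(oracle_runs(body), gap))
    n_runs <- Filter(min_frames_ok, oracle_merge(oracle_runs(nose), gap))
    push_runs[[m]] <- c(lapply(b_runs, function(r) c(r, lab = 1)),
                        lapply(n_runs, function(r) c(r, lab = 2)))
    for (r in b_runs) ev[[length(ev) + 1]] <-
      data.frame(label = "body_push", actor = m, start = r[["start"]], end = r[["end"]])
    for (r in n_runs) ev[[length(ev) + 1]] <-
      data.frame(label = "nose_push", actor = m, start = r[["start"]], end = r[["end"]])
    for (r in retreat_runs[[m]]) ev[[length(ev) + 1]] <-
      data.frame(label = "retreat", actor = m, start = r[["start"]], end = r[["end"]])
  }
  for (m in mice) {
    p <- setdiff(mice, m)
    for (r in push_runs[[p]]) {
      net <- abs(tracks[[m]]$s_tail[r[["end"]]] - tracks[[m]]$s_tail[r[["start"]] + 1])
      if (net < config$d_min_retreat_cm) {
        ev[[length(ev) + 1]] <- data.frame(label = "resist", actor = m,
                                           start = r[["start"]], end = r[["end"]])
      }
    }
  }
  if (!length(ev)) {
    return(data.frame(label = character(), actor = character(),
                      start_frame = integer(), end_frame = integer(),
                      start_s = numeric(), duration_s = numeric()))
  }
  df <- do.call(rbind, ev)
  df <- data.frame(label = df$label, actor = df$actor,
                   start_frame = as.integer(df$start),
                   end_frame = as.integer(df$end),
                   start_s = df$start / fps,
                   duration_s = (df$end - df$start) / fps)
  df[order(df$start_frame, df$actor, df$label), , drop = FALSE]
}

# --- numeric oracles ------------------------------------------------------

oracle_sliding_median <- function(x, fs, window_s = 10) {
  n <- length(x)
  k <- floor(window_s / 2 * fs + 1e-9)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - k):min(n, i + k)]
    out[i] <- (x[i] - median(w)) / median(w)
  }
  out
}

oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  dof <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tstat, df = dof, p = 2 * pt(-abs(tstat), dof))
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins; tables with probability <= observed (with the
# conventional relative tolerance) contribute.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  obs <- dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Event matching for precision/recall: greedy one-to-one match on label,
# actor and onset proximity.
match_events <- function(found, truth, tol_s = 0.2) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0
  if (nrow(found)) for (i in seq_len(nrow(found))) {
    cand <- which(!used & truth$label == found$label[i] &
                    truth$actor == found$actor[i] &
                    abs(truth$start_s - found$start_s[i]) <= tol_s + 1e-9)
    if (length(cand)) {
      used[cand[1]] <- TRUE
      tp <- tp + 1
    }
  }
  list(tp = tp, fp = nrow(found) - tp, fn = nrow(truth) - tp)
}

# Precision/recall for one label over lists of ethograms and truth tables.
label_pr <- function(ethograms, truths, label) {
  tp <- fp <- fn <- 0
  for (i in seq_along(ethograms)) {
    f <- as.data.frame(ethograms[[i]])
    f <- f[f$label == label, , drop = FALSE]
    tr <- as.data.frame(truths[[i]])
    tr <- tr[tr$label == label, , drop = FALSE]
    m <- match_events(f, tr)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  c(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn))
}
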