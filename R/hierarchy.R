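#' Detect the winner of a tube-test bout
#'
#' A mouse loses when its tailbase exits the tube span on its own entry side
#' by more than `win_margin_cm` while the partner's tailbase is still inside
#' the span; the first such frame decides.  Tailbase exit stands in for the
#' full-retreat criterion (both rear paws on the ground outside the tube),
#' since rear paws are not tracked keypoints.  A mouse's entry side is the
#' end behind it: the low-`x` end when `facing = +1`, the high-`x` end when
#' `facing = -1`.
#'
#' @inheritParams compute_velocity
#' @return A one-row tibble: `winner`, `loser` (NA if no exit), `exit_frame`,
#'   and `flag` (`"both_exited"` when both tails leave the span on the same
#'   frame, `"none"` otherwise).
#' @export
detect_win <- function(bout, config = ethogram_config()) {
  stopifnot(inherits(bout, "tube_bout"))
  a <- bout$mice[1]; b <- bout$mice[2]
  margin <- config$win_margin_cm
  exit_mask <- function(m) {
    tr <- bout_track(bout, m)
    if (unname(bout$facing[m]) > 0) {
      tr$tail_x < bout$x0 - margin
    } else {
      tr$tail_x > bout$x1 + margin
    }
  }
  inside_mask <- function(m) {
    tr <- bout_track(bout, m)
    tr$tail_x >= bout$x0 & tr$tail_x <= bout$x1
  }
  out_a <- exit_mask(a); out_b <- exit_mask(b)
  in_a <- inside_mask(a); in_b <- inside_mask(b)
  none <- tibble::tibble(winner = NA_character_, loser = NA_character_,
                         exit_frame = NA_integer_, flag = "none")
  raw_a <- if (any(out_a)) which(out_a)[1L] else Inf
  raw_b <- if (any(out_b)) which(out_b)[1L] else Inf
  if (is.finite(raw_a) && raw_a == raw_b) {
    none$flag <- "both_exited"
    return(none)
  }
  lose_a <- out_a & in_b
  lose_b <- out_b & in_a
  fa <- if (any(lose_a)) which(lose_a)[1L] else Inf
  fb <- if (any(lose_b)) which(lose_b)[1L] else Inf
  if (is.infinite(fa) && is.infinite(fb)) return(none)
  if (fa < fb) {
    tibble::tibble(winner = b, loser = a,
                   exit_frame = as.integer(fa - 1L), flag = "none")
  } else {
    tibble::tibble(winner = a, loser = b,
                   exit_frame = as.integer(fb - 1L), flag = "none")
  }
}

#' Rank a cage from one day of round-robin outcomes
#'
#' Mice are ranked by descending win count (rank 1 = most wins).  A two-way
#' tie on wins is broken by the head-to-head outcome between the tied pair;
#' any remaining tie is left as a shared (minimum) rank and flagged
#' unresolved.
#'
#' @param outcomes A data frame with columns `winner` and `loser`, one row
#'   per decided bout for a cage-day.
#' @param mice Optional character vector of all cage members (so that mice
#'   with zero wins are still ranked).  Defaults to the ids appearing in
#'   `outcomes`.
#' @return A tibble with `mouse`, `wins`, `rank`, `tie_flag`, plus an
#'   attribute `complete_round_robin` (every pair met exactly once).
#' @export
rank_cage <- function(outcomes, mice = NULL) {
  outcomes <- tibble::as_tibble(outcomes)
  if (is.null(mice)) mice <- sort(unique(c(outcomes$winner, outcomes$loser)))
  wins <- setNames(rep(0L, length(mice)), mice)
  tab <- table(factor(outcomes$winner, levels = mice))
  wins[names(tab)] <- as.integer(tab)

  ord <- order(-wins, mice)
  res <- tibble::tibble(mouse = mice[ord], wins = unname(wins[ord]),
                        rank = NA_integer_, tie_flag = FALSE)
  # competition ranks by win count, then tie handling within win-count groups
  pos <- 1L
  for (w in unique(res$wins)) {
    idx <- which(res$wins == w)
    if (length(idx) == 1L) {
      res$rank[idx] <- pos
    } else if (length(idx) == 2L) {
      pair <- res$mouse[idx]
      h2h <- outcomes[(outcomes$winner == pair[1] & outcomes$loser == pair[2]) |
                        (outcomes$winner == pair[2] & outcomes$loser == pair[1]), ]
      if (nrow(h2h) == 1L) {
        first <- h2h$winner[1L]
        res$rank[idx[res$mouse[idx] == first]] <- pos
        res$rank[idx[res$mouse[idx] != first]] <- pos + 1L
      } else {
        res$rank[idx] <- pos
        res$tie_flag[idx] <- TRUE
      }
    } else {
      res$rank[idx] <- pos
      res$tie_flag[idx] <- TRUE
    }
    pos <- pos + length(idx)
  }
  n <- length(mice)
  pairs_seen <- nrow(outcomes)
  attr(res, "complete_round_robin") <- pairs_seen == choose(n, 2) &&
    !anyDuplicated(t(apply(cbind(outcomes$winner, outcomes$loser), 1L, sort)))
  if (!isTRUE(attr(res, "complete_round_robin"))) {
    warn("outcomes do not form a complete round robin")
  }
  res
}

#' First day of a stable hierarchy
#'
#' A hierarchy is considered stable once every mouse's rank is identical for
#' four consecutive days.
#'
#' @param tables A data frame with columns `day`, `mouse`, `rank` covering
#'   consecutive days for one cage.
#' @param run_length Number of identical consecutive days required
#'   (default 4).
#' @return The smallest day `d` such that ranks on days `d .. d+run_length-1`
#'   are identical, or `NA` if none.
#' @export
assess_stability <- function(tables, run_length = 4L) {
  tables <- tibble::as_tibble(tables)
  days <- sort(unique(tables$day))
  members <- lapply(days, function(d) sort(tables$mouse[tables$day == d]))
  if (length(unique(members)) != 1L) {
    abort("cage membership differs across days")
  }
  ranks_by_day <- lapply(days, function(d) {
    td <- tables[tables$day == d, ]
    setNames(td$rank, td$mouse)[members[[1L]]]
  })
  if (length(days) < run_length) return(NA_integer_)
  for (i in seq_len(length(days) - run_length + 1L)) {
    same <- all(vapply(seq_len(run_length - 1L), function(k) {
      identical(unname(ranks_by_day[[i]]), unname(ranks_by_day[[i + k]]))
    }, logical(1)))
    if (same) return(as.integer(days[i]))
  }
  NA_integer_
}
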