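#' Sample a fixed-size action window around a time mark
#'
#' Takes the `k` actions immediately before the mark and the `k` actions
#' immediately at-or-after it (an action timestamped exactly at the mark
#' belongs to the "after" half), concatenated in stream order. Using a
#' fixed 2k-action window makes sequence-diversity statistics comparable
#' across players of different speeds, who would otherwise trivially
#' differ in unique-sequence counts. A game that cannot supply both
#' halves is excluded.
#'
#' @param game Single-game action tibble with `t_ms` and `action_type`.
#' @param mark Time mark in ms; default 600000 (the ten-minute mark).
#' @param k Actions per side; default 200.
#' @return Character vector of `2 * k` action types, or `NULL` when the
#'   game is too short on either side.
#' @export
sample_window <- function(game, mark = 600000, k = 200) {
  before <- which(game$t_ms < mark)
  after <- which(game$t_ms >= mark)
  if (length(before) < k || length(after) < k) return(NULL)
  idx <- c(before[(length(before) - k + 1):length(before)], after[1:k])
  game$action_type[idx]
}

#' Unique-sequence diversity statistic
#'
#' The number of distinct sliding (overlapping) subsequences of lengths
#' 2, 3 and 4 within a sample, summed. A constant stream scores exactly
#' 3 (one unique sequence per length); a maximally varied stream scores
#' close to `(m - 1) + (m - 2) + (m - 3)` for a sample of `m` actions.
#'
#' @param sample Character vector of action types, length at least 4.
#' @return Integer count of distinct length-2, length-3 and length-4
#'   subsequences, summed.
#' @export
unique_sequence_count <- function(sample) {
  m <- length(sample)
  if (m < 4) stop("sample must contain at least 4 actions")
  total <- 0L
  for (L in 2:4) {
    w <- sample[1:(m - L + 1)]
    for (j in 2:L) w <- paste(w, sample[j:(m - L + j)], sep = "-")
    total <- total + length(unique(w))
  }
  total
}

#' Permutation baseline of the diversity statistic
#'
#' The diversity statistic S expected if the player had arranged the
#' same multiset of actions in random order: `reps` seeded uniform
#' permutations of the sample are scored with
#' [unique_sequence_count()] and averaged. The permutation standard
#' deviation is attached as attribute `"sd_S"`.
#'
#' @param sample Character vector of action types.
#' @param reps Number of permutations; default 100.
#' @param seed Integer seed.
#' @return Mean of S over the permutations (`mean_S`), with attributes
#'   `"sd_S"` and `"S"` (the per-permutation values).
#' @export
permutation_baseline <- function(sample, reps = 100, seed = 1L) {
  S <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      unique_sequence_count(sample[sample.int(length(sample))])
    }, 0L)
  })
  out <- mean(S)
  attr(out, "sd_S") <- stats::sd(S)
  attr(out, "S") <- S
  out
}

#' Sequence randomness statistic of one game
#'
#' `randomness = G - mean(S)`: the observed unique-sequence count G of
#' the 2k-action window around the mark, minus the average count over
#' `reps` random permutations of the same actions. Near zero when the
#' player sequenced actions close to randomly; strongly negative when
#' behaviour was repetitive (few unique sequences).
#'
#' @param game Single-game action tibble.
#' @inheritParams sample_window
#' @inheritParams permutation_baseline
#' @return One-row tibble `G, mean_S, sd_S, randomness`, or `NULL` when
#'   the game is excluded by [sample_window()].
#' @export
randomness_statistic <- function(game, mark = 600000, k = 200,
                                 reps = 100, seed = 1L) {
  sample <- sample_window(game, mark = mark, k = k)
  if (is.null(sample)) return(NULL)
  G <- unique_sequence_count(sample)
  base <- permutation_baseline(sample, reps = reps, seed = seed)
  sd_s <- attr(base, "sd_S")
  base <- as.numeric(base)
  tibble::tibble(G = G, mean_S = base, sd_S = sd_s, randomness = G - base)
}

#' Randomness statistics for every game of an action table
#'
#' @param actions Multi-game action tibble.
#' @inheritParams randomness_statistic
#' @param seed Master seed; each game's permutation stream uses a seed
#'   derived from it and the game's position, so results are reproducible
#'   and independent across games.
#' @return Tibble `game_id, G, mean_S, sd_S, randomness, excluded`; rows
#'   for excluded games carry `excluded = TRUE` and `NA` statistics.
#' @export
cohort_diversity <- function(actions, mark = 600000, k = 200,
                             reps = 100, seed = 1L) {
  ids <- unique(actions$game_id)
  rows <- lapply(seq_along(ids), function(g) {
    res <- randomness_statistic(
      actions[actions$game_id == ids[g], , drop = FALSE],
      mark = mark, k = k, reps = reps, seed = seed + 1000L * g)
    if (is.null(res)) {
      tibble::tibble(game_id = ids[g], G = NA_integer_, mean_S = NA_real_,
                     sd_S = NA_real_, randomness = NA_real_, excluded = TRUE)
    } else {
      dplyr::bind_cols(tibble::tibble(game_id = ids[g]), res,
                       tibble::tibble(excluded = FALSE))
    }
  })
  dplyr::bind_rows(rows)
}
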