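#' Per-type baseline latencies of non-chunked actions
#'
#' For one annotated game, the mean latency of non-chunked actions of
#' each action type. Only actions with a defined latency (everything but
#' the game's first action) and `in_chunk = FALSE` enter; a type with no
#' eligible action has no baseline. Baselines are per game, never pooled
#' across games.
#'
#' @param game Annotated action tibble for a single game, with columns
#'   `action_type, latency_ms, in_chunk`.
#' @return Tibble `action_type, baseline_ms, n_used`.
#' @export
type_baselines <- function(game) {
  eligible <- game[!game$in_chunk & !is.na(game$latency_ms), , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(eligible, .data$action_type),
    baseline_ms = mean(.data$latency_ms),
    n_used = dplyr::n(),
    .groups = "drop"
  )
}

#' Per-action time savings of chunked actions
#'
#' The time saving of a chunked action is the same-type baseline latency
#' minus its actual latency; positive means the chunked action was
#' faster than a typical non-chunked action of its type. Chunked actions
#' whose type has no baseline, or whose latency is undefined (a game's
#' first action), are excluded and counted.
#'
#' @param game Annotated single-game tibble (see [type_baselines()]).
#' @param baselines Optional precomputed baselines; computed from `game`
#'   when omitted.
#' @return Tibble of the included chunked actions with columns `index`
#'   (row position in `game`), `action_type`, `latency_ms`,
#'   `is_first_action`, `savings_ms`; the number of excluded chunked
#'   actions is attached as attribute `"n_excluded"`.
#' @export
per_action_savings <- function(game, baselines = NULL) {
  if (is.null(baselines)) baselines <- type_baselines(game)
  chunked <- which(game$in_chunk)
  base <- baselines$baseline_ms[match(game$action_type[chunked],
                                      baselines$action_type)]
  lat <- game$latency_ms[chunked]
  ok <- !is.na(base) & !is.na(lat)
  out <- tibble::tibble(
    index = chunked[ok],
    action_type = game$action_type[chunked][ok],
    latency_ms = lat[ok],
    is_first_action = game$is_first_action[chunked][ok],
    savings_ms = base[ok] - lat[ok]
  )
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Overall time savings of one game, split by action role
#'
#' Sums per-action savings over the game, in seconds, split into the
#' contribution of first actions (classically slow, so typically
#' negative savings) and of subsequent within-chunk actions (classically
#' fast, so typically positive). The decomposition
#' `total = first + inter` holds exactly.
#'
#' @param game Annotated single-game tibble.
#' @return Tibble with one row: `total_savings_s, first_action_savings_s,
#'   inter_action_savings_s, n_chunked, n_excluded`.
#' @export
game_savings <- function(game) {
  sav <- per_action_savings(game)
  first_s <- sum(sav$savings_ms[sav$is_first_action]) / 1000
  inter_s <- sum(sav$savings_ms[!sav$is_first_action]) / 1000
  tibble::tibble(
    total_savings_s = first_s + inter_s,
    first_action_savings_s = first_s,
    inter_action_savings_s = inter_s,
    n_chunked = nrow(sav),
    n_excluded = attr(sav, "n_excluded")
  )
}

#' Time savings for every game of an annotated table
#'
#' @param annotations Annotated action tibble for many games (e.g. the
#'   `annotations` element of [detect_chunks()]).
#' @return Tibble with one row per game: `game_id` plus the columns of
#'   [game_savings()].
#' @export
cohort_savings <- function(annotations) {
  ids <- unique(annotations$game_id)
  rows <- lapply(ids, function(g) {
    dplyr::bind_cols(
      tibble::tibble(game_id = g),
      game_savings(annotations[annotations$game_id == g, , drop = FALSE]))
  })
  dplyr::bind_rows(rows)
}

#' Per-game mean latencies of chunk first actions vs within-chunk actions
#'
#' For every game with at least one chunked action having both roles
#' represented, the mean latency of chunk first actions and the mean
#' latency of subsequent within-chunk ("inter-action") latencies. These
#' per-game pairs feed a paired t-test of the classic chunk timing
#' signature (slow first action, fast followers).
#'
#' @param annotations Annotated multi-game action tibble.
#' @return Tibble `game_id, first_action_mean_ms, inter_action_mean_ms`;
#'   games without chunked actions are excluded and their number is
#'   attached as attribute `"n_excluded"`.
#' @export
first_vs_inter_summary <- function(annotations) {
  chunked <- annotations[annotations$in_chunk &
                           !is.na(annotations$latency_ms), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(chunked, .data$game_id),
    first_action_mean_ms = mean(.data$latency_ms[.data$is_first_action]),
    inter_action_mean_ms = mean(.data$latency_ms[!.data$is_first_action]),
    .groups = "drop"
  )
  keep <- is.finite(out$first_action_mean_ms) &
    is.finite(out$inter_action_mean_ms)
  n_all <- length(unique(annotations$game_id))
  res <- out[keep, , drop = FALSE]
  attr(res, "n_excluded") <- n_all - nrow(res)
  res
}

#' Mean inter-right-click latency of redundant click runs
#'
#' Detector-free latency probe: finds maximal runs of two or more
#' consecutive RightClick actions that contain no other action and are
#' punctuated on both sides by ScreenShift actions (a stream boundary
#' counts as a punctuating ScreenShift), then averages the latencies
#' within those runs, excluding each run's first click. Repeated
#' right-clicks after a screen shift are usually redundant commands, so
#' their speed tracks raw motor speed rather than strategy.
#'
#' @param game Single-game action tibble with `action_type, latency_ms`.
#' @return Mean within-run latency in ms, or `NA_real_` when no
#'   qualifying run exists.
#' @export
redundant_rightclick_latency <- function(game) {
  types <- game$action_type
  a <- length(types)
  if (a == 0) return(NA_real_)
  r <- rle(types)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  lats <- numeric(0)
  for (k in seq_along(r$values)) {
    if (r$values[k] != "RightClick" || r$lengths[k] < 2) next
    before_ok <- starts[k] == 1 || types[starts[k] - 1] == "ScreenShift"
    after_ok <- ends[k] == a || types[ends[k] + 1] == "ScreenShift"
    if (before_ok && after_ok) {
      within <- (starts[k] + 1):ends[k]
      lats <- c(lats, game$latency_ms[within])
    }
  }
  lats <- lats[!is.na(lats)]
  if (length(lats) == 0) return(NA_real_)
  mean(lats)
}
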