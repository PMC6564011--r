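#' Read a canonical action-log CSV
#'
#' Reads a timestamped action log with columns `game_id, league, species,
#' t_ms, action_type`, validates it, and computes per-action latencies.
#' One row is one action by one player in one game; `t_ms` is the
#' timestamp in integer milliseconds from game start and `action_type`
#' must be one of the seven values of [action_types()].
#'
#' The latency of an action is the time elapsed since the same game's
#' previous action, `t(i) - t(i-1)`; the first action of every game has
#' latency `NA`, never zero, and is excluded from every latency mean
#' downstream.
#'
#' @param path Path to a CSV file (UTF-8, header required).
#' @param sort If `TRUE`, rows are sorted by `t_ms` within each game
#'   (stable, preserving input order on ties); if `FALSE` (default),
#'   non-monotone timestamps are an error.
#' @param frame_rate Optional frames-per-second rate. When supplied, the
#'   `t_ms` column is interpreted as frame counts and converted to
#'   milliseconds via `round(t * 1000 / frame_rate)`.
#' @return A tibble of actions with columns `game_id, league, species,
#'   t_ms, action_type, latency_ms`, ordered by game and time.
#' @export
read_action_log <- function(path, sort = FALSE, frame_rate = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      game_id = readr::col_character(),
      league = readr::col_integer(),
      species = readr::col_character(),
      t_ms = readr::col_double(),
      action_type = readr::col_character()
    )
  )
  if (!is.null(frame_rate)) {
    stopifnot(is.numeric(frame_rate), frame_rate > 0)
    raw$t_ms <- round(raw$t_ms * 1000 / frame_rate)
  }
  validate_actions(raw, sort = sort)
}

#' Validate an in-memory action table and compute latencies
#'
#' @param actions Data frame with at least `game_id, t_ms, action_type`.
#' @inheritParams read_action_log
#' @return A tibble with latencies computed per game (see
#'   [read_action_log()]).
#' @export
validate_actions <- function(actions, sort = FALSE) {
  actions <- tibble::as_tibble(actions)
  needed <- c("game_id", "t_ms", "action_type")
  missing_cols <- setdiff(needed, names(actions))
  if (length(missing_cols) > 0) {
    stop("action table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!actions$action_type %in% action_types())
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown action_type %s at row %d (of %d offending rows)",
      dQuote(actions$action_type[bad[1]]), bad[1], length(bad)
    ))
  }
  if (any(actions$t_ms < 0, na.rm = TRUE)) {
    stop("timestamps must be non-negative")
  }
  # keep input order within a game as the tie/stability convention
  ord <- order(match(actions$game_id, unique(actions$game_id)))
  actions <- actions[ord, , drop = FALSE]
  if (sort) {
    actions <- dplyr::group_by(actions, .data$game_id)
    actions <- dplyr::arrange(actions, .data$t_ms, .by_group = TRUE)
    actions <- dplyr::ungroup(actions)
  } else {
    nonmono <- dplyr::summarise(
      dplyr::group_by(actions, .data$game_id),
      bad = any(diff(.data$t_ms) < 0),
      .groups = "drop"
    )
    if (any(nonmono$bad)) {
      stop("non-monotone timestamps in game(s): ",
           paste(nonmono$game_id[nonmono$bad], collapse = ", "),
           " (use sort = TRUE to reorder)")
    }
  }
  compute_latencies(actions)
}

#' Compute per-action latencies within each game
#'
#' @param actions Action tibble ordered by time within game.
#' @return The same tibble with a recomputed `latency_ms` column:
#'   `t_ms(i) - t_ms(i-1)` within a game, `NA` for each game's first
#'   action. Latencies are never computed across game boundaries.
#' @export
compute_latencies <- function(actions) {
  actions <- tibble::as_tibble(actions)
  actions$latency_ms <- NULL
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(actions, .data$game_id),
    latency_ms = .data$t_ms - dplyr::lag(.data$t_ms)
  ))
}

#' Write an action table to the canonical CSV
#'
#' Writes `game_id, league, species, t_ms, action_type` (the latency
#' column is derived, so it is not stored). Reading the file back with
#' [read_action_log()] reproduces the table field for field.
#'
#' @param actions Action tibble as produced by [read_action_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_action_log <- function(actions, path) {
  cols <- intersect(c("game_id", "league", "species", "t_ms", "action_type"),
                    names(actions))
  readr::write_csv(actions[, cols], path)
  invisible(path)
}

#' Aggregate raw screen samples into ScreenShift actions (I-DT)
#'
#' Dispersion-threshold identification of screen fixations: a maximal
#' window of consecutive samples whose dispersion
#' `(max(x) - min(x)) + (max(y) - min(y))` stays at or below
#' `dispersion_threshold` and whose duration is at least `min_duration`
#' is a fixation. One `ScreenShift` action is emitted at the onset (the
#' timestamp of the first sample) of each fixation; the movement between
#' two fixations is represented by the next fixation's onset event.
#'
#' The threshold defaults are uncalibrated placeholders: sensible
#' starting points for map-unit coordinates, but any serious use should
#' set them from the instrument's geometry.
#'
#' @param raw Data frame of raw screen samples with columns `t_ms, x, y`,
#'   sorted by `t_ms`.
#' @param dispersion_threshold Maximum dispersion of a fixation window, in
#'   the coordinate units of `x` and `y`. Default 2.0.
#' @param min_duration Minimum fixation duration in milliseconds.
#'   Default 250.
#' @return Tibble with columns `t_ms, action_type` ("ScreenShift"), one
#'   row per fixation onset.
#' @export
aggregate_fixations <- function(raw, dispersion_threshold = 2.0,
                                min_duration = 250) {
  if (dispersion_threshold <= 0 || min_duration <= 0) {
    stop("dispersion_threshold and min_duration must be positive")
  }
  stopifnot(nrow(raw) > 0, all(c("t_ms", "x", "y") %in% names(raw)))
  if (is.unsorted(raw$t_ms)) stop("raw screen samples must be sorted by t_ms")
  t <- raw$t_ms; x <- raw$x; y <- raw$y
  n <- length(t)
  onsets <- numeric(0)
  i <- 1L
  while (i <= n) {
    # grow the window from i for as long as dispersion stays under threshold
    xmin <- x[i]; xmax <- x[i]; ymin <- y[i]; ymax <- y[i]
    j <- i
    while (j < n) {
      nxmin <- min(xmin, x[j + 1L]); nxmax <- max(xmax, x[j + 1L])
      nymin <- min(ymin, y[j + 1L]); nymax <- max(ymax, y[j + 1L])
      if ((nxmax - nxmin) + (nymax - nymin) > dispersion_threshold) break
      xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      j <- j + 1L
    }
    if (t[j] - t[i] >= min_duration) {
      onsets <- c(onsets, t[i])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  tibble::tibble(t_ms = onsets, action_type = "ScreenShift")
}

#' Merge key actions with ScreenShift events into one stream
#'
#' Interleaves two time-sorted streams into a single stream and
#' recomputes latencies on the merged stream. On an exact timestamp tie
#' the key action is placed before the screen shift (a fixed convention
#' so that downstream n-grams are deterministic).
#'
#' @param key_actions Tibble of keyboard/mouse actions with `t_ms` and
#'   `action_type` (plus any metadata columns).
#' @param screen_shifts Tibble of ScreenShift actions with `t_ms` and
#'   `action_type`, e.g. from [aggregate_fixations()].
#' @return Merged tibble sorted by `t_ms` with recomputed `latency_ms`.
#'   Metadata columns (`game_id`, `league`, `species`) present on
#'   `key_actions` are filled onto the screen events.
#' @export
merge_streams <- function(key_actions, screen_shifts) {
  key_actions <- tibble::as_tibble(key_actions)
  screen_shifts <- tibble::as_tibble(screen_shifts)
  if (is.unsorted(key_actions$t_ms) || is.unsorted(screen_shifts$t_ms)) {
    stop("both streams must be sorted by t_ms")
  }
  for (col in c("game_id", "league", "species")) {
    if (col %in% names(key_actions) && !col %in% names(screen_shifts) &&
        nrow(screen_shifts) > 0) {
      screen_shifts[[col]] <- key_actions[[col]][1]
    }
  }
  key_actions$.src <- 0L
  screen_shifts$.src <- 1L
  merged <- dplyr::bind_rows(key_actions, screen_shifts)
  merged <- merged[order(merged$t_ms, merged$.src), , drop = FALSE]
  merged$.src <- NULL
  if (!"game_id" %in% names(merged)) merged$game_id <- "game"
  compute_latencies(merged)
}
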