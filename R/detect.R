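#' Partition an action sequence into non-overlapping n-gram tiles
#'
#' Tiles start at positions 0, n, 2n, ... of the stream; a trailing
#' remainder of fewer than `n` actions is discarded. For example the
#' sequence XYXY tiles into the two bigrams XY and XY.
#'
#' @param actions Character vector of action types.
#' @param n Tile length, one of 2, 3 or 4.
#' @return Tibble with columns `start_index` (0-based position of the
#'   tile's first action) and `ngram` (dash-joined action types).
#' @export
tile_ngrams <- function(actions, n) {
  stopifnot(n %in% 2:4)
  n_tiles <- floor(length(actions) / n)
  if (n_tiles == 0) {
    return(tibble::tibble(start_index = integer(0), ngram = character(0)))
  }
  idx <- matrix(seq_len(n_tiles * n), nrow = n)
  tibble::tibble(
    start_index = as.integer((seq_len(n_tiles) - 1L) * n),
    ngram = apply(matrix(actions[idx], nrow = n), 2, paste, collapse = "-")
  )
}

#' Drop tiles containing artifactual repeats
#'
#' A tile is dropped if and only if it contains two immediately adjacent
#' identical actions whose type is RightClick, Train or HotkeySelect.
#' These actions occur in long uninterrupted strings that are either
#' artifactual (held-down keys) or carry abnormally low latencies, so
#' tiles containing such repeats are excluded from the over-representation
#' test. Other repeats (e.g. Select-Select) are retained.
#'
#' @param tiles Tile tibble from [tile_ngrams()].
#' @return The retained tiles, original `start_index` values preserved.
#' @export
filter_repeat_tiles <- function(tiles) {
  pat <- vapply(repeat_drop_types(), function(tp) paste0(tp, "-", tp), "")
  drop <- rep(FALSE, nrow(tiles))
  for (p in pat) drop <- drop | grepl(p, tiles$ngram, fixed = TRUE)
  tiles[!drop, , drop = FALSE]
}

#' Split tiles into a training and a test set
#'
#' Seeded uniform random partition into halves; when the tile count is
#' odd the extra tile goes to the training set. The same seed always
#' yields the same partition.
#'
#' @param tiles Retained tile tibble.
#' @param seed Integer seed for the split.
#' @return List with elements `train` and `test`, each a tile tibble.
#' @export
split_train_test <- function(tiles, seed) {
  n_tiles <- nrow(tiles)
  if (n_tiles < 2) stop("need at least 2 tiles to split")
  perm <- withr::with_seed(seed, sample.int(n_tiles))
  n_train <- ceiling(n_tiles / 2)
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[-seq_len(n_train)])
  list(train = tiles[train_idx, , drop = FALSE],
       test = tiles[test_idx, , drop = FALSE])
}

#' Marginal action-type proportions of a game
#'
#' The proportion `p_i` of each of the seven action types among all `a`
#' actions of the game. Proportions are computed from the full stream,
#' before any tile is dropped, matching the definition of the detector's
#' null model: a player who picks one of the seven types at random `a`
#' times with these probabilities.
#'
#' @param actions Character vector of action types (the whole game).
#' @return Named numeric vector over the seven canonical types, summing
#'   to 1; types not present get proportion 0. The total count `a` is
#'   attached as attribute `"a"`.
#' @export
marginal_proportions <- function(actions) {
  a <- length(actions)
  if (a == 0) stop("cannot compute marginal proportions of an empty game")
  counts <- table(factor(actions, levels = action_types()))
  p <- as.numeric(counts) / a
  names(p) <- action_types()
  attr(p, "a") <- a
  p
}

#' Null probability of an n-gram under independent draws
#'
#' Under the null model the probability that a random tile equals a
#' given n-gram is the product of the marginal proportions of its
#' component actions, e.g. `p_i * p_j` for a bigram.
#'
#' @param ngram Character vector of action types, or a single dash-joined
#'   string.
#' @param marginals Named proportions from [marginal_proportions()].
#' @return The product probability, in \[0, 1\].
#' @export
ngram_null_probability <- function(ngram, marginals) {
  if (length(ngram) == 1 && grepl("-", ngram, fixed = TRUE)) {
    ngram <- strsplit(ngram, "-", fixed = TRUE)[[1]]
  }
  if (!all(ngram %in% names(marginals))) {
    stop("ngram contains types absent from the marginal profile")
  }
  prod(marginals[ngram])
}

#' Upper-tail binomial probability P(X >= K)
#'
#' The p-value of observing an n-gram at least `K` times among `n`
#' independent tiles when each tile matches with probability `p`.
#'
#' @param K Observed count, `0 <= K <= n`.
#' @param n Number of tiles (trials).
#' @param p Per-tile match probability.
#' @return `P(X >= K)` for `X ~ Binomial(n, p)`.
#' @export
binomial_upper_pvalue <- function(K, n, p) {
  stopifnot(length(K) == 1, length(n) == 1, length(p) == 1)
  if (K < 0 || K > n) stop("K must lie in [0, n]")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (K == 0) return(1)
  stats::pbinom(K - 1, size = n, prob = p, lower.tail = FALSE)
}

# Count occurrences of each distinct ngram among a set of tiles.
count_tile_ngrams <- function(tiles) {
  tab <- table(tiles$ngram)
  tibble::tibble(ngram = names(tab), K = as.integer(tab))
}

#' Nominate candidate chunks from the training set
#'
#' Every distinct n-gram observed among the training tiles gets an
#' upper-tail binomial p-value against its null probability; the `limit`
#' n-grams with the smallest training p-values move forward. Because the
#' candidates are selected by optimisation, the training p-values are
#' optimistic and are discarded from inference; they are retained in the
#' output only as a diagnostic. Ties at the cutoff are broken by higher
#' training count, then lexicographic n-gram order, so nomination is
#' deterministic.
#'
#' @param train_tiles Training tile tibble.
#' @param marginals Marginal proportions of the full game.
#' @param limit Maximum number of candidates (default 5).
#' @return Tibble `ngram, K_train, n_train, p_null, pval_train`, at most
#'   `limit` rows, in nomination order.
#' @export
nominate_candidates <- function(train_tiles, marginals, limit = 5) {
  stopifnot(nrow(train_tiles) > 0)
  counts <- count_tile_ngrams(train_tiles)
  n_train <- nrow(train_tiles)
  counts$n_train <- n_train
  counts$p_null <- vapply(counts$ngram, ngram_null_probability, 0,
                          marginals = marginals)
  counts$pval_train <- mapply(binomial_upper_pvalue, counts$K,
                              n_train, counts$p_null)
  ord <- order(counts$pval_train, -counts$K, counts$ngram)
  out <- counts[head(ord, limit), , drop = FALSE]
  names(out)[names(out) == "K"] <- "K_train"
  out[, c("ngram", "K_train", "n_train", "p_null", "pval_train")]
}

#' Confirm candidate chunks on the held-out test set
#'
#' Each candidate's count is re-taken over the test tiles only and a
#' fresh binomial p-value is computed with `n` equal to the retained
#' test-tile count. A candidate with test p-value strictly below `alpha`
#' is a confirmed chunk. The test set is untouched by the nomination
#' step, so these p-values are reliable.
#'
#' @param candidates Tibble from [nominate_candidates()].
#' @param test_tiles Test tile tibble (disjoint from training tiles).
#' @param marginals Marginal proportions of the full game.
#' @param alpha Per-test significance level, default 0.05 (strict `<`).
#' @return The candidate tibble with added columns `K_test, n_test,
#'   pval_test, confirmed`.
#' @export
confirm_chunks <- function(candidates, test_tiles, marginals, alpha = 0.05) {
  n_test <- nrow(test_tiles)
  counts <- count_tile_ngrams(test_tiles)
  K_test <- counts$K[match(candidates$ngram, counts$ngram)]
  K_test[is.na(K_test)] <- 0L
  candidates$K_test <- K_test
  candidates$n_test <- n_test
  candidates$pval_test <- mapply(binomial_upper_pvalue, K_test, n_test,
                                 candidates$p_null)
  candidates$confirmed <- candidates$pval_test < alpha
  candidates
}

#' Run the full chunk-detection procedure on one game
#'
#' For each length n in `lengths` independently: tile the stream into
#' non-overlapping n-grams, drop tiles with artifactual repeats, split
#' the tiles at random into training and test halves, nominate up to
#' `max_candidates` candidates by training-set binomial p-value, and
#' confirm them on the test set at level `alpha`. With the defaults a
#' game can yield at most 15 chunks (5 per length). A length whose
#' retained tile count is below 4 is skipped with a recorded reason.
#'
#' @param actions Character vector of action types (one game, in order).
#' @param alpha Per-test significance level (strict `<`). Default 0.05.
#' @param max_candidates Candidates nominated per length. Default 5.
#' @param lengths N-gram lengths to test. Default `2:4`.
#' @param seed Integer seed; the split for length n uses substream
#'   `seed + n` so lengths are independent but jointly reproducible.
#' @return List with elements:
#'   * `chunks`: tibble of all candidates across lengths with a `length`
#'     column and the confirmation fields of [confirm_chunks()];
#'   * `annotation`: tibble from [mark_chunked_actions()] for the
#'     confirmed chunks;
#'   * `skipped`: character vector of reasons for skipped lengths.
#' @export
detect_game_chunks <- function(actions, alpha = 0.05, max_candidates = 5,
                               lengths = 2:4, seed = 1L) {
  stopifnot(all(lengths %in% 2:4))
  chunk_rows <- list()
  skipped <- character(0)
  marginals <- marginal_proportions(actions)
  for (n in lengths) {
    tiles <- filter_repeat_tiles(tile_ngrams(actions, n))
    if (nrow(tiles) < 4) {
      skipped <- c(skipped, sprintf(
        "length %d skipped: %d retained tiles (< 4)", n, nrow(tiles)))
      next
    }
    halves <- split_train_test(tiles, seed = seed + n)
    cand <- nominate_candidates(halves$train, marginals,
                                limit = max_candidates)
    cand <- confirm_chunks(cand, halves$test, marginals, alpha = alpha)
    cand$length <- n
    chunk_rows[[as.character(n)]] <- cand
  }
  chunks <- if (length(chunk_rows) > 0) {
    dplyr::bind_rows(chunk_rows)
  } else {
    tibble::tibble(ngram = character(0), K_train = integer(0),
                   n_train = integer(0), p_null = numeric(0),
                   pval_train = numeric(0), K_test = integer(0),
                   n_test = integer(0), pval_test = numeric(0),
                   confirmed = logical(0), length = integer(0))
  }
  annotation <- mark_chunked_actions(actions,
                                     chunks$ngram[chunks$confirmed])
  list(chunks = chunks, annotation = annotation, skipped = skipped)
}

#' Mark which actions of a stream fall within confirmed chunks
#'
#' Every occurrence of every confirmed chunk n-gram anywhere in the full
#' stream (sliding, overlapping occurrences included) marks its actions
#' as in-chunk; positions covered by several chunks are unioned. A marked
#' action is a *first action* when its predecessor is unmarked or it
#' begins the game, so an uninterrupted run of chunked actions — however
#' many chunks compose it — has exactly one first action.
#'
#' @param actions Character vector of action types.
#' @param chunk_ngrams Character vector of confirmed chunk n-grams
#'   (dash-joined).
#' @return Tibble with one row per action: `index` (1-based), `action_type`,
#'   `in_chunk`, `is_first_action`, and `chunk_ids`, a list-column of the
#'   indices into `chunk_ngrams` owning each position.
#' @export
mark_chunked_actions <- function(actions, chunk_ngrams) {
  a <- length(actions)
  in_chunk <- rep(FALSE, a)
  owners <- vector("list", a)
  for (ci in seq_along(chunk_ngrams)) {
    cv <- strsplit(chunk_ngrams[ci], "-", fixed = TRUE)[[1]]
    L <- length(cv)
    if (L > a) next
    hit <- rep(TRUE, a - L + 1)
    for (j in seq_len(L)) {
      hit <- hit & (actions[seq(j, a - L + j)] == cv[j])
    }
    for (s in which(hit)) {
      pos <- s:(s + L - 1)
      in_chunk[pos] <- TRUE
      for (pp in pos) owners[[pp]] <- union(owners[[pp]], ci)
    }
  }
  prev <- c(FALSE, in_chunk[-a])
  if (a == 0) prev <- logical(0)
  tibble::tibble(
    index = seq_len(a),
    action_type = actions,
    in_chunk = in_chunk,
    is_first_action = in_chunk & !prev,
    chunk_ids = lapply(owners, function(o) if (is.null(o)) integer(0) else o)
  )
}

#' Detect chunks across a whole action table
#'
#' Applies [detect_game_chunks()] to every game in an action table (as
#' returned by [read_action_log()] or [simulate_cohort()]) and binds the
#' results. Each game's split seed is derived deterministically from the
#' master seed and the game's position in the table.
#'
#' @param actions Action tibble with `game_id`, `action_type` and
#'   (optionally) `t_ms`, `latency_ms` columns.
#' @inheritParams detect_game_chunks
#' @return List with `chunks` (tibble with `game_id` column prepended)
#'   and `annotations` (the input action rows with `in_chunk` and
#'   `is_first_action` columns added).
#' @export
detect_chunks <- function(actions, alpha = 0.05, max_candidates = 5,
                          lengths = 2:4, seed = 1L) {
  ids <- unique(actions$game_id)
  chunk_list <- vector("list", length(ids))
  ann_list <- vector("list", length(ids))
  for (g in seq_along(ids)) {
    rows <- actions[actions$game_id == ids[g], , drop = FALSE]
    res <- detect_game_chunks(rows$action_type, alpha = alpha,
                              max_candidates = max_candidates,
                              lengths = lengths,
                              seed = seed + 1000L * g)
    if (nrow(res$chunks) > 0) {
      chunk_list[[g]] <- dplyr::bind_cols(
        tibble::tibble(game_id = ids[g]), res$chunks)
    }
    rows$in_chunk <- res$annotation$in_chunk
    rows$is_first_action <- res$annotation$is_first_action
    ann_list[[g]] <- rows
  }
  list(chunks = dplyr::bind_rows(chunk_list),
       annotations = dplyr::bind_rows(ann_list))
}
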