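test_that("tiling is non-overlapping and discards the remainder", {
  expect_equal(tile_ngrams(c("X", "Y", "X", "Y"), 2)$ngram, c("X-Y", "X-Y"))
  expect_equal(nrow(tile_ngrams(rep(c("A", "B"), 500), 2)), 500)
  t5 <- tile_ngrams(c("A", "B", "C", "D", "E"), 2)
  expect_equal(nrow(t5), 2)
  expect_equal(t5$start_index, c(0L, 2L))
  expect_equal(nrow(tile_ngrams(rep("A", 11), 4)), 2)
})

test_that("repeat filtering drops only adjacent restricted repeats", {
  tiles <- tibble::tibble(
    start_index = as.integer(seq(0, 12, by = 4)),
    ngram = c("RightClick-RightClick",
              "Select-Select",
              "Select-Train-Train-Build",
              "Train-Select-Train-Build")
  )
  kept <- filter_repeat_tiles(tiles)
  expect_equal(kept$ngram, c("Select-Select", "Train-Select-Train-Build"))
  expect_equal(kept$start_index, c(4L, 12L))

  # oracle: direct scan for adjacent equal restricted types
  seqs <- list(c("Select", "Train", "Train", "Build"),
               c("HotkeySelect", "HotkeySelect", "Select", "Build"),
               c("Build", "Build", "Select", "Train"),
               c("RightClick", "Train", "RightClick", "Train"))
  for (sq in seqs) {
    drop <- any(sq[-length(sq)] == sq[-1] &
                  sq[-length(sq)] %in% c("RightClick", "Train", "HotkeySelect"))
    tl <- tibble::tibble(start_index = 0L,
                         ngram = paste(sq, collapse = "-"))
    expect_equal(nrow(filter_repeat_tiles(tl)) == 0, drop,
                 info = paste(sq, collapse = ","))
  }
})

test_that("train/test split halves the tiles reproducibly", {
  tiles <- tile_ngrams(rep(c("A", "B"), 500), 2)
  halves <- split_train_test(tiles, seed = 11)
  expect_equal(nrow(halves$train), 250)
  expect_equal(nrow(halves$test), 250)
  expect_equal(sort(c(halves$train$start_index, halves$test$start_index)),
               tiles$start_index)
  again <- split_train_test(tiles, seed = 11)
  expect_identical(halves, again)
  # odd count puts the extra tile in train
  odd <- split_train_test(tiles[1:5, ], seed = 1)
  expect_equal(nrow(odd$train), 3)
  expect_equal(nrow(odd$test), 2)
  expect_error(split_train_test(tiles[1, ], seed = 1), "at least 2")
})

test_that("marginal proportions count the full stream", {
  stream <- c("ScreenShift", "Select", "Train", "HotkeySelect",
              "RightClick", "RightClick", "RightClick", "Ability")
  p <- marginal_proportions(stream)
  expect_equal(unname(p["RightClick"]), 3 / 8)
  expect_equal(unname(p["Select"]), 1 / 8)
  expect_equal(unname(p["Build"]), 0)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(attr(p, "a"), 8)
  p1 <- marginal_proportions(rep("Train", 10))
  expect_equal(unname(p1["Train"]), 1)
  expect_error(marginal_proportions(character(0)), "empty")
})

test_that("null probability is the product of marginals", {
  m <- c(Select = 0.2, Train = 0.3, Build = 0, RightClick = 0.5)
  expect_equal(ngram_null_probability(c("Select", "Train"), m), 0.06)
  expect_equal(ngram_null_probability("Select-Train", m), 0.06)
  expect_equal(ngram_null_probability(c("Select", "Build", "Train"), m), 0)
  m2 <- c(Select = 0.5, Train = 0.5)
  expect_equal(ngram_null_probability(rep("Select", 4), m2), 0.0625)
})

test_that("binomial upper tail matches the direct-summation oracle", {
  expect_equal(binomial_upper_pvalue(0, 50, 0.2), 1)
  expect_equal(binomial_upper_pvalue(30, 50, 1), 1)
  # frozen value computed by term-by-term summation
  expect_equal(binomial_upper_pvalue(20, 250, 0.04), 0.00281440493811079,
               tolerance = 1e-10)
  grid <- expand.grid(n = c(5, 50, 250, 500), p = c(0.001, 0.04, 0.5, 0.97))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; p <- grid$p[i]
    for (K in unique(c(0, 1, round(n * p), round(n / 2), n))) {
      expect_equal(binomial_upper_pvalue(K, n, p), oracle_binom_tail(K, n, p),
                   tolerance = 1e-12, info = sprintf("K=%d n=%d p=%g", K, n, p))
    }
  }
  # nonincreasing in K
  pv <- vapply(0:50, binomial_upper_pvalue, 0, n = 50, p = 0.3)
  expect_true(all(diff(pv) <= 0))
  expect_error(binomial_upper_pvalue(51, 50, 0.3), "K")
})

test_that("nomination ranks by training p-value with deterministic ties", {
  m <- c(Select = 0.25, Train = 0.25, Build = 0.25, RightClick = 0.25)
  train <- tibble::tibble(
    start_index = as.integer(seq(0, 18, by = 2)),
    ngram = c(rep("Select-Train", 5), rep("Build-Select", 3),
              rep("Train-Build", 2))
  )
  cand <- nominate_candidates(train, m, limit = 5)
  expect_equal(cand$ngram[1], "Select-Train")
  expect_equal(cand$K_train, c(5L, 3L, 2L))
  expect_equal(cand$n_train, rep(10L, 3))
  expect_equal(cand$pval_train,
               vapply(cand$K_train, oracle_binom_tail, 0, n = 10, p = 1 / 16),
               tolerance = 1e-12)
  # equal p-values and counts fall back to lexicographic order
  tied <- tibble::tibble(start_index = c(0L, 2L, 4L, 6L),
                         ngram = c("Train-Build", "Build-Select",
                                   "Train-Build", "Build-Select"))
  c2 <- nominate_candidates(tied, m, limit = 1)
  expect_equal(c2$ngram, "Build-Select")
})

test_that("confirmation recounts on the held-out tiles at strict alpha", {
  m <- c(Select = 0.1, Train = 0.2, Build = 0.3, RightClick = 0.4)
  train <- tibble::tibble(start_index = 0L, ngram = "Select-Train")
  cand <- nominate_candidates(train, m)
  # candidate absent from the test set is never confirmed
  test_tiles <- tibble::tibble(start_index = as.integer(2 * (1:20)),
                               ngram = rep("Build-RightClick", 20))
  conf <- confirm_chunks(cand, test_tiles, m)
  expect_equal(conf$K_test, 0L)
  expect_equal(conf$pval_test, 1)
  expect_false(conf$confirmed)
  # a planted bigram filling 30% of the test tiles is confirmed
  test2 <- tibble::tibble(
    start_index = as.integer(2 * (1:200)),
    ngram = c(rep("Select-Train", 60), rep("Build-RightClick", 140))
  )
  conf2 <- confirm_chunks(cand, test2, m)
  expect_equal(conf2$pval_test, oracle_binom_tail(60, 200, 0.02),
               tolerance = 1e-12)
  expect_true(conf2$confirmed)
  # alpha = 0 can never confirm (strict inequality)
  expect_false(confirm_chunks(cand, test2, m, alpha = 0)$confirmed)
})

test_that("marking covers sliding occurrences and unions overlaps", {
  ann <- mark_chunked_actions(c("C", "A", "B", "C"), "A-B")
  expect_equal(ann$in_chunk, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(which(ann$is_first_action), 2L)

  ann2 <- mark_chunked_actions(c("A", "B", "A", "B"), "A-B")
  expect_true(all(ann2$in_chunk))
  expect_equal(which(ann2$is_first_action), 1L)

  ann3 <- mark_chunked_actions(c("A", "B", "A"), c("A-B", "B-A"))
  expect_true(all(ann3$in_chunk))
  expect_equal(which(ann3$is_first_action), 1L)
  expect_equal(ann3$chunk_ids[[2]], c(1L, 2L))

  # no chunks: all-false annotation of the right length
  ann4 <- mark_chunked_actions(c("A", "B"), character(0))
  expect_false(any(ann4$in_chunk))
  expect_equal(nrow(ann4), 2)

  # idempotence: marked positions from one pass fully determine the next
  types <- withr::with_seed(5, sample(c("A", "B", "C"), 60, replace = TRUE))
  once <- mark_chunked_actions(types, c("A-B", "C-A-B"))
  twice <- mark_chunked_actions(types, c("A-B", "C-A-B"))
  expect_identical(once, twice)
})

test_that("the full detector finds a heavily repeated planted bigram", {
  m <- c(Select = 0.05, HotkeySelect = 0.15, Train = 0.15, Build = 0.05,
         RightClick = 0.2, Ability = 0.2, ScreenShift = 0.2)
  stream <- planted_tile_stream(m, 1200, c("HotkeySelect", "Train"),
                                occupancy = 0.3, seed = 42)
  res <- detect_game_chunks(stream, seed = 9)
  confirmed <- res$chunks[res$chunks$confirmed, ]
  expect_true("HotkeySelect-Train" %in% confirmed$ngram[confirmed$length == 2])
  # bounds: confirmed within nominated, at most 5 per length, 15 per game
  expect_true(all(table(res$chunks$length) <= 5))
  expect_lte(sum(res$chunks$confirmed), 15)
  expect_equal(nrow(res$annotation), 1200)
})

test_that("detector output is reproducible and respects the seed stream", {
  m <- rep(1 / 7, 7)
  names(m) <- action_types()
  stream <- null_stream(m, 400, seed = 3)$action_type
  r1 <- detect_game_chunks(stream, seed = 5)
  r2 <- detect_game_chunks(stream, seed = 5)
  expect_identical(r1$chunks, r2$chunks)
})

test_that("detect_chunks annotates every game of a table", {
  sim <- simulate_cohort(c(0, 2, 0, 0, 0, 0, 2, 0), seed = 21,
                         duration_ms = 300000)
  res <- detect_chunks(sim$actions, seed = 2)
  expect_equal(nrow(res$annotations), nrow(sim$actions))
  expect_setequal(unique(res$annotations$game_id),
                  unique(sim$actions$game_id))
  expect_true(all(res$chunks$game_id %in% sim$actions$game_id))
  # first actions are always in-chunk
  expect_true(all(res$annotations$in_chunk[res$annotations$is_first_action]))
})
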