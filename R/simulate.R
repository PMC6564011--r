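#' Skill-graded base latency schedule
#'
#' Median per-action base latency (ms) for a given skill level, following
#' a geometric interpolation between roughly 1019 ms at league 1 and
#' 234 ms at league 8 — the span of mean action latencies across the
#' skill ladder that the analyses are designed to dissect.
#'
#' @param league Integer skill level(s) in 1..8.
#' @return Base latency in milliseconds.
#' @export
league_base_latency <- function(league) {
  stopifnot(all(league %in% 1:8))
  1019 * (234 / 1019)^((league - 1) / 7)
}

default_marginals <- function() {
  c(Select = 0.20, HotkeySelect = 0.10, Train = 0.10, Build = 0.05,
    RightClick = 0.25, Ability = 0.05, ScreenShift = 0.25)
}

default_repertoire <- function() {
  list(
    list(ngram = c("ScreenShift", "Select"), rate = 0.04),
    list(ngram = c("HotkeySelect", "Train"), rate = 0.03),
    list(ngram = c("Select", "Build", "RightClick"), rate = 0.02),
    list(ngram = c("ScreenShift", "Select", "RightClick", "Ability"),
         rate = 0.01)
  )
}

# fixed small species effect on base latency (nuisance factor)
species_latency_multiplier <- function(species) {
  mult <- c(Terran = 1.00, Zerg = 0.96, Protoss = 1.04,
            TerranRandom = 1.02, ZergRandom = 0.98, ProtossRandom = 1.06)
  unname(mult[species])
}

#' Construct a synthetic player profile
#'
#' Builds the generative parameters of one simulated player:
#' player-specific action-type marginals (a seeded jitter around a common
#' mix), a species label with a small latency effect, a skill-graded base
#' latency, a repertoire of chunk n-grams with usage rates, the
#' first-action slowdown and within-chunk speedup multipliers, lognormal
#' latency noise, and the rate and length of artifactual repeat bursts.
#' The function is deterministic in `(league, seed)`.
#'
#' @param league Skill level 1-8.
#' @param seed Integer seed for the player-specific draws.
#' @param overrides Named list of profile fields to override (any of
#'   `marginals, species, repertoire, base_latency,
#'   first_action_multiplier, within_chunk_multiplier, latency_sigma,
#'   repeat_run_rate, repeat_run_mean_length, repeat_run_multiplier`).
#' @return A list of class `"player_profile"` with the fields above.
#' @export
make_profile <- function(league, seed = 1L, overrides = list()) {
  stopifnot(length(league) == 1, league %in% 1:8)
  known <- c("marginals", "species", "repertoire", "base_latency",
             "first_action_multiplier", "within_chunk_multiplier",
             "latency_sigma", "repeat_run_rate", "repeat_run_mean_length",
             "repeat_run_multiplier")
  bad <- setdiff(names(overrides), known)
  if (length(bad) > 0) stop("unknown profile override(s): ",
                            paste(bad, collapse = ", "))
  prof <- withr::with_seed(seed, {
    # mild per-player jitter of the action mix (concentration 200)
    m <- default_marginals()
    jit <- stats::rgamma(length(m), shape = 200 * m)
    list(
      league = as.integer(league),
      species = sample(species_levels(), 1),
      marginals = stats::setNames(jit / sum(jit), names(m))
    )
  })
  base <- league_base_latency(league) * species_latency_multiplier(prof$species)
  prof$base_latency <- stats::setNames(rep(base, 7), action_types())
  prof$repertoire <- default_repertoire()
  prof$first_action_multiplier <- 1.28
  prof$within_chunk_multiplier <- 0.78
  prof$latency_sigma <- 0.5
  prof$repeat_run_rate <- 0.05
  prof$repeat_run_mean_length <- 4
  prof$repeat_run_multiplier <- 0.3
  for (nm in names(overrides)) prof[[nm]] <- overrides[[nm]]
  stopifnot(abs(sum(prof$marginals) - 1) < 1e-8,
            prof$first_action_multiplier > 0,
            prof$within_chunk_multiplier > 0)
  rates <- vapply(prof$repertoire, function(ch) ch$rate, 0)
  stopifnot(all(rates >= 0), sum(rates) + prof$repeat_run_rate <= 1)
  class(prof) <- "player_profile"
  prof
}

# lognormal draw with mean `mu` and log-scale sd `sigma`
lognormal_latency <- function(n, mu, sigma) {
  if (sigma == 0) return(rep(mu, n))
  stats::rlnorm(n, meanlog = log(mu) - sigma^2 / 2, sdlog = sigma)
}

#' Simulate one game from a player profile
#'
#' Repeated emission draws until the cumulative game time exceeds
#' `duration_ms`: with probability equal to its usage rate a repertoire
#' chunk is emitted (first action at `base * first_action_multiplier`,
#' subsequent actions at `base * within_chunk_multiplier`); with
#' probability `repeat_run_rate` a geometric-length burst of one
#' repeat-prone type (RightClick, Train or HotkeySelect) is emitted with
#' abnormally fast follow-up latencies; otherwise a single action is
#' drawn iid from the player's marginals at the base latency. All
#' latencies carry multiplicative lognormal noise with mean one, are
#' rounded to integer milliseconds, and timestamps are their cumulative
#' sums. Emissions never interleave.
#'
#' @param profile A [make_profile()] object.
#' @param duration_ms Target game duration in ms; default 900000 (15
#'   minutes).
#' @param seed Integer seed.
#' @return List with `actions` (tibble `t_ms, action_type, latency_ms`;
#'   the first action's latency is `NA`) and `truth` (tibble per action:
#'   `emitted_by_chunk, chunk_id, is_first_of_emission, role` where
#'   `role` is one of `chunk_first, chunk_within, repeat_first,
#'   repeat_within, single`).
#' @export
simulate_game <- function(profile, duration_ms = 900000, seed = 1L) {
  stopifnot(inherits(profile, "player_profile"), duration_ms > 0)
  rates <- vapply(profile$repertoire, function(ch) ch$rate, 0)
  cum_rates <- cumsum(rates)
  r_chunk <- sum(rates)
  r_rep <- profile$repeat_run_rate
  sigma <- profile$latency_sigma
  base <- profile$base_latency
  rep_types <- repeat_drop_types()
  rep_p <- profile$marginals[rep_types]
  rep_p <- if (sum(rep_p) > 0) rep_p / sum(rep_p) else rep(1 / 3, 3)
  withr::with_seed(seed, {
    types <- character(0); lat <- numeric(0)
    chunk_id <- integer(0); role <- character(0)
    total <- 0
    while (total <= duration_ms) {
      u <- stats::runif(1)
      if (u < r_chunk) {
        ci <- which(u < cum_rates)[1]
        ng <- profile$repertoire[[ci]]$ngram
        L <- length(ng)
        mult <- c(profile$first_action_multiplier,
                  rep(profile$within_chunk_multiplier, L - 1))
        l <- lognormal_latency(L, 1, sigma) * base[ng] * mult
        types <- c(types, ng); lat <- c(lat, l)
        chunk_id <- c(chunk_id, rep(ci, L))
        role <- c(role, "chunk_first", rep("chunk_within", L - 1))
      } else if (u < r_chunk + r_rep) {
        tp <- sample(rep_types, 1, prob = rep_p)
        p_geo <- 1 / max(profile$repeat_run_mean_length - 1, 1)
        L <- 2 + stats::rgeom(1, p_geo)
        mult <- c(1, rep(profile$repeat_run_multiplier, L - 1))
        l <- lognormal_latency(L, 1, sigma) * base[tp] * mult
        types <- c(types, rep(tp, L)); lat <- c(lat, l)
        chunk_id <- c(chunk_id, rep(NA_integer_, L))
        role <- c(role, "repeat_first", rep("repeat_within", L - 1))
      } else {
        tp <- sample(names(profile$marginals), 1, prob = profile$marginals)
        l <- lognormal_latency(1, base[tp], sigma)
        types <- c(types, tp); lat <- c(lat, l)
        chunk_id <- c(chunk_id, NA_integer_)
        role <- c(role, "single")
      }
      total <- total + sum(l)
    }
    lat <- pmax(1, round(lat))
    actions <- tibble::tibble(
      game_id = "sim",
      t_ms = cumsum(lat),
      action_type = types
    )
    actions <- compute_latencies(actions)
    actions$game_id <- NULL
    truth <- tibble::tibble(
      emitted_by_chunk = !is.na(chunk_id),
      chunk_id = chunk_id,
      is_first_of_emission = role %in% c("chunk_first", "repeat_first",
                                         "single"),
      role = role
    )
    list(actions = actions, truth = truth)
  })
}

#' Pure-noise action stream (the detector's null)
#'
#' Independent draws from a marginal distribution with unit-latency
#' timestamps: the exact null model of the chunk detector.
#'
#' @param marginals Named probability vector over (a subset of) the
#'   seven action types.
#' @param a Number of actions.
#' @param seed Integer seed.
#' @return Action tibble `game_id, t_ms, action_type, latency_ms`.
#' @export
null_stream <- function(marginals, a, seed = 1L) {
  stopifnot(a >= 1, abs(sum(marginals) - 1) < 1e-8)
  types <- withr::with_seed(seed, {
    sample(names(marginals), a, replace = TRUE, prob = marginals)
  })
  compute_latencies(tibble::tibble(
    game_id = "null",
    t_ms = as.numeric(0:(a - 1)),
    action_type = types
  ))
}

#' Action stream with an n-gram planted at a given tile occupancy
#'
#' Builds a stream as a sequence of length-`L` tiles (`L` the n-gram
#' length): each tile is the planted n-gram with probability `occupancy`
#' and otherwise `L` iid draws from the background marginals; a trailing
#' remainder is filled with iid draws. Because planting is tile-aligned,
#' `occupancy` is directly the expected share of non-overlapping tiles
#' occupied by the n-gram, the quantity the detector's binomial test
#' sees.
#'
#' @param marginals Background marginal distribution.
#' @param a Stream length in actions.
#' @param ngram Character vector of action types to plant.
#' @param occupancy Probability that a tile is the planted n-gram.
#' @param seed Integer seed.
#' @return Character vector of `a` action types.
#' @export
planted_tile_stream <- function(marginals, a, ngram, occupancy, seed = 1L) {
  stopifnot(occupancy >= 0, occupancy <= 1, a >= length(ngram))
  L <- length(ngram)
  n_tiles <- floor(a / L)
  withr::with_seed(seed, {
    planted <- stats::runif(n_tiles) < occupancy
    tiles <- lapply(seq_len(n_tiles), function(i) {
      if (planted[i]) ngram
      else sample(names(marginals), L, replace = TRUE, prob = marginals)
    })
    rest <- a - n_tiles * L
    tail <- if (rest > 0) {
      sample(names(marginals), rest, replace = TRUE, prob = marginals)
    } else character(0)
    c(unlist(tiles), tail)
  })
}

#' Simulate a cohort of players across skill levels
#'
#' Independent players per league, each with a seeded [make_profile()]
#' and one simulated game. The returned action table is in the canonical
#' action-log layout and the truth sidecar carries the generative labels
#' of every action.
#'
#' @param league_sizes Numeric vector of length 8: players per league
#'   (zeros allowed).
#' @param seed Master integer seed; every player's profile and game are
#'   derived from it deterministically.
#' @param duration_ms Game duration passed to [simulate_game()].
#' @param overrides Profile overrides applied to every player (see
#'   [make_profile()]).
#' @return List with `actions` (tibble `game_id, league, species, t_ms,
#'   action_type, latency_ms`), `truth` (per-action generative labels
#'   with `game_id`), and `profiles` (named list of profiles by game
#'   id).
#' @export
simulate_cohort <- function(league_sizes, seed = 1L, duration_ms = 900000,
                            overrides = list()) {
  stopifnot(length(league_sizes) == 8, all(league_sizes >= 0))
  act_list <- list(); truth_list <- list(); profiles <- list()
  for (lg in 1:8) {
    for (i in seq_len(league_sizes[lg])) {
      pseed <- seed + 100000L * lg + 97L * i
      prof <- make_profile(lg, seed = pseed, overrides = overrides)
      sim <- simulate_game(prof, duration_ms = duration_ms, seed = pseed + 1L)
      gid <- sprintf("L%d_P%03d", lg, i)
      acts <- sim$actions
      acts <- tibble::add_column(acts, game_id = gid, league = lg,
                                 species = prof$species, .before = 1)
      act_list[[gid]] <- acts
      truth_list[[gid]] <- tibble::add_column(sim$truth, game_id = gid,
                                              .before = 1)
      profiles[[gid]] <- prof
    }
  }
  list(actions = dplyr::bind_rows(act_list),
       truth = dplyr::bind_rows(truth_list),
       profiles = profiles)
}

#' Annotate simulated actions with their ground-truth chunk labels
#'
#' Converts the simulator's truth sidecar into the same `in_chunk` /
#' `is_first_action` annotation the detector produces, so the savings
#' and summary stages can be run against ground truth instead of
#' detected chunks.
#'
#' @param actions Action tibble from [simulate_cohort()] or a single
#'   [simulate_game()] result's `actions`.
#' @param truth Matching truth tibble.
#' @return The action tibble with `in_chunk` and `is_first_action`
#'   columns taken from the generative labels.
#' @export
truth_annotation <- function(actions, truth) {
  stopifnot(nrow(actions) == nrow(truth))
  actions$in_chunk <- truth$emitted_by_chunk
  actions$is_first_action <- truth$emitted_by_chunk &
    truth$role == "chunk_first"
  actions
}

#' Analytic expected time savings of a simulated game
#'
#' Under the generative model the expected per-action saving of a chunk
#' first action is `base * (1 - first_action_multiplier)` and of a
#' within-chunk action `base * (1 - within_chunk_multiplier)`, because
#' the same-type non-chunked baseline has expectation `base` (latency
#' noise has mean one). This sums those expectations over the chunked
#' actions that the savings estimator actually includes (defined
#' latency, baseline type available), giving the quantity the estimator
#' is unbiased for.
#'
#' @param annotated Truth-annotated single-game tibble (from
#'   [truth_annotation()]).
#' @param profile The generating [make_profile()] object.
#' @return One-row tibble `expected_total_s, expected_first_s,
#'   expected_inter_s`.
#' @export
expected_game_savings <- function(annotated, profile) {
  eligible_types <- unique(annotated$action_type[
    !annotated$in_chunk & !is.na(annotated$latency_ms)])
  inc <- annotated$in_chunk & !is.na(annotated$latency_ms) &
    annotated$action_type %in% eligible_types
  base <- profile$base_latency[annotated$action_type[inc]]
  first <- annotated$is_first_action[inc]
  exp_first <- sum(base[first] * (1 - profile$first_action_multiplier)) / 1000
  exp_inter <- sum(base[!first] * (1 - profile$within_chunk_multiplier)) / 1000
  tibble::tibble(
    expected_total_s = exp_first + exp_inter,
    expected_first_s = exp_first,
    expected_inter_s = exp_inter
  )
}
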