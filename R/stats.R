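#' Additive two-way ANOVA with partial eta squared
#'
#' Fits the additive (no-interaction) linear model
#' `response ~ factor1 + factor2` and reports, for each factor, the
#' marginal F test (each factor adjusted for the other, Type-II style)
#' together with partial eta squared
#' `SS_effect / (SS_effect + SS_residual)`. Designed for skill-level
#' analyses with League (ordinal 1-8, treated categorically) and a
#' categorical nuisance factor such as player species, on unbalanced
#' observational cohorts.
#'
#' A factor with fewer than two observed levels is dropped (with a
#' message), so the model degrades gracefully to a one-way ANOVA; with a
#' single remaining factor the marginal test coincides with the
#' classical one-way F.
#'
#' @param data Data frame of per-game summaries.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names; default
#'   `c("league", "species")`.
#' @param ss `"marginal"` (default) for each-adjusted-for-the-other
#'   Type-II tests, or `"sequential"` for Type-I tests in the order
#'   given.
#' @return Tibble `term, df, sum_sq, F, p, partial_eta_sq, df_residual`.
#' @export
anova_additive <- function(data, response,
                           factors = c("league", "species"),
                           ss = c("marginal", "sequential")) {
  ss <- match.arg(ss)
  stopifnot(response %in% names(data), all(factors %in% names(data)))
  df <- data.frame(.y = as.numeric(data[[response]]))
  kept <- character(0)
  for (f in factors) {
    fac <- droplevels(factor(data[[f]]))
    if (nlevels(fac) < 2) {
      message("factor ", f, " has a single observed level; dropped")
      next
    }
    df[[f]] <- fac
    kept <- c(kept, f)
  }
  if (length(kept) == 0) stop("no factor with at least two levels")
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (stats::var(df$.y) == 0) {
    # constant response: every effect and the residual are zero
    df_eff <- vapply(kept, function(f) nlevels(df[[f]]) - 1L, 1L)
    df_res <- nrow(df) - sum(df_eff) - 1L
    return(tibble::tibble(
      term = kept, df = unname(df_eff), sum_sq = 0, F = 0, p = 1,
      partial_eta_sq = 0, df_residual = df_res
    ))
  }
  fit <- stats::lm(stats::reformulate(kept, response = ".y"), data = df)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; aliased terms: ", paste(aliased, collapse = ", "))
  }
  tab <- if (ss == "marginal" && length(kept) > 1) {
    as.data.frame(car::Anova(fit, type = 2))
  } else {
    as.data.frame(stats::anova(fit))
  }
  names(tab) <- c("sum_sq", "df", "F", "p")[match(
    names(tab), c("Sum Sq", "Df", "F value", "Pr(>F)"))]
  res_row <- rownames(tab) == "Residuals"
  ss_res <- tab$sum_sq[res_row]
  df_res <- tab$df[res_row]
  eff <- tab[!res_row, , drop = FALSE]
  tibble::tibble(
    term = rownames(eff),
    df = eff$df,
    sum_sq = eff$sum_sq,
    F = eff$F,
    p = eff$p,
    partial_eta_sq = eff$sum_sq / (eff$sum_sq + ss_res),
    df_residual = df_res
  )
}

# shared shape for the t-type results
t_result <- function(estimate, t, df, p, ci, degenerate = FALSE) {
  tibble::tibble(estimate = estimate, t = t, df = df, p = p,
                 ci_lo = ci[1], ci_hi = ci[2], degenerate = degenerate)
}

#' Paired t-test on per-game measures
#'
#' Classical paired t-test on the differences `x - y` over games, with
#' `df = pairs - 1`. A zero-variance difference vector is reported as a
#' flagged degenerate result rather than an infinite statistic.
#'
#' @param x,y Numeric vectors of equal length, paired by game.
#' @return Tibble `estimate` (mean difference), `t, df, p, ci_lo, ci_hi,
#'   degenerate`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  if (length(d) < 2) stop("need at least 2 complete pairs")
  if (stats::sd(d) == 0) {
    return(t_result(mean(d), NA_real_, length(d) - 1, NA_real_,
                    c(mean(d), mean(d)), degenerate = TRUE))
  }
  ht <- stats::t.test(x[ok], y[ok], paired = TRUE)
  t_result(unname(ht$estimate), unname(ht$statistic),
           unname(ht$parameter), ht$p.value, ht$conf.int)
}

#' One-sample t-test
#'
#' @param x Numeric vector.
#' @param mu0 Null mean; default 0.
#' @return Tibble as in [paired_t()]; `estimate` is the sample mean.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0) {
    return(t_result(mean(x), NA_real_, length(x) - 1, NA_real_,
                    c(mean(x), mean(x)), degenerate = TRUE))
  }
  ht <- stats::t.test(x, mu = mu0)
  t_result(unname(ht$estimate), unname(ht$statistic),
           unname(ht$parameter), ht$p.value, ht$conf.int)
}

#' Pearson correlation with t statistic and Fisher-z interval
#'
#' @param x,y Numeric vectors of equal length, at least 3 complete pairs.
#' @return Tibble `r, t, df, p, ci_lo, ci_hi, degenerate`; the interval
#'   is the standard Fisher-z 95% CI.
#' @export
pearson_r_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, t = NA_real_, df = length(x) - 2,
                          p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                          degenerate = TRUE))
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  ci <- if (!is.null(ht$conf.int)) ht$conf.int else c(NA_real_, NA_real_)
  tibble::tibble(r = unname(ht$estimate), t = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 ci_lo = ci[1], ci_hi = ci[2], degenerate = FALSE)
}

#' Family-wise corrected pairwise comparisons between skill levels
#'
#' All pairwise two-sample t-tests between the groups (e.g. leagues),
#' with p-values adjusted for the family of `k(k-1)/2` comparisons.
#' Pooled-variance t-tests are the default, matching classic planned
#' comparison practice; Welch tests are available. Groups with fewer
#' than two observations are dropped with a warning.
#'
#' @param x Numeric response.
#' @param g Grouping vector (coerced to factor) of the same length.
#' @param method p-adjustment method; `"holm"` (default) or any method
#'   of [stats::p.adjust()].
#' @param var_equal Pooled (`TRUE`, default) or Welch (`FALSE`) per-pair
#'   variance.
#' @param alpha Family-wise significance level for the `significant`
#'   flag; default 0.05.
#' @return Tibble `group1, group2, mean_diff, t, df, p, p_adj,
#'   significant`, one row per pair.
#' @export
planned_comparisons <- function(x, g, method = "holm", var_equal = TRUE,
                                alpha = 0.05) {
  stopifnot(length(x) == length(g))
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(factor(g[ok]))
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("dropping group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !g %in% small
    x <- x[keep]; g <- droplevels(g[keep])
  }
  lev <- levels(g)
  if (length(lev) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(lev, 2)
  rows <- apply(pairs, 2, function(pr) {
    xi <- x[g == pr[1]]; xj <- x[g == pr[2]]
    if (stats::sd(c(xi - mean(xi), xj - mean(xj))) == 0) {
      return(tibble::tibble(group1 = pr[1], group2 = pr[2],
                            mean_diff = mean(xi) - mean(xj), t = NA_real_,
                            df = NA_real_, p = 1))
    }
    ht <- stats::t.test(xi, xj, var.equal = var_equal)
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   mean_diff = mean(xi) - mean(xj),
                   t = unname(ht$statistic), df = unname(ht$parameter),
                   p = ht$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = method)
  out$significant <- out$p_adj < alpha
  out
}

#' Assemble per-game summaries from the analysis outputs
#'
#' Joins the outputs of the detection, savings and diversity stages into
#' one per-game table: the response variables of every skill-level
#' analysis.
#'
#' @param annotations Annotated action tibble (from [detect_chunks()]).
#' @param chunks Chunk tibble (from [detect_chunks()]).
#' @param savings Optional per-game savings (from [cohort_savings()]);
#'   computed from `annotations` when omitted.
#' @param diversity Optional per-game diversity tibble (from
#'   [cohort_diversity()]).
#' @return Tibble `game_id, league, species, mean_latency_ms, n_chunks,
#'   prop_chunked, total_savings_s, first_action_savings_s,
#'   inter_action_savings_s` plus `randomness` when diversity results
#'   are supplied.
#' @export
build_game_summaries <- function(annotations, chunks, savings = NULL,
                                 diversity = NULL) {
  base <- dplyr::summarise(
    dplyr::group_by(annotations, .data$game_id),
    league = if ("league" %in% names(annotations)) .data$league[1] else NA,
    species = if ("species" %in% names(annotations)) .data$species[1] else NA,
    mean_latency_ms = mean(.data$latency_ms, na.rm = TRUE),
    prop_chunked = mean(.data$in_chunk),
    .groups = "drop"
  )
  n_chunks <- if (nrow(chunks) > 0) {
    dplyr::summarise(
      dplyr::group_by(chunks[chunks$confirmed, , drop = FALSE], .data$game_id),
      n_chunks = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble(game_id = character(0), n_chunks = integer(0))
  }
  out <- dplyr::left_join(base, n_chunks, by = "game_id")
  out$n_chunks[is.na(out$n_chunks)] <- 0L
  if (is.null(savings)) savings <- cohort_savings(annotations)
  out <- dplyr::left_join(
    out,
    savings[, c("game_id", "total_savings_s", "first_action_savings_s",
                "inter_action_savings_s")],
    by = "game_id")
  if (!is.null(diversity)) {
    out <- dplyr::left_join(out, diversity[, c("game_id", "randomness")],
                            by = "game_id")
  }
  out
}

#' Read a per-game summary table
#'
#' Reads a CSV of per-game summaries (for example one written by
#' [write_summary_tables()], or an externally produced table with
#' compatible columns) so the inferential layer can be rerun on it.
#' Column names can be remapped through `col_map`.
#'
#' @param path CSV path.
#' @param col_map Optional named character vector mapping canonical
#'   column names (names) to the file's column names (values).
#' @return Tibble with `league` and `species` coerced to factors.
#' @export
read_game_summaries <- function(path, col_map = NULL) {
  stopifnot(file.exists(path))
  tab <- readr::read_csv(path, col_types = readr::cols(),
                         show_col_types = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(tab)) {
        stop("mapped column not found: ", col_map[[canon]])
      }
      names(tab)[names(tab) == col_map[[canon]]] <- canon
    }
  }
  if ("league" %in% names(tab)) tab$league <- factor(tab$league)
  if ("species" %in% names(tab)) tab$species <- factor(tab$species)
  tab
}

#' Write the per-game and per-analysis summary tables
#'
#' Writes `game_level.csv` (one row per game) and one CSV per named
#' result table. Values round-trip through [read_game_summaries()] /
#' `readr::read_csv()` to full double precision.
#'
#' @param summaries Per-game summary tibble ([build_game_summaries()]).
#' @param dir Output directory, created if needed.
#' @param results Optional named list of additional result tibbles; each
#'   is written as `<name>.csv`.
#' @return Character vector of the files written, invisibly.
#' @export
write_summary_tables <- function(summaries, dir, results = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "game_level.csv")
  readr::write_csv(summaries, paths)
  for (nm in names(results)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(results[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
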