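#' Run a seeded IGT experiment
#'
#' Runs `n_runs` independent 100-trial IGT sessions under one condition.
#' Each run initialises the cortico-striatal weights uniformly at random on
#' (0, 1) and then loops: the spiking network selects a deck
#' ([simulate_trial()]), a card is drawn ([draw_card()]), the TD error is
#' computed on the learning scale (`outcome_scale * points`), transformed by
#' the condition ([condition_transform()]) and applied to the weights
#' ([update_weights()]).  Everything is deterministic given `(seed, run)`.
#'
#' @param condition condition label (see [dopamine_params()]).
#' @param n_runs number of runs (default 10).
#' @param electrode an [electrode_config()] or `NULL` for stimulation off.
#' @param config a [bg_network_config()].
#' @param schedule a [deck_schedule()].
#' @param dopamine a [dopamine_params()] for this condition.
#' @param seed base integer seed; run `r` uses a seed derived from
#'   `(seed, r)`.
#' @param keep_log keep the per-trial log (deck, outcome, delta, weights) as
#'   attribute `"log"`.
#' @param literal_input passed to [update_weights()].
#' @return an `igt_experiment`: data frame with columns `run`, `condition`,
#'   `bin1`..`bin5`, `total` (one row per run; `total` always equals the sum
#'   of the bins).
#' @export
run_igt_experiment <- function(condition = "HC", n_runs = 10,
                               electrode = NULL,
                               config = bg_network_config(),
                               schedule = deck_schedule(),
                               dopamine = dopamine_params(condition),
                               seed = 1, keep_log = FALSE,
                               literal_input = FALSE) {
  stopifnot(n_runs >= 1, inherits(config, "bg_config"))
  if (dopamine$condition != condition)
    stop("dopamine parameters are for condition ", dopamine$condition,
         ", experiment is ", condition)
  rows <- vector("list", n_runs)
  logs <- if (keep_log) vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- run_seed_for(seed, r)
    res <- run_igt_session(condition, electrode, config, schedule, dopamine,
                           run_seed, keep_log, literal_input)
    score <- igt_score(res$selections)
    rows[[r]] <- data.frame(run = r, condition = condition,
                            bin1 = score$bins[1], bin2 = score$bins[2],
                            bin3 = score$bins[3], bin4 = score$bins[4],
                            bin5 = score$bins[5], total = score$total)
    if (keep_log) logs[[r]] <- res$log
  }
  out <- do.call(rbind, rows)
  class(out) <- c("igt_experiment", "data.frame")
  attr(out, "electrode") <- electrode
  attr(out, "seed") <- seed
  if (keep_log) attr(out, "log") <- logs
  out
}

run_seed_for <- function(seed, run) {
  (as.double(seed) * 1009 + 104729 * run) %% (.Machine$integer.max - 1) + 1
}

# one 100-trial session; assumes set.seed has not been called for it yet
run_igt_session <- function(condition, electrode, config, schedule, dopamine,
                            run_seed, keep_log, literal_input) {
  set.seed(run_seed)
  w <- init_weights()
  n_trials <- 100
  selections <- character(n_trials)
  log <- if (keep_log)
    data.frame(trial = seq_len(n_trials), deck = NA_character_,
               reward = NA_real_, loss = NA_real_, delta = NA_real_,
               delta_eff = NA_real_, value = NA_real_,
               decision_ms = NA_real_, timeout = NA)
  for (k in seq_len(n_trials)) {
    trial <- simulate_trial(config, w, electrode = electrode,
                            condition = condition, seed = new_seed())
    deck <- trial$deck
    card <- draw_card(schedule, deck, k)
    v <- compute_value(w, deck)
    delta <- compute_delta(card$reward * config$outcome_scale,
                           card$loss * config$outcome_scale, v)
    delta_eff <- condition_transform(delta, dopamine)
    w <- update_weights(w, delta_eff, deck, dopamine,
                        w_max = config$w_max, literal_input = literal_input)
    selections[k] <- deck
    if (keep_log) {
      log$deck[k] <- deck
      log$reward[k] <- card$reward
      log$loss[k] <- card$loss
      log$delta[k] <- delta
      log$delta_eff[k] <- delta_eff
      log$value[k] <- v
      log$decision_ms[k] <- trial$decision_time
      log$timeout[k] <- trial$timeout
    }
  }
  list(selections = selections, weights = w, log = log)
}

#' Sweep a DBS parameter across experiments
#'
#' Runs one IGT experiment per parameter value with shared seeds across
#' values (a paired design: run `r` sees the same weight initialisation and
#' card randomness at every value, so stimulation-off at amplitude 0 is
#' bit-identical to an explicit off run).
#'
#' @param param `"position"`, `"amplitude"` or `"sigma"`.
#' @param values vector of parameter values (positions must be 1, 2 or 3).
#' @param electrode base [electrode_config()] providing the non-swept
#'   parameters.
#' @param ... passed to [run_igt_experiment()] (condition, n_runs, config,
#'   schedule, seed, ...).
#' @return an `igt_sweep`: stacked `igt_experiment` rows with `param` and
#'   `value` columns.
#' @export
dbs_sweep <- function(param = c("amplitude", "position", "sigma"), values,
                      electrode = electrode_config(), ...) {
  param <- match.arg(param)
  if (length(values) == 0) stop("empty value list")
  out <- lapply(values, function(v) {
    el <- switch(param,
      amplitude = electrode_config(center = electrode$center, amplitude = v,
                                   sigma = electrode$sigma,
                                   frequency = electrode$frequency,
                                   phase_width = electrode$phase_width),
      sigma = electrode_config(center = electrode$center,
                               amplitude = electrode$amplitude, sigma = v,
                               frequency = electrode$frequency,
                               phase_width = electrode$phase_width),
      position = electrode_config(position = v,
                                  amplitude = electrode$amplitude,
                                  sigma = electrode$sigma,
                                  frequency = electrode$frequency,
                                  phase_width = electrode$phase_width))
    tab <- run_igt_experiment(electrode = el, ...)
    tab$param <- param
    tab$value <- v
    tab
  })
  out <- do.call(rbind, out)
  class(out) <- c("igt_sweep", "data.frame")
  out
}

#' One-way fixed-effects ANOVA
#'
#' Between/within mean-square ratio over groups of equal size:
#' `F = MSB / MSW` with `(k - 1, N - k)` degrees of freedom and the p-value
#' from the F distribution.  With zero within-group variance the statistic
#' degenerates: equal means give an undefined F; unequal means give
#' `F = Inf`, `p = 0`, flagged.
#'
#' @param groups a named list of equal-length numeric vectors, or a data
#'   frame with columns `value` and `group`.
#' @return list with `F`, `df1`, `df2`, `p` and logical `degenerate`.
#' @export
anova_oneway <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  n <- lengths(groups)
  if (length(unique(n)) != 1) stop("groups must have equal size")
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  gm <- mean(x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- as.integer(k - 1)
  df2 <- as.integer(N - k)
  if (ssw == 0) {
    if (ssb == 0)
      return(list(F = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
                  degenerate = TRUE))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0, degenerate = TRUE))
  }
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE), degenerate = FALSE)
}

#' Bonferroni correction of post-hoc p-values
#'
#' `p_adj = min(1, m * p)` for each of `m` planned comparisons.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @param m number of comparisons (default `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni_posthoc <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' ANOVA and Bonferroni post-hoc analysis of IGT experiments
#'
#' Compares total IGT scores across conditions with a one-way ANOVA and all
#' pairwise Welch t-tests, Bonferroni-adjusted.
#'
#' @param ... named `igt_experiment` tables (names become group labels), or
#'   a single named list of them.
#' @return list with `anova` (see [anova_oneway()]) and `posthoc` (data
#'   frame: pair, p_raw, p_adj).
#' @export
igt_stats <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))
    tabs <- tabs[[1]]
  if (is.null(names(tabs)) || any(names(tabs) == ""))
    names(tabs) <- vapply(tabs, function(t) t$condition[1], character(1))
  groups <- lapply(tabs, function(t) t$total)
  av <- anova_oneway(groups)
  pairs <- utils::combn(names(groups), 2)
  praw <- apply(pairs, 2, function(pr)
    t.test(groups[[pr[1]]], groups[[pr[2]]])$p.value)
  posthoc <- data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                        p_raw = praw,
                        p_adj = bonferroni_posthoc(praw, ncol(pairs)))
  list(anova = av, posthoc = posthoc)
}

#' Write an experiment score table to CSV
#'
#' @param experiment an `igt_experiment` or `igt_sweep`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_scores_csv <- function(experiment, file) {
  write.csv(as.data.frame(experiment), file, row.names = FALSE)
  invisible(file)
}
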