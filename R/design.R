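#' Experimental design constants
#'
#' Factor levels and timing constants of the 3 (benefactor-intention) x
#' 3 (benefit-value) x 2 (emotion) help-reception design. Each trial shows a
#' 3-s scenario screen followed by a 0.5-s fixation, two rating screens whose
#' durations sum to 12 s (one of the permutations 8/4, 7/5, 6/6, 5/7, 4/8 s),
#' each followed by a 0.5-s fixation, for a constant 16.5-s trial.
#'
#' @name design_constants
#' @aliases INTENTION_LEVELS VALUE_LEVELS EMOTIONS RATING_ORDERS
#' @export INTENTION_LEVELS VALUE_LEVELS EMOTIONS RATING_ORDERS
NULL

INTENTION_LEVELS <- c("strong", "weak", "no")
VALUE_LEVELS <- c("high", "low", "zero")
EMOTIONS <- c("gratitude", "joy")
RATING_ORDERS <- c("gratitude_first", "joy_first")
STIM_DURATION <- 3.0
FIXATION_DURATION <- 0.5
TRIAL_SPAN <- 16.5
RATING_DURATION_PERMS <- matrix(
  c(8, 4, 7, 5, 6, 6, 5, 7, 4, 8),
  ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("rating1", "rating2"))
)
DEFAULT_TR <- 2.3
DEFAULT_N_VOLUMES <- 145

intention_percent_range <- list(strong = c(95L, 100L), weak = c(7L, 12L), no = c(0L, 0L))
value_amount_range <- list(high = c(800L, 1200L), low = c(80L, 120L), zero = c(0L, 0L))

#' Numeric modulator code for a factor level
#'
#' Strong/high map to 1, weak/low to 0, no/zero to -1.
#'
#' @param level character vector of levels.
#' @param factor_name "intention" or "value".
#' @return numeric vector of codes in \{1, 0, -1\}.
#' @export
level_code <- function(level, factor_name = c("intention", "value")) {
  factor_name <- match.arg(factor_name)
  lv <- if (factor_name == "intention") INTENTION_LEVELS else VALUE_LEVELS
  unname(c(1, 0, -1)[match(level, lv)])
}

#' Generate one run's pseudo-randomized trial schedule
#'
#' Produces 20 trials: 18 non-null trials covering each of the nine
#' intention-by-value cells exactly twice, plus 2 null trials at random
#' positions. Trial order is rejection-sampled so that no two consecutive
#' non-null trials share an intention level or a value level (null trials are
#' transparent to the adjacency check). Onsets tile at 16.5-s spacing from 0.
#'
#' @param run_index run number (>= 1).
#' @param rating_order "gratitude_first" or "joy_first" for every trial in
#'   this run.
#' @param seed integer seed.
#' @param n_trials total trials per run (default 20).
#' @param n_null null trials per run (default 2).
#' @param duration_assignment "uniform" draws each trial's rating-duration
#'   permutation independently; "balanced" cycles through the five
#'   permutations in shuffled blocks.
#' @param tr repetition time in seconds.
#' @param n_volumes volumes acquired per run.
#' @param max_tries rejection-sampling budget before an error is raised.
#' @return a \code{run_schedule}: a data.frame with one row per trial
#'   (columns \code{run_index, trial_index, onset, is_null, intention_level,
#'   intention_percent, value_level, value_amount, rating_order,
#'   stim_duration, fixation_duration, rating1_duration, rating2_duration})
#'   and attributes \code{tr}, \code{n_volumes}, \code{run_duration}.
#' @export
generate_run_schedule <- function(run_index, rating_order = RATING_ORDERS, seed,
                                  n_trials = 20L, n_null = 2L,
                                  duration_assignment = c("uniform", "balanced"),
                                  tr = DEFAULT_TR, n_volumes = DEFAULT_N_VOLUMES,
                                  max_tries = 2000L) {
  rating_order <- match.arg(rating_order)
  duration_assignment <- match.arg(duration_assignment)
  n_cond <- n_trials - n_null
  stop_if_not(n_cond %% 9L == 0L,
              "non-null trial count must be a multiple of the 9 design cells")
  set.seed(seed)

  cells <- expand.grid(intention = INTENTION_LEVELS, value = VALUE_LEVELS,
                       stringsAsFactors = FALSE)
  pool <- cells[rep(seq_len(9L), each = n_cond / 9L), ]

  # sequential constrained sampling with restarts: draw each next trial
  # uniformly among remaining trials differing from the previous one in both
  # factors; restart on a dead end
  ok <- FALSE
  for (try in seq_len(max_tries)) {
    remaining <- seq_len(nrow(pool))
    ord <- integer(n_cond)
    ord[1] <- sample(remaining, 1L)
    remaining <- setdiff(remaining, ord[1])
    dead <- FALSE
    for (k in 2:n_cond) {
      prev <- ord[k - 1]
      valid <- remaining[pool$intention[remaining] != pool$intention[prev] &
                           pool$value[remaining] != pool$value[prev]]
      if (!length(valid)) { dead <- TRUE; break }
      ord[k] <- if (length(valid) == 1L) valid else sample(valid, 1L)
      remaining <- setdiff(remaining, ord[k])
    }
    if (!dead) { ok <- TRUE; break }
  }
  if (!ok) stop("could not satisfy the adjacency constraint within ",
                max_tries, " tries", call. = FALSE)
  cand <- pool[ord, ]

  null_pos <- sort(sample.int(n_trials, n_null))
  is_null <- seq_len(n_trials) %in% null_pos
  intention <- rep(NA_character_, n_trials)
  value <- rep(NA_character_, n_trials)
  intention[!is_null] <- cand$intention
  value[!is_null] <- cand$value

  pct <- integer(n_trials)
  amt <- integer(n_trials)
  for (i in which(!is_null)) {
    rp <- intention_percent_range[[intention[i]]]
    ra <- value_amount_range[[value[i]]]
    pct[i] <- if (rp[1] == rp[2]) rp[1] else sample(rp[1]:rp[2], 1L)
    amt[i] <- if (ra[1] == ra[2]) ra[1] else sample(ra[1]:ra[2], 1L)
  }
  pct[is_null] <- NA_integer_
  amt[is_null] <- NA_integer_

  if (duration_assignment == "uniform") {
    perm_idx <- sample.int(5L, n_trials, replace = TRUE)
  } else {
    perm_idx <- unlist(lapply(seq_len(ceiling(n_trials / 5)),
                              function(i) sample.int(5L)))[seq_len(n_trials)]
  }
  durs <- RATING_DURATION_PERMS[perm_idx, , drop = FALSE]

  sched <- data.frame(
    run_index = run_index,
    trial_index = seq_len(n_trials),
    onset = (seq_len(n_trials) - 1) * TRIAL_SPAN,
    is_null = is_null,
    intention_level = intention,
    intention_percent = pct,
    value_level = value,
    value_amount = amt,
    rating_order = rating_order,
    stim_duration = STIM_DURATION,
    fixation_duration = FIXATION_DURATION,
    rating1_duration = durs[, "rating1"],
    rating2_duration = durs[, "rating2"],
    stringsAsFactors = FALSE
  )
  attr(sched, "tr") <- tr
  attr(sched, "n_volumes") <- n_volumes
  attr(sched, "run_duration") <- n_trials * TRIAL_SPAN
  stop_if_not(n_volumes * tr >= sched$onset[n_trials],
              "acquisition shorter than the last trial onset")
  class(sched) <- c("run_schedule", "data.frame")
  sched
}

#' Independently validate a run schedule
#'
#' Re-checks every timing and ordering constraint of a run schedule from
#' scratch: trial span 16.5 s, screen durations, onset tiling, 20 trials with
#' 2 nulls, exact cell balance, parameter ranges, and the adjacency rule that
#' consecutive non-null trials never share an intention or value level.
#'
#' @param sched a \code{run_schedule}.
#' @param n_trials,n_null expected counts.
#' @return TRUE invisibly, or a character vector of violations (with
#'   \code{error = FALSE}).
#' @param error raise an error on violation instead of returning messages.
#' @export
validate_run_schedule <- function(sched, n_trials = 20L, n_null = 2L, error = TRUE) {
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)

  if (nrow(sched) != n_trials) note("wrong trial count")
  if (sum(sched$is_null) != n_null) note("wrong null-trial count")

  span <- sched$stim_duration + 3 * sched$fixation_duration +
    sched$rating1_duration + sched$rating2_duration
  if (any(abs(span - TRIAL_SPAN) > 1e-9)) note("trial span != 16.5 s")
  if (any(sched$stim_duration != STIM_DURATION)) note("stimulus screen != 3 s")
  if (any(sched$fixation_duration != FIXATION_DURATION)) note("fixation != 0.5 s")
  pairs <- paste(sched$rating1_duration, sched$rating2_duration)
  legal <- paste(RATING_DURATION_PERMS[, 1], RATING_DURATION_PERMS[, 2])
  if (!all(pairs %in% legal)) note("illegal rating-duration permutation")
  if (any(abs(diff(sched$onset) - TRIAL_SPAN) > 1e-9) || sched$onset[1] != 0)
    note("onsets do not tile at 16.5 s from 0")

  nn <- sched[!sched$is_null, ]
  tab <- table(nn$intention_level, nn$value_level)
  if (!all(dim(tab) == c(3, 3)) || length(unique(c(tab))) != 1L)
    note("condition cells not exactly balanced")
  if (any(is.na(nn$intention_level)) || any(is.na(nn$value_level)))
    note("non-null trial without condition levels")
  if (any(!is.na(sched$intention_level[sched$is_null])))
    note("null trial carries condition levels")

  for (i in seq_len(nrow(nn))[-1]) {
    if (nn$intention_level[i] == nn$intention_level[i - 1] ||
        nn$value_level[i] == nn$value_level[i - 1])
      note("consecutive non-null trials share a factor level")
  }

  rng_ok <- mapply(function(lv, p) {
    r <- intention_percent_range[[lv]]; p >= r[1] && p <= r[2]
  }, nn$intention_level, nn$intention_percent)
  if (!all(rng_ok)) note("intention percent outside its condition range")
  rng_ok <- mapply(function(lv, a) {
    r <- value_amount_range[[lv]]; a >= r[1] && a <= r[2]
  }, nn$value_level, nn$value_amount)
  if (!all(rng_ok)) note("value amount outside its condition range")

  if (length(bad) && error) stop(paste(unique(bad), collapse = "; "), call. = FALSE)
  if (length(bad)) return(unique(bad))
  invisible(TRUE)
}

#' Generate a subject's multi-run design
#'
#' The per-run order of the two rating screens follows one of two
#' counterbalancing schemes, A-B-B-A-A-B or B-A-A-B-B-A, where A means the
#' gratitude rating comes first and B means the joy rating comes first.
#'
#' @param subject_id integer subject identifier.
#' @param order_scheme "ABBAAB" or "BAABBA".
#' @param seed integer seed.
#' @param n_runs number of runs to generate (default 6; 4 mirrors an
#'   incomplete participant).
#' @param ... passed to \code{\link{generate_run_schedule}}.
#' @return a \code{subject_design}: list with \code{subject_id},
#'   \code{order_scheme}, and \code{runs} (list of run schedules).
#' @export
generate_subject_design <- function(subject_id, order_scheme = c("ABBAAB", "BAABBA"),
                                    seed, n_runs = 6L, ...) {
  order_scheme <- match.arg(order_scheme)
  letters6 <- strsplit(order_scheme, "")[[1]]
  orders <- ifelse(letters6 == "A", "gratitude_first", "joy_first")[seq_len(n_runs)]
  runs <- lapply(seq_len(n_runs), function(r)
    generate_run_schedule(r, orders[r], seed = derive_seed(seed, subject_id, r), ...))
  structure(list(subject_id = subject_id, order_scheme = order_scheme, runs = runs),
            class = "subject_design")
}

#' Generate the full cohort of subject designs
#'
#' The two counterbalancing schemes alternate across subjects so each is used
#' by half the cohort.
#'
#' @param n_subjects cohort size (default 30).
#' @param seed master seed.
#' @param ... passed to \code{\link{generate_subject_design}}.
#' @return list of \code{subject_design} objects.
#' @export
generate_experiment <- function(n_subjects = 30L, seed, ...) {
  schemes <- rep(c("ABBAAB", "BAABBA"), length.out = n_subjects)
  lapply(seq_len(n_subjects), function(s)
    generate_subject_design(s, schemes[s], seed = seed, ...))
}

#' Stack a subject design's trials into one events table
#'
#' @param design a \code{subject_design}.
#' @return data.frame of all trials across runs.
#' @export
design_events <- function(design) {
  do.call(rbind, lapply(design$runs, as.data.frame))
}

#' Onset of each rating screen within a trial
#'
#' The first rating screen starts after the 3-s scenario screen and a 0.5-s
#' fixation; the second after the first rating and another fixation. Which
#' emotion each screen carries follows the run's rating order.
#'
#' @param trials data.frame of trials (rows of a run schedule).
#' @param emotion "gratitude" or "joy".
#' @return data.frame with \code{onset} and \code{duration} for that
#'   emotion's rating screen on each trial.
#' @export
rating_event_times <- function(trials, emotion = EMOTIONS) {
  emotion <- match.arg(emotion)
  first <- ifelse(trials$rating_order == "gratitude_first", "gratitude", "joy")
  is_first <- first == emotion
  onset1 <- trials$onset + trials$stim_duration + trials$fixation_duration
  onset2 <- onset1 + trials$rating1_duration + trials$fixation_duration
  data.frame(
    onset = ifelse(is_first, onset1, onset2),
    duration = ifelse(is_first, trials$rating1_duration, trials$rating2_duration)
  )
}
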