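#' Parameters of the ordinal rating generator
#'
#' Ratings are produced from a latent Gaussian model. For subject s, trial in
#' cell (i, v) and emotion e (coded +1/2 for gratitude, -1/2 for joy):
#' \deqn{y = \mu + a_i + b_v + e\,(m + g_i + h_v + d_{iv}) + u_s + \epsilon}
#' with subject intercept \eqn{u_s ~ N(0, subject_sd^2)} and residual
#' \eqn{\epsilon ~ N(0, residual_sd^2)}. The latent value is discretized at
#' \code{cutpoints} into the ordinal ratings 1 (weakly), 2 (moderately),
#' 3 (strongly). Each rating is independently missing with probability
#' \code{nonresponse_rate}.
#'
#' Defaults yield the qualitative behavioral pattern of interest: strong
#' positive main effects of both appraisal factors on both emotions, and a
#' gratitude-minus-joy difference that is positive only in the
#' strong-intention cells with low or zero value.
#'
#' @param grand_mean latent grand mean.
#' @param intention_effects named numeric, latent main effect of each
#'   intention level (strong, weak, no), shared by both emotions.
#' @param value_effects named numeric, main effect of each value level.
#' @param emotion_main latent gratitude-minus-joy difference common to all
#'   cells.
#' @param emotion_x_intention,emotion_x_value named numeric, per-level
#'   contributions to the gratitude-minus-joy difference.
#' @param emotion_x_cell 3 x 3 matrix (intention x value) of cell-specific
#'   contributions to the gratitude-minus-joy difference (the three-way
#'   structure).
#' @param subject_sd SD of the subject random intercept.
#' @param residual_sd SD of the trial-level residual.
#' @param cutpoints two increasing latent cutpoints separating ratings
#'   1 | 2 | 3.
#' @param nonresponse_rate probability a single rating is missing.
#' @return object of class \code{rating_params}.
#' @export
rating_params <- function(grand_mean = 1.95,
                          intention_effects = c(strong = 0.45, weak = -0.10, no = -0.35),
                          value_effects = c(high = 0.50, low = 0.00, zero = -0.50),
                          emotion_main = 0,
                          emotion_x_intention = c(strong = 0, weak = 0, no = 0),
                          emotion_x_value = c(high = 0, low = 0, zero = 0),
                          emotion_x_cell = NULL,
                          subject_sd = 0.20,
                          residual_sd = 0.40,
                          cutpoints = c(1.5, 2.5),
                          nonresponse_rate = 0.02) {
  if (is.null(emotion_x_cell)) {
    emotion_x_cell <- matrix(0, 3, 3)
    emotion_x_cell[1, 2:3] <- 0.30   # strong intention x low/zero value
  }
  dimnames(emotion_x_cell) <- list(INTENTION_LEVELS, VALUE_LEVELS)
  stop_if_not(all(diff(cutpoints) > 0), "cutpoints must be increasing")
  p <- list(grand_mean = grand_mean,
            intention_effects = intention_effects[INTENTION_LEVELS],
            value_effects = value_effects[VALUE_LEVELS],
            emotion_main = emotion_main,
            emotion_x_intention = emotion_x_intention[INTENTION_LEVELS],
            emotion_x_value = emotion_x_value[VALUE_LEVELS],
            emotion_x_cell = emotion_x_cell,
            subject_sd = subject_sd, residual_sd = residual_sd,
            cutpoints = cutpoints, nonresponse_rate = nonresponse_rate)
  lat <- latent_cell_means(structure(p, class = "rating_params"))
  if (any(lat < 1 - 1e-9 | lat > 3 + 1e-9))
    warning("latent cell means fall outside [1, 3]")
  structure(p, class = "rating_params")
}

#' Latent (pre-discretization) cell means of the rating model
#'
#' Closed-form expected latent value per intention x value x emotion cell,
#' before cutpoint discretization and before noise. Serves as the analytic
#' reference for the simulator.
#'
#' @param params a \code{rating_params}.
#' @return 3 x 3 x 2 array (intention x value x emotion).
#' @export
latent_cell_means <- function(params) {
  out <- array(NA_real_, c(3, 3, 2),
               dimnames = list(INTENTION_LEVELS, VALUE_LEVELS, EMOTIONS))
  for (i in INTENTION_LEVELS) for (v in VALUE_LEVELS) {
    base <- params$grand_mean + params$intention_effects[[i]] + params$value_effects[[v]]
    diff <- params$emotion_main + params$emotion_x_intention[[i]] +
      params$emotion_x_value[[v]] + params$emotion_x_cell[i, v]
    out[i, v, "gratitude"] <- base + diff / 2
    out[i, v, "joy"] <- base - diff / 2
  }
  out
}

#' Expected discretized rating means
#'
#' Marginal expectation of the ordinal rating in each cell, integrating the
#' Gaussian subject intercept and residual analytically:
#' \eqn{E[r] = 1 + P(y > c_1) + P(y > c_2)} with total SD
#' \eqn{\sqrt{subject\_sd^2 + residual\_sd^2}}.
#'
#' @param params a \code{rating_params}.
#' @return 3 x 3 x 2 array of expected ordinal means.
#' @export
expected_rating_means <- function(params) {
  mu <- latent_cell_means(params)
  s <- sqrt(params$subject_sd^2 + params$residual_sd^2)
  c1 <- params$cutpoints[1]; c2 <- params$cutpoints[2]
  if (s == 0) return(1 + (mu >= c1) + (mu >= c2))
  1 + pnorm((mu - c1) / s) + pnorm((mu - c2) / s)
}

#' Simulate per-trial ordinal emotion ratings for one subject
#'
#' Draws one subject intercept, then for every non-null trial draws latent
#' gratitude and joy values (independent residuals), discretizes them at the
#' cutpoints, and knocks out each rating independently with the nonresponse
#' rate. Null trials produce no record.
#'
#' @param design a \code{subject_design}.
#' @param params a \code{rating_params}.
#' @param seed integer seed.
#' @return data.frame with columns \code{subject_id, run_index, trial_index,
#'   intention_level, value_level, gratitude, joy} (NA where missing).
#' @export
generate_ratings <- function(design, params = rating_params(), seed) {
  set.seed(derive_seed(seed, design$subject_id, 7001L))
  u <- rnorm(1, 0, params$subject_sd)
  mu <- latent_cell_means(params)
  ev <- design_events(design)
  ev <- ev[!ev$is_null, ]
  n <- nrow(ev)

  disc <- function(y) 1L + (y >= params$cutpoints[1]) + (y >= params$cutpoints[2])
  idx <- cbind(match(ev$intention_level, INTENTION_LEVELS),
               match(ev$value_level, VALUE_LEVELS))
  g <- disc(mu[cbind(idx, 1L)] + u + rnorm(n, 0, params$residual_sd))
  j <- disc(mu[cbind(idx, 2L)] + u + rnorm(n, 0, params$residual_sd))
  g[runif(n) < params$nonresponse_rate] <- NA_integer_
  j[runif(n) < params$nonresponse_rate] <- NA_integer_

  data.frame(subject_id = design$subject_id,
             run_index = ev$run_index, trial_index = ev$trial_index,
             intention_level = ev$intention_level, value_level = ev$value_level,
             gratitude = as.integer(g), joy = as.integer(j),
             stringsAsFactors = FALSE)
}

#' Simulate ratings for a whole cohort
#'
#' @param designs list of \code{subject_design} objects.
#' @param params a \code{rating_params}.
#' @param seed master seed.
#' @return stacked data.frame of rating records.
#' @export
generate_cohort_ratings <- function(designs, params = rating_params(), seed) {
  do.call(rbind, lapply(designs, generate_ratings, params = params, seed = seed))
}
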