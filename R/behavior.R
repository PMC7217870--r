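#' Per-subject cell means of the emotion ratings
#'
#' Trials where either the gratitude or the joy rating is missing are
#' excluded from both emotions' aggregation before averaging, so every cell
#' mean for a subject is computed over the same trial set for the two
#' emotions.
#'
#' @param ratings stacked rating records (see \code{\link{generate_ratings}}).
#' @param drop_incomplete drop subjects with any empty cell (default FALSE;
#'   empty cells are flagged either way).
#' @return long data.frame with columns \code{subject_id, emotion,
#'   intention_level, value_level, rating} (the subject's cell mean) and
#'   \code{n_trials}; attribute \code{"empty_cells"} lists subject/cell
#'   combinations with no usable trials.
#' @export
subject_cell_means <- function(ratings, drop_incomplete = FALSE) {
  keep <- !is.na(ratings$gratitude) & !is.na(ratings$joy)
  r <- ratings[keep, ]
  long <- rbind(
    data.frame(subject_id = r$subject_id, emotion = "gratitude",
               intention_level = r$intention_level, value_level = r$value_level,
               rating = r$gratitude, stringsAsFactors = FALSE),
    data.frame(subject_id = r$subject_id, emotion = "joy",
               intention_level = r$intention_level, value_level = r$value_level,
               rating = r$joy, stringsAsFactors = FALSE)
  )
  agg <- aggregate(rating ~ subject_id + emotion + intention_level + value_level,
                   data = long, FUN = mean)
  cnt <- aggregate(rating ~ subject_id + emotion + intention_level + value_level,
                   data = long, FUN = length)
  agg$n_trials <- cnt$rating[match(
    interaction(agg$subject_id, agg$emotion, agg$intention_level, agg$value_level),
    interaction(cnt$subject_id, cnt$emotion, cnt$intention_level, cnt$value_level))]

  full <- expand.grid(subject_id = unique(ratings$subject_id), emotion = EMOTIONS,
                      intention_level = INTENTION_LEVELS, value_level = VALUE_LEVELS,
                      stringsAsFactors = FALSE)
  m <- merge(full, agg, all.x = TRUE)
  empty <- m[is.na(m$rating), c("subject_id", "emotion", "intention_level", "value_level")]
  if (nrow(empty) && drop_incomplete)
    m <- m[!(m$subject_id %in% unique(empty$subject_id)), ]
  m <- m[order(m$subject_id, m$emotion, m$intention_level, m$value_level), ]
  rownames(m) <- NULL
  attr(m, "empty_cells") <- empty
  m
}

#' Group summary of cell means
#'
#' Mean and SD across subjects of the per-subject cell means, one row per
#' emotion x intention x value cell.
#'
#' @param cell_means output of \code{\link{subject_cell_means}}.
#' @return data.frame with \code{emotion, intention_level, value_level, mean,
#'   sd, n_subjects}.
#' @export
cell_summary <- function(cell_means) {
  agg <- aggregate(rating ~ emotion + intention_level + value_level,
                   data = cell_means,
                   FUN = function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  out <- data.frame(agg[, 1:3],
                    mean = agg$rating[, "mean"], sd = agg$rating[, "sd"],
                    n_subjects = agg$rating[, "n"])
  out
}

#' Fully within-subject repeated-measures ANOVA
#'
#' Classical univariate decomposition for a balanced, complete
#' subject-by-cells table: each within-subject effect is tested against its
#' effect-by-subject interaction mean square (fitted through
#' \code{stats::aov} with an \code{Error(subject/...)} term). Partial
#' eta-squared is SS_effect / (SS_effect + SS_error). Greenhouse-Geisser
#' sphericity correction is available as an option; by default uncorrected
#' degrees of freedom are reported.
#'
#' @param data long data.frame of one value per subject x cell.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor column names.
#' @param subject name of the subject identifier column.
#' @param gg apply Greenhouse-Geisser correction to df and p.
#' @return data.frame (class \code{anova_table}) with one row per effect:
#'   \code{effect, df_num, df_den, SS, SS_error, F, p, partial_eta_sq} (and
#'   \code{gg_epsilon} if corrected).
#' @export
rm_anova <- function(data, dv = "rating", within, subject = "subject_id", gg = FALSE) {
  d <- data
  d$.subj <- factor(d[[subject]])
  for (w in within) d[[w]] <- factor(d[[w]])
  d$.y <- d[[dv]]

  tab <- table(d$.subj, interaction(d[within]))
  if (any(tab != 1L))
    stop("rm_anova requires a complete balanced table: exactly one value per subject per cell",
         call. = FALSE)

  rhs <- paste(within, collapse = "*")
  f <- as.formula(paste0(".y ~ ", rhs, " + Error(.subj/(", rhs, "))"))
  fit <- aov(f, data = d)
  sm <- summary(fit)

  rows <- list()
  for (stratum in sm) {
    st <- stratum[[1]]
    eff_rows <- rownames(st)[trimws(rownames(st)) != "Residuals"]
    if (!length(eff_rows)) next
    res_i <- which(trimws(rownames(st)) == "Residuals")
    for (e in eff_rows) {
      i <- which(rownames(st) == e)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = trimws(e),
        df_num = st$Df[i], df_den = st$Df[res_i],
        SS = st[["Sum Sq"]][i], SS_error = st[["Sum Sq"]][res_i],
        F = st[["F value"]][i], p = st[["Pr(>F)"]][i],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$partial_eta_sq <- out$SS / (out$SS + out$SS_error)

  if (gg) {
    out$gg_epsilon <- NA_real_
    for (i in seq_len(nrow(out))) {
      eps <- gg_epsilon(d, strsplit(out$effect[i], ":")[[1]], within)
      out$gg_epsilon[i] <- eps
      out$df_num[i] <- out$df_num[i] * eps
      out$df_den[i] <- out$df_den[i] * eps
      out$p[i] <- pf(out$F[i], out$df_num[i], out$df_den[i], lower.tail = FALSE)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

# Greenhouse-Geisser epsilon for one within-subject effect: eigen-structure of
# the covariance of the subject-level contrast scores for that effect.
gg_epsilon <- function(d, effect_factors, within) {
  ortho_contrasts <- function(k) {
    C <- contr.helmert(k)
    C / rep(sqrt(colSums(C^2)), each = k)
  }
  # kronecker(C_w, C) makes the earlier factors vary fastest in the row index,
  # matching expand.grid's ordering below
  C <- matrix(1, 1, 1)
  for (w in within) {
    k <- nlevels(d[[w]])
    Cw <- if (w %in% effect_factors) ortho_contrasts(k) else matrix(1 / sqrt(k), k, 1)
    C <- kronecker(Cw, C)
  }
  grid <- expand.grid(lapply(within, function(w) levels(d[[w]])),
                      stringsAsFactors = FALSE)
  key <- do.call(paste, c(grid, list(sep = "\r")))
  dkey <- do.call(paste, c(lapply(within, function(w) as.character(d[[w]])),
                           list(sep = "\r")))
  subs <- levels(d$.subj)
  Y <- t(vapply(subs, function(s) {
    sel <- d$.subj == s
    d$.y[sel][match(key, dkey[sel])]
  }, numeric(length(key))))
  S <- cov(Y %*% C)
  dd <- ncol(C)
  if (dd <= 1) return(1)
  sum(diag(S))^2 / (dd * sum(S * S))
}

#' Planned paired comparison between averaged cell sets
#'
#' Averages each subject's cell means over the cells selected by \code{a} and
#' over those selected by \code{b}, then runs a classical paired t-test
#' (df = n - 1). Cell sets are given as filters, e.g.
#' \code{list(emotion = "gratitude", intention_level = "strong",
#' value_level = c("low", "zero"))}; omitted fields match everything.
#'
#' @param cell_means output of \code{\link{subject_cell_means}}.
#' @param a,b cell filters (named lists).
#' @param dv value column name.
#' @return list with \code{t, df, p, mean_diff, mean_a, mean_b, n}.
#' @export
paired_comparison <- function(cell_means, a, b, dv = "rating") {
  pick <- function(filter) {
    keep <- rep(TRUE, nrow(cell_means))
    for (nm in names(filter)) keep <- keep & cell_means[[nm]] %in% filter[[nm]]
    x <- cell_means[keep, ]
    tapply(x[[dv]], x$subject_id, mean)
  }
  xa <- pick(a); xb <- pick(b)
  stop_if_not(identical(names(xa), names(xb)), "cell sets cover different subjects")
  n <- length(xa)
  stop_if_not(n >= 2, "need at least 2 subjects")
  d <- xa - xb
  if (sd(d) == 0) {
    # degenerate: identical (t = 0) or constant nonzero difference (t = +/-Inf)
    tt <- list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
               parameter = n - 1,
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- t.test(xa, xb, paired = TRUE)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(mean(xa - xb)), mean_a = mean(xa), mean_b = mean(xb), n = n)
}
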