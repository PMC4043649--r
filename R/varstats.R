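#' Cohort dispersion summary
#'
#' Per-population sample statistics across animals: n, mean, SD (n-1
#' denominator), SE, CV = SD/mean, and the percentile set used by
#' box-and-whisker displays (1, 10, 25, 50, 75, 90, 99; linear interpolation,
#' `quantile` type 7, fixed so summaries are bit-reproducible).
#'
#' @param table long data.frame with at least `population` and a value column.
#' @param value name of the value column (default `cells_per_ul`).
#' @param use_qc drop rows with `qc_pass == FALSE` when that column exists
#'   (default TRUE).
#' @return data.frame, one row per population. `cv` is a ratio (multiply by
#'   100 for percent); `cv` is `NA` with zero mean.
#' @export
cohort_summary <- function(table, value = "cells_per_ul", use_qc = TRUE) {
  if (use_qc && "qc_pass" %in% names(table)) table <- table[table$qc_pass, ]
  probs <- c(0.01, 0.10, 0.25, 0.50, 0.75, 0.90, 0.99)
  out <- lapply(split(table[[value]], table$population), function(v) {
    v <- v[is.finite(v)]
    n <- length(v)
    if (n < 2) stopf("cohort_summary needs >= 2 samples per population")
    m <- mean(v); s <- stats::sd(v)
    q <- stats::quantile(v, probs, type = 7, names = FALSE)
    data.frame(n = n, mean = m, sd = s, se = s / sqrt(n),
               cv = if (m == 0) NA_real_ else s / m,
               p1 = q[1], p10 = q[2], p25 = q[3], p50 = q[4],
               p75 = q[5], p90 = q[6], p99 = q[7])
  })
  res <- do.call(rbind, out)
  res <- cbind(population = rownames(res), res)
  rownames(res) <- NULL
  res
}

#' Duplicate inter-assay coefficient of variation
#'
#' Per pair, `CV_pair = SD(two values, n-1 denominator) / mean(two values)`;
#' the reported per-population statistic aggregates the per-pair CVs across
#' animals. With two replicates the plain mean of pair CVs underestimates the
#' underlying CV by the normal-theory factor c4 = sqrt(2/pi); the default
#' divides it out. `correct = "none"` gives the uncorrected mean,
#' `correct = "rms"` the root-mean-square aggregate (also consistent).
#'
#' @param table long data.frame with `population`, `animal_id` (or `pair`) and
#'   a value column; exactly two rows per animal x population.
#' @param value value column name.
#' @param correct aggregation: `"c4"` (default), `"none"` or `"rms"`.
#' @return data.frame per population: `n_pairs`, `cv` (ratio).
#' @export
inter_assay_cv <- function(table, value = "cells_per_ul",
                           correct = c("c4", "none", "rms")) {
  correct <- match.arg(correct)
  out <- lapply(split(table, table$population), function(df) {
    key <- if ("pair" %in% names(df) && !all(is.na(df$pair)))
      interaction(df$animal_id, df$pair, drop = TRUE) else df$animal_id
    pair_cv <- vapply(split(df[[value]], key), function(v) {
      v <- v[is.finite(v)]
      if (length(v) != 2) stopf("each pair needs exactly two values (got %d)",
                                length(v))
      if (mean(v) == 0) stopf("pair with zero mean: CV undefined")
      stats::sd(v) / mean(v)
    }, numeric(1))
    if (length(pair_cv) < 1) stopf("no pairs")
    cv <- switch(correct,
                 c4 = mean(pair_cv) / sqrt(2 / pi),
                 none = mean(pair_cv),
                 rms = sqrt(mean(pair_cv^2)))
    data.frame(n_pairs = length(pair_cv), cv = cv)
  })
  res <- do.call(rbind, out)
  res <- cbind(population = rownames(res), res)
  rownames(res) <- NULL
  res
}

#' Baseline-delta kinetics
#'
#' Subtracts each animal's day-0 (baseline) value from all of its
#' measurements, per subset, and summarizes group means with SE per day.
#' Additive shifts of one animal's trajectory cancel in its deltas.
#'
#' @param table long data.frame: `animal_id`, `group`, `day`, `population`,
#'   value column; every animal needs a day-0 row per population.
#' @param value value column name.
#' @return List: `deltas` (per animal-day-population) and `summary`
#'   (group x day x population mean, SE, n). Day-0 deltas are exactly 0.
#' @export
delta_kinetics <- function(table, value = "cells_per_ul") {
  need <- c("animal_id", "day", "population")
  if (!all(need %in% names(table))) stopf("table must have %s",
                                          paste(need, collapse = ", "))
  key <- paste(table$animal_id, table$population)
  base_rows <- table$day == 0
  if (!all(key %in% key[base_rows]))
    stopf("animal without a day-0 baseline measurement")
  baseline <- stats::setNames(table[[value]][base_rows], key[base_rows])
  deltas <- table
  deltas$delta <- table[[value]] - baseline[key]
  smry <- do.call(rbind, lapply(
    split(deltas, list(deltas$group, deltas$day, deltas$population), drop = TRUE),
    function(df) {
      v <- df$delta[is.finite(df$delta)]
      data.frame(group = df$group[1], day = df$day[1],
                 population = df$population[1], n = length(v),
                 mean_delta = mean(v),
                 se = stats::sd(v) / sqrt(length(v)), row.names = NULL)
    }))
  rownames(smry) <- NULL
  smry <- smry[order(smry$group, smry$population, smry$day), ]
  list(deltas = deltas, summary = smry)
}

#' CV time course of a study design
#'
#' Per day and subset, the coefficient of variation of absolute counts across
#' the animals measured that day. Applied to a sequential (intra-group) study
#' and a cross-sectional (inter-group) study it reproduces the
#' repeated-measures versus independent-cohorts dispersion comparison.
#'
#' @param table long data.frame: `day`, `population`, value column.
#' @param design label stored in the output (`"intra-group"` or
#'   `"inter-group"`).
#' @param value value column name.
#' @return data.frame: design, day, population, n, cv (ratio); days sorted.
#' @export
cv_timecourse <- function(table, design = "intra-group",
                          value = "cells_per_ul") {
  out <- do.call(rbind, lapply(
    split(table, list(table$day, table$population), drop = TRUE),
    function(df) {
      v <- df[[value]][is.finite(df[[value]])]
      if (length(v) < 2) stopf("need >= 2 animals at day %s", df$day[1])
      data.frame(design = design, day = df$day[1],
                 population = df$population[1], n = length(v),
                 cv = stats::sd(v) / mean(v), row.names = NULL)
    }))
  rownames(out) <- NULL
  out[order(out$population, out$day), ]
}

#' Rank correlation
#'
#' Spearman rank correlation with midrank ties (the study's correlation
#' statistic).
#'
#' @param x,y paired finite numeric vectors, n >= 3.
#' @param method passed to [stats::cor()]; default `"spearman"`.
#' @return Correlation coefficient.
#' @export
correlate <- function(x, y, method = "spearman") {
  if (length(x) != length(y)) stopf("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stopf("need at least 3 finite pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stopf("constant input vector: correlation undefined")
  stats::cor(x[ok], y[ok], method = method)
}

#' Compare group means
#'
#' Two groups: two-sided unpaired t-test. More than two: one-way ANOVA
#' followed by Tukey's HSD.
#'
#' @param value numeric response.
#' @param group group factor/character.
#' @return List: `test` ("t" or "anova"), `statistic`, `df`, `p_value`, and
#'   `tukey` (data.frame of pairwise contrasts) for the ANOVA path.
#' @export
group_compare <- function(value, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stopf("need >= 2 groups")
  if (any(table(group) < 2)) stopf("each group needs n >= 2")
  if (stats::sd(value) == 0)
    return(list(test = if (nlevels(group) == 2) "t" else "anova",
                statistic = 0, df = NA_real_, p_value = 1, tukey = NULL))
  if (nlevels(group) == 2) {
    tt <- stats::t.test(value ~ group, var.equal = FALSE)
    list(test = "t", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value, tukey = NULL)
  } else {
    fit <- stats::aov(value ~ group)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$group
    list(test = "anova", statistic = an[1, "F value"],
         df = c(an[1, "Df"], an[2, "Df"]), p_value = an[1, "Pr(>F)"],
         tukey = data.frame(contrast = rownames(tk), tk, row.names = NULL))
  }
}

#' Per-day group comparison with multiplicity correction
#'
#' Runs [group_compare()] on each day's deltas (or counts) for one subset and
#' adjusts p-values across days (Bonferroni by default), a simplification of
#' the two-way ANOVA interaction contrasts used for MI-versus-sham kinetics.
#'
#' @param table long data.frame: `group`, `day`, `population`, value column.
#' @param groups the two (or more) groups to compare.
#' @param population subset to test.
#' @param value value column name.
#' @param adjust [stats::p.adjust()] method across days.
#' @param exclude_baseline drop day 0 (deltas are identically 0 there).
#' @return data.frame: day, statistic, p_value, p_adj.
#' @export
compare_groups_by_day <- function(table, groups = c("MI", "SHAM"),
                                  population, value = "delta",
                                  adjust = "bonferroni",
                                  exclude_baseline = TRUE) {
  df <- table[table$group %in% groups & table$population == population, ]
  if (exclude_baseline) df <- df[df$day != 0, ]
  days <- sort(unique(df$day))
  res <- do.call(rbind, lapply(days, function(d) {
    sub <- df[df$day == d, ]
    gc <- group_compare(sub[[value]], sub$group)
    data.frame(day = d, statistic = gc$statistic, p_value = gc$p_value)
  }))
  res$p_adj <- stats::p.adjust(res$p_value, method = adjust)
  res
}
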