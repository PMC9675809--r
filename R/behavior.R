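#' One-way ANOVA on a behavioral measure across the four conditions
#'
#' Classical one-way between-groups ANOVA treating the subject-by-condition
#' cells as independent observations (4 conditions x N subjects gives
#' df = 3 and 4N - 4; with 71 subjects, F(3, 280)).
#'
#' @param table behavioral data frame with columns `subject`, `condition`,
#'   `n_correct`, `mean_rt`.
#' @param measure `"accuracy"` (number of correct responses) or `"rt"`
#'   (mean reaction time, ms).
#' @return list with `F`, `df_between`, `df_within`, `p`, and `degenerate`
#'   (TRUE when all observations are identical so F is 0/0).
#' @export
one_way_anova <- function(table, measure = c("accuracy", "rt")) {
  measure <- match.arg(measure)
  y <- if (measure == "accuracy") table$n_correct else table$mean_rt
  g <- factor(table$condition)
  .assert(nlevels(g) >= 2, "need at least 2 conditions", "too_few_groups")
  cnt <- table(g)
  if (any(cnt == 0)) .err("empty condition cell", "empty_cell")
  .assert(all(cnt >= 2), "need at least 2 observations per condition",
          "too_few_observations")
  if (stats::var(y) == 0)
    return(list(F = NA_real_, df_between = nlevels(g) - 1L,
                df_within = length(y) - nlevels(g), p = NA_real_,
                degenerate = TRUE))
  fit <- anova(lm(y ~ g))
  list(F = fit$`F value`[1], df_between = fit$Df[1], df_within = fit$Df[2],
       p = fit$`Pr(>F)`[1], degenerate = FALSE)
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' All six pairwise two-sample t-tests (pooled variance) between the four
#' conditions; each pair is judged against the adjusted threshold
#' `family_alpha / divisor`. The divisor defaults to 4, reproducing the
#' adjusted alpha of 0.05 / 4 = 0.0125 used in the study design this
#' simulator emulates (a deliberate divergence from the textbook divisor of
#' 6 pairs). A warning is issued when the omnibus ANOVA is not significant.
#'
#' @param table behavioral table as in [one_way_anova()].
#' @param measure `"accuracy"` or `"rt"`.
#' @param family_alpha family-wise alpha (default 0.05).
#' @param divisor Bonferroni divisor (default 4).
#' @return data frame of pairs with mean difference, t, raw p, and
#'   significance at the adjusted alpha (stored in the `adjusted_alpha`
#'   attribute).
#' @export
posthoc_bonferroni <- function(table, measure = c("accuracy", "rt"),
                               family_alpha = 0.05, divisor = 4) {
  measure <- match.arg(measure)
  omni <- one_way_anova(table, measure)
  if (!isTRUE(omni$degenerate) && !is.na(omni$p) && omni$p > family_alpha)
    warning("omnibus ANOVA is not significant; post-hoc tests are exploratory")
  y <- if (measure == "accuracy") table$n_correct else table$mean_rt
  g <- as.character(table$condition)
  conds <- intersect(.conditions, unique(g))
  adj <- family_alpha / divisor
  pairs <- combn(conds, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- y[g == pairs[1, i]]
    b <- y[g == pairs[2, i]]
    if (sd(c(a - mean(a), b - mean(b))) == 0) {
      p <- if (mean(a) == mean(b)) 1 else NA_real_
      tt <- list(statistic = c(t = 0), p.value = p)
    } else tt <- t.test(a, b, var.equal = TRUE)
    data.frame(condition_a = pairs[1, i], condition_b = pairs[2, i],
               mean_diff = mean(a) - mean(b),
               t = unname(tt$statistic), p_raw = tt$p.value,
               significant = !is.na(tt$p.value) && tt$p.value < adj,
               stringsAsFactors = FALSE)
  }))
  attr(out, "adjusted_alpha") <- adj
  attr(out, "omnibus") <- omni
  out
}
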