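# Statistics layer: the tests used throughout the analysis, each returned as
# a uniform `test_result` record so report tables stay traceable.
#
# Standard tests are delegated to base R (cor.test, fisher.test, ks.test,
# t.test, aov/TukeyHSD, lm/anova) and emmeans (Sidak comparisons after a
# mixed-design ANOVA); this file defines the uniform result surface, the
# degenerate-input policy, and the ANCOVA model comparison sequence.

test_result <- function(method, statistic = NA_real_, df = NA_real_,
                        p = NA_real_, adjusted_p = NA_real_, n = NA_integer_,
                        estimate = NA_real_, degenerate = FALSE) {
  tibble::tibble(method = method, statistic = statistic, df_txt = paste(df, collapse = ","),
                 p = p, adjusted_p = adjusted_p, n = paste(n, collapse = ","),
                 estimate = estimate, degenerate = degenerate)
}

#' Pearson correlation test
#'
#' Two-sided test of zero correlation via `t = r * sqrt((n - 2) / (1 - r^2))`
#' on n - 2 df. Zero-variance input returns a flagged degenerate record
#' rather than an error so pipelines on pathological data keep running.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return A one-row `test_result` tibble (`estimate` = r).
#' @export
pearson_test <- function(x, y) {
  abort_if(length(x) != length(y), "`x` and `y` must be paired")
  abort_if(length(x) < 3L, "need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(test_result("pearson", n = length(x), degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result("pearson", statistic = unname(ct$statistic),
              df = unname(ct$parameter), p = ct$p.value, n = length(x),
              estimate = unname(ct$estimate))
}

#' Two-sided Fisher exact test (probability method)
#'
#' Two-sided p-value for a 2x2 table as the sum of hypergeometric
#' probabilities (margins fixed) of all tables no more probable than the
#' observed one. This is the method implemented by `fisher.test` and by the
#' common commercial statistics packages.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome yes/no).
#' @return A one-row `test_result` tibble (`estimate` = conditional odds
#'   ratio estimate).
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  abort_if(!all(dim(tab) == c(2L, 2L)), "`tab` must be 2x2")
  abort_if(any(tab < 0), "cell counts must be non-negative")
  abort_if(sum(tab) < 1, "table must contain at least one observation")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  test_result("fisher_exact", p = ft$p.value, n = sum(tab),
              estimate = unname(ft$estimate))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |ECDF_x - ECDF_y|; the p-value is exact for small samples without
#' ties and asymptotic otherwise (base `ks.test` policy).
#'
#' @param x,y Numeric samples.
#' @return A one-row `test_result` tibble (`statistic` = D).
#' @export
ks_two_sample <- function(x, y) {
  abort_if(length(x) < 1L || length(y) < 1L, "both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(x, y))
  test_result("ks_two_sample", statistic = unname(kt$statistic),
              p = kt$p.value, n = c(length(x), length(y)))
}

#' Unpaired two-sample t test
#'
#' Pooled-variance two-sided t test by default (matching the source
#' analyses); Welch correction available via `welch = TRUE`. Two identical
#' constant samples are degenerate (zero variance) and flagged.
#'
#' @param x,y Numeric samples, each n >= 2.
#' @param welch Use the Welch unequal-variance form (default `FALSE`).
#' @return A one-row `test_result` tibble (`estimate` = mean(x) - mean(y)).
#' @export
unpaired_t <- function(x, y, welch = FALSE) {
  abort_if(length(x) < 2L || length(y) < 2L, "need n >= 2 per group")
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
    return(test_result("unpaired_t", statistic = 0,
                       p = 1, n = c(length(x), length(y)),
                       estimate = mean(x) - mean(y), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  test_result(if (welch) "welch_t" else "unpaired_t",
              statistic = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, n = c(length(x), length(y)),
              estimate = mean(x) - mean(y))
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for m planned comparisons.
#'
#' @param p Unadjusted p-values.
#' @param m Number of comparisons in the family (default `length(p)`).
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  abort_if(m < 1, "`m` must be >= 1")
  1 - (1 - p)^m
}

#' One-way ANOVA with Tukey HSD comparisons
#'
#' F = MS_between / MS_within, followed by Tukey honestly-significant-
#' difference pairwise comparisons from the studentized-range distribution
#' (Tukey-Kramer for unequal group sizes), both via base `aov`/`TukeyHSD`.
#'
#' @param values Numeric response.
#' @param groups Group factor aligned with `values` (>= 2 groups, each
#'   n >= 2).
#' @return List: `omnibus` (one-row `test_result`, F test) and `pairwise`
#'   (tibble of comparisons with differences and Tukey-adjusted p).
#' @export
oneway_anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  abort_if(nlevels(groups) < 2L, "need >= 2 groups")
  abort_if(any(table(groups) < 2L), "every group needs n >= 2")
  if (stats::sd(values - stats::ave(values, groups)) == 0) {
    # zero within-group variance: F undefined
    return(list(
      omnibus = test_result("oneway_anova", n = length(values),
                            degenerate = TRUE),
      pairwise = tibble::tibble()))
  }
  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$groups
  cmp <- tibble::tibble(
    comparison = rownames(tk), diff = tk[, "diff"],
    lwr = tk[, "lwr"], upr = tk[, "upr"], adjusted_p = tk[, "p adj"]
  )
  list(
    omnibus = test_result("oneway_anova", statistic = sm[["F value"]][1L],
                          df = sm[["Df"]], p = sm[["Pr(>F)"]][1L],
                          n = length(values)),
    pairwise = cmp
  )
}

#' Mixed-design (two-way repeated-measures) ANOVA with Sidak comparisons
#'
#' One between-subjects factor (group) crossed with a two-level
#' within-subject factor, fit as `aov(value ~ group * level + Error(subject))`
#' so the within and interaction effects are tested against the
#' subject-by-level error stratum. With two within levels sphericity holds
#' trivially, so no correction is applied. Planned comparisons are pairwise
#' group contrasts within each within-level, Sidak-adjusted
#' (`p_adj = 1 - (1 - p)^m`) via emmeans.
#'
#' @param data Data frame with columns `subject`, `group`, `level`, `value`;
#'   every subject must have a value at both levels.
#' @return List: `anova` (tibble of the three F tests: group, level,
#'   group:level) and `comparisons` (tibble of Sidak-adjusted group
#'   contrasts per level).
#' @export
twoway_rm_anova_sidak <- function(data) {
  needed <- c("subject", "group", "level", "value")
  abort_if(!all(needed %in% names(data)),
           paste("`data` needs columns:", paste(needed, collapse = ", ")))
  data <- data |>
    dplyr::mutate(subject = factor(.data$subject), group = factor(.data$group),
                  level = factor(.data$level))
  abort_if(nlevels(data$level) != 2L, "the within factor must have two levels")
  cells <- table(data$subject, data$level)
  abort_if(any(cells != 1L), "every subject needs exactly one value per level")
  abort_if(any(table(unique(data[, c("subject", "group")])$group) < 2L),
           "need >= 2 subjects per group")
  # inline the data in the call: emmeans re-evaluates it when refitting
  fit <- eval(bquote(stats::aov(value ~ group * level + Error(subject),
                                data = .(as.data.frame(data)))))
  sm <- summary(fit)
  btw <- sm[["Error: subject"]][[1L]]
  wth <- sm[["Error: Within"]][[1L]]
  eff <- function(tb, name) {
    i <- match(name, trimws(rownames(tb)))
    tibble::tibble(effect = name, df = tb[["Df"]][i],
                   df_error = tb[["Df"]][nrow(tb)],
                   statistic = tb[["F value"]][i], p = tb[["Pr(>F)"]][i])
  }
  an <- dplyr::bind_rows(eff(btw, "group"), eff(wth, "level"),
                         eff(wth, "group:level"))
  # within-subject stratum numerically empty (both levels identical per
  # subject): the within and interaction effects are exactly null
  if (sum(wth[["Sum Sq"]]) < 1e-9 * (sum(btw[["Sum Sq"]]) +
                                       sum(wth[["Sum Sq"]]) + 1e-300)) {
    an$statistic[an$effect != "group"] <- 0
    an$p[an$effect != "group"] <- 1
  }
  emm <- emmeans::emmeans(fit, ~ group | level, data = data)
  cmp <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "sidak"))
  comparisons <- tibble::tibble(
    level = cmp$level, contrast = cmp$contrast, estimate = cmp$estimate,
    se = cmp$SE, df = cmp$df, statistic = cmp$t.ratio, adjusted_p = cmp$p.value
  )
  list(anova = an, comparisons = comparisons)
}

#' ANCOVA comparison of regression slopes and intercepts
#'
#' Fits the full model `y ~ x * group`; slope equality is the F test of the
#' interaction block against the full model. When slope equality is not
#' rejected at `alpha`, intercept (elevation) equality is the F test of the
#' group block in the common-slope model `y ~ x + group`. With a single
#' group the result degenerates to plain OLS. Noiseless (zero-residual)
#' input yields exact coefficient estimates with flagged, undefined p-values.
#'
#' @param data Data frame with columns `x`, `y`, `group`.
#' @param alpha Slope-homogeneity gate for reporting the intercept test
#'   (default 0.05).
#' @return List: `p_slope_equal`, `p_intercept_equal` (`NA` unless slope
#'   equality was retained), `common_slope`, `per_group` (tibble of
#'   per-group OLS slope/intercept/n), `degenerate`.
#' @export
ancova_compare <- function(data, alpha = 0.05) {
  abort_if(!all(c("x", "y", "group") %in% names(data)),
           "`data` needs columns x, y, group")
  data$group <- factor(data$group)
  per_group <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      abort_if(nrow(d) < 3L, "each group needs n >= 3")
      abort_if(stats::sd(d$x) == 0, "degenerate x within a group")
      f <- stats::lm(y ~ x, data = d)
      tibble::tibble(slope = unname(stats::coef(f)[2L]),
                     intercept = unname(stats::coef(f)[1L]), n = nrow(d))
    }) |>
    dplyr::ungroup()
  if (nlevels(data$group) < 2L) {
    return(list(p_slope_equal = NA_real_, p_intercept_equal = NA_real_,
                common_slope = per_group$slope[1L], per_group = per_group,
                degenerate = FALSE))
  }
  full <- stats::lm(y ~ x * group, data = data)
  common <- stats::lm(y ~ x + group, data = data)
  base_m <- stats::lm(y ~ x, data = data)
  degenerate <- summary(full)$sigma < 1e-8 * max(stats::sd(data$y), 1e-8)
  p_slope <- stats::anova(common, full)[["Pr(>F)"]][2L]
  p_inter <- stats::anova(base_m, common)[["Pr(>F)"]][2L]
  if (!degenerate && !is.na(p_slope) && p_slope <= alpha) {
    p_inter <- NA_real_  # slopes differ; elevation comparison not meaningful
  }
  list(p_slope_equal = p_slope, p_intercept_equal = p_inter,
       common_slope = unname(stats::coef(common)["x"]),
       per_group = per_group,
       # group coefficient(s) of the common-slope model = intercept offsets
       intercept_offsets = stats::coef(common)[-(1:2)],
       degenerate = degenerate)
}
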