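# The statistics layer against first-principles oracles.

test_that("pearson test recovers perfect and degenerate correlation", {
  p1 <- pearson_test(0:2, 0:2)
  expect_equal(p1$estimate, 1)
  p2 <- pearson_test(0:3, -(0:3))
  expect_equal(p2$estimate, -1)
  pd <- pearson_test(c(1, 1, 1), 1:3)
  expect_true(pd$degenerate)
  # statistic follows t = r * sqrt((n - 2) / (1 - r^2))
  set.seed(501)
  x <- rnorm(15); y <- 0.4 * x + rnorm(15)
  p <- pearson_test(x, y)
  r <- p$estimate
  expect_equal(p$statistic, r * sqrt(13 / (1 - r^2)), tolerance = 1e-9)
  expect_equal(p$p, 2 * pt(-abs(p$statistic), 13), tolerance = 1e-12)
})

test_that("two-sided Fisher p equals hypergeometric enumeration", {
  # the reconstructed high-social-interest tables and their reported p values
  expect_equal(signif(fisher_exact_two_sided(rbind(c(5, 1), c(2, 7)))$p, 3),
               0.0406)
  expect_equal(fisher_exact_two_sided(rbind(c(5, 1), c(7, 6)))$p, 0.3331,
               tolerance = 1e-3)
  # degenerate column
  expect_equal(fisher_exact_two_sided(rbind(c(0, 4), c(0, 6)))$p, 1)

  set.seed(502)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(1, 4, 10), 1L)), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_two_sided(tab)$p
    expect_equal(p, oracle_fisher_p(tab), tolerance = 1e-7)
    expect_gt(p, 0); expect_lte(p, 1)
    # invariance to simultaneous row and column swaps
    expect_equal(fisher_exact_two_sided(tab[2:1, 2:1])$p, p,
                 tolerance = 1e-12)
  }
})

test_that("KS statistic spans identical and disjoint samples", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 6:10 + 0.5)$statistic, 1)
  set.seed(503)
  a <- rnorm(8); b <- rnorm(12)
  got <- ks_two_sample(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
})

test_that("unpaired t is two-sided pooled-variance and equals F for 2 groups", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  r <- unpaired_t(x, y)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_true(unpaired_t(c(2, 2), c(2, 2))$degenerate)

  set.seed(504)
  a <- rnorm(9, 1); b <- rnorm(7)
  tt <- unpaired_t(a, b)
  av <- oneway_anova_tukey(c(a, b), rep(c("a", "b"), c(9, 7)))
  expect_equal(tt$statistic^2, av$omnibus$statistic, tolerance = 1e-9)
  expect_equal(tt$p, av$omnibus$p, tolerance = 1e-9)
})

test_that("one-way ANOVA F matches first-principles sums of squares and
           Tukey p is never below the unadjusted pairwise p", {
  expect_true(oneway_anova_tukey(rep(c(1, 2), each = 3),
                                 rep(c("a", "b"), each = 3))$omnibus$degenerate)
  set.seed(505)
  for (i in 1:20) {
    g <- rep(c("a", "b", "c"), times = sample(3:9, 3, replace = TRUE))
    v <- rnorm(length(g)) + 0.5 * (g == "b")
    res <- oneway_anova_tukey(v, g)
    expect_equal(res$omnibus$statistic, oracle_anova_f(v, g),
                 tolerance = 1e-9)
    # unadjusted pairwise p from the pooled within MS
    ns <- table(g); k <- 3L; df_w <- length(v) - k
    ms_w <- sum(tapply(v, g, function(z) sum((z - mean(z))^2))) / df_w
    means <- tapply(v, g, mean)
    pairs <- utils::combn(names(ns), 2L)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      se <- sqrt(ms_w * (1 / ns[[a]] + 1 / ns[[b]]))
      p_un <- 2 * pt(-abs((means[[a]] - means[[b]]) / se), df_w)
      lab <- paste(sort(c(a, b), decreasing = TRUE), collapse = "-")
      p_tk <- res$pairwise$adjusted_p[res$pairwise$comparison == lab]
      expect_gte(p_tk + 1e-12, p_un)
    }
  }
})

test_that("Sidak adjustment is exact for m = 1 and never decreases p", {
  expect_equal(sidak_adjust(0.032, 1), 0.032)
  set.seed(506)
  p <- runif(50)
  for (m in c(1, 2, 3, 6)) {
    expect_true(all(sidak_adjust(p, m) >= p - 1e-12))
    expect_equal(sidak_adjust(p, m), 1 - (1 - p)^m)
  }
  expect_equal(sidak_adjust(c(0, 1), 5), c(0, 1))
})

test_that("mixed-design ANOVA matches the cell-means oracle and degenerates
           when the within factor has no effect", {
  set.seed(507)
  d <- tidyr::expand_grid(subject = paste0("m", 1:12),
                          level = c("hab", "test"))
  d$group <- rep(c("g1", "g2", "g3"), each = 4)[
    as.integer(sub("m", "", d$subject))]
  d$value <- rnorm(nrow(d)) + 2 * (d$group == "g2") +
    1.5 * (d$level == "test") * (d$group == "g3")
  res <- twoway_rm_anova_sidak(d)
  orc <- oracle_rm_anova(d)
  expect_equal(res$anova$statistic[res$anova$effect == "group"],
               orc$f_group, tolerance = 1e-8)
  expect_equal(res$anova$statistic[res$anova$effect == "level"],
               orc$f_level, tolerance = 1e-8)
  expect_equal(res$anova$statistic[res$anova$effect == "group:level"],
               orc$f_int, tolerance = 1e-8)
  expect_equal(nrow(res$comparisons), 6L)  # 3 group pairs x 2 levels

  # identical values at both within levels: level and interaction F = 0
  d0 <- d
  v1 <- rnorm(12)[as.integer(sub("m", "", d0$subject))]
  d0$value <- v1 + 2 * (d0$group == "g2")
  res0 <- twoway_rm_anova_sidak(d0)
  expect_equal(res0$anova$statistic[res0$anova$effect == "level"], 0)
  expect_equal(res0$anova$statistic[res0$anova$effect == "group:level"], 0)
})

test_that("ANCOVA recovers noiseless parallel lines exactly and reduces to
           OLS for one group", {
  x <- rep(seq(0, 5, by = 0.5), 2)
  g <- rep(c("a", "b"), each = 11)
  y <- ifelse(g == "a", 2 * x, 2 * x + 1)
  res <- ancova_compare(data.frame(x = x, y = y, group = g))
  expect_true(res$degenerate)
  expect_equal(res$common_slope, 2, tolerance = 1e-10)
  expect_equal(unname(res$intercept_offsets), 1, tolerance = 1e-10)
  expect_equal(res$per_group$slope, c(2, 2), tolerance = 1e-10)

  set.seed(508)
  x1 <- runif(10); y1 <- 1 + 3 * x1 + rnorm(10, 0, 0.2)
  solo <- ancova_compare(data.frame(x = x1, y = y1, group = "only"))
  o <- oracle_ols(x1, y1)
  expect_equal(solo$per_group$slope, o$slope, tolerance = 1e-9)
  expect_true(is.na(solo$p_slope_equal))

  # a slope difference of >= 5 SE is detected nearly always
  set.seed(509)
  hits <- replicate(60, {
    xa <- runif(12); xb <- runif(12)
    ya <- xa + rnorm(12, 0, 0.1)
    yb <- 2 * xb + rnorm(12, 0, 0.1)
    ancova_compare(data.frame(x = c(xa, xb), y = c(ya, yb),
                              group = rep(c("a", "b"), each = 12)))$p_slope_equal
  })
  expect_gte(mean(hits < 0.01), 0.95)
})
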