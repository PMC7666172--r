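# Independent brute-force oracles used to check the implementation paths.
# These are deliberately written as plain loops / first-principles formulas,
# sharing no code with the package internals.

# Mark every epoch inside a maximal run of >= 2 consecutive zeros.
oracle_zero_run_mask <- function(counts) {
  n <- length(counts)
  out <- rep(FALSE, n)
  i <- 1L
  while (i <= n) {
    if (counts[i] == 0L) {
      j <- i
      while (j < n && counts[j + 1L] == 0L) j <- j + 1L
      if (j - i + 1L >= 2L) out[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Per-sample loop counting upward threshold crossings of the absolute
# first difference of the vector norm, per epoch.
oracle_crossings <- function(samples, threshold, per_epoch) {
  norm <- apply(samples, 1L, function(v) sqrt(sum(v^2)))
  wave <- c(0, abs(diff(norm)))
  n_epochs <- nrow(samples) %/% per_epoch
  counts <- integer(n_epochs)
  prev_above <- FALSE
  for (k in seq_len(n_epochs * per_epoch)) {
    above <- wave[k] > threshold
    if (above && !prev_above) {
      e <- (k - 1L) %/% per_epoch + 1L
      counts[e] <- counts[e] + 1L
    }
    prev_above <- above
  }
  counts
}

# Enumerate maximal in-range runs meeting the frame-count threshold.
oracle_bouts <- function(in_range, fps, min_dur_s = 0.5) {
  min_frames <- ceiling(min_dur_s * fps)
  n <- length(in_range)
  res <- NULL
  i <- 1L
  while (i <= n) {
    if (isTRUE(in_range[i])) {
      j <- i
      while (j < n && isTRUE(in_range[j + 1L])) j <- j + 1L
      if (j - i + 1L >= min_frames) {
        res <- rbind(res, c((i - 1L) / fps, j / fps, (j - i + 1L) / fps))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(res)) {
    data.frame(start_s = numeric(), end_s = numeric(), duration_s = numeric())
  } else {
    data.frame(start_s = res[, 1], end_s = res[, 2], duration_s = res[, 3])
  }
}

# Full hypergeometric enumeration of the two-sided Fisher p (probability
# method), independent of fisher.test.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# OLS by normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2],
       sigma = sqrt(sum(res^2) / (length(y) - 2)))
}

# Brute-force point-to-segment distance by dense sampling of the segment.
oracle_point_segment <- function(px, py, a, b, n_grid = 20001L) {
  t <- seq(0, 1, length.out = n_grid)
  min(sqrt((px - (a[1] + t * (b[1] - a[1])))^2 +
             (py - (a[2] + t * (b[2] - a[2])))^2))
}

# One-way ANOVA F from first-principles sums of squares.
oracle_anova_f <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ss_b <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df_b <- nlevels(groups) - 1L
  df_w <- length(values) - nlevels(groups)
  (ss_b / df_b) / (ss_w / df_w)
}

# Balanced mixed-design ANOVA F statistics from the cell-means
# decomposition (between factor A, two-level within factor B, s subjects
# per group).
oracle_rm_anova <- function(data) {
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$level <- factor(data$level)
  a <- nlevels(data$group); b <- nlevels(data$level)
  subj_means <- tapply(data$value, data$subject, mean)
  subj_group <- tapply(as.character(data$group), data$subject, function(g) g[1])
  gm <- mean(data$value)
  grp_means <- tapply(data$value, data$group, mean)
  lvl_means <- tapply(data$value, data$level, mean)
  cell_means <- tapply(data$value, list(data$group, data$level), mean)
  n_per_group <- table(subj_group) / 1
  ss_group <- sum(b * table(factor(subj_group))[names(grp_means)] *
                    (grp_means - gm)^2)
  ss_subj_within <- b * sum((subj_means - grp_means[subj_group])^2)
  ss_level <- sum(table(data$level) * (lvl_means - gm)^2)
  ss_cells <- sum(tapply(data$value, list(data$group, data$level), length) *
                    (cell_means - gm)^2)
  ss_int <- ss_cells - ss_group - ss_level
  ss_tot <- sum((data$value - gm)^2)
  ss_resid <- ss_tot - ss_cells - ss_subj_within
  df_group <- a - 1L
  df_subj <- length(unique(data$subject)) - a
  df_level <- b - 1L
  df_int <- (a - 1L) * (b - 1L)
  df_resid <- df_subj * df_level
  list(
    f_group = (ss_group / df_group) / (ss_subj_within / df_subj),
    f_level = (ss_level / df_level) / (ss_resid / df_resid),
    f_int = (ss_int / df_int) / (ss_resid / df_resid)
  )
}

# Small deterministic session builder: centroid/nose positions given as
# matrices in cm, full likelihoods.
make_session <- function(cent, nose = cent, fps = 30, kind = "test",
                         lik_c = 1, lik_n = 1) {
  tracked_session(tibble::tibble(
    x_c = cent[, 1], y_c = cent[, 2], lik_c = lik_c,
    x_n = nose[, 1], y_n = nose[, 2], lik_n = lik_n
  ), fps = fps, kind = kind)
}
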