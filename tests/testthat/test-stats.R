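# Statistical workflow: the mixed-design ANOVA against a hand-computed
# sums-of-squares oracle, the pooled-variance t-tests, and the
# characteristics table.

make_long <- function(y, n_per_group = 3, k = 3) {
  n <- 2 * n_per_group
  data.frame(prep_id = rep(sprintf("s%02d", 1:n), each = k),
             arm = rep(c("drug", "vehicle"), each = n_per_group * k),
             time_min = rep(c(25, 30, 35), times = n),
             pct_of_stab = y)
}

# independent oracle: explicit split-plot sums of squares (equal group sizes)
split_plot_oracle <- function(d) {
  k <- length(unique(d$time_min))
  subj <- unique(d[, c("prep_id", "arm")])
  n <- nrow(subj)
  grand <- mean(d$pct_of_stab)
  m_subj <- tapply(d$pct_of_stab, d$prep_id, mean)
  m_g <- tapply(d$pct_of_stab, d$arm, mean)
  m_t <- tapply(d$pct_of_stab, d$time_min, mean)
  m_gt <- tapply(d$pct_of_stab, d[, c("arm", "time_min")], mean)
  n_g <- as.vector(table(subj$arm))
  ss_between <- k * sum((m_subj - grand)^2)
  ss_group <- k * sum(n_g * (m_g - grand)^2)
  ss_subj_wg <- ss_between - ss_group
  ss_time <- n * sum((m_t - grand)^2)
  dev <- sweep(sweep(m_gt, 1, m_g), 2, m_t) + grand
  ss_int <- sum(n_g * dev^2)
  ss_total <- sum((d$pct_of_stab - grand)^2)
  ss_err <- ss_total - ss_between - ss_time - ss_int
  df_subj <- n - 2
  df_err <- df_subj * (k - 1)
  list(F_group = (ss_group / 1) / (ss_subj_wg / df_subj),
       F_time = (ss_time / (k - 1)) / (ss_err / df_err),
       F_int = (ss_int / (k - 1)) / (ss_err / df_err))
}

test_that("mixed ANOVA matches the hand-computed sums of squares", {
  set.seed(33)
  d <- make_long(rnorm(18, mean = rep(c(105, 100), each = 9), sd = 4))
  out <- rm_anova(d)
  oracle <- split_plot_oracle(d)
  expect_equal(out$F[out$effect == "group"], oracle$F_group, tolerance = 1e-10)
  expect_equal(out$F[out$effect == "time"], oracle$F_time, tolerance = 1e-10)
  expect_equal(out$F[out$effect == "group:time"], oracle$F_int,
               tolerance = 1e-10)
  expect_true(all(out$p >= 0 & out$p <= 1))
})

test_that("identical groups give a zero group effect", {
  profiles <- matrix(c(100, 104, 108, 98, 101, 103, 95, 99, 97),
                     nrow = 3, byrow = TRUE)
  y <- c(as.vector(t(profiles)), as.vector(t(profiles)))
  out <- rm_anova(make_long(y))
  expect_equal(out$F[out$effect == "group"], 0, tolerance = 1e-12)
})

test_that("swapping the group labels leaves all F statistics unchanged", {
  set.seed(44)
  d <- make_long(rnorm(18, 100, 5))
  d2 <- d
  d2$arm <- ifelse(d$arm == "drug", "vehicle", "drug")
  f1 <- rm_anova(d)
  f2 <- rm_anova(d2)
  expect_equal(f1$F, f2$F, tolerance = 1e-10)
})

test_that("the ANOVA rejects unbalanced input rather than imputing", {
  d <- make_long(rnorm(18, 100, 5))
  expect_error(rm_anova(d[-1, ]), "unbalanced")
})

test_that("Greenhouse-Geisser epsilon is bounded and only affects within-subject tests", {
  set.seed(55)
  d <- make_long(rnorm(24, 100, 5), n_per_group = 4)
  plain <- rm_anova(d)
  gg <- rm_anova(d, gg = TRUE)
  eps <- gg$gg_epsilon[gg$effect == "time"]
  expect_gte(eps, 1 / 2)  # lower bound 1/(k-1) with k = 3
  expect_lte(eps, 1)
  expect_equal(gg$p[gg$effect == "group"], plain$p[plain$effect == "group"])
  expect_equal(gg$F, plain$F)  # only the reference distribution changes
  wi <- gg$effect != "group"
  expect_equal(gg$p[wi],
               pf(gg$F[wi], eps * gg$df1[wi], eps * gg$df2[wi],
                  lower.tail = FALSE))
})

test_that("per-timepoint t-tests match the pooled-variance closed form", {
  drug <- data.frame(time_min = 30, pct_of_stab = c(1, 2, 3))
  veh <- data.frame(time_min = 30, pct_of_stab = c(4, 5, 6))
  out <- per_timepoint_ttests(drug, veh, 30)
  expect_equal(out$t, -3.674, tolerance = 1e-3)
  expect_equal(out$df, 4)
  expect_equal(out$p, 0.0213116, tolerance = 1e-5)
  # swapping the groups flips the sign, p unchanged
  rev <- per_timepoint_ttests(veh, drug, 30)
  expect_equal(rev$t, -out$t, tolerance = 1e-12)
  expect_equal(rev$p, out$p, tolerance = 1e-12)
  # identical samples
  same <- per_timepoint_ttests(drug, drug, 30)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # property: closed form on random inputs
  set.seed(66)
  for (k in 1:10) {
    x <- rnorm(6, 100, 5)
    y <- rnorm(7, 95, 5)
    out <- per_timepoint_ttests(data.frame(time_min = 1, pct_of_stab = x),
                                data.frame(time_min = 1, pct_of_stab = y), 1)
    sp <- sqrt(((5) * var(x) + (6) * var(y)) / 11)
    t_hand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 6 + 1 / 7))
    expect_equal(out$t, t_hand, tolerance = 1e-10)
    expect_equal(out$p, 2 * pt(-abs(t_hand), 11), tolerance = 1e-10)
  }
})

test_that("characteristics table: Bonferroni arithmetic and structure", {
  set.seed(77)
  chars <- data.frame(group = rep(sprintf("g%d", 1:8), each = 4),
                      prep_id = sprintf("p%02d", 1:32),
                      mass_ug = rlnorm(32, log(700), 0.4),
                      L_max_mm = rlnorm(32, log(2.2), 0.2))
  tab <- characteristics_table(chars)
  expect_setequal(unique(tab$summary$characteristic),
                  c("mass_ug", "L_max_mm"))
  # m = choose(8, 2) = 28 pairs; p_adj = min(1, 28 * p_raw), never below raw
  expect_equal(nrow(tab$pairwise), 2 * 28)
  expect_equal(tab$pairwise$p_bonferroni,
               pmin(1, 28 * tab$pairwise$p_raw), tolerance = 1e-12)
  expect_true(all(tab$pairwise$p_bonferroni >= tab$pairwise$p_raw))
})
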