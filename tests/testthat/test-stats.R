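kw_toy <- data.frame(value = 1:9,
                     condition = rep(c("g1", "g2", "g3"), each = 3))

test_that("Kruskal-Wallis: hand-ranked H, degenerate and invariance cases", {
  res <- kruskal_wallis(kw_toy)
  expect_equal(res$statistic, 7.2)
  expect_equal(res$df, 2)

  same <- data.frame(value = rep(c(1, 2, 3), 2),
                     condition = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_wallis(same)$statistic, 0)

  ident <- data.frame(value = rep(5, 6),
                      condition = rep(c("a", "b"), each = 3))
  degen <- kruskal_wallis(ident)
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p_value, 1)

  set.seed(2)
  shuf <- kw_toy[sample(nrow(kw_toy)), ]
  expect_equal(kruskal_wallis(shuf)$statistic, res$statistic)
  # rank test: invariant under monotone transforms
  mono <- dplyr::mutate(kw_toy, value = exp(value / 2))
  expect_equal(kruskal_wallis(mono)$statistic, res$statistic)

  mixed <- dplyr::mutate(kw_toy, unit = rep(c("synapse", "image", "synapse"),
                                            each = 3))
  expect_error(kruskal_wallis(mixed), "mixed units")
})

test_that("Dunn's post hoc matches the mean-rank formula and Bonferroni rule", {
  ph <- dunn_posthoc(kw_toy, reference = "g1")
  # brute force z for g3 vs g1: ranks 1..9, no ties
  rbar <- tapply(rank(kw_toy$value), kw_toy$condition, mean)
  S <- 9 * 10 / 12
  z_expected <- (rbar[["g1"]] - rbar[["g3"]]) / sqrt(S * (1 / 3 + 1 / 3))
  expect_equal(ph$z[ph$group2 == "g3"], z_expected)
  expect_equal(ph$p_adjusted, pmin(1, 2 * ph$p_value))  # m = 2 comparisons

  ident <- data.frame(value = rep(c(4, 5, 6), 2),
                      condition = rep(c("a", "b"), each = 3))
  expect_equal(dunn_posthoc(ident)$p_adjusted, 1)

  # min(1, m p) with m = 3 all-pairs comparisons
  ph3 <- dunn_posthoc(kw_toy)
  expect_equal(nrow(ph3), 3)
  expect_equal(ph3$p_adjusted, pmin(1, 3 * ph3$p_value))

  expect_error(dunn_posthoc(kw_toy, reference = "nope"), "not present")
})

test_that("Friedman: perfect concordance statistic, ties, completeness", {
  d <- expand.grid(subject = 1:9, condition = c("c1", "c2", "c3"))
  d$value <- as.integer(d$condition) + 0.01 * d$subject
  res <- friedman_rm(d)
  expect_equal(res$statistic, 18)  # 2 * n at perfect concordance, k = 3

  flat <- dplyr::mutate(d, value = 1)
  expect_equal(friedman_rm(flat)$statistic, 0)

  set.seed(3)
  shuf <- d[sample(nrow(d)), ]
  expect_equal(friedman_rm(shuf)$statistic, res$statistic)

  expect_error(friedman_rm(d[-1, ]), "incomplete")

  ph <- friedman_rm(d, posthoc = TRUE, reference = "c1")$posthoc
  expect_equal(nrow(ph), 2)
  # perfect concordance: mean ranks 1, 2, 3; z = (1 - 3)/sqrt(k(k+1)/(6n))
  expect_equal(ph$z[ph$group2 == "c3"], -2 / sqrt(3 * 4 / (6 * 9)))
})

test_that("Wilcoxon signed-rank: exact cases and enumeration property", {
  res <- wilcoxon_signed_rank(c(2, 3, 1, 4, 6, 5))  # all positive, n = 6
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 2 / 64)

  neg <- wilcoxon_signed_rank(-c(2, 3, 1, 4, 6, 5))
  expect_equal(neg$p_value, res$p_value)  # sign symmetry

  expect_equal(wilcoxon_signed_rank(3.2)$p_value, 1)  # single pair

  expect_error(wilcoxon_signed_rank(rep(0, 4)), "degenerate")

  # paired interface
  expect_equal(wilcoxon_signed_rank(c(5, 7, 9), c(4, 5, 6))$statistic, 6)

  set.seed(4)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n, 0.3), 3)
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d))) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, wilcoxon_enumerate(d),
                 tolerance = 1e-12)
  }
})

test_that("RM-ANOVA: zero-variance factor, scale invariance, SS oracle", {
  d <- expand.grid(subject = paste0("s", 1:8), stage = c("t1", "t2"))
  d$genotype <- rep(rep(c("ctrl", "mut"), each = 4), 2)
  set.seed(5)
  d$value <- rnorm(nrow(d), 10)

  # zero stage effect by construction (per-stage deviations sum to zero in
  # every genotype) but non-degenerate residual: F for stage = 0
  d0 <- d
  pattern <- c(1, -1, 2, -2, 1, -1, 2, -2)
  subj_idx <- as.integer(factor(d0$subject))
  d0$value <- 10 + subj_idx +
    ifelse(d0$stage == "t1", pattern[subj_idx], 0)
  r0 <- rm_anova_two_way(d0, control = "ctrl")
  f_stage <- r0$anova$statistic[r0$anova$term == "stage"]
  expect_lt(f_stage, 1e-10)

  r1 <- rm_anova_two_way(d, control = "ctrl")
  r2 <- rm_anova_two_way(dplyr::mutate(d, value = 2 * value),
                         control = "ctrl")
  expect_equal(r1$anova$statistic, r2$anova$statistic, tolerance = 1e-9)
  expect_equal(nrow(r1$posthoc), 2)  # mut vs ctrl at each stage

  # brute-force sums-of-squares oracle for the within stratum (2 x 2)
  y <- d$value
  grand <- mean(y)
  cell <- tapply(y, list(d$genotype, d$stage), mean)
  gm <- rowMeans(cell); sm <- colMeans(cell)
  n_per_cell <- 4
  ss_stage <- n_per_cell * 2 * sum((sm - grand)^2)
  ss_int <- n_per_cell * sum((cell - outer(gm, rep(1, 2)) -
                                outer(rep(1, 2), sm) + grand)^2)
  subj_mean <- tapply(y, d$subject, mean)
  ss_within_err <- sum((y - subj_mean[as.character(d$subject)] -
                          sm[as.character(d$stage)] + grand)^2) - ss_int
  df_err <- (8 - 2) * (2 - 1)
  f_stage_oracle <- (ss_stage / 1) / (ss_within_err / df_err)
  f_int_oracle <- (ss_int / 1) / (ss_within_err / df_err)
  expect_equal(r1$anova$statistic[r1$anova$term == "stage"], f_stage_oracle,
               tolerance = 1e-8)
  expect_equal(r1$anova$statistic[r1$anova$term == "genotype:stage"],
               f_int_oracle, tolerance = 1e-8)

  expect_error(rm_anova_two_way(d[-1, ]), "complete")
})

test_that("blocker series normalize to baseline and exclude bad cells", {
  d <- data.frame(subject = rep(c("c1", "c2", "c3"), each = 3),
                  stage = rep(c("before", "aga", "aga_isr"), 3),
                  value = c(100, 50, 0, 80, 40, 20, 0, 10, 5))
  expect_warning(out <- normalized_blocker_series(d), "non-positive")
  expect_equal(sort(unique(out$subject)), c("c1", "c2"))
  c1 <- out[out$subject == "c1", ]
  expect_equal(c1$fraction[match(c("before", "aga", "aga_isr"), c1$stage)],
               c(1, 0.5, 0))
  # fractions invariant to units
  d2 <- dplyr::mutate(d, value = value * 1000)
  expect_warning(out2 <- normalized_blocker_series(d2), "non-positive")
  expect_equal(out$fraction, out2$fraction)
})

test_that("tidy and glance give broom-style summaries", {
  res <- kruskal_wallis(kw_toy)
  g <- glance(res)
  expect_equal(g$statistic, 7.2)
  expect_equal(g$n, 9)
  t1 <- tidy(res)
  expect_equal(t1$p_value, res$p_value)

  fr <- friedman_rm(
    expand.grid(subject = 1:4, condition = c("a", "b")) |>
      dplyr::mutate(value = c(1, 2, 3, 4, 5, 6, 7, 8)),
    posthoc = TRUE)
  expect_true(all(c("group1", "group2", "p_adjusted") %in% names(tidy(fr))))
})
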