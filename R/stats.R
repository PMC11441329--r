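# Nonparametric group statistics -----------------------------------------
#
# Units of analysis follow the measurement design: synapses for STED peak
# levels, images for confocal ROI summaries, cells for somata and
# electrophysiology. Every test takes a tidy table and returns a
# `synq_test` object with broom-style tidy()/glance() methods.

new_synq_test <- function(method, statistic, df, p_value, n,
                          posthoc = NULL, unit = NULL, extra = list()) {
  structure(
    c(list(method = method, statistic = statistic, df = df,
           p_value = p_value, n = n, posthoc = posthoc, unit = unit),
      extra),
    class = "synq_test")
}

#' @export
print.synq_test <- function(x, ...) {
  cat(sprintf("<synq_test> %s\n", x$method))
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g (n = %s%s)\n",
              x$statistic, paste(x$df, collapse = ", "), x$p_value,
              paste(x$n, collapse = "+"),
              if (!is.null(x$unit)) paste0(" ", x$unit) else ""))
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a synquant test result
#'
#' `tidy()` returns the post-hoc comparison table when one is present,
#' otherwise the omnibus row; `glance()` always returns the one-row omnibus
#' summary.
#'
#' @param x A `synq_test`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.synq_test <- function(x, ...) {
  if (!is.null(x$posthoc)) return(as_tibble(x$posthoc))
  glance.synq_test(x)
}

#' @rdname tidy.synq_test
#' @export
glance.synq_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic,
         df = paste(x$df, collapse = ","), p_value = x$p_value,
         n = sum(x$n))
}

check_unit <- function(data, unit_col = "unit") {
  if (unit_col %in% names(data)) {
    u <- unique(data[[unit_col]])
    if (length(u) > 1L)
      abort(sprintf("mixed units of analysis in one test: %s.",
                    paste(u, collapse = ", ")))
    return(u)
  }
  NULL
}

#' Kruskal-Wallis rank-sum test
#'
#' Single-factor multiple-group comparison on ranks (tie-corrected H
#' statistic, chi-square p with k - 1 df), the omnibus test used for peak
#' levels, ROI intensities and current amplitudes. If all values are
#' identical the test is degenerate: H = 0, p = 1.
#'
#' @param data Tidy data frame; an optional `unit` column is checked for
#'   consistency (mixing units of analysis is an error).
#' @param value,condition Column names (strings) of the measurement and the
#'   group label.
#' @return A `synq_test`.
#' @examples
#' d <- data.frame(v = 1:9, g = rep(c("a", "b", "c"), each = 3))
#' kruskal_wallis(d, "v", "g")  # H = 7.2
#' @export
kruskal_wallis <- function(data, value = "value", condition = "condition") {
  unit <- check_unit(data)
  v <- data[[value]]
  g <- factor(data[[condition]])
  if (nlevels(g) < 2) abort("need at least 2 groups.")
  if (any(table(g) < 1) || length(v) < 3)
    abort("need n >= 1 per group and total N >= 3.")
  n <- as.integer(table(g))
  if (length(unique(v)) == 1L) {
    return(new_synq_test("Kruskal-Wallis rank sum test", 0, nlevels(g) - 1L,
                         1, n, unit = unit))
  }
  kt <- stats::kruskal.test(v, g)
  new_synq_test("Kruskal-Wallis rank sum test",
                unname(kt$statistic), unname(kt$parameter),
                unname(kt$p.value), n, unit = unit)
}

#' Dunn's multiple-comparison post hoc test
#'
#' Pairwise z statistics on mean ranks with tie-corrected pooled variance:
#' `z = (Rbar_i - Rbar_j) / sqrt(S * (1/n_i + 1/n_j))` with
#' `S = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1))`. Adjusted p-values default
#' to the Bonferroni-type rule `min(1, m p)` over the `m` comparisons made
#' (all pairs, or each group versus a reference).
#'
#' @inheritParams kruskal_wallis
#' @param reference Optional reference group label; when given, only
#'   comparisons against it are made.
#' @param adjust A [stats::p.adjust()] method (default `"bonferroni"`).
#' @param alpha Significance level for the `reject` flag.
#' @return Tibble: `group1`, `group2`, `z`, `p_value`, `p_adjusted`,
#'   `reject`.
#' @export
dunn_posthoc <- function(data, value = "value", condition = "condition",
                         reference = NULL, adjust = "bonferroni",
                         alpha = 0.05) {
  v <- data[[value]]
  g <- factor(data[[condition]])
  if (nlevels(g) < 2) abort("need at least 2 groups.")
  if (!is.null(reference) && !reference %in% levels(g))
    abort(sprintf("reference group '%s' not present.", reference))
  N <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  n <- table(g)
  ties <- table(v)
  S <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(g), 2)
  if (!is.null(reference)) {
    keep <- pairs[1, ] == reference | pairs[2, ] == reference
    pairs <- pairs[, keep, drop = FALSE]
    # put the reference first
    flip <- pairs[1, ] != reference
    pairs[, flip] <- rbind(pairs[2, flip], pairs[1, flip])
  }
  z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) /
    sqrt(S * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  p <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(p, method = adjust)
  tibble(group1 = pairs[1, ], group2 = pairs[2, ],
         z = as.numeric(z), p_value = as.numeric(p),
         p_adjusted = as.numeric(padj),
         reject = as.numeric(padj) < alpha)
}

#' Friedman test with optional Dunn's post hoc
#'
#' Within-subject rank test for complete blocked designs (each subject
#' measured under every condition), as used for repeated pharmacology
#' stages on the same cells. Missing cells are an error (no imputation).
#' The post hoc compares conditions on within-block mean ranks:
#' `z = (Rbar_j - Rbar_k) / sqrt(k (k + 1) / (6 n))`.
#'
#' @param data Tidy data frame.
#' @param value,condition,subject Column names.
#' @param posthoc If `TRUE`, attach Dunn's comparisons.
#' @param reference Optional reference condition for the post hoc.
#' @param adjust,alpha Adjustment rule and significance level.
#' @return A `synq_test`.
#' @export
friedman_rm <- function(data, value = "value", condition = "condition",
                        subject = "subject", posthoc = FALSE,
                        reference = NULL, adjust = "bonferroni",
                        alpha = 0.05) {
  v <- data[[value]]
  g <- factor(data[[condition]])
  s <- factor(data[[subject]])
  k <- nlevels(g); n <- nlevels(s)
  if (k < 2 || n < 2) abort("need >= 2 conditions and >= 2 subjects.")
  counts <- table(s, g)
  if (any(counts != 1L))
    abort("incomplete or duplicated blocks: every subject needs exactly one value per condition.")
  if (length(unique(v)) == 1L) {
    res <- new_synq_test("Friedman rank sum test", 0, k - 1L, 1, n,
                         unit = "subject")
  } else {
    ft <- stats::friedman.test(v, g, s)
    res <- new_synq_test("Friedman rank sum test", unname(ft$statistic),
                         unname(ft$parameter), unname(ft$p.value), n,
                         unit = "subject")
  }
  if (posthoc) {
    # within-block ranks
    rmat <- tapply(v, list(s, g), identity)
    ranks <- t(apply(rmat, 1, rank))
    rbar <- colMeans(ranks)
    pairs <- utils::combn(levels(g), 2)
    if (!is.null(reference)) {
      if (!reference %in% levels(g))
        abort(sprintf("reference condition '%s' not present.", reference))
      keep <- pairs[1, ] == reference | pairs[2, ] == reference
      pairs <- pairs[, keep, drop = FALSE]
      flip <- pairs[1, ] != reference
      pairs[, flip] <- rbind(pairs[2, flip], pairs[1, flip])
    }
    z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) / sqrt(k * (k + 1) / (6 * n))
    p <- 2 * stats::pnorm(-abs(z))
    padj <- stats::p.adjust(p, method = adjust)
    res$posthoc <- tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                          z = as.numeric(z), p_value = as.numeric(p),
                          p_adjusted = as.numeric(padj),
                          reject = as.numeric(padj) < alpha)
  }
  res
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided paired test. Zero differences are dropped (with a message in
#' `n_zero`); for n <= 12 remaining pairs without ties among |differences|
#' the p-value is exact (signed-rank distribution over all 2^n sign
#' patterns), otherwise a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param x,y Paired measurements; or differences in `x` with `y = NULL`.
#' @return A `synq_test` with statistic `W+` (sum of positive ranks).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  if (!is.null(y) && length(x) != length(y)) abort("pairs incomplete.")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("degenerate: all differences are zero.")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (n <= 12 && !has_ties) {
    # exact two-sided p from the signed-rank distribution
    p_le <- stats::psignrank(w_pos, n)
    p_ge <- 1 - stats::psignrank(w_pos - 1, n)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "Wilcoxon matched-pairs signed rank test (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon matched-pairs signed rank test (normal approx.)"
  }
  new_synq_test(method, w_pos, NA_real_, p, n,
                extra = list(n_zero = n_zero))
}

#' Two-way repeated-measures ANOVA with Dunnett's post hoc
#'
#' Between-subject factor (e.g. genotype) crossed with a within-subject
#' factor (e.g. pharmacology stage) on a complete balanced design, fit with
#' `aov(value ~ between * within + Error(subject/within))`. Dunnett's
#' comparisons of the between-factor levels against a control are computed
#' per within-level via emmeans (`adjust = "dunnettx"`, a deterministic
#' Dunnett approximation).
#'
#' @param data Tidy data frame.
#' @param value,subject,between,within Column names.
#' @param control Control level of `between` (default: first level).
#' @param alpha Significance level for the `reject` flag.
#' @return A `synq_test`; `$anova` holds the full effect table, `$posthoc`
#'   the Dunnett comparisons, and the omnibus fields report the interaction.
#' @export
rm_anova_two_way <- function(data, value = "value", subject = "subject",
                             between = "genotype", within = "stage",
                             control = NULL, alpha = 0.05) {
  df <- tibble(
    value = data[[value]],
    subject = factor(data[[subject]]),
    between = factor(data[[between]]),
    within = factor(data[[within]])
  )
  counts <- table(df$subject, df$within)
  if (any(counts != 1L))
    abort("design must be complete: one value per subject and within-level.")
  per_group <- table(df$between) / nlevels(df$within)
  if (length(unique(per_group)) != 1L)
    abort("design must be balanced across between-factor levels.")
  control <- control %||% levels(df$between)[1]
  if (!control %in% levels(df$between))
    abort(sprintf("control level '%s' not present.", control))

  # do.call embeds the data in the recorded call so that emmeans can
  # re-evaluate the model outside this function's environment
  fit <- do.call(stats::aov,
                 list(value ~ between * within + Error(subject / within),
                      data = df))
  sm <- summary(fit)
  eff <- purrr::map(sm, function(stratum) {
    tb <- as.data.frame(stratum[[1]])
    tb$term <- trimws(rownames(tb))
    tb
  }) |> purrr::list_rbind()
  eff <- as_tibble(eff[eff$term != "Residuals",
                       c("term", "Df", "F value", "Pr(>F)")])
  names(eff) <- c("term", "df", "statistic", "p_value")
  eff$term <- sub("^between$", between, eff$term)
  eff$term <- sub("^within$", within, eff$term)
  eff$term <- sub("^between:within$", paste0(between, ":", within), eff$term)

  emm <- emmeans::emmeans(fit, stats::as.formula("~ between | within"),
                          data = df)
  ct <- emmeans::contrast(
    emm, method = "trt.vs.ctrl",
    ref = which(levels(df$between) == control), adjust = "dunnettx")
  ph <- as.data.frame(ct)
  posthoc <- tibble(
    comparison = ph$contrast,
    !!within := as.character(ph$within),
    estimate = ph$estimate,
    t = ph$t.ratio,
    p_adjusted = ph$p.value,
    reject = ph$p.value < alpha)

  inter <- eff[eff$term == paste0(between, ":", within), ]
  new_synq_test("Two-way repeated-measures ANOVA",
                statistic = inter$statistic, df = inter$df,
                p_value = inter$p_value,
                n = nlevels(df$subject), posthoc = posthoc, unit = "subject",
                extra = list(anova = eff, control = control))
}

#' Normalize a blocker wash-in series to its baseline
#'
#' Converts per-cell amplitude series (e.g. IPSC before, + blocker 1,
#' + blockers 1 and 2) to fractions of the baseline stage. Cells with a
#' non-positive baseline are excluded with a warning.
#'
#' @param data Tidy data frame.
#' @param value,subject,stage Column names.
#' @param baseline Label of the baseline stage (default `"before"`).
#' @return Tibble with a `fraction` column (baseline stage == 1).
#' @export
normalized_blocker_series <- function(data, value = "value",
                                      subject = "subject", stage = "stage",
                                      baseline = "before") {
  df <- tibble(subject = data[[subject]], stage = data[[stage]],
               value = data[[value]])
  if (!baseline %in% df$stage)
    abort(sprintf("baseline stage '%s' not present.", baseline))
  base <- df |>
    filter(.data$stage == baseline) |>
    select("subject", base = "value")
  bad <- base$subject[base$base <= 0]
  if (length(bad) > 0)
    warn(sprintf("excluding %d cell(s) with non-positive baseline: %s",
                 length(bad), paste(bad, collapse = ", ")))
  df |>
    inner_join(filter(base, .data$base > 0), by = "subject") |>
    mutate(fraction = .data$value / .data$base) |>
    select("subject", "stage", "value", "fraction")
}
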