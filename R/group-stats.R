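# Demographic tests and the per-region (ROI) group comparison battery.
# Tests follow the reported analysis choices: Student's pooled-variance t
# (not Welch) and Pearson's chi-square without continuity correction.

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance on `df = n_a + n_b - 2`, two-tailed.
#' A degenerate comparison (zero pooled variance) returns t = 0, p = 1 when
#' the means agree and errors otherwise.
#'
#' @param a,b Numeric sample vectors (each of length >= 2, finite).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `estimate`
#'   (mean difference a - b), `n_a`, `n_b`, `method`.
#' @examples
#' pooled_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
pooled_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("Each sample needs n >= 2.")
  if (!all(is.finite(a)) || !all(is.finite(b))) abort("Samples must be finite.")
  pooled_t_from_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
}

#' Pooled t-test from summary statistics
#'
#' Identical formula to [pooled_t_test()] applied to group means, SDs and
#' sizes (as printed in demographic tables). Vectorised over its arguments.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return Tibble with one row per comparison, columns as in
#'   [pooled_t_test()].
#' @examples
#' pooled_t_from_summary(29.49, 6.78, 108, 31.06, 7.76, 88)
#' @export
pooled_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (any(n_a < 2 | n_b < 2)) abort("Group sizes must be >= 2.")
  if (any(sd_a < 0 | sd_b < 0)) abort("SDs must be non-negative.")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  est <- mean_a - mean_b
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  degenerate <- sp2 == 0
  if (any(degenerate & est != 0)) {
    abort("Zero pooled variance with unequal means: degenerate comparison.")
  }
  statistic <- ifelse(degenerate, 0, est / se)
  p <- ifelse(degenerate, 1, 2 * pt(-abs(statistic), df))
  tibble::tibble(statistic = statistic, df = df, p_value = p,
                 estimate = est, n_a = n_a, n_b = n_b, method = "pooled_t")
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction, `df = 1` (the convention behind the reported
#' gender comparison).
#'
#' @param table 2x2 matrix of non-negative integer counts with all marginals
#'   positive.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_a`, `n_b` (row
#'   totals), `method`.
#' @examples
#' chi_square_2x2(matrix(c(19, 25, 89, 63), 2))
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    abort("`table` must be a 2x2 matrix of non-negative counts.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("All marginals of the 2x2 table must be positive.")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = 1,
                 p_value = ct$p.value,
                 n_a = sum(table[1, ]), n_b = sum(table[2, ]),
                 method = "pearson_chi_square")
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 148)
#' @export
bonferroni_threshold <- function(alpha, m) {
  check_scalar_prob(alpha, "alpha")
  if (m < 1) abort("`m` must be >= 1.")
  alpha / m
}

#' Demographic comparison table
#'
#' Age by pooled t-test, sex composition by Pearson chi-square, mirroring a
#' standard Table-1 layout.
#'
#' @param cohort An `scn_cohort`.
#' @return Tibble: `variable`, `statistic`, `df`, `p_value`, `n_a`, `n_b`,
#'   `method`.
#' @export
demographics_table <- function(cohort) {
  s <- cohort$subjects
  lev <- levels(s$group)
  age <- pooled_t_test(s$age[s$group == lev[1]], s$age[s$group == lev[2]])
  sex_tab <- t(table(s$sex, s$group))  # rows = groups, cols = sex levels
  sex <- chi_square_2x2(sex_tab)
  dplyr::bind_rows(
    dplyr::mutate(dplyr::select(age, -"estimate"), variable = "age"),
    dplyr::mutate(sex, variable = "sex")
  ) |>
    dplyr::relocate("variable")
}

#' Per-region group comparison of cortical thickness
#'
#' One pooled t-test per atlas region, case vs control, with the Bonferroni
#' threshold `alpha / n_regions`. Regions with zero variance in both groups
#' are reported non-significant with a warning instead of failing the whole
#' battery. Optionally the tests run on residuals after regressing out
#' age and sex (pooled fit); the mode used is recorded in the
#' `"adjustment"` attribute.
#'
#' @param cohort An `scn_cohort`.
#' @param alpha Family-wise error rate before Bonferroni division.
#' @param adjust `"none"` (default) or `"covariates"` (age/sex residuals).
#' @return Tibble with one row per region: `region`, `hemisphere`,
#'   `mean_case`, `sd_case`, `mean_control`, `sd_control`, `statistic`,
#'   `df`, `p_value`, `estimate`, `significant`, `direction`
#'   (`"case<control"` / `"case>control"` / `"equal"`). Attributes:
#'   `alpha`, `threshold`, `adjustment`.
#' @export
roi_group_comparison <- function(cohort, alpha = 0.05,
                                 adjust = c("none", "covariates")) {
  adjust <- match.arg(adjust)
  thick <- cohort$thickness
  if (adjust == "covariates") {
    thick <- residualize(thick,
                         cohort$subjects[, c("age", "sex"), drop = FALSE]) +
      matrix(colMeans(thick), nrow(thick), ncol(thick), byrow = TRUE)
  }
  g <- cohort$subjects$group
  lev <- levels(g)
  a <- thick[g == lev[1], , drop = FALSE]
  b <- thick[g == lev[2], , drop = FALSE]
  m_a <- colMeans(a); m_b <- colMeans(b)
  s_a <- apply(a, 2, sd); s_b <- apply(b, 2, sd)
  degenerate <- s_a == 0 & s_b == 0
  if (any(degenerate & m_a != m_b)) {
    abort(sprintf("Zero-variance region(s) with unequal means: %s",
                  paste(colnames(thick)[degenerate & m_a != m_b],
                        collapse = ", ")))
  }
  if (any(degenerate)) {
    warn(sprintf("%d zero-variance region(s) reported as non-significant.",
                 sum(degenerate)))
  }
  res <- pooled_t_from_summary(
    m_a, ifelse(degenerate, 1, s_a), nrow(a),
    m_b, ifelse(degenerate, 1, s_b), nrow(b)
  )
  res$statistic[degenerate] <- 0
  res$p_value[degenerate] <- 1
  thr <- bonferroni_threshold(alpha, ncol(thick))
  out <- tibble::tibble(
    region = cohort$atlas$region,
    hemisphere = cohort$atlas$hemisphere,
    mean_case = m_a, sd_case = s_a,
    mean_control = m_b, sd_control = s_b,
    statistic = res$statistic, df = res$df, p_value = res$p_value,
    estimate = res$estimate,
    significant = res$p_value < thr,
    direction = dplyr::case_when(
      m_a < m_b ~ "case<control",
      m_a > m_b ~ "case>control",
      TRUE ~ "equal"
    )
  )
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- thr
  attr(out, "adjustment") <- adjust
  out
}
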