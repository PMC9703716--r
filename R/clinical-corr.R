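# Correlation battery between regional thickness and clinical variables:
# Spearman for graded/continuous variables, point-biserial for 0/1 status
# variables. Pairwise-complete deletion per pair, so each (region, variable)
# reports its own n.

corr_result <- function(method, rho, p, n, flag = NA) {
  tibble::tibble(method = method, rho = rho, p_value = p, n = n,
                 undefined = isTRUE(flag))
}

#' Spearman rank correlation
#'
#' Average ranks for ties; two-tailed p from the t approximation on `n - 2`
#' degrees of freedom. A constant vector after pairwise deletion yields an
#' undefined (flagged) result rather than an error.
#'
#' @param x,y Numeric vectors; pairs with any `NA` are dropped
#'   (>= 3 complete pairs required).
#' @return One-row tibble: `method`, `rho`, `p_value`, `n`, `undefined`.
#' @examples
#' spearman_corr(1:4, c(4, 3, 2, 1))
#' @export
spearman_corr <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs >= 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(corr_result("spearman", NA_real_, NA_real_, n, flag = TRUE))
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), n - 2)
  }
  corr_result("spearman", rho, p, n)
}

#' Point-biserial correlation
#'
#' Pearson correlation between a 0/1-coded status variable and a continuous
#' variable, with the usual t-based p on `n - 2` df. Requires both levels
#' among the complete pairs; otherwise the result is flagged undefined.
#'
#' @param b Binary (0/1) vector.
#' @param y Numeric vector.
#' @return One-row tibble as in [spearman_corr()].
#' @examples
#' point_biserial(c(0, 0, 1, 1), c(1, 1, 2, 2))
#' @export
point_biserial <- function(b, y) {
  ok <- complete.cases(b, y)
  b <- b[ok]; y <- y[ok]
  n <- length(b)
  if (n < 3) abort("Point-biserial correlation needs >= 3 complete pairs.")
  if (!is_binary01(b)) abort("`b` must be coded 0/1.")
  if (length(unique(b)) < 2 || sd(y) == 0) {
    return(corr_result("point_biserial", NA_real_, NA_real_, n, flag = TRUE))
  }
  rho <- cor(b, y)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), n - 2)
  }
  corr_result("point_biserial", rho, p, n)
}

#' Clinical correlation battery over significant regions
#'
#' Correlates the thickness of each selected region with each clinical
#' variable within the patient (first) group: Spearman for continuous
#' variables, point-biserial for 0/1 variables. No multiplicity correction
#' by default (rows with `p < alpha` are flagged); an optional BH-FDR mode
#' flags on adjusted p instead. The choice is recorded in the
#' `"correction"` attribute.
#'
#' @param cohort An `scn_cohort` carrying clinical columns.
#' @param regions Character vector of regions (normally those flagged by
#'   [roi_group_comparison()]). An empty selection returns an empty table
#'   with a warning.
#' @param variables Clinical variables to use; default all in
#'   `cohort$clinical`. All-missing variables are dropped with a warning.
#' @param alpha Significance level (default 0.05).
#' @param fdr Flag on Benjamini-Hochberg adjusted p-values instead?
#' @return Tibble: `region`, `variable`, `method`, `n`, `rho`, `p_value`,
#'   `flagged`.
#' @export
correlation_battery <- function(cohort, regions, variables = NULL,
                                alpha = 0.05, fdr = FALSE) {
  variables <- variables %||% cohort$clinical$variable
  if (!length(regions)) {
    warn("Empty region set: returning an empty correlation table.")
    return(tibble::tibble(region = character(), variable = character(),
                          method = character(), n = integer(),
                          rho = double(), p_value = double(),
                          flagged = logical()))
  }
  if (!all(regions %in% cohort$atlas$region)) {
    abort(sprintf("Unknown region(s): %s",
                  paste(setdiff(regions, cohort$atlas$region), collapse = ", ")))
  }
  s <- cohort$subjects
  case <- s$group == levels(s$group)[1]
  keep <- vapply(variables, function(v) any(!is.na(s[[v]][case])), TRUE)
  if (any(!keep)) {
    warn(sprintf("Dropping all-missing variable(s): %s",
                 paste(variables[!keep], collapse = ", ")))
    variables <- variables[keep]
  }
  types <- setNames(cohort$clinical$type, cohort$clinical$variable)
  rows <- purrr::map_dfr(regions, function(r) {
    th <- cohort$thickness[case, r]
    purrr::map_dfr(variables, function(v) {
      y <- s[[v]][case]
      type <- types[[v]] %||% if (is_binary01(y)) "binary" else "continuous"
      res <- if (type == "binary") point_biserial(y, th) else
        spearman_corr(th, y)
      tibble::tibble(region = r, variable = v, method = res$method,
                     n = res$n, rho = res$rho, p_value = res$p_value)
    })
  })
  p_crit <- if (fdr) p.adjust(rows$p_value, method = "BH") else rows$p_value
  rows$flagged <- !is.na(p_crit) & p_crit < alpha
  attr(rows, "correction") <- if (fdr) "BH" else "none"
  attr(rows, "alpha") <- alpha
  rows
}
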