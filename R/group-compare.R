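# Permutation framework for between-group differences. Because each group
# yields exactly one network, inference relies on relabeling subjects:
# every permutation re-runs the full construction (re-residualization
# within the permuted groups included, so the observed statistic's pipeline
# is mirrored exactly), rebuilds both adjacency stacks over the grid, and
# recomputes the requested measures.

# metrics for one labeling: global [metric x density x group] array and
# nodal AUC [metric x region x group] array
eval_group_arrays <- function(thick, covars, case_mask, grid,
                              gmetrics, nmetrics, n_nulls, seed,
                              modularity_restarts) {
  masks <- list(case_mask, !case_mask)
  e_max <- ncol(thick) * (ncol(thick) - 1) / 2
  ks <- round_half_up(grid * e_max)
  gm_names <- c(gmetrics, if (n_nulls > 0) c("gamma", "lambda", "sigma"))
  global <- array(NA_real_, c(length(gm_names), length(grid), 2),
                  dimnames = list(gm_names, NULL, NULL))
  nodal <- if (length(nmetrics)) {
    array(NA_real_, c(length(nmetrics), ncol(thick), length(grid), 2),
          dimnames = list(nmetrics, NULL, NULL, NULL))
  }
  for (gi in 1:2) {
    rows <- masks[[gi]]
    resid <- if (ncol(covars)) {
      qrd <- qr(cbind(1, covars[rows, , drop = FALSE]))
      qr.resid(qrd, thick[rows, , drop = FALSE])
    } else {
      scale(thick[rows, , drop = FALSE], scale = FALSE)
    }
    sds <- apply(resid, 2, sd)
    if (any(sds == 0)) return(NULL)  # caller redraws the permutation
    M <- cor(resid)
    diag(M) <- 0
    ranking <- edge_ranking(M)
    A <- adjacency_from_ranking(ranking, ks[1])
    for (t in seq_along(grid)) {
      if (t > 1 && ks[t] > ks[t - 1]) {
        idx <- (ks[t - 1] + 1):ks[t]
        A[cbind(ranking$i[idx], ranking$j[idx])] <- 1
        A[cbind(ranking$j[idx], ranking$i[idx])] <- 1
      }
      for (m in gmetrics) {
        global[m, t, gi] <- switch(m,
          modularity = graph_modularity(A, modularity_restarts,
                                        seed + 101L * gi + t)$Q,
          global_metric_values(A, m)
        )
      }
      if (n_nulls > 0) {
        sw <- small_world(A, n_nulls, seed + 7919L * gi + t)
        global["gamma", t, gi] <- sw$gamma
        global["lambda", t, gi] <- sw$lambda
        global["sigma", t, gi] <- sw$sigma
      }
      if (length(nmetrics)) {
        nodal[, , t, gi] <- t(nodal_metric_values(A, nmetrics))
      }
    }
  }
  nodal_auc <- if (length(nmetrics)) {
    apply(nodal, c(1, 2, 4), function(v) metric_auc(grid, v))
  }
  list(global = global, nodal_auc = nodal_auc)
}

array_auc <- function(global, grid) {
  apply(global, c(1, 3), function(v) metric_auc(grid, v))
}

#' Permutation comparison of group network metrics
#'
#' Builds the observed per-group networks and metric curves, then draws
#' `n_perm` label permutations (group sizes preserved), re-running the full
#' construction for each to obtain null distributions of the between-group
#' difference (case minus control) per density and for the area under each
#' metric-versus-density curve (AUC). Two-tailed permutation p-values use
#' the add-one estimator `(count + 1) / (n_perm + 1)`; per-density p-values
#' are Benjamini-Hochberg adjusted across densities within each metric, and
#' nodal AUC p-values across nodes within each metric. Permutations that
#' produce a zero-variance region are redrawn (count reported).
#'
#' @param cohort An `scn_cohort`.
#' @param grid Density grid (default [density_grid()]).
#' @param global_metrics Global measures to test (see
#'   [global_metric_curves()]).
#' @param nodal_metrics Nodal measures tested on their density-AUC per node
#'   (default none; see [nodal_metric_curves()]).
#' @param n_perm Number of permutations (>= 100 for reported p-values).
#' @param seed Integer master seed.
#' @param alpha Significance level (default 0.05).
#' @param n_nulls Rewired nulls per (group, density) when the normalized
#'   measures `gamma`/`lambda`/`sigma` should also be tested (0 = skip).
#' @param covariates Covariate columns residualized out within each
#'   (permuted) group.
#' @param modularity_restarts Louvain restarts per modularity evaluation.
#' @return An `scn_comparison` object: `$global` (per-density tests),
#'   `$global_auc`, `$nodal_auc`, plus `$curves` (observed global curves),
#'   `$n_perm`, `$alpha`, `$seed`, `$grid`, `$groups`, `$n_redrawn`.
#' @export
scn_compare <- function(cohort, grid = density_grid(),
                        global_metrics = c("clustering", "path_length",
                                           "global_efficiency",
                                           "transitivity", "modularity"),
                        nodal_metrics = character(),
                        n_perm = 1000, seed = 1L, alpha = 0.05,
                        n_nulls = 0,
                        covariates = c("age", "sex"),
                        modularity_restarts = 10) {
  if (n_perm < 100) abort("`n_perm` must be >= 100 for reported p-values.")
  s <- cohort$subjects
  lev <- levels(s$group)
  case_mask <- s$group == lev[1]
  thick <- cohort$thickness
  covars <- as.matrix(as.data.frame(s[, covariates, drop = FALSE]))
  if (length(covariates) == 0) covars <- matrix(0, nrow(thick), 0)
  storage.mode(covars) <- "double"

  obs <- eval_group_arrays(thick, covars, case_mask, grid, global_metrics,
                           nodal_metrics, n_nulls, seed,
                           modularity_restarts)
  if (is.null(obs)) abort("A group has a zero-variance region in the observed data.")
  gm_names <- dimnames(obs$global)[[1]]
  obs_diff <- obs$global[, , 1, drop = FALSE][, , 1] -
    obs$global[, , 2, drop = FALSE][, , 1]
  obs_diff <- matrix(obs_diff, length(gm_names), length(grid),
                     dimnames = list(gm_names, NULL))
  obs_auc <- array_auc(obs$global, grid)          # metric x group
  obs_auc_diff <- obs_auc[, 1] - obs_auc[, 2]
  obs_nodal_diff <- if (length(nodal_metrics)) {
    matrix(obs$nodal_auc[, , 1] - obs$nodal_auc[, , 2],
           length(nodal_metrics), ncol(thick))
  }

  null_global <- array(NA_real_, c(n_perm, length(gm_names), length(grid)))
  null_auc <- matrix(NA_real_, n_perm, length(gm_names))
  null_nodal <- if (length(nodal_metrics)) {
    array(NA_real_, c(n_perm, length(nodal_metrics), ncol(thick)))
  }
  set.seed(seed)
  n <- nrow(thick)
  n_case <- sum(case_mask)
  n_redrawn <- 0L
  for (b in seq_len(n_perm)) {
    repeat {
      perm_mask <- logical(n)
      perm_mask[sample(n, n_case)] <- TRUE
      ev <- eval_group_arrays(thick, covars, perm_mask, grid,
                              global_metrics, nodal_metrics, n_nulls,
                              seed + b, modularity_restarts)
      if (!is.null(ev)) break
      n_redrawn <- n_redrawn + 1L
    }
    null_global[b, , ] <- matrix(ev$global[, , 1] - ev$global[, , 2],
                                 length(gm_names), length(grid))
    auc <- array_auc(ev$global, grid)
    null_auc[b, ] <- auc[, 1] - auc[, 2]
    if (length(nodal_metrics)) {
      null_nodal[b, , ] <- matrix(ev$nodal_auc[, , 1] - ev$nodal_auc[, , 2],
                                  length(nodal_metrics), ncol(thick))
    }
  }
  if (n_redrawn > 0) {
    inform(sprintf("%d permutation(s) redrawn due to zero-variance regions.",
                   n_redrawn))
  }

  global <- purrr::map_dfr(seq_along(gm_names), function(mi) {
    purrr::map_dfr(seq_along(grid), function(t) {
      nulls <- null_global[, mi, t]
      tibble::tibble(
        metric = gm_names[mi], density = grid[t],
        value_case = obs$global[mi, t, 1],
        value_control = obs$global[mi, t, 2],
        diff = obs_diff[mi, t],
        ci_low = unname(quantile(nulls, 0.025)),
        ci_high = unname(quantile(nulls, 0.975)),
        p_value = perm_pvalue(obs_diff[mi, t], nulls)
      )
    })
  }) |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(p_fdr = p.adjust(.data$p_value, method = "BH"),
                  significant = .data$p_fdr < alpha) |>
    dplyr::ungroup()

  global_auc <- purrr::map_dfr(seq_along(gm_names), function(mi) {
    nulls <- null_auc[, mi]
    tibble::tibble(
      metric = gm_names[mi],
      auc_case = obs_auc[mi, 1], auc_control = obs_auc[mi, 2],
      diff = obs_auc_diff[mi],
      ci_low = unname(quantile(nulls, 0.025)),
      ci_high = unname(quantile(nulls, 0.975)),
      p_value = perm_pvalue(obs_auc_diff[mi], nulls),
      significant = perm_pvalue(obs_auc_diff[mi], nulls) < alpha
    )
  })

  nodal_auc <- if (length(nodal_metrics)) {
    purrr::map_dfr(seq_along(nodal_metrics), function(mi) {
      purrr::map_dfr(seq_len(ncol(thick)), function(r) {
        nulls <- null_nodal[, mi, r]
        tibble::tibble(
          metric = nodal_metrics[mi],
          region = cohort$atlas$region[r],
          diff = obs_nodal_diff[mi, r],
          ci_low = unname(quantile(nulls, 0.025)),
          ci_high = unname(quantile(nulls, 0.975)),
          p_value = perm_pvalue(obs_nodal_diff[mi, r], nulls)
        )
      })
    }) |>
      dplyr::group_by(.data$metric) |>
      dplyr::mutate(p_fdr = p.adjust(.data$p_value, method = "BH"),
                    significant = .data$p_fdr < alpha) |>
      dplyr::ungroup()
  } else {
    tibble::tibble()
  }

  curves <- purrr::map_dfr(1:2, function(gi) {
    purrr::map_dfr(seq_along(gm_names), function(mi) {
      tibble::tibble(group = lev[gi], metric = gm_names[mi],
                     density = grid, value = obs$global[mi, , gi])
    })
  })

  structure(
    list(global = global, global_auc = global_auc, nodal_auc = nodal_auc,
         curves = curves, n_perm = n_perm, alpha = alpha, seed = seed,
         grid = grid, groups = lev, n_redrawn = n_redrawn,
         fdr_scope = "within metric across densities (global); across nodes (nodal AUC)"),
    class = "scn_comparison"
  )
}

#' @export
print.scn_comparison <- function(x, ...) {
  cat(sprintf(
    "<scn_comparison> %s vs %s, %d permutations, alpha = %.2f\n",
    x$groups[1], x$groups[2], x$n_perm, x$alpha
  ))
  sig <- dplyr::filter(x$global, .data$significant)
  cat(sprintf("  per-density FDR-significant: %d of %d tests\n",
              nrow(sig), nrow(x$global)))
  sig_auc <- dplyr::filter(x$global_auc, .data$significant)
  if (nrow(sig_auc)) {
    cat(sprintf("  AUC-significant metric(s): %s\n",
                paste(sig_auc$metric, collapse = ", ")))
  }
  invisible(x)
}

#' Identify network hubs by the betweenness z-criterion
#'
#' A hub is a node whose betweenness centrality is at least 2 standard
#' deviations above the network mean. Applied to an `scn_networks` object,
#' betweenness is first summarised per node as the area under its
#' betweenness-versus-density curve (one hub set per group over the whole
#' analysed range); a per-density mode is available.
#'
#' @param x An `scn_networks` object, or a numeric betweenness vector.
#' @param ... Passed to methods.
#' @return A tibble of class `scn_hubs`: `group`, `region`, `betweenness`,
#'   `threshold`, `is_hub` (all nodes are listed so the criterion is
#'   recomputable).
#' @export
identify_hubs <- function(x, ...) UseMethod("identify_hubs")

#' @rdname identify_hubs
#' @param atlas Atlas tibble matching the vector's length.
#' @param n_sd Number of standard deviations above the mean (default 2).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param group Group label recorded in the output.
#' @export
identify_hubs.numeric <- function(x, atlas, n_sd = 2,
                                  sd_type = c("sample", "population"),
                                  group = "group", ...) {
  sd_type <- match.arg(sd_type)
  if (length(x) != nrow(atlas)) {
    abort("Betweenness vector length must equal atlas size.")
  }
  s <- sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  thr <- mean(x) + n_sd * s
  out <- tibble::tibble(group = group, region = atlas$region,
                        betweenness = x, threshold = thr,
                        is_hub = s > 0 & x >= thr)
  class(out) <- c("scn_hubs", class(out))
  out
}

#' @rdname identify_hubs
#' @param mode `"auc"` (default) or `"density"`.
#' @param density Density to use when `mode = "density"`.
#' @export
identify_hubs.scn_networks <- function(x, n_sd = 2,
                                       sd_type = c("sample", "population"),
                                       mode = c("auc", "density"),
                                       density = NULL, ...) {
  mode <- match.arg(mode)
  sd_type <- match.arg(sd_type)
  out <- purrr::imap_dfr(x$networks, function(nw, g) {
    b <- if (mode == "auc") {
      B <- vapply(nw$adjacency, nodal_betweenness, numeric(nrow(nw$M)))
      apply(B, 1, function(v) metric_auc(nw$densities, v))
    } else {
      t <- which(abs(nw$densities - density) < 1e-9)
      if (!length(t)) abort("`density` is not on the network grid.")
      nodal_betweenness(nw$adjacency[[t]])
    }
    identify_hubs(b, x$atlas, n_sd = n_sd, sd_type = sd_type, group = g)
  })
  attr(out, "mode") <- mode
  class(out) <- c("scn_hubs", class(out))
  out
}

#' Shared and group-specific hubs
#'
#' @param a An `scn_hubs` table (one or two groups), or the first group's.
#' @param b Optional second `scn_hubs` table when `a` holds one group.
#' @return List with `shared` and one `only_<group>` character vector per
#'   group, order-stable (atlas order).
#' @export
hub_overlap <- function(a, b = NULL) {
  tab <- if (is.null(b)) a else dplyr::bind_rows(a, b)
  groups <- unique(tab$group)
  if (length(groups) != 2) abort("hub_overlap() needs exactly two groups.")
  hubs <- lapply(groups, function(g) {
    tab$region[tab$group == g & tab$is_hub]
  })
  out <- list(shared = intersect(hubs[[1]], hubs[[2]]))
  out[[paste0("only_", groups[1])]] <- setdiff(hubs[[1]], hubs[[2]])
  out[[paste0("only_", groups[2])]] <- setdiff(hubs[[2]], hubs[[1]])
  out
}
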