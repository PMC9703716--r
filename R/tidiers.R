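# broom-style tidiers for the package's result objects.

#' Tidy a network set into a long edge table
#'
#' @param x An `scn_networks` object.
#' @param ... Unused.
#' @return Tibble: `group`, `region_a`, `region_b`, `r` (association), one
#'   row per unordered region pair per group.
#' @method tidy scn_networks
#' @export
tidy.scn_networks <- function(x, ...) {
  purrr::imap_dfr(x$networks, function(nw, g) {
    ut <- which(upper.tri(nw$M), arr.ind = TRUE)
    tibble::tibble(group = g,
                   region_a = rownames(nw$M)[ut[, 1]],
                   region_b = colnames(nw$M)[ut[, 2]],
                   r = nw$M[ut])
  })
}

#' One-row summary of a network set
#'
#' @param x An `scn_networks` object.
#' @param ... Unused.
#' @return Tibble: node count, grid bounds, per-group and overall minimum
#'   connected density.
#' @method glance scn_networks
#' @export
glance.scn_networks <- function(x, ...) {
  dmins <- vapply(x$networks, `[[`, 0, "dmin")
  tibble::tibble(
    n_nodes = nrow(x$atlas),
    n_groups = length(x$networks),
    d_min = min(x$grid), d_max = max(x$grid),
    n_densities = length(x$grid),
    dmin_overall = x$dmin,
    !!!setNames(as.list(dmins), paste0("dmin_", names(x$networks)))
  )
}

#' Tidy a permutation comparison
#'
#' @param x An `scn_comparison` object.
#' @param which `"all"` (default), `"global"`, `"auc"` or `"nodal"`.
#' @param ... Unused.
#' @return Long tibble with a `scale` column distinguishing per-density
#'   tests, global AUC tests and nodal AUC tests.
#' @method tidy scn_comparison
#' @export
tidy.scn_comparison <- function(x, which = c("all", "global", "auc", "nodal"),
                                ...) {
  which <- match.arg(which)
  parts <- list()
  if (which %in% c("all", "global")) {
    parts$global <- dplyr::mutate(x$global, scale = "density",
                                  region = NA_character_)
  }
  if (which %in% c("all", "auc")) {
    parts$auc <- dplyr::mutate(
      dplyr::rename(x$global_auc, value_case = "auc_case",
                    value_control = "auc_control"),
      scale = "auc", density = NA_real_, region = NA_character_,
      p_fdr = NA_real_
    )
  }
  if (which %in% c("all", "nodal") && nrow(x$nodal_auc)) {
    parts$nodal <- dplyr::mutate(x$nodal_auc, scale = "nodal_auc",
                                 density = NA_real_,
                                 value_case = NA_real_,
                                 value_control = NA_real_)
  }
  dplyr::bind_rows(parts) |>
    dplyr::relocate("scale", "metric", "density", "region")
}

#' One-row summary of a permutation comparison
#'
#' @param x An `scn_comparison` object.
#' @param ... Unused.
#' @return Tibble with permutation count, alpha, and significant-test
#'   counts.
#' @method glance scn_comparison
#' @export
glance.scn_comparison <- function(x, ...) {
  tibble::tibble(
    n_perm = x$n_perm,
    alpha = x$alpha,
    n_metrics = length(unique(x$global$metric)),
    n_density_tests = nrow(x$global),
    n_density_significant = sum(x$global$significant),
    n_auc_significant = sum(x$global_auc$significant),
    n_nodal_significant = if (nrow(x$nodal_auc))
      sum(x$nodal_auc$significant) else NA_integer_,
    n_redrawn = x$n_redrawn
  )
}

#' Tidy a hub table down to the hubs
#'
#' @param x An `scn_hubs` table.
#' @param ... Unused.
#' @return The hub rows only, ordered by group then descending betweenness.
#' @method tidy scn_hubs
#' @export
tidy.scn_hubs <- function(x, ...) {
  dplyr::arrange(dplyr::filter(tibble::as_tibble(x), .data$is_hub),
                 .data$group, dplyr::desc(.data$betweenness))
}

#' One-row summary of a hub table
#'
#' @param x An `scn_hubs` table.
#' @param ... Unused.
#' @return Tibble with per-group hub counts and the shared-hub count.
#' @method glance scn_hubs
#' @export
glance.scn_hubs <- function(x, ...) {
  groups <- unique(x$group)
  counts <- vapply(groups, function(g) sum(x$is_hub[x$group == g]), 0L)
  shared <- if (length(groups) == 2) {
    length(hub_overlap(x)$shared)
  } else NA_integer_
  tibble::tibble(
    !!!setNames(as.list(counts), paste0("n_hubs_", groups)),
    n_shared = shared
  )
}
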