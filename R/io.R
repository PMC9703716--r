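# Tabular IO. Canonical dialect: tab-separated, UTF-8, '.' decimal, 'NA'
# missing token (the layout FreeSurfer region-table exports produce);
# comma-separated files are accepted by extension.

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    na = c("", "NA"), progress = FALSE)
}

find_id_column <- function(tbl) {
  hit <- intersect(c("subject_id", "id", "subject"), names(tbl))
  if (!length(hit)) {
    abort("No subject id column found (expected 'subject_id', 'id' or 'subject').")
  }
  hit[1]
}

#' Read a subjects-by-regions thickness table
#'
#' The header must name every atlas region (FreeSurfer `G_and_S_...` or the
#' `G&S_...` dialect, with `lh_`/`rh_` prefixes); columns are reordered to
#' atlas order, extra columns are dropped, row order is preserved.
#'
#' @param path TSV (or `.csv`) file, one row per subject.
#' @param atlas Region atlas tibble; default [destrieux_atlas()].
#' @return Tibble: `subject_id` then one numeric mm column per region, in
#'   atlas order.
#' @export
read_thickness_table <- function(path, atlas = destrieux_atlas()) {
  atlas <- validate_atlas(atlas)
  tbl <- read_delim_auto(path)
  id_col <- find_id_column(tbl)
  names(tbl)[names(tbl) != id_col] <-
    normalize_region_names(names(tbl)[names(tbl) != id_col])
  missing <- setdiff(atlas$region, names(tbl))
  if (length(missing)) {
    abort(sprintf("Thickness table is missing %d region column(s): %s",
                  length(missing), paste(missing, collapse = ", ")))
  }
  ids <- as.character(tbl[[id_col]])
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate subject id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out <- tbl[, atlas$region, drop = FALSE]
  for (j in seq_along(out)) {
    if (!is.numeric(out[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(out[[j]]))) &
                     !is.na(out[[j]]))[1]
      abort(sprintf("Non-numeric thickness value at row %d, column '%s'.",
                    bad %||% 1L, names(out)[j]))
    }
  }
  dplyr::bind_cols(tibble::tibble(subject_id = ids), out)
}

#' Read a subject metadata table
#'
#' Requires `subject_id` (or `id`), `group`, `age`, `sex`; any further
#' columns are kept as clinical variables with empty cells read as `NA`.
#' Exactly two group levels are enforced. `sex` may be 0/1 or M/F-style
#' labels (coded 1 = male).
#'
#' @param path TSV or CSV file.
#' @return Tibble with `subject_id`, `group` (factor, first-seen level
#'   first), `age`, `sex`, then clinical columns.
#' @export
read_subject_metadata <- function(path) {
  tbl <- read_delim_auto(path)
  id_col <- find_id_column(tbl)
  names(tbl)[names(tbl) == id_col] <- "subject_id"
  need <- setdiff(c("group", "age", "sex"), names(tbl))
  if (length(need)) {
    abort(sprintf("Metadata is missing column(s): %s",
                  paste(need, collapse = ", ")))
  }
  g <- as.character(tbl$group)
  lev <- unique(g[!is.na(g)])
  if (length(lev) != 2) {
    abort(sprintf("Exactly two group levels required, found %d (%s).",
                  length(lev), paste(lev, collapse = ", ")))
  }
  tbl$group <- factor(g, levels = lev)
  tbl$subject_id <- as.character(tbl$subject_id)
  if (!is.numeric(tbl$sex)) {
    sx <- toupper(substr(as.character(tbl$sex), 1, 1))
    tbl$sex <- ifelse(sx %in% c("M", "1"), 1,
                      ifelse(sx %in% c("F", "0"), 0, NA_real_))
  }
  dplyr::relocate(tbl, "subject_id", "group", "age", "sex")
}

#' Write a cohort to its two canonical tables
#'
#' Emits `thickness.tsv` (subject by region) and `metadata.tsv`, the same
#' layouts [read_thickness_table()] and [read_subject_metadata()] read.
#'
#' @param cohort An `scn_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  thick <- dplyr::bind_cols(
    tibble::tibble(subject_id = cohort$subjects$subject_id),
    tibble::as_tibble(cohort$thickness)
  )
  paths <- c(file.path(dir, "thickness.tsv"), file.path(dir, "metadata.tsv"))
  readr::write_tsv(thick, paths[1])
  readr::write_tsv(cohort$subjects, paths[2])
  invisible(paths)
}

matrix_to_tibble <- function(M) {
  dplyr::bind_cols(tibble::tibble(region = rownames(M)), tibble::as_tibble(M))
}

#' Read a region-by-region matrix written by [write_results()]
#'
#' @param path TSV with a `region` column and one column per region.
#' @return Numeric matrix with region dimnames.
#' @export
read_matrix_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  M <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(M) <- tbl[[1]]
  M
}

#' Write an analysis result bundle
#'
#' Accepts any subset of the pipeline's products and writes a deterministic
#' file set: per-region test table, demographics, correlation battery,
#' per-group association matrices and minimum connected densities, metric
#' curves, permutation comparison tables, hub table, plus a `summary.json`
#' index. Every p-value is stored alongside its statistic and n.
#'
#' @param bundle Named list with any of `demographics`, `roi`,
#'   `correlations`, `networks` (`scn_networks`), `global_curves`,
#'   `nodal_curves`, `comparison` (`scn_comparison`), `hubs`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a character vector of written file paths.
#' @export
write_results <- function(bundle, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }
  files <- character()
  put <- function(tbl, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(tbl, path)
    files <<- c(files, path)
  }
  if (!is.null(bundle$demographics)) put(bundle$demographics, "demographics.tsv")
  if (!is.null(bundle$roi)) put(bundle$roi, "roi_comparison.tsv")
  if (!is.null(bundle$correlations)) put(bundle$correlations, "clinical_correlations.tsv")
  if (!is.null(bundle$networks)) {
    nets <- bundle$networks
    for (g in names(nets$networks)) {
      put(matrix_to_tibble(nets$networks[[g]]$M),
          sprintf("association_matrix_%s.tsv", g))
    }
    put(tibble::tibble(
      group = names(nets$networks),
      dmin = vapply(nets$networks, `[[`, 0, "dmin")
    ), "min_connected_density.tsv")
  }
  if (!is.null(bundle$global_curves)) put(bundle$global_curves, "global_metric_curves.tsv")
  if (!is.null(bundle$nodal_curves)) put(bundle$nodal_curves, "nodal_metric_curves.tsv")
  if (!is.null(bundle$comparison)) {
    cmp <- bundle$comparison
    put(cmp$global, "comparison_global.tsv")
    if (!is.null(cmp$nodal) && nrow(cmp$nodal)) put(cmp$nodal, "comparison_nodal.tsv")
  }
  if (!is.null(bundle$hubs)) put(bundle$hubs, "hubs.tsv")
  if (!length(files)) warn("Empty result bundle: nothing written.")

  summary <- list(
    files = basename(files),
    components = names(bundle)[!vapply(bundle, is.null, TRUE)]
  )
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, json_path))
}
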