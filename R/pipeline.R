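# Config-driven end-to-end runner: load or simulate a cohort, demographic
# and ROI statistics, clinical correlations on the significant regions,
# network construction, metric curves, permutation comparison, hubs.
# Deterministic for a fixed config + seed; results are written once, at the
# end, so a toggled-off or failing stage leaves no partial result tables.

#' Default pipeline configuration
#'
#' A complete synthetic-cohort run at the emulated study scale. Every field
#' can be overridden in a YAML file or by editing the returned list.
#'
#' @param out_dir Output directory.
#' @param seed Master seed (mandatory for any run).
#' @return Named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = "scn_results", seed = 1L) {
  list(
    seed = seed,
    out_dir = out_dir,
    synthetic = list(n_case = 108, n_control = 88, n_regions = 148),
    input = NULL,                 # list(thickness =, metadata =) to use real tables
    grid = list(d_min = 0.38, d_max = 0.50, step = 0.01),
    covariates = c("age", "sex"),
    alpha = 0.05,
    n_perm = 1000,
    n_nulls = 20,
    global_metrics = c("clustering", "path_length", "global_efficiency",
                       "transitivity", "modularity"),
    nodal_metrics = character(),
    stages = c("demographics", "roi", "clinical", "scn", "metrics",
               "compare", "hubs"),
    write_cohort = TRUE
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; missing fields fall back to
#'   [default_pipeline_config()].
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  cfg[names(user)] <- user
  cfg
}

pipeline_cohort <- function(cfg) {
  if (!is.null(cfg$input)) {
    meta <- read_subject_metadata(cfg$input$metadata)
    atlas <- if (!is.null(cfg$input$atlas)) cfg$input$atlas else destrieux_atlas()
    thick <- read_thickness_table(cfg$input$thickness, atlas)
    return(as_cohort(thick, meta, atlas))
  }
  syn <- cfg$synthetic
  atlas <- if ((syn$n_regions %||% 148) == 148) destrieux_atlas() else
    region_atlas(sprintf("R%03d", seq_len(syn$n_regions)))
  args <- list(
    n_per_group = c(case = syn$n_case %||% 108, control = syn$n_control %||% 88),
    atlas = atlas,
    seed = cfg$seed
  )
  passthrough <- intersect(
    c("within_module_r", "between_module_r", "planted_hubs",
      "hub_coupling_r", "thinning", "n_modules"),
    names(syn)
  )
  args[passthrough] <- syn[passthrough]
  simulate_cohort(do.call(cohort_spec, args))
}

#' Run the full analysis pipeline
#'
#' Stages (in order): load/simulate -> demographics -> per-region group
#' comparison -> clinical correlations on the significant regions ->
#' network construction (with the minimum connected density) -> metric
#' curves -> permutation comparison with AUC analysis -> hub
#' identification. Results are written with [write_results()] together with
#' a manifest (config hash, seed, versions, per-stage wall time) and a
#' timestamped log.
#'
#' @param config Config list (see [default_pipeline_config()]) or `NULL`.
#' @param config_file Optional YAML path, read with
#'   [read_pipeline_config()].
#' @param ... Named overrides applied on top of the config (e.g. `seed`,
#'   `out_dir`, `n_perm`).
#' @return Invisibly, the result bundle (a named list also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config = NULL, config_file = NULL, ...) {
  cfg <- if (!is.null(config_file)) read_pipeline_config(config_file) else
    config %||% default_pipeline_config()
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  if (is.null(cfg$seed)) abort("The pipeline config must set a seed.")
  cfg_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  log_line("pipeline start; seed = %d; config hash = %s", cfg$seed, cfg_hash)

  bundle <- list()
  timings <- list()
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      log_line("stage '%s' FAILED: %s", name, conditionMessage(e))
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    log_line("stage '%s' done in %.2fs", name, timings[[name]])
    res
  }

  grid <- density_grid(cfg$grid$d_min, cfg$grid$d_max, cfg$grid$step)
  on <- function(stage) stage %in% cfg$stages

  cohort <- run_stage("load", pipeline_cohort(cfg))
  if (isTRUE(cfg$write_cohort) && is.null(cfg$input)) {
    write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
  }
  if (on("demographics")) {
    bundle$demographics <- run_stage("demographics", demographics_table(cohort))
  }
  if (on("roi")) {
    bundle$roi <- run_stage("roi", roi_group_comparison(cohort, cfg$alpha))
  }
  if (on("clinical")) {
    if (is.null(bundle$roi)) {
      warn("Clinical stage needs the ROI stage; skipping.")
    } else if (nrow(cohort$clinical) == 0) {
      log_line("no clinical variables; skipping clinical stage")
    } else {
      sig <- bundle$roi$region[bundle$roi$significant]
      bundle$correlations <- run_stage(
        "clinical", correlation_battery(cohort, sig, alpha = cfg$alpha)
      )
    }
  }
  if (on("scn")) {
    bundle$networks <- run_stage(
      "scn", build_networks(cohort, grid, cfg$covariates)
    )
  }
  if (on("metrics") && !is.null(bundle$networks)) {
    bundle$global_curves <- run_stage("metrics", global_metric_curves(
      bundle$networks, cfg$global_metrics,
      n_nulls = cfg$n_nulls %||% 0, seed = cfg$seed
    ))
    if (length(cfg$nodal_metrics)) {
      bundle$nodal_curves <- nodal_metric_curves(bundle$networks,
                                                 cfg$nodal_metrics)
    }
  }
  if (on("compare")) {
    bundle$comparison <- run_stage("compare", scn_compare(
      cohort, grid, global_metrics = cfg$global_metrics,
      nodal_metrics = cfg$nodal_metrics, n_perm = cfg$n_perm,
      seed = cfg$seed, alpha = cfg$alpha, covariates = cfg$covariates
    ))
  }
  if (on("hubs") && !is.null(bundle$networks)) {
    bundle$hubs <- run_stage("hubs", identify_hubs(bundle$networks))
  }

  files <- run_stage("write", write_results(bundle, cfg$out_dir))
  manifest <- list(
    package = "scnthick",
    version = as.character(utils::packageVersion("scnthick")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = cfg_hash,
    stages = cfg$stages,
    timings_s = timings,
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("pipeline done")
  invisible(bundle)
}
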