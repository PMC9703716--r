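# Synthetic cohort generation: multivariate-normal thickness per group with
# a block-modular target correlation, linear age/sex effects, planted hubs,
# then clinical variables through a Gaussian copula.

# target inter-regional correlation for one group, with PSD repair by
# eigenvalue clipping (block-constant targets can be slightly indefinite)
build_target_correlation <- function(spec, group, repair_tol = 0.1) {
  p <- nrow(spec$atlas)
  mods <- spec$module_assignment
  C <- matrix(spec$between_module_r[[group]], p, p)
  same <- outer(mods, mods, `==`)
  C[same] <- spec$within_module_r[[group]]
  hubs <- match(spec$planted_hubs, spec$atlas$region)
  for (h in hubs) {
    C[h, ] <- pmax(C[h, ], spec$hub_coupling_r)
    C[, h] <- pmax(C[, h], spec$hub_coupling_r)
  }
  diag(C) <- 1
  dimnames(C) <- list(spec$atlas$region, spec$atlas$region)

  ev <- eigen(C, symmetric = TRUE)
  repaired <- FALSE
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    C2 <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(C2))
    C2 <- C2 / tcrossprod(d)
    diag(C2) <- 1
    delta <- abs(C2 - C)
    if (max(delta) > repair_tol) {
      worst <- which(delta == max(delta), arr.ind = TRUE)[1, ]
      abort(sprintf(
        paste0("Target correlation for group '%s' is not positive ",
               "semi-definite and repair exceeds tolerance %.2f at the block ",
               "containing modules %d and %d."),
        group, repair_tol, mods[worst[1]], mods[worst[2]]
      ))
    }
    dimnames(C2) <- dimnames(C)
    C <- C2
    repaired <- TRUE
  }
  attr(C, "psd_repaired") <- repaired
  C
}

new_cohort <- function(subjects, thickness, atlas, clinical_meta = NULL) {
  atlas <- validate_atlas(atlas)
  if (nrow(thickness) != nrow(subjects)) {
    abort("Thickness row count must equal subject count.")
  }
  if (ncol(thickness) != nrow(atlas)) {
    abort("Thickness column count must equal atlas size.")
  }
  if (!all(is.finite(thickness)) || any(thickness <= 0)) {
    abort("Thickness entries must be finite and > 0 (mm).")
  }
  if (anyDuplicated(subjects$subject_id)) {
    abort("Duplicate subject ids.")
  }
  g <- subjects$group
  if (!is.factor(g)) g <- factor(g, levels = unique(as.character(g)))
  if (nlevels(g) != 2) {
    abort(sprintf("Exactly two group levels required, got %d.", nlevels(g)))
  }
  subjects$group <- g
  colnames(thickness) <- atlas$region
  rownames(thickness) <- subjects$subject_id
  structure(
    list(subjects = tibble::as_tibble(subjects), thickness = thickness,
         atlas = atlas,
         clinical = clinical_meta %||%
           tibble::tibble(variable = character(), type = character())),
    class = "scn_cohort"
  )
}

#' Assemble a cohort from thickness and metadata tables
#'
#' @param thickness Tibble from [read_thickness_table()] (or equivalent):
#'   `subject_id` plus one numeric column per atlas region.
#' @param metadata Tibble from [read_subject_metadata()]: `subject_id`,
#'   `group`, `age`, `sex`, plus optional clinical columns.
#' @param atlas Region atlas; default [destrieux_atlas()].
#' @return An `scn_cohort` object.
#' @export
as_cohort <- function(thickness, metadata, atlas = destrieux_atlas()) {
  atlas <- validate_atlas(atlas)
  if (!all(metadata$subject_id %in% thickness$subject_id)) {
    abort("Every metadata subject needs a thickness row.")
  }
  thickness <- thickness[match(metadata$subject_id, thickness$subject_id), ]
  mat <- as.matrix(thickness[, atlas$region, drop = FALSE])
  clin_cols <- setdiff(names(metadata),
                       c("subject_id", "group", "age", "sex"))
  meta <- tibble::tibble(
    variable = clin_cols,
    type = vapply(clin_cols, function(v) {
      if (is_binary01(metadata[[v]])) "binary" else "continuous"
    }, character(1))
  )
  new_cohort(metadata, mat, atlas, meta)
}

#' Generate a synthetic two-group cohort
#'
#' Thickness is drawn from a group-specific multivariate normal whose
#' correlation follows the module/hub structure of the spec, then shifted by
#' linear age and sex effects (age centred at the midpoint of the age range,
#' sex centred at 1/2, so the spec's region means are population means).
#' Fully deterministic given `spec$seed`.
#'
#' @param spec An [cohort_spec()] object.
#' @param clinical Attach the clinical variables too (default `TRUE`)?
#' @return An `scn_cohort`: `$subjects` tibble (id, group, age, sex,
#'   clinical columns), `$thickness` subjects-by-regions matrix in mm,
#'   `$atlas`, `$clinical` variable metadata.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(seed = 42))
#' dim(cohort$thickness)
#' @export
simulate_cohort <- function(spec, clinical = TRUE) {
  if (!inherits(spec, "scn_cohort_spec")) {
    abort("`spec` must come from cohort_spec().")
  }
  set.seed(spec$seed)
  p <- nrow(spec$atlas)
  parts <- lapply(spec$groups, function(g) {
    n <- spec$n_per_group[[g]]
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    sex <- rbinom(n, 1, spec$male_prevalence[[g]])
    C <- build_target_correlation(spec, g)
    L <- chol(C)
    E <- matrix(rnorm(n * p), n, p) %*% L
    thick <- sweep(E, 2, spec$region_sds[g, ], `*`) +
      matrix(spec$region_means[g, ], n, p, byrow = TRUE) +
      outer(age - mean(spec$age_range), spec$age_slope) +
      outer(sex - 0.5, spec$sex_offset)
    list(subjects = tibble::tibble(group = g, age = age, sex = sex),
         thickness = thick, repaired = attr(C, "psd_repaired"))
  })
  subjects <- dplyr::bind_rows(lapply(parts, `[[`, "subjects"))
  subjects <- tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(nrow(subjects))),
    group = factor(subjects$group, levels = spec$groups),
    age = subjects$age, sex = subjects$sex
  )
  thickness <- do.call(rbind, lapply(parts, `[[`, "thickness"))
  cohort <- new_cohort(subjects, thickness, spec$atlas)
  attr(cohort, "psd_repaired") <- any(vapply(parts, `[[`, TRUE, "repaired"))
  if (clinical && length(spec$clinical)) {
    cohort <- attach_clinical(cohort, spec)
  }
  cohort
}

#' Attach synthetic clinical variables to a cohort
#'
#' Each variable is generated through a Gaussian copula whose latent score
#' optionally correlates with the standardised thickness of a named region;
#' binary variables threshold the latent score at the prevalence quantile.
#' Missingness is missing-completely-at-random down to `n_obs` subjects.
#' Deterministic given `spec$seed` (an offset stream is used so thickness
#' draws are unaffected).
#'
#' @param cohort An `scn_cohort`.
#' @param spec The [cohort_spec()] holding `$clinical`.
#' @return The cohort with clinical columns added to `$subjects`.
#' @export
attach_clinical <- function(cohort, spec) {
  set.seed(spec$seed + 1013L)
  subjects <- cohort$subjects
  meta <- list()
  for (v in spec$clinical) {
    groups <- v$groups %||% levels(subjects$group)[1]
    idx <- which(subjects$group %in% groups)
    n <- length(idx)
    if (!is.null(v$coupling_region)) {
      if (!v$coupling_region %in% cohort$atlas$region) {
        abort(sprintf("Clinical variable '%s': unknown region '%s'.",
                      v$name, v$coupling_region))
      }
      z <- as.numeric(scale(cohort$thickness[idx, v$coupling_region]))
      latent <- v$coupling_rho * z +
        sqrt(1 - v$coupling_rho^2) * rnorm(n)
    } else {
      latent <- rnorm(n)
    }
    u <- pnorm(latent)
    val <- switch(
      paste(v$type, v$dist, sep = "."),
      binary.lognormal = ,
      binary.normal = as.numeric(u > 1 - v$prevalence),
      continuous.lognormal = qlnorm(u, v$location, v$scale),
      continuous.normal = qnorm(u, v$location, v$scale)
    )
    if (!is.null(v$digits)) val <- round(val, v$digits)
    if (!is.null(v$clip)) val <- pmin(pmax(val, v$clip[1]), v$clip[2])
    if (!is.null(v$n_obs) && v$n_obs < n) {
      observed <- sample(n, v$n_obs)
      val[setdiff(seq_len(n), observed)] <- NA_real_
    }
    col <- rep(NA_real_, nrow(subjects))
    col[idx] <- val
    subjects[[v$name]] <- col
    meta[[v$name]] <- v$type
  }
  cohort$subjects <- subjects
  cohort$clinical <- tibble::tibble(
    variable = names(meta), type = unlist(meta, use.names = FALSE)
  )
  cohort
}

#' @export
print.scn_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf(
    "<scn_cohort> %d subjects (%s), %d regions, %d clinical variable(s)\n",
    nrow(x$subjects),
    paste(sprintf("%s n=%d", names(tab), as.integer(tab)), collapse = ", "),
    nrow(x$atlas), nrow(x$clinical)
  ))
  invisible(x)
}

#' Extract the subjects-by-regions thickness matrix
#'
#' @param cohort An `scn_cohort`.
#' @return Numeric matrix (mm), rows = subjects, columns = atlas regions.
#' @export
thickness_matrix <- function(cohort) cohort$thickness
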