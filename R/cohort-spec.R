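# Specification objects for the synthetic two-group cohort generator.
#
# Defaults emulate the study design the package targets: a patient group of
# 108 and a control group of 88, 148 bilateral cortical regions with mean
# thickness between roughly 2 and 3 mm (SD 0.1-0.3 mm), cortical thinning of
# ~0.09 mm in 57 designated regions of the patient group, block-modular
# inter-regional correlation that is stronger within than between modules,
# two planted high-connectivity (hub) regions, linear age and sex effects,
# and a menu of clinical variables (durations, drug accumulations, antibody
# statuses, disease-activity and psychometric scores) with per-variable
# observation counts.

#' Describe one synthetic clinical variable
#'
#' Continuous variables are drawn through a Gaussian copula: a standard
#' normal latent score, optionally correlated with the (standardised)
#' thickness of one named region, is pushed through the quantile function of
#' the target distribution. Binary variables threshold the same latent score
#' at the quantile matching `prevalence`.
#'
#' @param name Column name in the subject table.
#' @param type `"continuous"` or `"binary"`.
#' @param dist Distribution family for continuous variables: `"lognormal"`
#'   (`location` = meanlog, `scale` = sdlog) or `"normal"`.
#' @param location,scale Distribution parameters (see `dist`).
#' @param prevalence Positive-class probability for binary variables.
#' @param groups Group labels the variable exists for (default the first,
#'   i.e. patient, group); other subjects get `NA`.
#' @param n_obs If smaller than the eligible subject count, only this many
#'   (missing-completely-at-random) subjects carry a value.
#' @param coupling_region,coupling_rho Optional region whose thickness the
#'   latent score correlates with at `coupling_rho`.
#' @param digits,clip Optional rounding and range clipping applied to the
#'   generated values (e.g. integer scores capped at 30).
#' @return An object of class `scn_clinical_variable`.
#' @examples
#' clinical_variable("anti_dsDNA", type = "binary", prevalence = 0.685)
#' @export
clinical_variable <- function(name,
                              type = c("continuous", "binary"),
                              dist = c("lognormal", "normal"),
                              location = 0,
                              scale = 1,
                              prevalence = NULL,
                              groups = NULL,
                              n_obs = NULL,
                              coupling_region = NULL,
                              coupling_rho = 0,
                              digits = NULL,
                              clip = NULL) {
  type <- match.arg(type)
  dist <- match.arg(dist)
  if (type == "binary") {
    check_scalar_prob(prevalence %||% NA_real_, "prevalence")
  }
  if (abs(coupling_rho) >= 1) {
    abort("`coupling_rho` must be in (-1, 1).")
  }
  structure(
    list(name = name, type = type, dist = dist, location = location,
         scale = scale, prevalence = prevalence, groups = groups,
         n_obs = n_obs, coupling_region = coupling_region,
         coupling_rho = coupling_rho, digits = digits, clip = clip),
    class = "scn_clinical_variable"
  )
}

#' Default synthetic clinical menu
#'
#' Medians and dispersions are set to the scale of the study population the
#' generator emulates (disease duration ~12 months, SLEDAI ~9, MMSE ~27,
#' anti-dsDNA prevalence 68.5%, lupus-anticoagulant assays observed in 79 of
#' 108 patients, and so on). Two variables are weakly coupled to regional
#' thickness so correlation-recovery can be exercised end to end.
#'
#' @return A list of [clinical_variable()] objects.
#' @export
default_clinical_spec <- function() {
  ln <- function(name, median, sdlog, ...) {
    clinical_variable(name, "continuous", "lognormal",
                      location = log(median), scale = sdlog, ...)
  }
  ab <- function(name, prev) {
    clinical_variable(name, "binary", prevalence = prev)
  }
  list(
    ln("disease_duration_months", 12, 1.54,
       coupling_region = "lh_S_precentral-inf-part", coupling_rho = -0.21),
    ln("glucocorticoid_g", 5.59, 1.99, n_obs = 84),
    ln("ctx_g", 2.60, 1.50, n_obs = 26),
    ln("hcq_g", 9.40, 2.98, n_obs = 46),
    ln("acl", 9.22, 0.56, n_obs = 79),
    ln("lac", 13.70, 0.90, n_obs = 79),
    ln("urine_protein_g24h", 0.80, 1.00),
    ln("ana_titer", 320, 1.00),
    ln("sledai", 9, 0.73, digits = 0),
    clinical_variable("mmse", "continuous", "normal", location = 27,
                      scale = 2.5, digits = 0, clip = c(0, 30),
                      coupling_region = "rh_G_and_S_cingul-Ant",
                      coupling_rho = 0.30),
    ln("hama", 5, 0.83, digits = 0),
    ln("hamd", 7, 1.07, digits = 0),
    ab("anti_dsDNA", 0.685), ab("anti_Sm", 0.463), ab("anti_U1RNP", 0.306),
    ab("anti_SSA52", 0.500), ab("anti_SSA60", 0.611), ab("anti_SSB", 0.352),
    ab("anti_histones", 0.556), ab("anti_P0", 0.509),
    ab("anti_nucleosome", 0.407), ab("anti_centromere", 0.028),
    ab("anti_DNP", 0.120)
  )
}

default_module_assignment <- function(atlas, n_modules = 6) {
  # contiguous blocks over base names, mirrored across hemispheres so a
  # region and its contralateral homologue share a module
  base <- unique(atlas$name)
  block <- ceiling(seq_along(base) * n_modules / length(base))
  setNames(block[match(atlas$name, base)], atlas$region)
}

default_thinned_regions <- function(atlas, n_left = 27, n_right = 30) {
  left <- atlas$region[atlas$hemisphere == "left"]
  right <- atlas$region[atlas$hemisphere == "right"]
  pick <- function(x, k) {
    if (length(x) <= k) x else x[unique(round(seq(1, length(x), length.out = k)))]
  }
  c(pick(left, min(n_left, length(left))),
    pick(right, min(n_right, length(right))))
}

#' Specify a synthetic two-group cohort
#'
#' All defaults describe the emulated study conditions; see the methods
#' vignette for how each was chosen. Group order matters: the first group is
#' treated as the patient ("case") group throughout the package.
#'
#' @param n_per_group Named vector of two group sizes (each >= 3); names
#'   become the group labels.
#' @param atlas Region atlas tibble, default [destrieux_atlas()].
#' @param region_means Group-by-region matrix of mean thickness (mm), rows in
#'   group order. Default: a bilateral 2.0-3.0 mm profile for controls, with
#'   `thinning` subtracted in `thinned_regions` for the first group.
#' @param region_sds Group-by-region matrix of SDs (mm, all > 0); default a
#'   bilateral 0.10-0.30 mm profile for both groups.
#' @param thinned_regions Regions thinned in the first group when
#'   `region_means` is not supplied; default 27 left + 30 right regions.
#' @param thinning Thinning magnitude in mm (default 0.09).
#' @param age_slope Thickness change per year of age (mm/year, default
#'   -0.005), scalar or per-region vector; age is centred at the midpoint of
#'   `age_range` so region means are population means.
#' @param sex_offset Thickness offset for male (sex = 1) subjects in mm
#'   (default 0.02), applied around a balanced reference.
#' @param age_range Uniform age range in years (default 18-50).
#' @param male_prevalence Per-group probability that sex = 1 (male).
#' @param module_assignment Named integer vector region -> module id;
#'   default 6 contiguous, hemisphere-mirrored blocks.
#' @param n_modules Number of default modules.
#' @param within_module_r,between_module_r Per-group target correlations
#'   inside and across modules (each in (-1, 1)).
#' @param planted_hubs Regions given `hub_coupling_r` correlation to *all*
#'   other regions, creating high-betweenness nodes. Default: two regions
#'   when the atlas contains them, otherwise none.
#' @param hub_coupling_r Hub coupling level (default 0.35).
#' @param clinical List of [clinical_variable()] specs;
#'   default [default_clinical_spec()] for the Destrieux atlas.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `scn_cohort_spec`.
#' @examples
#' spec <- cohort_spec(seed = 7)
#' spec$n_per_group
#' @export
cohort_spec <- function(n_per_group = c(case = 108, control = 88),
                        atlas = destrieux_atlas(),
                        region_means = NULL,
                        region_sds = NULL,
                        thinned_regions = NULL,
                        thinning = 0.09,
                        age_slope = -0.005,
                        sex_offset = 0.02,
                        age_range = c(18, 50),
                        male_prevalence = c(0.176, 0.284),
                        module_assignment = NULL,
                        n_modules = 6,
                        within_module_r = c(0.55, 0.45),
                        between_module_r = c(0.15, 0.15),
                        planted_hubs = NULL,
                        hub_coupling_r = 0.35,
                        clinical = NULL,
                        seed = 1L) {
  atlas <- validate_atlas(atlas)
  p <- nrow(atlas)
  if (length(n_per_group) != 2 || any(n_per_group < 3)) {
    abort("`n_per_group` must give exactly two group sizes, each >= 3.")
  }
  if (is.null(names(n_per_group))) names(n_per_group) <- c("case", "control")
  groups <- names(n_per_group)

  per_group <- function(x, name) {
    x <- if (length(x) == 1) c(x, x) else x
    if (length(x) != 2) abort(sprintf("`%s` must have length 1 or 2.", name))
    setNames(as.numeric(x), groups)
  }
  within_module_r <- per_group(within_module_r, "within_module_r")
  between_module_r <- per_group(between_module_r, "between_module_r")
  male_prevalence <- per_group(male_prevalence, "male_prevalence")
  if (any(abs(c(within_module_r, between_module_r)) >= 1)) {
    abort("Module correlations must lie in (-1, 1).")
  }
  if (abs(hub_coupling_r) >= 1) abort("`hub_coupling_r` must lie in (-1, 1).")

  half <- function(lo, hi) {
    base <- unique(atlas$name)
    prof <- seq(lo, hi, length.out = length(base))
    prof[match(atlas$name, base)]
  }
  if (is.null(region_sds)) {
    region_sds <- rbind(half(0.10, 0.30), half(0.10, 0.30))
  }
  if (is.null(region_means)) {
    control_means <- half(2.0, 3.0)
    thinned_regions <- thinned_regions %||% default_thinned_regions(atlas)
    case_means <- control_means -
      thinning * as.numeric(atlas$region %in% thinned_regions)
    region_means <- rbind(case_means, control_means)
  } else {
    thinned_regions <- thinned_regions %||% character()
  }
  region_means <- matrix(as.numeric(region_means), nrow = 2,
                         dimnames = list(groups, atlas$region))
  region_sds <- matrix(as.numeric(region_sds), nrow = 2,
                       dimnames = list(groups, atlas$region))
  if (ncol(region_means) != p || ncol(region_sds) != p) {
    abort("`region_means`/`region_sds` must have one column per region.")
  }
  if (any(region_sds <= 0)) abort("All region SDs must be > 0.")

  module_assignment <- module_assignment %||%
    default_module_assignment(atlas, n_modules)
  if (is.null(names(module_assignment))) {
    names(module_assignment) <- atlas$region
  }
  if (!setequal(names(module_assignment), atlas$region)) {
    abort("`module_assignment` must name every atlas region.")
  }
  module_assignment <- module_assignment[atlas$region]

  if (is.null(planted_hubs)) {
    candidates <- c("lh_G_and_S_cingul-Ant", "rh_G_front_middle")
    planted_hubs <- intersect(candidates, atlas$region)
  }
  if (!all(planted_hubs %in% atlas$region)) {
    abort(sprintf("Unknown planted hub region(s): %s",
                  paste(setdiff(planted_hubs, atlas$region), collapse = ", ")))
  }

  if (is.null(clinical)) {
    clinical <- default_clinical_spec()
    # keep only couplings the atlas can honour (reduced synthetic atlases)
    clinical <- lapply(clinical, function(v) {
      if (!is.null(v$coupling_region) && !v$coupling_region %in% atlas$region) {
        v$coupling_region <- NULL
        v$coupling_rho <- 0
      }
      v
    })
  }
  for (v in clinical) {
    if (!is.null(v$coupling_region) && !v$coupling_region %in% atlas$region) {
      abort(sprintf("Clinical variable '%s' couples to unknown region '%s'.",
                    v$name, v$coupling_region))
    }
  }
  if (anyDuplicated(vapply(clinical, `[[`, "", "name"))) {
    abort("Clinical variable names must be unique.")
  }

  structure(
    list(n_per_group = n_per_group, groups = groups, atlas = atlas,
         region_means = region_means, region_sds = region_sds,
         thinned_regions = thinned_regions, thinning = thinning,
         age_slope = rep(age_slope, length.out = p),
         sex_offset = rep(sex_offset, length.out = p),
         age_range = age_range, male_prevalence = male_prevalence,
         module_assignment = module_assignment,
         within_module_r = within_module_r,
         between_module_r = between_module_r,
         planted_hubs = planted_hubs, hub_coupling_r = hub_coupling_r,
         clinical = clinical, seed = as.integer(seed)),
    class = "scn_cohort_spec"
  )
}

#' @export
print.scn_cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<scn_cohort_spec> groups %s (n = %s), %d regions, %d modules, %d planted hub(s), seed %d\n",
    paste(x$groups, collapse = "/"),
    paste(x$n_per_group, collapse = "/"),
    nrow(x$atlas), length(unique(x$module_assignment)),
    length(x$planted_hubs), x$seed
  ))
  invisible(x)
}
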