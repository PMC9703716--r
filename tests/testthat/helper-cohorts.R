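# Shared fixture builders: reduced synthetic atlases and cohorts built in
# code at test time.

tiny_atlas <- function(n) region_atlas(sprintf("R%03d", seq_len(n)))

# fully independent regions, no covariate effects, no planted structure
independent_spec <- function(n_regions = 20, n = c(case = 30, control = 30),
                             seed = 1, ...) {
  cohort_spec(
    n_per_group = n, atlas = tiny_atlas(n_regions),
    within_module_r = 0, between_module_r = 0,
    planted_hubs = character(), thinning = 0,
    age_slope = 0, sex_offset = 0, seed = seed, ...
  )
}

# null cohort for permutation studies: realistic covariate effects but no
# group difference in means or covariance
null_cohort <- function(n_regions = 60, n_per_group = 40, seed = 1) {
  simulate_cohort(cohort_spec(
    n_per_group = c(case = n_per_group, control = n_per_group),
    atlas = tiny_atlas(n_regions),
    within_module_r = 0, between_module_r = 0,
    planted_hubs = character(), thinning = 0, seed = seed
  ), clinical = FALSE)
}

# cohort whose two groups are identical subject-for-subject
duplicated_group_cohort <- function(n = 20, n_regions = 12, seed = 7) {
  set.seed(seed)
  thick <- matrix(rnorm(n * n_regions, 2.5, 0.2), n, n_regions)
  atlas <- tiny_atlas(n_regions)
  thick2 <- rbind(thick, thick)
  meta <- tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(2 * n)),
    group = rep(c("case", "control"), each = n),
    age = rep(runif(n, 20, 45), 2),
    sex = rep(rbinom(n, 1, 0.5), 2)
  )
  tt <- dplyr::bind_cols(tibble::tibble(subject_id = meta$subject_id),
                         tibble::as_tibble(`colnames<-`(thick2, atlas$region)))
  as_cohort(tt, meta, atlas)
}
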