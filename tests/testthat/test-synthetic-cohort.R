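test_that("generated cohorts have the forced dimensions and valid structure", {
  cohort <- simulate_cohort(cohort_spec(seed = 11))
  expect_equal(dim(cohort$thickness), c(196, 148))
  expect_equal(nrow(cohort$subjects), 196)
  expect_equal(levels(cohort$subjects$group), c("case", "control"))
  expect_equal(as.integer(table(cohort$subjects$group)), c(108, 88))
  expect_true(all(is.finite(cohort$thickness)) && all(cohort$thickness > 0))
  expect_true(all(cohort$subjects$sex %in% c(0, 1)))
  expect_true(all(cohort$subjects$age >= 18 & cohort$subjects$age <= 50))
})

test_that("identical spec and seed reproduce the cohort exactly", {
  spec <- cohort_spec(n_per_group = c(case = 15, control = 12),
                      atlas = tiny_atlas(10), seed = 99)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$thickness, b$thickness)
  expect_identical(a$subjects, b$subjects)
})

test_that("independent spec yields near-zero off-diagonal correlations", {
  cohort <- simulate_cohort(independent_spec(n_regions = 20,
                                             n = c(case = 500, control = 500),
                                             seed = 3), clinical = FALSE)
  for (g in levels(cohort$subjects$group)) {
    r <- cor(cohort$thickness[cohort$subjects$group == g, ])
    off <- r[upper.tri(r)]
    expect_lt(max(abs(off)), 4.5 / sqrt(500))
    expect_lt(abs(mean(off)), 0.01)
  }
})

test_that("within-module correlation converges to its target", {
  # Fisher-z averaged within-module sample correlation across 20 seeds
  zs <- vapply(1:20, function(s) {
    spec <- cohort_spec(n_per_group = c(case = 500, control = 10),
                        atlas = tiny_atlas(20), n_modules = 4,
                        within_module_r = 0.6, between_module_r = 0,
                        planted_hubs = character(), thinning = 0,
                        age_slope = 0, sex_offset = 0, seed = 100 + s)
    cohort <- simulate_cohort(spec, clinical = FALSE)
    case <- cohort$subjects$group == "case"
    r <- cor(cohort$thickness[case, ])
    mods <- spec$module_assignment
    within <- outer(mods, mods, `==`) & upper.tri(r)
    mean(atanh(r[within]))
  }, 0)
  expect_gt(tanh(mean(zs)), 0.55)
  expect_lt(tanh(mean(zs)), 0.65)
})

test_that("realized means and SDs recover the spec at large n", {
  spec <- cohort_spec(n_per_group = c(case = 1000, control = 1000),
                      atlas = tiny_atlas(30), thinning = 0.09, seed = 21)
  cohort <- simulate_cohort(spec, clinical = FALSE)
  for (g in c("case", "control")) {
    idx <- cohort$subjects$group == g
    m <- colMeans(cohort$thickness[idx, ])
    tol <- 2 * spec$region_sds[g, ] / sqrt(sum(idx))
    # age/sex effects add variance around the target mean; allow their share
    tol <- tol + 0.01
    expect_gte(mean(abs(m - spec$region_means[g, ]) <= tol), 0.95)
  }
})

test_that("non-PSD block targets are repaired or rejected beyond tolerance", {
  # mildly indefinite: negative between-module correlation across 5 modules
  spec <- cohort_spec(n_per_group = c(case = 20, control = 20),
                      atlas = tiny_atlas(20), n_modules = 5,
                      within_module_r = 0.5, between_module_r = -0.2,
                      planted_hubs = character(), thinning = 0, seed = 1)
  cohort <- simulate_cohort(spec, clinical = FALSE)
  expect_true(attr(cohort, "psd_repaired"))
  # grossly indefinite: repair would distort the blocks too much
  bad <- cohort_spec(n_per_group = c(case = 20, control = 20),
                     atlas = tiny_atlas(20), n_modules = 5,
                     within_module_r = 0.5, between_module_r = -0.8,
                     planted_hubs = character(), thinning = 0, seed = 1)
  expect_error(simulate_cohort(bad, clinical = FALSE), "positive semi-definite")
})

test_that("binary clinical variables hit their prevalence and missingness", {
  cohort <- simulate_cohort(cohort_spec(seed = 5))
  s <- cohort$subjects
  case <- s$group == "case"
  pos <- sum(s$anti_dsDNA[case])
  # binomial around 0.685 * 108 = 73.98
  expect_true(abs(pos - 74) <= 3 * sqrt(108 * 0.685 * 0.315))
  expect_true(all(is.na(s$anti_dsDNA[!case])))
  expect_equal(sum(!is.na(s$acl[case])), 79)
  expect_equal(sum(!is.na(s$ctx_g[case])), 26)
})

test_that("a coupled clinical variable recovers its target correlation", {
  # Spearman rho across 20 seeds for a planted coupling of 0.5 at n = 1000
  rhos <- vapply(1:20, function(s) {
    spec <- cohort_spec(
      n_per_group = c(case = 1000, control = 10), atlas = tiny_atlas(10),
      within_module_r = 0, between_module_r = 0,
      planted_hubs = character(), thinning = 0,
      clinical = list(clinical_variable(
        "marker", "continuous", "lognormal", location = 1, scale = 0.5,
        coupling_region = "R001", coupling_rho = 0.5
      )),
      seed = 300 + s
    )
    cohort <- simulate_cohort(spec)
    case <- cohort$subjects$group == "case"
    spearman_corr(cohort$thickness[case, "R001"],
                  cohort$subjects$marker[case])$rho
  }, 0)
  expect_gt(mean(rhos), 0.4)
  expect_lt(mean(rhos), 0.6)
  # zero coupling leaves the correlation at noise level
  spec0 <- cohort_spec(
    n_per_group = c(case = 1000, control = 10), atlas = tiny_atlas(10),
    within_module_r = 0, between_module_r = 0, planted_hubs = character(),
    thinning = 0,
    clinical = list(clinical_variable("marker", "continuous", "lognormal",
                                      location = 1, scale = 0.5)),
    seed = 3
  )
  cohort0 <- simulate_cohort(spec0)
  case <- cohort0$subjects$group == "case"
  expect_lt(abs(spearman_corr(cohort0$thickness[case, "R001"],
                              cohort0$subjects$marker[case])$rho), 0.1)
})

test_that("planted modular covariance survives the downstream SCN stage", {
  for (s in 1:3) {
    spec <- cohort_spec(n_per_group = c(case = 300, control = 300),
                        atlas = tiny_atlas(24), n_modules = 4,
                        within_module_r = 0.5, between_module_r = 0.1,
                        planted_hubs = character(), thinning = 0,
                        seed = 400 + s)
    cohort <- simulate_cohort(spec, clinical = FALSE)
    nets <- build_networks(cohort, density_grid(0.38, 0.5, 0.01))
    mods <- spec$module_assignment
    within <- outer(mods, mods, `==`)
    for (nw in nets$networks) {
      M <- nw$M
      expect_gt(mean(M[within & upper.tri(M)]),
                mean(M[!within & upper.tri(M)]))
    }
  }
})
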