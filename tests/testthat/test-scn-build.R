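test_that("the default density grid has 13 drift-free points", {
  g <- density_grid()
  expect_length(g, 13)
  expect_equal(g[1], 0.38)
  expect_equal(g[13], 0.50)
  expect_true(all(abs(diff(g) - 0.01) < 1e-12))
  expect_error(density_grid(0, 0.5), "d_min")
})

test_that("residualization is exact OLS with orthogonal residuals", {
  set.seed(10)
  n <- 60
  age <- runif(n, 20, 50); sex <- rbinom(n, 1, 0.5)
  thick <- matrix(rnorm(n * 5, 2.5, 0.2), n, 5)
  res <- residualize(thick, data.frame(age = age, sex = sex))
  for (j in 1:5) {
    expect_lt(abs(cor(res[, j], age)), 1e-10)
    expect_lt(abs(cor(res[, j], sex)), 1e-10)
    expect_lt(abs(mean(res[, j])), 1e-12)
  }
  # thickness exactly linear in age leaves nothing
  lin <- outer(age, c(0.01, -0.02)) + 2.5
  expect_lt(max(abs(residualize(lin, data.frame(age = age)))), 1e-10)
  # zero-variance covariates are dropped -> centring only
  expect_message(
    cen <- residualize(thick, data.frame(const = rep(1, n))),
    "zero-variance"
  )
  expect_equal(cen, scale(thick, scale = FALSE), ignore_attr = TRUE)
  # collinear designs are rejected with the offending column named
  expect_error(
    residualize(thick, data.frame(age = age, age2 = 2 * age)),
    "age2"
  )
})

test_that("association matrices are symmetric, zero-diagonal and bounded", {
  set.seed(11)
  X <- matrix(rnorm(200), 20, 10)
  X[, 2] <- X[, 1]  # identical regions correlate at exactly 1
  colnames(X) <- sprintf("R%02d", 1:10)
  M <- association_matrix(X)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_equal(M[1, 2], 1)
  expect_true(all(abs(M) <= 1 + 1e-12))
  # subject order cannot matter
  expect_equal(association_matrix(X[sample(20), ]), M)
  X[, 3] <- 5
  expect_error(association_matrix(X), "R03")
})

test_that("density thresholding keeps exactly round(d * E_max) edges", {
  set.seed(12)
  p <- 148
  X <- matrix(rnorm(300 * p), 300, p)
  M <- association_matrix(X)
  A <- suppressWarnings(threshold_at_density(M, 0.38))
  expect_equal(sum(A) / 2, 4134)  # round(0.38 * 10878)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  # the complete graph necessarily admits non-positive associations
  expect_warning(A1 <- threshold_at_density(M, 1), "non-positive")
  expect_true(all(rowSums(A1) == p - 1))
})

test_that("thresholding is rank-invariant and ties break deterministically", {
  set.seed(13)
  X <- matrix(rnorm(50 * 12), 50, 12)
  M <- association_matrix(X)
  A <- threshold_at_density(M, 0.4)
  # any strictly increasing transform of the associations gives the same graph
  M2 <- tanh(3 * M); diag(M2) <- 0
  expect_equal(threshold_at_density(M2, 0.4), A, ignore_attr = TRUE)
  # exact ties at the cutoff resolve identically across calls
  Mt <- matrix(0.5, 6, 6); diag(Mt) <- 0
  Mt[1, 2] <- Mt[2, 1] <- 0.9
  expect_identical(threshold_at_density(Mt, 0.3),
                   threshold_at_density(Mt, 0.3))
})

test_that("edge sets are nested along the density grid", {
  cohort <- null_cohort(n_regions = 30, n_per_group = 25, seed = 14)
  nets <- suppressWarnings(build_networks(cohort))
  for (nw in nets$networks) {
    for (t in 2:length(nw$densities)) {
      prev <- nw$adjacency[[t - 1]]
      curr <- nw$adjacency[[t]]
      expect_true(all(curr[prev == 1] == 1))
      expect_equal(sum(curr) / 2, nw$edge_counts[t])
    }
  }
})

test_that("minimum connected density follows the documented edge-count rule", {
  # 4 nodes: the three strongest associations form a star around node 1,
  # so connectivity first occurs at 3 of 6 edges; on the 0.01 grid the
  # smallest density whose edge count reaches 3 is 0.42 (round(6 * 0.42) = 3)
  M <- matrix(0, 4, 4)
  M[1, 2] <- M[2, 1] <- 0.9
  M[1, 3] <- M[3, 1] <- 0.8
  M[1, 4] <- M[4, 1] <- 0.7
  M[2, 3] <- M[3, 2] <- 0.3
  M[2, 4] <- M[4, 2] <- 0.2
  M[3, 4] <- M[4, 3] <- 0.1
  res <- min_connected_density(M)
  expect_equal(res$overall, 0.42)
  k_grid <- vapply(density_grid(0.01, 1, 0.01),
                   function(d) sum(threshold_at_density(M, d)) / 2, 0)
  first <- density_grid(0.01, 1, 0.01)[which(k_grid >= 3)[1]]
  expect_equal(res$overall, first)

  # uniform positive 3-node matrix connects at the first density with 2 edges
  M3 <- matrix(0.5, 3, 3); diag(M3) <- 0
  expect_equal(min_connected_density(M3)$overall, 0.5)

  # two strong blocks with weak positive bridges: Dmin must exceed the
  # density spanned by within-block edges alone (6 of 15 pairs = 0.4)
  Mb <- matrix(0.1, 6, 6)
  Mb[1:3, 1:3] <- 0.9; Mb[4:6, 4:6] <- 0.9
  diag(Mb) <- 0
  expect_gt(min_connected_density(Mb)$overall, 0.4)
})

test_that("build_networks yields aligned per-group stacks and Dmin", {
  cohort <- simulate_cohort(cohort_spec(
    n_per_group = c(case = 40, control = 35), atlas = tiny_atlas(20),
    seed = 15
  ), clinical = FALSE)
  nets <- suppressWarnings(build_networks(cohort))
  expect_named(nets$networks, c("case", "control"))
  expect_length(nets$networks$case$adjacency, 13)
  expect_equal(rownames(nets$networks$case$M),
               rownames(nets$networks$control$M))
  expect_equal(nets$dmin, max(glance(nets)$dmin_case,
                              glance(nets)$dmin_control))
  # at grid densities >= Dmin every group graph is one component
  for (nw in nets$networks) {
    for (t in which(nw$densities >= nets$dmin)) {
      D <- oracle_distances(nw$adjacency[[t]])
      expect_true(all(is.finite(D)))
    }
  }
  # identical groups produce identical networks
  dup <- duplicated_group_cohort(n = 25, n_regions = 15)
  nd <- suppressWarnings(build_networks(dup))
  expect_equal(nd$networks$case$M, nd$networks$control$M)
  expect_identical(nd$networks$case$adjacency, nd$networks$control$adjacency)
})

test_that("planted modules are enriched among thresholded edges", {
  spec <- cohort_spec(n_per_group = c(case = 200, control = 200),
                      atlas = tiny_atlas(24), n_modules = 4,
                      within_module_r = 0.5, between_module_r = 0.1,
                      planted_hubs = character(), thinning = 0, seed = 16)
  cohort <- simulate_cohort(spec, clinical = FALSE)
  nets <- build_networks(cohort)
  mods <- spec$module_assignment
  within <- outer(mods, mods, `==`); diag(within) <- FALSE
  for (nw in nets$networks) {
    for (t in seq_along(nw$densities)) {
      A <- nw$adjacency[[t]]
      within_frac <- sum(A[within]) / sum(within)
      expect_gt(within_frac, nw$densities[t])
    }
  }
})
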