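test_that("simulate_bold is deterministic under a fixed seed", {
  design <- sim_design(grid_dim = c(4, 3, 2), n_timepoints = 40, seed = 7)
  a <- simulate_bold(design, "s1", seed = 123)
  b <- simulate_bold(design, "s1", seed = 123)
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(a$motion$params, b$motion$params)
  c_ <- simulate_bold(design, "s1", seed = 124)
  expect_false(identical(a$bold$data, c_$bold$data))
})

test_that("latent weights of zero give uncorrelated voxels and PAS ~ 0", {
  design <- sim_design(grid_dim = c(4, 2, 2), n_timepoints = 1500,
                       alpha_pair = 0, beta_hemi = 0, sigma_noise = 1, seed = 3)
  sim <- simulate_bold(design, "s1", seed = 11)
  res <- compute_pas(sim$bold, design$labeling, 0.2)
  expect_lt(max(abs(res$pas)), 0.05)
  C <- cor(sim$bold$data)
  expect_lt(max(abs(C[upper.tri(C)])), 0.15)
})

test_that("empirical correlations approach the closed-form latent values", {
  # alpha^2 = 0.5, beta^2 = 0.25, sigma^2 = 0.25 -> r_pair 0.5, r_intra 0.25
  design <- sim_design(grid_dim = c(6, 3, 2), n_timepoints = 2000, seed = 5)
  sim <- simulate_bold(design, "s1", seed = 21)
  lab <- design$labeling
  C <- cor(sim$bold$data)
  V <- n_voxels(design$mask)
  pair_r <- mapply(function(v, m) C[v, m],
                   seq_len(V)[!is.na(lab$mirror_index)],
                   lab$mirror_index[!is.na(lab$mirror_index)])
  same <- outer(lab$side, lab$side, `==`) & upper.tri(C)
  cross_nonpair <- outer(lab$side, lab$side, `!=`) & upper.tri(C)
  mirror_mat <- matrix(FALSE, V, V)
  ok <- which(!is.na(lab$mirror_index))
  mirror_mat[cbind(ok, lab$mirror_index[ok])] <- TRUE
  cross_nonpair <- cross_nonpair & !mirror_mat & !t(mirror_mat)

  expect_equal(mean(pair_r), 0.5, tolerance = 0.05)
  expect_equal(mean(C[same]), 0.25, tolerance = 0.05)
  expect_lt(abs(mean(C[cross_nonpair])), 0.05)
})

test_that("injected regional effects move PAS in the requested direction", {
  region <- list(voxels = 1:6, group = "GI_MDD", delta_pas_target = 0.6)
  design <- sim_design(grid_dim = c(6, 3, 2), n_timepoints = 1200,
                       region = region, seed = 9)
  gi <- simulate_bold(design, "s1", group = "GI_MDD", seed = 31)
  hc <- simulate_bold(design, "s2", group = "HC", seed = 31)
  lab <- design$labeling
  pas_gi <- compute_pas(gi$bold, lab, 0.2)
  pas_hc <- compute_pas(hc$bold, lab, 0.2)
  in_region <- pas_gi$voxel %in% region$voxels
  shift <- mean(pas_gi$pas[in_region]) - mean(pas_hc$pas[in_region])
  expect_gt(shift, 0.1)

  down <- list(voxels = 1:6, group = "GI_MDD", delta_pas_target = -0.6)
  design_d <- sim_design(grid_dim = c(6, 3, 2), n_timepoints = 1200,
                         region = down, seed = 9)
  gi_d <- simulate_bold(design_d, "s1", group = "GI_MDD", seed = 31)
  pas_gi_d <- compute_pas(gi_d$bold, lab, 0.2)
  shift_d <- mean(pas_gi_d$pas[in_region]) - mean(pas_hc$pas[in_region])
  expect_lt(shift_d, -0.1)

  expect_error(sim_design(grid_dim = c(4, 2, 2),
                          region = list(voxels = 1:100, group = "GI_MDD",
                                        delta_pas_target = 0.4)),
               "too small")
})

test_that("the simulated cohort matches the stated group structure", {
  design <- sim_design(grid_dim = c(4, 2, 2), n_timepoints = 20, seed = 2)
  cohort <- simulate_cohort(design, bold = FALSE)
  tab <- cohort$table
  expect_identical(nrow(tab), 80L)
  expect_equal(unname(table(tab$group)[c("GI_MDD", "NGI_MDD", "HC")]),
               c(35L, 17L, 28L), ignore_attr = TRUE)
  expect_s3_class(tab, "subject_table")
  expect_true(all(tab$gi_item[tab$group == "GI_MDD"] >= 1))
  expect_true(all(tab$gi_item[tab$group != "GI_MDD"] == 0))
  expect_true(all(is.na(tab$illness_duration[tab$group == "HC"])))
  expect_true(all(tab$hrsd17_total >= 0))
})

test_that("clinical generator reproduces its group models at large n", {
  design <- sim_design(grid_dim = c(4, 2, 2), n_gi = 4000, n_ngi = 2000,
                       n_hc = 2000, seed = 4)
  tab <- simulate_subject_table(design, effect_scale = rep(1, 8000))
  gi <- tab[tab$group == "GI_MDD", ]
  # hrsd17: normal(22.69, 3.41) effectively untruncated at this mean
  expect_equal(mean(gi$hrsd17_total), 22.69, tolerance = 0.15)
  expect_equal(sd(gi$hrsd17_total), 3.41, tolerance = 0.15)
  hc <- tab[tab$group == "HC", ]
  expect_equal(mean(hc$age), 30.14, tolerance = 0.4)
})

test_that("motion traces respect the exclusion rule as configured", {
  design <- sim_design(grid_dim = c(4, 2, 2), n_timepoints = 60, seed = 6)
  ok <- simulate_bold(design, "s1", seed = 41)
  expect_false(exclude_subject_by_motion(ok$motion))
  bad <- simulate_bold(design, "s2", seed = 41, force_motion_fail = TRUE)
  expect_true(exclude_subject_by_motion(bad$motion))
  expect_identical(ncol(ok$confounds), 26L)   # Friston-24 + CSF + WM
})

test_that("simulate_pas_stack injects group effects where asked", {
  region <- list(voxels = 5:10, group = "GI_MDD", delta = 0.4)
  sim <- simulate_pas_stack(c(GI_MDD = 20, NGI_MDD = 15), n_voxels = 40,
                            region = region, seed = 8)
  expect_identical(dim(sim$stack), c(35L, 40L))
  expect_identical(nrow(sim$table), 35L)
  gi_rows <- sim$table$group == "GI_MDD"
  gap <- colMeans(sim$stack[gi_rows, ]) - colMeans(sim$stack[!gi_rows, ])
  expect_gt(min(gap[5:10]), 0.2)
  expect_lt(max(abs(gap[-(5:10)])), 0.25)
  # same seed reproduces the stack
  sim2 <- simulate_pas_stack(c(GI_MDD = 20, NGI_MDD = 15), n_voxels = 40,
                             region = region, seed = 8)
  expect_identical(sim$stack, sim2$stack)
})
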