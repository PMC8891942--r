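test_that("hemisphere labeling splits by world x and excludes the midline", {
  # even grid centered at x = 0: equal halves, nothing excluded
  mask <- make_mask(c(6, 4, 4))
  lab <- label_hemispheres(mask)
  expect_equal(sum(lab$side == "LEFT"), sum(lab$side == "RIGHT"))
  expect_equal(sum(lab$side == "EXCLUDED"), 0L)

  # odd grid: the x = 0 column is excluded
  mask3 <- make_mask(c(3, 3, 3))
  lab3 <- label_hemispheres(mask3)
  x <- voxel_world_coords(mask3)[, 1]
  expect_true(all(lab3$side[x == 0] == "EXCLUDED"))
  expect_equal(sum(lab3$side == "EXCLUDED"), 9L)
  expect_true(all(is.na(lab3$mirror_index[lab3$side == "EXCLUDED"])))

  # mirror relation is an involution on its domain
  for (lb in list(lab, lab3)) {
    def <- which(!is.na(lb$mirror_index))
    expect_identical(lb$mirror_index[lb$mirror_index[def]], def)
    expect_true(all(lb$side[def] != lb$side[lb$mirror_index[def]]))
  }

  # single-hemisphere mask is an error
  arr <- array(FALSE, c(6, 4, 4))
  arr[1:2, , ] <- TRUE
  aff <- mask$affine
  expect_error(label_hemispheres(brain_mask(arr, aff)), "hemisphere has zero voxels")
})

test_that("blocked compute_pas matches the naive oracle across instance types", {
  mask <- make_mask(c(6, 4, 3))
  lab <- label_hemispheres(mask)
  for (rep_i in 1:12) {
    set.seed(100 + rep_i)
    Y <- matrix(rnorm(25 * n_voxels(mask)), 25, n_voxels(mask))
    if (rep_i %% 3 == 0) Y[, c(2, 9)] <- 7            # zero-variance voxels
    if (rep_i %% 4 == 0) Y[, 12] <- Y[, 30]           # duplicated series
    bold <- bold_dataset("s", Y, mask, 2)
    thr <- c(0, 0.2, 0.95)[1 + rep_i %% 3]
    fast <- compute_pas(bold, lab, thr, block_size = 7L)
    slow <- pas_oracle(bold, lab, thr)
    expect_pas_equal(fast, slow)
  }
})

test_that("an exact mirrored hemisphere yields PAS identically zero", {
  mask <- make_mask(c(6, 1, 1))
  lab <- label_hemispheres(mask)
  set.seed(42)
  left <- matrix(rnorm(30 * 3), 30, 3)
  Y <- matrix(0, 30, 6)
  left_idx <- which(lab$side == "LEFT")
  for (v in left_idx) Y[, v] <- left[, match(v, left_idx)]
  for (v in left_idx) Y[, lab$mirror_index[v]] <- Y[, v]   # exact copy
  bold <- bold_dataset("s", Y, mask, 2)
  res <- compute_pas(bold, lab, 0.2)
  expect_equal(res$pas, rep(0, 6))
  expect_pas_equal(res, pas_oracle(bold, lab, 0.2))
})

test_that("independent white noise gives near-zero PAS at threshold 0.2", {
  mask <- make_mask(c(4, 2, 2))
  lab <- label_hemispheres(mask)
  set.seed(9)
  bold <- bold_dataset("s", matrix(rnorm(4000 * 16), 4000, 16), mask, 2)
  res <- compute_pas(bold, lab, 0.2)
  # at T = 4000 no null correlation approaches 0.2
  expect_equal(res$n_inter_used + res$n_intra_used, rep(0L, 16))
  expect_equal(res$pas, rep(0, 16))
})

test_that("a constructed instance reproduces atanh(0.5) - atanh(0.9)", {
  # 2 voxels per hemisphere, 10 frames; basis columns are mean-zero and
  # orthonormal so designed inner products are exact correlations
  mask <- make_mask(c(4, 1, 1))
  lab <- label_hemispheres(mask)
  Q <- orthonormal_basis(10, 4, seed = 13)
  left_idx <- which(lab$side == "LEFT")
  right_idx <- which(lab$side == "RIGHT")
  Y <- matrix(0, 10, 4)
  Y[, left_idx[1]] <- Q[, 1]                                   # v
  Y[, left_idx[2]] <- 0.9 * Q[, 1] + sqrt(1 - 0.81) * Q[, 2]   # intra r = 0.9
  Y[, right_idx[1]] <- 0.5 * Q[, 1] + sqrt(1 - 0.25) * Q[, 3]  # inter r = 0.5
  Y[, right_idx[2]] <- Q[, 4]                                  # uncorrelated
  bold <- bold_dataset("s", Y, mask, 2)
  res <- compute_pas(bold, lab, 0.2)
  v <- match(left_idx[1], res$voxel)
  expect_equal(res$fc_inter[v], atanh(0.5), tolerance = 1e-10)
  expect_equal(res$fc_intra[v], atanh(0.9), tolerance = 1e-10)
  expect_equal(res$pas[v], atanh(0.5) - atanh(0.9), tolerance = 1e-10)
  expect_equal(res$pas[v], -0.9229, tolerance = 1e-4)
  expect_identical(res$n_inter_used[v], 1L)
  expect_identical(res$n_intra_used[v], 1L)
})

test_that("PAS is invariant to left/right relabeling and positive scaling,
           and survivor counts are monotone in the threshold", {
  mask <- make_mask(c(6, 3, 3))
  lab <- label_hemispheres(mask)
  set.seed(21)
  Y <- matrix(rnorm(40 * n_voxels(mask)), 40, n_voxels(mask)) +
    0.5 * rnorm(40)                                  # shared signal -> survivors
  bold <- bold_dataset("s", Y, mask, 2)
  base <- compute_pas(bold, lab, 0.2)

  # swap LEFT and RIGHT labels: each voxel keeps its own inter/intra split
  lab_swapped <- lab
  lab_swapped$side <- factor(
    c(LEFT = "RIGHT", RIGHT = "LEFT", EXCLUDED = "EXCLUDED")[as.character(lab$side)],
    levels = levels(lab$side))
  swapped <- compute_pas(bold, lab_swapped, 0.2)
  expect_equal(swapped$pas, base$pas)
  expect_equal(swapped$fc_inter, base$fc_inter)

  # positive rescaling of the whole series changes nothing
  bold_scaled <- bold_dataset("s", 3.7 * Y, mask, 2)
  expect_pas_equal(compute_pas(bold_scaled, lab, 0.2), base)

  # raising the threshold never adds survivors
  prev <- compute_pas(bold, lab, 0)
  for (thr in c(0.1, 0.2, 0.4, 0.7)) {
    cur <- compute_pas(bold, lab, thr)
    expect_true(all(cur$n_inter_used <= prev$n_inter_used))
    expect_true(all(cur$n_intra_used <= prev$n_intra_used))
    prev <- cur
  }
})

test_that("group_pas_stack stacks per-subject maps in order", {
  mask <- make_mask(c(4, 2, 2))
  lab <- label_hemispheres(mask)
  subs <- lapply(1:3, function(i) {
    set.seed(i)
    bold_dataset(paste0("s", i), matrix(rnorm(30 * 16), 30, 16), mask, 2)
  })
  stack <- group_pas_stack(subs, lab, 0.2)
  expect_identical(dim(stack), c(3L, 16L))
  expect_identical(rownames(stack), c("s1", "s2", "s3"))
  expect_equal(stack[2, ], compute_pas(subs[[2]], lab, 0.2)$pas)

  perm <- group_pas_stack(subs[c(3, 1, 2)], lab, 0.2)
  expect_equal(perm, stack[c(3, 1, 2), ])

  subs[[2]]$data[, ] <- 1   # all zero variance
  expect_error(group_pas_stack(subs, lab, 0.2), "subject 's2'")
})

test_that("degenerate inputs are rejected with clear errors", {
  mask <- make_mask(c(4, 2, 2))
  lab <- label_hemispheres(mask)
  bold <- make_bold(mask, 20)
  expect_error(compute_pas(bold, lab, -0.1), "fc_threshold")
  expect_error(compute_pas(bold, lab, 1), "fc_threshold")
  allflat <- bold_dataset("s", matrix(5, 20, 16), mask, 2)
  expect_error(compute_pas(allflat, lab, 0.2), "zero variance")
})
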