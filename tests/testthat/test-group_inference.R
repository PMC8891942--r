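make_table <- function(n_per_group = c(GI_MDD = 14, NGI_MDD = 10, HC = 12), seed = 1) {
  set.seed(seed)
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  validate_subject_table(data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = groups,
    age = round(rnorm(n, 30, 6), 1),
    gender = sample(c("male", "female"), n, replace = TRUE),
    education = round(rnorm(n, 14, 3), 1),
    mean_fd = round(runif(n, 0.02, 0.15), 4),
    stringsAsFactors = FALSE
  ))
}

test_that("build_design produces the documented structure", {
  tab <- make_table(c(GI_MDD = 30, NGI_MDD = 22, HC = 28))
  d <- build_design(tab)
  expect_identical(dim(d$X_full), c(80L, 7L))      # intercept + 2 group + 4 cov
  expect_identical(dim(d$X_reduced), c(80L, 5L))
  expect_identical(d$reference, "HC")
  expect_lt(max(abs(colSums(d$X_full[, 4:7]))), 1e-9)   # centered covariates

  # no group factor: full design equals the reduced design
  d1 <- build_design(tab, groups = "HC",
                     covariates = c("age", "education"))
  expect_identical(d1$X_full, d1$X_reduced)

  # collinear covariates are named in the error
  tab$age2 <- tab$age
  expect_error(build_design(tab, covariates = c("age", "age2")), "collinear")
})

test_that("ancova_f_map equals R's anova() partial F voxel by voxel", {
  tab <- make_table(seed = 2)
  d <- build_design(tab)
  set.seed(3)
  Y <- matrix(rnorm(36 * 8), 36, 8)
  res <- ancova_f_map(Y, d)
  for (v in c(1, 4, 8)) {
    df <- data.frame(y = Y[, v], g = factor(tab$group, levels = c("HC", "GI_MDD", "NGI_MDD")),
                     age = tab$age, gender = tab$gender,
                     education = tab$education, mean_fd = tab$mean_fd)
    full <- stats::lm(y ~ g + age + gender + education + mean_fd, df)
    red <- stats::lm(y ~ age + gender + education + mean_fd, df)
    an <- stats::anova(red, full)
    expect_equal(res$statistic[v], an$F[2], tolerance = 1e-10)
    expect_equal(res$p[v], an$`Pr(>F)`[2], tolerance = 1e-10)
  }

  # constant voxel across subjects: F = 0, p = 1
  Y[, 2] <- 0.7
  res2 <- ancova_f_map(Y, d)
  expect_equal(res2$statistic[2], 0)
  expect_equal(res2$p[2], 1)
})

test_that("ancova with no covariates reduces to classical one-way ANOVA", {
  tab <- make_table(seed = 4)
  d <- build_design(tab, covariates = character(0))
  set.seed(5)
  Y <- matrix(rnorm(36 * 6), 36, 6)
  res <- ancova_f_map(Y, d)
  for (v in seq_len(6)) {
    gs <- lapply(split(Y[, v], tab$group), function(x)
      list(n = length(x), mean = mean(x), sd = sd(x)))
    ref <- anova_from_summary(gs)
    expect_equal(res$statistic[v], ref$F, tolerance = 1e-8)
  }
})

test_that("posthoc t maps match lm, square to the partial F, and carry the sign", {
  tab <- make_table(seed = 6)
  d2 <- build_design(tab, groups = c("GI_MDD", "NGI_MDD"))
  set.seed(7)
  Y <- matrix(rnorm(24 * 10), 24, 10)
  Y[tab$group[d2$rows] == "GI_MDD", 4] <- Y[tab$group[d2$rows] == "GI_MDD", 4] + 2
  tm <- posthoc_t_map(Y, d2)
  fm <- ancova_f_map(Y, d2)
  expect_equal(tm$statistic^2, fm$statistic, tolerance = 1e-8)
  expect_equal(tm$p, fm$p, tolerance = 1e-8)
  expect_gt(tm$statistic[4], 0)          # first-listed group is higher

  sub <- tab[d2$rows, ]
  df <- data.frame(y = Y[, 4], g = factor(sub$group, levels = c("NGI_MDD", "GI_MDD")),
                   age = sub$age, gender = sub$gender,
                   education = sub$education, mean_fd = sub$mean_fd)
  fit <- summary(stats::lm(y ~ g + age + gender + education + mean_fd, df))
  expect_equal(tm$statistic[4], fit$coefficients["gGI_MDD", "t value"],
               tolerance = 1e-10)

  # reversing the listed order flips the sign
  d2r <- build_design(tab, groups = c("NGI_MDD", "GI_MDD"))
  tmr <- posthoc_t_map(Y, d2r)
  expect_equal(tmr$statistic, -tm$statistic, tolerance = 1e-10)

  # two groups with identical values and no covariates: t = 0 exactly
  tab_eq <- make_table(c(GI_MDD = 10, NGI_MDD = 10), seed = 12)
  d_eq <- build_design(tab_eq, groups = c("GI_MDD", "NGI_MDD"),
                       covariates = character(0))
  y_eq <- rnorm(10)
  t_eq <- posthoc_t_map(matrix(c(y_eq, y_eq), 20, 1), d_eq)
  expect_equal(t_eq$statistic[1], 0, tolerance = 1e-12)
  expect_error(posthoc_t_map(Y, build_design(tab)), "exactly two groups")
})

test_that("fdr_bh implements the step-up rule", {
  r <- fdr_bh(c(0.01, 0.02, 0.03), 0.05)
  expect_equal(r$q, c(0.03, 0.03, 0.03))
  expect_true(all(r$reject))

  expect_false(any(fdr_bh(rep(1, 10), 0.05)$reject))
  r1 <- fdr_bh(0.04, 0.05)
  expect_equal(r1$q, 0.04)
  expect_true(r1$reject)
  expect_identical(fdr_bh(numeric(0))$q, numeric(0))

  # brute-force agreement on random vectors (full sweep in acceptance)
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(fdr_bh(p, 0.05), bh_brute(p, 0.05), tolerance = 1e-12)
  }
})

test_that("cluster extraction matches brute-force flood fill", {
  mask <- make_mask(c(7, 6, 5))
  lab <- label_hemispheres(mask)
  keep_lin <- mask$indices[lab$keep]
  set.seed(9)
  for (rep_i in 1:6) {
    stat <- rnorm(sum(lab$keep))
    sig <- runif(sum(lab$keep)) < 0.25
    sm <- data.frame(statistic = stat, p = 0.5, flagged = FALSE)
    class(sm) <- c("stat_map", "data.frame")
    flags <- array(FALSE, mask$dim); flags[keep_lin] <- sig
    signs <- array(0, mask$dim); signs[keep_lin] <- sign(stat)
    for (conn in c(6, 18, 26)) {
      cl <- extract_clusters(sm, sig, lab, mask, connectivity = conn)
      ref <- flood_fill_brute(flags, signs, conn)
      got <- lapply(cl, function(r) sort(keep_lin[r$voxels]))
      expect_identical(length(got), length(ref))
      expect_setequal(lapply(got, paste, collapse = ","),
                      lapply(ref, paste, collapse = ","))
    }
  }
})

test_that("cluster records report sizes, peaks and subject means correctly", {
  mask <- make_mask(c(6, 4, 3))
  lab <- label_hemispheres(mask)
  V <- sum(lab$keep)
  stat <- rep(0, V); sig <- rep(FALSE, V)

  # no significant voxels -> empty list
  sm <- data.frame(statistic = stat, p = 1, flagged = FALSE)
  class(sm) <- c("stat_map", "data.frame")
  expect_length(extract_clusters(sm, sig, lab, mask), 0)

  # two blobs of sizes 5 and 3 in disjoint grid regions
  blob1 <- c(1, 2, 7, 8, 13)       # grid-linear indices, x-y plane z = 1
  blob2 <- c(70, 71, 69)
  cols1 <- match(blob1, mask$indices)
  cols2 <- match(blob2, mask$indices)
  stat[c(cols1, cols2)] <- c(3, 4.5, 2, 2, 2, -3, -5, -2)
  sig[c(cols1, cols2)] <- TRUE
  sm <- data.frame(statistic = stat, p = 0.01, flagged = FALSE)
  class(sm) <- c("stat_map", "data.frame")
  set.seed(10)
  stack <- matrix(rnorm(4 * V), 4, V)
  cl <- extract_clusters(sm, sig, lab, mask, connectivity = 26, pas_stack = stack)
  expect_length(cl, 2)
  sizes <- sort(vapply(cl, function(r) r$n_voxels, 0L))
  expect_identical(sizes, c(3L, 5L))
  pos <- cl[[which(vapply(cl, function(r) r$sign, 0L) == 1)]]
  expect_equal(pos$peak_stat, 4.5)
  expect_equal(pos$subject_means, rowMeans(stack[, cols1]))
  # min extent filters the small blob
  cl2 <- extract_clusters(sm, sig, lab, mask, connectivity = 26, min_extent = 4)
  expect_length(cl2, 1)

  # corner-touching voxels: one cluster at 26-connectivity, two at 6
  stat2 <- rep(1, V); sig2 <- rep(FALSE, V)
  corner <- c(match(1, mask$indices), match(1 + 1 + 6 + 24, mask$indices))
  sig2[corner] <- TRUE
  sm2 <- data.frame(statistic = stat2, p = 0.01, flagged = FALSE)
  class(sm2) <- c("stat_map", "data.frame")
  expect_length(extract_clusters(sm2, sig2, lab, mask, connectivity = 26), 1)
  expect_length(extract_clusters(sm2, sig2, lab, mask, connectivity = 6), 2)
})

test_that("summary-statistic tests are exact against raw data", {
  set.seed(11)
  raw <- list(rnorm(14, 10, 2), rnorm(9, 12, 3), rnorm(11, 9, 1.5))
  gs <- lapply(raw, function(x) list(n = length(x), mean = mean(x), sd = sd(x)))
  g_fac <- factor(rep(1:3, lengths(raw)))
  ref <- stats::oneway.test(c(raw[[1]], raw[[2]], raw[[3]]) ~ g_fac,
                            var.equal = TRUE)
  got <- anova_from_summary(gs)
  expect_equal(got$F, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)

  tt <- stats::t.test(raw[[1]], raw[[2]], var.equal = TRUE)
  got_t <- ttest_from_summary(gs[[1]], gs[[2]])
  expect_equal(got_t$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(got_t$p, tt$p.value, tolerance = 1e-10)

  expect_equal(anova_from_summary(list(list(n = 5, mean = 3, sd = 1),
                                       list(n = 7, mean = 3, sd = 2)))$F, 0)
  expect_equal(ttest_from_summary(list(n = 5, mean = 3, sd = 1),
                                  list(n = 7, mean = 3, sd = 2))$t, 0)
  expect_error(anova_from_summary(list(list(n = 5, mean = 3, sd = -1),
                                       list(n = 7, mean = 3, sd = 2))), "SD")
})

test_that("chi-square matches the hand expansion and chisq.test", {
  got <- chi_square_independence(rbind(c(10, 20), c(20, 10)))
  expect_equal(got$chi2, 20 / 3, tolerance = 1e-12)   # 6.667 by hand
  expect_equal(got$df, 1)
  ref <- stats::chisq.test(rbind(c(13, 6, 14), c(22, 11, 14)), correct = FALSE)
  got2 <- chi_square_independence(rbind(c(13, 6, 14), c(22, 11, 14)))
  expect_equal(got2$chi2, unname(ref$statistic), tolerance = 1e-12)

  same <- rbind(c(10, 20), c(5, 10))
  expect_equal(chi_square_independence(same)$chi2, 0, tolerance = 1e-12)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "marginal")
})
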