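#' Simulation design for synthetic two-hemisphere BOLD cohorts
#'
#' The generator is a latent-factor model: each voxel's series is
#' \deqn{x_v(t) = \alpha\, s_{pair(v)}(t) + \beta\, s_{side(v)}(t) + \sigma\, e_v(t)}
#' with `s_pair` shared exactly by a homotopic pair, `s_hemi` shared by all
#' voxels on one side, and all latents independent unit-variance Gaussian
#' noise. Expected correlations are closed form:
#' r_pair = alpha^2 / (alpha^2 + beta^2 + sigma^2) for homotopic pairs,
#' r_intra = beta^2 / (alpha^2 + beta^2 + sigma^2) for same-side pairs, and
#' ~0 for non-homotopic cross-side pairs. Regional group effects are
#' injected by raising `alpha` (more inter-hemispheric coupling, PAS up) or
#' `beta` (more intra-hemispheric coupling, PAS down) inside a voxel region
#' for one group.
#'
#' Defaults mirror the cohort this package emulates: 35 / 17 / 28 subjects
#' (GI-MDD / nGI-MDD / HC), 240 retained frames at TR 2 s, and clinical
#' scores drawn from the published per-group summary statistics.
#'
#' @param grid_dim 3D grid (even first dimension keeps the midline empty).
#' @param voxel_size_mm isotropic voxel size.
#' @param n_timepoints frames per subject.
#' @param tr_seconds sampling interval.
#' @param alpha_pair,beta_hemi,sigma_noise latent weights (variances
#'   alpha^2 / beta^2 / sigma^2).
#' @param n_gi,n_ngi,n_hc group sizes.
#' @param region optional list `voxels` (in-mask voxel indices), `group`,
#'   `delta_pas_target` (sign sets direction, magnitude the intended PAS
#'   shift) describing an injected regional effect.
#' @param motion_scale_mm typical random-walk translation amplitude;
#'   rotations scale as `motion_scale_mm / 50`.
#' @param seed base seed for the hierarchical random streams.
#' @return a list of class `sim_design`.
#' @export
sim_design <- function(grid_dim = c(8, 6, 5),
                       voxel_size_mm = 3,
                       n_timepoints = 240,
                       tr_seconds = 2,
                       alpha_pair = sqrt(0.5),
                       beta_hemi = sqrt(0.25),
                       sigma_noise = sqrt(0.25),
                       n_gi = 35, n_ngi = 17, n_hc = 28,
                       region = NULL,
                       motion_scale_mm = 0.1,
                       seed = 1L) {
  if (alpha_pair^2 + beta_hemi^2 + sigma_noise^2 <= 0) {
    stop("alpha_pair^2 + beta_hemi^2 + sigma_noise^2 must be positive")
  }
  if (min(n_gi, n_ngi, n_hc) < 2) stop("group sizes must be >= 2")
  if (n_timepoints < 3) stop("need at least 3 frames")
  mask <- .sim_mask(grid_dim, voxel_size_mm)
  labeling <- label_hemispheres(mask)
  if (!is.null(region)) {
    if (is.null(region$voxels) || is.null(region$group) || is.null(region$delta_pas_target)) {
      stop("region must have voxels, group and delta_pas_target")
    }
    if (max(region$voxels) > n_voxels(mask)) {
      stop("grid too small to host the region spec")
    }
  }
  structure(
    list(grid_dim = grid_dim, voxel_size_mm = voxel_size_mm,
         n_timepoints = n_timepoints, tr_seconds = tr_seconds,
         alpha_pair = alpha_pair, beta_hemi = beta_hemi,
         sigma_noise = sigma_noise,
         n_gi = n_gi, n_ngi = n_ngi, n_hc = n_hc,
         region = region, motion_scale_mm = motion_scale_mm,
         seed = as.integer(seed),
         mask = mask, labeling = labeling),
    class = "sim_design"
  )
}

# full-grid mask with the world origin at the grid center, so an even
# first dimension leaves no voxel centered on the midline
.sim_mask <- function(grid_dim, voxel_size_mm) {
  affine <- diag(4)
  affine[1, 1] <- affine[2, 2] <- affine[3, 3] <- voxel_size_mm
  affine[1:3, 4] <- -voxel_size_mm * (grid_dim - 1) / 2
  brain_mask(array(TRUE, dim = grid_dim), affine)
}

# one derived 31-bit stream per (seed, index) pair; keeps every subject
# reproducible in isolation
.sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483647)
}

#' Simulate one subject's BOLD run, motion trace and confounds
#'
#' @param design a `sim_design`.
#' @param subject_id character scalar.
#' @param group the subject's group (decides whether the regional effect
#'   applies).
#' @param seed stream seed; derived from the design seed by default.
#' @param effect_scale subject-level multiplier on the injected regional
#'   effect (used to link clinical scores to effect strength).
#' @param force_motion_fail if TRUE the random walk is scaled to violate
#'   the 2 mm exclusion rule (for testing the exclusion path).
#' @return list with `bold` (`bold_dataset`), `motion` (`motion_trace`)
#'   and `confounds` (Friston-24 + CSF/WM columns).
#' @export
simulate_bold <- function(design, subject_id, group = "HC", seed = NULL,
                          effect_scale = 1, force_motion_fail = FALSE) {
  stopifnot(inherits(design, "sim_design"))
  if (is.null(seed)) seed <- design$seed
  set.seed(seed)
  mask <- design$mask
  lab <- design$labeling
  V <- n_voxels(mask)
  Tn <- design$n_timepoints

  # pair identity: a voxel and its mirror share one latent; unpaired
  # voxels get a private one
  pair_id <- integer(V)
  nxt <- 0L
  for (v in seq_len(V)) {
    m <- lab$mirror_index[v]
    if (!is.na(m) && m < v && pair_id[m] > 0L) {
      pair_id[v] <- pair_id[m]
    } else {
      nxt <- nxt + 1L
      pair_id[v] <- nxt
    }
  }
  s_pair <- matrix(stats::rnorm(Tn * nxt), Tn, nxt)
  s_hemi <- matrix(stats::rnorm(Tn * 2), Tn, 2)
  noise <- matrix(stats::rnorm(Tn * V), Tn, V)

  alpha <- rep(design$alpha_pair, V)
  beta <- rep(design$beta_hemi, V)
  reg <- design$region
  if (!is.null(reg) && identical(group, reg$group)) {
    bump <- sqrt(abs(reg$delta_pas_target)) * effect_scale
    if (reg$delta_pas_target >= 0) {
      alpha[reg$voxels] <- alpha[reg$voxels] + bump
    } else {
      beta[reg$voxels] <- beta[reg$voxels] + bump
    }
  }
  hemi_col <- ifelse(lab$side == "LEFT", 1L, 2L)  # EXCLUDED rides with RIGHT
  X <- s_pair[, pair_id, drop = FALSE] * rep(alpha, each = Tn) +
    s_hemi[, hemi_col, drop = FALSE] * rep(beta, each = Tn) +
    design$sigma_noise * noise

  # bounded random walk motion; rescaled so the exclusion rule passes or
  # fails as requested
  walk <- apply(matrix(stats::rnorm(Tn * 6), Tn, 6), 2L, cumsum)
  walk <- sweep(walk, 2L, colMeans(walk))
  peak <- max(abs(walk[, 1:3]), 1e-9)
  target <- if (force_motion_fail) 2.5 else design$motion_scale_mm
  walk[, 1:3] <- walk[, 1:3] * target / peak
  peak_rot <- max(abs(walk[, 4:6]), 1e-9)
  walk[, 4:6] <- walk[, 4:6] * (target / 50) / peak_rot
  motion <- motion_trace(subject_id, walk)

  confounds <- confound_matrix(motion, csf = stats::rnorm(Tn), wm = stats::rnorm(Tn))
  list(bold = bold_dataset(subject_id, X, mask, design$tr_seconds),
       motion = motion, confounds = confounds)
}

# published per-group clinical summary parameters (mean, sd) used as the
# generator's defaults; zeros have sd 0
.clinical_model <- list(
  age = list(GI_MDD = c(30.86, 6.84), NGI_MDD = c(30.29, 8.05), HC = c(30.14, 5.00)),
  education = list(GI_MDD = c(14.51, 3.28), NGI_MDD = c(12.94, 3.46), HC = c(14.61, 2.69)),
  illness_duration = list(GI_MDD = c(6.23, 4.63), NGI_MDD = c(6.94, 3.98), HC = c(NA, NA)),
  hrsd17_total = list(GI_MDD = c(22.69, 3.41), NGI_MDD = c(20.18, 2.67), HC = c(0.89, 0.88)),
  anxiety_somatization = list(GI_MDD = c(7.31, 1.92), NGI_MDD = c(6.41, 1.66), HC = c(0.39, 0.57)),
  weight_loss = list(GI_MDD = c(0.80, 0.83), NGI_MDD = c(0.06, 0.24), HC = c(0, 0)),
  cognitive_disturbance = list(GI_MDD = c(3.71, 1.78), NGI_MDD = c(3.41, 1.50), HC = c(0, 0)),
  retardation = list(GI_MDD = c(6.40, 1.42), NGI_MDD = c(6.76, 1.56), HC = c(0.18, 0.39)),
  sleep_disturbance = list(GI_MDD = c(4.46, 1.42), NGI_MDD = c(3.53, 1.28), HC = c(0.32, 0.55))
)
.gender_p_female <- c(GI_MDD = 22 / 35, NGI_MDD = 11 / 17, HC = 14 / 28)

#' Simulate a group-structured subject table
#'
#' Covariates and clinical scores are drawn from per-group normal models
#' truncated at 0, parameterized by the published group summaries, so at
#' large n the generated table reproduces the summary-statistics tests it
#' feeds. For GI-MDD subjects the GI item (HRSD item 12, range 1-2 in
#' patients with symptoms) increases monotonically with `effect_scale`;
#' it is 0 elsewhere.
#'
#' @param design a `sim_design`.
#' @param effect_scale optional per-subject multipliers (length = total n)
#'   linking the injected regional effect to the GI item.
#' @param seed stream seed.
#' @return a `subject_table` (without `mean_fd`; that comes from QC).
#' @export
simulate_subject_table <- function(design, effect_scale = NULL, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (is.null(seed)) seed <- .sub_seed(design$seed, 0L)
  set.seed(seed)
  groups <- rep(c("GI_MDD", "NGI_MDD", "HC"), c(design$n_gi, design$n_ngi, design$n_hc))
  n <- length(groups)
  if (is.null(effect_scale)) effect_scale <- rep(1, n)
  stopifnot(length(effect_scale) == n)

  draw <- function(var) {
    vapply(groups, function(g) {
      ms <- .clinical_model[[var]][[g]]
      if (anyNA(ms)) return(NA_real_)
      if (ms[2] == 0) return(ms[1])
      max(0, stats::rnorm(1, ms[1], ms[2]))
    }, 0)
  }
  gi_item <- ifelse(
    groups == "GI_MDD",
    pmin(2, pmax(1, round(1 + 1.5 * (effect_scale - 0.5) + stats::rnorm(n, 0, 0.25)))),
    0
  )
  df <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = groups,
    age = round(draw("age"), 2),
    gender = ifelse(stats::runif(n) < .gender_p_female[groups], "female", "male"),
    education = round(draw("education"), 2),
    illness_duration = round(draw("illness_duration"), 2),
    hrsd17_total = round(draw("hrsd17_total"), 1),
    anxiety_somatization = round(draw("anxiety_somatization"), 1),
    weight_loss = round(draw("weight_loss"), 1),
    cognitive_disturbance = round(draw("cognitive_disturbance"), 1),
    retardation = round(draw("retardation"), 1),
    sleep_disturbance = round(draw("sleep_disturbance"), 1),
    gi_item = gi_item,
    stringsAsFactors = FALSE
  )
  validate_subject_table(df)
}

#' Simulate a full cohort (subject table plus per-subject BOLD runs)
#'
#' Every source of randomness descends from the design seed through one
#' hierarchical stream (cohort stream, then one stream per subject), so a
#' single subject can be regenerated in isolation. When `out_dir` is given
#' the cohort is written to disk (NIfTI per subject, motion/confound TSVs,
#' subject table, mask, manifest); otherwise everything stays in memory.
#'
#' @param design a `sim_design`.
#' @param out_dir optional output directory.
#' @param bold generate BOLD runs (set FALSE for a table-only cohort).
#' @return list with `table`, `mask`, `labeling`, `effect_scale` and,
#'   when `bold = TRUE`, `subjects` (list of [simulate_bold()] outputs).
#' @export
simulate_cohort <- function(design, out_dir = NULL, bold = TRUE) {
  stopifnot(inherits(design, "sim_design"))
  n <- design$n_gi + design$n_ngi + design$n_hc
  set.seed(.sub_seed(design$seed, 999999L))
  # subject-level effect strength; drives both the BOLD effect and gi_item
  effect_scale <- stats::runif(n, 0.5, 1.5)
  table <- simulate_subject_table(design, effect_scale = effect_scale)

  subjects <- NULL
  if (bold) {
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      subjects[[i]] <- simulate_bold(
        design, table$subject_id[i], group = table$group[i],
        seed = .sub_seed(design$seed, i), effect_scale = effect_scale[i]
      )
    }
    names(subjects) <- table$subject_id
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mask(design$mask, file.path(out_dir, "mask.nii.gz"))
    write_subject_table(table, file.path(out_dir, "subjects.tsv"))
    if (bold) {
      for (s in subjects) {
        sid <- s$bold$subject_id
        write_bold(s$bold, file.path(out_dir, paste0(sid, "_bold.nii.gz")))
        write_motion(s$motion, file.path(out_dir, paste0(sid, "_motion.tsv")))
        utils::write.table(as.data.frame(s$confounds),
                           file.path(out_dir, paste0(sid, "_confounds.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    manifest <- data.frame(subject_id = table$subject_id,
                           bold = paste0(table$subject_id, "_bold.nii.gz"),
                           motion = paste0(table$subject_id, "_motion.tsv"),
                           confounds = paste0(table$subject_id, "_confounds.tsv"))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = table, mask = design$mask, labeling = design$labeling,
       effect_scale = effect_scale, subjects = subjects)
}

#' Simulate a subject-by-voxel PAS stack directly
#'
#' Analytic shortcut for inference-level simulations (type-I error and
#' power studies): per-subject PAS values are drawn around a common
#' spatial baseline with independent Gaussian subject noise, skipping BOLD
#' generation entirely. A regional group effect adds `delta` to the listed
#' voxels for the target group, scaled per subject by `effect_scale`.
#'
#' @param n_per_group named integer vector, e.g.
#'   `c(GI_MDD = 35, NGI_MDD = 17, HC = 28)`.
#' @param n_voxels voxels in the map.
#' @param pas_sd per-subject PAS standard deviation (default 0.2, a
#'   realistic voxel-level spread for Fisher-z differences).
#' @param region optional list `voxels`, `group`, `delta`.
#' @param effect_scale optional per-subject multipliers for the region
#'   effect (defaults to 1).
#' @param table optional pre-built `subject_table` (rows must follow the
#'   group order of `n_per_group`); one is simulated when absent.
#' @param seed RNG seed.
#' @return list `stack` (subject-by-voxel matrix), `table`,
#'   `effect_scale`.
#' @export
simulate_pas_stack <- function(n_per_group = c(GI_MDD = 35, NGI_MDD = 17, HC = 28),
                               n_voxels = 200, pas_sd = 0.2,
                               region = NULL, effect_scale = NULL,
                               table = NULL, seed = 1L) {
  set.seed(seed)
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  if (is.null(effect_scale)) effect_scale <- rep(1, n)
  baseline <- stats::rnorm(n_voxels, 0, 0.05)   # stable spatial profile
  stack <- matrix(stats::rnorm(n * n_voxels, 0, pas_sd), n, n_voxels,
                  byrow = FALSE) + rep(baseline, each = n)
  if (!is.null(region)) {
    hit <- groups == region$group
    stack[hit, region$voxels] <- stack[hit, region$voxels] +
      region$delta * effect_scale[hit]
  }
  if (is.null(table)) {
    design <- sim_design(n_gi = max(2, sum(groups == "GI_MDD")),
                         n_ngi = max(2, sum(groups == "NGI_MDD")),
                         n_hc = max(2, sum(groups == "HC")),
                         seed = seed)
    n_sim <- design$n_gi + design$n_ngi + design$n_hc
    table <- simulate_subject_table(design, effect_scale = rep(1, n_sim),
                                    seed = .sub_seed(seed, 17L))
    table <- table[table$group %in% groups, , drop = FALSE]
    table <- table[order(match(table$group, names(n_per_group))), , drop = FALSE]
    table$mean_fd <- round(stats::runif(n, 0.03, 0.15), 4)
  }
  rownames(stack) <- table$subject_id
  list(stack = stack, table = table, effect_scale = effect_scale)
}
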