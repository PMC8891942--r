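#' Assign in-mask voxels to hemispheres
#'
#' Voxels are labeled by the sign of their world-space x coordinate under
#' the radiological-free convention negative x = left. A voxel whose center
#' lies within half a voxel width of the x = 0 plane is EXCLUDED: it joins
#' neither hemisphere and never appears in a partner set. Each voxel's
#' homotopic mirror (the in-mask voxel whose world coordinates are
#' (-x, y, z)) is recorded where one exists; the relation is an involution.
#'
#' @param mask a `brain_mask`.
#' @return a list of class `hemisphere_labeling`: `side` (factor LEFT /
#'   RIGHT / EXCLUDED per in-mask voxel), `mirror_index` (integer index of
#'   the homotopic partner in mask order, NA when absent), and `keep`
#'   (logical, TRUE for non-excluded voxels).
#' @export
label_hemispheres <- function(mask) {
  stopifnot(inherits(mask, "brain_mask"))
  xyz <- voxel_world_coords(mask)
  # voxel extent along world x: how far one step of any grid axis moves x
  vw <- max(abs(mask$affine[1, 1:3]))
  if (vw <= 0) stop("mask affine has no x extent")
  side <- ifelse(abs(xyz[, 1]) < vw / 2, "EXCLUDED",
                 ifelse(xyz[, 1] < 0, "LEFT", "RIGHT"))
  side <- factor(side, levels = c("LEFT", "RIGHT", "EXCLUDED"))
  if (!any(side == "LEFT") || !any(side == "RIGHT")) {
    stop("a hemisphere has zero voxels; asymmetry is undefined")
  }

  # match mirrored world coordinates by grid cell
  inv <- solve(mask$affine)
  mirrored <- cbind(-xyz[, 1], xyz[, 2], xyz[, 3], 1) %*% t(inv[1:3, , drop = FALSE])
  ijk <- round(mirrored)
  ok <- rowSums(abs(mirrored - ijk) > 1e-6) == 0 &
    ijk[, 1] >= 0 & ijk[, 1] < mask$dim[1] &
    ijk[, 2] >= 0 & ijk[, 2] < mask$dim[2] &
    ijk[, 3] >= 0 & ijk[, 3] < mask$dim[3]
  lin <- rep(NA_integer_, length(side))
  lin[ok] <- as.integer(ijk[ok, 1] + 1 + mask$dim[1] * (ijk[ok, 2] + mask$dim[2] * ijk[ok, 3]))
  pos <- match(lin, mask$indices)          # NA if mirror cell not in mask
  pos[side == "EXCLUDED"] <- NA_integer_
  pos[!is.na(pos) & side[pmax(pos, 1L)] == "EXCLUDED"] <- NA_integer_

  structure(
    list(side = side, mirror_index = pos, keep = side != "EXCLUDED"),
    class = "hemisphere_labeling"
  )
}

#' @export
print.hemisphere_labeling <- function(x, ...) {
  cat(sprintf("hemisphere_labeling: %d left, %d right, %d excluded\n",
              sum(x$side == "LEFT"), sum(x$side == "RIGHT"),
              sum(x$side == "EXCLUDED")))
  invisible(x)
}

# correlations above this are treated as degenerate duplicates of the
# target series and never survive, so no Fisher z can be infinite and a
# mirrored duplicate hemisphere yields PAS exactly 0
.r_clip <- 0.999999

#' Voxel-wise parameter of asymmetry
#'
#' For each non-excluded voxel v the Pearson correlation with every other
#' non-excluded voxel is computed over the retained frames; only r strictly
#' above `fc_threshold` survive (a positive threshold simultaneously drops
#' negative correlations), survivors are Fisher-z transformed
#' (z = atanh(r)), and
#' \deqn{PAS(v) = \bar z_{inter}(v) - \bar z_{intra}(v)}
#' where the two means run over contralateral and ipsilateral survivors
#' (the voxel itself never partners with itself). An empty survivor set
#' contributes 0 with a support count of 0, so PAS is defined everywhere.
#' Zero-variance voxel series have undefined correlations and never
#' survive, and correlations above 0.999999 are treated as degenerate
#' duplicates of the target series and excluded — so an exact mirrored
#' copy of a hemisphere gives PAS = 0 everywhere and no Fisher z can be
#' infinite.
#'
#' The correlation matrix is never materialized in full: partner
#' correlations are processed in blocks of `block_size` voxels, giving
#' results identical to the naive oracle at bounded memory.
#'
#' @param bold a `bold_dataset` (scrubbed frames are ignored).
#' @param labeling a `hemisphere_labeling` for the same mask.
#' @param fc_threshold strict lower bound on r, in `[0, 1)`.
#' @param block_size voxels per block.
#' @return a data frame of class `pas_map`, one row per non-excluded voxel
#'   (in mask order): `pas`, `fc_inter`, `fc_intra`, `n_inter_used`,
#'   `n_intra_used`, `side`, `voxel` (index into the mask's in-mask order).
#' @export
compute_pas <- function(bold, labeling, fc_threshold = 0.2, block_size = 256L) {
  stopifnot(inherits(bold, "bold_dataset"), inherits(labeling, "hemisphere_labeling"))
  if (length(labeling$side) != ncol(bold$data)) {
    stop("labeling covers a different voxel count than the BOLD data")
  }
  if (fc_threshold < 0 || fc_threshold >= 1) stop("fc_threshold must be in [0, 1)")
  keep_vox <- which(labeling$keep)
  Y <- bold$data[bold$frame_keep, keep_vox, drop = FALSE]
  n <- nrow(Y)
  if (n < 3L) stop(sprintf("only %d retained frame(s); need >= 3 for correlation", n))

  ctr <- sweep(Y, 2L, colMeans(Y))
  ss <- sqrt(colSums(ctr^2))
  zero_var <- ss <= 0 | !is.finite(ss)
  if (all(zero_var)) stop("all voxel series have zero variance")
  Xs <- sweep(ctr, 2L, ifelse(zero_var, 1, ss), `/`)
  Xs[, zero_var] <- 0

  V <- length(keep_vox)
  is_left <- labeling$side[keep_vox] == "LEFT"
  sum_left <- sum_right <- n_left <- n_right <- numeric(V)

  for (start in seq(1L, V, by = block_size)) {
    idx <- start:min(start + block_size - 1L, V)
    C <- crossprod(Xs, Xs[, idx, drop = FALSE])       # V x b correlations
    S <- C > fc_threshold & C <= .r_clip
    S[zero_var, ] <- FALSE
    S[, zero_var[idx]] <- FALSE
    S[cbind(idx, seq_along(idx))] <- FALSE            # self never a partner
    Z <- atanh(pmin(pmax(C, -.r_clip), .r_clip))
    W <- Z * S
    sum_left[idx]  <- colSums(W[is_left, , drop = FALSE])
    sum_right[idx] <- colSums(W[!is_left, , drop = FALSE])
    n_left[idx]    <- colSums(S[is_left, , drop = FALSE])
    n_right[idx]   <- colSums(S[!is_left, , drop = FALSE])
  }

  own_sum <- ifelse(is_left, sum_left, sum_right)
  own_n <- ifelse(is_left, n_left, n_right)
  other_sum <- ifelse(is_left, sum_right, sum_left)
  other_n <- ifelse(is_left, n_right, n_left)
  fc_intra <- ifelse(own_n > 0, own_sum / own_n, 0)
  fc_inter <- ifelse(other_n > 0, other_sum / other_n, 0)

  out <- data.frame(
    voxel = keep_vox,
    side = labeling$side[keep_vox],
    pas = fc_inter - fc_intra,
    fc_inter = fc_inter,
    fc_intra = fc_intra,
    n_inter_used = as.integer(other_n),
    n_intra_used = as.integer(own_n)
  )
  class(out) <- c("pas_map", "data.frame")
  out
}

#' Naive PAS reference implementation (test oracle)
#'
#' Identical contract to [compute_pas()], written as explicit loops over the
#' full pairwise correlation structure. Quadratic in voxels; intended for
#' instances of at most a few hundred voxels inside tests.
#'
#' @inheritParams compute_pas
#' @export
pas_oracle <- function(bold, labeling, fc_threshold = 0.2) {
  stopifnot(inherits(bold, "bold_dataset"), inherits(labeling, "hemisphere_labeling"))
  if (fc_threshold < 0 || fc_threshold >= 1) stop("fc_threshold must be in [0, 1)")
  keep_vox <- which(labeling$keep)
  if (length(keep_vox) > 500L) stop("pas_oracle is restricted to small instances")
  Y <- bold$data[bold$frame_keep, keep_vox, drop = FALSE]
  n <- nrow(Y)
  if (n < 3L) stop(sprintf("only %d retained frame(s); need >= 3 for correlation", n))
  V <- length(keep_vox)
  sds <- apply(Y, 2L, stats::sd)
  if (all(sds == 0)) stop("all voxel series have zero variance")
  side <- as.character(labeling$side[keep_vox])

  pas <- fc_inter <- fc_intra <- numeric(V)
  n_inter <- n_intra <- integer(V)
  for (v in seq_len(V)) {
    inter_z <- c(); intra_z <- c()
    if (sds[v] > 0) {
      for (w in seq_len(V)) {
        if (w == v || sds[w] == 0) next
        r <- stats::cor(Y[, v], Y[, w])
        if (!is.finite(r) || r <= fc_threshold || r > .r_clip) next
        z <- atanh(min(max(r, -.r_clip), .r_clip))
        if (side[w] == side[v]) intra_z <- c(intra_z, z) else inter_z <- c(inter_z, z)
      }
    }
    fc_inter[v] <- if (length(inter_z)) mean(inter_z) else 0
    fc_intra[v] <- if (length(intra_z)) mean(intra_z) else 0
    n_inter[v] <- length(inter_z)
    n_intra[v] <- length(intra_z)
    pas[v] <- fc_inter[v] - fc_intra[v]
  }
  out <- data.frame(voxel = keep_vox, side = factor(side, levels = levels(labeling$side)),
                    pas = pas, fc_inter = fc_inter, fc_intra = fc_intra,
                    n_inter_used = n_inter, n_intra_used = n_intra)
  class(out) <- c("pas_map", "data.frame")
  out
}

#' Stack per-subject PAS maps into a subject-by-voxel matrix
#'
#' @param datasets list of `bold_dataset`s sharing one mask and labeling,
#'   in subject-table order.
#' @param labeling shared `hemisphere_labeling`.
#' @param fc_threshold passed to [compute_pas()].
#' @return numeric matrix, one row per subject (named by `subject_id`), one
#'   column per non-excluded voxel.
#' @export
group_pas_stack <- function(datasets, labeling, fc_threshold = 0.2) {
  if (!length(datasets)) stop("no datasets supplied")
  rows <- lapply(datasets, function(b) {
    res <- tryCatch(compute_pas(b, labeling, fc_threshold),
                    error = function(e) {
                      stop(sprintf("compute_pas failed for subject '%s': %s",
                                   b$subject_id, conditionMessage(e)), call. = FALSE)
                    })
    res$pas
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(datasets, function(b) b$subject_id, "")
  out
}
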