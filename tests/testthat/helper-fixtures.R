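# shared fixture builders and independent brute-force oracles

# full-grid mask centered on x = 0; even nx leaves the midline empty
make_mask <- function(dims = c(6, 4, 3), voxel = 3) {
  aff <- diag(4)
  aff[1, 1] <- aff[2, 2] <- aff[3, 3] <- voxel
  aff[1:3, 4] <- -voxel * (dims - 1) / 2
  brain_mask(array(TRUE, dim = dims), aff)
}

make_bold <- function(mask, n_frames = 30, seed = 1, sd = 1) {
  set.seed(seed)
  bold_dataset("sub-test", matrix(rnorm(n_frames * n_voxels(mask), sd = sd),
                                  n_frames, n_voxels(mask)), mask, tr = 2)
}

make_motion <- function(n = 20, seed = 1, scale = 0.05) {
  set.seed(seed)
  motion_trace("sub-test", matrix(rnorm(n * 6, sd = scale), n, 6))
}

# brute-force BH step-up, straight from the definition
bh_brute <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (rank_i in seq_len(m)) {
    cand <- vapply(rank_i:m, function(j) m * p[o[j]] / j, 0)
    q[o[rank_i]] <- min(1, min(cand))
  }
  list(q = q, reject = q < alpha)
}

# brute-force recursive flood fill over a 3D logical array, splitting by
# the sign array; returns a list of sorted member-index vectors
flood_fill_brute <- function(flags, signs, connectivity) {
  dims <- dim(flags)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[rowSums(abs(offs)) <= c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)], ,
               drop = FALSE]
  seen <- array(FALSE, dims)
  comps <- list()
  for (start in which(flags)) {
    if (seen[start]) next
    sgn <- signs[start]
    comp <- integer(0)
    frontier <- start
    seen[start] <- TRUE
    while (length(frontier)) {
      cur <- frontier[1]; frontier <- frontier[-1]
      comp <- c(comp, cur)
      ijk <- arrayInd(cur, dims)
      for (r in seq_len(nrow(offs))) {
        nb <- ijk + offs[r, ]
        if (any(nb < 1) || any(nb > dims)) next
        q <- nb[1] + dims[1] * (nb[2] - 1 + dims[2] * (nb[3] - 1))
        if (!seen[q] && flags[q] && signs[q] == sgn) {
          seen[q] <- TRUE
          frontier <- c(frontier, q)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# construct mean-zero columns with exactly the requested pairwise
# correlations against an orthonormal basis (Gram-Schmidt style)
orthonormal_basis <- function(n_frames, k, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n_frames * (k + 1)), n_frames, k + 1)
  M[, 1] <- 1                       # constant first, projected out below
  Q <- qr.Q(qr(M))[, -1, drop = FALSE]
  Q                                  # columns: mean zero, unit norm, orthogonal
}

expect_pas_equal <- function(a, b, tol = 1e-10) {
  expect_equal(a$pas, b$pas, tolerance = tol)
  expect_equal(a$fc_inter, b$fc_inter, tolerance = tol)
  expect_equal(a$fc_intra, b$fc_intra, tolerance = tol)
  expect_identical(a$n_inter_used, b$n_inter_used)
  expect_identical(a$n_intra_used, b$n_intra_used)
}
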