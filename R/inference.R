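#' Build the covariate-adjusted group design matrix
#'
#' Treatment coding with HC as the reference level when present (otherwise
#' the last group listed), gender coded male = 0 / female = 1, and every
#' covariate mean-centered. Also returns the reduced (covariates-only)
#' design used by the partial-F group test.
#'
#' @param table a `subject_table`.
#' @param groups character subset of GI_MDD / NGI_MDD / HC to retain, in
#'   the order contrasts should be signed (first-listed group gets the
#'   positive sign in two-group models).
#' @param covariates covariate column names; `gender` is recoded, all
#'   others must be numeric and complete.
#' @return list of class `pas_design`: `X_full`, `X_reduced`, `df_group`,
#'   `group_cols`, `rows` (indices into `table`), `groups`, `subject_id`.
#' @export
build_design <- function(table,
                         groups = c("GI_MDD", "NGI_MDD", "HC"),
                         covariates = c("age", "gender", "education", "mean_fd")) {
  stopifnot(inherits(table, "data.frame"))
  groups <- match.arg(groups, c("GI_MDD", "NGI_MDD", "HC"), several.ok = TRUE)
  rows <- which(table$group %in% groups)
  if (length(rows) < length(groups) + length(covariates) + 1L) {
    stop("not enough subjects for the requested design")
  }
  sub <- table[rows, , drop = FALSE]

  covs <- NULL
  for (cv in covariates) {
    if (!cv %in% names(sub)) stop("covariate not in subject table: ", cv)
    x <- if (cv == "gender") ifelse(sub$gender == "female", 1, 0) else as.numeric(sub[[cv]])
    if (anyNA(x)) stop("covariate has missing values: ", cv)
    covs <- cbind(covs, x - mean(x))
  }
  if (!is.null(covs)) colnames(covs) <- covariates

  ref <- if ("HC" %in% groups) "HC" else groups[length(groups)]
  non_ref <- setdiff(groups, ref)
  G <- NULL
  for (g in non_ref) G <- cbind(G, as.numeric(sub$group == g))
  if (!is.null(G)) colnames(G) <- paste0("group_", non_ref)

  ones <- rep(1, nrow(sub))
  X_full <- cbind(intercept = ones, G, covs)
  X_reduced <- cbind(intercept = ones, covs)
  qrf <- qr(X_full)
  if (qrf$rank < ncol(X_full)) {
    dropped <- colnames(X_full)[qrf$pivot[(qrf$rank + 1):ncol(X_full)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  structure(
    list(X_full = X_full, X_reduced = X_reduced,
         df_group = length(non_ref),
         group_cols = colnames(G),
         rows = rows, groups = groups, reference = ref,
         subject_id = sub$subject_id, group = sub$group),
    class = "pas_design"
  )
}

.resid_rss <- function(X, Y) {
  Q <- qr.Q(qr(X))
  R <- Y - Q %*% crossprod(Q, Y)
  colSums(R^2)
}

#' Voxel-wise ANCOVA F map for the group factor
#'
#' Per voxel, the partial F comparing the full model (group + covariates)
#' to the reduced model (covariates only):
#' F = ((RSS_r - RSS_f) / df_group) / (RSS_f / df_resid). A voxel with zero
#' full-model residual variance gets p = 0 and is flagged, unless the
#' reduced model also fits perfectly (then F = 0, p = 1).
#'
#' @param pas_stack subject-by-voxel matrix, rows aligned with the design.
#' @param design a `pas_design` from [build_design()].
#' @return a data frame of class `stat_map`: `statistic`, `p`, `flagged`,
#'   with attributes `df1`, `df2` and `type = "F"`.
#' @export
ancova_f_map <- function(pas_stack, design) {
  stopifnot(inherits(design, "pas_design"))
  Y <- as.matrix(pas_stack)
  if (nrow(Y) != nrow(design$X_full)) {
    stop(sprintf("PAS stack has %d rows but design has %d", nrow(Y), nrow(design$X_full)))
  }
  df2 <- nrow(Y) - ncol(design$X_full)
  if (df2 < 1L) stop("non-positive residual degrees of freedom")
  df1 <- design$df_group
  rss_f <- .resid_rss(design$X_full, Y)
  rss_r <- .resid_rss(design$X_reduced, Y)
  eps <- 1e-12 * pmax(colSums(Y^2), 1)
  Fv <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  flagged <- rss_f <= eps
  degenerate_null <- flagged & (rss_r - rss_f) <= eps
  Fv[degenerate_null] <- 0; p[degenerate_null] <- 1
  sig_perfect <- flagged & !degenerate_null
  Fv[sig_perfect] <- Inf; p[sig_perfect] <- 0
  if (any(sig_perfect)) warning(sum(sig_perfect), " voxel(s) with zero residual variance; p set to 0")
  out <- data.frame(statistic = Fv, p = p, flagged = flagged)
  attr(out, "df1") <- df1; attr(out, "df2") <- df2; attr(out, "type") <- "F"
  class(out) <- c("stat_map", "data.frame")
  out
}

#' Voxel-wise covariate-adjusted two-group t map
#'
#' Fits the full two-group model per voxel and returns the t statistic of
#' the group indicator. Positive t means the first-listed group of the
#' design is higher.
#'
#' @param pas_stack subject-by-voxel matrix, rows aligned with the design.
#' @param design a two-group `pas_design`; its first-listed group carries
#'   the positive sign.
#' @return a `stat_map` data frame with attribute `df` and `type = "t"`.
#' @export
posthoc_t_map <- function(pas_stack, design) {
  stopifnot(inherits(design, "pas_design"))
  if (design$df_group != 1L) stop("posthoc_t_map needs exactly two groups")
  Y <- as.matrix(pas_stack)
  X <- design$X_full
  if (nrow(Y) != nrow(X)) stop("PAS stack rows do not match the design")
  df <- nrow(Y) - ncol(X)
  if (df < 1L) stop("non-positive residual degrees of freedom")

  # sign convention: indicator = 1 for the first-listed group
  jcol <- match(design$group_cols, colnames(X))
  flip <- design$reference == design$groups[1]
  XtX_inv <- solve(crossprod(X))
  beta <- XtX_inv %*% crossprod(X, Y)
  resid <- Y - X %*% beta
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * XtX_inv[jcol, jcol])
  tval <- beta[jcol, ] / se
  if (flip) tval <- -tval
  tval[se == 0] <- 0
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  flagged <- sigma2 <= 1e-12 * pmax(colMeans(Y^2), 1)
  p[flagged] <- ifelse(abs(beta[jcol, flagged]) > 0, 0, 1)
  out <- data.frame(statistic = tval, p = p, flagged = flagged)
  attr(out, "df") <- df; attr(out, "type") <- "t"
  class(out) <- c("stat_map", "data.frame")
  out
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up rule: with p sorted ascending,
#' q_i = min over j >= i of (m p_j / j), clipped at 1; reject where
#' q < alpha.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `q` (adjusted values, input order) and `reject`
#'   (logical). Empty input gives empty output.
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (!length(p)) return(list(q = numeric(0), reject = logical(0)))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, reject = q < alpha)
}

.connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6" = g[ord == 1, , drop = FALSE],
         "18" = g[ord <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26"))
}

#' Extract supra-threshold clusters from a statistic map
#'
#' Connected components of significant voxels, with positive and negative
#' effects labeled separately. The peak is the voxel maximizing the
#' absolute statistic (ties broken by lowest grid index, so output is
#' deterministic); its world coordinates come from the mask affine.
#'
#' @param stat_map a `stat_map` over non-excluded voxels.
#' @param significant logical per non-excluded voxel (e.g. BH rejections).
#' @param labeling the `hemisphere_labeling` used to build the map.
#' @param mask the shared `brain_mask`.
#' @param connectivity 6, 18 or 26 (face / face+edge / face+edge+corner).
#' @param min_extent drop clusters smaller than this many voxels.
#' @param pas_stack optional subject-by-voxel matrix; when given, each
#'   record carries the per-subject mean PAS over the cluster.
#' @return a list of cluster records (class `cluster_set`), each with
#'   `id`, `sign`, `n_voxels`, `peak_grid` (0-based ijk), `peak_mm`,
#'   `peak_stat`, `voxels` (indices into the non-excluded set), and
#'   optionally `subject_means`.
#' @export
extract_clusters <- function(stat_map, significant, labeling, mask,
                             connectivity = 26, min_extent = 0,
                             pas_stack = NULL) {
  stopifnot(inherits(mask, "brain_mask"))
  keep_vox <- which(labeling$keep)
  stopifnot(length(significant) == length(keep_vox),
            nrow(stat_map) == length(keep_vox))
  offs <- .connectivity_offsets(connectivity)

  stat_vol <- array(0, dim = mask$dim)
  flag_vol <- array(FALSE, dim = mask$dim)
  col_vol <- array(NA_integer_, dim = mask$dim)   # grid -> non-excluded column
  lin <- mask$indices[keep_vox]
  stat_vol[lin] <- stat_map$statistic
  flag_vol[lin] <- significant
  col_vol[lin] <- seq_along(keep_vox)

  dims <- mask$dim
  visited <- array(FALSE, dim = dims)
  records <- list()
  next_id <- 1L
  seeds <- which(flag_vol)                # ascending grid order
  for (seed in seeds) {
    if (visited[seed]) next
    sgn <- sign(stat_vol[seed])
    stack <- seed
    visited[seed] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      ijk <- arrayInd(cur, dims)
      nb <- sweep(offs, 2L, as.integer(ijk), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb_lin <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1 + dims[2] * (nb[ok, 3] - 1))
      for (q in nb_lin) {
        if (!visited[q] && flag_vol[q] && sign(stat_vol[q]) == sgn) {
          visited[q] <- TRUE
          stack <- c(stack, q)
        }
      }
    }
    if (length(members) < min_extent) next
    members <- sort(members)
    peak <- members[which.max(abs(stat_vol[members]))]  # first max = lowest index
    peak_ijk <- as.integer(arrayInd(peak, dims)) - 1L
    peak_mm <- as.numeric(mask$affine[1:3, ] %*% c(peak_ijk, 1))
    rec <- list(id = next_id, sign = as.integer(sgn),
                n_voxels = length(members),
                peak_grid = peak_ijk, peak_mm = peak_mm,
                peak_stat = stat_vol[peak],
                voxels = col_vol[members])
    if (!is.null(pas_stack)) {
      rec$subject_means <- rowMeans(as.matrix(pas_stack)[, rec$voxels, drop = FALSE])
    }
    records[[next_id]] <- rec
    next_id <- next_id + 1L
  }
  structure(records, class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  if (!length(x)) {
    cat("cluster_set: no clusters\n")
    return(invisible(x))
  }
  cat(sprintf("cluster_set: %d cluster(s)\n", length(x)))
  for (r in x) {
    cat(sprintf("  #%d sign %+d size %d peak (%g, %g, %g) mm stat %.4f\n",
                r$id, r$sign, r$n_voxels,
                r$peak_mm[1], r$peak_mm[2], r$peak_mm[3], r$peak_stat))
  }
  invisible(x)
}

#' Cluster records as a table
#' @param clusters a `cluster_set`.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(id = integer(0), sign = integer(0), n_voxels = integer(0),
                      peak_x = numeric(0), peak_y = numeric(0), peak_z = numeric(0),
                      peak_stat = numeric(0)))
  }
  do.call(rbind, lapply(clusters, function(r) {
    data.frame(id = r$id, sign = r$sign, n_voxels = r$n_voxels,
               peak_x = r$peak_mm[1], peak_y = r$peak_mm[2], peak_z = r$peak_mm[3],
               peak_stat = r$peak_stat)
  }))
}

#' One-way ANOVA from group summaries
#'
#' Reconstructs between- and within-group sums of squares from each group's
#' size, mean and sample SD (n - 1 denominator); exact when the summaries
#' are exact.
#'
#' @param groups list of lists/data frames with fields `n`, `mean`, `sd`.
#' @return list `F`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  n <- vapply(groups, function(g) as.numeric(g$n), 0)
  m <- vapply(groups, function(g) as.numeric(g$mean), 0)
  s <- vapply(groups, function(g) as.numeric(g$sd), 0)
  if (any(n < 2)) stop("every group needs n >= 2")
  if (any(s < 0)) stop("negative SD")
  N <- sum(n); k <- length(n)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- k - 1; df2 <- N - k
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Pooled two-sample t test from group summaries
#'
#' @param a,b lists with fields `n`, `mean`, `sd` (sample SD).
#' @return list `t`, `df`, `p` (two-sided).
#' @export
ttest_from_summary <- function(a, b) {
  n1 <- as.numeric(a$n); n2 <- as.numeric(b$n)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (a$sd < 0 || b$sd < 0) stop("negative SD")
  sp2 <- ((n1 - 1) * a$sd^2 + (n2 - 1) * b$sd^2) / (n1 + n2 - 2)
  tval <- (a$mean - b$mean) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

#' Pearson chi-square test of independence
#'
#' No continuity correction, matching the usual reporting for r x c
#' demographic tables.
#'
#' @param counts integer matrix of observed counts.
#' @return list `chi2`, `df`, `p`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in the contingency table")
  E <- outer(rs, cs) / sum(counts)
  chi2 <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
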