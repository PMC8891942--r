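#' Spearman rank correlation with t-approximation p value
#'
#' Pearson correlation of mid-ranks (average ranks on ties), pairwise
#' complete; the two-sided p value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)). A constant input has no rank
#' variance: rho is returned as NA with `valid = FALSE` so callers can
#' drop the pair from a multiple-testing family.
#'
#' @param x,y numeric vectors of equal length.
#' @return list `rho`, `p`, `n` (pairwise-complete count), `valid`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  if (sx == 0 || sy == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, valid = FALSE))
  }
  rho <- stats::cov(rx, ry) / (sx * sy)
  rho <- min(max(rho, -1), 1)
  if (abs(rho) == 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n, valid = TRUE)
}

#' Cluster-by-clinical-variable Spearman correlation grid
#'
#' One Spearman test per (cluster, variable) pair over the filtered
#' subjects, with Benjamini-Hochberg correction across the whole grid of
#' valid (non-degenerate) pairs. Mirrors the usual brain-behavior matrix:
#' rho with significance marks.
#'
#' @param cluster_means subject-by-cluster numeric matrix with column
#'   names; row names are subject ids.
#' @param table a `subject_table` covering those subjects.
#' @param variables clinical column names to test.
#' @param groups subject filter; default pools both patient groups.
#' @param alpha BH level.
#' @return data frame of class `correlation_grid`: `cluster`, `variable`,
#'   `rho`, `p`, `q`, `n`, `significant`, `valid`.
#' @export
correlation_grid <- function(cluster_means, table, variables,
                             groups = c("GI_MDD", "NGI_MDD"), alpha = 0.05) {
  if (!length(variables)) stop("no clinical variables given")
  cluster_means <- as.matrix(cluster_means)
  if (is.null(colnames(cluster_means))) {
    colnames(cluster_means) <- paste0("cluster_", seq_len(ncol(cluster_means)))
  }
  rows <- which(table$group %in% groups)
  if (length(rows) < 3L) stop("fewer than 3 subjects after group filtering")
  if (!is.null(rownames(cluster_means))) {
    idx <- match(table$subject_id[rows], rownames(cluster_means))
    if (anyNA(idx)) stop("cluster_means is missing subject(s): ",
                         paste(table$subject_id[rows][is.na(idx)], collapse = ", "))
  } else {
    if (nrow(cluster_means) != nrow(table)) {
      stop("unnamed cluster_means rows must align with the subject table")
    }
    idx <- rows
  }
  cm <- cluster_means[idx, , drop = FALSE]
  sub <- table[rows, , drop = FALSE]

  out <- NULL
  for (cl in colnames(cm)) {
    for (v in variables) {
      if (!v %in% names(sub)) stop("clinical variable not in table: ", v)
      res <- spearman_cor(cm[, cl], as.numeric(sub[[v]]))
      out <- rbind(out, data.frame(cluster = cl, variable = v,
                                   rho = res$rho, p = res$p, n = res$n,
                                   valid = res$valid, stringsAsFactors = FALSE))
    }
  }
  out$q <- NA_real_
  out$significant <- FALSE
  valid <- which(out$valid)
  if (length(valid)) {
    adj <- fdr_bh(out$p[valid], alpha)
    out$q[valid] <- adj$q
    out$significant[valid] <- adj$reject
  }
  out <- out[, c("cluster", "variable", "rho", "p", "q", "n", "significant", "valid")]
  class(out) <- c("correlation_grid", "data.frame")
  out
}
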