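#' Support vector machine via sequential minimal optimization
#'
#' C-classification SVM trained by Platt's SMO on the dual problem, with a
#' deterministic second-choice heuristic (maximal |E_i - E_j|) so repeated
#' fits of the same data give the same model. Supports the radial basis
#' kernel exp(-gamma * ||u - v||^2) and the linear kernel. This is a small
#' self-contained solver in the LIBSVM family, adequate for the cohort
#' sizes this package targets (tens of subjects).
#'
#' @param X subject-by-feature numeric matrix.
#' @param y labels coercible to two classes; internally mapped to -1 / +1.
#' @param positive the label treated as +1.
#' @param kernel `"radial"` or `"linear"`.
#' @param cost soft-margin C > 0.
#' @param gamma RBF width; default `1 / (n_features * var(X))` with `var`
#'   the overall variance of the training entries (the common "scale"
#'   policy; after standardization this is close to `1 / n_features`).
#' @param tol KKT tolerance.
#' @param max_passes outer passes without progress before stopping.
#' @return an object of class `pasym_svm`.
#' @export
svm_train <- function(X, y, positive = NULL, kernel = c("radial", "linear"),
                      cost = 1, gamma = NULL, tol = 1e-3, max_passes = 200L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (anyNA(X)) stop("features contain missing values")
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2L) stop("need exactly 2 classes in the training labels")
  if (is.null(positive)) positive <- classes[1]
  if (!positive %in% classes) stop("positive class not present in labels")
  negative <- setdiff(classes, positive)
  yy <- ifelse(y == positive, 1, -1)
  n <- nrow(X)
  if (min(table(yy)) < 1L) stop("a training fold contains one class only")
  if (cost <= 0) stop("cost must be positive")
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X)) * (length(X) - 1) / length(X)
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  }

  K <- .svm_kernel(X, X, kernel, gamma)
  alpha <- numeric(n)
  b <- 0
  fcache <- rep(0, n)                # f(x_i) without b... maintained with b below
  E <- function(i) fcache[i] + b - yy[i]

  take_step <- function(i, j) {
    if (i == j) return(FALSE)
    ai <- alpha[i]; aj <- alpha[j]
    yi <- yy[i]; yj <- yy[j]
    Ei <- E(i); Ej <- E(j)
    s <- yi * yj
    if (s > 0) {
      L <- max(0, ai + aj - cost); H <- min(cost, ai + aj)
    } else {
      L <- max(0, aj - ai); H <- min(cost, cost + aj - ai)
    }
    if (L >= H) return(FALSE)
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 0) return(FALSE)
    aj_new <- aj + yj * (Ei - Ej) / eta
    aj_new <- min(max(aj_new, L), H)
    if (abs(aj_new - aj) < 1e-10 * (aj_new + aj + 1e-10)) return(FALSE)
    ai_new <- ai + s * (aj - aj_new)

    b1 <- b - Ei - yi * (ai_new - ai) * K[i, i] - yj * (aj_new - aj) * K[i, j]
    b2 <- b - Ej - yi * (ai_new - ai) * K[i, j] - yj * (aj_new - aj) * K[j, j]
    b_new <- if (ai_new > 0 && ai_new < cost) b1
             else if (aj_new > 0 && aj_new < cost) b2
             else (b1 + b2) / 2

    fcache <<- fcache + yi * (ai_new - ai) * K[, i] + yj * (aj_new - aj) * K[, j]
    alpha[i] <<- ai_new; alpha[j] <<- aj_new
    b <<- b_new
    TRUE
  }

  examine <- function(i) {
    Ei <- E(i)
    r <- Ei * yy[i]
    if ((r < -tol && alpha[i] < cost) || (r > tol && alpha[i] > 0)) {
      Evec <- fcache + b - yy
      j <- which.max(abs(Evec - Ei))
      if (take_step(i, j)) return(TRUE)
      for (j in seq_len(n)) {
        if (alpha[j] > 0 && alpha[j] < cost && take_step(i, j)) return(TRUE)
      }
      for (j in seq_len(n)) {
        if (take_step(i, j)) return(TRUE)
      }
    }
    FALSE
  }

  examine_all <- TRUE
  passes <- 0L
  while (passes < max_passes) {
    # vectorized KKT screen; examine() re-checks each candidate because
    # earlier steps in the same pass change the error cache
    Evec <- fcache + b - yy
    r_all <- Evec * yy
    viol <- (r_all < -tol & alpha < cost) | (r_all > tol & alpha > 0)
    idx <- if (examine_all) which(viol)
           else which(viol & alpha > 0 & alpha < cost)
    changed <- 0L
    for (i in idx) changed <- changed + examine(i)
    if (examine_all) {
      if (changed == 0L) break
      examine_all <- FALSE
    } else if (changed == 0L) {
      examine_all <- TRUE
    }
    passes <- passes + 1L
  }

  sv <- alpha > 1e-12
  structure(
    list(sv_x = X[sv, , drop = FALSE], sv_coef = (alpha * yy)[sv], b = b,
         kernel = kernel, gamma = gamma, cost = cost,
         positive = positive, negative = negative),
    class = "pasym_svm"
  )
}

.svm_kernel <- function(A, B, kernel, gamma) {
  if (kernel == "linear") return(tcrossprod(A, B))
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Decision values and class predictions of a trained SVM
#'
#' A decision value of exactly 0 predicts the negative class.
#'
#' @param model a `pasym_svm`.
#' @param newdata feature matrix with the training columns.
#' @param decision return raw decision values instead of labels.
#' @export
svm_predict <- function(model, newdata, decision = FALSE) {
  stopifnot(inherits(model, "pasym_svm"))
  newdata <- as.matrix(newdata)
  K <- .svm_kernel(newdata, model$sv_x, model$kernel, model$gamma)
  f <- as.numeric(K %*% model$sv_coef) + model$b
  if (decision) return(f)
  ifelse(f > 0, model$positive, model$negative)
}

#' Leave-one-out cross-validated SVM discrimination
#'
#' Each subject is predicted by a model trained on the other N - 1, with
#' features standardized using training-fold statistics only (no leakage;
#' a zero training SD leaves that feature centered but unscaled). Reports
#' the confusion counts and the accuracy / sensitivity / specificity
#' fractions in `percent%(num/den)` form.
#'
#' @param features subject-by-feature numeric matrix (row names optional).
#' @param labels two-class labels, one per subject.
#' @param positive the class counted as positive (sensitivity numerator).
#' @param kernel,cost,gamma passed to [svm_train()].
#' @param standardize standardize within each training fold (default TRUE).
#' @return a list of class `loocv_result`: counts, rates, formatted
#'   strings and per-subject predictions.
#' @export
loocv_svm <- function(features, labels, positive, kernel = "radial",
                      cost = 1, gamma = NULL, standardize = TRUE) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("features and labels disagree on N")
  if (anyNA(X)) stop("features contain missing values")
  classes <- unique(labels)
  if (length(classes) != 2L) stop("need exactly two classes")
  if (!positive %in% classes) stop("positive class absent from labels")
  if (min(table(labels)) < 2L) stop("need >= 2 subjects per class for LOOCV")

  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr_x <- X[-i, , drop = FALSE]
    te_x <- X[i, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(tr_x)
      sd_ <- apply(tr_x, 2L, stats::sd)
      sd_[sd_ == 0] <- 1
      tr_x <- sweep(sweep(tr_x, 2L, mu), 2L, sd_, `/`)
      te_x <- sweep(sweep(te_x, 2L, mu), 2L, sd_, `/`)
    }
    model <- svm_train(tr_x, labels[-i], positive = positive,
                       kernel = kernel, cost = cost, gamma = gamma)
    pred[i] <- svm_predict(model, te_x)
  }

  actual_pos <- labels == positive
  tp <- sum(pred == positive & actual_pos)
  tn <- sum(pred != positive & !actual_pos)
  fp <- sum(pred == positive & !actual_pos)
  fn <- sum(pred != positive & actual_pos)
  frac <- function(num, den) {
    list(value = num / den, num = num, den = den,
         label = sprintf("%.2f%%(%d/%d)", round(100 * num / den, 2), num, den))
  }
  structure(
    list(accuracy = frac(tp + tn, n),
         sensitivity = frac(tp, sum(actual_pos)),
         specificity = frac(tn, sum(!actual_pos)),
         confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
         predictions = stats::setNames(pred, rownames(X)),
         positive = positive),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV SVM (positive = %s): accuracy %s, sensitivity %s, specificity %s\n",
              x$positive, x$accuracy$label, x$sensitivity$label, x$specificity$label))
  invisible(x)
}

#' LOOCV performance over a list of feature subsets
#'
#' One [loocv_svm()] run per subset, reported in the given order. A
#' duplicated name within a subset is deduplicated with a warning; an
#' unknown feature name is an error.
#'
#' @param features subject-by-feature matrix with column names.
#' @param labels,positive,kernel,cost,gamma as in [loocv_svm()].
#' @param subsets list of character vectors of feature names.
#' @return data frame, one row per subset: `features`, `accuracy`,
#'   `sensitivity`, `specificity` (formatted strings) plus the numeric
#'   rates; the per-subset `loocv_result`s are attached as attribute
#'   `results`.
#' @export
feature_subset_sweep <- function(features, labels, subsets, positive,
                                 kernel = "radial", cost = 1, gamma = NULL) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) stop("features need column names")
  if (!length(subsets)) stop("no feature subsets given")
  results <- vector("list", length(subsets))
  rows <- NULL
  for (k in seq_along(subsets)) {
    sel <- subsets[[k]]
    if (!length(sel)) stop("empty feature subset at position ", k)
    if (anyDuplicated(sel)) {
      warning("duplicated feature name(s) in subset ", k, "; deduplicated")
      sel <- unique(sel)
    }
    unknown <- setdiff(sel, colnames(X))
    if (length(unknown)) stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
    res <- loocv_svm(X[, sel, drop = FALSE], labels, positive,
                     kernel = kernel, cost = cost, gamma = gamma)
    results[[k]] <- res
    rows <- rbind(rows, data.frame(
      features = paste(sel, collapse = " + "),
      accuracy = res$accuracy$label,
      sensitivity = res$sensitivity$label,
      specificity = res$specificity$label,
      accuracy_value = res$accuracy$value,
      sensitivity_value = res$sensitivity$value,
      specificity_value = res$specificity$value,
      stringsAsFactors = FALSE
    ))
  }
  attr(rows, "results") <- results
  rows
}
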