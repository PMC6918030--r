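# Layout-quality evaluation: how well do the two displayed coordinates
# separate a binary grouping of the samples? Measured, as is standard for
# ordination displays, by the AUC of a logistic regression of the group
# index on the two coordinates under leave-one-out cross-validation.

#' Binary sample labels
#'
#' @param values vector of 0/1 group indicators (logicals accepted).
#' @param ids sample identifiers (default: names of `values`).
#' @return Object of class `binary_labels`.
#' @export
binary_labels <- function(values, ids = names(values)) {
  v <- as.integer(values)
  if (any(is.na(v)) || !all(v %in% c(0L, 1L))) {
    stop("labels must be 0/1")
  }
  if (is.null(ids)) ids <- paste0("sample", seq_along(v))
  ids <- as.character(ids)
  if (length(ids) != length(v)) stop("ID/label length mismatch")
  .check_unique(ids, "sample ID")
  structure(list(ids = ids, values = v), class = "binary_labels")
}

.label_values <- function(labels) {
  if (inherits(labels, "binary_labels")) labels$values
  else binary_labels(labels)$values
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive sample receives a higher
#' score than a randomly chosen negative one, with ties counting one half
#' (the Mann-Whitney convention, equal to trapezoidal integration of the
#' ROC curve over all thresholds).
#'
#' @param scores numeric vector of classifier scores (higher = more
#'   positive); any strictly increasing transform leaves the AUC
#'   unchanged.
#' @param labels a [binary_labels()] or 0/1 vector containing both
#'   classes.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .label_values(labels)
  if (length(scores) != length(y)) stop("score/label length mismatch")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("labels must contain both classes")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Ridge-penalized logistic regression by Newton/IRLS. The small fixed
# penalty (not applied to the intercept) keeps the fit defined on
# separable data, which LOO over a well-separated ordination produces
# routinely.
.ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 100L,
                            tol = 1e-10) {
  X1 <- cbind(1, as.matrix(X))
  d <- ncol(X1)
  pen <- diag(c(0, rep(lambda, d - 1)), d)
  beta <- numeric(d)
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X1 %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X1, y - mu) - pen %*% beta
    hess <- crossprod(X1, w * X1) + pen
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) {
      step <- solve(hess + diag(1e-8, d), grad)
    }
    beta <- beta + step
    if (max(abs(step)) < tol * max(1, max(abs(beta)))) break
  }
  beta
}

.logistic_predict <- function(beta, X) {
  stats::plogis(pmin(pmax(drop(cbind(1, as.matrix(X)) %*% beta), -30), 30))
}

#' Leave-one-out logistic-regression AUC of a 2-D layout
#'
#' For each sample, a logistic regression of the group index on the two
#' layout coordinates is fitted on the remaining samples and used to
#' predict the held-out sample's group probability; the AUC of these n
#' held-out probabilities summarizes how well the layout separates the
#' groups. A small fixed ridge penalty keeps the fits defined when the
#' classes are linearly separable.
#'
#' @param points n x 2 matrix of layout coordinates (e.g.
#'   `layout$sample_points`).
#' @param labels a [binary_labels()] or 0/1 vector, both classes present,
#'   `n >= 4`.
#' @param ridge penalty on the coordinate coefficients (default `1e-6`).
#' @return AUC of the held-out probabilities. Degenerate layouts in which
#'   all points coincide return 0.5 with a warning.
#' @export
loo_logistic_auc <- function(points, labels, ridge = 1e-6) {
  pts <- as.matrix(points)
  y <- .label_values(labels)
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 samples for leave-one-out")
  if (length(y) != n) stop("label/point length mismatch")
  if (sum(y) == 0 || sum(y) == n) stop("labels must contain both classes")
  if (all(abs(sweep(pts, 2, pts[1, ])) < 1e-12)) {
    warning("all layout points identical; AUC undefined, returning 0.5")
    return(0.5)
  }
  prob <- vapply(seq_len(n), function(i) {
    beta <- .ridge_logistic(pts[-i, , drop = FALSE], y[-i], lambda = ridge)
    .logistic_predict(beta, pts[i, , drop = FALSE])
  }, numeric(1))
  roc_auc(prob, y)
}

#' Training-sample logistic AUC of a 2-D layout
#'
#' Fits one ridge-penalized logistic regression on all samples and returns
#' the AUC of the fitted probabilities — the resubstitution measure of
#' linear separability used by the simulation contrast.
#'
#' @inheritParams loo_logistic_auc
#' @return Training AUC in `[0, 1]`.
#' @export
training_logistic_auc <- function(points, labels, ridge = 1e-6) {
  pts <- as.matrix(points)
  y <- .label_values(labels)
  beta <- .ridge_logistic(pts, y, lambda = ridge)
  roc_auc(.logistic_predict(beta, pts), y)
}
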