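#' Classifier specification
#'
#' Describes the classifier the evaluation loop should fit: the paper's
#' k-nearest-neighbour rule (default `k = 1`, Euclidean distance) or a
#' cubic-kernel support vector machine. The KNN rule is implemented in this
#' package; the SVM is delegated to \pkg{e1071} behind the same fit/predict
#' interface (polynomial kernel \eqn{(x^T x_i + 1)^3}).
#'
#' @param classifier `"knn"` or `"svm_cubic"`.
#' @param k Number of neighbours (KNN only; default 1).
#' @param metric Distance metric for KNN: `"euclidean"`, `"mahalanobis"` or
#'   `"minkowski"`.
#' @param p Minkowski order (used when `metric = "minkowski"`; default 3).
#' @param standardize Centre/scale features (by training-split mean and
#'   standard deviation) before fitting? Default `TRUE`, mirroring the
#'   standardisation the MATLAB Classification Learner applies to
#'   distance-based models; without it the Euclidean distance over the
#'   entropy features is dominated by the log-energy-entropy columns, whose
#'   numeric scale is about four orders of magnitude above the other two
#'   families.
#' @return A `fbewt_classifier_spec` list.
#' @export
classifier_spec <- function(classifier = c("knn", "svm_cubic"), k = 1,
                            metric = c("euclidean", "mahalanobis", "minkowski"),
                            p = 3, standardize = TRUE) {
  classifier <- match.arg(classifier)
  metric <- match.arg(metric)
  if (length(k) != 1L || k < 1 || k != round(k)) {
    stop_fbewt("`k` must be a single positive integer.", "fbewt_invalid_argument")
  }
  structure(
    list(classifier = classifier, k = as.integer(k), metric = metric,
         p = p, standardize = isTRUE(standardize)),
    class = "fbewt_classifier_spec"
  )
}

#' Fit a k-nearest-neighbour model
#'
#' Stores the training matrix and labels; prediction follows the three
#' steps of the KNN rule: compute the distance from the query to every
#' training row, sort ascending, and take the majority label among the `k`
#' nearest (distance ties broken towards the lowest training-row index,
#' vote ties towards the class of the nearest tied neighbour).
#'
#' @param x Numeric training matrix (observations x features).
#' @param y Vector of training labels (length `nrow(x)`).
#' @param k Number of neighbours (default 1, the paper's evaluation choice).
#' @param metric `"euclidean"` (default), `"mahalanobis"` or `"minkowski"`.
#' @param p Minkowski order (default 3).
#' @return A `fbewt_knn` model object.
#' @export
knn_fit <- function(x, y, k = 1,
                    metric = c("euclidean", "mahalanobis", "minkowski"), p = 3) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (nrow(x) == 0L) {
    stop_fbewt("empty training set.", "fbewt_invalid_state")
  }
  if (length(y) != nrow(x)) {
    stop_fbewt("`y` must have one label per training row.",
               "fbewt_invalid_argument")
  }
  if (k > nrow(x)) {
    stop_fbewt("`k` cannot exceed the number of training observations.",
               "fbewt_invalid_argument")
  }
  cov_inv <- NULL
  if (metric == "mahalanobis") {
    cv <- stats::cov(x)
    # ridge for numerically singular covariance
    diag(cv) <- diag(cv) + 1e-8 * mean(diag(cv))
    cov_inv <- solve(cv)
  }
  structure(
    list(x = x, y = y, k = as.integer(k), metric = metric, p = p,
         cov_inv = cov_inv),
    class = "fbewt_knn"
  )
}

# Distance from every training row to every query row: n_train x n_query.
.knn_distances <- function(model, q) {
  x <- model$x
  switch(model$metric,
    euclidean = {
      d2 <- outer(rowSums(x^2), rep(1, nrow(q))) +
        outer(rep(1, nrow(x)), rowSums(q^2)) - 2 * tcrossprod(x, q)
      sqrt(pmax(d2, 0))
    },
    mahalanobis = {
      ci <- model$cov_inv
      xa <- x %*% ci
      d2 <- outer(rowSums(xa * x), rep(1, nrow(q))) +
        outer(rep(1, nrow(x)), rowSums((q %*% ci) * q)) - 2 * tcrossprod(xa, q)
      sqrt(pmax(d2, 0))
    },
    minkowski = {
      p <- model$p
      apply(q, 1, function(v) rowSums(abs(sweep(x, 2, v))^p)^(1 / p))
    }
  )
}

#' Predict with a fitted KNN model
#'
#' @param object A `fbewt_knn` model.
#' @param newdata Numeric matrix (or vector for a single query) with the
#'   training feature dimensionality.
#' @param ... Unused.
#' @return Vector of predicted labels, one per query row.
#' @export
predict.fbewt_knn <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x)) {
    stop_fbewt("query dimensionality does not match the training matrix.",
               "fbewt_invalid_argument")
  }
  D <- .knn_distances(object, newdata)
  k <- object$k
  idx_train <- seq_len(nrow(object$x))
  out <- vapply(seq_len(ncol(D)), function(j) {
    # ascending distance, exact ties resolved by lowest training-row index
    ord <- order(D[, j], idx_train)[seq_len(k)]
    labs <- object$y[ord]
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) winners else
      as.character(labs[labs %in% winners][1])
  }, character(1))
  # restore the label type of y
  if (is.numeric(object$y)) as.numeric(out) else out
}

#' Fit a classifier from a specification
#'
#' Uniform interface over the two supported classifiers. KNN is fitted with
#' [knn_fit()]; `"svm_cubic"` is fitted with [e1071::svm()] using the
#' polynomial kernel of degree 3, `coef0 = 1`, `gamma = 1` (the cubic kernel
#' \eqn{(x^T x_i + 1)^3}).
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric training matrix.
#' @param y Training labels (coerced to factor for the SVM).
#' @return A fitted model with a `predict()` method returning labels.
#' @export
fit_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "fbewt_classifier_spec"))
  x <- as.matrix(x)
  if (spec$standardize) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    scaler <- list(mu = mu, sd = sdv)
  } else {
    scaler <- NULL
  }
  fit <- if (spec$classifier == "knn") {
    knn_fit(x, y, k = spec$k, metric = spec$metric, p = spec$p)
  } else {
    e1071::svm(x, factor(y), kernel = "polynomial", degree = 3,
               gamma = 1, coef0 = 1, scale = FALSE)
  }
  structure(list(fit = fit, spec = spec, scaler = scaler,
                 numeric_y = is.numeric(y)),
            class = "fbewt_classifier")
}

#' @export
predict.fbewt_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$scaler)) {
    newdata <- sweep(sweep(newdata, 2, object$scaler$mu), 2,
                     object$scaler$sd, "/")
  }
  out <- predict(object$fit, newdata)
  if (object$numeric_y && !is.numeric(out)) {
    out <- as.numeric(as.character(out))
  }
  out
}
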