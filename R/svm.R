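#' Fit a per-sample-weighted linear SVM
#'
#' Linear-kernel maximum-margin classifier in which each sample's
#' misclassification penalty is scaled by its own weight — the base learner
#' needed by boosting-style reweighting schemes. The primal objective per
#' binary problem is
#' \deqn{\tfrac12\|\theta\|^2 + C \sum_i w_i \max(0, 1 - y_i(\theta^\top x_i + b))^2,}
#' minimised by L-BFGS-B with analytic gradients (the squared hinge makes
#' the objective differentiable, so the fit is smooth and deterministic).
#' Multiclass problems are decomposed one-vs-rest; prediction takes the
#' class with the largest decision value, ties going to the lowest label in
#' canonical sorted order.
#'
#' Weights are normalised internally so that only their relative sizes
#' matter: scaling all weights by a constant leaves the fit unchanged, and
#' rows with weight 0 are dropped, so a zero-weight sample gives exactly the
#' model refitted without that sample. Features are standardised with
#' weighted training-set means and standard deviations (stored in the
#' model), so heterogeneous volt-scaled features contribute comparably.
#'
#' @param X numeric matrix, samples x features.
#' @param y class labels (character or factor), length `nrow(X)`.
#' @param weights non-negative per-sample weights; default uniform.
#' @param C misclassification cost (> 0).
#' @param scaleFeatures standardise features with weighted statistics.
#' @param maxit L-BFGS-B iteration cap per binary problem.
#' @return A [LinearSVM-class] model.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
#' y <- rep(c("a", "b"), each = 20)
#' fit <- fitWeightedSVM(X, y)
#' mean(predict(fit, X) == y)  # 1
#' @export
fitWeightedSVM <- function(X, y, weights = NULL, C = 1, scaleFeatures = TRUE,
                           maxit = 300L) {
    X <- as.matrix(X)
    y <- as.character(y)
    if (length(y) != nrow(X))
        stop("X and y disagree in length")
    if (is.null(weights)) weights <- rep(1, nrow(X))
    if (length(weights) != nrow(X) || any(!is.finite(weights)) ||
        any(weights < 0))
        stop("weights must be finite, non-negative, one per sample")
    keep <- weights > 0
    if (sum(keep) == 0L)
        stop("total weight must be positive")
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    w <- weights[keep]
    classes <- sort(unique(y))
    if (length(classes) < 2L)
        stop("degenerate fit: training data contain a single class ('",
             classes, "')")
    w <- w * length(w) / sum(w)   # scale-invariance in the weights
    if (scaleFeatures) {
        ctr <- colSums(X * w) / sum(w)
        Xc <- sweep(X, 2, ctr)
        sc <- sqrt(colSums(Xc^2 * w) / sum(w))
        sc[sc < 1e-10] <- 1
    } else {
        ctr <- rep(0, ncol(X)); sc <- rep(1, ncol(X))
        Xc <- X
    }
    Xs <- sweep(Xc, 2, sc, "/")
    p <- ncol(Xs)
    W <- matrix(0, length(classes), p,
                dimnames = list(classes, colnames(X)))
    b <- numeric(length(classes))
    for (k in seq_along(classes)) {
        yk <- ifelse(y == classes[k], 1, -1)
        fit <- .fitBinarySquaredHinge(Xs, yk, w, C, maxit)
        W[k, ] <- fit$theta
        b[k] <- fit$b
    }
    new("LinearSVM", classes = classes, W = W, b = b,
        center = ctr, scale = sc, cost = C)
}

# Binary L2-regularised weighted squared-hinge SVM in the primal.
.fitBinarySquaredHinge <- function(Xs, y, w, C, maxit) {
    p <- ncol(Xs)
    obj <- function(par) {
        theta <- par[seq_len(p)]; b <- par[p + 1L]
        margin <- 1 - y * (drop(Xs %*% theta) + b)
        xi <- pmax(margin, 0)
        0.5 * sum(theta^2) + C * sum(w * xi^2)
    }
    grad <- function(par) {
        theta <- par[seq_len(p)]; b <- par[p + 1L]
        margin <- 1 - y * (drop(Xs %*% theta) + b)
        xi <- pmax(margin, 0)
        coefs <- -2 * C * w * xi * y
        c(theta + drop(crossprod(Xs, coefs)), sum(coefs))
    }
    res <- stats::optim(rep(0, p + 1L), obj, grad, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1e5))
    list(theta = res$par[seq_len(p)], b = res$par[p + 1L])
}

#' Predict classes with a fitted linear SVM
#'
#' @param object a [LinearSVM-class].
#' @param newdata numeric matrix, samples x features (same feature order as
#'   at fit time).
#' @param decisionValues return the per-class decision matrix instead of
#'   labels.
#' @param ... ignored.
#' @return character vector of predicted labels, or a samples x classes
#'   decision-value matrix.
#' @export
setMethod("predict", "LinearSVM",
    function(object, newdata, decisionValues = FALSE, ...) {
        newdata <- as.matrix(newdata)
        if (ncol(newdata) != ncol(object@W))
            stop("feature dimension mismatch: model has ", ncol(object@W),
                 ", data has ", ncol(newdata))
        Xs <- sweep(sweep(newdata, 2, object@center), 2, object@scale, "/")
        dec <- Xs %*% t(object@W)
        dec <- sweep(dec, 2, object@b, "+")
        colnames(dec) <- object@classes
        if (decisionValues) return(dec)
        # ties.method = "first": ties break to the lowest canonical label
        object@classes[max.col(dec, ties.method = "first")]
    })

#' Recognition accuracy
#'
#' Fraction of exact label matches.
#' @param predicted,truth equal-length label vectors.
#' @return numeric in `[0, 1]`.
#' @export
evaluateAccuracy <- function(predicted, truth) {
    if (length(predicted) != length(truth) || length(truth) == 0L)
        stop("predicted and truth must be non-empty and equal in length")
    mean(as.character(predicted) == as.character(truth))
}
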