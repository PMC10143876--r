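#' Source discount factor
#'
#' The fixed multiplicative discount applied to misclassified source-domain
#' sample weights in instance-based boosting transfer:
#' \deqn{\beta = \frac{1}{1 + \sqrt{2\ln(n_{source})/N}}.}
#' By convention `beta = 1` when the source set is empty (no source weights
#' to discount).
#'
#' @param nSource number of source-domain training samples.
#' @param N maximum boosting iterations.
#' @return numeric in (0, 1].
#' @examples
#' sourceDiscount(520, 50)  # ~0.6666
#' @export
sourceDiscount <- function(nSource, N) {
    if (nSource == 0) return(1)
    1 / (1 + sqrt(2 * log(nSource) / N))
}

#' Fit a multiclass TrAdaBoost ensemble
#'
#' Instance-based transfer learning: boosting over weighted linear SVMs on
#' the pooled source + target training set, where the two domains follow
#' opposite weight dynamics. Each iteration `t`:
#'
#' 1. normalise the pooled weights to sum 1;
#' 2. fit the base learner ([fitWeightedSVM()]) on the weighted pool;
#' 3. compute the weighted 0/1 error `eps_t` on target rows only
#'    (normalised by the total target weight);
#' 4. clip `eps_t` into `[epsMin, epsMax]` (the degenerate-error policy);
#' 5. set `beta_t = eps_t / (1 - eps_t)`;
#' 6. multiply misclassified source rows' weights by the fixed discount
#'    `beta` (decrease) and misclassified target rows' weights by
#'    `1 / beta_t` (increase).
#'
#' Source samples that keep disagreeing with the target concept are thus
#' progressively silenced, while hard target samples gain influence — the
#' mechanism that lets abundant out-of-domain data assist a small in-domain
#' training set. If the raw target error is >= 0.5 for more than
#' `maxBadRounds` consecutive rounds the ensemble stops early
#' (`nTrained < N`). With an empty source set the procedure reduces to
#' AdaBoost on the target data.
#'
#' The fit is deterministic: the base learner uses penalty weights (not
#' resampling) and a deterministic optimiser.
#'
#' @param sourceX,sourceY source-domain features (samples x features) and
#'   labels; may be empty (`NULL` or 0 rows).
#' @param targetX,targetY target-domain training features and labels; must
#'   be non-empty with >= 2 classes.
#' @param N maximum boosting iterations (>= 1).
#' @param C base-learner misclassification cost.
#' @param epsMin,epsMax clipping bounds keeping `beta_t` inside (0, 1).
#'   `epsMin = NULL` (the default) floors the error at
#'   `1 / (2 * n_target)`, a Laplace-style smoothing that caps the
#'   per-round target upweight and the vote weight when a round classifies
#'   every target training sample correctly — unavoidable whenever the
#'   target training set is much smaller than the feature dimension.
#' @param maxBadRounds consecutive raw-error >= 0.5 rounds tolerated before
#'   early stopping.
#' @param recordWeights attach the per-iteration weight trajectory (list of
#'   pre-/post-update weight vectors, the miss indicator and the row-origin
#'   flag) as attribute `"weightHistory"` of the result.
#' @return A [TrAdaBoostModel-class].
#' @seealso [sourceDiscount()], [tradaboostPredict()]
#' @export
tradaBoost <- function(sourceX, sourceY, targetX, targetY, N = 50L, C = 1,
                       epsMin = NULL, epsMax = 0.499, maxBadRounds = 5L,
                       recordWeights = FALSE) {
    if (is.null(sourceX)) {
        sourceX <- matrix(numeric(0), 0L, ncol(targetX))
        sourceY <- character(0)
    }
    sourceX <- as.matrix(sourceX); targetX <- as.matrix(targetX)
    sourceY <- as.character(sourceY); targetY <- as.character(targetY)
    if (nrow(targetX) == 0L)
        stop("target training set must be non-empty")
    if (length(unique(targetY)) < 2L)
        stop("target training set must contain at least 2 classes")
    N <- as.integer(N)
    if (N < 1L) stop("N must be >= 1")
    nS <- nrow(sourceX); nT <- nrow(targetX)
    if (is.null(epsMin)) epsMin <- 1 / (2 * sqrt(nT))
    X <- rbind(sourceX, targetX)
    y <- c(sourceY, targetY)
    isTarget <- c(rep(FALSE, nS), rep(TRUE, nT))
    beta <- sourceDiscount(nS, N)
    w <- rep(1 / (nS + nT), nS + nT)
    hyps <- vector("list", N)
    betaT <- numeric(N)
    badRun <- 0L
    nTrained <- 0L
    history <- if (recordWeights) vector("list", N) else NULL
    for (t in seq_len(N)) {
        w <- w / sum(w)
        h <- fitWeightedSVM(X, y, weights = w, C = C)
        pred <- predict(h, X)
        miss <- pred != y
        epsRaw <- sum(w[isTarget & miss]) / sum(w[isTarget])
        eps <- min(max(epsRaw, epsMin), epsMax)
        bt <- eps / (1 - eps)
        hyps[[t]] <- h
        betaT[t] <- bt
        nTrained <- t
        wPre <- w
        w[!isTarget & miss] <- w[!isTarget & miss] * beta
        w[isTarget & miss] <- w[isTarget & miss] / bt
        if (recordWeights)
            history[[t]] <- list(pre = wPre, post = w, miss = miss,
                                 isTarget = isTarget)
        if (epsRaw >= 0.5) {
            badRun <- badRun + 1L
            if (badRun > maxBadRounds) break
        } else badRun <- 0L
    }
    out <- new("TrAdaBoostModel", hypotheses = hyps[seq_len(nTrained)],
               betaT = betaT[seq_len(nTrained)], betaSource = beta, N = N,
               nTrained = nTrained, classes = sort(unique(y)))
    if (recordWeights)
        attr(out, "weightHistory") <- history[seq_len(nTrained)]
    out
}

# First iteration taking part in the final vote: the ensemble votes over
# the last half of the planned iterations, ceil(N/2)..nTrained; if early
# stopping ends before ceil(N/2), every completed iteration votes.
.voteStart <- function(model) {
    max(1L, min(as.integer(ceiling(model@N / 2)), model@nTrained))
}

#' Predict with a TrAdaBoost ensemble
#'
#' Weighted plurality vote over the hypotheses of the last half of the
#' iterations (`ceil(N/2)..nTrained`), each voting with weight
#' `ln(1 / beta_t)`; ties break to the lowest class label in canonical
#' order. In the binary case this vote is exactly the logarithm of the
#' classical product-form final hypothesis.
#'
#' @param object a [TrAdaBoostModel-class].
#' @param newdata numeric matrix, samples x features.
#' @param ... ignored.
#' @return character vector of predicted labels.
#' @export
setMethod("predict", "TrAdaBoostModel", function(object, newdata, ...) {
    tradaboostPredict(object, newdata)
})

#' @rdname predict-TrAdaBoostModel-method
#' @param model a [TrAdaBoostModel-class].
#' @param X numeric matrix, samples x features.
#' @export
tradaboostPredict <- function(model, X) {
    X <- as.matrix(X)
    if (model@nTrained < 1L)
        stop("model has no trained hypotheses")
    if (ncol(X) != ncol(model@hypotheses[[1L]]@W))
        stop("feature dimension mismatch")
    votes <- matrix(0, nrow(X), length(model@classes),
                    dimnames = list(NULL, model@classes))
    for (t in .voteStart(model):model@nTrained) {
        pred <- predict(model@hypotheses[[t]], X)
        wt <- log(1 / model@betaT[t])
        votes[cbind(seq_len(nrow(X)), match(pred, model@classes))] <-
            votes[cbind(seq_len(nrow(X)), match(pred, model@classes))] + wt
    }
    model@classes[max.col(votes, ties.method = "first")]
}
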