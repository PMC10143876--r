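# Internal helpers: seed streams and stratified index utilities.

# Deterministic child seed derived from a root seed and a stream name, so
# independent pipeline stages (generation, splits, subsets, ...) never share
# a random stream. Kept strictly below 2^31.
.childSeed <- function(seed, stream) {
    h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
    as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. seed = NULL uses (and advances) the global RNG.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Stratified interleaved ordering: shuffle within each stratum, then order
# all indices by within-stratum rank scaled by stratum size. Prefixes of the
# returned ordering are nested, approximately proportional stratified
# subsets for any requested size.
.stratifiedOrder <- function(labels) {
    labels <- as.character(labels)
    n <- length(labels)
    pos <- numeric(n)
    for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        # rank r of n_c maps to (r - u)/n_c with a small deterministic
        # per-class phase so ties across classes break reproducibly
        pos[idx] <- (seq_along(idx) - 0.5) / length(idx) +
            seq_along(idx) * 1e-9
    }
    order(pos)
}

# Exact-size stratified split: Tt train indices preserving class
# proportions (largest-remainder allocation), remainder is the test set.
.stratifiedSplit <- function(labels, Tt) {
    labels <- as.character(labels)
    n <- length(labels)
    classes <- sort(unique(labels))
    sizes <- vapply(classes, function(cl) sum(labels == cl), integer(1))
    if (any(sizes < 2L))
        stop("stratification impossible: class '",
             classes[which(sizes < 2L)[1L]], "' has fewer than 2 samples")
    if (Tt >= n)
        stop("Tt must be smaller than the number of samples")
    quota <- Tt * sizes / n
    take <- pmax(1L, floor(quota))
    rem <- Tt - sum(take)
    if (rem > 0) {
        extra <- order(quota - floor(quota), decreasing = TRUE)
        i <- 1L
        while (rem > 0) {
            k <- extra[(i - 1L) %% length(classes) + 1L]
            if (take[k] < sizes[k] - 1L) {
                take[k] <- take[k] + 1L
                rem <- rem - 1L
            }
            i <- i + 1L
        }
    } else if (rem < 0) {
        shrink <- order(quota - floor(quota))
        i <- 1L
        while (rem < 0) {
            k <- shrink[(i - 1L) %% length(classes) + 1L]
            if (take[k] > 1L) {
                take[k] <- take[k] - 1L
                rem <- rem + 1L
            }
            i <- i + 1L
        }
    }
    train <- integer(0)
    for (j in seq_along(classes)) {
        idx <- which(labels == classes[j])
        train <- c(train, idx[sample.int(length(idx), take[j])])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
}
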