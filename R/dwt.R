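# Periodised discrete wavelet transform (pyramid algorithm).
#
# Decomposition low-pass filters for the Daubechies family. db1 is the Haar
# pair; dbK has 2K taps and K vanishing moments. High-pass follows by the
# quadrature-mirror relation hi[j] = (-1)^j * lo[L - 1 - j].
.dbFilters <- list(
    db1 = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255126037, 0.22414386804201339,
            0.83651630373780790, 0.48296291314453416),
    db4 = c(-0.010597401785069032, 0.032883011666885206,
            0.030841381835560764, -0.187034811719093090,
            -0.027983769416859854, 0.630880767929858910,
            0.714846570552915700, 0.230377813308896500)
)

# One periodised analysis step: for even n, approximation coefficients
# cA[k] = sum_j lo[j] * x[(2k + L/2 - j) mod n], k = 0..n/2-1 (0-based).
.dwtStep <- function(x, lo) {
    n <- length(x)
    if (n %% 2L != 0L)
        stop("periodised DWT requires an even length at every level (got ", n, ")")
    L <- length(lo)
    k0 <- 2L * (seq_len(n %/% 2L) - 1L)
    idx <- outer(k0, (L %/% 2L) - (seq_len(L) - 1L), "+") %% n + 1L
    as.numeric(matrix(x[idx], ncol = L) %*% lo)
}

# Level-`level` approximation coefficients of the periodised DWT.
.dwtApprox <- function(x, wavelet = "db4", level = 3L) {
    lo <- .dbFilters[[wavelet]]
    if (is.null(lo))
        stop("unknown wavelet: '", wavelet, "' (available: ",
             paste(names(.dbFilters), collapse = ", "), ")")
    for (l in seq_len(level)) x <- .dwtStep(x, lo)
    x
}
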