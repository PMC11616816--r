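# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never clobbers the
# session stream.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Deterministic per-trial sub-seed, independent of trial order, so epoch
# simulation commutes with trial shuffling. Kept below 2^31.
trialSeed <- function(seed, index) {
    as.integer((as.double(seed) %% 2147483629 * 48271 + index * 16807) %%
                   2147483629) + 1L
}

# Half-open window [start, end) on a time axis in ms.
windowIndex <- function(times, window) {
    if (length(window) != 2L || window[2L] <= window[1L])
        stop("window must be an increasing (start, end) pair in ms")
    idx <- which(times >= window[1L] & times < window[2L])
    if (!length(idx))
        stop("window [", window[1L], ", ", window[2L],
             ") contains no samples")
    idx
}

stopifnotScalarProb <- function(p, name) {
    if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
        stop(name, " must be a probability in [0, 1]")
    invisible(p)
}
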