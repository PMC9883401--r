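# Deterministic derivation of component seeds from one master seed, so each
# simulator stage (or lncRNA-drug pair) can be regenerated independently.
# Kept below 2^31 - 1 (R integers are 32-bit).
.deriveSeed <- function(seed, key) {
    h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
    as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% 2147483629)
}

# Evaluate fn() under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
.withSeed <- function(seed, fn) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    fn()
}
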