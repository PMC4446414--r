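# Internal helpers: seeded evaluation and O(1) interval statistics on
# coverage tracks via prefix sums.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. seed = NULL runs unseeded.
withSeed <- function(seed, code) {
    if (is.null(seed))
        return(force(code))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had)
        old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Prefix sums over a coverage track. Returns, per strand, cumulative sums
# of the abundance, its square, and the zero indicator, each with a
# leading 0 so that interval [s, e] statistics are cs[e+1] - cs[s].
trackPrefix <- function(track) {
    mk <- function(v) {
        v <- as.numeric(v)
        list(sum = c(0, cumsum(v)),
             sq = c(0, cumsum(v * v)),
             zero = c(0, cumsum(v == 0)))
    }
    list("+" = mk(track@plus), "-" = mk(track@minus),
         len = length(track@plus))
}

# Vectorized interval sums on a prefix structure; empty intervals
# (e < s) contribute 0.
prefixSum <- function(cs, s, e) {
    out <- cs[pmax(e, s - 1L) + 1L] - cs[s]
    out[e < s] <- 0
    out
}

# Interval statistics on one strand of a prefix structure.
# Returns length, sum, zero-count, sum of squares (vectorized over s/e).
intervalStats <- function(pre, strand, s, e) {
    p <- pre[[strand[1L]]]
    if (length(unique(strand)) > 1L) {
        n <- pmax(e - s + 1L, 0L)
        out <- list(n = n, sum = numeric(length(s)),
                    zero = numeric(length(s)), sq = numeric(length(s)))
        for (st in unique(strand)) {
            i <- strand == st
            out$sum[i] <- prefixSum(pre[[st]]$sum, s[i], e[i])
            out$zero[i] <- prefixSum(pre[[st]]$zero, s[i], e[i])
            out$sq[i] <- prefixSum(pre[[st]]$sq, s[i], e[i])
        }
        return(out)
    }
    list(n = pmax(e - s + 1L, 0L),
         sum = prefixSum(p$sum, s, e),
         zero = prefixSum(p$zero, s, e),
         sq = prefixSum(p$sq, s, e))
}

# Mean abundance of intervals; empty intervals give 0.
intervalMean <- function(pre, strand, s, e) {
    st <- intervalStats(pre, strand, s, e)
    ifelse(st$n > 0L, st$sum / st$n, 0)
}

# Expression ratio between two region means: (max + eps) / (min + eps).
exprRatio <- function(a, b, eps = 1) {
    (pmax(a, b) + eps) / (pmin(a, b) + eps)
}

stopIfNot <- function(cond, msg) {
    if (!cond) stop(msg, call. = FALSE)
}
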