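# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, code) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# "34 of 57" -> "59.65%"; percentages reported to 2 decimals.
formatPct <- function(k, n) sprintf("%.2f%%", 100 * k / n)

.checkCount <- function(x, name, min = 0L) {
    if (length(x) != 1L || is.na(x) || x != round(x) || x < min)
        stop("'", name, "' must be a single integer >= ", min)
    as.integer(x)
}

zeroPad <- function(i, n) sprintf(paste0("%0", nchar(as.character(n)), "d"), i)
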