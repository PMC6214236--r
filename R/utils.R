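## Internal helpers shared across modules.

## Connected components of the site graph induced by fragments: two sites
## are linked when some fragment covers both. Plain union-find with path
## compression; fragments connect all their sites through the first one.
.fragmentComponents <- function(siteLists, n) {
    parent <- seq_len(n)
    find <- function(x) {
        while (parent[x] != x) {
            parent[x] <<- parent[parent[x]]
            x <- parent[x]
        }
        x
    }
    for (s in siteLists) {
        if (length(s) < 2L) next
        r <- find(s[1L])
        for (k in s[-1L]) {
            rk <- find(k)
            if (rk != r) parent[rk] <- r
        }
    }
    vapply(seq_len(n), find, integer(1L))
}

## Coerce a haplotype given as "0100", "01-0" or an integer/numeric vector
## (NA or '-' marking unphased sites) to an integer vector with NA gaps.
.asHap <- function(x) {
    if (is.character(x) && length(x) == 1L) {
        ch <- strsplit(x, "")[[1L]]
        out <- suppressWarnings(as.integer(ch))
        if (!all(ch %in% c("0", "1", "-")))
            stop("haplotype strings may only contain 0, 1 and -")
        return(out)
    }
    out <- as.integer(x)
    if (!all(out %in% c(0L, 1L, NA_integer_)))
        stop("haplotype alleles must be 0, 1 or NA")
    out
}

## Deterministic derived seeds below 2^31 for reproducible sub-streams.
.deriveSeeds <- function(seed, n) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
}
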