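## Internal helpers shared across modules.

## round-half-up to `digits` decimals (base round() is round-half-even;
## printed report tables use conventional half-up rounding)
roundHalfUp <- function(x, digits = 2) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

## random DNA of length n at a given GC fraction, as a character scalar
randomDnaChr <- function(n, gc) {
    if (n == 0) return("")
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

randomProteinChr <- function(n) paste(sample(AA20, n, replace = TRUE),
                                      collapse = "")

## substitute exactly `k` positions (sampled from `pool`, or 1:n) of a
## character-vector sequence with a different symbol from `alphabet`
substitutePositions <- function(chars, pos, alphabet) {
    for (i in pos) {
        alt <- setdiff(alphabet, chars[i])
        chars[i] <- alt[sample.int(length(alt), 1L)]
    }
    chars
}

## numeric rolling k-mer codes (base 4) for a DNA character scalar.
## Returns a vector of length L - k + 1; positions touching a non-ACGT
## base get NA. Codes fit exactly in doubles for k <= 26.
kmerCodes <- function(seqChr, k) {
    v <- utf8ToInt(seqChr)
    base <- rep(NA_real_, length(v))
    base[v == 65L] <- 0  # A
    base[v == 67L] <- 1  # C
    base[v == 71L] <- 2  # G
    base[v == 84L] <- 3  # T
    L <- length(base)
    if (L < k) return(numeric(0))
    n <- L - k + 1L
    code <- numeric(n)
    for (j in 0:(k - 1)) code <- code + base[(1 + j):(n + j)] * 4^(k - 1 - j)
    code
}

## disjoint union-find used for single-linkage clustering
ufFind <- function(parent, i) {
    while (parent[i] != i) {
        parent[i] <- parent[parent[i]]
        i <- parent[i]
    }
    i
}

ufComponents <- function(n, edges) {
    parent <- seq_len(n)
    if (nrow(edges)) for (e in seq_len(nrow(edges))) {
        ri <- ufFind(parent, edges[e, 1])
        rj <- ufFind(parent, edges[e, 2])
        if (ri != rj) parent[rj] <- ri
    }
    vapply(seq_len(n), function(i) ufFind(parent, i), integer(1))
}

## split a sorted numeric vector into groups wherever the gap exceeds `maxGap`
splitByGap <- function(x, maxGap) {
    if (!length(x)) return(integer(0))
    cumsum(c(1L, as.integer(diff(x) > maxGap)))
}

chrNames <- function(genome) names(genome)

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
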