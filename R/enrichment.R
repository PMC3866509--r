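#' Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric tail probability for the table
#' `(a, b; c, d)` = (in-set & in-category, in-set & not, out & in-category,
#' out & not). The one-sided `greater` alternative tests over-representation
#' of the category in the set; the two-sided p sums the probabilities of all
#' tables with fixed margins that are no more probable than the observed one.
#'
#' @param a,b,c,d non-negative integer cells
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`
#' @return p-value
#' @export
fisherExact <- function(a, b, c, d, alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    cells <- c(a, b, c, d)
    stopIfNot(all(cells >= 0) && all(cells == round(cells)),
              "cells must be non-negative integers")
    K <- a + c          # category size
    n <- a + b          # set size
    N <- a + b + c + d  # universe
    if (N == 0) return(1)
    if (alternative == "greater")
        return(phyper(a - 1, K, N - K, n, lower.tail = FALSE))
    xs <- max(0, n - (N - K)):min(n, K)
    px <- dhyper(xs, K, N - K, n)
    sum(px[px <= dhyper(a, K, N - K, n) * (1 + 1e-7)])
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i}
#' (m * p_(j) / j)` over the sorted p-values, returned in input order and
#' capped at 1.
#'
#' @param p vector of p-values in \[0, 1\]
#' @return q-values, monotone non-decreasing in p-value rank
#' @export
bhFdr <- function(p) {
    stopIfNot(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
    m <- length(p)
    if (!m) return(numeric(0))
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
}

#' Gene-set enrichment over categories
#'
#' One-sided Fisher exact test of each category's over-representation in the
#' gene set against the universe, with Benjamini-Hochberg FDR control.
#' Categories without any set member are skipped before the FDR correction
#' (reducing the number of tests); the default FDR threshold of 0.25 is the
#' permissive level conventional for subtelomeric gene-family screens.
#'
#' @param geneSet character vector of gene ids (must be a non-empty subset
#'   of the universe)
#' @param categoryMap data.frame `gene_id`, `category`
#' @param universe character vector of all gene ids
#' @param fdr FDR threshold for the `enriched` flag (default 0.25)
#' @param dropEmpty skip categories with no set member before FDR (default
#'   `TRUE`)
#' @return data.frame: `category`, `a`, `b`, `c`, `d`, `p`, `q`, `enriched`,
#'   ordered by p-value
#' @export
geneSetEnrichment <- function(geneSet, categoryMap, universe, fdr = 0.25,
                              dropEmpty = TRUE) {
    stopIfNot(length(geneSet) > 0, "empty gene set")
    stopIfNot(all(geneSet %in% universe), "gene set must be within universe")
    geneSet <- unique(geneSet)
    universe <- unique(universe)
    cm <- categoryMap[categoryMap$gene_id %in% universe, , drop = FALSE]
    rows <- lapply(split(cm$gene_id, cm$category), function(memb) {
        memb <- unique(memb)
        a <- sum(memb %in% geneSet)
        data.frame(a = a, b = length(geneSet) - a,
                   c = length(memb) - a,
                   d = length(universe) - length(geneSet) - length(memb) + a)
    })
    out <- do.call(rbind, rows)
    out <- cbind(data.frame(category = names(rows), stringsAsFactors = FALSE),
                 out)
    if (dropEmpty) out <- out[out$a > 0, , drop = FALSE]
    stopIfNot(nrow(out) > 0, "no category has a member in the gene set")
    out$p <- vapply(seq_len(nrow(out)), function(i)
        fisherExact(out$a[i], out$b[i], out$c[i], out$d[i]), numeric(1))
    out$q <- bhFdr(out$p)
    out$enriched <- out$q < fdr
    rownames(out) <- NULL
    out[order(out$p, out$category), , drop = FALSE]
}
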