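# Independent brute-force oracles used to validate the production code.

# O(N * |S|) enrichment walk: recomputes P_hit(S, i) and P_miss(S, i) from
# scratch at every position, straight from the defining sums.
naiveEnrichmentScore <- function(metric, hit, p = 1) {
    N <- length(metric)
    stopifnot(length(hit) == N, !is.unsorted(rev(metric)))
    NR <- sum(abs(metric[hit])^p)
    NH <- sum(hit)
    D <- numeric(N)
    for (i in seq_len(N)) {
        phit <- sum(abs(metric[seq_len(i)][hit[seq_len(i)]])^p) / NR
        pmiss <- sum(!hit[seq_len(i)]) / (N - NH)
        D[i] <- phit - pmiss
    }
    # same documented tie-break as the production code: positive peak wins
    dPos <- max(D)
    dNeg <- min(D)
    list(es = if (dPos + dNeg >= -1e-12) dPos else dNeg, walk = D)
}

# Textbook step-up BH, written independently of stats::p.adjust.
naiveBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# Exact upper-tail hypergeometric by enumeration over all feasible overlaps.
naiveHyperUpper <- function(k, nB, M, nA) {
    ks <- max(0, nA + nB - M):min(nA, nB)
    probs <- choose(nB, ks) * choose(M - nB, nA - ks) / choose(M, nA)
    sum(probs[ks >= k])
}

# Plain-string IUPAC consensus scan, independent of Biostrings.
naiveMotifCount <- function(seq, pattern = "DRACH") {
    map <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
             R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
             K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
             H = "[ACT]", V = "[ACG]", N = "[ACGTN]")
    seq <- chartr("Uu", "Tt", toupper(seq))
    rex <- paste0("(?=", paste(map[strsplit(toupper(pattern), "")[[1]]],
                               collapse = ""), ")")
    m <- gregexpr(rex, seq, perl = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
}

# Plain-string normalized CpG, independent of Biostrings.
naiveNormCpG <- function(seq) {
    ch <- strsplit(seq, "")[[1]]
    keep <- ch != "N"
    gc <- sum(ch[keep] %in% c("G", "C")) / sum(keep)
    if (gc == 0 || length(ch) < 2) return(NA_real_)
    di <- paste0(ch[-length(ch)], ch[-1])
    (sum(di == "CG") / (length(ch) - 1)) / (gc / 2)^2
}

makeRanked <- function(metric, genes = sprintf("g%03d", seq_along(metric)),
                       drugId = "drug") {
    o <- order(-metric, genes)
    new("RankedGenes", genes = genes[o], metric = metric[o], drugId = drugId)
}

tempfileFasta <- function(sq) {
    f <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(sq$sequences, f)
    f
}

# Small helper building an M6AExpression straight from a numeric matrix.
exprFromMatrix <- function(values, roles, transformed = TRUE) {
    M6AExpression(values, roles, transformed = transformed)
}
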