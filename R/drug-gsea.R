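#' Rank mRNAs by correlation with drug IC50
#'
#' Computes, for every mRNA, the Pearson correlation between its log2
#' expression and the per-sample IC50 of one drug over pairwise-complete
#' samples, and returns the genes sorted by that correlation in descending
#' order. Genes whose expression most tracks resistance (high IC50) rank
#' first. Ties are broken lexicographically by gene id so the ranking is
#' deterministic.
#'
#' @param expr a log2-transformed [M6AExpression-class]; only rows with role
#'   \code{"mRNA"} are ranked.
#' @param ic50 numeric vector of IC50 values named by sample id; missing
#'   entries are dropped (pairwise-complete use). Fewer than 3 complete
#'   samples is an error.
#' @param drugId label stored with the ranking.
#' @return a [RankedGenes-class].
#' @export
rankByDrug <- function(expr, ic50, drugId = "drug") {
    stopifnot(is(expr, "M6AExpression"))
    if (!isTransformed(expr))
        stop("drug ranking requires a log2-transformed expression matrix")
    if (is.null(names(ic50)))
        stop("ic50 must be named by sample id")
    roles <- geneRoles(expr)
    genes <- names(roles)[roles == "mRNA"]
    if (!length(genes)) stop("no mRNA rows in the expression matrix")
    common <- intersect(colnames(expr), names(ic50)[!is.na(ic50)])
    if (length(common) < 3L)
        stop("fewer than 3 samples with both expression and IC50")
    v <- exprValues(expr)[genes, common, drop = FALSE]
    y <- ic50[common]
    if (stats::sd(y) == 0)
        stop("IC50 vector is constant: ranking correlation undefined")
    const <- apply(v, 1L, stats::sd) == 0
    if (any(const)) {
        warning(sum(const), " constant mRNA(s) dropped from the ranking")
        v <- v[!const, , drop = FALSE]
        genes <- genes[!const]
    }
    r <- as.vector(stats::cor(t(v), y))
    o <- order(-r, genes)
    new("RankedGenes", genes = genes[o], metric = r[o], drugId = drugId)
}

# Core running-sum walk. hitIdx: integer positions of hits in the ranking;
# w: |metric|^p weights for all positions.
.esWalk <- function(hitIdx, w, N) {
    nh <- length(hitIdx)
    NR <- sum(w[hitIdx])
    stepv <- rep.int(-1 / (N - nh), N)
    stepv[hitIdx] <- w[hitIdx] / NR
    cumsum(stepv)
}

# Signed extreme of the walk. When the positive peak and the negative
# trough have equal magnitude (to within 1e-12; this arises structurally,
# e.g. a single mid-list hit), the positive peak wins - a documented,
# deterministic tie-break.
.esFromWalk <- function(D) {
    dPos <- max(D)
    dNeg <- min(D)
    if (dPos + dNeg >= -1e-12) dPos else dNeg
}

#' Weighted enrichment score of a gene set against a ranking
#'
#' Runs the weighted Kolmogorov-Smirnov walk over the ranked list: at each
#' position the running sum gains \eqn{|r_j|^p / N_R} when the gene is in
#' the set ("hit", with \eqn{N_R = \sum_{g_j \in S} |r_j|^p}) and loses
#' \eqn{1 / (N - N_H)} otherwise ("miss"). The enrichment score is the
#' signed value of the walk at its maximal absolute deviation from zero
#' (when the positive peak and the negative trough tie in magnitude, the
#' positive peak is taken); the walk always returns to zero at the end of
#' the list.
#'
#' @param ranked a [RankedGenes-class].
#' @param set character vector, a subset of the ranked genes; the empty set
#'   and the full gene list are errors (the walk is undefined).
#' @param weightP weight exponent p, default 1.
#' @param useAbs logical; weight hits by |r|^p (default, the canonical
#'   weighted-KS convention) or by r^p.
#' @return list with \code{es} (in \[-1, 1\]), \code{walk} (the running
#'   sum), \code{index} (position of the extreme), \code{nHits}.
#' @examples
#' rg <- new("RankedGenes", genes = paste0("g", 1:4),
#'           metric = c(4, 3, 2, 1), drugId = "d")
#' enrichmentScore(rg, "g2")$es  # 2/3
#' @export
enrichmentScore <- function(ranked, set, weightP = 1, useAbs = TRUE) {
    stopifnot(is(ranked, "RankedGenes"))
    N <- length(ranked@genes)
    set <- unique(set)
    unknown <- setdiff(set, ranked@genes)
    if (length(unknown))
        stop("set contains genes absent from the ranking: ", unknown[1L])
    nh <- length(set)
    if (nh == 0L || nh == N)
        stop("gene set must be a non-empty proper subset of the ranking")
    w <- if (useAbs) abs(ranked@metric)^weightP else ranked@metric^weightP
    hitIdx <- which(ranked@genes %in% set)
    if (sum(w[hitIdx]) <= 0)
        stop("total hit weight N_R is not positive: walk undefined")
    D <- .esWalk(hitIdx, w, N)
    es <- .esFromWalk(D)
    list(es = es, walk = D, index = which.max(D * sign(es)), nHits = nh)
}

#' Permutation p-value for an enrichment score
#'
#' Draws \code{B} random gene sets of the same size uniformly without
#' replacement from the ranked genes, recomputes the enrichment score for
#' each, and estimates the significance of the observed score against the
#' same-signed portion of the null:
#' p = (1 + #\{b : sign match and |ES_b| >= |ES_obs|\}) /
#'     (1 + #\{b : sign match\}).
#' Conditioning on the sign keeps the sign-specific calls calibrated, and
#' the add-one form keeps p >= 1/(B+1) (never zero). An observed score of
#' exactly zero returns p = 1.
#'
#' @param ranked a [RankedGenes-class].
#' @param set gene set as in [enrichmentScore()].
#' @param B number of permutations (>= 1), default 1000.
#' @param seed optional integer; when supplied the draw is reproducible and
#'   the caller's RNG state is restored afterwards.
#' @param weightP,useAbs passed to [enrichmentScore()].
#' @return list with \code{p} and \code{es} (the observed score).
#' @export
permutationPvalue <- function(ranked, set, B = 1000, seed = NULL,
                              weightP = 1, useAbs = TRUE) {
    if (B < 1) stop("B must be >= 1")
    obs <- enrichmentScore(ranked, set, weightP = weightP, useAbs = useAbs)
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit(if (!is.null(old))
            assign(".Random.seed", old, envir = globalenv()), add = TRUE)
        set.seed(seed)
    }
    N <- length(ranked@genes)
    w <- if (useAbs) abs(ranked@metric)^weightP else ranked@metric^weightP
    nh <- obs$nHits
    esNull <- vapply(seq_len(B), function(b) {
        idx <- sample.int(N, nh)
        .esFromWalk(.esWalk(idx, w, N))
    }, numeric(1))
    p <- .splitNullP(obs$es, esNull)
    list(p = p, es = obs$es)
}

.splitNullP <- function(esObs, esNull) {
    if (esObs == 0) return(1)
    same <- sign(esNull) == sign(esObs)
    (1 + sum(same & abs(esNull) >= abs(esObs))) / (1 + sum(same))
}

#' Call drug-resistant and drug-sensitive lncRNAs
#'
#' Benjamini-Hochberg adjustment of the permutation p-values over all
#' lncRNA-drug pairs of one screen, then: positive enrichment score with
#' q below the threshold = \code{"resistant"}, negative with q below =
#' \code{"sensitive"}, otherwise \code{"ns"}.
#'
#' @param results data.frame with at least columns \code{es} and
#'   \code{p_perm} (one row per lncRNA-drug pair).
#' @param qMax FDR threshold, default 0.05.
#' @return the input with added columns \code{q} and \code{call}.
#' @export
callDrugAssociations <- function(results, qMax = 0.05) {
    if (nrow(results) == 0L) {
        results$q <- numeric(0)
        results$call <- character(0)
        return(results)
    }
    results$q <- bhAdjust(results$p_perm)
    results$call <- ifelse(
        results$q < qMax,
        ifelse(results$es > 0, "resistant", "sensitive"), "ns")
    results$call[results$es == 0] <- "ns"
    results
}

#' Screen lncRNA ceRNA sets against a panel of drugs
#'
#' For every drug, ranks the mRNAs by IC50 correlation once, then scores
#' each lncRNA's ceRNA target set with the enrichment walk and a permutation
#' null, and finally calls resistant/sensitive associations with BH control
#' over all pairs of the screen.
#'
#' @param sets named list of mRNA gene sets (e.g. a
#'   [CeRNANetwork-class]'s target sets), or a [CeRNANetwork-class].
#' @param expr a log2-transformed [M6AExpression-class].
#' @param drugs drug-by-sample IC50 matrix (see [readDrugResponse()]).
#' @param B permutations per pair, default 1000.
#' @param seed integer; per-pair seeds are derived deterministically.
#' @param weightP,useAbs passed to [enrichmentScore()].
#' @param qMax FDR threshold for the calls, default 0.05.
#' @return data.frame with one row per lncRNA-drug pair: \code{lncrna_id},
#'   \code{drug_id}, \code{es}, \code{n_hits}, \code{p_perm}, \code{q},
#'   \code{call}. Pairs whose target set has no gene in the ranking are
#'   dropped with a warning.
#' @export
drugScreen <- function(sets, expr, drugs, B = 1000, seed = 1,
                       weightP = 1, useAbs = TRUE, qMax = 0.05) {
    if (is(sets, "CeRNANetwork")) sets <- sets@targetSets
    if (!length(sets)) stop("no lncRNA target sets supplied")
    rows <- list()
    nDropped <- 0L
    for (d in rownames(drugs)) {
        ranked <- rankByDrug(expr, drugs[d, ], drugId = d)
        for (l in names(sets)) {
            s <- intersect(sets[[l]], ranked@genes)
            if (length(s) == 0L || length(s) == length(ranked@genes)) {
                nDropped <- nDropped + 1L
                next
            }
            pp <- permutationPvalue(
                ranked, s, B = B,
                seed = .deriveSeed(seed, paste(d, l, sep = "|")),
                weightP = weightP, useAbs = useAbs)
            rows[[length(rows) + 1L]] <- data.frame(
                lncrna_id = l, drug_id = d, es = pp$es,
                n_hits = length(s), p_perm = pp$p,
                stringsAsFactors = FALSE)
        }
    }
    if (nDropped)
        warning(nDropped, " lncRNA-drug pair(s) dropped: degenerate target set")
    res <- if (length(rows)) do.call(rbind, rows) else
        data.frame(lncrna_id = character(), drug_id = character(),
                   es = numeric(), n_hits = integer(), p_perm = numeric(),
                   stringsAsFactors = FALSE)
    callDrugAssociations(res, qMax = qMax)
}
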