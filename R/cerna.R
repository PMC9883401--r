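#' Candidate lncRNA-miRNA-mRNA axes
#'
#' Enumerates every triple in which one miRNA experimentally targets both a
#' lncRNA from the m6A-related set and an mRNA, by joining the
#' miRNA-lncRNA and miRNA-mRNA halves of the interaction catalog on the
#' shared miRNA. An empty result is allowed.
#'
#' @param catalog interaction data.frame (columns \code{mirna_id},
#'   \code{target_id}, \code{target_class}).
#' @param relatedLncrnas character vector of m6A-related lncRNA ids; only
#'   these appear on the lncRNA side.
#' @return data.frame with columns \code{lncrna_id}, \code{mirna_id},
#'   \code{mrna_id}, unique rows.
#' @export
candidateAxes <- function(catalog, relatedLncrnas) {
    lncHalf <- catalog[catalog$target_class == "lncRNA" &
                       catalog$target_id %in% relatedLncrnas, ]
    mrnaHalf <- catalog[catalog$target_class == "mRNA", ]
    if (nrow(lncHalf) == 0L || nrow(mrnaHalf) == 0L)
        return(data.frame(lncrna_id = character(), mirna_id = character(),
                          mrna_id = character(), stringsAsFactors = FALSE))
    ax <- merge(
        data.frame(mirna_id = lncHalf$mirna_id,
                   lncrna_id = lncHalf$target_id, stringsAsFactors = FALSE),
        data.frame(mirna_id = mrnaHalf$mirna_id,
                   mrna_id = mrnaHalf$target_id, stringsAsFactors = FALSE),
        by = "mirna_id")
    ax <- unique(ax[, c("lncrna_id", "mirna_id", "mrna_id")])
    rownames(ax) <- NULL
    ax
}

#' Filter candidate axes into a ceRNA network
#'
#' Applies the ceRNA sign/threshold rules on the log2 expression matrix:
#' a triple is retained when the lncRNA-mRNA correlation is positive
#' (r > \code{rMin}, q < \code{qMax}) and both miRNA-lncRNA and miRNA-mRNA
#' correlations are negative (r < -\code{rMin}, q < \code{qMax}).
#' Benjamini-Hochberg adjustment uses two families within the cohort: all
#' tested miRNA-target correlations form one family and all lncRNA-mRNA
#' correlations the other. Axes naming molecules absent from the matrix are
#' skipped with a warning (catalog/matrix mismatch is expected in practice).
#'
#' @param axes candidate axes from [candidateAxes()].
#' @param expr a log2-transformed [M6AExpression-class] containing lncRNA,
#'   miRNA and mRNA rows.
#' @param rMin correlation magnitude threshold (strict), default 0.3.
#' @param qMax FDR threshold (strict), default 0.05.
#' @param cancerId cohort label.
#' @return a [CeRNANetwork-class].
#' @export
filterTriples <- function(axes, expr, rMin = 0.3, qMax = 0.05,
                          cancerId = "cancer") {
    stopifnot(is(expr, "M6AExpression"))
    if (!isTransformed(expr))
        stop("ceRNA filtering requires a log2-transformed expression matrix")
    empty <- new("CeRNANetwork", triples = .emptyTriples(),
                 targetSets = list(), cancerId = cancerId)
    if (nrow(axes) == 0L) return(empty)
    v <- exprValues(expr)
    present <- axes$lncrna_id %in% rownames(v) &
        axes$mirna_id %in% rownames(v) & axes$mrna_id %in% rownames(v)
    if (any(!present)) {
        warning(sum(!present),
                " axis/axes skipped: molecule absent from expression matrix")
        axes <- axes[present, , drop = FALSE]
        if (nrow(axes) == 0L) return(empty)
    }
    n <- ncol(v)
    corP <- function(aIds, bIds) {
        keys <- unique(paste(aIds, bIds, sep = "\r"))
        parts <- strsplit(keys, "\r", fixed = TRUE)
        aa <- vapply(parts, `[`, character(1), 1L)
        bb <- vapply(parts, `[`, character(1), 2L)
        r <- vapply(seq_along(aa), function(i)
            stats::cor(v[aa[i], ], v[bb[i], ]), numeric(1))
        data.frame(key = keys, r = r, p = .pearsonP(r, n),
                   stringsAsFactors = FALSE)
    }
    lm <- corP(axes$lncrna_id, axes$mrna_id)    # lncRNA-mRNA family
    ml <- corP(axes$mirna_id, axes$lncrna_id)   # miRNA-target family...
    mm <- corP(axes$mirna_id, axes$mrna_id)     # ...both halves together
    lm$q <- bhAdjust(lm$p)
    mirFam <- bhAdjust(c(ml$p, mm$p))
    ml$q <- mirFam[seq_len(nrow(ml))]
    mm$q <- mirFam[nrow(ml) + seq_len(nrow(mm))]
    key <- function(a, b) paste(a, b, sep = "\r")
    iLM <- match(key(axes$lncrna_id, axes$mrna_id), lm$key)
    iML <- match(key(axes$mirna_id, axes$lncrna_id), ml$key)
    iMM <- match(key(axes$mirna_id, axes$mrna_id), mm$key)
    tr <- data.frame(
        cancer_id = cancerId,
        lncrna_id = axes$lncrna_id, mirna_id = axes$mirna_id,
        mrna_id = axes$mrna_id,
        r_lnc_mrna = lm$r[iLM], q_lnc_mrna = lm$q[iLM],
        r_mir_lnc = ml$r[iML], q_mir_lnc = ml$q[iML],
        r_mir_mrna = mm$r[iMM], q_mir_mrna = mm$q[iMM],
        stringsAsFactors = FALSE)
    keep <- tr$r_lnc_mrna > rMin & tr$q_lnc_mrna < qMax &
        tr$r_mir_lnc < -rMin & tr$q_mir_lnc < qMax &
        tr$r_mir_mrna < -rMin & tr$q_mir_mrna < qMax
    tr <- tr[keep, , drop = FALSE]
    rownames(tr) <- NULL
    sets <- if (nrow(tr))
        lapply(split(tr$mrna_id, tr$lncrna_id), function(x) unique(x))
    else list()
    new("CeRNANetwork", triples = tr, targetSets = sets, cancerId = cancerId)
}

.emptyTriples <- function() {
    data.frame(cancer_id = character(), lncrna_id = character(),
               mirna_id = character(), mrna_id = character(),
               r_lnc_mrna = numeric(), q_lnc_mrna = numeric(),
               r_mir_lnc = numeric(), q_mir_lnc = numeric(),
               r_mir_mrna = numeric(), q_mir_mrna = numeric(),
               stringsAsFactors = FALSE)
}

#' ceRNA target set of a lncRNA
#'
#' The deduplicated set of mRNA partners of one lncRNA over all its retained
#' triples - the "hit" gene set scored against drug IC50 rankings.
#'
#' @param x a [CeRNANetwork-class].
#' @param lncrnaId a lncRNA id present in the network (unknown id is an
#'   error).
#' @return character vector of mRNA ids.
#' @name targetSet
#' @aliases targetSet,CeRNANetwork-method
#' @export
setMethod("targetSet", "CeRNANetwork", function(x, lncrnaId) {
    if (!lncrnaId %in% names(x@targetSets))
        stop(sprintf("lncRNA '%s' is not in the ceRNA network", lncrnaId))
    x@targetSets[[lncrnaId]]
})

#' Triples of a ceRNA network
#'
#' @param x a [CeRNANetwork-class].
#' @return the triples data.frame.
#' @export
cernaTriples <- function(x) {
    stopifnot(is(x, "CeRNANetwork"))
    x@triples
}
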