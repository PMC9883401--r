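#' Classify lncRNAs as cancer-common or cancer-specific
#'
#' Counts, per lncRNA, the cancers in which it has at least one passing
#' screen record. lncRNAs significant in (at least the configurable
#' fraction of) all analysed cancers are \code{"common"}, in exactly one
#' \code{"specific"} (the cancer is recorded), otherwise
#' \code{"intermediate"}. The three labels partition the lncRNAs with at
#' least one record.
#'
#' @param records screen records row-bound across cancers (output of
#'   [screenRegulators()] per cohort).
#' @param cancers character vector of all analysed cancer ids (>= 2);
#'   every cancer appearing in \code{records} must be listed.
#' @param commonMinFraction minimum fraction of the analysed cancers for
#'   the common label, default 1 (literally all). The common rule takes
#'   precedence if a lenient fraction makes both labels apply.
#' @return data.frame: \code{lncrna_id}, \code{n_cancers_significant},
#'   \code{label}, \code{specific_cancer} (\code{NA} unless specific),
#'   \code{n_regulators} (distinct regulators across all cancers).
#' @export
classifyLncrnas <- function(records, cancers, commonMinFraction = 1) {
    if (length(cancers) < 2L)
        stop("classification requires at least 2 cancers")
    if (anyDuplicated(cancers)) stop("duplicate cancer ids")
    extra <- setdiff(unique(records$cancer_id), cancers)
    if (length(extra))
        stop("records reference cancers not in the cancer list: ",
             paste(extra, collapse = ", "))
    if (commonMinFraction <= 0 || commonMinFraction > 1)
        stop("commonMinFraction must lie in (0, 1]")
    if (nrow(records) == 0L)
        return(data.frame(lncrna_id = character(),
                          n_cancers_significant = integer(),
                          label = character(), specific_cancer = character(),
                          n_regulators = integer(), stringsAsFactors = FALSE))
    byLnc <- split(records, records$lncrna_id)
    commonMin <- ceiling(commonMinFraction * length(cancers))
    out <- do.call(rbind, lapply(byLnc, function(d) {
        cc <- unique(d$cancer_id)
        nC <- length(cc)
        label <- if (nC >= commonMin) "common"
        else if (nC == 1L) "specific"
        else "intermediate"
        data.frame(lncrna_id = d$lncrna_id[1L],
                   n_cancers_significant = nC,
                   label = label,
                   specific_cancer = if (label == "specific") cc else
                       NA_character_,
                   n_regulators = length(unique(d$regulator_id)),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Between-cancer expression deviation of a lncRNA
#'
#' Default (\code{mode = "sd"}): the sample standard deviation, across
#' cancers, of the per-cancer mean log2 expression - low values mark
#' lncRNAs expressed at a stable level across tumor types. Alternative
#' (\code{mode = "cv"}): coefficient of variation over all samples pooled.
#' A lncRNA present in fewer than 2 cohorts has an undefined deviation,
#' returned as \code{NA} with a warning.
#'
#' @param exprList named list of [M6AExpression-class] objects, one per
#'   cancer.
#' @param lncrnaId gene id to profile.
#' @param mode \code{"sd"} (default) or \code{"cv"}.
#' @return numeric(1), or \code{NA} when undefined.
#' @export
expressionDeviation <- function(exprList, lncrnaId, mode = c("sd", "cv")) {
    mode <- match.arg(mode)
    has <- vapply(exprList, function(e) lncrnaId %in% rownames(e), logical(1))
    if (sum(has) < 2L) {
        warning(sprintf(
            "lncRNA '%s' present in fewer than 2 cohorts: deviation undefined",
            lncrnaId))
        return(NA_real_)
    }
    vals <- lapply(exprList[has], function(e) exprValues(e)[lncrnaId, ])
    if (mode == "sd") {
        stats::sd(vapply(vals, mean, numeric(1)))
    } else {
        pooled <- unlist(vals, use.names = FALSE)
        stats::sd(pooled) / mean(pooled)
    }
}

#' Hypergeometric enrichment of one gene set in another
#'
#' Upper-tail hypergeometric test P(X >= k) for the overlap k between a
#' query set (draws) and an annotation set (successes) within a finite
#' universe, e.g. cancer-specific lncRNAs against tissue-elevated lncRNAs.
#'
#' @param setA query set (character), a subset of \code{universe}.
#' @param setB annotation set (character), a subset of \code{universe}.
#' @param universe character vector of all eligible ids.
#' @return list with \code{k} (overlap), \code{nA}, \code{nB}, \code{M}
#'   (universe size), \code{p} (upper-tail probability).
#' @export
hypergeomEnrichment <- function(setA, setB, universe) {
    universe <- unique(universe)
    setA <- unique(setA)
    setB <- unique(setB)
    if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
        stop("both sets must be subsets of the universe")
    k <- length(intersect(setA, setB))
    M <- length(universe)
    p <- stats::phyper(k - 1, length(setB), M - length(setB), length(setA),
                       lower.tail = FALSE)
    list(k = k, nA = length(setA), nB = length(setB), M = M, p = p)
}
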