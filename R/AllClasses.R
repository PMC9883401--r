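#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

.GENE_ROLES <- c("regulator", "lncRNA", "miRNA", "mRNA")

#' Expression matrix with gene roles
#'
#' An \code{M6AExpression} is a \linkS4class{SummarizedExperiment} holding a
#' single dense assay \code{"expr"} of gene-by-sample abundance. Rows carry a
#' mandatory \code{role} annotation (one of \code{"regulator"},
#' \code{"lncRNA"}, \code{"miRNA"}, \code{"mRNA"}) in \code{rowData}. The
#' object tracks whether values are on the TPM scale (as loaded) or have been
#' log2-transformed, because the expression-breadth filter is only defined on
#' the TPM scale and all correlation screens require the log2 scale.
#'
#' @slot (inherited) see \linkS4class{SummarizedExperiment}.
#' @seealso [M6AExpression()], [filterExpressed()], [log2Transform()]
#' @exportClass M6AExpression
setClass("M6AExpression", contains = "SummarizedExperiment")

setValidity("M6AExpression", function(object) {
    msg <- character()
    if (!("expr" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'expr' is required")
    v <- SummarizedExperiment::assay(object, "expr")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene and sample identifiers (dimnames) are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, sprintf("duplicate gene id: %s",
                              rownames(object)[duplicated(rownames(object))][1L]))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, sprintf("duplicate sample id: %s",
                              colnames(object)[duplicated(colnames(object))][1L]))
    if (!("role" %in% colnames(SummarizedExperiment::rowData(object)))) {
        msg <- c(msg, "rowData column 'role' is required")
    } else {
        role <- SummarizedExperiment::rowData(object)$role
        bad <- setdiff(unique(role), .GENE_ROLES)
        if (length(bad))
            msg <- c(msg, sprintf("unknown role label(s): %s",
                                  paste(bad, collapse = ", ")))
    }
    tr <- S4Vectors::metadata(object)$transformed
    if (!is.logical(tr) || length(tr) != 1L || is.na(tr))
        msg <- c(msg, "metadata 'transformed' must be TRUE or FALSE")
    if (is.numeric(v)) {
        if (any(!is.finite(v)))
            msg <- c(msg, "expression values must be finite")
        else if (isFALSE(tr) && any(v < 0))
            msg <- c(msg, "TPM-scale expression values must be >= 0")
    } else {
        msg <- c(msg, "expression values must be numeric")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an M6AExpression object
#'
#' @param values numeric matrix, genes in rows, samples in columns; must carry
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param roles character vector of gene roles, one per row of \code{values}
#'   (or a named vector covering all gene ids); each must be one of
#'   \code{"regulator"}, \code{"lncRNA"}, \code{"miRNA"}, \code{"mRNA"}.
#' @param transformed logical(1); \code{FALSE} for TPM-scale input,
#'   \code{TRUE} for log2-transformed values.
#' @return a validated [M6AExpression-class] object.
#' @examples
#' m <- matrix(runif(12), 3, 4,
#'             dimnames = list(c("METTL3", "L1", "G1"), paste0("S", 1:4)))
#' x <- M6AExpression(m, c("regulator", "lncRNA", "mRNA"))
#' @export
M6AExpression <- function(values, roles, transformed = FALSE) {
    if (!is.matrix(values))
        values <- as.matrix(values)
    if (!is.null(names(roles)))
        roles <- unname(roles[rownames(values)])
    if (length(roles) != nrow(values))
        stop("'roles' must supply one role per gene")
    se <- SummarizedExperiment(
        assays = list(expr = values),
        rowData = DataFrame(role = as.character(roles),
                            row.names = rownames(values)),
        metadata = list(transformed = transformed))
    new("M6AExpression", se)
}

setMethod("show", "M6AExpression", function(object) {
    cat(sprintf("M6AExpression: %d genes x %d samples (%s scale)\n",
                nrow(object), ncol(object),
                if (isTRUE(S4Vectors::metadata(object)$transformed))
                    "log2" else "TPM"))
    tab <- table(factor(SummarizedExperiment::rowData(object)$role,
                        levels = .GENE_ROLES))
    cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
})

#' Ranked gene list for enrichment scoring
#'
#' Genes ordered by the Pearson correlation between their expression and a
#' drug's per-sample IC50 (descending). Ties in the metric are broken
#' lexicographically by gene id so the ordering is deterministic.
#'
#' @slot genes character, ordered gene ids.
#' @slot metric numeric, the per-gene ranking correlation (same order).
#' @slot drugId character(1), label of the drug that produced the ranking.
#' @exportClass RankedGenes
setClass("RankedGenes",
         representation(genes = "character", metric = "numeric",
                        drugId = "character"))

setValidity("RankedGenes", function(object) {
    msg <- character()
    if (length(object@genes) != length(object@metric))
        msg <- c(msg, "genes and metric must have equal length")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene ids must be unique")
    if (any(!is.finite(object@metric)))
        msg <- c(msg, "metric values must be finite")
    if (is.unsorted(rev(object@metric)))
        msg <- c(msg, "metric must be sorted in descending order")
    if (length(msg)) msg else TRUE
})

setMethod("show", "RankedGenes", function(object) {
    cat(sprintf("RankedGenes: %d genes ranked for drug '%s'\n",
                length(object@genes), object@drugId))
    cat(sprintf("  metric range: [%.3f, %.3f]\n",
                min(object@metric), max(object@metric)))
})

#' A ceRNA network of filtered lncRNA-miRNA-mRNA triples
#'
#' Holds the triples that survived the sign/threshold correlation filters and
#' an index from each lncRNA to its deduplicated set of partner mRNAs (the
#' "target set" scored against drug rankings).
#'
#' @slot triples data.frame, one row per retained triple with the three
#'   correlations and their FDR-adjusted q-values.
#' @slot targetSets named list, lncRNA id -> character vector of mRNA ids.
#' @slot cancerId character(1).
#' @exportClass CeRNANetwork
setClass("CeRNANetwork",
         representation(triples = "data.frame", targetSets = "list",
                        cancerId = "character"))

setValidity("CeRNANetwork", function(object) {
    msg <- character()
    tr <- object@triples
    if (nrow(tr)) {
        need <- c("lncrna_id", "mirna_id", "mrna_id")
        if (!all(need %in% colnames(tr)))
            msg <- c(msg, "triples must have lncrna_id, mirna_id, mrna_id")
        else {
            idx <- split(tr$mrna_id, tr$lncrna_id)
            idx <- lapply(idx, function(x) sort(unique(x)))
            got <- lapply(object@targetSets, sort)
            if (!identical(got[order(names(got))], idx[order(names(idx))]))
                msg <- c(msg, "targetSets index inconsistent with triples")
            if (any(lengths(object@targetSets) == 0L))
                msg <- c(msg, "target sets must be non-empty")
        }
    } else if (length(object@targetSets)) {
        msg <- c(msg, "targetSets must be empty when there are no triples")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "CeRNANetwork", function(object) {
    cat(sprintf(
        "CeRNANetwork (%s): %d triples, %d lncRNAs, %d miRNAs, %d mRNAs\n",
        object@cancerId, nrow(object@triples),
        length(unique(object@triples$lncrna_id)),
        length(unique(object@triples$mirna_id)),
        length(unique(object@triples$mrna_id))))
})

#' Simulation design for synthetic cohorts
#'
#' Bundles every tunable of the synthetic-cohort generator: cohort size,
#' numbers of molecules of each role, the planted regulator-lncRNA
#' correlation, the ceRNA sponging loadings, the drug-response coupling, the
#' survival model, and the sequence composition model. All randomness in the
#' generator flows from the single \code{seed} through a deterministic
#' per-component derivation, so each stage can be regenerated independently.
#'
#' @seealso [SimParams()] for the constructor and default study conditions.
#' @exportClass SimParams
setClass("SimParams",
         representation(
             nSamples = "numeric", nLncrnas = "numeric", nMirnas = "numeric",
             nMrnas = "numeric",
             rhoSignal = "numeric", fracRelated = "numeric",
             fracNegative = "numeric",
             nTripleLncrnas = "numeric", mrnasPerTriple = "numeric",
             spongeRhoMirna = "numeric", spongeRhoShared = "numeric",
             nDecoyPairs = "numeric",
             nDrugs = "numeric", nEffectGenes = "numeric",
             drugEffectSize = "numeric", drugNoiseSd = "numeric",
             baselineHazard = "numeric", survivalBeta = "numeric",
             censoringFraction = "numeric",
             nSequences = "numeric", seqLength = "numeric",
             gcTarget = "numeric", cpgEnrichment = "numeric",
             drachPlanted = "numeric",
             seed = "numeric"))

setValidity("SimParams", function(object) {
    msg <- character()
    cnt <- c(nSamples = object@nSamples, nLncrnas = object@nLncrnas,
             nMirnas = object@nMirnas, nMrnas = object@nMrnas,
             nSequences = object@nSequences, seqLength = object@seqLength)
    if (any(cnt < 1) || any(cnt != round(cnt)))
        msg <- c(msg, "molecule/sample/sequence counts must be positive integers")
    nn <- c(object@nTripleLncrnas, object@mrnasPerTriple, object@nDecoyPairs,
            object@nDrugs, object@nEffectGenes, object@drachPlanted)
    if (any(nn < 0) || any(nn != round(nn)))
        msg <- c(msg, "planted counts must be non-negative integers")
    if (abs(object@rhoSignal) >= 1)
        msg <- c(msg, "|rhoSignal| must be < 1")
    fr <- c(object@fracRelated, object@fracNegative, object@gcTarget)
    if (any(fr < 0 | fr > 1))
        msg <- c(msg, "fractions must lie in [0, 1]")
    if (object@censoringFraction < 0 || object@censoringFraction >= 1)
        msg <- c(msg, "censoringFraction must lie in [0, 1)")
    if (object@spongeRhoMirna^2 + object@spongeRhoShared^2 >= 1)
        msg <- c(msg, "sponging loadings imply variance >= 1")
    nRel <- round(object@fracRelated * object@nLncrnas)
    if (nRel + object@nTripleLncrnas > object@nLncrnas)
        msg <- c(msg, "more planted lncRNAs requested than available")
    if (object@nTripleLncrnas > object@nMirnas)
        msg <- c(msg, "more sponged lncRNAs than available miRNAs")
    if (object@nTripleLncrnas * object@mrnasPerTriple > object@nMrnas)
        msg <- c(msg, "more planted triple mRNAs requested than available")
    if (object@nEffectGenes > object@nMrnas)
        msg <- c(msg, "more drug effect genes requested than available mRNAs")
    if (object@baselineHazard <= 0)
        msg <- c(msg, "baselineHazard must be > 0")
    if (object@drugNoiseSd < 0)
        msg <- c(msg, "drugNoiseSd must be >= 0")
    if (object@cpgEnrichment < 0)
        msg <- c(msg, "cpgEnrichment must be >= 0")
    if (length(object@seed) != 1L || object@seed != round(object@seed))
        msg <- c(msg, "seed must be a single integer")
    if (length(msg)) msg else TRUE
})
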