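#' Accessors for M6AExpression
#'
#' \code{exprValues} returns the dense gene-by-sample matrix,
#' \code{geneRoles} the named vector of per-gene role labels, and
#' \code{isTransformed} whether values are on the log2 scale.
#'
#' @param x an [M6AExpression-class] object.
#' @return \code{exprValues}: numeric matrix; \code{geneRoles}: named
#'   character vector; \code{isTransformed}: logical(1).
#' @name exprValues
#' @aliases exprValues,M6AExpression-method
#' @export
setMethod("exprValues", "M6AExpression", function(x)
    SummarizedExperiment::assay(x, "expr"))

#' @rdname exprValues
#' @name geneRoles
#' @aliases geneRoles,M6AExpression-method
#' @export
setMethod("geneRoles", "M6AExpression", function(x) {
    r <- SummarizedExperiment::rowData(x)$role
    names(r) <- rownames(x)
    r
})

#' @rdname exprValues
#' @name isTransformed
#' @aliases isTransformed,M6AExpression-method
#' @export
setMethod("isTransformed", "M6AExpression", function(x)
    isTRUE(S4Vectors::metadata(x)$transformed))

#' The 21-gene m6A regulator catalog
#'
#' The curated catalog of m6A machinery genes used throughout the screen:
#' 11 readers (m6A-binding proteins), 8 writers (methyltransferase complex
#' members) and 2 erasers (demethylases).
#'
#' @return data.frame with columns \code{symbol} and \code{category}
#'   (\code{"reader"}, \code{"writer"} or \code{"eraser"}).
#' @examples
#' table(m6aRegulators()$category)
#' @export
m6aRegulators <- function() {
    readers <- c("HNRNPA2B1", "HNRNPC", "IGF2BP1", "IGF2BP2", "IGF2BP3",
                 "RBMX", "YTHDC1", "YTHDC2", "YTHDF1", "YTHDF2", "YTHDF3")
    writers <- c("METTL14", "METTL16", "METTL3", "RBM15", "RBM15B",
                 "VIRMA", "WTAP", "ZC3H13")
    erasers <- c("ALKBH5", "FTO")
    data.frame(
        symbol = c(readers, writers, erasers),
        category = rep(c("reader", "writer", "eraser"),
                       c(length(readers), length(writers), length(erasers))),
        stringsAsFactors = FALSE)
}

#' Read an expression matrix from TSV
#'
#' Expected layout: header row of sample ids; column 1 \code{gene_id},
#' column 2 \code{role}, remaining columns numeric abundance on the TPM
#' scale. Duplicate gene or sample ids, unknown role labels, and
#' non-numeric body cells are hard errors that name the offending entry.
#'
#' @param path path to a tab-separated file.
#' @return an [M6AExpression-class] with \code{transformed = FALSE}.
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    if (ncol(df) < 3L)
        stop("expression TSV needs gene_id, role and at least one sample column")
    geneIds <- df[[1L]]
    roles <- df[[2L]]
    sampleIds <- colnames(df)[-(1:2)]
    if (anyDuplicated(geneIds))
        stop(sprintf("duplicate gene id: %s",
                     geneIds[duplicated(geneIds)][1L]))
    if (anyDuplicated(sampleIds))
        stop(sprintf("duplicate sample id: %s",
                     sampleIds[duplicated(sampleIds)][1L]))
    bad <- setdiff(unique(roles), .GENE_ROLES)
    if (length(bad))
        stop(sprintf("unknown role label '%s' (gene %s)", bad[1L],
                     geneIds[match(bad[1L], roles)]))
    body <- as.matrix(df[, -(1:2), drop = FALSE])
    vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
    if (anyNA(vals)) {
        idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric value '%s' at gene %s, sample %s",
                     body[idx[1L], idx[2L]], geneIds[idx[1L]],
                     sampleIds[idx[2L]]))
    }
    dimnames(vals) <- list(geneIds, sampleIds)
    M6AExpression(vals, roles, transformed = FALSE)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [readExpressionMatrix()]: \code{gene_id}, \code{role}, then one
#' column per sample. Values are written at full double precision so that a
#' read/write/read cycle round-trips.
#'
#' @param x an [M6AExpression-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path) {
    stopifnot(is(x, "M6AExpression"))
    v <- exprValues(x)
    out <- data.frame(gene_id = rownames(v), role = unname(geneRoles(x)),
                      stringsAsFactors = FALSE, check.names = FALSE)
    body <- apply(v, 2L, function(col) sprintf("%.17g", col))
    out <- cbind(out, as.data.frame(body, check.names = FALSE))
    colnames(out) <- c("gene_id", "role", colnames(v))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a miRNA-target interaction catalog
#'
#' TSV with header \code{mirna_id}, \code{target_id}, \code{target_class};
#' \code{target_class} must be \code{"lncRNA"} or \code{"mRNA"}. Pairs are
#' deduplicated after loading.
#'
#' @param path path to a tab-separated file.
#' @return data.frame with the three columns, unique rows.
#' @export
readInteractionCatalog <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    need <- c("mirna_id", "target_id", "target_class")
    if (!all(need %in% colnames(df)))
        stop("interaction TSV needs columns: ", paste(need, collapse = ", "))
    df <- unique(df[, need])
    bad <- setdiff(unique(df$target_class), c("lncRNA", "mRNA"))
    if (length(bad))
        stop(sprintf("unknown target_class '%s'", bad[1L]))
    rownames(df) <- NULL
    df
}

#' @rdname readInteractionCatalog
#' @param catalog interaction data.frame as returned by
#'   [readInteractionCatalog()].
#' @export
writeInteractionCatalog <- function(catalog, path) {
    utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a drug response (IC50) table
#'
#' TSV with header: column 1 \code{drug_id}, remaining columns per-sample
#' IC50 (missing entries allowed as \code{NA}). The IC50 scale (e.g. natural
#' log, as distributed by GDSC) is recorded by the caller, never converted.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, drugs in rows, samples in columns.
#' @export
readDrugResponse <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    drugs <- as.character(df[[1L]])
    if (anyDuplicated(drugs))
        stop(sprintf("duplicate drug id: %s", drugs[duplicated(drugs)][1L]))
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- drugs
    m
}

#' @rdname readDrugResponse
#' @param ic50 drug-by-sample numeric matrix.
#' @export
writeDrugResponse <- function(ic50, path) {
    out <- data.frame(drug_id = rownames(ic50),
                      as.data.frame(ic50, check.names = FALSE),
                      check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a clinical survival table
#'
#' TSV with header \code{sample_id}, \code{time_days}, \code{event};
#' follow-up times must be positive and events coded 0 (censored) / 1
#' (death observed).
#'
#' @param path path to a tab-separated file.
#' @return data.frame with the three columns, validated.
#' @export
readClinicalTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    need <- c("sample_id", "time_days", "event")
    if (!all(need %in% colnames(df)))
        stop("clinical TSV needs columns: ", paste(need, collapse = ", "))
    df <- df[, need]
    df$sample_id <- as.character(df$sample_id)
    if (anyDuplicated(df$sample_id))
        stop(sprintf("duplicate sample id: %s",
                     df$sample_id[duplicated(df$sample_id)][1L]))
    if (any(!is.finite(df$time_days)) || any(df$time_days <= 0))
        stop("follow-up times must be finite and > 0")
    if (!all(df$event %in% c(0, 1)))
        stop("event must be 0 (censored) or 1 (death)")
    df
}

#' @rdname readClinicalTable
#' @param clinical clinical data.frame.
#' @export
writeClinicalTable <- function(clinical, path) {
    utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Filter genes by expression breadth
#'
#' Retains exactly the genes with abundance > 0 in at least
#' \code{minFraction} of samples (inclusive threshold). Defined on the TPM
#' scale only; applying it after log2 transformation is an error because the
#' zero-vs-nonzero distinction is destroyed by the pseudocount.
#'
#' @param x an [M6AExpression-class] with \code{transformed = FALSE}.
#' @param minFraction proportion in \[0, 1\]; default 0.7.
#' @return the filtered [M6AExpression-class]; sample set and the order of
#'   surviving genes unchanged.
#' @name filterExpressed
#' @aliases filterExpressed,M6AExpression-method
#' @export
setMethod("filterExpressed", "M6AExpression", function(x, minFraction = 0.7) {
    if (isTransformed(x))
        stop("expression-breadth filter is defined on the TPM scale only")
    if (minFraction < 0 || minFraction > 1)
        stop("minFraction must lie in [0, 1]")
    keep <- rowMeans(exprValues(x) > 0) >= minFraction
    x[keep, ]
})

#' Log2-transform an expression matrix
#'
#' Replaces every value v by log2(v + offset) and flags the object as
#' transformed. Transforming twice is an error.
#'
#' @param x an [M6AExpression-class] with \code{transformed = FALSE}.
#' @param offset pseudocount, must be > 0 (default 1, the standard
#'   log2(TPM + 1) convention).
#' @return the transformed [M6AExpression-class].
#' @name log2Transform
#' @aliases log2Transform,M6AExpression-method
#' @export
setMethod("log2Transform", "M6AExpression", function(x, offset = 1) {
    if (isTransformed(x))
        stop("expression matrix is already log2-transformed")
    if (!is.numeric(offset) || length(offset) != 1L || offset <= 0)
        stop("offset must be a single value > 0")
    v <- log2(exprValues(x) + offset)
    M6AExpression(v, geneRoles(x), transformed = TRUE)
})
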