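#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson coefficient together with the two-sided p-value from
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom (the same
#' test \code{stats::cor.test} performs). Zero-variance input is a defined
#' error rather than a silent NaN.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list with elements \code{r} and \code{p}.
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    if (length(x) < 3L)
        stop("at least 3 observations are required")
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("inputs must be finite")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero-variance input: Pearson correlation is undefined")
    r <- stats::cor(x, y)
    list(r = r, p = .pearsonP(r, length(x)))
}

# two-sided p for a Pearson r at sample size n (vectorised)
.pearsonP <- function(r, n) {
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p[abs(r) == 1] <- 0
    p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via \code{stats::p.adjust(method = "BH")},
#' order-preserving with the input and capped at 1. Values outside \[0, 1\]
#' are an error.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of q-values, same order as \code{p}.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Screen lncRNAs for correlation with m6A regulators
#'
#' Computes the Pearson correlation of every (lncRNA, regulator) pair on the
#' log2 scale, adjusts the p-values by Benjamini-Hochberg within the chosen
#' family, and reports the pairs with |r| strictly above \code{rMin} and
#' q strictly below \code{qMax} - the operational definition of an
#' m6A-related lncRNA.
#'
#' @param expr a log2-transformed [M6AExpression-class].
#' @param catalog regulator catalog data.frame (columns \code{symbol},
#'   \code{category}); default [m6aRegulators()]. Regulators absent from the
#'   matrix are reported in a warning and skipped; none present is an error.
#' @param rMin correlation magnitude threshold (strict), default 0.3.
#' @param qMax FDR threshold (strict), default 0.05.
#' @param cancerId cohort label attached to every record.
#' @param fdrScope \code{"cancer"} (default): one BH family over all tested
#'   pairs in the cohort; \code{"regulator"}: one family per regulator.
#' @param candidates optional character vector restricting the lncRNAs tested
#'   (e.g. those with prior m6A evidence); \code{NULL} tests all lncRNAs.
#' @return data.frame of correlation records: \code{cancer_id},
#'   \code{lncrna_id}, \code{regulator_id}, \code{category}, \code{r},
#'   \code{p}, \code{q}, \code{sign}.
#' @seealso [summarizeScreen()], [classifyLncrnas()]
#' @export
screenRegulators <- function(expr, catalog = m6aRegulators(), rMin = 0.3,
                             qMax = 0.05, cancerId = "cancer",
                             fdrScope = c("cancer", "regulator"),
                             candidates = NULL) {
    stopifnot(is(expr, "M6AExpression"))
    fdrScope <- match.arg(fdrScope)
    if (!isTransformed(expr))
        stop("screen requires a log2-transformed expression matrix")
    roles <- geneRoles(expr)
    regs <- intersect(catalog$symbol, names(roles))
    missing <- setdiff(catalog$symbol, regs)
    if (length(missing))
        warning("regulators absent from the matrix, skipped: ",
                paste(missing, collapse = ", "))
    if (!length(regs))
        stop("no catalog regulator present in the expression matrix")
    lncs <- names(roles)[roles == "lncRNA"]
    if (!is.null(candidates))
        lncs <- intersect(lncs, candidates)
    if (!length(lncs))
        return(.emptyScreen())
    v <- exprValues(expr)
    lv <- t(v[lncs, , drop = FALSE])
    rv <- t(v[regs, , drop = FALSE])
    const <- apply(lv, 2L, stats::sd) == 0
    if (any(const)) {
        warning(sum(const), " constant lncRNA(s) dropped from the screen")
        lncs <- lncs[!const]
        lv <- lv[, !const, drop = FALSE]
        if (!length(lncs)) return(.emptyScreen())
    }
    if (any(apply(rv, 2L, stats::sd) == 0))
        stop("constant regulator expression: correlation undefined")
    n <- nrow(lv)
    if (n < 3L) stop("at least 3 samples are required")
    R <- stats::cor(lv, rv)
    P <- .pearsonP(R, n)
    rec <- data.frame(
        cancer_id = cancerId,
        lncrna_id = rep(lncs, times = length(regs)),
        regulator_id = rep(regs, each = length(lncs)),
        r = as.vector(R), p = as.vector(P),
        stringsAsFactors = FALSE)
    rec$category <- catalog$category[match(rec$regulator_id, catalog$symbol)]
    if (fdrScope == "cancer") {
        rec$q <- bhAdjust(rec$p)
    } else {
        rec$q <- stats::ave(rec$p, rec$regulator_id, FUN = bhAdjust)
    }
    rec <- rec[abs(rec$r) > rMin & rec$q < qMax, , drop = FALSE]
    rec$sign <- ifelse(rec$r > 0, "positive", "negative")
    rownames(rec) <- NULL
    rec[, c("cancer_id", "lncrna_id", "regulator_id", "category",
            "r", "p", "q", "sign")]
}

.emptyScreen <- function() {
    data.frame(cancer_id = character(), lncrna_id = character(),
               regulator_id = character(), category = character(),
               r = numeric(), p = numeric(), q = numeric(),
               sign = character(), stringsAsFactors = FALSE)
}

#' Summarize a regulator-lncRNA screen
#'
#' Landscape summaries over one or more cohorts: positive/negative record
#' counts per cancer, lncRNA counts per regulator, the number of regulators
#' linked to each lncRNA (with its median), and the proportion of lncRNAs
#' linked to each regulator category. A lncRNA linked to both a reader and a
#' writer counts once in each category's proportion.
#'
#' @param records screen records as returned by [screenRegulators()]
#'   (possibly row-bound across cancers).
#' @param catalog regulator catalog, default [m6aRegulators()].
#' @return list with elements \code{perCancer}, \code{perRegulator},
#'   \code{perLncrna}, \code{medianRegulatorsPerLncrna},
#'   \code{categoryProportion}.
#' @export
summarizeScreen <- function(records, catalog = m6aRegulators()) {
    if (nrow(records) == 0L) {
        return(list(
            perCancer = data.frame(cancer_id = character(),
                                   positive = integer(), negative = integer()),
            perRegulator = data.frame(regulator_id = character(),
                                      n_lncrnas = integer()),
            perLncrna = data.frame(lncrna_id = character(),
                                   n_regulators = integer()),
            medianRegulatorsPerLncrna = NA_real_,
            categoryProportion = stats::setNames(
                rep(NA_real_, 3L), c("reader", "writer", "eraser"))))
    }
    perCancer <- do.call(rbind, lapply(
        split(records, records$cancer_id), function(d)
            data.frame(cancer_id = d$cancer_id[1L],
                       positive = sum(d$sign == "positive"),
                       negative = sum(d$sign == "negative"))))
    rownames(perCancer) <- NULL
    pr <- tapply(records$lncrna_id, records$regulator_id,
                 function(x) length(unique(x)))
    perRegulator <- data.frame(regulator_id = names(pr),
                               n_lncrnas = as.integer(pr))
    pl <- tapply(records$regulator_id, records$lncrna_id,
                 function(x) length(unique(x)))
    perLncrna <- data.frame(lncrna_id = names(pl),
                            n_regulators = as.integer(pl))
    nLnc <- length(unique(records$lncrna_id))
    catProp <- vapply(c("reader", "writer", "eraser"), function(cat) {
        length(unique(records$lncrna_id[records$category == cat])) / nLnc
    }, numeric(1))
    list(perCancer = perCancer, perRegulator = perRegulator,
         perLncrna = perLncrna,
         medianRegulatorsPerLncrna = stats::median(perLncrna$n_regulators),
         categoryProportion = catProp)
}
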