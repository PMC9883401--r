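#' @importFrom survival Surv survdiff coxph
NULL

#' Median split of an expression vector
#'
#' Samples with expression strictly above the median go to \code{"high"},
#' the rest (including ties at the median) to \code{"low"}, so the median
#' itself is always grouped consistently. A degenerate vector (all values
#' equal) or a split leaving a group empty is an error.
#'
#' @param x numeric vector, n >= 4.
#' @return factor with levels \code{"low"}, \code{"high"}, same length and
#'   names as \code{x}.
#' @examples
#' medianSplit(c(1, 2, 2, 3))  # high = {3}
#' @export
medianSplit <- function(x) {
    if (length(x) < 4L)
        stop("median split requires at least 4 samples")
    if (any(!is.finite(x)))
        stop("expression values must be finite")
    if (max(x) == min(x))
        stop("degenerate expression vector: all values equal")
    g <- factor(ifelse(x > stats::median(x), "high", "low"),
                levels = c("low", "high"))
    if (any(table(g) == 0L))
        stop("median split leaves a group empty")
    names(g) <- names(x)
    g
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves: at each distinct
#' event time the observed minus expected deaths in one group with the
#' hypergeometric variance; chi-square statistic on 1 degree of freedom
#' (computed by \code{survival::survdiff}). The statistic depends on times
#' only through their ranks.
#'
#' @param time positive follow-up times.
#' @param event event indicator, 1 = death observed, 0 = censored.
#' @param group factor with exactly two levels.
#' @param zeroEvents what to do when a group has no events:
#'   \code{"error"} (default) or \code{"na"} (return \code{NA} statistics,
#'   flagged).
#' @return list with \code{chi2}, \code{p}, \code{n} (per-group sizes),
#'   \code{events} (per-group event counts).
#' @export
logrankTest <- function(time, event, group, zeroEvents = c("error", "na")) {
    zeroEvents <- match.arg(zeroEvents)
    group <- droplevels(as.factor(group))
    if (nlevels(group) != 2L)
        stop("log-rank test requires exactly two groups")
    stopifnot(length(time) == length(event), length(time) == length(group))
    ev <- tapply(event, group, sum)
    nn <- table(group)
    if (any(ev == 0)) {
        if (zeroEvents == "error")
            stop("group with zero events: log-rank statistic undefined")
        return(list(chi2 = NA_real_, p = NA_real_, n = as.vector(nn),
                    events = as.vector(ev)))
    }
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    chi2 <- unname(sd$chisq)
    list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
         n = as.vector(nn), events = as.vector(ev))
}

#' Univariate Cox proportional-hazards regression
#'
#' Fits the Cox partial likelihood for a single covariate by Newton
#' iteration with Breslow tie handling (via \code{survival::coxph}); returns
#' the hazard ratio exp(beta) and a Wald p-value. Constant covariates,
#' fewer than 2 events, non-convergence and monotone likelihood (perfect
#' separation, detected as an effectively infinite coefficient) are errors
#' with diagnostics.
#'
#' @param time positive follow-up times.
#' @param event event indicator (0/1).
#' @param covariate numeric vector (e.g. expression, or a 0/1 median-split
#'   indicator).
#' @return list with \code{hr}, \code{beta}, \code{se}, \code{p} (Wald),
#'   \code{n}, \code{nEvents}.
#' @export
coxUnivariate <- function(time, event, covariate) {
    stopifnot(length(time) == length(event),
              length(time) == length(covariate))
    if (is.factor(covariate))
        covariate <- as.numeric(covariate) - 1
    if (stats::sd(covariate) == 0)
        stop("constant covariate: Cox regression undefined")
    if (sum(event) < 2)
        stop("Cox regression requires at least 2 events")
    fit <- tryCatch(
        suppressWarnings(survival::coxph(
            survival::Surv(time, event) ~ covariate, ties = "breslow")),
        error = function(e)
            stop("Cox fit failed: ", conditionMessage(e)))
    beta <- unname(stats::coef(fit))
    se <- sqrt(unname(diag(fit$var)))[1L]
    if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15)
        stop(sprintf(
            "monotone partial likelihood (beta = %.3g, se = %.3g): separation",
            beta, se))
    z <- beta / se
    list(hr = exp(beta), beta = beta, se = se,
         p = 2 * stats::pnorm(-abs(z)),
         n = length(time), nEvents = sum(event))
}

#' Median-split survival screen over a lncRNA panel
#'
#' For each lncRNA: splits the cohort at its median expression, compares the
#' two groups with the log-rank test, and fits a univariate Cox model
#' (default on the high/low indicator, so the hazard ratio is high-vs-low).
#' Benjamini-Hochberg adjustment is applied across the panel, separately for
#' the two tests.
#'
#' @param expr an [M6AExpression-class] (any scale; the split and fit use
#'   the values as given).
#' @param clinical clinical data.frame (see [readClinicalTable()]); samples
#'   are matched to the expression columns by \code{sample_id}.
#' @param lncrnas optional character vector restricting the panel;
#'   \code{NULL} uses every lncRNA row.
#' @param covariateMode \code{"median"} (default, 0/1 indicator) or
#'   \code{"continuous"} (expression itself) for the Cox covariate.
#' @return data.frame with one row per analysable lncRNA: \code{lncrna_id},
#'   \code{n_high}, \code{n_low}, \code{chi2}, \code{p_logrank},
#'   \code{q_logrank}, \code{hr}, \code{p_cox}, \code{q_cox}. lncRNAs whose
#'   split or fit is degenerate are skipped with a warning.
#' @export
survivalScreen <- function(expr, clinical, lncrnas = NULL,
                           covariateMode = c("median", "continuous")) {
    stopifnot(is(expr, "M6AExpression"))
    covariateMode <- match.arg(covariateMode)
    roles <- geneRoles(expr)
    panel <- names(roles)[roles == "lncRNA"]
    if (!is.null(lncrnas)) panel <- intersect(panel, lncrnas)
    if (!length(panel)) stop("no lncRNA to analyse")
    common <- intersect(colnames(expr), clinical$sample_id)
    if (length(common) < 4L)
        stop("fewer than 4 samples shared between expression and clinical data")
    cl <- clinical[match(common, clinical$sample_id), ]
    v <- exprValues(expr)[panel, common, drop = FALSE]
    rows <- list()
    skipped <- character()
    for (l in panel) {
        res <- tryCatch({
            g <- medianSplit(v[l, ])
            lr <- logrankTest(cl$time_days, cl$event, g)
            cov <- if (covariateMode == "median")
                as.numeric(g) - 1 else v[l, ]
            cx <- coxUnivariate(cl$time_days, cl$event, cov)
            data.frame(lncrna_id = l,
                       n_high = sum(g == "high"), n_low = sum(g == "low"),
                       chi2 = lr$chi2, p_logrank = lr$p,
                       hr = cx$hr, p_cox = cx$p,
                       stringsAsFactors = FALSE)
        }, error = function(e) NULL)
        if (is.null(res)) skipped <- c(skipped, l)
        else rows[[length(rows) + 1L]] <- res
    }
    if (length(skipped))
        warning(length(skipped), " lncRNA(s) skipped (degenerate split/fit): ",
                paste(utils::head(skipped, 5L), collapse = ", "))
    if (!length(rows))
        stop("no lncRNA yielded a valid survival comparison")
    out <- do.call(rbind, rows)
    out$q_logrank <- bhAdjust(out$p_logrank)
    out$q_cox <- bhAdjust(out$p_cox)
    rownames(out) <- NULL
    out
}
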