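#' @importFrom Biostrings DNAStringSet DNAString letterFrequency vcountPattern
#'   width readDNAStringSet writeXStringSet
NULL

# Coerce character / DNAString / DNAStringSet input to DNAStringSet with
# U -> T so RNA sequences are accepted.
.asDNA <- function(seqs) {
    if (is(seqs, "DNAStringSet")) return(seqs)
    if (is(seqs, "XString")) return(DNAStringSet(as.character(seqs)))
    tryCatch(
        DNAStringSet(chartr("Uu", "Tt", toupper(as.character(seqs)))),
        error = function(e)
            stop("sequences must be over the alphabet {A, C, G, T, N}",
                 call. = FALSE))
}

.checkAlphabet <- function(x) {
    cnt <- letterFrequency(x, c("A", "C", "G", "T", "N"))
    if (any(rowSums(cnt) != width(x)))
        stop("sequences must be over the alphabet {A, C, G, T, N} (U allowed)")
    invisible(cnt)
}

#' GC content of sequences
#'
#' Fraction (G + C) / (length excluding N); N bases are excluded from both
#' numerator and denominator. Empty or all-N sequences are an error.
#'
#' @param seqs character vector, \code{DNAString} or \code{DNAStringSet}
#'   (RNA alphabet is accepted, U is read as T).
#' @return numeric vector of GC fractions in \[0, 1\].
#' @examples
#' gcContent(c("ATAT", "GCGC", "ACGTN"))
#' @export
gcContent <- function(seqs) {
    x <- .asDNA(seqs)
    cnt <- .checkAlphabet(x)
    denom <- width(x) - cnt[, "N"]
    if (any(denom == 0))
        stop("empty or all-N sequence: GC content undefined")
    unname((cnt[, "G"] + cnt[, "C"]) / denom)
}

#' Normalized CpG (observed / expected) ratio
#'
#' Observed CpG fraction is the count of "CG" dinucleotides divided by the
#' number of dinucleotide positions (length - 1); the expected fraction is
#' (GC content / 2)^2. Sequences with zero GC content or fewer than two
#' bases have an undefined ratio, signalled as \code{NA} (never 0 or Inf).
#'
#' @param seqs character vector, \code{DNAString} or \code{DNAStringSet}.
#' @return numeric vector of observed/expected ratios (>= 0, or \code{NA}
#'   where undefined).
#' @examples
#' normalizedCpG("CGCG")  # (2/3) / 0.25 = 8/3
#' @export
normalizedCpG <- function(seqs) {
    x <- .asDNA(seqs)
    cnt <- .checkAlphabet(x)
    denom <- width(x) - cnt[, "N"]
    if (any(denom == 0))
        stop("empty or all-N sequence: normalized CpG undefined")
    gc <- (cnt[, "G"] + cnt[, "C"]) / denom
    obs <- vcountPattern("CG", x) / (width(x) - 1)
    res <- obs / (gc / 2)^2
    res[gc == 0 | width(x) < 2] <- NA_real_
    unname(res)
}

#' Count IUPAC consensus motif matches
#'
#' Scans every position of each sequence for a match to an IUPAC consensus
#' pattern (default the m6A consensus \code{"DRACH"}: D = A/G/T, R = A/G,
#' H = A/C/T). Overlapping matches are all counted. A pattern longer than
#' the sequence yields 0, not an error.
#'
#' @param seqs character vector, \code{DNAString} or \code{DNAStringSet}.
#' @param pattern IUPAC consensus string, default \code{"DRACH"}.
#' @return integer vector of match counts.
#' @examples
#' motifCount("GGACAGGACT")  # 2
#' @export
motifCount <- function(seqs, pattern = "DRACH") {
    x <- .asDNA(seqs)
    pat <- chartr("Uu", "Tt", toupper(pattern))
    if (!all(strsplit(pat, "")[[1L]] %in%
             names(Biostrings::IUPAC_CODE_MAP)))
        stop("pattern must use IUPAC nucleotide codes")
    res <- integer(length(x))
    ok <- width(x) >= nchar(pat)
    if (any(ok))
        res[ok] <- vcountPattern(pat, x[ok], fixed = FALSE)
    res
}

#' Per-sequence feature table
#'
#' Computes length, GC content, CpG dinucleotide count, normalized CpG ratio
#' and DRACH motif count for every sequence, with an optional externally
#' supplied conservation score column (e.g. mean phastCons; never computed
#' here).
#'
#' @param seqs a named \code{DNAStringSet} (e.g. from
#'   \code{Biostrings::readDNAStringSet}) or named character vector.
#' @param pattern motif consensus passed to [motifCount()].
#' @param conservation optional numeric vector, named by sequence id.
#' @return data.frame with one row per sequence: \code{seq_id},
#'   \code{length}, \code{gc}, \code{cpg_count}, \code{norm_cpg},
#'   \code{drach_count} (and \code{conservation} if supplied).
#' @export
sequenceFeatures <- function(seqs, pattern = "DRACH", conservation = NULL) {
    x <- .asDNA(seqs)
    if (is.null(names(x)))
        names(x) <- paste0("seq", seq_along(x))
    out <- data.frame(
        seq_id = names(x),
        length = width(x),
        gc = gcContent(x),
        cpg_count = vcountPattern("CG", x),
        norm_cpg = normalizedCpG(x),
        drach_count = motifCount(x, pattern),
        stringsAsFactors = FALSE)
    if (!is.null(conservation))
        out$conservation <- unname(conservation[out$seq_id])
    rownames(out) <- NULL
    out
}

#' Normalized CpG profile around transcription start sites
#'
#' Slides fixed-width windows across a flank on either side of each TSS and
#' averages the normalized CpG ratio per window offset across all records.
#' Offsets are strand-aware: on minus-strand records the genomic direction is
#' mirrored so that positive offsets are always downstream of the TSS.
#' Windows that fall (partly) outside the sequence are clipped; windows with
#' an undefined ratio are excluded from the mean and counted.
#'
#' @param seqs named \code{DNAStringSet} of source sequences (names matched
#'   against the BED chrom field).
#' @param tss TSS records: a \code{GRanges}, or a path to a BED file
#'   (0-based half-open; read with \code{rtracklayer::import}). The TSS is
#'   the 5' end of each range.
#' @param flank half-width of the profiled region in nt (default 2000).
#' @param window window width in nt (default 200); must not exceed
#'   \code{flank}.
#' @param step distance between window centers in nt (default 100).
#' @return data.frame with columns \code{offset} (window center relative to
#'   the TSS), \code{mean_norm_cpg}, \code{n_windows} (windows contributing),
#'   \code{n_undefined} (windows excluded as undefined or out of range).
#' @export
tssNormCpGProfile <- function(seqs, tss, flank = 2000, window = 200,
                              step = 100) {
    x <- .asDNA(seqs)
    if (is.null(names(x)))
        stop("source sequences must be named")
    if (window < 2 || step < 1)
        stop("window must be >= 2 nt and step >= 1 nt")
    if (flank < window)
        stop("flank smaller than window: invalid profile geometry")
    if (is.character(tss))
        tss <- rtracklayer::import(tss)
    if (!is(tss, "GRanges"))
        stop("tss must be a GRanges or a BED file path")
    chroms <- as.character(GenomicRanges::seqnames(tss))
    if (!all(chroms %in% names(x)))
        stop("TSS record on unknown sequence: ",
             setdiff(chroms, names(x))[1L])
    strand <- as.character(GenomicRanges::strand(tss))
    tssPos <- ifelse(strand == "-", GenomicRanges::end(tss),
                     GenomicRanges::start(tss))
    offsets <- seq(-flank, flank, by = step)
    half <- window / 2
    acc <- matrix(0, nrow = length(offsets), ncol = 2,
                  dimnames = list(NULL, c("sum", "n")))
    nUndef <- integer(length(offsets))
    for (i in seq_along(tss)) {
        s <- x[[chroms[i]]]
        len <- length(s)
        dir <- if (strand[i] == "-") -1 else 1
        for (j in seq_along(offsets)) {
            center <- tssPos[i] + dir * offsets[j]
            from <- max(1, floor(center - half))
            to <- min(len, ceiling(center + half) - 1)
            if (to - from + 1 < 2) {
                nUndef[j] <- nUndef[j] + 1L
                next
            }
            val <- normalizedCpG(Biostrings::subseq(
                DNAStringSet(s), start = from, end = to))
            if (is.na(val)) {
                nUndef[j] <- nUndef[j] + 1L
            } else {
                acc[j, "sum"] <- acc[j, "sum"] + val
                acc[j, "n"] <- acc[j, "n"] + 1
            }
        }
    }
    data.frame(offset = offsets,
               mean_norm_cpg = ifelse(acc[, "n"] > 0,
                                      acc[, "sum"] / acc[, "n"], NA_real_),
               n_windows = as.integer(acc[, "n"]),
               n_undefined = nUndef)
}

#' Compare a feature between two lncRNA groups
#'
#' Two-sided equal-variance Student's t test (used for conservation scores,
#' CpG counts and motif counts) or two-sample Kolmogorov-Smirnov test (used
#' for normalized CpG distributions). Undefined (\code{NA}) entries must be
#' removed by the caller; their presence is an error.
#'
#' @param a,b numeric vectors of feature values for the two groups.
#' @param test \code{"student_t"} (default) or \code{"ks"}.
#' @param feature optional feature label carried into the result.
#' @return data.frame with columns \code{feature}, \code{test},
#'   \code{statistic}, \code{p}.
#' @export
compareGroups <- function(a, b, test = c("student_t", "ks"),
                          feature = NA_character_) {
    test <- match.arg(test)
    if (anyNA(a) || anyNA(b))
        stop("undefined entries must be removed before group comparison")
    if (any(!is.finite(a)) || any(!is.finite(b)))
        stop("feature values must be finite")
    if (test == "student_t") {
        if (length(a) < 2L || length(b) < 2L)
            stop("t test requires at least 2 values per group")
        ht <- stats::t.test(a, b, var.equal = TRUE)
        stat <- unname(ht$statistic)
        # identical groups give 0/0 in the t statistic; define t = 0, p = 1
        if (is.nan(stat)) {
            stat <- 0
            p <- 1
        } else p <- ht$p.value
    } else {
        if (length(a) < 1L || length(b) < 1L)
            stop("KS test requires at least 1 value per group")
        ht <- suppressWarnings(stats::ks.test(a, b))
        stat <- unname(ht$statistic)
        p <- ht$p.value
    }
    data.frame(feature = feature, test = test, statistic = stat, p = p,
               stringsAsFactors = FALSE)
}
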