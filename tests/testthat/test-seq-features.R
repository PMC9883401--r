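test_that("gcContent counts G+C over non-N bases", {
    expect_equal(gcContent("ATAT"), 0)
    expect_equal(gcContent("GCGC"), 1)
    expect_equal(gcContent("ACGTN"), 0.5)
    expect_equal(gcContent(c("ACGT", "GGGG")), c(0.5, 1))
    expect_error(gcContent("NNN"), "all-N")
    expect_error(gcContent("ACGX"), "alphabet")
})

test_that("normalizedCpG implements observed/(GC/2)^2 and flags undefined", {
    expect_equal(normalizedCpG("CGCG"), (2 / 3) / 0.25)
    expect_equal(normalizedCpG("CCGG"), (1 / 3) / 0.25)
    expect_true(is.na(normalizedCpG("ATATAT")))  # gc = 0: undefined, not 0
    set.seed(31)
    for (i in 1:25) {
        s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                   collapse = "")
        expect_equal(normalizedCpG(s), naiveNormCpG(s))
    }
})

test_that("motifCount scans all positions with IUPAC semantics", {
    expect_equal(motifCount("AAAAA"), 0L)
    expect_equal(motifCount("GGACT"), 1L)
    expect_equal(motifCount("GGACAGGACT"), 2L)
    expect_equal(motifCount("GGA"), 0L)          # pattern longer than seq
    expect_equal(motifCount("GGACU"), 1L)        # RNA alphabet accepted
    expect_error(motifCount("ACGT", pattern = "DRAZH"), "IUPAC")
    set.seed(17)
    for (i in 1:25) {
        s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                   collapse = "")
        expect_equal(motifCount(s), naiveMotifCount(s))
        expect_equal(motifCount(s, "RRACH"), naiveMotifCount(s, "RRACH"))
    }
})

test_that("motif counts are superadditive under concatenation", {
    set.seed(3)
    for (i in 1:10) {
        a <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
        b <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
        joined <- paste0(a, "TTTT", b)
        # boundary windows can only add matches, never remove them
        expect_gte(motifCount(joined), motifCount(a) + motifCount(b))
        expect_equal(motifCount(joined), naiveMotifCount(joined))
    }
    # a junction engineered to admit no cross-boundary window: exact equality
    a <- "GGACT"    # one DRACH; does not end in a DRAC prefix
    b <- "AGGACT"   # one DRACH; does not start in a RACH suffix
    expect_equal(motifCount(paste0(a, "TTTT", b)),
                 motifCount(a) + motifCount(b))
})

test_that("TSS profile equals direct window recomputation", {
    set.seed(8)
    s <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
    seqs <- Biostrings::DNAStringSet(setNames(s, "chr1"))
    tss <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(start = 600, width = 1),
                                  strand = "+")
    prof <- tssNormCpGProfile(seqs, tss, flank = 400, window = 200,
                              step = 100)
    expect_equal(prof$offset, seq(-400, 400, 100))
    for (j in seq_len(nrow(prof))) {
        center <- 600 + prof$offset[j]
        win <- substr(s, floor(center - 100), ceiling(center + 100) - 1)
        expect_equal(prof$mean_norm_cpg[j], naiveNormCpG(win),
                     label = paste("offset", prof$offset[j]))
    }
    expect_error(tssNormCpGProfile(seqs, tss, flank = 100, window = 200),
                 "flank")
})

test_that("a CpG-rich center peaks at offset zero and minus strands mirror", {
    # flanks carry GC but no CpG (O/E = 0); the core is a pure CpG island
    flankSeq <- paste(rep("GACT", 250), collapse = "")
    core <- paste(rep("CG", 100), collapse = "")
    s <- paste0(flankSeq, core, flankSeq)   # CpG island at positions 1001-1200
    seqs <- Biostrings::DNAStringSet(setNames(s, "chr1"))
    center <- 1100L
    for (strand in c("+", "-")) {
        tss <- GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(start = center, width = 1),
            strand = strand)
        prof <- tssNormCpGProfile(seqs, tss, flank = 600, window = 150,
                                  step = 150)
        peak <- prof$offset[which.max(prof$mean_norm_cpg)]
        expect_equal(peak, 0, label = paste("strand", strand))
    }
})

test_that("asymmetric profiles flip between strands", {
    # island strictly downstream of the TSS on the plus strand
    s <- paste0(paste(rep("GACT", 300), collapse = ""),
                paste(rep("CG", 100), collapse = ""),
                paste(rep("GACT", 100), collapse = ""))
    seqs <- Biostrings::DNAStringSet(setNames(s, "chr1"))
    tss <- function(st) GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(start = 1000, width = 1), strand = st)
    plus <- tssNormCpGProfile(seqs, tss("+"), flank = 400, window = 200,
                              step = 200)
    minus <- tssNormCpGProfile(seqs, tss("-"), flank = 400, window = 200,
                               step = 200)
    expect_gt(plus$mean_norm_cpg[plus$offset == 400],
              plus$mean_norm_cpg[plus$offset == -400])
    expect_gt(minus$mean_norm_cpg[minus$offset == -400],
              minus$mean_norm_cpg[minus$offset == 400])
})

test_that("group comparisons dispatch the right test and handle ties", {
    same <- compareGroups(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$statistic, 0)
    expect_equal(same$p, 1)
    ks <- compareGroups(c(1, 2, 3), c(1, 2, 3), test = "ks")
    expect_equal(ks$statistic, 0)
    # equal-variance two-sample t: pooled sd 1.291, se 0.913 -> t = -1.0954
    tt <- compareGroups(c(1, 2, 3, 4), c(2, 3, 4, 5))
    expect_equal(tt$statistic, -1.0954451, tolerance = 1e-6)
    expect_equal(tt$p, 0.3153336, tolerance = 1e-6)
    expect_error(compareGroups(c(1, NA), c(1, 2)), "undefined")
})

test_that("sequenceFeatures joins optional conservation scores", {
    x <- Biostrings::DNAStringSet(c(a = "ACGCGT", b = "ATATAT"))
    f <- sequenceFeatures(x, conservation = c(b = 0.2, a = 0.9))
    expect_equal(f$conservation, c(0.9, 0.2))
    expect_equal(f$cpg_count, c(2L, 0L))
    expect_true(is.na(f$norm_cpg[2]))
})
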