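writeExprFixture <- function(lines) {
    f <- withr::local_tempfile(fileext = ".tsv",
                               .local_envir = parent.frame())
    writeLines(lines, f)
    f
}

test_that("expression TSV parsing validates ids, roles and numeric body", {
    good <- c("gene_id\trole\tS1\tS2\tS3\tS4",
              "METTL3\tregulator\t1.5\t2\t0\t3",
              "LNC1\tlncRNA\t0\t1\t2\t3",
              "G1\tmRNA\t4\t5\t6\t7")
    x <- readExpressionMatrix(writeExprFixture(good))
    expect_s4_class(x, "M6AExpression")
    expect_equal(dim(x), c(3L, 4L))
    expect_false(isTransformed(x))
    expect_equal(unname(geneRoles(x)), c("regulator", "lncRNA", "mRNA"))

    dup <- c(good, "LNC1\tlncRNA\t1\t1\t1\t1")
    expect_error(readExpressionMatrix(writeExprFixture(dup)), "LNC1")

    na <- c(good[1:2], "LNC1\tlncRNA\t0\tNA\t2\t3")
    expect_error(readExpressionMatrix(writeExprFixture(na)), "LNC1.*S2")

    role <- c(good[1], "X1\tpseudogene\t1\t2\t3\t4")
    expect_error(readExpressionMatrix(writeExprFixture(role)), "pseudogene")
})

test_that("expression matrices round-trip through write/read", {
    set.seed(11)
    v <- matrix(round(runif(20, 0, 50), 6), 5, 4,
                dimnames = list(paste0("G", 1:5), paste0("S", 1:4)))
    x <- M6AExpression(v, rep(c("lncRNA", "mRNA"), c(2, 3)))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionMatrix(x, f)
    y <- readExpressionMatrix(f)
    expect_identical(rownames(y), rownames(x))
    expect_identical(colnames(y), colnames(x))
    expect_identical(geneRoles(y), geneRoles(x))
    expect_equal(exprValues(y), exprValues(x))
})

test_that("expression-breadth filter keeps genes at or above the threshold", {
    v <- rbind(
        keep7 = c(rep(1, 7), rep(0, 3)),   # 7/10 nonzero, boundary case
        drop6 = c(rep(1, 6), rep(0, 4)),   # 6/10 nonzero
        zero = rep(0, 10))
    colnames(v) <- paste0("S", 1:10)
    x <- M6AExpression(v, rep("mRNA", 3))
    f <- filterExpressed(x, minFraction = 0.7)
    expect_identical(rownames(f), "keep7")
    expect_identical(colnames(f), colnames(x))
    all <- filterExpressed(x, minFraction = 0)
    expect_identical(rownames(all), rownames(x))
    expect_error(filterExpressed(log2Transform(x)), "TPM")
})

test_that("log2 transform applies the pseudocount and refuses to repeat", {
    v <- matrix(c(0, 3, 7, 1), 2, 2,
                dimnames = list(c("a", "b"), c("S1", "S2")))
    x <- M6AExpression(v, c("mRNA", "mRNA"))
    t <- log2Transform(x)
    expect_true(isTransformed(t))
    expect_equal(exprValues(t),
                 matrix(c(0, 2, 3, 1), 2, 2, dimnames = dimnames(v)))
    expect_error(log2Transform(t), "already")
    expect_error(log2Transform(x, offset = 0), "offset")
})

test_that("filter and transform commute with sample subsetting", {
    set.seed(21)
    v <- matrix(rbinom(200, 1, 0.75) * runif(200, 0.1, 9), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("S%02d", 1:10)))
    x <- M6AExpression(v, rep("mRNA", 20))
    sub <- paste0("S0", 1:5)
    a <- log2Transform(filterExpressed(x[, sub], 0.6))
    b <- log2Transform(filterExpressed(x, 0))[, sub]
    keep <- intersect(rownames(a), rownames(b))
    expect_equal(exprValues(a[keep, ]), exprValues(b)[keep, ])
})

test_that("M6AExpression validity rejects malformed objects", {
    v <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("S1", "S2")))
    expect_error(M6AExpression(v, c("mRNA", "alien")), "role")
    expect_error(M6AExpression(-v, c("mRNA", "mRNA")), ">= 0")
    expect_error(M6AExpression(v * NA, c("mRNA", "mRNA")), "finite|numeric")
})

test_that("drug and clinical tables validate on load", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("drug_id\tS1\tS2\tS3", "D1\t1.5\tNA\t2", "D2\t0\t1\t2"), f)
    m <- readDrugResponse(f)
    expect_equal(dim(m), c(2L, 3L))
    expect_true(is.na(m["D1", "S2"]))

    g <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample_id\ttime_days\tevent", "S1\t10\t1", "S2\t5\t0"), g)
    cl <- readClinicalTable(g)
    expect_equal(nrow(cl), 2L)
    writeLines(c("sample_id\ttime_days\tevent", "S1\t0\t1"), g)
    expect_error(readClinicalTable(g), "> 0")
    writeLines(c("sample_id\ttime_days\tevent", "S1\t3\t2"), g)
    expect_error(readClinicalTable(g), "event")
})

test_that("interaction catalogs deduplicate and validate target classes", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("mirna_id\ttarget_id\ttarget_class",
                 "M1\tL1\tlncRNA", "M1\tL1\tlncRNA", "M1\tG1\tmRNA"), f)
    cat <- readInteractionCatalog(f)
    expect_equal(nrow(cat), 2L)
    writeLines(c("mirna_id\ttarget_id\ttarget_class", "M1\tX\tcircRNA"), f)
    expect_error(readInteractionCatalog(f), "circRNA")
})
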