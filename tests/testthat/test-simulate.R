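test_that("the same design and seed reproduce a cohort byte-for-byte", {
    p <- SimParams(nSamples = 40, nLncrnas = 12, nMirnas = 4, nMrnas = 15,
                   nTripleLncrnas = 1, mrnasPerTriple = 3, nDecoyPairs = 5,
                   nSequences = 3, seqLength = 300, seed = 9)
    run <- function(dir) {
        co <- simulateCohort(p)
        ex <- log2Transform(co$expr)
        writeCohort(co, dir,
                    drugs = simulateDrugResponse(p, ex, co$truth),
                    clinical = simulateSurvival(p, co$expr, co$truth),
                    sequences = simulateSequences(p))
        dir
    }
    d1 <- run(withr::local_tempdir())
    d2 <- run(withr::local_tempdir())
    for (f in list.files(d1, recursive = TRUE)) {
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = paste("md5 of", f))
    }
    # and every emitted table parses back through the readers
    expect_s4_class(readExpressionMatrix(file.path(d1, "expression.tsv")),
                    "M6AExpression")
    expect_true(nrow(readInteractionCatalog(
        file.path(d1, "interactions.tsv"))) > 0)
    expect_true(nrow(readDrugResponse(file.path(d1, "drugs.tsv"))) > 0)
    expect_true(nrow(readClinicalTable(file.path(d1, "clinical.tsv"))) > 0)
    expect_length(Biostrings::readDNAStringSet(file.path(d1, "lncrna.fa")), 3)
})

test_that("planted regulator-lncRNA pairs realize the target correlation", {
    p <- SimParams(nSamples = 500, rhoSignal = 0.6, fracRelated = 0.2,
                   nTripleLncrnas = 0, seed = 33)
    co <- simulateCohort(p)
    ex <- log2Transform(co$expr)
    v <- exprValues(ex)
    tp <- co$truth$relatedPairs
    expect_equal(nrow(tp), 12L)
    for (i in seq_len(nrow(tp))) {
        r <- cor(v[tp$lncrna_id[i], ], v[tp$regulator_id[i], ])
        s <- if (tp$sign[i] == "positive") 1 else -1
        expect_lt(abs(r - s * 0.6), 0.1)
    }
})

test_that("planted sponging triples realize the ceRNA sign pattern", {
    p <- SimParams(nSamples = 500, nTripleLncrnas = 2, mrnasPerTriple = 5,
                   seed = 14)
    co <- simulateCohort(p)
    v <- exprValues(log2Transform(co$expr))
    tr <- co$truth$triples
    expect_equal(nrow(tr), 10L)
    rLncMrna <- mapply(function(a, b) cor(v[a, ], v[b, ]),
                       tr$lncrna_id, tr$mrna_id)
    rMirLnc <- mapply(function(a, b) cor(v[a, ], v[b, ]),
                      tr$mirna_id, tr$lncrna_id)
    rMirMrna <- mapply(function(a, b) cor(v[a, ], v[b, ]),
                       tr$mirna_id, tr$mrna_id)
    # population values: 0.61, -0.6, -0.6
    expect_true(all(abs(rLncMrna - 0.61) < 0.15))
    expect_true(all(abs(rMirLnc + 0.6) < 0.15))
    expect_true(all(abs(rMirMrna + 0.6) < 0.15))
})

test_that("zero planting fractions yield empty truth", {
    p <- SimParams(nSamples = 30, fracRelated = 0, nTripleLncrnas = 0,
                   nDecoyPairs = 0, seed = 2)
    co <- simulateCohort(p)
    expect_equal(nrow(co$truth$relatedPairs), 0L)
    expect_equal(nrow(co$truth$triples), 0L)
    expect_equal(nrow(co$interactions), 0L)
})

test_that("over-planted designs are rejected at construction", {
    expect_error(SimParams(nLncrnas = 10, fracRelated = 1,
                           nTripleLncrnas = 2), "more planted")
    expect_error(SimParams(rhoSignal = 1), "rhoSignal")
    expect_error(SimParams(spongeRhoMirna = 0.9, spongeRhoShared = 0.6),
                 "variance")
})

test_that("noise-free single-gene drug coupling gives perfect correlation", {
    p <- SimParams(nSamples = 60, nTripleLncrnas = 1, mrnasPerTriple = 1,
                   nDrugs = 1, nEffectGenes = 1, drugEffectSize = 1,
                   drugNoiseSd = 0, seed = 5)
    co <- simulateCohort(p)
    ex <- log2Transform(co$expr)
    dr <- simulateDrugResponse(p, ex, co$truth)
    g <- dr$drugEffects$gene[1]
    expect_equal(cor(exprValues(ex)[g, ], dr$ic50[1, ]), 1)
    expect_identical(dr$drugEffects$direction[1], "resistance")
})

test_that("a null drug has near-zero correlation with every gene", {
    p <- SimParams(nSamples = 500, nDrugs = 1, drugEffectSize = 0,
                   seed = 19)
    co <- simulateCohort(p)
    ex <- log2Transform(co$expr)
    dr <- simulateDrugResponse(p, ex, co$truth)
    roles <- geneRoles(ex)
    v <- exprValues(ex)[roles == "mRNA", ]
    r <- abs(cor(t(v), dr$ic50[1, ]))
    # null |r| has mean ~ sqrt(2/(pi n)) = 0.036 at n = 500
    expect_lt(mean(r), 0.06)
    expect_true(all(dr$drugEffects$direction == "null"))
})

test_that("censoring fraction zero leaves every event observed", {
    p <- SimParams(nSamples = 50, censoringFraction = 0, seed = 3)
    co <- simulateCohort(p)
    sv <- simulateSurvival(p, co$expr, co$truth)
    expect_true(all(sv$clinical$event == 1L))
    expect_true(all(sv$clinical$time_days > 0))
})

test_that("uniform censoring approximates the requested fraction", {
    p <- SimParams(nSamples = 2000, censoringFraction = 0.3, seed = 8)
    co <- simulateCohort(p)
    sv <- simulateSurvival(p, co$expr, co$truth)
    expect_lt(abs(mean(sv$clinical$event == 0) - 0.3), 0.05)
})

test_that("sequence truth is exact on the emitted strings", {
    p <- SimParams(nSequences = 5, seqLength = 800, gcTarget = 0.5,
                   cpgEnrichment = 2, drachPlanted = 3, seed = 12)
    sq <- simulateSequences(p)
    expect_identical(unname(tools::md5sum(tempfileFasta(sq))),
                     unname(tools::md5sum(tempfileFasta(
                         simulateSequences(p)))))
    # planted motifs are a lower bound on the realized count
    expect_true(all(sq$truth$drach_count >= sq$truth$planted_drach))
    # truth agrees with the Biostrings-based feature module on every record
    feats <- sequenceFeatures(sq$sequences)
    expect_equal(feats$gc, sq$truth$gc)
    expect_equal(feats$cpg_count, sq$truth$cpg_count)
    expect_equal(feats$drach_count, sq$truth$drach_count)
})

test_that("long sequences concentrate near the GC target", {
    p <- SimParams(nSequences = 2, seqLength = 10000, gcTarget = 0.5,
                   cpgEnrichment = 1, drachPlanted = 0, seed = 4)
    sq <- simulateSequences(p)
    expect_true(all(sq$truth$gc > 0.45 & sq$truth$gc < 0.55))
})

test_that("motif planting refuses sequences shorter than the motif", {
    expect_error(
        simulateSequences(SimParams(seqLength = 4, drachPlanted = 1)),
        "longer than the sequence")
})
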