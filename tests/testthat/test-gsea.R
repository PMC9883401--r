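test_that("drug ranking orders genes by IC50 correlation deterministically", {
    set.seed(6)
    n <- 30
    v <- matrix(rnorm(5 * n) + 10, 5, n,
                dimnames = list(paste0("G", 1:5), paste0("S", 1:n)))
    ic50 <- setNames(v["G3", ], colnames(v))   # G3 identical to the IC50
    v["G1", ] <- -ic50                          # G1 perfectly anti-correlated
    ex <- M6AExpression(v - min(v) + 1, rep("mRNA", 5), transformed = TRUE)
    rk <- rankByDrug(ex, ic50, drugId = "cisplatin")
    expect_identical(rk@genes[1], "G3")
    expect_equal(rk@metric[1], 1)
    expect_identical(rk@genes[5], "G1")
    expect_equal(rk@metric[5], -1)
    # permuting the gene rows does not change the ranking
    ex2 <- M6AExpression(v[c(4, 2, 5, 1, 3), ] - min(v) + 1, rep("mRNA", 5),
                         transformed = TRUE)
    rk2 <- rankByDrug(ex2, ic50, drugId = "cisplatin")
    expect_identical(rk2@genes, rk@genes)
    expect_equal(rk2@metric, rk@metric)
    # fewer than 3 complete pairs is an error
    expect_error(rankByDrug(ex, ic50[1:2]), "fewer than 3")
    short <- ic50; short[3:n] <- NA
    expect_error(rankByDrug(ex, short), "fewer than 3")
})

test_that("enrichment scores match the hand-derived walks", {
    rg <- makeRanked(c(4, 3, 2, 1), genes = paste0("g", 1:4))
    expect_equal(enrichmentScore(rg, "g1")$es, 1)
    expect_equal(enrichmentScore(rg, "g4")$es, -1)
    es2 <- enrichmentScore(rg, "g2")
    expect_equal(es2$es, 2 / 3)
    expect_equal(es2$walk, c(-1 / 3, 2 / 3, 1 / 3, 0))
    expect_error(enrichmentScore(rg, paste0("g", 1:4)), "proper subset")
    expect_error(enrichmentScore(rg, character(0)), "proper subset")
    expect_error(enrichmentScore(rg, "g9"), "absent")
    zero <- makeRanked(c(1, 0, -1), genes = c("a", "b", "c"))
    expect_error(enrichmentScore(zero, "b"), "N_R")
})

test_that("the production walk equals the naive oracle on random instances", {
    set.seed(99)
    for (i in 1:200) {
        N <- sample(5:50, 1)
        metric <- sort(rnorm(N), decreasing = TRUE)
        nh <- sample(seq_len(N - 1), 1)
        hit <- rep(FALSE, N)
        hit[sample.int(N, nh)] <- TRUE
        if (sum(abs(metric[hit])) == 0) next
        rg <- makeRanked(metric)
        got <- enrichmentScore(rg, rg@genes[hit])
        ref <- naiveEnrichmentScore(metric, hit)
        expect_equal(got$es, ref$es, tolerance = 1e-12)
        expect_equal(got$walk, ref$walk, tolerance = 1e-12)
        expect_lt(abs(got$walk[N]), 1e-12)   # walk conservation
        expect_lte(abs(got$es), 1)
    }
})

test_that("permutation p-values are reproducible and match their definition", {
    set.seed(4)
    metric <- sort(rnorm(40), decreasing = TRUE)
    rg <- makeRanked(metric)
    s <- rg@genes[c(2, 5, 9)]
    p1 <- permutationPvalue(rg, s, B = 150, seed = 11)
    p2 <- permutationPvalue(rg, s, B = 150, seed = 11)
    expect_identical(p1, p2)
    # recompute from the same seeded draws with the naive oracle
    esObs <- enrichmentScore(rg, s)$es
    esNull <- withr::with_seed(11, vapply(1:150, function(b) {
        idx <- sample.int(40, 3)
        hit <- rep(FALSE, 40); hit[idx] <- TRUE
        naiveEnrichmentScore(metric, hit)$es
    }, numeric(1)))
    same <- sign(esNull) == sign(esObs)
    expect_equal(p1$p,
                 (1 + sum(same & abs(esNull) >= abs(esObs))) / (1 + sum(same)))
    # B = 1 can only produce 1/2 or 1
    ps <- vapply(1:20, function(i)
        permutationPvalue(rg, s, B = 1, seed = i)$p, numeric(1))
    expect_true(all(ps %in% c(0.5, 1)))
    expect_error(permutationPvalue(rg, s, B = 0), "B")
})

test_that("resistant/sensitive calls follow the sign and FDR rule", {
    res <- data.frame(
        lncrna_id = c("L1", "L2", "L3"), drug_id = "D1",
        es = c(0.5, -0.5, -0.5), n_hits = 5,
        p_perm = c(0.001, 0.9, 0.002), stringsAsFactors = FALSE)
    out <- callDrugAssociations(res, qMax = 0.05)
    expect_identical(out$call, c("resistant", "ns", "sensitive"))
    expect_equal(out$q, bhAdjust(res$p_perm))
})

test_that("drug screen recovers the planted resistance coupling", {
    p <- SimParams(nSamples = 300, seed = 55)
    co <- simulateCohort(p)
    ex <- log2Transform(filterExpressed(co$expr))
    dr <- simulateDrugResponse(p, ex, co$truth)
    ax <- candidateAxes(co$interactions, co$truth$tripleLncrnas)
    net <- filterTriples(ax, ex)
    ds <- drugScreen(net, ex, dr$ic50, B = 200, seed = 21)
    for (d in unique(dr$drugEffects$drug_id)) {
        l <- dr$drugEffects$coupled_lncrna[dr$drugEffects$drug_id == d][1]
        row <- ds[ds$drug_id == d & ds$lncrna_id == l, ]
        expect_equal(nrow(row), 1L)
        expect_gt(row$es, 0)
        expect_identical(row$call, "resistant")
    }
})
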