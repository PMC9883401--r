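#' Construct a simulation design
#'
#' Defaults define the reference study conditions used throughout the
#' package's validation: cohorts of 500 samples; a planted regulator-lncRNA
#' correlation of 0.6 with one fifth of lncRNAs m6A-related (one fifth of
#' those with negative sign); two sponged lncRNAs, each sharing one miRNA
#' with five mRNAs at loadings (-0.6 on the miRNA, 0.5 on a shared latent),
#' giving population correlations of -0.6 (miRNA sides) and 0.61
#' (lncRNA-mRNA); two drugs whose IC50 is a unit-weight sum of five planted
#' resistance genes plus unit Gaussian noise; exponential survival with a
#' planted log hazard ratio of log 2 on the high-expression group and 30%
#' uniform censoring; and 2 kb sequences at GC 0.5 with 2x CpG enrichment
#' and 3 planted DRACH motifs.
#'
#' @param nSamples samples per cohort (default 500).
#' @param nLncrnas,nMirnas,nMrnas molecule counts (defaults 60, 10, 80);
#'   the 21 catalog regulators are always included.
#' @param rhoSignal planted regulator-lncRNA correlation magnitude (0.6).
#' @param fracRelated fraction of lncRNAs planted as m6A-related (0.2).
#' @param fracNegative fraction of planted pairs with negative sign (0.2).
#' @param nTripleLncrnas sponged lncRNAs, one miRNA each (2).
#' @param mrnasPerTriple mRNAs de-repressed per sponged lncRNA (5).
#' @param spongeRhoMirna magnitude of the (negative) miRNA loading (0.6).
#' @param spongeRhoShared loading on the shared positive latent (0.5).
#' @param nDecoyPairs random non-planted interaction-catalog pairs (20).
#' @param nDrugs,nEffectGenes,drugEffectSize,drugNoiseSd drug model
#'   (2 drugs, 5 effect genes, weight 1, noise sd 1).
#' @param baselineHazard,survivalBeta,censoringFraction survival model
#'   (0.002 per day, log 2, 0.3).
#' @param nSequences,seqLength,gcTarget,cpgEnrichment,drachPlanted sequence
#'   model (20 sequences, 2000 nt, GC 0.5, CpG factor 2, 3 motifs).
#' @param seed master seed; every stage derives its own stream from it.
#' @return a validated [SimParams-class].
#' @export
SimParams <- function(nSamples = 500, nLncrnas = 60, nMirnas = 10,
                      nMrnas = 80, rhoSignal = 0.6, fracRelated = 0.2,
                      fracNegative = 0.2, nTripleLncrnas = 2,
                      mrnasPerTriple = 5, spongeRhoMirna = 0.6,
                      spongeRhoShared = 0.5, nDecoyPairs = 20,
                      nDrugs = 2, nEffectGenes = 5, drugEffectSize = 1,
                      drugNoiseSd = 1, baselineHazard = 0.002,
                      survivalBeta = log(2), censoringFraction = 0.3,
                      nSequences = 20, seqLength = 2000, gcTarget = 0.5,
                      cpgEnrichment = 2, drachPlanted = 3, seed = 1) {
    new("SimParams", nSamples = nSamples, nLncrnas = nLncrnas,
        nMirnas = nMirnas, nMrnas = nMrnas, rhoSignal = rhoSignal,
        fracRelated = fracRelated, fracNegative = fracNegative,
        nTripleLncrnas = nTripleLncrnas, mrnasPerTriple = mrnasPerTriple,
        spongeRhoMirna = spongeRhoMirna, spongeRhoShared = spongeRhoShared,
        nDecoyPairs = nDecoyPairs, nDrugs = nDrugs,
        nEffectGenes = nEffectGenes, drugEffectSize = drugEffectSize,
        drugNoiseSd = drugNoiseSd, baselineHazard = baselineHazard,
        survivalBeta = survivalBeta, censoringFraction = censoringFraction,
        nSequences = nSequences, seqLength = seqLength, gcTarget = gcTarget,
        cpgEnrichment = cpgEnrichment, drachPlanted = drachPlanted,
        seed = seed)
}

# Latent N(0,1) values are mapped to a positive TPM scale as 2^(z + 4)
# (log-normal abundance, median TPM 16). After the pipeline's log2(TPM + 1)
# the values are z + 4 + log2(1 + 2^-(z+4)), i.e. the planted Pearson
# structure survives the round trip essentially intact, and every gene
# passes the TPM > 0 breadth filter.
.LOG2_MEAN <- 4
.toTPM <- function(z) 2^(z + .LOG2_MEAN)

#' Simulate an expression cohort with planted ground truth
#'
#' Draws regulator expression i.i.d. Gaussian in a latent space; plants
#' m6A-related lncRNAs as rho * z_regulator + sqrt(1 - rho^2) * noise (with
#' the configured sign); plants sponged lncRNAs and their mRNA partners with
#' a negative loading on a shared miRNA plus a shared positive latent (the
#' ceRNA sign pattern); leaves all other genes independent; and maps every
#' latent value to the TPM scale. The interaction catalog contains the
#' planted miRNA-lncRNA and miRNA-mRNA pairs plus random decoys. The truth
#' tables are exhaustive: any downstream discovery absent from them is a
#' false positive by construction. The same design and seed reproduce the
#' cohort byte-for-byte.
#'
#' @param params a [SimParams-class].
#' @param cancerId cohort label; it also salts the random stream, so
#'   different cancers share the planted identities but have independent
#'   sample draws.
#' @return list with \code{expr} (TPM-scale [M6AExpression-class]),
#'   \code{interactions} (catalog data.frame) and \code{truth} (list with
#'   \code{relatedPairs}, \code{triples}, \code{tripleLncrnas}).
#' @export
simulateCohort <- function(params, cancerId = "cancer01") {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    p <- params
    n <- p@nSamples
    regs <- m6aRegulators()$symbol
    lncIds <- sprintf("LNC%04d", seq_len(p@nLncrnas))
    mirIds <- sprintf("MIR%03d", seq_len(p@nMirnas))
    mrnaIds <- sprintf("GENE%04d", seq_len(p@nMrnas))
    samples <- sprintf("S%04d", seq_len(n))
    nRel <- round(p@fracRelated * p@nLncrnas)
    nTri <- p@nTripleLncrnas

    .withSeed(.deriveSeed(p@seed, paste0("expression|", cancerId)), function() {
        Zreg <- matrix(stats::rnorm(length(regs) * n), length(regs), n,
                       dimnames = list(regs, samples))
        Zlnc <- matrix(stats::rnorm(p@nLncrnas * n), p@nLncrnas, n,
                       dimnames = list(lncIds, samples))
        Zmir <- matrix(stats::rnorm(p@nMirnas * n), p@nMirnas, n,
                       dimnames = list(mirIds, samples))
        Zmrna <- matrix(stats::rnorm(p@nMrnas * n), p@nMrnas, n,
                        dimnames = list(mrnaIds, samples))

        relatedPairs <- data.frame(lncrna_id = character(),
                                   regulator_id = character(),
                                   sign = character(),
                                   stringsAsFactors = FALSE)
        if (nRel > 0) {
            relLnc <- lncIds[seq_len(nRel)]
            relReg <- regs[((seq_len(nRel) - 1L) %% length(regs)) + 1L]
            nNeg <- round(p@fracNegative * nRel)
            sgn <- rep(1, nRel)
            if (nNeg > 0) sgn[seq_len(nNeg)] <- -1
            rho <- p@rhoSignal
            for (i in seq_len(nRel)) {
                Zlnc[relLnc[i], ] <- sgn[i] * rho * Zreg[relReg[i], ] +
                    sqrt(1 - rho^2) * stats::rnorm(n)
            }
            relatedPairs <- data.frame(
                lncrna_id = relLnc, regulator_id = relReg,
                sign = ifelse(sgn > 0, "positive", "negative"),
                stringsAsFactors = FALSE)
        }

        triples <- data.frame(lncrna_id = character(),
                              mirna_id = character(),
                              mrna_id = character(), stringsAsFactors = FALSE)
        if (nTri > 0) {
            a <- p@spongeRhoMirna
            b <- p@spongeRhoShared
            resid <- sqrt(1 - a^2 - b^2)
            triLnc <- lncIds[p@nLncrnas - nTri + seq_len(nTri)]
            triMir <- mirIds[seq_len(nTri)]
            rows <- vector("list", nTri)
            for (j in seq_len(nTri)) {
                m <- Zmir[triMir[j], ]
                u <- stats::rnorm(n)
                Zlnc[triLnc[j], ] <- -a * m + b * u + resid * stats::rnorm(n)
                gidx <- (j - 1L) * p@mrnasPerTriple +
                    seq_len(p@mrnasPerTriple)
                gIds <- mrnaIds[gidx]
                for (g in gIds)
                    Zmrna[g, ] <- -a * m + b * u + resid * stats::rnorm(n)
                rows[[j]] <- data.frame(lncrna_id = triLnc[j],
                                        mirna_id = triMir[j],
                                        mrna_id = gIds,
                                        stringsAsFactors = FALSE)
            }
            triples <- do.call(rbind, rows)
        }

        values <- .toTPM(rbind(Zreg, Zlnc, Zmir, Zmrna))
        roles <- rep(c("regulator", "lncRNA", "miRNA", "mRNA"),
                     c(length(regs), p@nLncrnas, p@nMirnas, p@nMrnas))
        expr <- M6AExpression(values, roles, transformed = FALSE)

        interactions <- triples
        if (nrow(interactions)) {
            interactions <- rbind(
                unique(data.frame(mirna_id = triples$mirna_id,
                                  target_id = triples$lncrna_id,
                                  target_class = "lncRNA",
                                  stringsAsFactors = FALSE)),
                data.frame(mirna_id = triples$mirna_id,
                           target_id = triples$mrna_id,
                           target_class = "mRNA", stringsAsFactors = FALSE))
        } else {
            interactions <- data.frame(mirna_id = character(),
                                       target_id = character(),
                                       target_class = character(),
                                       stringsAsFactors = FALSE)
        }
        if (p@nDecoyPairs > 0) {
            freeMir <- if (nTri < p@nMirnas)
                mirIds[(nTri + 1L):p@nMirnas] else mirIds
            decoys <- data.frame(
                mirna_id = sample(freeMir, p@nDecoyPairs, replace = TRUE),
                target_id = sample(c(lncIds, mrnaIds), p@nDecoyPairs,
                                   replace = TRUE),
                stringsAsFactors = FALSE)
            decoys$target_class <-
                ifelse(startsWith(decoys$target_id, "LNC"), "lncRNA", "mRNA")
            interactions <- unique(rbind(interactions, decoys))
        }
        rownames(interactions) <- NULL

        list(expr = expr, interactions = interactions,
             truth = list(relatedPairs = relatedPairs, triples = triples,
                          tripleLncrnas = unique(triples$lncrna_id)))
    })
}

#' Simulate drug IC50 coupled to planted resistance genes
#'
#' For each drug the per-sample IC50 is a weighted sum of the log2
#' expression of its effect genes plus Gaussian noise; a positive weight
#' makes the gene resistance-associated (expression up, IC50 up). When the
#' cohort carries planted ceRNA triples, each drug's effect genes are drawn
#' from the target mRNAs of one sponged lncRNA (cycling through them), so
#' that lncRNA's ceRNA set is genuinely enriched at the resistant end of the
#' drug's gene ranking; without triples the effect genes are random mRNAs.
#'
#' @param params a [SimParams-class].
#' @param expr the cohort's log2-transformed [M6AExpression-class].
#' @param truth the cohort's truth list (from [simulateCohort()]).
#' @return list with \code{ic50} (drug-by-sample matrix) and
#'   \code{drugEffects} (data.frame \code{drug_id}, \code{gene},
#'   \code{weight}, \code{direction}, \code{coupled_lncrna}).
#' @export
simulateDrugResponse <- function(params, expr, truth) {
    stopifnot(is(params, "SimParams"), is(expr, "M6AExpression"))
    if (!isTransformed(expr))
        stop("drug response simulation requires log2-transformed expression")
    p <- params
    if (p@nDrugs == 0)
        return(list(ic50 = matrix(numeric(0), 0, ncol(expr),
                                  dimnames = list(NULL, colnames(expr))),
                    drugEffects = data.frame()))
    roles <- geneRoles(expr)
    mrnas <- names(roles)[roles == "mRNA"]
    v <- exprValues(expr)
    .withSeed(.deriveSeed(p@seed, "drugs"), function() {
        drugIds <- sprintf("DRUG%02d", seq_len(p@nDrugs))
        ic50 <- matrix(NA_real_, p@nDrugs, ncol(v),
                       dimnames = list(drugIds, colnames(v)))
        eff <- vector("list", p@nDrugs)
        triLnc <- truth$tripleLncrnas
        for (d in seq_len(p@nDrugs)) {
            if (length(triLnc)) {
                l <- triLnc[((d - 1L) %% length(triLnc)) + 1L]
                pool <- truth$triples$mrna_id[truth$triples$lncrna_id == l]
            } else {
                l <- NA_character_
                pool <- sample(mrnas, p@nEffectGenes)
            }
            genes <- utils::head(pool, p@nEffectGenes)
            if (!all(genes %in% rownames(v)))
                stop("drug effect gene absent from the expression matrix")
            w <- rep(p@drugEffectSize, length(genes))
            signal <- if (length(genes))
                as.vector(w %*% v[genes, , drop = FALSE]) else 0
            ic50[d, ] <- signal + stats::rnorm(ncol(v), sd = p@drugNoiseSd)
            eff[[d]] <- data.frame(
                drug_id = drugIds[d], gene = genes, weight = w,
                direction = ifelse(w > 0, "resistance",
                                   ifelse(w < 0, "sensitivity", "null")),
                coupled_lncrna = l, stringsAsFactors = FALSE)
        }
        list(ic50 = ic50, drugEffects = do.call(rbind, eff))
    })
}

#' Simulate exponential survival with a planted hazard ratio
#'
#' Survival times are exponential with hazard h0 * exp(beta * x_high),
#' where x_high indicates above-median expression of the planted lncRNA
#' (the first m6A-related lncRNA by default). Censoring is independent
#' uniform on \[0, c\] with c solved numerically so the expected censoring
#' fraction matches the design; a censoring fraction of 0 leaves every
#' event observed.
#'
#' @param params a [SimParams-class].
#' @param expr the cohort's [M6AExpression-class] (any scale; the median
#'   split is scale-invariant).
#' @param truth the cohort's truth list.
#' @param lncrnaId lncRNA carrying the planted effect; default the first
#'   planted related lncRNA (first lncRNA row if none was planted). Must be
#'   present in the matrix.
#' @return list with \code{clinical} (data.frame \code{sample_id},
#'   \code{time_days}, \code{event}) and \code{survivalTruth}
#'   (\code{lncrna_id}, \code{beta}).
#' @export
simulateSurvival <- function(params, expr, truth, lncrnaId = NULL) {
    stopifnot(is(params, "SimParams"), is(expr, "M6AExpression"))
    p <- params
    roles <- geneRoles(expr)
    if (is.null(lncrnaId)) {
        lncrnaId <- if (nrow(truth$relatedPairs))
            truth$relatedPairs$lncrna_id[1L]
        else names(roles)[roles == "lncRNA"][1L]
    }
    if (!lncrnaId %in% rownames(expr))
        stop(sprintf("lncRNA '%s' absent from the expression matrix",
                     lncrnaId))
    x <- exprValues(expr)[lncrnaId, ]
    high <- as.numeric(medianSplit(x)) - 1
    rate <- p@baselineHazard * exp(p@survivalBeta * high)
    .withSeed(.deriveSeed(p@seed, "survival"), function() {
        tt <- stats::rexp(length(x), rate = rate)
        if (p@censoringFraction > 0) {
            cf <- p@censoringFraction
            # E[censored | c] for uniform censoring on [0, c] against the
            # cohort's mixture of exponential rates
            expCens <- function(cc)
                mean((1 - exp(-rate * cc)) / (rate * cc)) - cf
            upper <- 10 / min(rate)
            cc <- stats::uniroot(expCens, c(1e-8, upper), tol = 1e-10)$root
            cens <- stats::runif(length(x), 0, cc)
            event <- as.integer(tt <= cens)
            time <- pmin(tt, cens)
        } else {
            event <- rep(1L, length(x))
            time <- tt
        }
        list(clinical = data.frame(sample_id = names(x), time_days = time,
                                   event = event, stringsAsFactors = FALSE),
             survivalTruth = data.frame(lncrna_id = lncrnaId,
                                        beta = p@survivalBeta,
                                        stringsAsFactors = FALSE))
    })
}

#' Simulate lncRNA sequences with planted composition and motifs
#'
#' Sequences are drawn from a first-order composition model whose stationary
#' base frequencies hit the GC target in expectation and whose C-to-G
#' transition probability is multiplied by the CpG enrichment factor (then
#' renormalized). The requested number of DRACH 5-mers is spliced in at
#' evenly spaced, non-overlapping, recorded positions. The truth table
#' stores exact GC, CpG and DRACH counts recomputed post hoc on each emitted
#' string with plain string operations, independent of the Biostrings-based
#' feature module. A TSS record at each sequence midpoint is emitted for
#' profile analyses.
#'
#' @param params a [SimParams-class]; planting motifs longer than the
#'   sequence is an error.
#' @return list with \code{sequences} (named \code{DNAStringSet}),
#'   \code{truth} (data.frame \code{seq_id}, \code{length}, \code{gc},
#'   \code{cpg_count}, \code{drach_count}, \code{planted_drach}) and
#'   \code{tss} (\code{GRanges}, alternating strands).
#' @export
simulateSequences <- function(params) {
    stopifnot(is(params, "SimParams"))
    p <- params
    if (p@drachPlanted > 0 && p@seqLength < 5)
        stop("planted motifs are longer than the sequence")
    bases <- c("A", "C", "G", "T")
    gc <- p@gcTarget
    p0 <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    # guard degenerate GC targets so every row remains a distribution
    p0 <- pmax(p0, 1e-9)
    p0 <- p0 / sum(p0)
    trans <- rbind(A = p0, C = p0, G = p0, T = p0)
    pG <- min(p0[["G"]] * p@cpgEnrichment, 0.95)
    trans["C", ] <- p0 * (1 - pG) / (1 - p0[["G"]])
    trans["C", "G"] <- pG
    .withSeed(.deriveSeed(p@seed, "sequences"), function() {
        ids <- sprintf("LNCSEQ%03d", seq_len(p@nSequences))
        seqs <- character(p@nSequences)
        planted <- integer(p@nSequences)
        for (s in seq_len(p@nSequences)) {
            L <- p@seqLength
            ch <- character(L)
            ch[1L] <- sample(bases, 1L, prob = p0)
            for (i in 2L:L)
                ch[i] <- sample(bases, 1L, prob = trans[ch[i - 1L], ])
            k <- p@drachPlanted
            if (k > 0) {
                starts <- floor(seq_len(k) * (L - 4) / (k + 1)) + 1L
                for (st in starts) {
                    motif <- c(sample(c("A", "G", "T"), 1L),
                               sample(c("A", "G"), 1L), "A", "C",
                               sample(c("A", "C", "T"), 1L))
                    ch[st:(st + 4L)] <- motif
                }
                planted[s] <- k
            }
            seqs[s] <- paste(ch, collapse = "")
        }
        truth <- data.frame(
            seq_id = ids, length = nchar(seqs),
            gc = .rawGC(seqs), cpg_count = .rawCount(seqs, "CG"),
            drach_count = .rawCount(seqs, "(?=[AGT][AG]AC[ACT])",
                                    perl = TRUE),
            planted_drach = planted, stringsAsFactors = FALSE)
        dss <- Biostrings::DNAStringSet(seqs)
        names(dss) <- ids
        mid <- floor(p@seqLength / 2)
        tss <- GenomicRanges::GRanges(
            seqnames = ids,
            ranges = IRanges::IRanges(start = mid, width = 1L),
            strand = rep_len(c("+", "-"), p@nSequences))
        list(sequences = dss, truth = truth, tss = tss)
    })
}

# post-hoc truth counters, deliberately independent of Biostrings
.rawGC <- function(s) {
    vapply(strsplit(s, ""), function(ch) {
        keep <- ch != "N"
        sum(ch[keep] %in% c("G", "C")) / sum(keep)
    }, numeric(1))
}

.rawCount <- function(s, pattern, perl = FALSE) {
    vapply(s, function(x) {
        m <- gregexpr(pattern, x, perl = perl)[[1L]]
        if (m[1L] == -1L) 0L else length(m)
    }, integer(1), USE.NAMES = FALSE)
}

#' Write a simulated cohort to a directory of text files
#'
#' Emits \code{expression.tsv}, \code{interactions.tsv} and the truth
#' tables; with drug, clinical or sequence components supplied, also
#' \code{drugs.tsv}, \code{clinical.tsv}, \code{lncrna.fa} and
#' \code{tss.bed}. All outputs are plain text and byte-deterministic for a
#' fixed design and seed.
#'
#' @param cohort list from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param drugs optional list from [simulateDrugResponse()].
#' @param clinical optional list from [simulateSurvival()].
#' @param sequences optional list from [simulateSequences()].
#' @return invisibly, the output directory.
#' @export
writeCohort <- function(cohort, dir, drugs = NULL, clinical = NULL,
                        sequences = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeExpressionMatrix(cohort$expr, file.path(dir, "expression.tsv"))
    writeInteractionCatalog(cohort$interactions,
                            file.path(dir, "interactions.tsv"))
    truthDir <- file.path(dir, "truth")
    dir.create(truthDir, showWarnings = FALSE)
    utils::write.table(cohort$truth$relatedPairs,
                       file.path(truthDir, "related_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$truth$triples,
                       file.path(truthDir, "triples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(drugs)) {
        writeDrugResponse(drugs$ic50, file.path(dir, "drugs.tsv"))
        utils::write.table(drugs$drugEffects,
                           file.path(truthDir, "drug_effects.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(clinical)) {
        writeClinicalTable(clinical$clinical, file.path(dir, "clinical.tsv"))
        utils::write.table(clinical$survivalTruth,
                           file.path(truthDir, "survival.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(sequences)) {
        Biostrings::writeXStringSet(sequences$sequences,
                                    file.path(dir, "lncrna.fa"))
        rtracklayer::export(sequences$tss, file.path(dir, "tss.bed"))
        utils::write.table(sequences$truth,
                           file.path(truthDir, "sequences.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}
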