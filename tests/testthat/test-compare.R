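test_that("a model maps onto itself as the identity", {
    sim <- generateMotifPair(generatorProfile(seed = 2), nA = 50,
        nB = 50, seed = 2)
    model <- buildConsensus(sim$alnA)
    map <- mapColumns(model, model)
    expect_equal(map$matches[, "colA"], seq_len(ncol(model)))
    expect_equal(map$matches[, "colB"], seq_len(ncol(model)))
    expect_length(map$unmatchedA, 0)
    expect_length(map$unmatchedB, 0)
})

test_that("an inserted hairpin shows up as an unmatched run", {
    sim <- generateMotifPair(generatorProfile(seed = 4), nA = 150,
        nB = 150, seed = 4)
    modelA <- buildConsensus(sim$alnA)  # carries the 10-column element
    modelB <- buildConsensus(sim$alnB)
    map <- mapColumns(modelA, modelB)
    span <- sim$truth$element$spanA
    expect_equal(sort(map$unmatchedA), span[1]:span[2])
    expect_length(map$unmatchedB, 0)
    # all other columns matched in order
    expect_equal(nrow(map$matches), ncol(modelB))
})

test_that("column maps are monotone and complete for arbitrary profiles", {
    for (seed in c(21, 22, 23)) {
        mA <- modelFromProbs(randomProbs(17, seed))
        mB <- modelFromProbs(randomProbs(12, seed + 100))
        map <- mapColumns(mA, mB)
        expect_true(all(diff(map$matches[, "colA"]) > 0))
        expect_true(all(diff(map$matches[, "colB"]) > 0))
        expect_equal(sort(c(map$matches[, "colA"], map$unmatchedA)),
            seq_len(17))
        expect_equal(sort(c(map$matches[, "colB"], map$unmatchedB)),
            seq_len(12))
    }
})

test_that("the aligner attains the brute-force DP optimum", {
    gapOpen <- -1.0; gapExtend <- -0.2
    for (seed in c(31, 32, 33, 34)) {
        set.seed(seed)
        nA <- sample(5:30, 1); nB <- sample(5:30, 1)
        mA <- modelFromProbs(randomProbs(nA, seed))
        mB <- modelFromProbs(randomProbs(nB, seed + 50))
        S <- MotifContrast:::.matchScoreMatrix(mA, mB)
        map <- mapColumns(mA, mB, gapOpen, gapExtend)
        oracle <- oracleAlignScore(S, gapOpen, gapExtend)
        expect_equal(map$score, oracle, tolerance = 1e-9)
        # the returned path itself realises that score
        expect_equal(columnMapScore(map, S, gapOpen, gapExtend),
            oracle, tolerance = 1e-9)
    }
})

test_that("a curated anchor map overrides the automatic alignment", {
    mA <- modelFromProbs(randomProbs(8, 61))
    mB <- modelFromProbs(randomProbs(8, 62))
    anchors <- data.frame(colA = c(1, 3, 8), colB = c(2, 4, 7))
    map <- mapColumns(mA, mB, anchors = anchors)
    expect_equal(map$matches[, "colA"], c(1L, 3L, 8L))
    expect_equal(map$matches[, "colB"], c(2L, 4L, 7L))
    expect_equal(map$unmatchedA, c(2L, 4:7))
    expect_error(mapColumns(mA, mB,
        anchors = data.frame(colA = c(3, 1), colB = c(1, 2))),
        "strictly increasing")
})

test_that("identity contrasts are graded by the tau thresholds", {
    prof <- function(nA, nC, nG, nU, nGap = 0L)
        MotifContrast:::.columnProfileFromCounts(
            c(A = nA, C = nC, G = nG, U = nU, gap = nGap))
    # always-G vs never-G: the strict archetype
    f <- identityContrast(prof(0L, 0L, 100L, 0L), prof(100L, 0L, 0L, 0L))
    expect_equal(f$grade, "strict")
    expect_equal(f$contrast, 1.0)
    expect_equal(f$nt, "A")  # maximal contrast reported on one of the pair
    # identical profiles: no feature
    expect_null(identityContrast(prof(50L, 50L, 0L, 0L),
        prof(50L, 50L, 0L, 0L)))
    # 0.92 vs 0.08: high, not strict
    f <- identityContrast(prof(8L, 92L, 0L, 0L), prof(92L, 8L, 0L, 0L))
    expect_equal(f$grade, "high")
    expect_equal(f$contrast, 0.84)
    # low-presence columns are not judged on identity
    expect_null(identityContrast(prof(40L, 0L, 0L, 0L, 60L),
        prof(100L, 0L, 0L, 0L)))
})

test_that("element presence measures span occupancy", {
    aln <- toyAln(a = "AAGGGGGGAA", b = "AAGGGGGGAA", c = "AA------AA",
        ss = "..........")
    expect_equal(elementPresence(aln, c(3, 8)), 2 / 3)
    expect_equal(elementPresence(aln, c(3, 8), minResidues = 1L), 2 / 3)
    expect_equal(elementPresence(aln, c(1, 2), minResidues = 2L), 1.0)
    full <- toyAln(a = "GGGG", b = "CCCC")
    expect_equal(elementPresence(full, c(1, 4), minResidues = 4L), 1.0)
    expect_error(elementPresence(full, c(0, 4)), "outside")
})

test_that("planted features are recovered and graded correctly", {
    sim <- generateMotifPair(generatorProfile(seed = 5), nA = 200,
        nB = 200, seed = 5)
    mA <- buildConsensus(sim$alnA)
    mB <- buildConsensus(sim$alnB)
    map <- mapColumns(mA, mB)
    feats <- findDiscriminatingFeatures(sim$alnA, sim$alnB, mA, mB, map)
    strict <- feats[feats$grade == "strict", ]
    idf <- strict[strict$kind == "identity_contrast", ]
    expect_setequal(idf$colA, sim$truth$contrasts$colA)
    expect_setequal(idf$colB, sim$truth$contrasts$colB)
    el <- strict[strict$kind == "element_presence", ]
    expect_equal(nrow(el), 1L)
    expect_equal(c(el$spanStart, el$spanEnd), sim$truth$element$spanA)
    expect_equal(nrow(strict), 4L)  # nothing else reaches strict
    # output is sorted by contrast, descending
    expect_true(all(diff(feats$contrast) <= 0))
})

test_that("feature detection is symmetric under motif swap", {
    sim <- generateMotifPair(generatorProfile(seed = 6), nA = 120,
        nB = 120, seed = 6)
    mA <- buildConsensus(sim$alnA)
    mB <- buildConsensus(sim$alnB)
    fAB <- findDiscriminatingFeatures(sim$alnA, sim$alnB, mA, mB,
        mapColumns(mA, mB))
    fBA <- findDiscriminatingFeatures(sim$alnB, sim$alnA, mB, mA,
        mapColumns(mB, mA))
    expect_equal(nrow(fAB), nrow(fBA))
    expect_equal(sort(fAB$contrast), sort(fBA$contrast))
    expect_equal(table(fAB$grade), table(fBA$grade))
    idAB <- fAB[fAB$kind == "identity_contrast", ]
    idBA <- fBA[fBA$kind == "identity_contrast", ]
    expect_setequal(idAB$colA, idBA$colB)
    expect_setequal(idAB$colB, idBA$colA)
})

test_that("two samples of one null profile yield no strict features", {
    prof <- generatorProfile(seed = 8, nContrasts = 0L,
        plantElement = FALSE)
    for (seed in c(81, 82, 83)) {
        simA <- generateMotifPair(prof, nA = 200, nB = 1, seed = seed)
        simB <- generateMotifPair(prof, nA = 200, nB = 1,
            seed = seed + 1000)
        mA <- buildConsensus(simA$alnA)
        mB <- buildConsensus(simB$alnA)
        feats <- findDiscriminatingFeatures(simA$alnA, simB$alnA, mA, mB,
            mapColumns(mA, mB))
        expect_equal(sum(feats$grade == "strict"), 0L)
    }
})

test_that("sub-strict planted contrasts are graded high", {
    prof <- generatorProfile(seed = 9, contrastHi = 0.95)
    sim <- generateMotifPair(prof, nA = 400, nB = 400, seed = 9)
    mA <- buildConsensus(sim$alnA)
    mB <- buildConsensus(sim$alnB)
    feats <- findDiscriminatingFeatures(sim$alnA, sim$alnB, mA, mB,
        mapColumns(mA, mB))
    idf <- feats[feats$kind == "identity_contrast" &
        feats$colA %in% sim$truth$contrasts$colA, ]
    expect_equal(nrow(idf), 3L)
    expect_true(all(idf$grade == "high"))
})

test_that("feature count is monotone non-increasing in tauHi", {
    sim <- generateMotifPair(generatorProfile(seed = 10), nA = 150,
        nB = 150, seed = 10)
    mA <- buildConsensus(sim$alnA)
    mB <- buildConsensus(sim$alnB)
    map <- mapColumns(mA, mB)
    counts <- vapply(c(0.90, 0.95, 0.97, 0.99), function(tau) {
        f <- findDiscriminatingFeatures(sim$alnA, sim$alnB, mA, mB, map,
            tauHi = tau)
        sum(f$grade == "strict")
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("gene subsetting filters by case-folded domain labels", {
    md <- data.frame(
        gene_domain = c("PRK07324", "prk07324", "GNAT;PRK07324", "GNAT",
            NA, "COG2076", "MATE", "PRK07324", "GNAT", "COG2076"),
        row.names = sprintf("s%02d", 1:10))
    aln <- randomAln(10, 8, seed = 77)
    aln <- MotifAlignment(gappedSeqs(aln), ssCons(aln), metadata =
        data.frame(md, row.names = seqIDs(aln)), name = "g")
    sub <- suppressMessages(subsetByGene(aln, "PRK07324"))
    expect_equal(nrow(sub), 4L)
    expect_warning(suppressMessages(subsetByGene(aln, "NOPE")),
        "no sequences")
    sub0 <- suppressWarnings(suppressMessages(subsetByGene(aln, "NOPE")))
    expect_equal(nrow(sub0), 0L)
    noMd <- randomAln(3, 8, seed = 78)
    expect_error(subsetByGene(noMd, "PRK07324"), "gene_domain")
})
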