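test_that("column profiles report exact counts and fractions", {
    aln <- toyAln(a1 = "AG", a2 = "AG", a3 = "AG", a4 = "AG", a5 = "AG",
        a6 = "AG", a7 = "AG", a8 = "AC", a9 = "AC", a10 = "A-")
    p1 <- columnProfile(aln, 1L)
    expect_equal(unname(p1$identityFractions[["A"]]), 1.0)
    expect_equal(p1$presentFraction, 1.0)
    p2 <- columnProfile(aln, 2L)
    expect_equal(unname(p2$identityFractions[["G"]]), 7 / 9)
    expect_equal(p2$presentFraction, 0.9)
    expect_equal(sum(p2$identityFractions), 1.0)
    expect_error(columnProfile(aln, 3L), "out of range")

    # half gap, all-G residues
    aln <- toyAln(b1 = "G", b2 = "G", b3 = "G", b4 = "G", b5 = "G",
        b6 = "-", b7 = "-", b8 = "-", b9 = "-", b10 = "-")
    p <- columnProfile(aln, 1L)
    expect_equal(p$presentFraction, 0.5)
    expect_equal(unname(p$identityFractions[["G"]]), 1.0)
})

test_that("conservation tiers follow the 97/90/75 and 50 thresholds", {
    mk <- function(nA, nC, nGap) {
        counts <- c(A = nA, C = nC, G = 0L, U = 0L, gap = nGap)
        MotifContrast:::.columnProfileFromCounts(counts)
    }
    t <- conservationTiers(mk(100L, 0L, 0L))
    expect_equal(t$identityTier, 97L)
    expect_equal(t$majorityNt, "A")
    expect_equal(t$presentTier, 97L)

    t <- conservationTiers(mk(80L, 20L, 0L))
    expect_equal(t$identityTier, 75L)
    expect_equal(t$presentTier, 97L)

    t <- conservationTiers(mk(55L, 0L, 45L))
    expect_equal(t$identityTier, 97L)   # identity among residues only
    expect_equal(t$presentTier, 50L)

    t <- conservationTiers(mk(50L, 50L, 0L))
    expect_equal(t$identityTier, 0L)

    # monotone: raising the majority fraction never lowers the tier
    tiers <- vapply(50:100, function(nA)
        conservationTiers(mk(nA, 100L - nA, 0L))$identityTier,
        integer(1))
    expect_true(all(diff(tiers) >= 0))
})

test_that("mutual information matches hand-derivable cases", {
    # invariant G:C pair in all rows: zero-entropy marginals
    aln <- toyAln(a = "GAAC", b = "GCGC", c = "GGUC", d = "GUAC",
        e = "GAGC", ss = "<..>")
    cs <- covariationScore(aln, 1L, 4L)
    expect_equal(cs$mi_bits, 0)
    expect_false(cs$covarying)
    expect_equal(cs$canonical_fraction, 1.0)

    # equiprobable {AU, GC, UA} over 30 rows: MI = log2(3)
    pairs <- rep(c("AU", "GC", "UA"), each = 10)
    rows <- sprintf("%sCC%s", substr(pairs, 1, 1), substr(pairs, 2, 2))
    names(rows) <- sprintf("r%02d", seq_along(rows))
    aln <- MotifAlignment(rows, "<..>")
    cs <- covariationScore(aln, 1L, 4L)
    expect_equal(cs$mi_bits, log2(3))
    expect_equal(cs$n_pair_types, 3L)
    expect_equal(cs$canonical_fraction, 1.0)
    expect_true(cs$covarying)
})

test_that("MI equals the brute-force entropy oracle on small alignments", {
    for (seed in 1:6) {
        aln <- randomAln(nrow = sample(5:20, 1), ncolumns = 8,
            seed = 100 + seed, gapProb = 0.15)
        codes <- MotifContrast:::.alnCodes(aln)
        miInfo <- MotifContrast:::.miMatrix(codes)
        for (i in 1:7) for (j in (i + 1):8) {
            expect_equal(miInfo$mi[i, j], bruteMI(aln, i, j),
                tolerance = 1e-10)
        }
    }
})

test_that("APC-corrected MI is near zero for independent columns", {
    aln <- randomAln(nrow = 1000, ncolumns = 12, seed = 42)
    ss <- "<<..<..>..>>"
    aln <- MotifAlignment(gappedSeqs(aln), ss, name = "null")
    model <- buildConsensus(aln)
    cov <- covariation(model)
    expect_true(all(abs(cov$mi_apc_bits) < 0.02))
    expect_false(any(cov$covarying))
})

test_that("pairs with few joint observations carry a low-support flag", {
    rows <- c(a = "AU----", b = "AU----", c = "AU----", d = "--GCAA",
        e = "--GCAA")
    aln <- MotifAlignment(rows, "<....>")
    expect_warning(cs <- covariationScore(aln, 1L, 6L), "low-support")
    expect_true(cs$low_support)
})

test_that("buildConsensus profiles every column deterministically", {
    sim <- generateMotifPair(generatorProfile(seed = 3), nA = 500,
        nB = 5, seed = 3)
    model <- buildConsensus(sim$alnA)
    expect_equal(ncol(model), ncol(sim$alnA))
    expect_equal(model@nRows, 500L)
    # planted >= 0.97-conservation columns reproduce their majority nt
    prof <- generatorProfile(seed = 3)
    idf <- identityFractions(model)
    shift <- function(col) ifelse(col > prof$element$after, col + 10L,
        col)
    for (k in seq_len(prof$nColumns)) {
        pmax <- max(prof$probsA[, k])
        if (pmax >= 0.97) {
            planted <- rownames(prof$probsA)[which.max(prof$probsA[, k])]
            expect_equal(model@identityNt[shift(k)], planted)
        }
    }
    # deterministic given the alignment
    model2 <- buildConsensus(sim$alnA)
    expect_equal(profileCounts(model2), profileCounts(model))
    expect_equal(covariation(model2), covariation(model))
})

test_that("single-row and empty alignments behave at the boundaries", {
    aln <- toyAln(only = "GGCAAUCC", ss = "<<....>>")
    model <- buildConsensus(aln)
    expect_true(all(model@identityTier == 97L))
    expect_true(all(model@presentTier == 97L))
    empty <- new("MotifAlignment", name = "e", rows = character(0),
        ssCons = "....", metadata = S4Vectors::DataFrame())
    expect_error(buildConsensus(empty), "empty")
})

test_that("consensus export files carry one row per column", {
    sim <- generateMotifPair(generatorProfile(seed = 11), nA = 30,
        nB = 5, seed = 11)
    model <- buildConsensus(sim$alnA)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeConsensusTSV(model, tsv)
    tab <- read.delim(tsv)
    expect_equal(nrow(tab), ncol(model))
    expect_true(all(c("majority_nt", "identity_tier", "present_tier",
        "pair_partner", "mi_bits") %in% colnames(tab)))
    js <- withr::local_tempfile(fileext = ".json")
    writeConsensusJSON(model, js)
    obj <- jsonlite::read_json(js)
    expect_equal(length(obj$columns), ncol(model))
})
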