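buildPairModels <- function(seed = 13, nA = 200, nB = 200, ...) {
    prof <- generatorProfile(seed = seed, ...)
    sim <- generateMotifPair(prof, nA = nA, nB = nB, seed = seed)
    mA <- buildConsensus(sim$alnA)
    mB <- buildConsensus(sim$alnB)
    feats <- findDiscriminatingFeatures(sim$alnA, sim$alnB, mA, mB,
        mapColumns(mA, mB))
    list(sim = sim, mA = mA, mB = mB, feats = feats, prof = prof)
}

test_that("a model's own consensus aligns back without gaps", {
    x <- buildPairModels(seed = 14, nA = 100, nB = 20)
    cons <- consensusSequence(x$mA)
    gapped <- alignToModel(x$mA, cons)
    chars <- strsplit(gapped, "")[[1]]
    highPresent <- presentFraction(x$mA) >= 0.97
    expect_false(any(chars[highPresent] == "-"))
    expect_equal(attr(gapped, "insertions"), 0L)
})

test_that("deleting one conserved residue produces exactly one gap", {
    x <- buildPairModels(seed = 15, nA = 100, nB = 20)
    cons <- consensusSequence(x$mA)
    # remove a residue in the conserved core
    mutated <- paste0(substr(cons, 1, 29), substr(cons, 31, nchar(cons)))
    gapped <- alignToModel(x$mA, mutated)
    chars <- strsplit(gapped, "")[[1]]
    expect_equal(sum(chars == "-"), 1L)
    expect_equal(attr(gapped, "insertions"), 0L)
    # an arbitrary sequence still aligns (contract)
    rand <- paste(sample(c("A", "C", "G", "U"), 40, replace = TRUE),
        collapse = "")
    expect_silent(alignToModel(x$mA, rand))
})

test_that("PSSM scores match hand computation on a toy model", {
    probs <- matrix(c(
        1.0, 0, 0, 0,
        0, 0.5, 0.5, 0,
        0.25, 0.25, 0.25, 0.25,
        0, 0, 0, 1.0), 4, 4,
        dimnames = list(c("A", "C", "G", "U"), NULL))
    model <- modelFromProbs(probs, n = 400)
    a <- 0.01
    expected <- log2((1 + a) / (0.25 + a)) +    # A at column 1
        log2((0.5 + a) / (0.25 + a)) +          # C at column 2
        log2((0.25 + a) / (0.25 + a)) +         # G at column 3
        log2((0 + a) / (0.25 + a))              # A at column 4 (mismatch)
    expect_equal(pssmScore(model, "ACGA"), expected, tolerance = 1e-12)
    # uniform-profile model scores 0 for any residue string
    uni <- modelFromProbs(matrix(0.25, 4, 6,
        dimnames = list(c("A", "C", "G", "U"), NULL)), n = 400)
    expect_equal(pssmScore(uni, "ACGUAC"), 0, tolerance = 1e-12)
    expect_equal(pssmScore(uni, "GGGGGG"), 0, tolerance = 1e-12)
})

test_that("the consensus string maximises the PSSM score per column", {
    x <- buildPairModels(seed = 16, nA = 150, nB = 20)
    cons <- consensusSequence(x$mA, minPresent = 0)
    base <- pssmScore(x$mA, paste(x$mA@identityNt, collapse = ""))
    for (col in c(5L, 26L, 40L)) {
        for (nt in setdiff(c("A", "C", "G", "U"),
            x$mA@identityNt[col])) {
            alt <- x$mA@identityNt
            alt[col] <- nt
            expect_lte(pssmScore(x$mA, paste(alt, collapse = "")), base)
        }
    }
})

test_that("held-out sequences classify to their own motif", {
    x <- buildPairModels(seed = 17)
    held <- generateMotifPair(x$prof, nA = 100, nB = 100, seed = 1700)
    seqsA <- gsub("-", "", gappedSeqs(held$alnA), fixed = TRUE)
    seqsB <- gsub("-", "", gappedSeqs(held$alnB), fixed = TRUE)
    resA <- classifyFasta(x$mA, x$mB, x$feats, seqsA)
    resB <- classifyFasta(x$mA, x$mB, x$feats, seqsB)
    acc <- mean(c(resA$label == "A", resB$label == "B"))
    expect_gte(acc, 0.95)
})

test_that("training sequences classify to their own motif", {
    x <- buildPairModels(seed = 18)
    seqsA <- gsub("-", "", gappedSeqs(x$sim$alnA), fixed = TRUE)[1:100]
    seqsB <- gsub("-", "", gappedSeqs(x$sim$alnB), fixed = TRUE)[1:100]
    resA <- classifyFasta(x$mA, x$mB, x$feats, seqsA)
    resB <- classifyFasta(x$mA, x$mB, x$feats, seqsB)
    acc <- mean(c(resA$label == "A", resB$label == "B"))
    expect_gte(acc, 0.99)
})

test_that("classification is mirrored when the models are swapped", {
    x <- buildPairModels(seed = 19, nA = 120, nB = 120)
    featsBA <- findDiscriminatingFeatures(x$sim$alnB, x$sim$alnA, x$mB,
        x$mA, mapColumns(x$mB, x$mA))
    seqs <- gsub("-", "", gappedSeqs(x$sim$alnA), fixed = TRUE)[1:20]
    for (s in seqs) {
        ab <- classifySequence(x$mA, x$mB, x$feats, s)
        ba <- classifySequence(x$mB, x$mA, featsBA, s)
        expect_equal(ab$delta, -ba$delta, tolerance = 1e-9)
        mirror <- c(A = "B", B = "A", ambiguous = "ambiguous")
        expect_equal(ba$label, unname(mirror[ab$label]))
    }
})

test_that("delta flips sign when discriminating positions are swapped", {
    x <- buildPairModels(seed = 20, plantElement = FALSE)
    consA <- strsplit(consensusSequence(x$mA, minPresent = 0), "")[[1]]
    truth <- x$sim$truth$contrasts
    rA <- classifySequence(x$mA, x$mB, x$feats,
        paste(consA, collapse = ""))
    expect_equal(rA$label, "A")
    expect_gt(rA$delta, 0)
    swapped <- consA
    swapped[truth$colA] <- truth$ntB
    rSwap <- classifySequence(x$mA, x$mB, x$feats,
        paste(swapped, collapse = ""))
    expect_lt(rSwap$delta, 0)
})

test_that("a balanced chimera is reported as ambiguous", {
    # two planted contrasts, no element: give the chimera one from each
    x <- buildPairModels(seed = 24, nContrasts = 2L,
        plantElement = FALSE)
    truth <- x$sim$truth$contrasts
    consA <- strsplit(consensusSequence(x$mA, minPresent = 0), "")[[1]]
    chimera <- consA
    chimera[truth$colA[2]] <- truth$ntB[2]
    r <- classifySequence(x$mA, x$mB, x$feats,
        paste(chimera, collapse = ""))
    expect_lt(abs(r$delta), 2)
    expect_equal(sum(r$votes == "A"), sum(r$votes == "B"))
    expect_equal(r$label, "ambiguous")
})

test_that("FASTA classification writes one row per sequence", {
    x <- buildPairModels(seed = 25, nA = 60, nB = 60)
    fa <- withr::local_tempfile(fileext = ".fa")
    writeFastaUngapped(x$sim$alnA[1:5], fa)
    res <- classifyFasta(x$mA, x$mB, x$feats, fa)
    expect_equal(nrow(res), 5L)
    expect_true(all(c("seq_id", "label", "score_A", "score_B", "delta",
        "votes") %in% colnames(res)))
    expect_true(all(res$label == "A"))
})
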