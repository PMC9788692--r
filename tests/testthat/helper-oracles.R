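# Independent oracle implementations used to validate the package's
# algorithms on small instances, plus small fixture builders. These are
# deliberately written with different algorithms/idioms than the package
# code they check.

NTS <- c("A", "C", "G", "U")

# build a MotifAlignment from plain strings with an all-unpaired
# structure unless one is given
toyAln <- function(..., ss = NULL, metadata = NULL, name = "toy") {
    rows <- c(...)
    if (is.null(names(rows)))
        names(rows) <- paste0("s", seq_along(rows))
    if (is.null(ss)) ss <- strrep(".", nchar(rows[[1]]))
    MotifAlignment(rows, ss, metadata = metadata, name = name)
}

# random ungapped alignment with iid uniform columns
randomAln <- function(nrow, ncolumns, seed, gapProb = 0) {
    set.seed(seed)
    m <- matrix(sample(NTS, nrow * ncolumns, replace = TRUE),
        nrow, ncolumns)
    if (gapProb > 0)
        m[matrix(runif(nrow * ncolumns) < gapProb, nrow)] <- "-"
    rows <- apply(m, 1, paste, collapse = "")
    names(rows) <- sprintf("r%03d", seq_len(nrow))
    MotifAlignment(rows, strrep(".", ncolumns), name = "random")
}

# mutual information oracle: naive double loop over observed symbol
# pairs, H(X) + H(Y) - H(X,Y) over rows with both columns non-gap
bruteMI <- function(aln, i, j) {
    chars <- strsplit(gappedSeqs(aln), "")
    x <- vapply(chars, `[`, "", i)
    y <- vapply(chars, `[`, "", j)
    keep <- x %in% NTS & y %in% NTS
    x <- x[keep]; y <- y[keep]
    if (!length(x)) return(0)
    H <- function(v) {
        p <- table(v) / length(v)
        -sum(p * log2(p))
    }
    H(x) + H(y) - H(paste(x, y))
}

# affine-gap global alignment oracle: top-down memoized recursion over
# (i, j, state); returns the optimal score only
oracleAlignScore <- function(S, gapOpen, gapExtend) {
    nA <- nrow(S); nB <- ncol(S)
    memo <- new.env(parent = emptyenv())
    best <- function(i, j, state) {
        # best score of an alignment of A[1..i] vs B[1..j] whose last
        # operation is `state` (1 = match, 2 = A-col unmatched, 3 = B-col)
        key <- paste(i, j, state)
        if (!is.null(memo[[key]])) return(memo[[key]])
        val <- if (state == 1L) {
            if (i == 0L && j == 0L) 0
            else if (i == 0L || j == 0L) -Inf
            else S[i, j] + max(best(i - 1L, j - 1L, 1L),
                best(i - 1L, j - 1L, 2L), best(i - 1L, j - 1L, 3L))
        } else if (state == 2L) {
            if (i == 0L) -Inf
            else max(best(i - 1L, j, 1L) + gapOpen,
                best(i - 1L, j, 2L) + gapExtend)
        } else {
            if (j == 0L) -Inf
            else max(best(i, j - 1L, 1L) + gapOpen,
                best(i, j - 1L, 3L) + gapExtend)
        }
        memo[[key]] <- val
        val
    }
    max(best(nA, nB, 1L), best(nA, nB, 2L), best(nA, nB, 3L))
}

# score of a ColumnMap under the affine model, computed from the map's
# own structure (matches plus contiguous unmatched runs)
columnMapScore <- function(map, S, gapOpen, gapExtend) {
    sc <- sum(S[map$matches])
    runCost <- function(cols) {
        if (!length(cols)) return(0)
        runs <- split(cols, cumsum(c(1, diff(sort(cols)) != 1)))
        sum(vapply(runs, function(r)
            gapOpen + gapExtend * (length(r) - 1L), numeric(1)))
    }
    sc + runCost(map$unmatchedA) + runCost(map$unmatchedB)
}

# exact two-sided Fisher p oracle: direct enumeration with
# log-binomial-coefficient probabilities (no dhyper)
oracleFisherP <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    N <- r1 + r2
    if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1.0)
    ks <- max(0, c1 - r2):min(r1, c1)
    logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(N, c1)
    p <- exp(logp)
    pObs <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(N, c1))
    min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

# fake consensus model directly from a residue-probability matrix
# (4 x C) for alignment tests; n pseudo-rows, no gaps
modelFromProbs <- function(probs, ss = NULL, n = 1000L,
                           name = "profile") {
    C <- ncol(probs)
    if (is.null(ss)) ss <- strrep(".", C)
    counts <- rbind(round(probs * n), gap = 0L)
    rownames(counts) <- c(NTS, "gap")
    storage.mode(counts) <- "integer"
    nr <- colSums(counts)[1]
    # adjust first row so all columns sum identically
    for (k in seq_len(C)) {
        excess <- sum(counts[, k]) - nr
        counts[which.max(counts[1:4, k]), k] <-
            counts[which.max(counts[1:4, k]), k] - excess
    }
    tiers <- lapply(seq_len(C), function(k)
        MotifContrast:::.columnProfileFromCounts(counts[, k]))
    tierInfo <- lapply(tiers, conservationTiers)
    new("ConsensusModel", name = name, counts = counts,
        nRows = as.integer(nr), ssCons = ss,
        pairTable = parseSSCons(ss),
        identityTier = vapply(tierInfo, `[[`, integer(1), "identityTier"),
        identityNt = vapply(tierInfo, function(t)
            if (is.na(t$majorityNt)) "-" else t$majorityNt, character(1)),
        presentTier = vapply(tierInfo, `[[`, integer(1), "presentTier"),
        covariation = data.frame())
}

# random residue-probability matrix (columns are Dirichlet-ish draws)
randomProbs <- function(C, seed, concentrated = TRUE) {
    set.seed(seed)
    p <- matrix(rexp(4 * C), 4, C, dimnames = list(NTS, NULL))
    if (concentrated) {
        for (k in seq_len(C)) {
            major <- sample.int(4, 1)
            p[major, k] <- p[major, k] + runif(1, 2, 12)
        }
    }
    sweep(p, 2, colSums(p), "/")
}
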