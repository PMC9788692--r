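# Column mapping between two consensus models and detection of
# discriminating features (identity contrasts and presence/absence of
# structural elements).

DEFAULT_TAUS <- list(hi = 0.97, lo = 0.03, hi2 = 0.90, lo2 = 0.10)

.pairedColumns <- function(model) {
    paired <- logical(ncol(model))
    pt <- pairTable(model)
    if (nrow(pt)) paired[c(pt$i, pt$j)] <- TRUE
    paired
}

# profile-profile column match score: dot product of identity fractions
# plus a bonus when pairing status agrees
.matchScoreMatrix <- function(modelA, modelB, pairBonus = 0.5) {
    fA <- identityFractions(modelA)
    fB <- identityFractions(modelB)
    pA <- .pairedColumns(modelA)
    pB <- .pairedColumns(modelB)
    S <- crossprod(fA, fB)
    S + pairBonus * outer(pA, pB, "==")
}

#' Map columns between two consensus models
#'
#' Global profile-profile alignment by dynamic programming (Gotoh affine
#' gaps). The match score of columns a and b is the dot product of their
#' nucleotide identity fractions plus a bonus of \code{pairBonus} when
#' both columns are paired or both are unpaired. Deterministic; ties are
#' broken toward the diagonal (match state). A curated anchor map can be
#' supplied instead to bypass the automatic alignment.
#'
#' @param modelA,modelB \linkS4class{ConsensusModel}s of the two motifs.
#' @param gapOpen,gapExtend affine gap penalties (defaults -1.0, -0.2).
#' @param pairBonus bonus for agreeing pairing status (default 0.5).
#' @param anchors optional data.frame (or two-column TSV path, see
#'   [readAnchorMap()]) with columns \code{colA}, \code{colB}: a curated
#'   column correspondence, strictly increasing in both coordinates.
#' @return list of class \code{ColumnMap} with \code{matches} (two-column
#'   integer matrix \code{colA}, \code{colB}, strictly increasing in both)
#'   and \code{unmatchedA}, \code{unmatchedB} (column indices present in
#'   only one model). Every column of each model appears exactly once.
#' @export
mapColumns <- function(modelA, modelB, gapOpen = -1.0, gapExtend = -0.2,
                       pairBonus = 0.5, anchors = NULL) {
    stopifnot(is(modelA, "ConsensusModel"), is(modelB, "ConsensusModel"))
    nA <- ncol(modelA)
    nB <- ncol(modelB)
    if (nA == 0L || nB == 0L) stop("both models must be non-empty")
    if (!is.null(anchors)) {
        if (is.character(anchors)) anchors <- readAnchorMap(anchors)
        return(.columnMapFromAnchors(anchors, nA, nB))
    }
    S <- .matchScoreMatrix(modelA, modelB, pairBonus)
    .affineAlign(S, nA, nB, gapOpen, gapExtend)
}

# Gotoh three-state global alignment over a precomputed score matrix.
# States: M (match), X (gap in B: A column unmatched), Y (gap in A).
# Tie preference M > X > Y, which keeps the traceback on the diagonal.
.affineAlign <- function(S, nA, nB, gapOpen, gapExtend) {
    NEG <- -1e18
    M <- matrix(NEG, nA + 1L, nB + 1L)
    X <- matrix(NEG, nA + 1L, nB + 1L)
    Y <- matrix(NEG, nA + 1L, nB + 1L)
    M[1, 1] <- 0
    if (nA) X[2:(nA + 1L), 1] <- gapOpen + gapExtend * (0:(nA - 1L))
    if (nB) Y[1, 2:(nB + 1L)] <- gapOpen + gapExtend * (0:(nB - 1L))
    ptrM <- matrix(0L, nA + 1L, nB + 1L)  # 1=M, 2=X, 3=Y (predecessor state)
    ptrX <- matrix(0L, nA + 1L, nB + 1L)
    ptrY <- matrix(0L, nA + 1L, nB + 1L)
    if (nA) ptrX[2:(nA + 1L), 1] <- c(1L, rep(2L, nA - 1L))
    if (nB) ptrY[1, 2:(nB + 1L)] <- c(1L, rep(3L, nB - 1L))
    for (i in seq_len(nA)) {
        for (j in seq_len(nB)) {
            prev <- c(M[i, j], X[i, j], Y[i, j])
            b <- which.max(prev)     # ties -> lowest index -> prefers M
            M[i + 1L, j + 1L] <- prev[b] + S[i, j]
            ptrM[i + 1L, j + 1L] <- b
            fromM <- M[i, j + 1L] + gapOpen
            fromX <- X[i, j + 1L] + gapExtend
            if (fromM >= fromX) {
                X[i + 1L, j + 1L] <- fromM; ptrX[i + 1L, j + 1L] <- 1L
            } else {
                X[i + 1L, j + 1L] <- fromX; ptrX[i + 1L, j + 1L] <- 2L
            }
            fromM <- M[i + 1L, j] + gapOpen
            fromY <- Y[i + 1L, j] + gapExtend
            if (fromM >= fromY) {
                Y[i + 1L, j + 1L] <- fromM; ptrY[i + 1L, j + 1L] <- 1L
            } else {
                Y[i + 1L, j + 1L] <- fromY; ptrY[i + 1L, j + 1L] <- 3L
            }
        }
    }
    finals <- c(M[nA + 1L, nB + 1L], X[nA + 1L, nB + 1L],
        Y[nA + 1L, nB + 1L])
    state <- which.max(finals)
    i <- nA; j <- nB
    ma <- integer(0); mb <- integer(0)
    ua <- integer(0); ub <- integer(0)
    while (i > 0L || j > 0L) {
        if (state == 1L) {
            ma <- c(i, ma); mb <- c(j, mb)
            state <- ptrM[i + 1L, j + 1L]
            i <- i - 1L; j <- j - 1L
        } else if (state == 2L) {
            ua <- c(i, ua)
            state <- ptrX[i + 1L, j + 1L]
            i <- i - 1L
        } else {
            ub <- c(j, ub)
            state <- ptrY[i + 1L, j + 1L]
            j <- j - 1L
        }
    }
    structure(list(
        matches = cbind(colA = ma, colB = mb),
        unmatchedA = ua,
        unmatchedB = ub,
        score = max(finals)
    ), class = "ColumnMap")
}

.columnMapFromAnchors <- function(anchors, nA, nB) {
    stopifnot(all(c("colA", "colB") %in% colnames(anchors)))
    a <- as.integer(anchors$colA)
    b <- as.integer(anchors$colB)
    ord <- order(a)
    a <- a[ord]; b <- b[ord]
    if (any(diff(a) <= 0L) || any(diff(b) <= 0L))
        stop("anchor map must be strictly increasing in both coordinates")
    if (length(a) && (max(a) > nA || max(b) > nB || min(a) < 1L ||
        min(b) < 1L))
        stop("anchor map columns outside the models")
    structure(list(
        matches = cbind(colA = a, colB = b),
        unmatchedA = setdiff(seq_len(nA), a),
        unmatchedB = setdiff(seq_len(nB), b),
        score = NA_real_
    ), class = "ColumnMap")
}

#' Read a curated column anchor map
#'
#' @param path two-column TSV with header \code{colA}, \code{colB}.
#' @return data.frame usable as the \code{anchors} argument of
#'   [mapColumns()].
#' @export
readAnchorMap <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.table(path, header = TRUE, sep = "\t")
}

.gradeContrast <- function(fA, fB, taus) {
    if ((fA >= taus$hi && fB <= taus$lo) || (fB >= taus$hi && fA <= taus$lo))
        return("strict")
    if ((fA >= taus$hi2 && fB <= taus$lo2) ||
        (fB >= taus$hi2 && fA <= taus$lo2))
        return("high")
    "weak"
}

#' Nucleotide identity contrast between two matched columns
#'
#' Evaluates every nucleotide's identity fraction in both profiles and
#' returns the maximal-contrast feature when its grade is at least
#' \code{high}: strict means >= \code{tauHi} in one motif and <=
#' \code{tauLo} in the other; high uses \code{tauHi2}/\code{tauLo2}.
#' Columns that are less than 50 percent present in either motif are not
#' evaluated for identity (they are the business of element presence).
#'
#' @param profA,profB \code{ColumnProfile}s of the matched columns.
#' @param tauHi,tauLo strict thresholds (defaults 0.97, 0.03).
#' @param tauHi2,tauLo2 high thresholds (defaults 0.90, 0.10).
#' @return one-row data.frame (kind \code{identity_contrast}) or NULL.
#' @export
identityContrast <- function(profA, profB, tauHi = 0.97, tauLo = 0.03,
                             tauHi2 = 0.90, tauLo2 = 0.10) {
    taus <- list(hi = tauHi, lo = tauLo, hi2 = tauHi2, lo2 = tauLo2)
    if (profA$presentFraction < 0.5 || profB$presentFraction < 0.5)
        return(NULL)
    best <- NULL
    for (nt in RNA_ALPHABET) {
        fA <- profA$identityFractions[[nt]]
        fB <- profB$identityFractions[[nt]]
        grade <- .gradeContrast(fA, fB, taus)
        if (grade == "weak") next
        contrast <- abs(fA - fB)
        if (is.null(best) || contrast > best$contrast) {
            best <- data.frame(kind = "identity_contrast",
                nt = nt, freqA = fA, freqB = fB,
                contrast = contrast, grade = grade)
        }
    }
    best
}

#' Occupancy of a column span
#'
#' Fraction of rows with at least \code{minResidues} non-gap characters
#' inside the span. Used to detect structural elements (e.g. an extra
#' hairpin) present in one motif but absent from its homolog; the default
#' \code{minResidues = 6} is the minimal hairpin (2 bp stem + 2 nt loop).
#'
#' @param aln a \linkS4class{MotifAlignment}.
#' @param span integer vector of column indices (or \code{c(from, to)}
#'   range given as a length-2 vector of the endpoints).
#' @param minResidues minimum number of residues for a row to count.
#' @return occupancy fraction in [0, 1].
#' @export
elementPresence <- function(aln, span, minResidues = 6L) {
    stopifnot(is(aln, "MotifAlignment"))
    if (length(span) == 2L && span[2] >= span[1])
        span <- span[1]:span[2]
    if (any(span < 1L) || any(span > ncol(aln)))
        stop("span outside the alignment columns")
    codes <- .alnCodes(aln)[, span, drop = FALSE]
    mean(rowSums(codes != 5L) >= minResidues)
}

.maximalRuns <- function(cols, minLen) {
    if (!length(cols)) return(list())
    cols <- sort(cols)
    breaks <- c(0L, which(diff(cols) > 1L), length(cols))
    runs <- lapply(seq_len(length(breaks) - 1L), function(k)
        cols[(breaks[k] + 1L):breaks[k + 1L]])
    Filter(function(r) length(r) >= minLen, runs)
}

#' Detect discriminating features between two mapped motifs
#'
#' Scans all matched column pairs for nucleotide identity contrasts and
#' all maximal runs of unmatched columns (length >= \code{minRun}) for
#' structural-element presence/absence, grading each feature as strict,
#' high or weak by the contrast thresholds. Only strict and high features
#' are returned, sorted by contrast (descending).
#'
#' @param alnA,alnB the two \linkS4class{MotifAlignment}s.
#' @param modelA,modelB their \linkS4class{ConsensusModel}s.
#' @param map a \code{ColumnMap} from [mapColumns()].
#' @param tauHi,tauLo,tauHi2,tauLo2 contrast thresholds, see
#'   [identityContrast()].
#' @param minRun minimum unmatched-run length to test as an element
#'   (default 4).
#' @param minResidues see [elementPresence()].
#' @return data.frame with columns \code{kind} (\code{identity_contrast}
#'   or \code{element_presence}), \code{motif} (carrier of an element, or
#'   \code{both}), \code{colA}, \code{colB} (matched column; NA for the
#'   model lacking an element), \code{spanStart}, \code{spanEnd} (element
#'   span in the carrier; NA for identity), \code{nt}, \code{freqA},
#'   \code{freqB}, \code{contrast}, \code{grade}.
#' @export
findDiscriminatingFeatures <- function(alnA, alnB, modelA, modelB, map,
                                       tauHi = 0.97, tauLo = 0.03,
                                       tauHi2 = 0.90, tauLo2 = 0.10,
                                       minRun = 4L, minResidues = 6L) {
    stopifnot(inherits(map, "ColumnMap"))
    countsA <- profileCounts(modelA)
    countsB <- profileCounts(modelB)
    feats <- list()
    for (k in seq_len(nrow(map$matches))) {
        ca <- map$matches[k, "colA"]
        cb <- map$matches[k, "colB"]
        f <- identityContrast(
            .columnProfileFromCounts(countsA[, ca]),
            .columnProfileFromCounts(countsB[, cb]),
            tauHi, tauLo, tauHi2, tauLo2)
        if (!is.null(f)) {
            f$motif <- "both"
            f$colA <- ca; f$colB <- cb
            f$spanStart <- NA_integer_; f$spanEnd <- NA_integer_
            feats[[length(feats) + 1L]] <- f
        }
    }
    taus <- list(hi = tauHi, lo = tauLo, hi2 = tauHi2, lo2 = tauLo2)
    addElement <- function(run, carrierAln, motif) {
        occ <- elementPresence(carrierAln, run, minResidues)
        grade <- .gradeContrast(occ, 0, taus)
        if (grade == "weak") return(NULL)
        data.frame(kind = "element_presence", nt = NA_character_,
            freqA = if (motif == "A") occ else 0,
            freqB = if (motif == "B") occ else 0,
            contrast = occ, grade = grade, motif = motif,
            colA = NA_integer_, colB = NA_integer_,
            spanStart = min(run), spanEnd = max(run))
    }
    for (run in .maximalRuns(map$unmatchedA, minRun)) {
        f <- addElement(run, alnA, "A")
        if (!is.null(f)) feats[[length(feats) + 1L]] <- f
    }
    for (run in .maximalRuns(map$unmatchedB, minRun)) {
        f <- addElement(run, alnB, "B")
        if (!is.null(f)) feats[[length(feats) + 1L]] <- f
    }
    cols <- c("kind", "motif", "colA", "colB", "spanStart", "spanEnd",
        "nt", "freqA", "freqB", "contrast", "grade")
    if (!length(feats))
        return(stats::setNames(
            data.frame(matrix(nrow = 0L, ncol = length(cols))), cols))
    out <- do.call(rbind, lapply(feats, function(f) f[, cols]))
    ord <- order(-out$contrast, out$kind,
        ifelse(is.na(out$colA), out$spanStart, out$colA),
        ifelse(is.na(out$colB), 0L, out$colB))
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Subset an alignment by downstream-gene domain
#'
#' Keeps rows whose \code{gene_domain} metadata equals the query after
#' case folding. Multi-label annotations (semicolon-separated) match if
#' any label equals the query.
#'
#' @param aln a \linkS4class{MotifAlignment} with \code{gene_domain}
#'   metadata.
#' @param domain domain name to match.
#' @return the matching \linkS4class{MotifAlignment} (may be empty, with
#'   a warning).
#' @export
subsetByGene <- function(aln, domain) {
    stopifnot(is(aln, "MotifAlignment"))
    md <- alnMetadata(aln)
    if (!"gene_domain" %in% colnames(md) ||
        all(is.na(md$gene_domain)))
        stop("no gene_domain metadata in alignment '", alnName(aln), "'")
    labels <- strsplit(tolower(as.character(md$gene_domain)), ";")
    hit <- vapply(labels, function(l)
        any(trimws(l) == tolower(domain)), logical(1))
    hit[is.na(hit)] <- FALSE
    if (!any(hit)) {
        warning("no sequences with gene_domain '", domain, "'")
        out <- aln[integer(0)]
    } else {
        out <- aln[which(hit)]
    }
    message(nrow(out), " sequence(s) match gene_domain '", domain, "'")
    out
}

#' Export a discriminating-feature table
#'
#' @param features data.frame from [findDiscriminatingFeatures()].
#' @param path output path (TSV; a path ending in \code{.json} writes
#'   JSON).
#' @return the path, invisibly.
#' @export
writeFeatures <- function(features, path) {
    if (grepl("\\.json$", path)) {
        jsonlite::write_json(features, path, auto_unbox = TRUE,
            digits = NA, na = "null")
    } else {
        utils::write.table(features, path, sep = "\t", quote = FALSE,
            row.names = FALSE)
    }
    invisible(path)
}
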