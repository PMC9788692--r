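# Sequence classification into one of two homologous motifs:
# profile log-odds (PSSM) scoring of a model-aligned sequence, with a
# discriminating-feature vote to break small score margins.

PSSM_ALPHA <- 0.01

#' Align an ungapped sequence to a consensus model
#'
#' Global dynamic-programming alignment of the sequence against the
#' model's column profiles (same affine-gap scoring family as
#' [mapColumns()]; the residue-vs-column score is the column's identity
#' fraction of that residue). Residues aligned between model columns
#' (insertions) are recorded in the \code{"insertions"} attribute and do
#' not appear in the gapped string.
#'
#' @param model a \linkS4class{ConsensusModel}.
#' @param seq ungapped RNA sequence (character; T is normalized to U).
#' @param gapOpen,gapExtend affine gap penalties (defaults -1.0, -0.2).
#' @return gapped character string with exactly one position per model
#'   column; attribute \code{"insertions"} counts dropped residues.
#' @export
alignToModel <- function(model, seq, gapOpen = -1.0, gapExtend = -0.2) {
    stopifnot(is(model, "ConsensusModel"))
    seq <- .normalizeSeq(seq)
    seq <- gsub("-", "", seq, fixed = TRUE)
    res <- strsplit(seq, "")[[1]]
    if (length(res) < 10L)
        stop("sequence too short to align (need >= 10 residues)")
    codes <- match(res, RNA_ALPHABET)
    if (anyNA(codes))
        stop("non-ACGU residues in sequence: ",
            paste(unique(res[is.na(codes)]), collapse = ", "))
    f <- identityFractions(model)          # 4 x C
    S <- f[codes, , drop = FALSE]          # L x C: score of residue l at column c
    amap <- .affineAlign(S, length(res), ncol(model), gapOpen, gapExtend)
    gapped <- rep(GAP_CHAR, ncol(model))
    gapped[amap$matches[, "colB"]] <- res[amap$matches[, "colA"]]
    out <- paste(gapped, collapse = "")
    attr(out, "insertions") <- length(amap$unmatchedA)
    attr(out, "score") <- amap$score
    out
}

#' Profile log-odds (PSSM) score of a model-aligned sequence
#'
#' Sum over model columns of log2((f(x) + alpha) / (0.25 + alpha)) for
#' the aligned residue x, with pseudocount alpha = 0.01 and a uniform
#' 0.25-per-nucleotide background. Gap columns contribute
#' log2((g_c + alpha) / (gbar + alpha)) where g_c is the column's gap
#' frequency and gbar the model's mean gap frequency.
#'
#' @param model a \linkS4class{ConsensusModel}.
#' @param gappedSeq gapped string with one position per model column
#'   (e.g. from [alignToModel()]).
#' @param alpha pseudocount (default 0.01).
#' @return score in bits.
#' @export
pssmScore <- function(model, gappedSeq, alpha = PSSM_ALPHA) {
    stopifnot(is(model, "ConsensusModel"))
    res <- strsplit(.normalizeSeq(as.character(gappedSeq)), "")[[1]]
    C <- ncol(model)
    if (length(res) != C)
        stop("gapped sequence has ", length(res),
            " positions but the model has ", C, " columns")
    f <- identityFractions(model)
    gapFreq <- if (model@nRows > 0)
        profileCounts(model)["gap", ] / model@nRows else numeric(C)
    gbar <- mean(gapFreq)
    codes <- match(res, RNA_ALPHABET)
    score <- 0
    for (c in seq_len(C)) {
        if (is.na(codes[c])) {
            score <- score + log2((gapFreq[c] + alpha) / (gbar + alpha))
        } else {
            score <- score + log2((f[codes[c], c] + alpha) / (0.25 + alpha))
        }
    }
    unname(score)
}

#' Majority-consensus sequence of a model
#'
#' The majority nucleotide at every column whose present fraction is at
#' least \code{minPresent}; other columns are skipped.
#'
#' @param model a \linkS4class{ConsensusModel}.
#' @param minPresent present-fraction cutoff (default 0.5).
#' @return ungapped character string.
#' @export
consensusSequence <- function(model, minPresent = 0.5) {
    keep <- presentFraction(model) >= minPresent & model@identityNt != "-"
    paste(model@identityNt[keep], collapse = "")
}

# One vote per discriminating feature. Identity contrasts are read at
# the matched column pair in BOTH model alignments and abstain when the
# two alignments disagree (a global aligner can shift a mismatching
# residue away from a conserved column, so a single alignment is not
# trustworthy evidence). Element features need concordant evidence:
# occupancy of the span in the carrier's alignment and surplus
# (insertion) residues when aligned to the model lacking the element.
.featureVote <- function(features, gappedA, gappedB, minResidues = 6L) {
    if (is.null(features) || !nrow(features)) return(character(0))
    resA <- strsplit(as.character(gappedA), "")[[1]]
    resB <- strsplit(as.character(gappedB), "")[[1]]
    insA <- attr(gappedA, "insertions")
    insB <- attr(gappedB, "insertions")
    vapply(seq_len(nrow(features)), function(k) {
        f <- features[k, ]
        if (f$kind == "identity_contrast") {
            hiSide <- if (f$freqA >= f$freqB) "A" else "B"
            loSide <- setdiff(c("A", "B"), hiSide)
            rA <- resA[f$colA]
            rB <- resB[f$colB]
            obs <- if (rA == rB) rA
                else if (rA == GAP_CHAR) rB
                else if (rB == GAP_CHAR) rA
                else GAP_CHAR          # conflicting alignments: abstain
            if (obs == GAP_CHAR) return("abstain")
            if (obs == f$nt) hiSide else loSide
        } else {  # element_presence
            carrier <- f$motif
            other <- setdiff(c("A", "B"), carrier)
            res <- if (carrier == "A") resA else resB
            insOther <- if (carrier == "A") insB else insA
            span <- f$spanStart:f$spanEnd
            occupied <- sum(res[span] != GAP_CHAR) >= minResidues
            surplus <- !is.null(insOther) && insOther >= minResidues
            if (occupied && surplus) carrier
            else if (!occupied && !surplus) other
            else "abstain"
        }
    }, character(1))
}

#' Classify a sequence into motif A or motif B
#'
#' Aligns the sequence to both consensus models, scores it with each
#' model's PSSM, and labels it by the higher score when the margin
#' \code{|delta|} reaches \code{deltaMin} bits. Below that margin the
#' discriminating features vote (each identity contrast votes for the
#' motif whose favoured nucleotide is observed; each element feature
#' votes by span occupancy); a tied vote yields \code{ambiguous}.
#'
#' @param modelA,modelB \linkS4class{ConsensusModel}s of the two motifs.
#' @param features discriminating features from
#'   [findDiscriminatingFeatures()] (may be NULL).
#' @param seq ungapped RNA sequence.
#' @param deltaMin score margin in bits below which the feature vote
#'   decides (default 2).
#' @return list of class \code{ClassificationResult}: \code{label} (A, B
#'   or ambiguous), \code{scoreA}, \code{scoreB}, \code{delta} (bits,
#'   scoreA - scoreB), \code{votes}.
#' @export
classifySequence <- function(modelA, modelB, features, seq,
                             deltaMin = 2) {
    gappedA <- alignToModel(modelA, seq)
    gappedB <- alignToModel(modelB, seq)
    scoreA <- pssmScore(modelA, gappedA)
    scoreB <- pssmScore(modelB, gappedB)
    delta <- scoreA - scoreB
    votes <- .featureVote(features, gappedA, gappedB)
    if (abs(delta) >= deltaMin) {
        label <- if (delta > 0) "A" else "B"
    } else {
        nA <- sum(votes == "A"); nB <- sum(votes == "B")
        label <- if (nA > nB) "A" else if (nB > nA) "B" else "ambiguous"
    }
    structure(list(label = label, scoreA = scoreA, scoreB = scoreB,
        delta = delta, votes = votes), class = "ClassificationResult")
}

#' @export
print.ClassificationResult <- function(x, ...) {
    cat("ClassificationResult: label =", x$label,
        sprintf("(scoreA = %.2f, scoreB = %.2f, delta = %.2f bits)\n",
            x$scoreA, x$scoreB, x$delta))
    if (length(x$votes))
        cat("  feature votes:", paste(x$votes, collapse = " "), "\n")
    invisible(x)
}

#' Classify all sequences of a FASTA file
#'
#' @param modelA,modelB \linkS4class{ConsensusModel}s.
#' @param features discriminating features (may be NULL).
#' @param fasta path to a FASTA file of ungapped sequences, or a named
#'   character vector of sequences.
#' @param deltaMin see [classifySequence()].
#' @return data.frame with columns \code{seq_id}, \code{label},
#'   \code{score_A}, \code{score_B}, \code{delta}, \code{votes}.
#' @export
classifyFasta <- function(modelA, modelB, features, fasta, deltaMin = 2) {
    seqs <- if (is.character(fasta) && length(fasta) == 1L &&
        file.exists(fasta)) readFastaRNA(fasta) else fasta
    if (is.null(names(seqs)))
        names(seqs) <- paste0("seq", seq_along(seqs))
    rows <- lapply(names(seqs), function(id) {
        r <- classifySequence(modelA, modelB, features, seqs[[id]],
            deltaMin)
        data.frame(seq_id = id, label = r$label, score_A = r$scoreA,
            score_B = r$scoreB, delta = r$delta,
            votes = paste(r$votes, collapse = ""))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
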