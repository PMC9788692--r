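# Per-column conservation profiles, R2R-convention consensus tiers, and
# mutual-information covariation statistics with average product
# correction (APC).

# integer codes: 1..4 = A,C,G,U; 5 = gap (includes ambiguity codes)
.alnCodes <- function(aln) {
    rows <- gappedSeqs(aln)
    if (!length(rows)) stop("empty alignment")
    m <- matrix(unlist(strsplit(rows, ""), use.names = FALSE),
        nrow = length(rows), byrow = TRUE)
    codes <- matrix(5L, nrow(m), ncol(m))
    for (k in seq_along(RNA_ALPHABET))
        codes[m == RNA_ALPHABET[k]] <- k
    rownames(codes) <- names(rows)
    codes
}

.profileCounts <- function(codes) {
    C <- ncol(codes)
    counts <- matrix(0L, 5L, C, dimnames = list(c(RNA_ALPHABET, "gap"),
        NULL))
    for (k in 1:5)
        counts[k, ] <- colSums(codes == k)
    counts
}

#' Per-column nucleotide profile
#'
#' Exact counts of A, C, G, U and gap at one alignment column, with the
#' present (non-gap) fraction and nucleotide identity fractions among
#' non-gap residues.
#'
#' @param aln a \linkS4class{MotifAlignment}.
#' @param col 1-based column index.
#' @return list of class \code{ColumnProfile} with elements \code{counts}
#'   (named A,C,G,U,gap), \code{nRows}, \code{presentFraction} and
#'   \code{identityFractions} (named per nucleotide, summing to 1 when any
#'   residue is present).
#' @export
columnProfile <- function(aln, col) {
    stopifnot(is(aln, "MotifAlignment"))
    C <- ncol(aln)
    if (!is.numeric(col) || length(col) != 1L || col < 1L || col > C)
        stop("column index out of range [1, ", C, "]: ", col)
    codes <- .alnCodes(aln)[, col]
    counts <- vapply(1:5, function(k) sum(codes == k), integer(1))
    names(counts) <- c(RNA_ALPHABET, "gap")
    .columnProfileFromCounts(counts)
}

.columnProfileFromCounts <- function(counts) {
    n <- sum(counts)
    nres <- n - counts[["gap"]]
    idf <- if (nres > 0) counts[RNA_ALPHABET] / nres else
        stats::setNames(rep(0, 4L), RNA_ALPHABET)
    structure(list(
        counts = counts,
        nRows = n,
        presentFraction = if (n > 0) nres / n else 0,
        identityFractions = idf
    ), class = "ColumnProfile")
}

IDENTITY_TIERS <- c(97L, 90L, 75L)
PRESENT_TIERS <- c(97L, 90L, 75L, 50L)

#' Conservation tiers of a column profile
#'
#' Tiers follow the R2R drawing convention: nucleotide identity at 97, 90
#' or 75 percent (of non-gap residues) and present fraction at 97, 90, 75
#' or 50 percent. A tier of 0 means no threshold is met.
#'
#' @param profile a \code{ColumnProfile} from [columnProfile()].
#' @return list with \code{identityTier}, \code{majorityNt} and
#'   \code{presentTier}.
#' @export
conservationTiers <- function(profile) {
    idf <- profile$identityFractions
    best <- max(idf)
    majority <- if (best > 0) RNA_ALPHABET[which.max(idf)] else
        NA_character_
    eps <- 1e-9  # guard against representation error at the thresholds
    it <- IDENTITY_TIERS[best >= IDENTITY_TIERS / 100 - eps]
    pt <- PRESENT_TIERS[profile$presentFraction >= PRESENT_TIERS / 100 - eps]
    list(
        identityTier = if (length(it)) it[1] else 0L,
        majorityNt = majority,
        presentTier = if (length(pt)) pt[1] else 0L
    )
}

# Joint pair counts for all column pairs at once, by indicator cross
# products: N[[a]][[b]][i, j] = rows with code a at column i and b at j.
.pairCountMats <- function(codes) {
    ind <- lapply(1:4, function(k) (codes == k) * 1)
    nongap <- (codes != 5L) * 1
    N <- vector("list", 16L)
    for (a in 1:4) for (b in 1:4)
        N[[(a - 1L) * 4L + b]] <- crossprod(ind[[a]], ind[[b]])
    list(N = N, njoint = crossprod(nongap, nongap))
}

# Full MI matrix in bits (pairwise deletion of gapped rows), plus the
# joint-support matrix. O(C^2) memory.
.miMatrix <- function(codes) {
    pc <- .pairCountMats(codes)
    njoint <- pc$njoint
    C <- ncol(codes)
    # marginals conditional on the partner being non-gap
    Amarg <- vector("list", 4L)  # Amarg[[a]][i,j] = rows: col i == a, col j non-gap
    Bmarg <- vector("list", 4L)
    for (a in 1:4) {
        Amarg[[a]] <- Reduce(`+`, pc$N[(a - 1L) * 4L + 1:4])
        Bmarg[[a]] <- Reduce(`+`, pc$N[(0:3) * 4L + a])
    }
    mi <- matrix(0, C, C)
    denom <- pmax(njoint, 1)
    for (a in 1:4) for (b in 1:4) {
        Nab <- pc$N[[(a - 1L) * 4L + b]]
        term <- Nab / denom *
            (log2(pmax(Nab, 1)) + log2(denom) -
             log2(pmax(Amarg[[a]], 1)) - log2(pmax(Bmarg[[b]], 1)))
        term[Nab == 0] <- 0
        mi <- mi + term
    }
    mi[njoint == 0] <- 0
    mi <- pmax(mi, 0)  # clamp tiny negative rounding error
    diag(mi) <- 0
    list(mi = mi, njoint = njoint, pairCounts = pc$N)
}

# APC term matrix: apc[i,j] = mean MI of i * mean MI of j / overall mean,
# with the background restricted to pairs with >= minJoint joint rows.
.apcMatrix <- function(miInfo, minJoint = 5L) {
    mi <- miInfo$mi
    valid <- miInfo$njoint >= minJoint
    diag(valid) <- FALSE
    C <- ncol(mi)
    nv <- rowSums(valid)
    rowMean <- ifelse(nv > 0, rowSums(mi * valid) / pmax(nv, 1L), 0)
    tot <- sum(mi * valid)
    npairs <- sum(valid)
    overall <- if (npairs > 0) tot / npairs else 0
    if (overall <= 0) return(matrix(0, C, C))
    outer(rowMean, rowMean) / overall
}

.covariationRow <- function(miInfo, apc, i, j, tauMI, minJoint = 5L) {
    nj <- miInfo$njoint[i, j]
    mi <- miInfo$mi[i, j]
    miApc <- mi - apc[i, j]
    # canonical pair composition among jointly present rows
    canonIdx <- vapply(CANONICAL_PAIRS, function(p) {
        a <- match(substr(p, 1, 1), RNA_ALPHABET)
        b <- match(substr(p, 2, 2), RNA_ALPHABET)
        (a - 1L) * 4L + b
    }, integer(1))
    ccounts <- vapply(canonIdx, function(k) miInfo$pairCounts[[k]][i, j],
        numeric(1))
    canonFrac <- if (nj > 0) sum(ccounts) / nj else 0
    nTypes <- if (nj > 0) sum(ccounts / nj >= 0.05) else 0L
    data.frame(
        i = i, j = j,
        n_joint = as.integer(nj),
        mi_bits = mi,
        mi_apc_bits = miApc,
        canonical_fraction = canonFrac,
        n_pair_types = as.integer(nTypes),
        covarying = (miApc > tauMI) && (canonFrac >= 0.9) && (nTypes >= 2L),
        low_support = nj < minJoint
    )
}

#' Covariation statistic for one consensus pair
#'
#' Mutual information (base 2) of the joint residue distribution over
#' rows where both columns are non-gap, corrected by the average product
#' correction (APC) computed over all column pairs of the alignment with
#' at least 5 jointly present rows. A pair is called covarying when the
#' APC-corrected MI exceeds \code{tauMI}, at least 90 percent of jointly
#' present rows form a canonical (Watson-Crick or GU) pair, and at least
#' two distinct canonical pair types occur at frequency >= 0.05.
#'
#' @param aln a \linkS4class{MotifAlignment}.
#' @param i,j 1-based column indices of the pair (i < j).
#' @param tauMI covariation threshold on APC-corrected MI, in bits
#'   (default 0.3).
#' @return one-row data.frame with \code{mi_bits}, \code{mi_apc_bits},
#'   \code{canonical_fraction}, \code{n_pair_types}, \code{covarying} and
#'   \code{low_support} (fewer than 5 jointly present rows).
#' @export
covariationScore <- function(aln, i, j, tauMI = 0.3) {
    stopifnot(is(aln, "MotifAlignment"))
    C <- ncol(aln)
    if (i < 1L || j > C || i >= j)
        stop("invalid column pair (", i, ", ", j, ")")
    codes <- .alnCodes(aln)
    miInfo <- .miMatrix(codes)
    apc <- .apcMatrix(miInfo)
    row <- .covariationRow(miInfo, apc, i, j, tauMI)
    if (row$low_support)
        warning("pair (", i, ", ", j, ") has fewer than 5 jointly ",
            "present rows; statistic is low-support")
    row
}

#' Build the consensus conservation model of a motif alignment
#'
#' Profiles every column, assigns identity/present tiers, parses the
#' consensus structure into base pairs, and scores every pair for
#' covariation. Deterministic given the alignment.
#'
#' @param aln a \linkS4class{MotifAlignment} with a consensus structure.
#' @param tauMI covariation threshold in bits (default 0.3).
#' @return a \linkS4class{ConsensusModel}.
#' @examples
#' aln <- MotifAlignment(c(s1 = "GGCAACC", s2 = "GGAAACC"), "<<...>>")
#' buildConsensus(aln)
#' @export
buildConsensus <- function(aln, tauMI = 0.3) {
    stopifnot(is(aln, "MotifAlignment"))
    if (nrow(aln) == 0L) stop("cannot build a consensus of an empty alignment")
    codes <- .alnCodes(aln)
    counts <- .profileCounts(codes)
    C <- ncol(counts)
    tiers <- lapply(seq_len(C), function(k)
        conservationTiers(.columnProfileFromCounts(counts[, k])))
    pt <- parseSSCons(ssCons(aln))
    cov <- if (nrow(pt)) {
        miInfo <- .miMatrix(codes)
        apc <- .apcMatrix(miInfo)
        rows <- lapply(seq_len(nrow(pt)), function(k)
            .covariationRow(miInfo, apc, pt$i[k], pt$j[k], tauMI))
        cbind(do.call(rbind, rows)[, -(1:2)],
            data.frame(i = pt$i, j = pt$j, layer = pt$layer))[,
            c("i", "j", "layer", "n_joint", "mi_bits", "mi_apc_bits",
              "canonical_fraction", "n_pair_types", "covarying",
              "low_support")]
    } else {
        data.frame(i = integer(0), j = integer(0), layer = character(0),
            n_joint = integer(0), mi_bits = numeric(0),
            mi_apc_bits = numeric(0), canonical_fraction = numeric(0),
            n_pair_types = integer(0), covarying = logical(0),
            low_support = logical(0))
    }
    new("ConsensusModel",
        name = alnName(aln),
        counts = counts,
        nRows = nrow(aln),
        ssCons = ssCons(aln),
        pairTable = pt,
        identityTier = vapply(tiers, `[[`, integer(1), "identityTier"),
        identityNt = vapply(tiers, function(t)
            if (is.na(t$majorityNt)) "-" else t$majorityNt, character(1)),
        presentTier = vapply(tiers, `[[`, integer(1), "presentTier"),
        covariation = cov)
}

#' Export a consensus model as TSV
#'
#' One row per column: majority nucleotide, identity fraction and tiers,
#' pairing partner and covariation statistics for paired columns.
#'
#' @param model a \linkS4class{ConsensusModel}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeConsensusTSV <- function(model, path) {
    tab <- conservationTable(model)
    cov <- covariation(model)
    tab$mi_bits <- NA_real_
    tab$mi_apc_bits <- NA_real_
    tab$covarying <- NA
    if (nrow(cov)) {
        for (k in seq_len(nrow(cov))) {
            for (col in c(cov$i[k], cov$j[k])) {
                tab$mi_bits[col] <- cov$mi_bits[k]
                tab$mi_apc_bits[col] <- cov$mi_apc_bits[k]
                tab$covarying[col] <- cov$covarying[k]
            }
        }
    }
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Export a consensus model as JSON
#'
#' @param model a \linkS4class{ConsensusModel}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeConsensusJSON <- function(model, path) {
    obj <- list(
        name = model@name,
        n_rows = model@nRows,
        ss_cons = model@ssCons,
        columns = conservationTable(model),
        covariation = covariation(model)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
        na = "null")
    invisible(path)
}
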