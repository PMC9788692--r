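# Seeded synthetic-data generation: a pair of homologous structured-RNA
# motif alignments with planted discriminating features and correlated
# metadata, plus assay readouts (binding isotherms, termination products,
# linear calibrations). Every generator is a pure function of its
# arguments and seed.

.withSeed <- function(seed, code) {
    glob <- globalenv()
    had <- exists(".Random.seed", envir = glob, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = glob) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = glob)
        else if (exists(".Random.seed", envir = glob, inherits = FALSE))
            rm(".Random.seed", envir = glob)
    })
    set.seed(seed)
    force(code)
}

# canonical pair-type sampling distribution used for all consensus stems
PAIR_TYPE_PROBS <- c(GC = 0.45, CG = 0.25, AU = 0.15, UA = 0.10,
    GU = 0.05)

#' Default generator profile for a homologous motif pair
#'
#' Describes two motifs sharing a 61-column base architecture (two
#' hairpins connected by a pseudoknot, the 3' hairpin being a putative
#' intrinsic terminator), with planted differences: by default three
#' strict nucleotide identity contrasts (frequency 1 in one motif, 0 in
#' the other) and a 10-column hairpin element inserted into the
#' terminator loop of motif A only. Gene-context labels are correlated
#' with motif membership (motif A is dominated by a transaminase-like
#' domain at probability 0.55; motif B by a guanidine-exporter-like
#' domain), sequences are spread over three phyla, and motif A's
#' environment labels are gut-enriched (5:1 gut:non-gut among known
#' labels, versus a balanced background).
#'
#' @param seed integer seed stored with the profile (generators default
#'   to it).
#' @param conservation identity probability of the conserved unpaired
#'   columns (default 0.97).
#' @param contrastHi,contrastLo planted contrast frequencies (defaults 1
#'   and 0).
#' @param nContrasts number of planted identity contrasts (0 to 3,
#'   default 3).
#' @param plantElement plant the motif-A-only hairpin element (default
#'   TRUE).
#' @return list of class \code{GeneratorProfile}.
#' @export
generatorProfile <- function(seed = 101L, conservation = 0.97,
                             contrastHi = 1.0, contrastLo = 0.0,
                             nContrasts = 3L, plantElement = TRUE) {
    stopifnot(nContrasts %in% 0:3, conservation > 0.25,
        conservation <= 1, contrastHi > contrastLo)
    ss <- paste0("::::", "<<<<<<", "..", "AAAA", "..", ">>>>>>",
        "....", "aaaa", "...", "<<<<<<<<", "....", ">>>>>>>>",
        "::::::")
    C <- nchar(ss)  # 61
    pairs <- parseSSCons(ss)
    pairedCols <- c(pairs$i, pairs$j)
    # deterministic majority-nucleotide pattern for unpaired columns
    majority <- strsplit(paste0(
        "GAUC", "......", "GC", "....", "UA", "......",
        "ACGU", "....", "AUC", "........", "GCAA", "........",
        "UUUUUU"), "")[[1]]
    stopifnot(length(majority) == C)
    probs <- matrix(0, 4L, C, dimnames = list(RNA_ALPHABET, NULL))
    spread <- function(major, p) {
        v <- rep((1 - p) / 3, 4L)
        v[match(major, RNA_ALPHABET)] <- p
        v
    }
    tails <- c(1:4, 56:61)
    for (k in seq_len(C)) {
        if (k %in% pairedCols) next
        p <- if (k %in% tails) 0.40 else conservation
        nt <- majority[k]
        if (nt == ".") nt <- RNA_ALPHABET[1L + (k %% 4L)]
        probs[, k] <- spread(nt, p)
    }
    presentProb <- rep(1, C)
    presentProb[tails] <- 0.85
    probsA <- probs
    probsB <- probs
    contrastDef <- data.frame(
        column = c(26L, 27L, 34L),
        ntA = c("C", "A", "U"),
        ntB = c("G", "G", "C"),
        stringsAsFactors = FALSE)[seq_len(nContrasts), , drop = FALSE]
    mk <- function(hiNt, loNt) {
        v <- rep(0, 4L)
        v[match(hiNt, RNA_ALPHABET)] <- contrastHi
        v[match(loNt, RNA_ALPHABET)] <- 1 - contrastHi
        v
    }
    for (k in seq_len(nrow(contrastDef))) {
        col <- contrastDef$column[k]
        probsA[, col] <- mk(contrastDef$ntA[k], contrastDef$ntB[k])
        probsB[, col] <- mk(contrastDef$ntB[k], contrastDef$ntA[k])
    }
    contrastDef$freqHi <- rep(contrastHi, nrow(contrastDef))
    contrastDef$freqLo <- rep(contrastLo, nrow(contrastDef))
    element <- if (plantElement) list(
        after = 45L,                    # inside the terminator loop
        ssLocal = "<<<....>>>",
        carrier = "A"
    ) else NULL
    structure(list(
        ssCons = ss,
        nColumns = C,
        probsA = probsA,
        probsB = probsB,
        pairTable = pairs,
        pairTypeProbs = PAIR_TYPE_PROBS,
        presentProb = presentProb,
        contrasts = contrastDef,
        element = element,
        geneAssoc = list(
            A = c(PRK07324 = 0.55, GNAT = 0.15, MATE = 0.10,
                COG2423 = 0.07, ALDH = 0.05, CRYM = 0.03,
                PERM = 0.02, HYPO = 0.03),
            B = c(COG2076 = 0.55, GNAT = 0.12, MATE = 0.09,
                PERM = 0.08, UREA_CARB = 0.06, GDH = 0.04,
                HYPO = 0.06)),
        envAssoc = list(
            A = c(gut = 0.79167, non_gut = 0.15833, unknown = 0.05),
            B = c(gut = 0.30, non_gut = 0.65, unknown = 0.05)),
        phyla = c(Actinobacteria = 0.3, Bacteroidetes = 0.3,
            Firmicutes = 0.4),
        seed = as.integer(seed)
    ), class = "GeneratorProfile")
}

.sampleColumns <- function(n, probs, pairs, pairTypeProbs, presentProb,
                           mode, mutationRate) {
    C <- ncol(probs)
    m <- matrix("", n, C)
    unpaired <- setdiff(seq_len(C), c(pairs$i, pairs$j))
    sampleNt <- function(n, p) RNA_ALPHABET[sample.int(4L, n,
        replace = TRUE, prob = p)]
    types <- names(pairTypeProbs)
    samplePair <- function(n) types[sample.int(length(types), n,
        replace = TRUE, prob = pairTypeProbs)]
    if (mode == "independent") {
        for (k in unpaired) m[, k] <- sampleNt(n, probs[, k])
        for (r in seq_len(nrow(pairs))) {
            t <- samplePair(n)
            m[, pairs$i[r]] <- substr(t, 1L, 1L)
            m[, pairs$j[r]] <- substr(t, 2L, 2L)
        }
    } else {  # star tree: shared ancestor, per-sequence mutations
        anc <- character(C)
        for (k in unpaired) anc[k] <- sampleNt(1L, probs[, k])
        ancPair <- samplePair(nrow(pairs))
        for (k in unpaired) {
            mut <- stats::runif(n) < mutationRate
            m[, k] <- anc[k]
            if (any(mut)) m[mut, k] <- sampleNt(sum(mut), probs[, k])
        }
        for (r in seq_len(nrow(pairs))) {
            t <- rep(ancPair[r], n)
            mut <- stats::runif(n) < mutationRate
            if (any(mut)) t[mut] <- samplePair(sum(mut))
            m[, pairs$i[r]] <- substr(t, 1L, 1L)
            m[, pairs$j[r]] <- substr(t, 2L, 2L)
        }
    }
    for (k in which(presentProb < 1)) {
        gap <- stats::runif(n) >= presentProb[k]
        m[gap, k] <- GAP_CHAR
    }
    m
}

.sampleLabels <- function(n, probs) {
    names(probs)[sample.int(length(probs), n, replace = TRUE,
        prob = probs)]
}

#' Generate a pair of homologous motif alignments with planted truth
#'
#' Samples \code{nA} and \code{nB} sequences from the motif-specific
#' column distributions of a \code{GeneratorProfile} (stems sampled as
#' complementary pair types so that consensus pairs covary; the planted
#' element emitted only in the carrier motif, as a complementary stem
#' plus sampled loop), together with gene-context, phylum and
#' environment metadata. Fully reproducible from the seed.
#'
#' @param profile a \code{GeneratorProfile} from [generatorProfile()].
#' @param nA,nB numbers of sequences (>= 1).
#' @param seed seed (default: the profile's seed).
#' @param mode \code{"independent"} (columns sampled independently, the
#'   default) or \code{"star"} (per-sequence mutations from a shared
#'   ancestor; a classifier stress test).
#' @param mutationRate per-position mutation probability in star mode.
#' @return list with \code{alnA}, \code{alnB}
#'   (\linkS4class{MotifAlignment}s) and \code{truth} (planted contrasts
#'   with their column coordinates in each motif, the element span, and
#'   the association probabilities).
#' @export
generateMotifPair <- function(profile, nA = 200L, nB = 200L,
                              seed = profile$seed,
                              mode = c("independent", "star"),
                              mutationRate = 0.1) {
    stopifnot(inherits(profile, "GeneratorProfile"), nA >= 1L, nB >= 1L)
    mode <- match.arg(mode)
    if (!is.null(profile$element) &&
        (profile$element$after < 1L ||
         profile$element$after > profile$nColumns))
        stop("planted element position outside the base model")
    if (any(profile$contrasts$column > profile$nColumns))
        stop("planted contrast column outside the base model")
    .withSeed(seed, {
        mA <- .sampleColumns(nA, profile$probsA, profile$pairTable,
            profile$pairTypeProbs, profile$presentProb, mode,
            mutationRate)
        mB <- .sampleColumns(nB, profile$probsB, profile$pairTable,
            profile$pairTypeProbs, profile$presentProb, mode,
            mutationRate)
        ssA <- profile$ssCons
        elementSpanA <- NULL
        if (!is.null(profile$element)) {
            el <- profile$element
            elSS <- el$ssLocal
            Lel <- nchar(elSS)
            elPairs <- parseSSCons(elSS)
            elM <- .sampleColumns(nA, matrix(0.25, 4L, Lel,
                dimnames = list(RNA_ALPHABET, NULL)), elPairs,
                profile$pairTypeProbs, rep(1, Lel), "independent",
                mutationRate)
            after <- el$after
            mA <- cbind(mA[, seq_len(after), drop = FALSE], elM,
                mA[, (after + 1L):ncol(mA), drop = FALSE])
            ssA <- paste0(substr(profile$ssCons, 1L, after), elSS,
                substr(profile$ssCons, after + 1L, profile$nColumns))
            elementSpanA <- c(after + 1L, after + Lel)
        }
        mdFor <- function(n, motif) {
            data.frame(
                gene_domain = .sampleLabels(n, profile$geneAssoc[[motif]]),
                phylum = .sampleLabels(n, profile$phyla),
                environment = .sampleLabels(n, profile$envAssoc[[motif]]),
                stringsAsFactors = FALSE)
        }
        mdA <- mdFor(nA, "A")
        mdB <- mdFor(nB, "B")
        rowsA <- apply(mA, 1L, paste, collapse = "")
        rowsB <- apply(mB, 1L, paste, collapse = "")
        names(rowsA) <- sprintf("varA_%04d", seq_len(nA))
        names(rowsB) <- sprintf("refB_%04d", seq_len(nB))
        alnA <- MotifAlignment(rowsA, ssA, metadata = mdA,
            name = "motifA")
        alnB <- MotifAlignment(rowsB, profile$ssCons, metadata = mdB,
            name = "motifB")
        shift <- function(col) {
            if (is.null(elementSpanA)) return(col)
            ifelse(col > profile$element$after,
                col + diff(elementSpanA) + 1L, col)
        }
        truth <- list(
            contrasts = data.frame(
                colBase = profile$contrasts$column,
                colA = shift(profile$contrasts$column),
                colB = profile$contrasts$column,
                ntA = profile$contrasts$ntA,
                ntB = profile$contrasts$ntB,
                freqHi = profile$contrasts$freqHi,
                freqLo = profile$contrasts$freqLo),
            element = if (is.null(elementSpanA)) NULL else list(
                spanA = elementSpanA, carrier = "A"),
            geneAssoc = profile$geneAssoc,
            envAssoc = profile$envAssoc,
            seed = seed,
            mode = mode)
        list(alnA = alnA, alnB = alnB, truth = truth)
    })
}

#' Generate a synthetic in-line probing band table
#'
#' Modulated band = baseline * (1 - fMax * occupancy(c)) with
#' multiplicative lognormal noise; constant band = baseline with the
#' same noise model; a no-ligand lane is included. Occupancy follows a
#' Hill isotherm c^n / (kd^n + c^n) (zero when \code{kd} is infinite).
#'
#' @param kd true dissociation constant (molar; \code{Inf} for no
#'   binding).
#' @param hillN true Hill coefficient (default 1).
#' @param fMax maximal fractional intensity change (default 0.5).
#' @param concs concentration series (default the 16-lane two-fold
#'   series from 20 mM down to ~0.61 uM).
#' @param noiseSd standard deviation of the lognormal noise (0 = exact).
#' @param seed RNG seed.
#' @param baseline baseline band intensity.
#' @return a \code{BandTable} data.frame (no-ligand lane first).
#' @export
generateProbingTable <- function(kd, hillN = 1, fMax = 0.5,
                                 concs = dilutionSeries(20e-3, 2, 16),
                                 noiseSd = 0, seed = 1L, baseline = 1) {
    stopifnot(noiseSd >= 0, fMax >= 0, fMax <= 1)
    .withSeed(seed, {
        occ <- if (is.finite(kd))
            concs^hillN / (kd^hillN + concs^hillN) else rep(0,
                length(concs))
        occ <- c(0, occ)  # no-ligand lane first
        n <- length(occ)
        noise <- function() exp(stats::rnorm(n, 0, noiseSd))
        tab <- data.frame(
            lane_id = c("no_ligand", sprintf("lane_%02d",
                seq_along(concs))),
            conc_molar = c(NA_real_, concs),
            modulated = baseline * (1 - fMax * occ) * noise(),
            constant = baseline * noise(),
            stringsAsFactors = FALSE)
        .asBandTable(tab)
    })
}

#' Generate a synthetic transcription-termination record
#'
#' Band intensities for the terminated and full-length products of a
#' single-round body-labelled transcription, with the adenosine-content
#' distortion applied (intensity proportional to product A count) and
#' multiplicative lognormal noise.
#'
#' @param readthrough expected full-length fraction in [0, 1].
#' @param aCounts named vector \code{c(term = ..., full = ...)} of
#'   adenosine counts.
#' @param noiseSd lognormal noise sd (0 = exact).
#' @param seed RNG seed.
#' @param scale intensity scale factor.
#' @return list with \code{term}, \code{full}, \code{a_term},
#'   \code{a_full} and the true \code{readthrough}.
#' @export
generateTerminationData <- function(readthrough,
                                    aCounts = c(term = 30L, full = 60L),
                                    noiseSd = 0, seed = 1L,
                                    scale = 1000) {
    stopifnot(readthrough >= 0, readthrough <= 1, noiseSd >= 0)
    .withSeed(seed, {
        noise <- function() exp(stats::rnorm(1L, 0, noiseSd))
        list(
            term = scale * (1 - readthrough) * aCounts[["term"]] * noise(),
            full = scale * readthrough * aCounts[["full"]] * noise(),
            a_term = aCounts[["term"]],
            a_full = aCounts[["full"]],
            readthrough = readthrough)
    })
}

#' Generate a synthetic DTNB calibration table
#'
#' @param slope true slope (absorbance per molar).
#' @param intercept true intercept (absorbance).
#' @param concs calibration CoA concentrations (molar).
#' @param noiseSd additive absorbance noise sd.
#' @param seed RNG seed.
#' @return data.frame with \code{conc_molar} and \code{absorbance}.
#' @export
generateCalibrationTable <- function(slope, intercept,
                                     concs = seq(0, 5e-4, length.out = 6),
                                     noiseSd = 0, seed = 1L) {
    .withSeed(seed, data.frame(
        conc_molar = concs,
        absorbance = intercept + slope * concs +
            stats::rnorm(length(concs), 0, noiseSd)))
}
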