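#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")
GAP_CHAR <- "-"

# canonical (Watson-Crick + wobble) pair types, as "XY" strings
CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' MotifAlignment: an annotated structured-RNA multiple alignment
#'
#' Holds gapped RNA sequences of equal length, a consensus secondary
#' structure string (\code{SS_cons}, with pseudoknot layers written as
#' matched upper/lower-case letters) and per-sequence metadata
#' (downstream-gene domain, phylum, environment). This is the unit of all
#' comparative analysis in the package.
#'
#' @slot name single character, alignment name.
#' @slot rows named character vector of gapped sequences over
#'   \code{A,C,G,U,-} (IUPAC ambiguity codes are tolerated but treated as
#'   gaps by profile computations); names are the unique sequence ids.
#' @slot ssCons consensus structure string, same width as the rows.
#' @slot metadata \code{DataFrame} with one row per sequence (rownames =
#'   sequence ids); recognised columns are \code{gene_domain},
#'   \code{phylum} and \code{environment} (one of \code{gut},
#'   \code{non_gut}, \code{unknown}); extra Stockholm \code{#=GS} tags are
#'   kept verbatim as additional columns.
#'
#' @aliases MotifAlignment-class
#' @exportClass MotifAlignment
setClass("MotifAlignment",
    representation(
        name = "character",
        rows = "character",
        ssCons = "character",
        metadata = "DataFrame"
    ),
    prototype(
        name = "alignment",
        rows = character(0),
        ssCons = "",
        metadata = S4Vectors::DataFrame()
    )
)

setValidity("MotifAlignment", function(object) {
    msg <- character(0)
    if (length(object@name) != 1L)
        msg <- c(msg, "'name' must be a single string")
    if (length(object@ssCons) != 1L)
        msg <- c(msg, "'ssCons' must be a single string")
    w <- nchar(object@ssCons)
    if (length(object@rows)) {
        ids <- names(object@rows)
        if (is.null(ids) || anyNA(ids) || any(ids == ""))
            msg <- c(msg, "all rows must be named by a sequence id")
        else if (anyDuplicated(ids))
            msg <- c(msg, paste0("duplicated sequence ids: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
        bad <- nchar(object@rows) != w
        if (any(bad))
            msg <- c(msg, paste0("sequence length differs from SS_cons (",
                w, " columns) for: ",
                paste(utils::head(ids[bad], 5L), collapse = ", ")))
        if (nrow(object@metadata) &&
            !identical(rownames(object@metadata), ids))
            msg <- c(msg, "metadata rownames must equal the sequence ids")
    }
    # layer balance is checked by the structure parser
    ok <- tryCatch({
        parseSSCons(object@ssCons)
        TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) msg <- c(msg, ok)
    if (length(msg)) msg else TRUE
})

#' ConsensusModel: per-column conservation profile of a motif alignment
#'
#' Summarises a \linkS4class{MotifAlignment}: per-column nucleotide/gap
#' counts, conservation tiers in the R2R convention (97/90/75 percent
#' nucleotide identity; 97/90/75/50 percent present), the consensus base
#' pairs, and per-pair covariation statistics (mutual information in bits
#' with average product correction, canonical-pair fraction, number of
#' canonical pair types).
#'
#' @slot name motif name.
#' @slot counts 5 x C integer matrix (rows \code{A,C,G,U,gap}).
#' @slot nRows number of aligned sequences.
#' @slot ssCons the consensus structure string.
#' @slot pairTable data.frame with columns \code{i}, \code{j},
#'   \code{layer} (\code{nested}/\code{pseudoknot}), 1-based columns.
#' @slot identityTier integer per column: 0 (none), 75, 90 or 97.
#' @slot identityNt majority nucleotide per column.
#' @slot presentTier integer per column: 0, 50, 75, 90 or 97.
#' @slot covariation data.frame, one row per consensus pair, with columns
#'   \code{i,j,layer,n_joint,mi_bits,mi_apc_bits,canonical_fraction,
#'   n_pair_types,covarying,low_support}.
#'
#' @aliases ConsensusModel-class
#' @exportClass ConsensusModel
setClass("ConsensusModel",
    representation(
        name = "character",
        counts = "matrix",
        nRows = "integer",
        ssCons = "character",
        pairTable = "data.frame",
        identityTier = "integer",
        identityNt = "character",
        presentTier = "integer",
        covariation = "data.frame"
    )
)

setValidity("ConsensusModel", function(object) {
    msg <- character(0)
    if (!identical(rownames(object@counts), c(RNA_ALPHABET, "gap")))
        msg <- c(msg, "counts rows must be A,C,G,U,gap")
    C <- ncol(object@counts)
    if (C && any(colSums(object@counts) != object@nRows))
        msg <- c(msg, "each column's counts must sum to nRows")
    if (length(object@identityTier) != C ||
        length(object@presentTier) != C ||
        length(object@identityNt) != C)
        msg <- c(msg, "tier vectors must have one entry per column")
    if (nchar(object@ssCons) != C)
        msg <- c(msg, "ssCons width must equal the number of columns")
    if (length(msg)) msg else TRUE
})

#' ContingencyResult: a 2x2 exact-test result
#'
#' @slot table 2x2 integer matrix of counts.
#' @slot oddsRatio sample odds ratio (a*d)/(b*c); \code{Inf} when only the
#'   denominator is zero, \code{NaN} when 0/0 (see \code{degenerate}).
#' @slot pValue two-sided exact p-value (sum of hypergeometric
#'   probabilities not exceeding that of the observed table).
#' @slot degenerate TRUE when a margin is zero (p fixed at 1) or the odds
#'   ratio is 0/0.
#' @slot method statistic used: \code{"fisher"} or \code{"chisq-yates"}.
#'
#' @aliases ContingencyResult-class
#' @exportClass ContingencyResult
setClass("ContingencyResult",
    representation(
        table = "matrix",
        oddsRatio = "numeric",
        pValue = "numeric",
        degenerate = "logical",
        method = "character"
    )
)

setValidity("ContingencyResult", function(object) {
    msg <- character(0)
    if (!all(dim(object@table) == c(2L, 2L)))
        msg <- c(msg, "table must be 2x2")
    if (any(object@table < 0))
        msg <- c(msg, "counts must be non-negative")
    p <- object@pValue
    if (length(p) != 1L || is.na(p) || p < 0 || p > 1 + 1e-12)
        msg <- c(msg, "pValue must be a single number in [0,1]")
    if (length(msg)) msg else TRUE
})

#' BindingCurve: a fitted ligand-binding isotherm
#'
#' Result of fitting a Hill isotherm f(c) = fmax * c^n / (Kd^n + c^n) to a
#' relative-intensity-change series from an in-line probing experiment.
#' When saturation is not reached within the tested concentration range
#' the apparent Kd is not reported and the series is normalized to the
#' value at the highest concentration instead of to the fitted plateau.
#'
#' @slot concs molar concentration series (no-ligand lane excluded).
#' @slot relChange relative intensity change per concentration.
#' @slot normalized series scaled so the maximum magnitude is 1.
#' @slot kd apparent dissociation constant (molar); \code{NA} when not
#'   saturated.
#' @slot fitKd raw fitted Kd parameter of the Hill model, reported even
#'   when no apparent Kd is called (useful for recovery diagnostics).
#' @slot hillN fitted Hill coefficient (bounded to [0.5, 3]).
#' @slot fMax fitted plateau of the response magnitude.
#' @slot saturated TRUE when the fitted Kd is at most max(conc)/5 and the
#'   two highest-concentration fitted values are within 10 percent of
#'   fMax.
#' @slot fitResidual root-mean-square residual of the fit.
#' @slot flags character vector of quality flags (e.g.
#'   \code{"non_monotone"}, \code{"degenerate"}).
#'
#' @aliases BindingCurve-class
#' @exportClass BindingCurve
setClass("BindingCurve",
    representation(
        concs = "numeric",
        relChange = "numeric",
        normalized = "numeric",
        kd = "numeric",
        fitKd = "numeric",
        hillN = "numeric",
        fMax = "numeric",
        saturated = "logical",
        fitResidual = "numeric",
        flags = "character"
    )
)

setValidity("BindingCurve", function(object) {
    msg <- character(0)
    n <- length(object@concs)
    if (length(object@relChange) != n || length(object@normalized) != n)
        msg <- c(msg, "concs, relChange and normalized must align")
    if (n && max(abs(object@normalized)) > 1 + 1e-9)
        msg <- c(msg, "normalized values must have maximum magnitude 1")
    if (!object@saturated && !is.na(object@kd))
        msg <- c(msg, "kd must be NA when the curve is not saturated")
    if (length(msg)) msg else TRUE
})

#' Calibration: a linear absorbance-vs-concentration calibration
#'
#' Ordinary least-squares line through at least three calibration points,
#' as used to convert DTNB (Ellman's reagent) absorbance readings into
#' released CoA concentrations in acetyltransferase assays.
#'
#' @slot slope absorbance units per molar.
#' @slot intercept absorbance at zero concentration.
#' @slot rSquared coefficient of determination.
#' @slot n number of calibration points.
#'
#' @aliases Calibration-class
#' @exportClass Calibration
setClass("Calibration",
    representation(
        slope = "numeric",
        intercept = "numeric",
        rSquared = "numeric",
        n = "integer"
    )
)

setValidity("Calibration", function(object) {
    if (object@n < 3L) "calibration requires at least 3 points" else TRUE
})
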