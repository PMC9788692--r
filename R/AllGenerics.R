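# Generics and accessors for the package's S4 classes.

#' @rdname MotifAlignment-class
#' @param x,object a \linkS4class{MotifAlignment}
#' @export
setGeneric("seqIDs", function(x) standardGeneric("seqIDs"))

#' @rdname MotifAlignment-class
#' @export
setGeneric("gappedSeqs", function(x) standardGeneric("gappedSeqs"))

#' @rdname MotifAlignment-class
#' @export
setGeneric("ssCons", function(x) standardGeneric("ssCons"))

#' @rdname MotifAlignment-class
#' @export
setGeneric("alnMetadata", function(x) standardGeneric("alnMetadata"))

#' @rdname MotifAlignment-class
#' @export
setGeneric("alnName", function(x) standardGeneric("alnName"))

#' @rdname MotifAlignment-class
#' @export
setMethod("seqIDs", "MotifAlignment", function(x) names(x@rows))

#' @rdname MotifAlignment-class
#' @export
setMethod("gappedSeqs", "MotifAlignment", function(x) x@rows)

#' @rdname MotifAlignment-class
#' @export
setMethod("ssCons", "MotifAlignment", function(x) x@ssCons)

#' @rdname MotifAlignment-class
#' @export
setMethod("alnMetadata", "MotifAlignment", function(x) x@metadata)

#' @rdname MotifAlignment-class
#' @export
setMethod("alnName", "MotifAlignment", function(x) x@name)

#' @rdname MotifAlignment-class
#' @export
setMethod("nrow", "MotifAlignment", function(x) length(x@rows))

#' @rdname MotifAlignment-class
#' @export
setMethod("ncol", "MotifAlignment", function(x) nchar(x@ssCons))

#' @rdname MotifAlignment-class
#' @param i integer or character index of sequences to keep
#' @param j,...,drop ignored (column subsetting is not supported; columns
#'   are an invariant of the alignment)
#' @export
setMethod("[", "MotifAlignment", function(x, i, j, ..., drop = FALSE) {
    if (!missing(j)) stop("column subsetting of a MotifAlignment is not supported")
    rows <- x@rows[i]
    if (anyNA(rows)) stop("unknown sequence id or index")
    md <- x@metadata
    if (nrow(md)) md <- md[match(names(rows), rownames(md)), , drop = FALSE]
    new("MotifAlignment", name = x@name, rows = rows, ssCons = x@ssCons,
        metadata = md)
})

setMethod("show", "MotifAlignment", function(object) {
    cat("MotifAlignment '", object@name, "': ", nrow(object),
        " sequences x ", ncol(object), " columns\n", sep = "")
    if (nrow(object)) {
        cat("  SS_cons: ", .clip(object@ssCons), "\n", sep = "")
        ids <- seqIDs(object)
        for (id in utils::head(ids, 4L))
            cat("  ", format(id, width = 12L), " ",
                .clip(object@rows[[id]]), "\n", sep = "")
        if (length(ids) > 4L) cat("  ... and", length(ids) - 4L, "more\n")
        if (ncol(object@metadata))
            cat("  metadata:", paste(colnames(object@metadata),
                collapse = ", "), "\n")
    }
})

.clip <- function(s, width = 60L) {
    if (nchar(s) > width) paste0(substr(s, 1L, width - 3L), "...") else s
}

#' @rdname ConsensusModel-class
#' @param x,object a \linkS4class{ConsensusModel}
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname ConsensusModel-class
#' @export
setGeneric("identityFractions", function(x) standardGeneric("identityFractions"))

#' @rdname ConsensusModel-class
#' @export
setGeneric("presentFraction", function(x) standardGeneric("presentFraction"))

#' @rdname ConsensusModel-class
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname ConsensusModel-class
#' @export
setGeneric("covariation", function(x) standardGeneric("covariation"))

#' @rdname ConsensusModel-class
#' @export
setGeneric("conservationTable", function(x) standardGeneric("conservationTable"))

#' @rdname ConsensusModel-class
#' @export
setMethod("profileCounts", "ConsensusModel", function(x) x@counts)

#' @rdname ConsensusModel-class
#' @export
setMethod("identityFractions", "ConsensusModel", function(x) {
    res <- x@counts[RNA_ALPHABET, , drop = FALSE]
    tot <- colSums(res)
    f <- sweep(res, 2L, pmax(tot, 1L), "/")
    f[, tot == 0L] <- 0
    f
})

#' @rdname ConsensusModel-class
#' @export
setMethod("presentFraction", "ConsensusModel", function(x) {
    if (x@nRows == 0L) return(numeric(ncol(x@counts)))
    1 - x@counts["gap", ] / x@nRows
})

#' @rdname ConsensusModel-class
#' @export
setMethod("pairTable", "ConsensusModel", function(x) x@pairTable)

#' @rdname ConsensusModel-class
#' @export
setMethod("covariation", "ConsensusModel", function(x) x@covariation)

#' @rdname ConsensusModel-class
#' @export
setMethod("ncol", "ConsensusModel", function(x) ncol(x@counts))

#' Tabular view of a consensus model
#'
#' One row per column: majority nucleotide, identity fraction, identity
#' and present tiers, pairing partner and layer.
#'
#' @rdname ConsensusModel-class
#' @return a data.frame with one row per alignment column.
#' @export
setMethod("conservationTable", "ConsensusModel", function(x) {
    C <- ncol(x@counts)
    idf <- identityFractions(x)
    partner <- integer(C)
    layer <- rep(NA_character_, C)
    pt <- x@pairTable
    if (nrow(pt)) {
        partner[pt$i] <- pt$j
        partner[pt$j] <- pt$i
        layer[pt$i] <- pt$layer
        layer[pt$j] <- pt$layer
    }
    data.frame(
        column = seq_len(C),
        majority_nt = x@identityNt,
        identity_fraction = if (C) apply(idf, 2L, max) else numeric(0),
        identity_tier = x@identityTier,
        present_fraction = presentFraction(x),
        present_tier = x@presentTier,
        pair_partner = ifelse(partner == 0L, NA_integer_, partner),
        pair_layer = layer
    )
})

setMethod("show", "ConsensusModel", function(object) {
    cat("ConsensusModel '", object@name, "': ", ncol(object@counts),
        " columns from ", object@nRows, " sequences\n", sep = "")
    cat("  pairs: ", nrow(object@pairTable), " (",
        sum(object@pairTable$layer == "pseudoknot"), " pseudoknot); ",
        sum(object@covariation$covarying), " covarying\n", sep = "")
    cat("  identity tiers >=97/90/75: ",
        sum(object@identityTier == 97L), "/",
        sum(object@identityTier == 90L), "/",
        sum(object@identityTier == 75L), " columns\n", sep = "")
})

setMethod("show", "ContingencyResult", function(object) {
    cat("ContingencyResult (", object@method, ")\n", sep = "")
    print(object@table)
    cat("  odds ratio:", format(object@oddsRatio, digits = 4L),
        " two-sided p:", format(object@pValue, digits = 4L),
        if (object@degenerate) " [degenerate]" else "", "\n")
})

#' @rdname ContingencyResult-class
#' @param x,object a \linkS4class{ContingencyResult}
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname ContingencyResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname ContingencyResult-class
#' @export
setMethod("oddsRatio", "ContingencyResult", function(x) x@oddsRatio)

#' @rdname ContingencyResult-class
#' @export
setMethod("pValue", "ContingencyResult", function(x) x@pValue)

setMethod("show", "BindingCurve", function(object) {
    cat("BindingCurve: ", length(object@concs), " concentrations, ",
        if (object@saturated) {
            paste0("apparent Kd = ", format(object@kd, digits = 3L), " M")
        } else "no saturation (Kd not reported)", "\n", sep = "")
    cat("  Hill n = ", format(object@hillN, digits = 3L),
        ", fMax = ", format(object@fMax, digits = 3L),
        ", rms residual = ", format(object@fitResidual, digits = 3L),
        "\n", sep = "")
    if (length(object@flags)) cat("  flags:", paste(object@flags,
        collapse = ", "), "\n")
})

setMethod("show", "Calibration", function(object) {
    cat("Calibration: slope ", format(object@slope, digits = 4L),
        " AU/M, intercept ", format(object@intercept, digits = 4L),
        " AU, r^2 = ", format(object@rSquared, digits = 4L),
        " (n = ", object@n, ")\n", sep = "")
})
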