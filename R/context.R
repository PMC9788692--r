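# Gene-context frequency tables and exact-test enrichment for
# gene/environment associations.

.domainCounts <- function(aln) {
    md <- alnMetadata(aln)
    if (!"gene_domain" %in% colnames(md)) return(table(character(0)))
    labs <- as.character(md$gene_domain)
    labs <- labs[!is.na(labs)]
    # multi-label annotations: semicolon-separated, counted once per label
    labs <- unlist(lapply(strsplit(labs, ";"), function(l)
        unique(trimws(l))))
    table(labs[labs != ""])
}

#' Gene-context frequency table for two motifs
#'
#' Counts, per motif, the RNAs associated with each downstream-gene
#' domain and reports percentages of the full motif totals (so unlabeled
#' RNAs dilute the percentages, and the listed classes sum to less than
#' 100 percent when rarer genes exist). Rows are the union of each
#' motif's \code{topK} most frequent domains, sorted by the larger of the
#' two percentages.
#'
#' @param alnA,alnB the two \linkS4class{MotifAlignment}s.
#' @param topK number of top domains per motif to include (default 6).
#' @return data.frame with columns \code{domain}, \code{countA},
#'   \code{pctA}, \code{countB}, \code{pctB}; attributes \code{nA},
#'   \code{nB} hold the totals.
#' @export
geneFrequencyTable <- function(alnA, alnB, topK = 6L) {
    tA <- .domainCounts(alnA)
    tB <- .domainCounts(alnB)
    if (!length(tA) && !length(tB))
        stop("no gene_domain metadata in either alignment")
    topOf <- function(t) {
        if (!length(t)) return(character(0))
        ord <- order(-as.integer(t), names(t))
        utils::head(names(t)[ord], topK)
    }
    domains <- union(topOf(tA), topOf(tB))
    nA <- nrow(alnA); nB <- nrow(alnB)
    countA <- as.integer(tA[domains]); countA[is.na(countA)] <- 0L
    countB <- as.integer(tB[domains]); countB[is.na(countB)] <- 0L
    out <- data.frame(
        domain = domains,
        countA = countA,
        pctA = 100 * countA / nA,
        countB = countB,
        pctB = 100 * countB / nB
    )
    out <- out[order(-pmax(out$pctA, out$pctB), out$domain), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "nA") <- nA
    attr(out, "nB") <- nB
    out
}

#' Exact test on a 2x2 contingency table
#'
#' Two-sided Fisher exact p-value by full hypergeometric enumeration:
#' the sum of probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table. The odds ratio
#' is the sample odds ratio (a*d)/(b*c). A chi-square test with Yates
#' correction is available as an alternative statistic.
#'
#' @param table 2x2 matrix (or length-4 vector, row-wise a,b,c,d) of
#'   non-negative integer counts.
#' @param method \code{"fisher"} (default) or \code{"chisq-yates"}.
#' @return a \linkS4class{ContingencyResult}.
#' @examples
#' fisherExact2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' @export
fisherExact2x2 <- function(table, method = c("fisher", "chisq-yates")) {
    method <- match.arg(method)
    if (is.vector(table) && length(table) == 4L)
        table <- matrix(table, 2L, 2L, byrow = TRUE)
    tab <- round(as.matrix(table))
    if (!all(dim(tab) == 2L) || any(tab < 0) || any(is.na(tab)))
        stop("need a 2x2 table of non-negative counts")
    storage.mode(tab) <- "integer"
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
    num <- as.numeric(a) * d
    den <- as.numeric(b) * cc
    degenerate <- FALSE
    orat <- if (den > 0) num / den else if (num > 0) Inf else {
        degenerate <- TRUE
        NaN
    }
    r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
    if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L) {
        p <- 1.0
        degenerate <- TRUE
    } else if (method == "fisher") {
        N <- r1 + r2
        kRange <- max(0L, c1 - r2):min(r1, c1)
        probs <- stats::dhyper(kRange, r1, r2, c1)
        pObs <- stats::dhyper(a, r1, r2, c1)
        p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
    } else {
        p <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
    }
    new("ContingencyResult", table = tab, oddsRatio = orat,
        pValue = p, degenerate = degenerate, method = method)
}

#' Environment enrichment of a motif against a background
#'
#' Builds a 2x2 table of gut vs non-gut counts for the motif's sequences
#' (metadata column \code{environment}; \code{unknown} rows excluded)
#' against a supplied background of sampled metagenomes, and tests it
#' with [fisherExact2x2()]. The odds ratio is
#' (motif gut * background non-gut) / (motif non-gut * background gut).
#'
#' @param aln a \linkS4class{MotifAlignment} with environment metadata.
#' @param background named numeric vector \code{c(gut = ..., non_gut =
#'   ...)} of background sample counts.
#' @param method passed to [fisherExact2x2()].
#' @return a \linkS4class{ContingencyResult}; the motif row comes first.
#' @export
environmentEnrichment <- function(aln, background,
                                  method = c("fisher", "chisq-yates")) {
    stopifnot(is(aln, "MotifAlignment"))
    if (!all(c("gut", "non_gut") %in% names(background)))
        stop("background must be a named vector with 'gut' and 'non_gut'")
    md <- alnMetadata(aln)
    if (!"environment" %in% colnames(md))
        stop("no environment metadata in alignment '", alnName(aln), "'")
    env <- as.character(md$environment)
    env <- env[!is.na(env) & env != "unknown"]
    if (!length(env))
        stop("all environments are unknown in alignment '",
            alnName(aln), "'")
    tab <- matrix(c(sum(env == "gut"), sum(env == "non_gut"),
        background[["gut"]], background[["non_gut"]]),
        2L, 2L, byrow = TRUE,
        dimnames = list(c("motif", "background"), c("gut", "non_gut")))
    fisherExact2x2(tab, method = match.arg(method))
}

#' Export an enrichment result as JSON
#'
#' @param result a \linkS4class{ContingencyResult}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeEnrichmentJSON <- function(result, path) {
    obj <- list(
        table = result@table,
        odds_ratio = if (is.finite(result@oddsRatio)) result@oddsRatio
            else as.character(result@oddsRatio),
        p_two_sided = result@pValue,
        degenerate = result@degenerate,
        method = result@method
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
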