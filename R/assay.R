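# Quantification of the three wet-lab assay families: in-line probing
# band modulation and binding-curve fitting, transcription-termination
# product ratios, and DTNB (Ellman's reagent) acetylation calibration.

#' Read a band-intensity table (in-line probing gel quantification)
#'
#' CSV columns: \code{lane_id}, \code{conc_molar} (empty/NA for the
#' no-ligand lane), \code{modulated}, \code{constant}.
#'
#' @param path CSV path.
#' @return data.frame of class \code{BandTable}.
#' @export
readBandTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("lane_id", "conc_molar", "modulated", "constant")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("band table missing column(s): ", paste(miss, collapse = ", "))
    .asBandTable(tab)
}

.asBandTable <- function(tab) {
    if (nrow(tab) < 2L) stop("a band table needs at least 2 lanes")
    if (sum(is.na(tab$conc_molar)) > 1L)
        stop("at most one no-ligand lane (empty conc_molar) is permitted")
    if (any(tab$modulated < 0) || any(tab$constant < 0))
        stop("band intensities must be non-negative")
    class(tab) <- c("BandTable", "data.frame")
    tab
}

#' Relative intensity change of a modulated band
#'
#' Per lane, the modulated band intensity is divided by the constant
#' band intensity; the relative change at each ligand concentration is
#' that ratio minus the ratio of the no-ligand lane. The no-ligand lane
#' is excluded from the returned series, which is ordered by increasing
#' concentration.
#'
#' @param table a \code{BandTable} (see [readBandTable()]).
#' @return list with \code{concs} (molar) and \code{relChange}.
#' @export
relativeIntensityChange <- function(table) {
    tab <- .asBandTable(as.data.frame(table))
    zero <- tab$constant <= 0
    if (any(zero))
        stop("zero constant-band intensity in lane(s): ",
            paste(tab$lane_id[zero], collapse = ", "))
    noLigand <- is.na(tab$conc_molar)
    if (!any(noLigand))
        stop("no-ligand lane (empty conc_molar) is missing")
    r <- tab$modulated / tab$constant
    r0 <- r[noLigand]
    keep <- !noLigand
    ord <- order(tab$conc_molar[keep])
    list(concs = tab$conc_molar[keep][ord],
        relChange = (r[keep] - r0)[ord])
}

#' Normalize a series to its largest magnitude
#'
#' Divides by the maximum absolute value; signs are preserved and the
#' maximum magnitude becomes 1. Idempotent and scale invariant.
#'
#' @param relChange numeric series with at least one nonzero value.
#' @return normalized series.
#' @export
normalizeSeries <- function(relChange) {
    m <- max(abs(relChange))
    if (!is.finite(m) || m == 0)
        stop("cannot normalize an all-zero series")
    relChange / m
}

#' Geometric dilution series
#'
#' @param top highest concentration (molar).
#' @param factor dilution factor per step (> 1).
#' @param n number of concentrations (>= 1).
#' @return concentrations top, top/factor, ..., length n (descending).
#' @examples
#' range(dilutionSeries(20e-3, 2, 16)) # 6.1e-07 .. 2e-02 M
#' @export
dilutionSeries <- function(top, factor, n) {
    stopifnot(top > 0, factor > 1, n >= 1)
    top / factor^(0:(n - 1L))
}

#' Fit a Hill binding isotherm to a relative-intensity-change series
#'
#' Fits f(c) = fmax * c^n / (Kd^n + c^n) by nonlinear least squares
#' (Levenberg-Marquardt; the Hill coefficient n is free within
#' [0.5, 3]). The response sign is detected automatically (in-line
#' probing modulation may decrease a band). The curve is called
#' saturated when the fitted Kd is at most max(conc)/5 and the fitted
#' values at the two highest concentrations are within 10 percent of
#' fmax; otherwise no apparent Kd is reported and the series is
#' normalized to the value at the highest concentration rather than to
#' the fitted plateau.
#'
#' @param concs molar concentrations (>= 5 values spanning >= 2 orders
#'   of magnitude).
#' @param relChange relative intensity changes, same length.
#' @return a \linkS4class{BindingCurve}.
#' @importFrom minpack.lm nlsLM
#' @export
fitBindingCurve <- function(concs, relChange) {
    stopifnot(length(concs) == length(relChange))
    if (length(concs) < 5L)
        stop("need at least 5 concentrations")
    if (max(concs) / min(concs) < 100)
        stop("concentrations must span at least 2 orders of magnitude")
    ord <- order(concs)
    concs <- concs[ord]; relChange <- relChange[ord]
    flags <- character(0)
    sgn <- if (sum(relChange) < 0) -1 else 1
    y <- sgn * relChange
    if (stats::sd(y) < 1e-12 || max(abs(y)) == 0) {
        warning("degenerate (constant) response; no fit possible")
        norm <- if (max(abs(relChange)) > 0)
            relChange / abs(relChange[length(relChange)]) else
            relChange
        return(new("BindingCurve", concs = concs, relChange = relChange,
            normalized = norm, kd = NA_real_, fitKd = NA_real_,
            hillN = NA_real_, fMax = NA_real_, saturated = FALSE,
            fitResidual = 0, flags = "degenerate"))
    }
    # monotonicity check (binding responses should increase with dose)
    if (stats::cor(rank(concs), rank(y)) < 0.8) {
        warning("response series is non-monotone beyond noise tolerance; ",
            "fit attempted anyway")
        flags <- c(flags, "non_monotone")
    }
    fmax0 <- max(y)
    kd0 <- concs[which.min(abs(y - fmax0 / 2))]
    dat <- data.frame(c = concs, y = y)
    fit <- tryCatch(
        minpack.lm::nlsLM(y ~ fmax * c^n / (kd^n + c^n), data = dat,
            start = list(fmax = fmax0, kd = kd0, n = 1),
            lower = c(fmax = 1e-12, kd = min(concs) / 1e6, n = 0.5),
            upper = c(fmax = Inf, kd = max(concs) * 1e9, n = 3),
            control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    if (is.null(fit)) {
        warning("binding-curve fit failed to converge")
        return(new("BindingCurve", concs = concs, relChange = relChange,
            normalized = relChange / max(abs(relChange)),
            kd = NA_real_, fitKd = NA_real_, hillN = NA_real_,
            fMax = NA_real_, saturated = FALSE, fitResidual = NA_real_,
            flags = c(flags, "fit_failed")))
    }
    par <- stats::coef(fit)
    fitted <- par[["fmax"]] * concs^par[["n"]] /
        (par[["kd"]]^par[["n"]] + concs^par[["n"]])
    topTwo <- utils::tail(fitted, 2L)
    resid <- sqrt(mean((y - fitted)^2))
    # a saturated call also needs a plateau resolvable above the noise,
    # otherwise a flat noise-dominated series would masquerade as an
    # already-saturated binder
    saturated <- par[["kd"]] <= max(concs) / 5 &&
        all(topTwo >= 0.9 * par[["fmax"]]) &&
        par[["fmax"]] > 3 * resid
    norm <- if (saturated) relChange / max(abs(relChange)) else
        relChange / abs(relChange[length(relChange)])
    norm <- norm / max(1, max(abs(norm)))  # guard: magnitude cap at 1
    new("BindingCurve",
        concs = concs, relChange = relChange, normalized = norm,
        kd = if (saturated) unname(par[["kd"]]) else NA_real_,
        fitKd = unname(par[["kd"]]),
        hillN = unname(par[["n"]]), fMax = unname(par[["fmax"]]),
        saturated = saturated,
        fitResidual = resid,
        flags = flags)
}

#' Fraction of terminated transcript in a termination assay
#'
#' Band intensities from body-labelled ([alpha-32P]-ATP) transcription
#' reactions scale with the adenosine content of each product, so the
#' intensities are divided by the products' A counts before the
#' terminated fraction (term / (term + full)) is computed. Set
#' \code{correctA = FALSE} to skip the correction.
#'
#' @param term,full intensities of the terminated and full-length
#'   product bands (non-negative, not both zero).
#' @param aTerm,aFull adenosine counts of the two products (> 0).
#' @param correctA apply the A-count correction (default TRUE).
#' @return list of class \code{TerminationResult}: \code{fracTerminated},
#'   \code{intensities}, \code{aCounts}.
#' @examples
#' terminatedFraction(100, 100, aTerm = 30, aFull = 60)$fracTerminated
#' @export
terminatedFraction <- function(term, full, aTerm, aFull,
                               correctA = TRUE) {
    stopifnot(aTerm > 0, aFull > 0)
    if (term < 0 || full < 0) stop("intensities must be non-negative")
    if (term == 0 && full == 0)
        stop("both product bands are zero; nothing to quantify")
    if (!correctA) { aTerm <- 1; aFull <- 1 }
    t <- term / aTerm
    f <- full / aFull
    structure(list(
        fracTerminated = t / (t + f),
        intensities = c(term = term, full = full),
        aCounts = c(term = aTerm, full = aFull)
    ), class = "TerminationResult")
}

#' Linear DTNB calibration from CoA standards
#'
#' Ordinary least-squares line through absorbance readings of known CoA
#' concentrations (>= 3 points), as used to quantify CoA released by
#' acetyltransferase activity.
#'
#' @param coaConcs CoA concentrations (molar).
#' @param absorbances absorbance readings (e.g. at 412-420 nm).
#' @return a \linkS4class{Calibration}.
#' @export
dtnbCalibrate <- function(coaConcs, absorbances) {
    stopifnot(length(coaConcs) == length(absorbances))
    if (length(coaConcs) < 3L)
        stop("need at least 3 calibration points")
    if (stats::var(coaConcs) == 0)
        stop("calibration concentrations have zero variance")
    fit <- stats::lm(absorbances ~ coaConcs)
    new("Calibration",
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        rSquared = suppressWarnings(summary(fit)$r.squared),
        n = length(coaConcs))
}

#' Convert an absorbance reading into released CoA
#'
#' @param absorbance measured absorbance.
#' @param cal a \linkS4class{Calibration}.
#' @return CoA concentration (molar), clipped at >= 0 (with a warning
#'   when the raw value is negative).
#' @export
activityFromAbsorbance <- function(absorbance, cal) {
    stopifnot(is(cal, "Calibration"))
    conc <- (absorbance - cal@intercept) / cal@slope
    if (any(conc < 0)) {
        warning("negative inferred concentration clipped to 0")
        conc <- pmax(conc, 0)
    }
    conc
}

#' OD-normalized reporter fluorescence
#'
#' @param fluorescence raw fluorescence reading.
#' @param od optical density at 600 nm (> 0).
#' @return fluorescence / od.
#' @export
normalizedFluorescence <- function(fluorescence, od) {
    if (any(od <= 0)) stop("OD600 must be positive")
    fluorescence / od
}
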