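#' Construct a PlateKinetics object
#'
#' @param assay `"DPPH"` or `"ABTS"`.
#' @param wells data.frame of readings with columns `well`, `role`,
#'   `analyte`, `concentration`, `conc_units`, `time_min`, `absorbance`.
#' @param flags character, optional QC flags.
#' @return a [PlateKinetics-class].
#' @export
PlateKinetics <- function(assay, wells, flags = character()) {
    wells$role <- as.character(wells$role)
    wells$analyte <- as.character(wells$analyte)
    wells <- wells[order(wells$well, wells$time_min), , drop = FALSE]
    rownames(wells) <- NULL
    new("PlateKinetics", assay = assay, wells = wells, flags = flags)
}

#' @describeIn PlateKinetics the readings data.frame.
#' @param x a `PlateKinetics`.
#' @export
setMethod("plateWells", "PlateKinetics", function(x) x@wells)

#' @describeIn PlateKinetics the assay name.
#' @export
setMethod("plateAssay", "PlateKinetics", function(x) x@assay)

setMethod("show", "PlateKinetics", function(object) {
    w <- object@wells
    cat(sprintf("PlateKinetics (%s): %d wells, %d readings\n", object@assay,
                length(unique(w$well)), nrow(w)))
    cat(sprintf("  roles: %s\n",
                paste(sprintf("%s=%d", names(table(w$role[!duplicated(w$well)])),
                              table(w$role[!duplicated(w$well)])),
                      collapse = " ")))
    if (length(object@flags))
        cat(sprintf("  flags: %s\n", paste(object@flags, collapse = "; ")))
})

#' Radical-scavenging inhibition percentage
#'
#' `100 * (absRadical - (absSample - absControl)) / absRadical`: the sample
#' reading is corrected by its radical-free colour control before being
#' referenced to the uninhibited radical absorbance. Values may be negative
#' (pro-oxidant behaviour or noise); clip only at presentation.
#'
#' @param absRadical absorbance of the radical blank (must be > 0).
#' @param absSample absorbance of sample + radical.
#' @param absControl absorbance of sample + solvent (no radical); default 0.
#' @return inhibition in percent (vectorized).
#' @examples
#' inhibitionPercent(0.9, 0.63, 0)  # 30
#' @export
inhibitionPercent <- function(absRadical, absSample, absControl = 0) {
    if (any(absRadical <= 0))
        .alStop("al_assay_error", "radical blank absorbance must be > 0")
    100 * (absRadical - (absSample - absControl)) / absRadical
}

## readings of one well at the time closest to timePoint
.atTime <- function(w, timePoint) {
    pick <- function(d) d[which.min(abs(d$time_min - timePoint)), , drop = FALSE]
    do.call(rbind, lapply(split(w, w$well), pick))
}

#' Reduce plate kinetics to a dose-response curve
#'
#' For one analyte, computes replicate-wise inhibition at the reading
#' nearest `timePoint` (default 120 min, the end of the incubation) and
#' averages over replicate wells per concentration. The radical blank is the
#' mean over `radical_blank` wells at that time; each sample well is paired
#' with the mean of the `sample_control` wells of the same analyte and
#' concentration.
#'
#' @param x a [PlateKinetics-class].
#' @param analyte analyte id to reduce (default: the single non-standard
#'   analyte present).
#' @param timePoint reading time in minutes.
#' @param role which measurement role carries the analyte: `"sample"` for
#'   extracts, `"standard"` for the Trolox standard.
#' @return a [DoseResponseCurve-class].
#' @export
setMethod("buildCurve", "PlateKinetics",
function(x, analyte = NULL, timePoint = 120, role = c("sample", "standard")) {
    role <- match.arg(role)
    w <- plateWells(x)
    if (is.null(analyte)) {
        cand <- unique(w$analyte[w$role == role])
        if (length(cand) != 1L)
            .alStop("al_assay_error",
                    "analyte must be given when the plate has %d '%s' analytes",
                    length(cand), role)
        analyte <- cand
    }
    rb <- w[w$role == "radical_blank", , drop = FALSE]
    if (!nrow(rb))
        .alStop("al_assay_error", "no radical_blank wells on the plate")
    absR <- mean(.atTime(rb, timePoint)$absorbance)

    sm <- .atTime(w[w$role == role & w$analyte == analyte, , drop = FALSE],
                  timePoint)
    if (!nrow(sm))
        .alStop("al_assay_error", "no '%s' wells for analyte '%s'",
                role, analyte)
    ct <- .atTime(w[w$role == "sample_control" & w$analyte == analyte, ,
                    drop = FALSE], timePoint)
    units <- unique(sm$conc_units)

    pts <- lapply(split(sm, sm$concentration), function(d) {
        conc <- d$concentration[1]
        cc <- ct[ct$concentration == conc, , drop = FALSE]
        if (!nrow(cc))
            .alStop("al_assay_error",
                    "no sample_control wells for '%s' at concentration %g",
                    analyte, conc)
        inh <- inhibitionPercent(absR, d$absorbance, mean(cc$absorbance))
        data.frame(concentration = conc, inhibition = mean(inh),
                   sd = stats::sd(inh), n = length(inh))
    })
    pts <- do.call(rbind, pts)
    pts <- pts[order(pts$concentration), , drop = FALSE]
    rownames(pts) <- NULL
    new("DoseResponseCurve", assay = plateAssay(x), analyte = analyte,
        timePoint = timePoint, points = pts,
        concUnits = if (length(units)) units[1] else NA_character_)
})

#' @describeIn DoseResponseCurve the per-concentration points.
#' @param x a `DoseResponseCurve`.
#' @export
setMethod("curvePoints", "DoseResponseCurve", function(x) x@points)

setMethod("show", "DoseResponseCurve", function(object) {
    cat(sprintf("DoseResponseCurve (%s, %s) at %g min\n", object@assay,
                object@analyte, object@timePoint))
    print(object@points)
})

#' Estimate the ICx from a linear dose-response regression
#'
#' Ordinary least squares of mean inhibition on concentration;
#' `ic = (level - intercept) / slope`. A non-positive slope means the curve
#' carries no usable dose-response signal and raises a no-convergence error
#' rather than returning a number. An IC outside the tested concentration
#' range is returned but flagged `extrapolated`.
#'
#' @param x a [DoseResponseCurve-class].
#' @param level target inhibition in percent (e.g. 50 for ABTS, 20 for DPPH).
#' @return a [ScavengingResult-class] (its `te` slot is `NA` until
#'   [troloxEquivalents()] is applied).
#' @export
setMethod("estimateICx", "DoseResponseCurve", function(x, level) {
    p <- curvePoints(x)
    fit <- stats::lm(inhibition ~ concentration, data = p)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    if (!is.finite(slope) || slope <= 1e-10)
        .alStop("al_no_convergence",
                "dose-response slope is %s; no ICx can be estimated",
                format(slope))
    ic <- (level - intercept) / slope
    r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits are fine
    new("ScavengingResult", assay = x@assay, analyte = x@analyte,
        level = level, ic = ic, slope = slope, intercept = intercept,
        r2 = if (is.finite(r2)) r2 else NA_real_,
        extrapolated = ic < min(p$concentration) | ic > max(p$concentration),
        concUnits = x@concUnits, te = NA_real_)
})

#' @describeIn ScavengingResult the estimated IC value.
#' @param x a `ScavengingResult`.
#' @export
setMethod("icValue", "ScavengingResult", function(x) x@ic)

#' @describeIn ScavengingResult the Trolox equivalents (`NA` if unset).
#' @export
setMethod("troloxEq", "ScavengingResult", function(x) x@te)

setMethod("show", "ScavengingResult", function(object) {
    cat(sprintf("ScavengingResult (%s, %s): IC%g = %.4g %s%s\n",
                object@assay, object@analyte, object@level, object@ic,
                object@concUnits,
                if (object@extrapolated) " [extrapolated]" else ""))
    cat(sprintf("  slope %.4g, intercept %.4g, R2 %.4g\n", object@slope,
                object@intercept, object@r2))
    if (!is.na(object@te))
        cat(sprintf("  TE = %.4g umol/g\n", object@te))
})

#' Trolox equivalents from paired IC values
#'
#' `TE = 1000 * icTrolox / icSample`, in umol Trolox per g of extract, where
#' `icTrolox` (umol/L) and `icSample` (ug/mL) refer to the same assay and
#' the same inhibition level. When [ScavengingResult-class] objects are
#' supplied, assay and level agreement is enforced and the sample result is
#' returned with its `te` slot filled.
#'
#' @param sample IC of the extract (ug/mL) or its `ScavengingResult`.
#' @param standard IC of Trolox (umol/L) or its `ScavengingResult`.
#' @return numeric TE, or the sample `ScavengingResult` with `te` set.
#' @examples
#' troloxEquivalents(29.4, 18.74)  # ~637.4
#' @export
troloxEquivalents <- function(sample, standard) {
    if (is(sample, "ScavengingResult") && is(standard, "ScavengingResult")) {
        if (sample@assay != standard@assay)
            .alStop("al_assay_error", "assay mismatch: %s vs %s",
                    sample@assay, standard@assay)
        if (sample@level != standard@level)
            .alStop("al_assay_error",
                    "inhibition level mismatch: IC%g vs IC%g",
                    sample@level, standard@level)
        sample@te <- troloxEquivalents(icValue(sample), icValue(standard))
        return(sample)
    }
    if (!is.numeric(sample) || !is.numeric(standard) ||
        any(sample <= 0) || any(standard <= 0))
        .alStop("al_assay_error", "IC values must be positive numbers")
    1000 * standard / sample
}
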