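#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Container for fatty acid relative-abundance profiles
#'
#' `FAProfileSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"abundance"` assay holding relative abundances (% of total FA;
#' fatty acids in rows, replicate samples in columns). `rowData` carries the
#' parsed fatty acid catalog (chain length, double bonds, delta positions,
#' omega class, saturation class) and `colData` the `species` and `replicate`
#' of each sample. Row names are canonical fatty acid labels.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [FAProfileSet()] for construction, [classSummary()],
#'   [nutritionalIndices()], [indexTable()].
#' @export
setClass("FAProfileSet", contains = "SummarizedExperiment")

setValidity("FAProfileSet", function(object) {
    msg <- character()
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'abundance' is required")
    else {
        a <- SummarizedExperiment::assay(object, "abundance")
        if (anyNA(a))
            msg <- c(msg, "abundances must not contain NA")
        else if (any(a < 0))
            msg <- c(msg, "abundances must be non-negative")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("species", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'species' and 'replicate'")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("carbons", "doubleBonds", "omegaClass", "saturationClass")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, paste("rowData must contain", paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Microplate kinetics for one radical-scavenging assay
#'
#' Raw well time-series for a DPPH or ABTS plate. Each row of `wells` is one
#' absorbance reading: columns `well`, `role` (one of `radical_blank`,
#' `sample`, `sample_control`, `standard`), `analyte`, `concentration`,
#' `conc_units`, `time_min`, `absorbance`. Times within a well must be
#' strictly increasing and non-negative.
#'
#' @slot assay character, `"DPPH"` or `"ABTS"`.
#' @slot wells data.frame of readings (see Description).
#' @slot flags character, simulation/QC flags attached by producers.
#' @export
setClass("PlateKinetics",
    representation(assay = "character", wells = "data.frame",
                   flags = "character"))

setValidity("PlateKinetics", function(object) {
    msg <- character()
    if (length(object@assay) != 1L || !object@assay %in% c("DPPH", "ABTS"))
        msg <- c(msg, "assay must be 'DPPH' or 'ABTS'")
    w <- object@wells
    need <- c("well", "role", "analyte", "concentration", "conc_units",
              "time_min", "absorbance")
    if (!all(need %in% colnames(w)))
        msg <- c(msg, paste("wells must have columns",
                            paste(need, collapse = ", ")))
    else {
        if (!all(w$role %in% c("radical_blank", "sample", "sample_control",
                               "standard")))
            msg <- c(msg, "unknown well role")
        if (any(w$time_min < 0))
            msg <- c(msg, "times must be non-negative")
        bad <- vapply(split(w$time_min, w$well),
                      function(t) any(diff(t) <= 0), logical(1))
        if (any(bad))
            msg <- c(msg, "times within a well must be strictly increasing")
        if (any(!is.na(w$concentration[w$role == "radical_blank"])))
            msg <- c(msg, "radical_blank wells must have no concentration")
    }
    if (length(msg)) msg else TRUE
})

#' Dose-response curve of inhibition versus concentration
#'
#' Per-concentration mean inhibition (%) with replicate SD, reduced from a
#' [PlateKinetics] object at one time point.
#'
#' @slot assay character, `"DPPH"` or `"ABTS"`.
#' @slot analyte character, analyte identifier.
#' @slot timePoint numeric, reading time used (min).
#' @slot points data.frame with `concentration`, `inhibition`, `sd`, `n`.
#' @slot concUnits character, concentration units.
#' @export
setClass("DoseResponseCurve",
    representation(assay = "character", analyte = "character",
                   timePoint = "numeric", points = "data.frame",
                   concUnits = "character"))

setValidity("DoseResponseCurve", function(object) {
    msg <- character()
    p <- object@points
    if (!all(c("concentration", "inhibition", "sd", "n") %in% colnames(p)))
        msg <- c(msg, "points must have concentration, inhibition, sd, n")
    else if (length(unique(p$concentration)) < 2L)
        msg <- c(msg, "at least 2 distinct concentrations required")
    if (length(msg)) msg else TRUE
})

#' Reduced radical-scavenging result
#'
#' ICx estimate from the linear dose-response regression, optionally with
#' Trolox equivalents once a matching standard result is supplied.
#'
#' @slot assay character, `"DPPH"` or `"ABTS"`.
#' @slot analyte character.
#' @slot level numeric, inhibition level (%) the IC refers to (e.g. 20, 50).
#' @slot ic numeric, concentration at `level` (units in `concUnits`).
#' @slot slope,intercept,r2 numeric, regression diagnostics.
#' @slot extrapolated logical, TRUE when `ic` lies outside the tested range.
#' @slot concUnits character.
#' @slot te numeric, Trolox equivalents (umol/g), `NA` until computed.
#' @export
setClass("ScavengingResult",
    representation(assay = "character", analyte = "character",
                   level = "numeric", ic = "numeric", slope = "numeric",
                   intercept = "numeric", r2 = "numeric",
                   extrapolated = "logical", concUnits = "character",
                   te = "numeric"))

#' Kruskal-Wallis / Dunn group comparison of one variable
#'
#' @slot variable character, name of the compared variable.
#' @slot omnibus list with `statistic`, `df`, `p.value` of the
#'   Kruskal-Wallis omnibus test.
#' @slot pairwise data.frame with `group1`, `group2`, `z`, `p`, `q`.
#' @slot letters named character, one entry per group; a letter shared by two
#'   groups marks a significant pair (q below `alpha`), following the
#'   inverted compact-letter convention used for these data.
#' @slot alpha numeric, significance threshold on adjusted q.
#' @slot method character, multiplicity adjustment (`"BH"` or `"BY"`).
#' @export
setClass("GroupComparison",
    representation(variable = "character", omnibus = "list",
                   pairwise = "data.frame", letters = "character",
                   alpha = "numeric", method = "character"))
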