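#' Construct an FAProfileSet from an abundance matrix
#'
#' @param abundance numeric matrix, fatty acids in rows (row names are FA
#'   labels in any tolerated spelling) and samples in columns; values are
#'   relative abundances in % of total FA.
#' @param species character, one species id per column.
#' @param replicate character, one replicate id per column; defaults to
#'   `"r1"` for every column.
#' @param missingCells optional data.frame with columns `species` and
#'   `fa_label` naming cells known to be unreported in the source table
#'   (carried as zeros but flagged downstream).
#' @return an [FAProfileSet-class] with canonical row names and the parsed
#'   catalog in `rowData`.
#' @examples
#' m <- matrix(c(40, 10, 50), ncol = 1,
#'             dimnames = list(c("C16:0", "C18:1 (ω-9)",
#'                               "C18:3 ∆9,12,15 (ω-3)"), "s1"))
#' fp <- FAProfileSet(m, species = "demo")
#' classSummary(fp)
#' @export
FAProfileSet <- function(abundance, species,
                         replicate = rep("r1", ncol(abundance)),
                         missingCells = NULL) {
    stopifnot(is.matrix(abundance), is.numeric(abundance),
              !is.null(rownames(abundance)),
              length(species) == ncol(abundance),
              length(replicate) == ncol(abundance))
    catalog <- parseFaLabel(rownames(abundance))
    if (anyDuplicated(catalog$label))
        .alStop("al_consistency_error",
                "duplicate fatty acids after canonicalization: %s",
                paste(unique(catalog$label[duplicated(catalog$label)]),
                      collapse = ", "))
    rownames(abundance) <- catalog$label
    if (is.null(colnames(abundance)))
        colnames(abundance) <- paste(species, replicate, sep = ".")
    if (!is.null(missingCells)) {
        missingCells$fa_label <- canonicalFaLabel(missingCells$fa_label)
        stopifnot(all(missingCells$species %in% species),
                  all(missingCells$fa_label %in% catalog$label))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = abundance),
        rowData = catalog,
        colData = S4Vectors::DataFrame(
            species = as.character(species),
            replicate = as.character(replicate),
            row.names = colnames(abundance)))
    obj <- new("FAProfileSet", se)
    S4Vectors::metadata(obj)$normalized <- FALSE
    S4Vectors::metadata(obj)$missing_cells <- missingCells
    obj
}

#' @describeIn FAProfileSet parsed fatty acid catalog (`rowData`).
#' @param x an `FAProfileSet`.
#' @export
setMethod("faCatalog", "FAProfileSet", function(x)
    SummarizedExperiment::rowData(x))

#' @describeIn FAProfileSet species id per sample.
#' @export
setMethod("faSpecies", "FAProfileSet", function(x)
    SummarizedExperiment::colData(x)$species)

#' @describeIn FAProfileSet replicate id per sample.
#' @export
setMethod("faReplicate", "FAProfileSet", function(x)
    SummarizedExperiment::colData(x)$replicate)

setMethod("show", "FAProfileSet", function(object) {
    callNextMethod()
    sp <- faSpecies(object)
    cat(sprintf("species(%d): %s\n", length(unique(sp)),
                paste(utils::head(unique(sp), 5), collapse = ", ")))
    cat(sprintf("normalized: %s\n",
                isTRUE(S4Vectors::metadata(object)$normalized)))
})

#' Close relative abundances to 100 percent
#'
#' Rescales every sample so its abundances sum to exactly 100. Samples whose
#' raw sum falls outside \[95, 105\] are rejected: such a profile is either
#' incomplete or not a relative-abundance vector, and silently closing it
#' would hide the defect.
#'
#' @param x an [FAProfileSet-class].
#' @param tolerance numeric length-2, admissible raw-sum interval.
#' @return the rescaled `FAProfileSet` (zero entries preserved).
#' @export
setMethod("normalizeProfiles", "FAProfileSet",
function(x, tolerance = c(95, 105)) {
    a <- SummarizedExperiment::assay(x, "abundance")
    s <- colSums(a)
    bad <- s < tolerance[1] | s > tolerance[2]
    if (any(bad))
        .alStop("al_normalize_error",
                "profile sum outside [%g, %g]: %s", tolerance[1], tolerance[2],
                paste(sprintf("%s=%.3f", colnames(a)[bad], s[bad]),
                      collapse = ", "))
    SummarizedExperiment::assay(x, "abundance") <-
        sweep(a, 2, s / 100, "/")
    S4Vectors::metadata(x)$normalized <- TRUE
    x
})

## Sum abundances of catalog rows matched by (carbons, doubleBonds,
## omegaClass); used for the named index terms so that positional isomers
## with the same omega class pool together.
.faTerm <- function(a, cat, carbons, db, omega = NULL) {
    sel <- cat$carbons == carbons & cat$doubleBonds == db
    if (!is.null(omega))
        sel <- sel & !is.na(cat$omegaClass) & cat$omegaClass == omega
    if (!any(sel)) return(numeric(ncol(a)))
    colSums(a[sel, , drop = FALSE])
}

.classSums <- function(a, cat) {
    sat <- cat$saturationClass
    pufa <- sat == "PUFA"
    list(sfa = colSums(a[sat == "SFA", , drop = FALSE]),
         mufa = colSums(a[sat == "MUFA", , drop = FALSE]),
         pufa = colSums(a[pufa, , drop = FALSE]),
         n3 = colSums(a[pufa & !is.na(cat$omegaClass) & cat$omegaClass == 3L,
                        , drop = FALSE]),
         n6 = colSums(a[pufa & !is.na(cat$omegaClass) & cat$omegaClass == 6L,
                        , drop = FALSE]))
}

#' Saturation-class and omega-class sums per sample
#'
#' Sums relative abundances over SFA/MUFA/PUFA, over omega-3 and omega-6
#' PUFA (only PUFA with a known omega class of 3 or 6 contribute), and forms
#' the omega-6/omega-3 ratio. The ratio is reported `NA` when the omega-3
#' sum is zero -- never 0 or infinity.
#'
#' @param x an [FAProfileSet-class].
#' @return a [S4Vectors::DataFrame] with one row per sample: `species`,
#'   `replicate`, `sfa`, `mufa`, `pufa`, `pufa_n6`, `pufa_n3`, `n6_over_n3`.
#' @export
setMethod("classSummary", "FAProfileSet", function(x) {
    a <- SummarizedExperiment::assay(x, "abundance")
    cs <- .classSums(a, faCatalog(x))
    ratio <- ifelse(cs$n3 > 0, cs$n6 / cs$n3, NA_real_)
    S4Vectors::DataFrame(
        species = faSpecies(x), replicate = faReplicate(x),
        sfa = unname(cs$sfa), mufa = unname(cs$mufa), pufa = unname(cs$pufa),
        pufa_n6 = unname(cs$n6), pufa_n3 = unname(cs$n3),
        n6_over_n3 = unname(ratio),
        row.names = colnames(a))
})

#' Lipid nutritional-quality indices per sample
#'
#' Computes, per sample, the Ulbricht-Southgate atherogenicity index
#' \deqn{AI = (C12:0 + 4 \cdot C14:0 + C16:0) /
#'       (\Sigma MUFA + \Sigma \omega6 + \Sigma \omega3),}
#' the thrombogenicity index
#' \deqn{TI = (C14:0 + C16:0 + C18:0) /
#'       (0.5\,\Sigma MUFA + 0.5\,\Sigma \omega6 + 3\,\Sigma \omega3 +
#'        \Sigma \omega3 / \Sigma \omega6),}
#' and the hypocholesterolemic/hypercholesterolemic ratio
#' \deqn{h/H = (C18:1\omega9 + C18:2\omega6 + C18:3\omega3 + C20:4\omega6 +
#'        C20:5\omega3) / (C14:0 + C16:0).}
#' Absent fatty acids contribute 0. The TI ratio term is 0 when the omega-3
#' sum is 0; TI is `NA` when the omega-6 sum is 0 while omega-3 is positive
#' (undefined ratio term). Any index with a zero denominator is `NA`. All
#' three indices are pure ratios, invariant under uniform rescaling of the
#' profile.
#'
#' @param x an [FAProfileSet-class].
#' @return a [S4Vectors::DataFrame] with one row per sample: `species`,
#'   `replicate`, `ai`, `ti`, `h_over_h`.
#' @export
setMethod("nutritionalIndices", "FAProfileSet", function(x) {
    a <- SummarizedExperiment::assay(x, "abundance")
    ## indices are defined on percentages closed to 100: the TI ratio term is
    ## dimensionless while the other denominator terms carry the profile
    ## scale, so closure is what makes TI well-defined and all three indices
    ## invariant under uniform rescaling
    s <- colSums(a)
    a <- sweep(a, 2, ifelse(s > 0, s / 100, 1), "/")
    cat <- faCatalog(x)
    cs <- .classSums(a, cat)
    c12 <- .faTerm(a, cat, 12L, 0L)
    c14 <- .faTerm(a, cat, 14L, 0L)
    c16 <- .faTerm(a, cat, 16L, 0L)
    c18 <- .faTerm(a, cat, 18L, 0L)

    denomU <- cs$mufa + cs$n6 + cs$n3
    ai <- ifelse(denomU > 0, (c12 + 4 * c14 + c16) / denomU, NA_real_)

    ratio <- ifelse(cs$n3 == 0, 0,
                    ifelse(cs$n6 > 0, cs$n3 / cs$n6, NA_real_))
    denomT <- 0.5 * cs$mufa + 0.5 * cs$n6 + 3 * cs$n3 + ratio
    ti <- ifelse(!is.na(denomT) & denomT > 0,
                 (c14 + c16 + c18) / denomT, NA_real_)

    hNum <- .faTerm(a, cat, 18L, 1L, 9L) + .faTerm(a, cat, 18L, 2L, 6L) +
        .faTerm(a, cat, 18L, 3L, 3L) + .faTerm(a, cat, 20L, 4L, 6L) +
        .faTerm(a, cat, 20L, 5L, 3L)
    hDen <- c14 + c16
    hh <- ifelse(hDen > 0, hNum / hDen, NA_real_)

    S4Vectors::DataFrame(
        species = faSpecies(x), replicate = faReplicate(x),
        ai = unname(ai), ti = unname(ti), h_over_h = unname(hh),
        row.names = colnames(a))
})

#' Per-species summary of class sums and nutritional indices
#'
#' Computes [classSummary()] and [nutritionalIndices()] per replicate, then
#' reports the per-species mean and sample standard deviation (n - 1) of
#' every quantity, at full precision (round only at presentation, e.g. with
#' [roundHalfUp()]). Species whose source profile carries known-unreported
#' cells (see `missingCells` in [FAProfileSet()]) are flagged
#' `complete_profile = FALSE`: their quantities involving the missing fatty
#' acids are not reproducible and are reported as computed, not patched.
#'
#' @param x an [FAProfileSet-class] (>= 1 replicate per species).
#' @return a [S4Vectors::DataFrame], one row per species, with `<q>_mean`
#'   and `<q>_sd` columns for sfa, mufa, pufa, pufa_n6, pufa_n3, n6_over_n3,
#'   ai, ti and h_over_h, plus `n` and `complete_profile`.
#' @export
setMethod("indexTable", "FAProfileSet", function(x) {
    cs <- classSummary(x)
    ni <- nutritionalIndices(x)
    qnames <- c("sfa", "mufa", "pufa", "pufa_n6", "pufa_n3", "n6_over_n3",
                "ai", "ti", "h_over_h")
    per <- cbind(as.data.frame(cs),
                 as.data.frame(ni)[, c("ai", "ti", "h_over_h")])
    sp <- unique(per$species)
    rows <- lapply(sp, function(s) {
        d <- per[per$species == s, qnames, drop = FALSE]
        stats <- lapply(qnames, function(q) {
            v <- d[[q]]
            c(mean = mean(v), sd = stats::sd(v))
        })
        out <- unlist(stats)
        names(out) <- as.vector(t(outer(qnames, c("mean", "sd"),
                                        paste, sep = "_")))
        c(out, n = nrow(d))
    })
    tab <- S4Vectors::DataFrame(species = sp, do.call(rbind, rows))
    mc <- S4Vectors::metadata(x)$missing_cells
    tab$complete_profile <- !(tab$species %in% mc$species)
    tab
})

#' Round half away from zero
#'
#' Presentation rounding matching the convention of printed index tables
#' (0.05 rounds to 0.1), unlike base R's round-half-even.
#'
#' @param x numeric.
#' @param digits integer, decimal places.
#' @return rounded numeric.
#' @examples
#' roundHalfUp(c(0.25, 0.35), 1)  # 0.3 0.4
#' @export
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}
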