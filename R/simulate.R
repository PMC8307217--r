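## Synthetic-data generators. The profile generator emulates the replicate
## structure of a GC-MS FAME relative-abundance table: multiplicative
## log-normal noise per fatty acid (so the per-FA coefficient of variation is
## directly controllable, matching SDs roughly proportional to means) followed
## by closure of each replicate to 100%. The plate generator emits raw
## microplate time-series whose 120-min values encode a known linear
## dose-response truth, so ICx recovery can be tested against ground truth.

#' Configuration for simulating replicate fatty acid profiles
#'
#' @param means species-by-FA numeric matrix of mean relative abundances in
#'   % (row names species, column names FA labels). Default: the packaged
#'   seven-species GC-MS means, [table1Means()].
#' @param cv per-FA coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param nReplicates replicates per species (default 5).
#' @param seed integer RNG seed.
#' @return a list of class `ProfileSimConfig`.
#' @export
profileSimConfig <- function(means = table1Means(), cv = 0.05,
                             nReplicates = 5L, seed = 1L) {
    stopifnot(is.matrix(means), !is.null(rownames(means)),
              !is.null(colnames(means)), all(means >= 0),
              nReplicates >= 1L)
    if (cv < 0)
        .alStop("al_sim_error", "cv must be non-negative")
    structure(list(means = means, cv = cv,
                   nReplicates = as.integer(nReplicates),
                   seed = as.integer(seed)),
              class = "ProfileSimConfig")
}

#' Simulate replicate fatty acid profiles around given means
#'
#' Mean rows are first closed to 100%. Each replicate perturbs every
#' abundance by an independent log-normal factor with unit mean and the
#' configured CV, then the replicate vector is re-closed to 100%. Zero means
#' stay exactly zero. Deterministic for a fixed seed.
#'
#' @param config a [profileSimConfig()].
#' @return an [FAProfileSet-class] with
#'   `nrow(means) * nReplicates` samples.
#' @export
simulateProfiles <- function(config) {
    stopifnot(inherits(config, "ProfileSimConfig"))
    set.seed(config$seed)
    m <- config$means
    m <- sweep(m, 1, rowSums(m) / 100, "/")          # close the truth rows
    sigma <- sqrt(log(1 + config$cv^2))
    cols <- list()
    species <- character(); replicate <- character()
    for (s in rownames(m)) {
        for (r in seq_len(config$nReplicates)) {
            f <- exp(stats::rnorm(ncol(m), 0, sigma) - sigma^2 / 2)
            v <- m[s, ] * f
            v <- v / sum(v) * 100
            cols[[length(cols) + 1L]] <- v
            species <- c(species, s)
            replicate <- c(replicate, sprintf("r%d", r))
        }
    }
    ab <- do.call(cbind, cols)
    rownames(ab) <- colnames(m)
    colnames(ab) <- paste(abbreviate(species, 8), replicate, sep = ".")
    FAProfileSet(ab, species = species, replicate = replicate)
}

#' Configuration for simulating plate kinetics
#'
#' Defaults mirror the plate protocol the reduction code expects: extract
#' dilutions 25/125/250/500 ug/mL (Trolox standard 5/12.5/25/37.5 umol/L),
#' triplicate wells, readings every 5 min for 120 min, radical working
#' solution absorbance 0.9 AU.
#'
#' @param assay `"ABTS"` or `"DPPH"`.
#' @param trueIc ground-truth IC at `level`, in ug/mL.
#' @param level inhibition level in % the IC refers to; default 50 for ABTS
#'   and 20 for DPPH.
#' @param slope truth slope in % inhibition per (ug/mL); the truth line is
#'   anchored so inhibition(trueIc) = level. Default `level / trueIc`
#'   (line through the origin).
#' @param radicalAbs0 radical working-solution absorbance (AU).
#' @param noiseSd additive Gaussian absorbance noise per reading (AU).
#' @param concentrations extract concentrations (ug/mL).
#' @param troloxTrueIc ground-truth Trolox IC at `level`, in umol/L
#'   (default 18.75 for ABTS, 10 for DPPH).
#' @param troloxConcentrations Trolox standard concentrations (umol/L).
#' @param timeGrid reading times in minutes.
#' @param nReplicates wells per condition.
#' @param controlOffset constant colour absorbance of the radical-free
#'   sample controls (AU); exercises the colour-correction path.
#' @param decayRate first-order reaction rate (1/min) shaping the kinetic
#'   decay; only the final reading enters the IC estimate.
#' @param analyte analyte id for the extract wells.
#' @param seed integer RNG seed.
#' @return a list of class `AssaySimConfig`.
#' @export
assaySimConfig <- function(assay = c("ABTS", "DPPH"), trueIc = 100,
                           level = NULL, slope = NULL, radicalAbs0 = 0.9,
                           noiseSd = 0,
                           concentrations = c(25, 125, 250, 500),
                           troloxTrueIc = NULL,
                           troloxConcentrations = c(5, 12.5, 25, 37.5),
                           timeGrid = seq(0, 120, by = 5),
                           nReplicates = 3L, controlOffset = 0.01,
                           decayRate = 0.3, analyte = "extract",
                           seed = 1L) {
    assay <- match.arg(assay)
    if (is.null(level)) level <- if (assay == "ABTS") 50 else 20
    if (is.null(slope)) slope <- level / trueIc
    if (is.null(troloxTrueIc))
        troloxTrueIc <- if (assay == "ABTS") 18.75 else 10
    stopifnot(trueIc > 0, level > 0, radicalAbs0 > 0,
              all(concentrations > 0), !anyDuplicated(concentrations),
              all(troloxConcentrations > 0), nReplicates >= 1L)
    if (noiseSd < 0)
        .alStop("al_sim_error", "noiseSd must be non-negative")
    structure(list(assay = assay, trueIc = trueIc, level = level,
                   slope = slope, radicalAbs0 = radicalAbs0,
                   noiseSd = noiseSd, concentrations = concentrations,
                   troloxTrueIc = troloxTrueIc,
                   troloxConcentrations = troloxConcentrations,
                   timeGrid = timeGrid,
                   nReplicates = as.integer(nReplicates),
                   controlOffset = controlOffset, decayRate = decayRate,
                   analyte = analyte, seed = as.integer(seed)),
              class = "AssaySimConfig")
}

## exponential decay from A0 at t=0 toward target; with the default rate the
## residual at 120 min is below double precision, so the final reading equals
## the target for all practical purposes
.kinSeries <- function(target, a0, times, rate) {
    target + (a0 - target) * exp(-rate * times)
}

#' Simulate microplate kinetics with a known dose-response truth
#'
#' Truth inhibition at the final reading is linear in concentration,
#' anchored so that `inhibition(trueIc) = level` (and analogously for the
#' Trolox standard). Sample absorbance decays exponentially from
#' `controlOffset + radicalAbs0` toward the truth value; radical blanks stay
#' at `radicalAbs0`; sample controls carry the constant colour offset.
#' Gaussian noise of `noiseSd` AU is added to every reading. When the truth
#' inhibition exceeds 100% at the highest tested concentration the returned
#' object is flagged (the linear truth is not clipped: clipping would bias
#' the downstream regression the generator exists to validate).
#'
#' @param config an [assaySimConfig()].
#' @return a [PlateKinetics-class] with radical blanks, extract wells with
#'   matched controls, and Trolox standard wells with matched controls.
#' @export
simulatePlate <- function(config) {
    stopifnot(inherits(config, "AssaySimConfig"))
    set.seed(config$seed)
    tg <- config$timeGrid
    flags <- character()

    truth <- function(conc, slope, trueIc)
        config$level + slope * (conc - trueIc)
    rows <- list()
    emit <- function(well, role, analyte, conc, units, series) {
        rows[[length(rows) + 1L]] <<- data.frame(
            well = well, role = role, analyte = analyte,
            concentration = conc, conc_units = units, time_min = tg,
            absorbance = series + stats::rnorm(length(tg), 0, config$noiseSd))
    }

    for (r in seq_len(config$nReplicates))
        emit(sprintf("RB%d", r), "radical_blank", "radical", NA, NA,
             rep(config$radicalAbs0, length(tg)))

    a0 <- config$controlOffset + config$radicalAbs0
    emitAnalyte <- function(analyte, role, concs, units, slope, trueIc) {
        if (max(truth(concs, slope, trueIc)) > 100)
            flags <<- c(flags, sprintf(
                "truth inhibition exceeds 100%% at %g %s for '%s'",
                max(concs), units, analyte))
        for (conc in concs) {
            target <- config$controlOffset +
                config$radicalAbs0 * (1 - truth(conc, slope, trueIc) / 100)
            for (r in seq_len(config$nReplicates)) {
                emit(sprintf("%s_%g_S%d", analyte, conc, r), role, analyte,
                     conc, units,
                     .kinSeries(target, a0, tg, config$decayRate))
                emit(sprintf("%s_%g_C%d", analyte, conc, r),
                     "sample_control", analyte, conc, units,
                     rep(config$controlOffset, length(tg)))
            }
        }
    }
    emitAnalyte(config$analyte, "sample", config$concentrations, "ug/mL",
                config$slope, config$trueIc)
    emitAnalyte("trolox", "standard", config$troloxConcentrations, "umol/L",
                config$level / config$troloxTrueIc, config$troloxTrueIc)

    PlateKinetics(config$assay, do.call(rbind, rows), flags = flags)
}
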