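#' Read a fatty acid table into an FAProfileSet
#'
#' Two CSV dialects (RFC-4180, UTF-8, decimal point) are supported. `long`:
#' columns `species,replicate,fa_label,abundance_pct`, one row per cell;
#' duplicate (species, replicate, fa) triples are an error. `wide`: first
#' column the FA label, one column per species, a single replicate per
#' species; blank cells mean "not detected" and are read as 0.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @param missingCells optional data.frame (`species`, `fa_label`) of cells
#'   known to be unreported; see [FAProfileSet()].
#' @return an [FAProfileSet-class].
#' @export
readFaTable <- function(path, dialect = c("long", "wide"),
                        missingCells = NULL) {
    dialect <- match.arg(dialect)
    d <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
    if (!nrow(d))
        .alStop("al_io_error", "empty fatty acid table: %s", path)
    if (dialect == "long") {
        need <- c("species", "replicate", "fa_label", "abundance_pct")
        if (!all(need %in% colnames(d)))
            .alStop("al_io_error", "long dialect needs columns %s",
                    paste(need, collapse = ", "))
        canon <- vapply(seq_len(nrow(d)), function(i)
            tryCatch(canonicalFaLabel(d$fa_label[i]), al_error = function(e)
                .alStop("al_io_error", "line %d: %s", i + 1L,
                        conditionMessage(e))),
            character(1))
        key <- paste(d$species, d$replicate, canon, sep = "\r")
        if (anyDuplicated(key))
            .alStop("al_io_error", "duplicate (species, replicate, fa): %s",
                    gsub("\r", "/", key[duplicated(key)][1]))
        samp <- unique(d[, c("species", "replicate")])
        fas <- unique(canon)
        ab <- matrix(0, nrow = length(fas), ncol = nrow(samp),
                     dimnames = list(fas, NULL))
        ci <- match(paste(d$species, d$replicate),
                    paste(samp$species, samp$replicate))
        val <- d$abundance_pct
        val[is.na(val)] <- 0          # blank cell = not detected
        ab[cbind(match(canon, fas), ci)] <- val
        FAProfileSet(ab, species = samp$species, replicate = samp$replicate,
                     missingCells = missingCells)
    } else {
        fas <- d[[1]]
        ab <- as.matrix(d[, -1, drop = FALSE])
        if (ncol(ab) < 1L)
            .alStop("al_io_error", "wide dialect needs >= 1 species column")
        ab[is.na(ab)] <- 0
        mode(ab) <- "numeric"
        rownames(ab) <- fas
        FAProfileSet(ab, species = colnames(ab),
                     replicate = rep("mean", ncol(ab)),
                     missingCells = missingCells)
    }
}

#' Write an FAProfileSet as a long-format CSV
#'
#' Writes `species,replicate,fa_label,abundance_pct` with canonical labels;
#' [readFaTable()] on the output restores an identical object.
#'
#' @param x an [FAProfileSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFaTable <- function(x, path) {
    a <- SummarizedExperiment::assay(x, "abundance")
    d <- data.frame(
        species = rep(faSpecies(x), each = nrow(a)),
        replicate = rep(faReplicate(x), each = nrow(a)),
        fa_label = rep(rownames(a), ncol(a)),
        abundance_pct = as.vector(a))
    utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read / write plate kinetics CSV
#'
#' CSV dialect `assay,well,role,analyte,concentration,conc_units,time_min,
#' absorbance`. A file must describe a single assay.
#'
#' @param path CSV file path.
#' @return [PlateKinetics-class] (`readPlateTable`) or `path`
#'   (`writePlateTable`).
#' @export
readPlateTable <- function(path) {
    d <- utils::read.csv(path, fileEncoding = "UTF-8")
    need <- c("assay", "well", "role", "analyte", "concentration",
              "conc_units", "time_min", "absorbance")
    if (!all(need %in% colnames(d)))
        .alStop("al_io_error", "plate CSV needs columns %s",
                paste(need, collapse = ", "))
    assay <- unique(d$assay)
    if (length(assay) != 1L)
        .alStop("al_io_error", "plate CSV must describe one assay, found: %s",
                paste(assay, collapse = ", "))
    PlateKinetics(assay, d[, setdiff(need, "assay")])
}

#' @rdname readPlateTable
#' @param x a [PlateKinetics-class] to write.
#' @export
writePlateTable <- function(x, path) {
    w <- plateWells(x)
    utils::write.csv(cbind(assay = plateAssay(x), w), path,
                     row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Packaged seven-species GC-MS fatty acid means
#'
#' Mean relative abundances (% of total FA, n = 5 analytical replicates) of
#' 32 fatty acids across seven commercial microalgae, as printed in the
#' source GC-MS FAME screening. Blank cells are "not detected" (0). The
#' C16:0 cell of *Chlorella vulgaris* is blank in the printed table although
#' its class sums imply roughly 17% palmitic acid; the cell is carried as 0
#' and the species flagged, never silently patched.
#'
#' @return `table1Means()`: species-by-FA numeric matrix.
#' @export
table1Means <- function() {
    p <- system.file("extdata", "table1_fa_means.csv",
                     package = "algaeLipids", mustWork = TRUE)
    d <- utils::read.csv(p, check.names = FALSE, fileEncoding = "UTF-8")
    m <- t(as.matrix(d[, -1, drop = FALSE]))
    colnames(m) <- d[[1]]
    m[is.na(m)] <- 0
    m
}

#' @rdname table1Means
#' @return `table1Profiles()`: the same data as an [FAProfileSet-class]
#'   (one "mean" sample per species) with the known-unreported C16:0 cell
#'   flagged in `metadata()$missing_cells`.
#' @export
table1Profiles <- function() {
    p <- system.file("extdata", "table1_fa_means.csv",
                     package = "algaeLipids", mustWork = TRUE)
    readFaTable(p, dialect = "wide",
                missingCells = data.frame(
                    species = "Chlorella vulgaris", fa_label = "C16:0"))
}

#' Species metadata for the packaged profiles
#'
#' @return data.frame with `species`, `abbrev` and `phylum` for the seven
#'   packaged microalgae.
#' @export
speciesPhyla <- function() {
    p <- system.file("extdata", "species_phyla.csv",
                     package = "algaeLipids", mustWork = TRUE)
    utils::read.csv(p, fileEncoding = "UTF-8")
}

#' Printed radical-scavenging reference results
#'
#' IC values (ug/mL) and Trolox equivalents (umol/g) reported for the
#' packaged species in the ABTS (IC50) and DPPH (IC20) assays; used for
#' cross-consistency checks of the TE formula.
#'
#' @return data.frame with `assay`, `species`, `inhibition_level`,
#'   `ic_ug_ml`, `te_umol_g`.
#' @export
scavengingReference <- function() {
    p <- system.file("extdata", "scavenging_reference.csv",
                     package = "algaeLipids", mustWork = TRUE)
    utils::read.csv(p, fileEncoding = "UTF-8")
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Orchestrates the stages on a fatty acid table (and optional plate
#' kinetics): class sums and nutritional indices per species, glog + PCA +
#' Ward clustering, Kruskal-Wallis/Dunn letters for the indices when
#' replicates allow it, and ICx/TE reduction of each plate. Writes
#' `class_summary.csv`, `index_table.csv`, `pca_scores.csv`,
#' `pca_loadings.csv`, `cluster_tree.nwk`, `scavenging_results.csv` (when
#' plates are given) and a machine-readable `manifest.json` (seed,
#' parameters, row counts, warnings). Any stage error aborts with a
#' stage-tagged message.
#'
#' @param profiles an [FAProfileSet-class], or a path to a long-format FA
#'   CSV.
#' @param plates optional named list of [PlateKinetics-class] objects or CSV
#'   paths; names are ignored, assays are taken from the objects.
#' @param outdir output directory (created if absent).
#' @param seed integer seed recorded in the manifest and used for any
#'   stochastic option.
#' @param lambda glog parameter (`NULL` = data-driven default).
#' @param linkage clustering linkage method.
#' @param adjust multiplicity adjustment for the letters.
#' @param levels named numeric, inhibition level per assay.
#' @return invisibly, a list with the computed tables and the manifest.
#' @export
runFullAnalysis <- function(profiles, plates = NULL, outdir = "algaeLipids_out",
                            seed = 1L, lambda = NULL, linkage = "ward.D2",
                            adjust = "BH", levels = c(ABTS = 50, DPPH = 20)) {
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
    }
    if (is.character(profiles))
        profiles <- stage("read", readFaTable(profiles, "long"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    warnings <- character()

    cs <- stage("lipid_metrics", classSummary(profiles))
    tab <- stage("lipid_metrics", indexTable(profiles))
    if (any(!tab$complete_profile))
        warnings <- c(warnings, sprintf(
            "incomplete source profile, quantities not reproducible: %s",
            paste(tab$species[!tab$complete_profile], collapse = ", ")))
    utils::write.csv(as.data.frame(cs),
                     file.path(outdir, "class_summary.csv"), row.names = FALSE)

    reps <- table(faSpecies(profiles))
    letters <- NULL
    if (all(reps >= 2)) {
        ni <- nutritionalIndices(profiles)
        letters <- stage("stats", lapply(
            stats::setNames(nm = c("ai", "ti", "h_over_h")),
            function(v) significanceLetters(
                kruskalDunn(ni[[v]], ni$species, method = adjust,
                            variable = v))))
        for (v in names(letters))
            tab[[paste0(v, "_letters")]] <-
                letters[[v]][match(tab$species, names(letters[[v]]))]
    }
    utils::write.csv(as.data.frame(tab),
                     file.path(outdir, "index_table.csv"), row.names = FALSE)

    g <- stage("stats", glogTransform(profiles, lambda = lambda))
    pca <- stage("stats", runPca(g))
    utils::write.csv(data.frame(sample = rownames(pca$scores),
                                pca$scores, check.names = FALSE),
                     file.path(outdir, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(fa = rownames(pca$loadings),
                                pca$loadings, check.names = FALSE),
                     file.path(outdir, "pca_loadings.csv"), row.names = FALSE)
    tree <- stage("stats", hierarchicalClustering(g, linkage = linkage))
    treeToNewick(tree, file.path(outdir, "cluster_tree.nwk"))

    scav <- NULL
    if (!is.null(plates)) {
        scav <- do.call(rbind, lapply(plates, function(p) {
            if (is.character(p)) p <- stage("read", readPlateTable(p))
            lev <- levels[[plateAssay(p)]]
            res <- stage("antioxidant_assay", {
                sample <- estimateICx(buildCurve(p, role = "sample"), lev)
                std <- estimateICx(buildCurve(p, role = "standard"), lev)
                troloxEquivalents(sample, std)
            })
            if (res@extrapolated)
                warnings <<- c(warnings, sprintf(
                    "%s IC%g for '%s' extrapolated beyond tested range",
                    res@assay, res@level, res@analyte))
            data.frame(assay = res@assay, analyte = res@analyte,
                       level = res@level, ic = icValue(res),
                       conc_units = res@concUnits, te = troloxEq(res),
                       slope = res@slope, intercept = res@intercept,
                       r2 = res@r2, extrapolated = res@extrapolated)
        }))
        utils::write.csv(scav, file.path(outdir, "scavenging_results.csv"),
                         row.names = FALSE)
    }

    manifest <- list(
        package = "algaeLipids",
        version = as.character(utils::packageVersion("algaeLipids")),
        seed = seed,
        parameters = list(lambda = attr(g, "lambda"), linkage = linkage,
                          adjust = adjust, levels = as.list(levels)),
        n_species = length(unique(faSpecies(profiles))),
        n_samples = ncol(profiles), n_fatty_acids = nrow(profiles),
        n_plates = length(plates),
        warnings = warnings)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(classSummary = cs, indexTable = tab, pca = pca,
                   tree = tree, scavenging = scav, letters = letters,
                   manifest = manifest))
}
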