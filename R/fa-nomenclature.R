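## Fatty acid shorthand: "C<carbons>:<doubleBonds> [delta list] [(omega tag)]",
## e.g. "C20:5 ∆5,8,11,14,17 (ω-3)". Delta positions are numbered
## from the carboxyl carbon (1-based); the omega class counts from the methyl
## terminus, so omega = carbons - max(delta).

.alStop <- function(class, fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c(class, "al_error")))
}

## strip typographic decoration (superscript carets, asterisks), unify the
## delta and omega glyphs, drop parentheses -- transport noise, not chemistry
.normalizeFaText <- function(x) {
    s <- trimws(x)
    s <- gsub("[\\^*]", "", s)
    s <- gsub("[Δ∆△]", "d", s)
    s <- gsub("ω", "n", s)
    s <- gsub("\\bw-", "n-", s)
    s <- gsub("[()]", " ", s)
    s <- gsub(",\\s+", ",", s)
    gsub("\\s+", " ", trimws(s))
}

.parseOneFa <- function(label) {
    s <- .normalizeFaText(label)
    if (!nzchar(s))
        .alStop("al_parse_error", "empty fatty acid label")
    m <- regexec("^C(\\d+):(\\d+)(?: d(\\d+(?:,\\d+)*))?(?: n-(\\d+))?$", s)
    g <- regmatches(s, m)[[1]]
    if (length(g) == 0L)
        .alStop("al_parse_error", "malformed fatty acid label: '%s'", label)
    carbons <- as.integer(g[2])
    db <- as.integer(g[3])
    delta <- if (nzchar(g[4])) as.integer(strsplit(g[4], ",")[[1]]) else integer()
    omegaTag <- if (nzchar(g[5])) as.integer(g[5]) else NA_integer_

    if (carbons < 4L)
        .alStop("al_parse_error", "'%s': chain must have >= 4 carbons", label)
    if (db >= carbons)
        .alStop("al_parse_error",
                "'%s': %d double bonds impossible on %d carbons",
                label, db, carbons)
    if (length(delta)) {
        if (length(delta) != db)
            .alStop("al_consistency_error",
                    "'%s': %d delta positions for %d double bonds",
                    label, length(delta), db)
        if (any(diff(delta) <= 0))
            .alStop("al_consistency_error",
                    "'%s': delta positions must be strictly increasing", label)
        if (any(delta < 2L | delta > carbons - 1L))
            .alStop("al_consistency_error",
                    "'%s': delta positions must lie in [2, carbons-1]", label)
    }
    omega <- NA_integer_
    if (length(delta)) {
        inferred <- carbons - max(delta)
        if (!is.na(omegaTag) && omegaTag != inferred)
            .alStop("al_consistency_error",
                    "'%s': omega tag n-%d contradicts delta list (implies n-%d)",
                    label, omegaTag, inferred)
        omega <- inferred
    } else if (!is.na(omegaTag)) {
        omega <- omegaTag        # tag without delta list: taken as authoritative
    }
    if (!is.na(omega) && omega < 1L)
        .alStop("al_consistency_error", "'%s': omega class must be >= 1", label)
    list(carbons = carbons, doubleBonds = db, delta = delta, omega = omega)
}

.satClass <- function(db) {
    ifelse(db == 0L, "SFA", ifelse(db == 1L, "MUFA", "PUFA"))
}

.canonicalOne <- function(carbons, db, delta, omega) {
    s <- sprintf("C%d:%d", carbons, db)
    if (length(delta))
        s <- paste0(s, " d", paste(delta, collapse = ","))
    if (!is.na(omega))
        s <- paste0(s, sprintf(" n-%d", omega))
    s
}

#' Parse fatty acid shorthand into a structured catalog
#'
#' Parses labels of the form `"C<carbons>:<doubleBonds> [delta list]
#' [(omega tag)]"`, tolerating typographic decoration (superscript markers,
#' Greek delta/omega glyphs, spacing variants). The omega class is inferred
#' from the delta list when only the latter is given; an omega tag that
#' contradicts the delta list raises a consistency error rather than being
#' silently corrected.
#'
#' @param labels character vector of fatty acid labels.
#' @return A [S4Vectors::DataFrame] with one row per label: `input`, the
#'   canonical `label`, `carbons`, `doubleBonds`, `deltaPositions`
#'   (an [IRanges::IntegerList]; empty when no positions are annotated),
#'   `omegaClass` (`NA` when unknown) and `saturationClass`
#'   (`SFA`/`MUFA`/`PUFA`).
#' @examples
#' parseFaLabel(c("C20:5 ∆5,8,11,14,17 (ω-3)", "C18:0"))
#' @export
parseFaLabel <- function(labels) {
    if (!length(labels) || !is.character(labels))
        .alStop("al_parse_error", "labels must be a non-empty character vector")
    parsed <- lapply(labels, .parseOneFa)
    carbons <- vapply(parsed, `[[`, integer(1), "carbons")
    db <- vapply(parsed, `[[`, integer(1), "doubleBonds")
    omega <- vapply(parsed, `[[`, integer(1), "omega")
    delta <- lapply(parsed, `[[`, "delta")
    canon <- mapply(.canonicalOne, carbons, db, delta, omega)
    S4Vectors::DataFrame(
        input = as.character(labels),
        label = unname(canon),
        carbons = carbons,
        doubleBonds = db,
        deltaPositions = IRanges::IntegerList(delta),
        omegaClass = omega,
        saturationClass = .satClass(db))
}

#' Infer the omega class from annotated delta positions
#'
#' Fills `omegaClass` as `carbons - max(deltaPositions)` for catalog rows
#' whose delta list is present. Rows without a delta list cannot be inferred:
#' if their omega class is also absent a warning is raised and `NA` is kept.
#' The operation is idempotent.
#'
#' @param catalog a catalog as returned by [parseFaLabel()].
#' @return the catalog with `omegaClass` filled where inferable.
#' @export
inferOmega <- function(catalog) {
    stopifnot(is(catalog, "DataFrame"),
              all(c("carbons", "deltaPositions", "omegaClass") %in%
                  colnames(catalog)))
    len <- lengths(catalog$deltaPositions)
    maxd <- vapply(seq_len(nrow(catalog)), function(i)
        if (len[i]) max(catalog$deltaPositions[[i]]) else NA_integer_,
        integer(1))
    inferable <- len > 0L
    catalog$omegaClass[inferable] <-
        catalog$carbons[inferable] - maxd[inferable]
    orphan <- !inferable & is.na(catalog$omegaClass) &
        catalog$doubleBonds > 0L
    if (any(orphan))
        warning(warningCondition(
            sprintf("cannot infer omega class for: %s",
                    paste(catalog$label[orphan], collapse = ", ")),
            class = c("al_cannot_infer", "al_warning")))
    catalog
}

#' Canonical fatty acid label
#'
#' Deterministic canonical spelling `"C<c>:<d>[ d<p1,...>][ n-<omega>]"`.
#' Differently decorated spellings of the same fatty acid map to one
#' canonical string, and parse -> canonicalize -> parse is the identity.
#'
#' @param x character labels (parsed first) or a catalog from
#'   [parseFaLabel()].
#' @return character vector of canonical labels.
#' @examples
#' canonicalFaLabel("C16:1 ∆^9^ (ω-7)")
#' @export
canonicalFaLabel <- function(x) {
    if (is.character(x))
        x <- parseFaLabel(x)
    stopifnot(is(x, "DataFrame"))
    x$label
}
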