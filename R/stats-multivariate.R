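#' Generalized logarithm (glog) transform
#'
#' Cell-wise `log2((x + sqrt(x^2 + lambda^2)) / 2)`, a variance-stabilizing
#' transform defined for zero-containing compositional data. For
#' `x >> lambda` it approaches `log2(x)`; at `x = 0` it equals
#' `log2(lambda/2)`. The default `lambda` is the smallest positive value in
#' the matrix, a common metabolomics convention; the value used is recorded
#' in the `"lambda"` attribute (matrix method) or in `metadata()`.
#'
#' @param x numeric matrix of non-negative values, or an
#'   [FAProfileSet-class] (samples in columns; the transform is applied to
#'   the abundance matrix and returned as a samples-by-FA matrix ready for
#'   multivariate analysis).
#' @param lambda positive transform parameter, or `NULL` for the default.
#' @return transformed matrix with attribute `lambda`.
#' @examples
#' glogTransform(matrix(c(0, 1, 10, 100), 2), lambda = 1)
#' @export
setMethod("glogTransform", "matrix", function(x, lambda = NULL) {
    if (any(x < 0, na.rm = TRUE))
        .alStop("al_stats_error", "glog input must be non-negative")
    if (is.null(lambda)) {
        pos <- x[x > 0]
        if (!length(pos))
            .alStop("al_stats_error",
                    "cannot choose a default lambda from an all-zero matrix")
        lambda <- min(pos)
    }
    if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
        .alStop("al_stats_error", "lambda must be a positive number")
    out <- log2((x + sqrt(x^2 + lambda^2)) / 2)
    attr(out, "lambda") <- lambda
    out
})

#' @rdname glogTransform
#' @export
setMethod("glogTransform", "FAProfileSet", function(x, lambda = NULL) {
    m <- t(SummarizedExperiment::assay(x, "abundance"))
    glogTransform(m, lambda = lambda)
})

#' Principal component analysis with deterministic signs
#'
#' Eigen-decomposition of the covariance of the column-centered matrix
#' (unscaled: glog-transformed inputs are already variance stabilized).
#' Component signs are fixed by making the largest-magnitude entry of each
#' loading vector positive, so results are reproducible across platforms.
#' A degenerate input (a single distinct row) yields zero total variance and
#' is reported as zero informative components rather than failing.
#'
#' @param x numeric matrix, observations in rows.
#' @param center logical, column-center before decomposition (default TRUE).
#' @return a list with `scores` (rows by component), `loadings` (variables
#'   by component), `varianceFraction` (non-increasing, summing to 1 over
#'   all components), and `totalVariance`.
#' @export
runPca <- function(x, center = TRUE) {
    x <- as.matrix(x)
    if (nrow(x) < 2L || ncol(x) < 2L)
        .alStop("al_stats_error", "PCA needs >= 2 rows and >= 2 columns")
    pc <- stats::prcomp(x, center = center, scale. = FALSE)
    ev <- pc$sdev^2
    total <- sum(ev)
    if (total <= 1e-12 * max(1, mean(x^2))) {
        return(list(scores = pc$x[, 0, drop = FALSE],
                    loadings = pc$rotation[, 0, drop = FALSE],
                    varianceFraction = numeric(), totalVariance = 0))
    }
    flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
    flip[flip == 0] <- 1
    list(scores = sweep(pc$x, 2, flip, "*"),
         loadings = sweep(pc$rotation, 2, flip, "*"),
         varianceFraction = ev / total,
         totalVariance = total)
}

#' Hierarchical clustering of profiles
#'
#' Euclidean distance with Ward's minimum-variance linkage (`"ward.D2"`),
#' the defaults of common metabolomics pipelines; both are configurable.
#' Rows are ordered lexicographically by label before the distance
#' computation so ties break deterministically.
#'
#' @param x numeric matrix, one row per leaf (row names become leaf labels).
#' @param distance distance measure passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return an [stats::hclust] tree.
#' @seealso [treeToNewick()] for export.
#' @export
hierarchicalClustering <- function(x, distance = "euclidean",
                                   linkage = "ward.D2") {
    x <- as.matrix(x)
    if (nrow(x) < 2L)
        .alStop("al_stats_error", "clustering needs >= 2 leaves")
    if (is.null(rownames(x)))
        rownames(x) <- sprintf("leaf%03d", seq_len(nrow(x)))
    x <- x[order(rownames(x)), , drop = FALSE]
    stats::hclust(stats::dist(x, method = distance), method = linkage)
}

#' Export a cluster tree in Newick format
#'
#' @param tree an [stats::hclust] object.
#' @param path optional file path; when given the Newick string is written
#'   there and the path returned invisibly.
#' @return the Newick string (invisibly when written to `path`).
#' @export
treeToNewick <- function(tree, path = NULL) {
    phy <- ape::as.phylo(tree)
    txt <- ape::write.tree(phy)
    if (!is.null(path)) {
        writeLines(txt, path)
        return(invisible(path))
    }
    txt
}

## Dunn z statistics on the joint ranking with tie correction:
## z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j)),
## T = sum(t^3 - t) over tied groups.
.dunnZ <- function(values, groups) {
    r <- rank(values)
    N <- length(values)
    ties <- table(values)
    Tcorr <- sum(ties^3 - ties)
    rbar <- tapply(r, groups, mean)
    n <- tapply(r, groups, length)
    g <- names(rbar)
    pairs <- utils::combn(g, 2)
    z <- apply(pairs, 2, function(p) {
        se <- sqrt((N * (N + 1) / 12 - Tcorr / (12 * (N - 1))) *
                   (1 / n[[p[1]]] + 1 / n[[p[2]]]))
        (rbar[[p[1]]] - rbar[[p[2]]]) / se
    })
    data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z)
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Runs the tie-corrected Kruskal-Wallis test over all groups, then Dunn's
#' pairwise z tests on the joint ranking, with Benjamini-Hochberg (default)
#' or Benjamini-Yekutieli adjustment of the pairwise p-values. Groups with
#' fewer than two values are kept in the omnibus statistic but excluded from
#' the post-hoc comparisons with a warning. Letters follow the inverted
#' compact-letter convention in which a letter SHARED by two groups marks a
#' significant pair (q < `alpha`).
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`.
#' @param method multiplicity adjustment: `"BH"` or `"BY"`.
#' @param alpha significance threshold on adjusted q.
#' @param variable name of the compared variable (bookkeeping only).
#' @return a [GroupComparison-class].
#' @export
kruskalDunn <- function(values, groups, method = c("BH", "BY"),
                        alpha = 0.05, variable = "value") {
    method <- match.arg(method)
    stopifnot(length(values) == length(groups))
    groups <- as.character(groups)
    if (length(unique(groups)) < 2L)
        .alStop("al_stats_error", "need >= 2 groups")
    kw <- stats::kruskal.test(values, factor(groups))

    n <- table(groups)
    small <- names(n)[n < 2]
    if (length(small)) {
        warning(warningCondition(
            sprintf("excluded from post-hoc (n < 2): %s",
                    paste(small, collapse = ", ")),
            class = c("al_small_group", "al_warning")))
        keep <- !groups %in% small
        values <- values[keep]; groups <- groups[keep]
    }
    pw <- .dunnZ(values, groups)
    pw$p <- 2 * stats::pnorm(-abs(pw$z))
    pw$q <- stats::p.adjust(pw$p, method = method)

    cmp <- new("GroupComparison", variable = variable,
               omnibus = list(statistic = unname(kw$statistic),
                              df = unname(kw$parameter),
                              p.value = kw$p.value),
               pairwise = pw, letters = character(), alpha = alpha,
               method = method)
    cmp@letters <- significanceLetters(cmp)
    cmp
}

#' Letter encoding of significant pairs
#'
#' Assigns one letter per significant pair (q < `alpha`) to both of its
#' members, so that two groups share a letter exactly when they differ
#' significantly. Groups in no significant pair get an empty string.
#'
#' @param x a [GroupComparison-class].
#' @param alpha threshold; defaults to the one stored in `x`.
#' @return named character vector, one entry per group.
#' @export
setMethod("significanceLetters", "GroupComparison",
function(x, alpha = x@alpha) {
    pw <- x@pairwise
    grp <- sort(unique(c(pw$group1, pw$group2)))
    out <- stats::setNames(rep("", length(grp)), grp)
    sig <- which(pw$q < alpha)
    pool <- c(letters, paste0(rep(letters, each = 26), letters))
    for (i in seq_along(sig)) {
        l <- pool[i]
        for (g in c(pw$group1[sig[i]], pw$group2[sig[i]]))
            out[g] <- if (nzchar(out[g])) paste0(out[g], ",", l) else l
    }
    out
})

setMethod("show", "GroupComparison", function(object) {
    cat(sprintf("GroupComparison '%s': Kruskal-Wallis H = %.4g (df %d, p = %.3g)\n",
                object@variable, object@omnibus$statistic, object@omnibus$df,
                object@omnibus$p.value))
    cat(sprintf("  %d pairs, %d significant at q < %g (%s)\n",
                nrow(object@pairwise), sum(object@pairwise$q < object@alpha),
                object@alpha, object@method))
})

#' Correlation between two per-species quantities
#'
#' Reports both the product-moment (Pearson) and rank (Spearman)
#' coefficients with p-values, since printed correlation methods are often
#' unstated. Zero variance in either vector yields `NA` coefficients.
#'
#' @param x,y paired numeric vectors (>= 3 points).
#' @return data.frame with one row per method: `method`, `estimate`, `p`.
#' @export
correlatePairs <- function(x, y) {
    stopifnot(length(x) == length(y))
    if (length(x) < 3L)
        .alStop("al_stats_error", "need >= 3 paired points")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(data.frame(method = c("pearson", "spearman"),
                          estimate = NA_real_, p = NA_real_))
    pe <- stats::cor.test(x, y, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(method = c("pearson", "spearman"),
               estimate = c(unname(pe$estimate), unname(sp$estimate)),
               p = c(pe$p.value, sp$p.value))
}
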