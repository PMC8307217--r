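test_that("glog transform has the right closed form, limit and monotonicity", {
    expect_equal(glogTransform(matrix(0), lambda = 1)[1, 1], -1)
    # approaches log2 for x >> lambda
    x <- matrix(c(100, 1000, 1e5), 1)
    g <- glogTransform(x, lambda = 1)
    expect_lt(max(abs(g - log2(x)) / log2(x)), 0.001)
    # strictly increasing on any column
    col <- matrix(sort(runif(50, 0, 10)), ncol = 1)
    expect_true(all(diff(glogTransform(col, lambda = 0.5)) > 0))
    expect_error(glogTransform(matrix(1:4, 2), lambda = 0),
                 class = "al_stats_error")
    expect_error(glogTransform(matrix(-1)), class = "al_stats_error")
    # default lambda is the smallest positive entry, and is recorded
    m <- matrix(c(0, 0.3, 2, 5), 2)
    expect_equal(attr(glogTransform(m), "lambda"), 0.3)
})

test_that("PCA matches a covariance-eigenvalue oracle with stable signs", {
    set.seed(5)
    m <- matrix(rnorm(20), 5, 4)
    pca <- runPca(m)
    expect_equal(sum(pca$varianceFraction), 1, tolerance = 1e-12)
    expect_true(all(diff(pca$varianceFraction) <= 1e-12))
    ev <- eigen(cov(scale(m, scale = FALSE)), symmetric = TRUE)$values
    expect_equal(pca$varianceFraction, ev / sum(ev), tolerance = 1e-10)

    # rank-1 data: all variance on PC1
    r1 <- outer(c(1, 2, 3, 5), c(2, -1, 4))
    expect_equal(runPca(r1)$varianceFraction[1], 1, tolerance = 1e-12)

    # variance fractions invariant to row permutation
    perm <- m[c(3, 1, 5, 2, 4), ]
    expect_equal(runPca(perm)$varianceFraction, pca$varianceFraction,
                 tolerance = 1e-12)

    # single distinct row: zero informative components, no failure
    flat <- matrix(1, 4, 3)
    expect_equal(length(runPca(flat)$varianceFraction), 0L)
})

test_that("clustering is deterministic with zero heights for identical leaves", {
    two <- matrix(c(1, 2, 1, 2), 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), NULL))
    hc <- hierarchicalClustering(two)
    expect_equal(hc$height, 0)
    dup <- matrix(1:3, 5, 3, byrow = TRUE,
                  dimnames = list(letters[1:5], NULL))
    expect_equal(hierarchicalClustering(dup)$height, rep(0, 4))
    # deterministic under row shuffling (lexicographic leaf ordering)
    set.seed(9)
    m <- matrix(rnorm(24), 6, 4, dimnames = list(letters[1:6], NULL))
    h1 <- hierarchicalClustering(m)
    h2 <- hierarchicalClustering(m[sample(6), ])
    expect_equal(h1$height, h2$height)
    expect_equal(h1$merge, h2$merge)
    expect_equal(treeToNewick(h1), treeToNewick(h2))
})

test_that("Dunn z equals the brute-force oracle and is antisymmetric", {
    # frozen instance with a tie, expected values from the rank oracle
    vals <- c(1.1, 2.3, 3.1, 4.2, 5.0, 6.1, 2.3, 3.5, 7.7)
    grp <- rep(c("g1", "g2", "g3"), each = 3)
    cmp <- kruskalDunn(vals, grp)
    expect_equal(cmp@pairwise$z,
                 c(-2.020899209126, -1.347266139417, 0.673633069709),
                 tolerance = 1e-10)
    # randomized instances against the oracle
    for (s in 1:5) {
        set.seed(s)
        v <- round(rnorm(12), 1)          # rounding induces occasional ties
        g <- rep(c("a", "b", "c"), 4)
        got <- kruskalDunn(v, g)@pairwise
        expect_equal(got$z, unname(oracleDunnZ(v, g)), tolerance = 1e-10)
    }
    # antisymmetry under swapping a pair's labels
    relab <- c(g1 = "g2", g2 = "g1", g3 = "g3")[grp]
    sw <- kruskalDunn(vals, relab)@pairwise
    expect_equal(sw$z[sw$group1 == "g1" & sw$group2 == "g2"],
                 -cmp@pairwise$z[1], tolerance = 1e-12)
})

test_that("BH adjustment is monotone and controls the null family", {
    set.seed(21)
    v <- rnorm(35); g <- rep(letters[1:7], each = 5)
    pw <- kruskalDunn(v, g)@pairwise
    expect_true(all(pw$q >= pw$p - 1e-15))
    expect_equal(order(pw$q, pw$p), order(pw$p))   # q ordering follows p

    # under the null, BH sharply reduces the chance of any flagged pair
    reps <- 200
    anyRaw <- anyAdj <- logical(reps)
    set.seed(99)
    for (i in seq_len(reps)) {
        pw <- kruskalDunn(rnorm(35), g)@pairwise
        anyRaw[i] <- any(pw$p < 0.05)
        anyAdj[i] <- any(pw$q < 0.05)
    }
    expect_gt(mean(anyRaw), 2 * mean(anyAdj))
})

test_that("letters encode exactly the significant pairs, symmetrically", {
    set.seed(4)
    v <- c(rnorm(5, 0), rnorm(5, 6), rnorm(5, 12), rnorm(5, 0.2))
    g <- rep(c("w", "x", "y", "z"), each = 5)
    cmp <- kruskalDunn(v, g)
    let <- significanceLetters(cmp)
    fromLetters <- character()
    grps <- names(let)
    for (i in seq_along(grps)) for (j in seq_along(grps)) if (i < j) {
        shared <- intersect(strsplit(let[i], ",")[[1]],
                            strsplit(let[j], ",")[[1]])
        if (length(shared))
            fromLetters <- c(fromLetters,
                             paste(sort(c(grps[i], grps[j])), collapse = "|"))
    }
    pw <- cmp@pairwise
    sig <- pw[pw$q < cmp@alpha, c("group1", "group2")]
    fromQ <- vapply(seq_len(nrow(sig)), function(k)
        paste(sort(c(sig$group1[k], sig$group2[k])), collapse = "|"),
        character(1))
    expect_true(length(fromQ) >= 1)
    expect_setequal(fromLetters, fromQ)

    # identical groups: nothing significant, no letters anywhere
    same <- kruskalDunn(rep(c(3, 1, 4, 1, 5), 3), rep(c("a", "b", "c"), 5))
    expect_true(all(!nzchar(significanceLetters(same))))

    # a singleton group is excluded from the post-hoc with a warning
    expect_warning(
        small <- kruskalDunn(c(rnorm(5), rnorm(5), 1),
                             c(rep("a", 5), rep("b", 5), "c")),
        class = "al_small_group")
    expect_false("c" %in% c(small@pairwise$group1, small@pairwise$group2))
})

test_that("correlation reports both coefficients with a sound rank p-value", {
    x <- c(1, 2, 3, 4, 5, 6, 7)
    out <- correlatePairs(x, 2 * x + 1)
    expect_equal(out$estimate[out$method == "pearson"], 1)
    anti <- correlatePairs(x, rev(x)^3)
    expect_equal(anti$estimate[anti$method == "spearman"], -1)
    # zero variance: absent coefficients
    expect_true(all(is.na(correlatePairs(x, rep(2, 7))$estimate)))

    set.seed(31)
    y <- x + rnorm(7, 0, 3)
    got <- correlatePairs(x, y)
    pPerm <- oracleSpearmanPermP(x, y)
    expect_equal(got$p[got$method == "spearman"], pPerm, tolerance = 0.05)
})
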