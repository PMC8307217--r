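test_that("class sums match a brute-force oracle on the packaged table", {
    fp <- table1Profiles()
    cs <- classSummary(fp)
    oracle <- oracleClassSums()
    for (s in rownames(oracle)) {
        got <- as.data.frame(cs[cs$species == s, ])
        expect_equal(unname(unlist(
            got[, c("sfa", "mufa", "pufa", "pufa_n6", "pufa_n3")])),
            unname(oracle[s, ]), tolerance = 1e-12)
    }
    # printed reference points, at the table's 1-decimal precision
    expect_equal(cs$mufa[cs$species == "Spirulina sp."], 10.9)
    expect_equal(cs$pufa_n3[cs$species == "Scenedesmus obliquus"], 55.9)
    cv <- cs[cs$species == "Chlorella vulgaris", ]
    expect_equal(roundHalfUp(cv$n6_over_n3, 1), 0.6)
    # no omega-3 detected: ratio must be absent, not 0 or Inf
    expect_true(is.na(cs$n6_over_n3[cs$species == "Spirulina sp."]))
})

test_that("omega sums and other-class PUFA partition total PUFA", {
    fp <- table1Profiles()
    cs <- classSummary(fp)
    a <- SummarizedExperiment::assay(fp, "abundance")
    cat <- faCatalog(fp)
    other <- cat$saturationClass == "PUFA" &
        (is.na(cat$omegaClass) | !cat$omegaClass %in% c(3L, 6L))
    expect_equal(cs$pufa_n3 + cs$pufa_n6 +
                     unname(colSums(a[other, , drop = FALSE])),
                 cs$pufa, tolerance = 1e-12)
})

test_that("profiles close to exactly 100 and out-of-tolerance sums reject", {
    sim <- simulateProfiles(profileSimConfig(cv = 0.03, nReplicates = 2,
                                             seed = 11))
    norm <- normalizeProfiles(sim)
    expect_equal(unname(colSums(SummarizedExperiment::assay(norm))),
                 rep(100, ncol(norm)), tolerance = 1e-9)
    # already normalized: idempotent
    norm2 <- normalizeProfiles(norm)
    expect_equal(SummarizedExperiment::assay(norm2),
                 SummarizedExperiment::assay(norm))
    # the C. vulgaris column sums to 82.8 (blank C16:0): must be rejected
    expect_error(normalizeProfiles(table1Profiles()),
                 class = "al_normalize_error")
    expect_error(normalizeProfiles(table1Profiles()), "Chlorella")
})

test_that("nutritional indices reproduce the printed per-species values", {
    fp <- table1Profiles()
    ni <- as.data.frame(nutritionalIndices(fp))
    rownames(ni) <- ni$species
    # intermediate arithmetic frozen from the printed mean columns
    expect_equal(ni["Spirulina sp.", "ai"], 39.0 / 55.6, tolerance = 1e-12)
    expect_equal(ni["Spirulina sp.", "ti"], 44.1 / 27.8, tolerance = 1e-12)
    expect_equal(ni["Spirulina sp.", "h_over_h"], 24.0 / 38.7,
                 tolerance = 1e-12)
    expect_equal(roundHalfUp(ni["Scenedesmus obliquus", "ai"], 1), 0.2)
    expect_equal(roundHalfUp(ni["Scenedesmus obliquus", "ti"], 1), 0.1)
    expect_equal(roundHalfUp(ni["Phaeodactylum tricornutum", "h_over_h"], 1),
                 1.8)
})

test_that("indices are invariant under uniform rescaling", {
    fp <- demoProfile()
    base <- as.data.frame(nutritionalIndices(fp))
    for (c0 in c(0.2, 1, 7.5)) {
        m <- SummarizedExperiment::assay(fp) * c0
        scaled <- FAProfileSet(m, species = "demo")
        got <- as.data.frame(nutritionalIndices(scaled))
        expect_equal(got$ai, base$ai, tolerance = 1e-12)
        expect_equal(got$ti, base$ti, tolerance = 1e-12)
        expect_equal(got$h_over_h, base$h_over_h, tolerance = 1e-12)
        cs <- as.data.frame(classSummary(scaled))
        expect_equal(cs$n6_over_n3,
                     as.data.frame(classSummary(fp))$n6_over_n3,
                     tolerance = 1e-12)
    }
})

test_that("AI and TI respond monotonically to marker fatty acids", {
    vals <- c(`C14:0` = 3, `C16:0` = 25, `C18:1 (ω-9)` = 30,
              `C18:2 ∆9,12 (ω-6)` = 22, `C20:5 ∆5,8,11,14,17 (ω-3)` = 20)
    idx <- function(v) as.data.frame(nutritionalIndices(demoProfile(v)))
    base <- idx(vals)
    up14 <- vals; up14["C14:0"] <- up14["C14:0"] + 2
    expect_gt(idx(up14)$ai, base$ai)
    expect_gt(idx(up14)$ti, base$ti)
    upEpa <- vals; upEpa["C20:5 ∆5,8,11,14,17 (ω-3)"] <- 25
    expect_lt(idx(upEpa)$ti, base$ti)
})

test_that("degenerate denominators yield absent values, not numbers", {
    mufaOnly <- demoProfile(c(`C16:1 ∆9 (ω-7)` = 60, `C18:1 (ω-9)` = 40))
    ni <- as.data.frame(nutritionalIndices(mufaOnly))
    expect_equal(ni$ai, 0)                  # zero numerator, valid denominator
    expect_true(is.na(ni$h_over_h))         # no C14:0/C16:0
    # omega-3 present but no omega-6: TI ratio term undefined
    n3only <- demoProfile(c(`C14:0` = 10, `C16:0` = 40,
                            `C18:3 ∆9,12,15 (ω-3)` = 50))
    expect_true(is.na(as.data.frame(nutritionalIndices(n3only))$ti))
    # nothing detected at all
    zero <- demoProfile(c(`C16:0` = 0, `C18:0` = 0))
    niz <- as.data.frame(nutritionalIndices(zero))
    expect_true(is.na(niz$ai) && is.na(niz$ti) && is.na(niz$h_over_h))
})

test_that("indexTable aggregates replicates and flags incomplete species", {
    # five identical replicates: SD exactly zero everywhere
    m <- SummarizedExperiment::assay(demoProfile())[, rep(1, 5)]
    colnames(m) <- paste0("r", 1:5)
    fp <- FAProfileSet(m, species = rep("demo", 5),
                       replicate = paste0("r", 1:5))
    tab <- as.data.frame(indexTable(fp))
    sds <- unlist(tab[grepl("_sd$", colnames(tab))])
    expect_equal(unname(sds), rep(0, length(sds)))
    expect_true(tab$complete_profile)

    # the packaged table flags only the species with the unreported cell
    t1 <- as.data.frame(indexTable(table1Profiles()))
    expect_equal(t1$species[!t1$complete_profile], "Chlorella vulgaris")
    expect_equal(nrow(t1), 7L)
})

test_that("simulated replicate means converge to the generating-mean indices", {
    means <- table1Means()[c("Spirulina sp.", "Scenedesmus obliquus"), ]
    truth <- as.data.frame(nutritionalIndices(
        FAProfileSet(t(means), species = rownames(means))))
    sim <- simulateProfiles(profileSimConfig(means, cv = 0.05,
                                             nReplicates = 400, seed = 3))
    got <- as.data.frame(nutritionalIndices(sim))
    for (s in rownames(means)) {
        g <- got[got$species == s, ]
        tr <- truth[truth$species == s, ]
        expect_equal(mean(g$ai), tr$ai, tolerance = 0.01)
        if (!is.na(tr$ti))
            expect_equal(mean(g$ti), tr$ti, tolerance = 0.01)
        expect_equal(mean(g$h_over_h), tr$h_over_h, tolerance = 0.01)
    }
})
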