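## Independent oracles: deliberately naive re-derivations that do not share
## code with the package implementation.

fixturePath <- function(name)
    system.file("extdata", name, package = "algaeLipids", mustWork = TRUE)

## raw fixture table as printed: species columns, blank = 0
rawFixture <- function() {
    d <- read.csv(fixturePath("table1_fa_means.csv"), check.names = FALSE,
                  fileEncoding = "UTF-8")
    d[is.na(d)] <- 0
    d
}

## classify one printed label by regex only: double bonds from ":<d>",
## omega from the printed "(ω-n)" tag
oracleClassSums <- function() {
    d <- rawFixture()
    db <- as.integer(sub("^C\\d+:(\\d+).*$", "\\1", d$fa_label))
    omega <- suppressWarnings(as.integer(
        ifelse(grepl("ω-\\d+", d$fa_label),
               sub(".*ω-(\\d+).*", "\\1", d$fa_label), NA)))
    sat <- ifelse(db == 0, "SFA", ifelse(db == 1, "MUFA", "PUFA"))
    species <- colnames(d)[-1]
    out <- lapply(species, function(s) {
        v <- d[[s]]
        c(sfa = sum(v[sat == "SFA"]),
          mufa = sum(v[sat == "MUFA"]),
          pufa = sum(v[sat == "PUFA"]),
          pufa_n6 = sum(v[sat == "PUFA" & !is.na(omega) & omega == 6]),
          pufa_n3 = sum(v[sat == "PUFA" & !is.na(omega) & omega == 3]))
    })
    structure(do.call(rbind, out), dimnames = list(species, NULL))
}

## step-by-step Dunn z on a small instance: joint ranks, tie correction,
## pairwise z, in the plainest possible style
oracleDunnZ <- function(values, groups) {
    r <- rank(values)
    N <- length(values)
    tie <- table(values)
    Tcorr <- sum(tie^3 - tie)
    gs <- sort(unique(groups))
    z <- c()
    labs <- c()
    for (i in seq_along(gs)) for (j in seq_along(gs)) if (i < j) {
        ri <- mean(r[groups == gs[i]]); rj <- mean(r[groups == gs[j]])
        ni <- sum(groups == gs[i]); nj <- sum(groups == gs[j])
        se <- sqrt((N * (N + 1) / 12 - Tcorr / (12 * (N - 1))) *
                   (1 / ni + 1 / nj))
        z <- c(z, (ri - rj) / se)
        labs <- c(labs, paste(gs[i], gs[j]))
    }
    setNames(z, labs)
}

## Monte-Carlo permutation p-value for the Spearman rank correlation
oracleSpearmanPermP <- function(x, y, B = 4000, seed = 7) {
    set.seed(seed)
    obs <- abs(cor(rank(x), rank(y)))
    perm <- replicate(B, abs(cor(rank(x), rank(sample(y)))))
    mean(perm >= obs - 1e-12)
}

## small synthetic profile matrix for unit tests
demoProfile <- function(vals = c(`C12:0` = 2, `C14:0` = 3, `C16:0` = 25,
                                 `C18:0` = 5, `C18:1 (ω-9)` = 15,
                                 `C18:2 ∆9,12 (ω-6)` = 20,
                                 `C18:3 ∆9,12,15 (ω-3)` = 20,
                                 `C20:5 ∆5,8,11,14,17 (ω-3)` = 10),
                        species = "demo", replicate = "r1") {
    m <- matrix(vals, ncol = 1, dimnames = list(names(vals), NULL))
    FAProfileSet(m, species = species, replicate = replicate)
}
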