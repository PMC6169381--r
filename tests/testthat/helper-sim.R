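# Shared builders for a small NAM test population:
# 10 families (4 EL, 3 BX, 3 PI) x 50 RILs on 2 chromosomes of 100 cM.

tinyMap <- function(nChr = 2, len = 100, m = 20, seed = 101)
    simulateMap(nChr, len, m, spacing = "uniform", seed = seed)

tinyPanel <- function(gm, counts = c(EL = 4L, BX = 3L, PI = 3L),
                      seed = 102, forceSeg = integer(0)) {
    fp <- simulateFounders(gm, counts, seed = seed)
    if (length(forceSeg)) {
        h <- haplotypes(fp)
        h[forceSeg, colnames(h) != commonParent(fp)] <- 1L
        h[forceSeg, commonParent(fp)] <- 0L
        fp <- FounderPanel(h, founderGroups(fp))
    }
    fp
}

tinyPop <- function(seed = 103, nPerFamily = 50, gm = tinyMap(),
                    panel = tinyPanel(gm), finalGeneration = 5L,
                    missingRate = 0) {
    deriveRILs(panel, setdiff(founderIds(panel), commonParent(panel)),
               nPerFamily, finalGeneration, gm,
               missingRate = missingRate, seed = seed)
}

# single-QTL architecture with hand-set founder effects
qtlArch <- function(panel, qtlMarkers, effects, polyVar = 0,
                    trait = "yield") {
    fd <- founderIds(panel)
    eff <- matrix(0, length(fd), length(qtlMarkers),
                  dimnames = list(fd, qtlMarkers))
    if (is.matrix(effects)) eff[rownames(effects), ] <- effects
    else eff[setdiff(fd, commonParent(panel)), ] <- effects
    tr <- list(list(qtl = qtlMarkers, effects = eff, polyVar = polyVar))
    names(tr) <- trait
    new("TraitArchitecture", traits = tr, founders = fd,
        common = commonParent(panel))
}

# marker-free structured null phenotype: family effects + iid noise
nullPhenotype <- function(pop, sdFam = 120, sdNoise = 100, seed = 1) {
    set.seed(seed)
    fam <- families(pop)
    fe <- stats::setNames(stats::rnorm(length(unique(fam)), 0, sdFam),
                          unique(fam))
    y <- fe[fam] + stats::rnorm(ncol(pop), 0, sdNoise)
    stats::setNames(as.numeric(y), colnames(pop))
}

# one dataset of the single-QTL power scenario: a 150-unit QTL
# segregating in every family, family-structured background
powerScenario <- function(seed, qtlIdx = 10, effect = 150,
                          nPerFamily = 50) {
    sds <- NAMtools:::deriveSeeds(seed, 4)
    gm <- tinyMap(seed = sds[1])
    fp <- tinyPanel(gm, seed = sds[1], forceSeg = qtlIdx)
    pop <- deriveRILs(fp, setdiff(founderIds(fp), commonParent(fp)),
                      nPerFamily, 5L, gm, seed = sds[2])
    arch <- qtlArch(fp, markerIds(gm)[qtlIdx], effect)
    g <- geneticValues(pop, arch, seed = sds[3])
    y <- g[, "yield"] + nullPhenotype(pop, seed = sds[4])
    list(gm = gm, pop = pop, y = y, qtlIdx = qtlIdx)
}

# brute-force single-linkage chaining by transitive closure, the
# independent oracle for binRegions
bruteChain <- function(cM, gap = 5) {
    n <- length(cM)
    adj <- abs(outer(cM, cM, "-")) <= gap
    grp <- seq_len(n)
    repeat {
        changed <- FALSE
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (adj[i, j] && grp[j] != grp[i]) {
                grp[grp == grp[j]] <- grp[i]
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    match(grp, unique(grp[order(cM)]))
}
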