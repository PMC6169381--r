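test_that("stage-1 block BLUPs match the closed-form balanced shrinkage", {
    df <- balancedCheckData()
    be <- fitCheckBlockModel(df, "y")
    vc <- varComp(be)
    lam <- vc["varBlk"] / (vc["varBlk"] + vc["varRes"] / 6)
    dev <- tapply(df$y, df$block, mean) - mean(df$y)
    expect_equal(unname(blockEffects(be)[names(dev)]),
                 as.vector(lam * dev), tolerance = 1e-6)
    # random-effect BLUPs centre on zero, and shrinkage dominates
    expect_lt(abs(mean(blockEffects(be))), 1e-6)
    expect_true(all(abs(blockEffects(be)[names(dev)]) <= abs(dev) + 1e-10))
    expect_lt(stats::var(blockEffects(be)), stats::var(dev))
})

test_that("stage-1 handles null block variance and zero-information blocks", {
    df <- balancedCheckData(varBlk = 0, seed = 2)
    be <- fitCheckBlockModel(df, "y",
                             allBlocks = c(unique(df$block), "b_empty"))
    expect_lt(varComp(be)["varBlk"], 0.05)
    expect_lt(max(abs(blockEffects(be))), 0.2)
    expect_equal(unname(blockEffects(be)["b_empty"]), 0)
    expect_error(fitCheckBlockModel(df[df$block == "b01", ], "y"),
                 "2 blocks")
})

test_that("stage-1 detects the confounded single-block-per-check design", {
    df <- balancedCheckData(nChk = 2, nBlk = 2)
    df <- df[(df$entry == "chk1") == (df$block == "b01"), ]
    expect_error(fitCheckBlockModel(df, "y"), "unidentifiable")
})

test_that("planting-date slope is recovered with nominal coverage", {
    hits <- 0
    for (rep in 1:60) {
        df <- balancedCheckData(nBlk = 15, seed = rep + 200)
        dates <- stats::setNames(sample(130:155, 15, TRUE),
                                 unique(df$block))
        df$plantingDate <- dates[df$block]
        df$y <- df$y + 2.0 * (df$plantingDate - 140)
        be <- fitCheckBlockModel(df, "y")
        ci <- be@beta["pldate"] + c(-1.96, 1.96) * be@slopeSE
        if (ci[1] <= 2.0 && 2.0 <= ci[2]) hits <- hits + 1
    }
    expect_gte(hits / 60, 0.9)
})

test_that("stage-2 entry BLUPs match the closed-form balanced shrinkage", {
    bd <- balancedEntryData()
    eb <- fitEntryModel(asPlotTable(bd$df),
                        zeroBlockEffects(unique(bd$df$block)))
    vc <- varComp(eb)
    lam <- vc$varG / (vc$varG + vc$varRes / 4)
    dev <- tapply(bd$df$y, bd$df$entry, mean) - mean(bd$df$y)
    v <- blupVector(eb, "y")
    expect_equal(unname(v[names(dev)]), as.vector(lam * dev),
                 tolerance = 1e-6)
})

test_that("noiseless data reproduce true genotypic values exactly", {
    bd <- balancedEntryData(n = 100, varRes = 0)
    eb <- fitEntryModel(asPlotTable(bd$df),
                        zeroBlockEffects(unique(bd$df$block)))
    v <- blupVector(eb, "y")
    expect_gt(stats::cor(v[names(bd$g)], bd$g), 0.9999)
})

test_that("stage-2 REML recovers the generating variance components", {
    bd <- balancedEntryData(n = 1000, r = 4, varG = 3, varRes = 1,
                            seed = 4)
    eb <- fitEntryModel(asPlotTable(bd$df),
                        zeroBlockEffects(unique(bd$df$block)))
    vc <- varComp(eb)
    expect_lt(abs(vc$varG - 3) / 3, 0.15)
    expect_lt(abs(vc$varRes - 1), 0.15)
    expect_error(fitEntryModel(asPlotTable(transform(bd$df, y = NA)),
                               zeroBlockEffects(unique(bd$df$block))),
                 "no non-missing")
})

test_that("stage-2 estimates the slopes of both fixed covariates", {
    bd <- balancedEntryData(n = 300, r = 4, seed = 5)
    df <- bd$df
    blocks <- unique(df$block)
    be <- zeroBlockEffects(blocks)
    be@blockBlups[] <- c(-2, -1, 1, 2)
    df$plantingDate <- 140 + as.integer(factor(df$environment)) * 3
    df$y <- df$y + 1.5 * (df$plantingDate - mean(df$plantingDate)) +
        0.8 * be@blockBlups[df$block]
    eb <- fitEntryModel(asPlotTable(df), be)
    vc <- varComp(eb)
    expect_lt(abs(vc$betaPldate - 1.5), 0.5)
    expect_lt(abs(vc$betaBlk - 0.8), 0.5)
})

test_that("heritability follows the harmonic-mean formulas", {
    h <- heritability(1, 1, envCounts = rep(1, 50))
    expect_equal(h@H, 0.5)
    h2 <- heritability(4, 2, envCounts = rep(4, 50))
    expect_equal(h2@H, 4 / 4.5)
    expect_equal(heritability(1, 1, c(2, 4, 4))@eBar, 3)
    expect_error(heritability(1, 1, numeric(0)), "empty")
    # family-mean basis
    hf <- heritability(0, 2, envCounts = rep(4, 50),
                       basis = "family_mean", varAmong = 10,
                       varWithin = 5, familySizes = rep(20, 10))
    expect_equal(hf@H, 10 / (10 + 5 / 20 + 2 / 80))
    # H rises with eBar at fixed components
    expect_gt(heritability(4, 2, rep(8, 50))@H,
              heritability(4, 2, rep(2, 50))@H)
})

test_that("heritability CIs bracket H and tighten with replication", {
    h1 <- heritability(4, 2, envCounts = rep(4, 50))
    expect_true(h1@ci[1] <= h1@H && h1@H <= h1@ci[2])
    h2 <- heritability(4, 2, envCounts = rep(4, 1000))
    expect_lt(diff(h2@ci), diff(h1@ci))
    h3 <- heritability(4, 2, envCounts = rep(8, 1000))
    expect_lt(diff(h3@ci), diff(h2@ci))
})

test_that("among-family variance decomposition behaves at its extremes", {
    set.seed(6)
    fam <- rep(sprintf("f%02d", 1:20), each = 30)
    # equal family means
    v1 <- stats::rnorm(length(fam))
    r1 <- varianceAmongFamilies(v1, fam)
    expect_lt(r1$proportion, 0.05)
    # no within-family variance
    means <- stats::setNames(stats::rnorm(20, 0, 5), unique(fam))
    r2 <- varianceAmongFamilies(means[fam] +
                                stats::rnorm(length(fam), 0, 1e-4), fam)
    expect_gt(r2$proportion, 0.99)
    expect_error(varianceAmongFamilies(v1, rep("f1", length(fam))),
                 "2 families")
})

test_that("genotypic correlations use the shared-entry BLUP matrix", {
    set.seed(7)
    n <- 1000
    ent <- sprintf("e%04d", 1:n)
    a <- stats::rnorm(n); b <- stats::rnorm(n)
    mk <- function(tr, v) data.frame(entry = ent, trait = tr, blup = v)
    eb <- new("EntryBlups",
              blups = rbind(mk("t1", a), mk("t2", b),
                            mk("t3", a + stats::rnorm(n, 0, 0.2))),
              varcomp = data.frame(),
              envCounts = data.frame(),
              entryInfo = data.frame(entry = ent, family = "f",
                                     type = "ril"))
    cc <- geneticCorrelations(eb)
    expect_equal(diag(cc), c(t1 = 1, t2 = 1, t3 = 1))
    expect_equal(cc, t(cc))
    expect_lt(abs(cc["t1", "t2"]), 0.1)       # independent traits
    expect_gt(cc["t1", "t3"], 0.9)            # shared architecture
    expect_error(geneticCorrelations(eb, "t1"), "2 traits")
})
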