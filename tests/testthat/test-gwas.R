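test_that("kinship matches a hand-computed VanRaden matrix", {
    # 4 entries x 3 markers, computed independently entry by entry
    X <- rbind(a = c(0L, 2L, 1L), b = c(2L, 0L, 1L),
               c = c(0L, 0L, 2L), d = c(2L, 2L, 0L))
    colnames(X) <- c("m1", "m2", "m3")
    p <- c(1, 1, 1) / 2
    cc <- sum(2 * p * (1 - p))
    Zc <- X - matrix(2 * p, 4, 3, byrow = TRUE)
    Kh <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4)
        Kh[i, j] <- sum(Zc[i, ] * Zc[j, ]) / cc
    dimnames(Kh) <- list(rownames(X), rownames(X))
    K <- computeKinship(X)
    expect_equal(kinship(K), Kh, tolerance = 1e-10)
    expect_true(validObject(K))
})

test_that("duplicate inbred entries share diagonal and off-diagonal values", {
    set.seed(41)
    X <- matrix(2L * stats::rbinom(60, 1, 0.4), nrow = 6)
    X[2, ] <- X[1, ]
    rownames(X) <- letters[1:6]
    colnames(X) <- sprintf("m%02d", 1:10)
    K <- kinship(computeKinship(X))
    expect_equal(K[1, 2], K[1, 1], tolerance = 1e-10)
})

test_that("window exclusion equals recomputation from scratch", {
    set.seed(42)
    X <- matrix(sample(c(0L, 2L), 200, TRUE), nrow = 10)
    rownames(X) <- letters[1:10]
    colnames(X) <- sprintf("m%02d", 1:20)
    drop <- c("m03", "m04", "m05")
    K1 <- kinship(computeKinship(X, exclude = drop))
    K2 <- kinship(computeKinship(X[, setdiff(colnames(X), drop)]))
    expect_equal(K1, K2, tolerance = 1e-12)
    expect_error(computeKinship(X, exclude = colnames(X)),
                 "all markers excluded")
})

test_that("constant phenotypes and monomorphic markers yield null records", {
    gm <- tinyMap()
    fp <- tinyPanel(gm)
    pop <- tinyPop(seed = 43, nPerFamily = 20, gm = gm, panel = fp)
    y <- stats::setNames(rep(1.0, ncol(pop)), colnames(pop))
    res <- scanMarker(markerIds(gm)[5], y, pop)
    expect_equal(res$rec$negLog10P, 0)
    expect_true(all(res$alpha[!is.na(res$alpha)] == 0))
    # all founders identical to the common parent: nothing segregates
    fp0 <- simulateFounders(gm, c(EL = 2, BX = 2, PI = 2),
                            alleleFreq = 0, seed = 44)
    pop0 <- deriveRILs(fp0, setdiff(founderIds(fp0), commonParent(fp0)),
                       20, 5, gm, seed = 45)
    y0 <- nullPhenotype(pop0, sdFam = 0, seed = 46)
    res0 <- scanMarker(markerIds(gm)[5], y0, pop0)
    expect_equal(res0$rec$status, "monomorphic")
    expect_equal(res0$rec$negLog10P, 0)
    expect_true(all(is.na(res0$alpha)))
})

test_that("family effects are not estimable where the marker cannot segregate", {
    gm <- tinyMap()
    fp <- tinyPanel(gm, seed = 47)
    pop <- tinyPop(seed = 48, nPerFamily = 30, gm = gm, panel = fp)
    y <- nullPhenotype(pop, seed = 49)
    haps <- haplotypes(fp)
    mk <- markerIds(gm)[3]
    same <- haps[mk, ] == haps[mk, commonParent(fp)]
    res <- scanMarker(mk, y, pop)
    for (f in names(res$alpha)) {
        fd <- sub("^fam_", "", f)
        if (same[fd]) expect_true(is.na(res$alpha[[f]]))
    }
})

test_that("single-family scan without polygenic term tracks marker regression", {
    sc <- powerScenario(50)
    keep <- families(sc$pop) == families(sc$pop)[1]
    pop1 <- sc$pop[, keep]
    y1 <- sc$y[colnames(pop1)]
    mk <- markerIds(sc$gm)[sc$qtlIdx]
    res <- scanMarker(mk, y1, pop1,
                      scanConfig(window = 0, polygenic = FALSE))
    w <- doseMatrix(pop1)[mk, ] / 2
    ols <- summary(stats::lm(y1 ~ w))
    pOls <- ols$coefficients["w", "Pr(>|t|)"]
    expect_lt(abs(res$rec$negLog10P - (-log10(pOls))),
              max(1, 0.5 * -log10(pOls)))
    # BLUP alpha shrinks toward (never past) the OLS slope
    b <- ols$coefficients["w", "Estimate"]
    expect_equal(sign(res$alpha[[1]]), sign(b))
    expect_lte(abs(res$alpha[[1]]), abs(b) * 1.05)
})

test_that("the scan is scale-equivariant", {
    sc <- powerScenario(51)
    mk <- markerIds(sc$gm)[sc$qtlIdx]
    r1 <- scanMarker(mk, sc$y, sc$pop)
    r2 <- scanMarker(mk, sc$y * 10, sc$pop)
    expect_equal(r2$rec$negLog10P, r1$rec$negLog10P, tolerance = 1e-3)
    est <- !is.na(r1$alpha)
    expect_equal(unname(r2$alpha[est]), unname(10 * r1$alpha[est]),
                 tolerance = 1e-3)
})

test_that("a planted QTL is found and permutation destroys it", {
    sc <- powerScenario(52)
    res <- genomeScan(sc$y, sc$pop, scanConfig(), trait = "yield")
    st <- scanTable(res)
    pk <- which.max(st$negLog10P)
    expect_gte(st$negLog10P[pk], 3)
    expect_lte(abs(pk - sc$qtlIdx), 2)
    set.seed(53)
    yp <- stats::setNames(sample(sc$y), names(sc$y))
    stp <- scanTable(genomeScan(yp, sc$pop, scanConfig(),
                                trait = "yield"))
    expect_lt(max(stp$negLog10P, na.rm = TRUE),
              max(st$negLog10P, na.rm = TRUE) - 3)
})

test_that("window exclusion preserves power at the tested locus", {
    peaks <- vapply(54:56, function(s) {
        sc <- powerScenario(s)
        mk <- markerIds(sc$gm)[sc$qtlIdx]
        p5 <- scanMarker(mk, sc$y, sc$pop,
                         scanConfig(window = 5))$rec$negLog10P
        p0 <- scanMarker(mk, sc$y, sc$pop,
                         scanConfig(window = 0))$rec$negLog10P
        p5 - p0
    }, 0)
    expect_gte(mean(peaks), 0)
})

test_that("effect tables carry group annotation and sign conventions", {
    sc <- powerScenario(57)
    res <- genomeScan(sc$y, sc$pop, scanConfig(), trait = "yield")
    eff <- estimateFamilyEffects(res, sc$pop, onlySignificant = TRUE)
    expect_true(all(c("family", "founder", "group", "effect", "pev")
                    %in% names(eff)))
    expect_true(all(eff$group[!is.na(eff$group)] %in%
                    c("EL", "BX", "PI")))
    # the +150 QTL should show positive estimable effects at the peak
    st <- scanTable(res)
    pkm <- st$marker[which.max(st$negLog10P)]
    pe <- eff$effect[eff$marker == pkm]
    expect_gt(mean(pe[!is.na(pe)] > 0), 0.9)
})
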