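# hand-built single-family population for exact MAF arithmetic
handPop <- function(doses, origins = NULL, nFam = 1L) {
    M <- nrow(doses)
    gm <- GeneticMap(rep("1", M), rownames(doses),
                     bp = seq_len(M) * 1e5, cM = seq_len(M) - 1)
    n <- ncol(doses)
    haps <- cbind(common = rep(0L, M), fd1 = rep(1L, M))
    rownames(haps) <- rownames(doses)
    fp <- FounderPanel(haps, c("COMMON", "EL"))
    if (is.null(origins)) {
        origins <- matrix("common", M, n, dimnames = dimnames(doses))
        origins[which(doses == 2L)] <- "founder"
        origins[which(doses == 1L)] <- "heterozygous"
        origins[which(is.na(doses))] <- NA_character_
    }
    RILPopulation(doses, origins, gm, family = rep("famA", n),
                  founder = rep("fd1", n), panel = fp)
}

test_that("per-family MAF classification follows the strict 10% rule", {
    # marker m1: monomorphic; m2: 18 minor / 182 alleles = 0.0989 (low);
    # m3: 20 / 200 = 0.10 exactly (kept); m4: clearly segregating
    n <- 100
    d <- rbind(m1 = rep(0L, n),
               m2 = c(rep(2L, 9), rep(0L, 82), rep(NA, 9)),
               m3 = c(rep(2L, 10), rep(0L, 90)),
               m4 = c(rep(2L, 50), rep(0L, 50)))
    colnames(d) <- sprintf("r%03d", 1:n)
    pop <- handPop(d)
    flt <- filterMarkers(pop, 0.10)
    st <- stats::setNames(flt$report$status, flt$report$marker)
    expect_equal(unname(st[c("m1", "m2", "m3", "m4")]),
                 c("monomorphic", "low_MAF", "segregating", "segregating"))
    expect_equal(flt$report$maf[flt$report$marker == "m2"], 18 / 182)
    expect_equal(sort(flt$eliminated), c("m1", "m2"))
    expect_equal(flt$keep$famA, c("m3", "m4"))
})

test_that("filtering is idempotent", {
    pop <- tinyPop(seed = 30, nPerFamily = 30)
    flt <- filterMarkers(pop)
    keep <- Reduce(union, flt$keep)
    flt2 <- filterMarkers(pop[keep, ])
    expect_identical(
        sort(unique(flt2$report$marker[flt2$report$status ==
                                       "segregating"])),
        sort(keep))
})

test_that("family with no genotyped RILs is reported as undefined", {
    d <- rbind(m1 = rep(NA_integer_, 10), m2 = rep(c(0L, 2L), 5))
    colnames(d) <- sprintf("r%02d", 1:10)
    pop <- handPop(d)
    flt <- filterMarkers(pop)
    expect_equal(flt$report$status[flt$report$marker == "m1"],
                 "undefined")
    expect_false("m1" %in% flt$eliminated)
})

test_that("RIL QC flags self-pollinations and non-parental alleles", {
    # parents: common = 0,0,0,0 and founder = 1,1,1,0 — both carry
    # allele 0 at m4, so dose 2 there is a non-parental allele
    haps <- cbind(common = c(0L, 0L, 0L, 0L), fd1 = c(1L, 1L, 1L, 0L))
    rownames(haps) <- paste0("m", 1:4)
    fp <- FounderPanel(haps, c("COMMON", "EL"))
    d <- cbind(clean = c(2L, 0L, 2L, 0L),
               selfC = c(0L, 0L, 0L, 0L),       # identical to common
               selfF = c(2L, 2L, 2L, 0L),       # identical to founder
               alien = c(2L, 0L, 2L, 2L))       # m4 allele from neither
    rownames(d) <- paste0("m", 1:4)
    gm <- GeneticMap(rep("1", 4), paste0("m", 1:4),
                     bp = 1:4 * 1e5, cM = 0:3)
    orig <- matrix("common", 4, 4, dimnames = dimnames(d))
    pop <- RILPopulation(d, orig, gm, family = rep("famA", 4),
                         founder = rep("fd1", 4), panel = fp)
    qc <- qcRILs(pop)
    fl <- stats::setNames(qc$flags$flag, qc$flags$ril)
    expect_equal(unname(fl[c("clean", "selfC", "selfF", "alien")]),
                 c("pass", "identical_to_parent", "identical_to_parent",
                   "non_parental_allele"))
})

test_that("families with majority non-parental RILs are reported for removal", {
    haps <- cbind(common = rep(0L, 3), fd1 = rep(0L, 3))
    rownames(haps) <- paste0("m", 1:3)
    fp <- FounderPanel(haps, c("COMMON", "EL"))
    # both parents all-0: any nonzero dose is non-parental
    d <- cbind(a = c(2L, 0L, 0L), b = c(0L, 2L, 0L), c = c(0L, 0L, 0L))
    rownames(d) <- paste0("m", 1:3)
    gm <- GeneticMap(rep("1", 3), paste0("m", 1:3), bp = 1:3 * 1e5,
                     cM = 0:2)
    orig <- matrix("common", 3, 3, dimnames = dimnames(d))
    pop <- RILPopulation(d, orig, gm, family = rep("famA", 3),
                         founder = rep("fd1", 3), panel = fp)
    qc <- qcRILs(pop)
    expect_equal(qc$familiesToDrop, "famA")   # 2 of 3 non-parental
})

test_that("cM interpolation is exact at knots, linear between, clamped outside", {
    expect_equal(interpolateCM(150, c(100, 200), c(1, 2)), 1.5)
    expect_equal(interpolateCM(100, c(100, 200), c(1, 2)), 1.0)
    expect_equal(interpolateCM(c(50, 250), c(100, 200), c(1, 2)),
                 c(1, 2))                      # terminal clamping
    expect_error(interpolateCM(1, numeric(0), numeric(0)), "empty")
    # brute-force segment-search oracle on random frames
    set.seed(31)
    for (rep in 1:5) {
        fb <- sort(sample(1e6, 5))
        fc <- cumsum(stats::runif(5, 0, 10))
        q <- sample(1e6, 100)
        got <- interpolateCM(q, fb, fc)
        want <- vapply(q, function(x) {
            if (x <= fb[1]) return(fc[1])
            if (x >= fb[5]) return(fc[5])
            i <- max(which(fb <= x))
            fc[i] + (fc[i + 1] - fc[i]) * (x - fb[i]) / (fb[i + 1] - fb[i])
        }, 0)
        expect_equal(got, want, tolerance = 1e-12)
        # monotonicity
        o <- order(q)
        expect_true(!is.unsorted(got[o]))
    }
})

test_that("dense-marker projection is origin-faithful and conservative", {
    # joint simulation at the union map; framework = every 3rd marker
    gm <- simulateMap(2, 100, 60, spacing = "random", seed = 32)
    fp <- tinyPanel(gm, c(EL = 2, BX = 2, PI = 2), seed = 33)
    pop <- deriveRILs(fp, setdiff(founderIds(fp), commonParent(fp)),
                      40, 5, gm, seed = 34)
    fwIdx <- seq(1, nMarkers(gm), by = 3)
    dnIdx <- setdiff(seq_len(nMarkers(gm)), fwIdx)
    fwPop <- pop[fwIdx, ]
    dnMap <- GeneticMap(gm@chromosome[dnIdx], gm@marker[dnIdx],
                        gm@bp[dnIdx], gm@cM[dnIdx])
    dnPanel <- FounderPanel(haplotypes(fp)[dnIdx, , drop = FALSE],
                            founderGroups(fp))
    proj <- projectDenseMarkers(fwPop, dnPanel, dnMap)
    truth <- doseMatrix(pop)[dnIdx, ]
    ok <- !is.na(proj)
    expect_gt(mean(ok), 0.5)                  # most intervals projectable
    expect_gte(mean(proj[ok] == truth[ok]), 0.95)
    # conservation: projected dose is always a parental homozygote
    haps <- haplotypes(dnPanel)
    cd <- SummarizedExperiment::colData(fwPop)
    for (j in seq_len(ncol(fwPop))) {
        pj <- proj[, j]
        allowed <- cbind(2L * haps[, commonParent(fp)],
                         2L * haps[, cd$founder[j]])
        bad <- !is.na(pj) & pj != allowed[, 1] & pj != allowed[, 2]
        expect_false(any(bad))
    }
})

test_that("recombinant or heterozygous intervals project as missing", {
    gm <- GeneticMap(rep("1", 3), c("f1", "d1", "f2"),
                     bp = c(1e5, 2e5, 3e5), cM = c(0, 1, 2))
    haps <- cbind(common = c(0L, 0L, 0L), fd1 = c(1L, 1L, 1L))
    rownames(haps) <- c("f1", "d1", "f2")
    fp <- FounderPanel(haps, c("COMMON", "EL"))
    fwMap <- GeneticMap(rep("1", 2), c("f1", "f2"), bp = c(1e5, 3e5),
                        cM = c(0, 2))
    d <- cbind(conc = c(2L, 2L), recomb = c(0L, 2L), het = c(1L, 2L))
    rownames(d) <- c("f1", "f2")
    orig <- cbind(conc = c("founder", "founder"),
                  recomb = c("common", "founder"),
                  het = c("heterozygous", "founder"))
    rownames(orig) <- c("f1", "f2")
    fwPop <- RILPopulation(d, orig, fwMap, family = rep("famA", 3),
                           founder = rep("fd1", 3), panel = fp)
    dnMap <- GeneticMap("1", "d1", 2e5, 1)
    dnPanel <- FounderPanel(haps["d1", , drop = FALSE],
                            c("COMMON", "EL"))
    proj <- projectDenseMarkers(fwPop, dnPanel, dnMap)
    expect_equal(proj["d1", "conc"], 2L)      # concordant founder interval
    expect_true(is.na(proj["d1", "recomb"]))
    expect_true(is.na(proj["d1", "het"]))
})
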