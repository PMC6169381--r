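mkHits <- function(cM, chr = "1", p = NULL) {
    n <- length(cM)
    data.frame(marker = sprintf("%s_m%03d", rep(chr, n), seq_len(n)),
               chromosome = rep(chr, n), cM = cM,
               negLog10P = if (is.null(p)) rep(4, n) else p,
               stringsAsFactors = FALSE)
}

test_that("region chaining follows the strict 5 cM gap rule", {
    r1 <- binRegions(mkHits(c(1, 3, 4)))
    expect_equal(nrow(r1), 1L)
    r2 <- binRegions(mkHits(c(1, 7)))
    expect_equal(nrow(r2), 2L)                # gap 6 > 5 splits
    r3 <- binRegions(mkHits(c(1, 6)))
    expect_equal(nrow(r3), 1L)                # gap exactly 5 stays
    expect_equal(nrow(binRegions(mkHits(numeric(0)))), 0L)
})

test_that("region peaks use max -log10(p) with the documented tie rule", {
    h <- mkHits(c(1, 2, 3), p = c(4, 9, 7))
    expect_equal(binRegions(h)$peakMarker, "1_m002")
    ht <- mkHits(c(5, 2, 3), p = c(8, 8, 8))
    expect_equal(binRegions(ht)$peakMarker, "1_m002")  # lowest cM wins
})

test_that("chaining equals the brute-force transitive-closure oracle", {
    set.seed(60)
    for (rep in 1:200) {
        n <- sample(2:25, 1)
        cm <- sort(round(stats::runif(n, 0, 60), 2))
        h <- mkHits(cm, p = stats::runif(n, 3, 10))
        got <- binRegions(h)
        oracle <- bruteChain(cm)
        expect_equal(nrow(got), length(unique(oracle)))
        # same partition: markers grouped identically
        memb <- rep(seq_len(nrow(got)),
                    vapply(strsplit(got$markers, ","), length, 0L))
        ord <- order(h$cM, h$marker)
        expect_equal(unname(memb), unname(oracle[ord]))
        # partition property: every marker in exactly one region
        expect_equal(sort(unlist(strsplit(got$markers, ","))),
                     sort(h$marker))
    }
})

test_that("chaining is stable under input permutation", {
    set.seed(61)
    h <- mkHits(sort(stats::runif(15, 0, 40)), p = stats::runif(15, 3, 8))
    a <- binRegions(h)
    b <- binRegions(h[sample(nrow(h)), ])
    expect_equal(a, b)
})

test_that("cross-trait bins group peaks within 5 cM", {
    r <- rbind(binRegions(mkHits(10), trait = "yield"),
               binRegions(mkHits(12), trait = "maturity"))
    b <- crossTraitBins(r)
    expect_equal(nrow(b), 1L)
    expect_true(b$multiTrait)
    r2 <- rbind(binRegions(mkHits(10), trait = "yield"),
                binRegions(mkHits(16), trait = "maturity"))
    b2 <- crossTraitBins(r2)
    expect_equal(nrow(b2), 2L)
    expect_false(any(b2$multiTrait))
    # every region lands in exactly one bin
    expect_equal(sum(vapply(strsplit(b2$members, ","), length, 0L)),
                 nrow(r2))
})

test_that("cross-trait binning equals the brute-force oracle", {
    set.seed(62)
    for (rep in 1:50) {
        n <- sample(2:15, 1)
        regions <- data.frame(
            trait = sample(c("yd", "mt", "ht"), n, TRUE),
            chromosome = "1",
            peakCM = sort(round(stats::runif(n, 0, 50), 1)),
            peakMarker = sprintf("m%02d", seq_len(n)),
            stringsAsFactors = FALSE)
        b <- crossTraitBins(regions)
        expect_equal(nrow(b), length(unique(bruteChain(regions$peakCM))))
    }
})

test_that("allele-effect patterns are classified with zero exclusion", {
    expect_equal(classifyAllelePattern(c(-1, -2, -3))$label,
                 "all_negative")
    expect_equal(classifyAllelePattern(c(2, 1, 0.5))$label,
                 "all_positive")
    expect_equal(classifyAllelePattern(c(5, rep(-1, 30)))$label,
                 "all_but_1_negative")
    expect_equal(classifyAllelePattern(c(rep(2, 14), rep(-3, 2)))$label,
                 "all_but_2_positive")
    expect_equal(classifyAllelePattern(c(rep(1, 15), rep(-1, 15)))$label,
                 "mixed")
    expect_equal(classifyAllelePattern(c(0, 0, -1))$label,
                 "all_negative")               # zeros count as neither
    expect_equal(classifyAllelePattern(c(NA, NA))$label, "undefined")
    # sign-symmetry property
    set.seed(63)
    for (rep in 1:50) {
        e <- stats::rnorm(sample(3:20, 1))
        a <- classifyAllelePattern(e)$label
        b <- classifyAllelePattern(-e)$label
        flip <- function(x) {
            y <- gsub("negative", "TMP", x)
            y <- gsub("positive", "negative", y)
            gsub("TMP", "positive", y)
        }
        expect_equal(b, flip(a))
    }
})

test_that("group effect summaries average estimable pairs equally", {
    et <- data.frame(
        marker = "m1",
        family = sprintf("f%d", 1:5),
        group = c("EL", "EL", "BX", "PI", "PI"),
        effect = c(2, 4, -3, -8, -2), stringsAsFactors = FALSE)
    gs <- groupEffectSummary(et)
    gm <- stats::setNames(gs$groupMeans$meanEffect, gs$groupMeans$group)
    expect_equal(gm[c("EL", "BX", "PI")],
                 c(EL = 3, BX = -3, PI = -5))
    expect_equal(gs$overallMean, mean(et$effect))
    # a BX-positive allele at a marker with no EL positive is flagged
    et2 <- rbind(et, data.frame(marker = "m2", family = "f3",
                                group = "BX", effect = 7))
    ex <- groupEffectSummary(et2)$exoticPositives
    expect_equal(ex$marker, "m2")
    expect_equal(ex$group, "BX")
})
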