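#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination
#' fraction assuming no crossover interference:
#' r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d genetic distance(s) in cM.
#' @return recombination fraction(s) in [0, 0.5).
#' @examples
#' haldane(c(1, 10, 50))
#' @export
haldane <- function(d) {
    stopifnot(all(d >= 0))
    (1 - exp(-2 * d / 100)) / 2
}

#' Simulate a genetic map
#'
#' Generates marker positions on one or more chromosomes, in both cM
#' and bp. Terminal markers sit at 0 and at the chromosome length;
#' interior markers are either uniformly spaced or drawn uniformly at
#' random. Physical positions follow either a constant bp-per-cM rate
#' or a piecewise-linear warp (random segment rates), so that bp is
#' strictly increasing and monotone with cM.
#'
#' @param nChromosomes number of chromosomes.
#' @param cMLength chromosome length(s) in cM (recycled).
#' @param nMarkers markers per chromosome (recycled), at least 2.
#' @param spacing "uniform" (equal cM spacing) or "random".
#' @param bpModel "linear" (constant \code{bpPerCM}) or "piecewise"
#'   (random per-segment rates around \code{bpPerCM}).
#' @param bpPerCM physical distance per cM; default 1 Mb/cM.
#' @param nWarpSegments segments for the piecewise model.
#' @param seed optional RNG seed.
#' @return A [GeneticMap-class].
#' @examples
#' simulateMap(1, 100, 11)  # markers at 0, 10, ..., 100 cM
#' @export
simulateMap <- function(nChromosomes, cMLength, nMarkers,
                        spacing = c("uniform", "random"),
                        bpModel = c("linear", "piecewise"),
                        bpPerCM = 1e6, nWarpSegments = 4L, seed = NULL) {
    spacing <- match.arg(spacing)
    bpModel <- match.arg(bpModel)
    if (nChromosomes < 1L) stop("nChromosomes must be positive")
    cMLength <- rep_len(cMLength, nChromosomes)
    nMarkers <- rep_len(as.integer(nMarkers), nChromosomes)
    if (any(cMLength <= 0)) stop("chromosome lengths must be positive")
    if (any(nMarkers < 2L)) stop("at least 2 markers per chromosome")
    if (bpPerCM <= 0) stop("bpPerCM must be positive")
    if (!is.null(seed)) set.seed(seed)

    chrom <- marker <- character(0)
    bp <- integer(0)
    cm <- numeric(0)
    for (c in seq_len(nChromosomes)) {
        L <- cMLength[c]
        m <- nMarkers[c]
        pos <- if (spacing == "uniform" || m == 2L) {
            seq(0, L, length.out = m)
        } else {
            c(0, sort(stats::runif(m - 2L, 0, L)), L)
        }
        bpc <- switch(bpModel,
            linear = pos * bpPerCM,
            piecewise = {
                brk <- seq(0, L, length.out = nWarpSegments + 1L)
                rate <- bpPerCM * exp(stats::rnorm(nWarpSegments, 0, 0.5))
                cumbp <- c(0, cumsum(rate * diff(brk)))
                seg <- pmin(findInterval(pos, brk, rightmost.closed = TRUE),
                            nWarpSegments)
                cumbp[seg] + rate[seg] * (pos - brk[seg])
            })
        bpc <- round(bpc) + 1
        # rounding can collapse very close markers; restore strictness
        for (i in seq_along(bpc)[-1])
            if (bpc[i] <= bpc[i - 1]) bpc[i] <- bpc[i - 1] + 1
        chrom <- c(chrom, rep(as.character(c), m))
        marker <- c(marker, sprintf("c%d_m%03d", c, seq_len(m)))
        bp <- c(bp, as.integer(bpc))
        cm <- c(cm, pos)
    }
    GeneticMap(chrom, marker, bp, cm)
}

#' Simulate a homozygous founder panel
#'
#' Creates the common (hub) parent plus the requested numbers of EL, BX
#' and PI founders, all fully homozygous. The common parent carries
#' allele 0 at every marker; each founder draws allele 1 independently
#' per marker with the configured frequency, so the founder-vs-common
#' allele-sharing fraction is (1 - frequency) in expectation.
#'
#' @param map a [GeneticMap-class].
#' @param groupCounts named counts for EL, BX and PI founders; the
#'   defaults are the 17/15/8 of the 40-family soybean NAM panel.
#' @param alleleFreq frequency of the non-common allele in founders:
#'   a scalar, or a named vector with entries EL, BX, PI.
#' @param commonId id for the common parent.
#' @param seed optional RNG seed.
#' @return A [FounderPanel-class] with 1 + sum(groupCounts) lines.
#' @examples
#' gm <- simulateMap(1, 100, 20)
#' simulateFounders(gm, seed = 1)  # 41 lines: 1 common + 40 founders
#' @export
simulateFounders <- function(map, groupCounts = c(EL = 17L, BX = 15L, PI = 8L),
                             alleleFreq = 0.5, commonId = "IA3023",
                             seed = NULL) {
    if (!all(c("EL", "BX", "PI") %in% names(groupCounts)))
        stop("groupCounts must name EL, BX and PI")
    if (any(groupCounts <= 0)) stop("group counts must be positive")
    if (!is.null(seed)) set.seed(seed)
    M <- nMarkers(map)
    freqFor <- function(g) {
        f <- if (length(alleleFreq) == 1L) alleleFreq else alleleFreq[[g]]
        if (is.null(f) || is.na(f) || f < 0 || f > 1)
            stop("alleleFreq must supply a frequency in [0, 1] for ", g)
        f
    }
    ids <- commonId
    grp <- "COMMON"
    haps <- matrix(0L, nrow = M, ncol = 1L)
    for (g in c("EL", "BX", "PI")) {
        k <- as.integer(groupCounts[[g]])
        h <- matrix(stats::rbinom(M * k, 1L, freqFor(g)), nrow = M)
        haps <- cbind(haps, h)
        ids <- c(ids, sprintf("%s%02d", g, seq_len(k)))
        grp <- c(grp, rep(g, k))
    }
    dimnames(haps) <- list(markerIds(map), ids)
    FounderPanel(haps, grp)
}
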