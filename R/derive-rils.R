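#' @include simulate-map.R
NULL

# Per-marker switch probabilities for one meiosis: Haldane recombination
# fractions between adjacent markers, 0.5 at each chromosome start so
# chromosomes assort independently.
.switchProbs <- function(map) {
    rv <- numeric(nMarkers(map))
    idx <- split(seq_len(nMarkers(map)), factor(map@chromosome,
                 levels = chromosomes(map)))
    for (i in idx) {
        rv[i[1]] <- 0.5
        if (length(i) > 1L) rv[i[-1]] <- haldane(diff(map@cM[i]))
    }
    rv
}

# One gamete per column: H1, H2 are M x n logical origin haplotypes of
# the parents' two chromosomes; returns an M x n logical mosaic.
.gametes <- function(H1, H2, rv) {
    M <- nrow(H1); n <- ncol(H1)
    sw <- matrix(stats::runif(M * n) < rv, nrow = M)
    sel <- if (M == 1L) sw else apply(sw, 2, cumsum) %% 2 == 1
    ifelse(sel, H2, H1)
}

#' Derive recombinant inbred lines by single-seed descent
#'
#' Simulates each mating of the common parent to a founder: the F1 is
#' selfed to produce a single F2 individual per line, which is advanced
#' by single-seed descent (one offspring per generation) to the final
#' generation. Meiosis uses the Haldane map function on the map's cM
#' distances (no interference). Residual heterozygosity at generation g
#' is (1/2)^(g-1) per locus in expectation.
#'
#' @param panel a [FounderPanel-class].
#' @param matings founder ids mated to the common parent (distinct).
#' @param nPerFamily RILs per mating; the soybean NAM design used 140.
#' @param finalGeneration inbreeding generation g >= 2 (default 5,
#'   i.e. F2 to F5 single-seed descent).
#' @param map a [GeneticMap-class] matching the panel's markers.
#' @param missingRate fraction of (marker, RIL) genotype calls set to
#'   missing, completely at random.
#' @param seed optional RNG seed.
#' @return A [RILPopulation-class] with one family per mating
#'   (family id \code{fam_<founder>}).
#' @examples
#' gm <- simulateMap(2, 100, 20, seed = 1)
#' fp <- simulateFounders(gm, c(EL = 2, BX = 1, PI = 1), seed = 2)
#' pop <- deriveRILs(fp, founderIds(fp)[-1], 10, map = gm, seed = 3)
#' @export
deriveRILs <- function(panel, matings, nPerFamily, finalGeneration = 5L,
                       map, missingRate = 0, seed = NULL) {
    stopifnot(is(panel, "FounderPanel"), is(map, "GeneticMap"))
    if (!identical(rownames(haplotypes(panel)), markerIds(map)))
        stop("panel markers do not match map")
    if (finalGeneration < 2L) stop("finalGeneration must be >= 2")
    if (nPerFamily < 1L) stop("nPerFamily must be positive")
    if (missingRate < 0 || missingRate >= 1)
        stop("missingRate must lie in [0, 1)")
    common <- commonParent(panel)
    matings <- as.character(matings)
    if (anyDuplicated(matings)) stop("matings must list distinct founders")
    if (common %in% matings) stop("a founder cannot be the common parent")
    absent <- setdiff(matings, founderIds(panel))
    if (length(absent))
        stop("founder(s) not in panel: ", paste(absent, collapse = ", "))
    if (!is.null(seed)) set.seed(seed)

    rv <- .switchProbs(map)
    M <- nMarkers(map)
    haps <- haplotypes(panel)
    commonHap <- haps[, common]

    doseL <- originL <- vector("list", length(matings))
    fam <- rilIds <- character(0)
    for (k in seq_along(matings)) {
        fd <- matings[k]
        famId <- paste0("fam_", fd)
        # F1 origin haplotypes: one chromosome set from each parent
        H1 <- matrix(FALSE, M, nPerFamily)
        H2 <- matrix(TRUE, M, nPerFamily)
        for (g in seq_len(finalGeneration - 1L)) {
            G1 <- .gametes(H1, H2, rv)
            G2 <- .gametes(H1, H2, rv)
            H1 <- G1; H2 <- G2
        }
        fdHap <- haps[, fd]
        A1 <- ifelse(H1, fdHap, commonHap)
        A2 <- ifelse(H2, fdHap, commonHap)
        dose <- A1 + A2
        orig <- matrix("heterozygous", M, nPerFamily)
        orig[H1 & H2] <- "founder"
        orig[!H1 & !H2] <- "common"
        if (missingRate > 0) {
            na <- stats::runif(M * nPerFamily) < missingRate
            dose[na] <- NA_integer_
            orig[na] <- NA_character_
        }
        doseL[[k]] <- dose
        originL[[k]] <- orig
        fam <- c(fam, rep(famId, nPerFamily))
        rilIds <- c(rilIds, sprintf("%s_%03d", famId, seq_len(nPerFamily)))
    }
    dose <- do.call(cbind, doseL)
    origin <- do.call(cbind, originL)
    mode(dose) <- "integer"
    dimnames(dose) <- dimnames(origin) <- list(markerIds(map), rilIds)
    RILPopulation(dose, origin, map, family = fam,
                  founder = rep(matings, each = nPerFamily), panel = panel)
}
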