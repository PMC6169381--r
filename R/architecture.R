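#' Assign trait architectures with founder-group-structured QTL effects
#'
#' Samples QTL positions from the map and draws, for every non-common
#' founder and every QTL, an allele-substitution effect from a normal
#' distribution whose mean and sd depend on the founder's group (EL, BX
#' or PI). Effects are expressed on the homozygous-substitution scale:
#' the trait difference between a line homozygous for the founder
#' allele and one homozygous for the common allele. The common parent's
#' effects are zero by construction. Traits can share QTL via a
#' pleiotropy specification with a configured effect correlation.
#'
#' @param map a [GeneticMap-class].
#' @param panel a [FounderPanel-class].
#' @param nQtl named integer vector: QTL count per trait.
#' @param effectDist named list (one element per trait); each element a
#'   list with components EL, BX, PI, each c(mean, sd) in trait units.
#' @param polyVar named numeric: polygenic variance per trait
#'   (default 0).
#' @param pleiotropy optional list of specs, each a list with elements
#'   \code{traits} (>= 2 trait ids), \code{nShared} (count of shared
#'   QTL) and \code{effectCor} (correlation of shared effects; 1 means
#'   identical effects).
#' @param seed optional RNG seed.
#' @return A [TraitArchitecture-class].
#' @export
assignTraitArchitecture <- function(map, panel, nQtl, effectDist,
                                    polyVar = NULL, pleiotropy = NULL,
                                    seed = NULL) {
    stopifnot(is(map, "GeneticMap"), is(panel, "FounderPanel"))
    traits <- names(nQtl)
    if (is.null(traits) || any(!nzchar(traits)))
        stop("nQtl must be a named vector of QTL counts per trait")
    if (length(effectDist) == 0L) stop("effectDist must not be empty")
    if (!all(traits %in% names(effectDist)))
        stop("effectDist must cover every trait in nQtl")
    if (any(nQtl > nMarkers(map)))
        stop("more QTL requested than markers on the map")
    if (is.null(polyVar)) polyVar <- stats::setNames(rep(0, length(traits)),
                                                    traits)
    if (!is.null(seed)) set.seed(seed)

    fd <- founderIds(panel)
    grp <- founderGroups(panel)
    common <- commonParent(panel)

    drawEffects <- function(trait, qtl) {
        eff <- matrix(0, nrow = length(fd), ncol = length(qtl),
                      dimnames = list(fd, qtl))
        for (g in c("EL", "BX", "PI")) {
            pars <- unlist(effectDist[[trait]][[g]])
            if (is.null(pars) || length(pars) < 2L)
                stop("effectDist for trait ", trait,
                     " lacks (mean, sd) for group ", g)
            rows <- fd[grp == g]
            eff[rows, ] <- stats::rnorm(length(rows) * length(qtl),
                                        pars[1], pars[2])
        }
        eff
    }

    archs <- list()
    for (tr in traits) {
        qtl <- sample(markerIds(map), nQtl[[tr]])
        archs[[tr]] <- list(qtl = qtl, effects = drawEffects(tr, qtl),
                            polyVar = as.numeric(polyVar[[tr]] %||% 0))
    }

    for (sp in pleiotropy %||% list()) {
        if (length(sp$traits) < 2L)
            stop("a pleiotropy spec needs at least two traits")
        rho <- sp$effectCor %||% 1
        shared <- sample(markerIds(map), sp$nShared)
        lead <- sp$traits[1]
        leadEff <- drawEffects(lead, shared)
        for (tr in sp$traits) {
            fresh <- drawEffects(tr, shared)
            eff <- if (tr == lead) leadEff else
                rho * leadEff + sqrt(1 - rho^2) * fresh
            keep <- !(archs[[tr]]$qtl %in% shared)
            archs[[tr]]$qtl <- c(archs[[tr]]$qtl[keep], shared)
            archs[[tr]]$effects <-
                cbind(archs[[tr]]$effects[, keep, drop = FALSE], eff)
        }
    }
    new("TraitArchitecture", traits = archs, founders = fd, common = common)
}

#' True genotypic values of a RIL population
#'
#' For each RIL and trait: the sum over QTL of the founder-specific
#' substitution effect times half the RIL's dose of the founder allele
#' (so a line homozygous for the founder allele receives the full
#' effect), plus a genomically structured polygenic value built from
#' small normal effects at every non-QTL marker, scaled so the
#' polygenic variance matches the architecture's \code{polyVar}.
#'
#' @param pop a [RILPopulation-class].
#' @param arch a [TraitArchitecture-class].
#' @param seed optional RNG seed (polygenic draws).
#' @return RILs x traits numeric matrix. Attribute \code{"components"}
#'   holds, per trait, the QTL part, the polygenic part and the drawn
#'   per-marker polygenic effects (for independent re-computation).
#' @export
geneticValues <- function(pop, arch, seed = NULL) {
    stopifnot(is(pop, "RILPopulation"), is(arch, "TraitArchitecture"))
    if (!is.null(seed)) set.seed(seed)
    dose <- doseMatrix(pop)
    fam <- families(pop)
    founder <- colData(pop)$founder
    panel <- metadata(pop)$founderPanel
    if (is.null(panel)) stop("population carries no founder panel")
    haps <- haplotypes(panel)
    common <- commonParent(panel)
    traits <- traitNames(arch)

    out <- matrix(0, ncol(pop), length(traits),
                  dimnames = list(colnames(pop), traits))
    comps <- list()
    for (tr in traits) {
        a <- traitQtl(arch, tr)
        bad <- setdiff(a$qtl, rownames(dose))
        if (length(bad))
            stop("architecture markers absent from population: ",
                 paste(bad, collapse = ", "))
        qtlVal <- numeric(ncol(pop))
        for (q in a$qtl) {
            fdAllele <- haps[q, founder]           # per-RIL founder allele
            cmAllele <- haps[q, common]
            d <- dose[q, ]                          # dose of allele "1"
            fdDose <- ifelse(fdAllele == 1L, d, 2L - d)
            fdDose[fdAllele == cmAllele] <- 0L      # marker not segregating
            eff <- a$effects[cbind(founder, q)]
            qtlVal <- qtlVal + ifelse(is.na(fdDose), 0, fdDose / 2) * eff
        }
        polyVal <- numeric(ncol(pop))
        u <- NULL
        if (a$polyVar > 0) {
            bg <- setdiff(rownames(dose), a$qtl)
            X <- t(dose[bg, , drop = FALSE])
            X[is.na(X)] <- 0
            p <- colMeans(X) / 2
            cc <- sum(2 * p * (1 - p))
            if (cc <= 0) stop("no segregating background markers for ",
                              "polygenic component of trait ", tr)
            u <- stats::rnorm(length(bg), 0, sqrt(a$polyVar / cc))
            names(u) <- bg
            polyVal <- drop(sweep(X, 2, 2 * p) %*% u)
        }
        out[, tr] <- qtlVal + polyVal
        comps[[tr]] <- list(qtl = qtlVal, poly = polyVal, markerEffects = u)
    }
    attr(out, "components") <- comps
    out
}
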