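#' Per-family marker filtering on minor allele frequency
#'
#' Classifies every marker within every family as segregating,
#' monomorphic (MAF = 0) or low_MAF (0 < MAF < threshold), computing
#' MAF from allele counts with missing genotypes excluded. Following
#' the elimination rule for severe segregation distortion, a marker is
#' placed on the genome-wide eliminated list if it is monomorphic or
#' below threshold in any family. The threshold is strict: a family
#' MAF exactly at the threshold is retained as segregating. Families
#' with zero genotyped RILs at a marker get status "undefined" and do
#' not contribute to elimination.
#'
#' @param pop a [RILPopulation-class].
#' @param mafThreshold minor allele frequency below which a marker is
#'   flagged (default 0.10).
#' @return list with \code{report} (data.frame family, marker, maf,
#'   status), \code{keep} (per-family list of segregating marker ids)
#'   and \code{eliminated} (marker ids failing in any family).
#' @export
filterMarkers <- function(pop, mafThreshold = 0.10) {
    stopifnot(is(pop, "RILPopulation"))
    if (mafThreshold <= 0 || mafThreshold > 0.5)
        stop("mafThreshold must lie in (0, 0.5]")
    dose <- doseMatrix(pop)
    fam <- families(pop)
    out <- list()
    for (f in unique(fam)) {
        d <- dose[, fam == f, drop = FALSE]
        alt <- rowSums(d, na.rm = TRUE)
        tot <- 2L * rowSums(!is.na(d))
        p <- ifelse(tot > 0, alt / tot, NA_real_)
        maf <- pmin(p, 1 - p)
        status <- ifelse(is.na(maf), "undefined",
                  ifelse(maf == 0, "monomorphic",
                  ifelse(maf < mafThreshold, "low_MAF", "segregating")))
        out[[f]] <- data.frame(family = f, marker = rownames(dose),
                               maf = maf, status = status,
                               stringsAsFactors = FALSE)
    }
    report <- do.call(rbind, out)
    rownames(report) <- NULL
    keep <- lapply(split(report, report$family), function(r)
        r$marker[r$status == "segregating"])
    bad <- unique(report$marker[report$status %in%
                                c("monomorphic", "low_MAF")])
    list(report = report,
         keep = keep[unique(fam)],
         eliminated = rownames(dose)[rownames(dose) %in% bad])
}

#' Quality-control flags for RILs against their parents
#'
#' Flags a RIL \code{non_parental_allele} if any non-missing marker
#' carries an allele absent from both of its parents, or
#' \code{identical_to_parent} if it matches either parent at every
#' non-missing marker (a likely inadvertent self-pollination);
#' otherwise \code{pass}. The non-parental flag takes precedence.
#' Families where more than half of the RILs carry non-parental
#' alleles are reported for removal (the signature of a mating made
#' with an unintended line).
#'
#' @param pop a [RILPopulation-class].
#' @param panel a [FounderPanel-class]; defaults to the panel stored
#'   in the population.
#' @return list with \code{flags} (data.frame ril, family, flag) and
#'   \code{familiesToDrop} (families with > 50\% non-parental RILs).
#' @export
qcRILs <- function(pop, panel = NULL) {
    stopifnot(is(pop, "RILPopulation"))
    if (is.null(panel)) panel <- metadata(pop)$founderPanel
    if (is.null(panel)) stop("no founder panel available")
    dose <- doseMatrix(pop)
    cd <- colData(pop)
    haps <- haplotypes(panel)
    common <- commonParent(panel)

    flags <- character(ncol(pop))
    for (j in seq_len(ncol(pop))) {
        d <- dose[, j]
        ok <- !is.na(d)
        fdAl <- haps[, cd$founder[j]]
        cmAl <- haps[, common]
        # parental allele content at each marker: doses reachable from
        # the two (homozygous) parents
        altInParents <- pmax(fdAl, cmAl)          # is allele "1" present?
        refInParents <- 1L - pmin(fdAl, cmAl)     # is allele "0" present?
        nonPar <- ok & ((d > 0 & altInParents == 0L) |
                        (d < 2 & refInParents == 0L))
        if (any(nonPar)) { flags[j] <- "non_parental_allele"; next }
        idCommon <- all(d[ok] == 2L * cmAl[ok])
        idFounder <- all(d[ok] == 2L * fdAl[ok])
        flags[j] <- if (idCommon || idFounder) "identical_to_parent"
                    else "pass"
    }
    res <- data.frame(ril = colnames(pop), family = cd$family,
                      flag = flags, stringsAsFactors = FALSE)
    fr <- tapply(res$flag == "non_parental_allele", res$family, mean)
    list(flags = res, familiesToDrop = names(fr)[fr > 0.5])
}

#' Interpolate genetic positions from physical positions
#'
#' Linear interpolation of cM against bp on a per-chromosome frame of
#' (bp, cM) anchor points. Queries at an anchor return its cM exactly;
#' queries outside the terminal anchors are clamped to the terminal cM
#' values (no extrapolation, so positions can never go negative or
#' exceed the map end).
#'
#' @param queryBp physical positions to interpolate.
#' @param frameBp,frameCM the anchor frame: bp strictly increasing,
#'   cM non-decreasing, at least 2 points.
#' @return numeric cM positions for the queries.
#' @examples
#' interpolateCM(150, c(100, 200), c(1, 2))  # 1.5
#' @export
interpolateCM <- function(queryBp, frameBp, frameCM) {
    if (length(frameBp) == 0L) stop("empty interpolation frame")
    if (length(frameBp) < 2L) stop("frame needs at least 2 points")
    if (length(frameBp) != length(frameCM))
        stop("frameBp and frameCM lengths differ")
    if (is.unsorted(frameBp, strictly = TRUE))
        stop("frame bp must be strictly increasing")
    stats::approx(frameBp, frameCM, xout = queryBp, method = "linear",
                  rule = 2, ties = "ordered")$y
}

#' Project dense founder-only markers onto RILs
#'
#' Uses the framework (genotyped) markers' parental-origin calls to
#' infer RIL genotypes at dense markers typed only on the founder
#' panel. A dense marker flanked by two framework markers whose origin
#' calls agree and are homozygous (both "common" or both "founder")
#' receives the corresponding parent's genotype (dose 0 or 2); when
#' the flanks disagree (a recombinant interval), are heterozygous, or
#' missing, the call is left missing. Dense markers outside the
#' outermost framework markers inherit the nearest framework marker's
#' origin call. Projection can only ever emit an allele carried by one
#' of the two parents.
#'
#' @param pop a [RILPopulation-class] at the framework markers.
#' @param densePanel a [FounderPanel-class] typed at the dense markers
#'   (same founders as the population's panel).
#' @param denseMap a [GeneticMap-class] for the dense markers.
#' @return dense markers x RILs integer dose matrix with NA for
#'   unprojectable calls.
#' @export
projectDenseMarkers <- function(pop, densePanel, denseMap) {
    stopifnot(is(pop, "RILPopulation"), is(densePanel, "FounderPanel"),
              is(denseMap, "GeneticMap"))
    if (!identical(rownames(haplotypes(densePanel)), markerIds(denseMap)))
        stop("densePanel markers do not match denseMap")
    fwMap <- getMap(pop)
    orig <- originMatrix(pop)
    cd <- colData(pop)
    haps <- haplotypes(densePanel)
    common <- commonParent(densePanel)

    out <- matrix(NA_integer_, nMarkers(denseMap), ncol(pop),
                  dimnames = list(markerIds(denseMap), colnames(pop)))
    for (chr in chromosomes(denseMap)) {
        di <- which(denseMap@chromosome == chr)
        fi <- which(fwMap@chromosome == chr)
        if (length(fi) == 0L) next
        fwBp <- fwMap@bp[fi]
        # left framework flank; 0 before the first marker. Intervals are
        # closed on both ends with the left flank winning bp ties.
        left <- findInterval(denseMap@bp[di], fwBp)
        right <- pmin(left + 1L, length(fi))
        leftC <- pmax(left, 1L)                   # terminal extension
        exact <- left >= 1L & denseMap@bp[di] == fwBp[pmax(left, 1L)]
        right[exact] <- leftC[exact]
        oL <- orig[fi[leftC], , drop = FALSE]
        oR <- orig[fi[right], , drop = FALSE]
        agree <- !is.na(oL) & !is.na(oR) & oL == oR &
            (oL == "common" | oL == "founder")
        for (k in seq_along(di)) {
            dm <- markerIds(denseMap)[di[k]]
            ok <- which(agree[k, ])
            if (!length(ok)) next
            parent <- ifelse(oL[k, ok] == "common", common,
                             cd$founder[ok])
            out[di[k], ok] <- 2L * haps[dm, parent]
        }
    }
    out
}
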