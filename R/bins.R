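#' Chain significant markers into MTA regions
#'
#' Single-linkage chaining within chromosome: markers sorted by cM are
#' grouped into one region while consecutive gaps are at most
#' \code{gap} cM; a strictly larger gap starts a new region. Markers
#' exactly \code{gap} cM apart stay together. Each region's peak is
#' its maximum -log10(p) marker, ties broken by lower cM then
#' lexicographic marker id.
#'
#' @param hits data.frame with columns marker, chromosome, cM,
#'   negLog10P (e.g. the significant rows of a scan table).
#' @param gap chaining distance in cM (default 5).
#' @param trait optional trait label attached to the output.
#' @return data.frame, one row per region: trait, chromosome, start,
#'   end (cM span), peakMarker, peakCM, peakNegLog10P, nMarkers,
#'   markers (comma-separated, cM order).
#' @export
binRegions <- function(hits, gap = 5, trait = NA_character_) {
    if (is.null(hits) || nrow(hits) == 0L)
        return(data.frame(trait = character(0), chromosome = character(0),
            start = numeric(0), end = numeric(0),
            peakMarker = character(0), peakCM = numeric(0),
            peakNegLog10P = numeric(0), nMarkers = integer(0),
            markers = character(0), stringsAsFactors = FALSE))
    stopifnot(all(c("marker", "chromosome", "cM") %in% names(hits)))
    if (!"negLog10P" %in% names(hits)) hits$negLog10P <- NA_real_
    out <- list()
    for (chr in unique(hits$chromosome)) {
        h <- hits[hits$chromosome == chr, ]
        h <- h[order(h$cM, h$marker), ]
        grp <- cumsum(c(1, diff(h$cM) > gap))
        for (g in unique(grp)) {
            r <- h[grp == g, ]
            pk <- order(-r$negLog10P, r$cM, r$marker)[1]
            out[[length(out) + 1L]] <- data.frame(
                trait = trait, chromosome = chr,
                start = min(r$cM), end = max(r$cM),
                peakMarker = r$marker[pk], peakCM = r$cM[pk],
                peakNegLog10P = r$negLog10P[pk], nMarkers = nrow(r),
                markers = paste(r$marker, collapse = ","),
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    res[order(res$chromosome, res$start), ]
}

#' Extract and bin significant markers from a scan
#'
#' Convenience wrapper: selects markers at or above the scan's
#' threshold and chains them with [binRegions()].
#'
#' @param scan a [GwasScanResult-class].
#' @param gap chaining distance in cM.
#' @return region data.frame as from [binRegions()].
#' @export
significantRegions <- function(scan, gap = 5) {
    st <- scanTable(scan)
    hits <- st[!is.na(st$negLog10P) &
               st$negLog10P >= scan@config$threshold, ]
    binRegions(hits, gap = gap, trait = scan@trait)
}

#' Cross-trait bins of MTA regions
#'
#' Chains per-trait region peaks across traits within chromosome:
#' peaks more than \code{gap} cM apart fall in separate bins (peaks at
#' exactly \code{gap} cM stay together). Mirrors the chromosome-by-bin
#' layout used to tabulate multi-trait coincidence.
#'
#' @param regions data.frame of regions from [binRegions()] (rows from
#'   several traits concatenated).
#' @param gap chaining distance in cM (default 5).
#' @return data.frame: chromosome, bin (index within chromosome),
#'   binStart, binEnd (peak cM span), traits (comma-separated),
#'   nTraits, multiTrait flag, members (trait:peakMarker list).
#' @export
crossTraitBins <- function(regions, gap = 5) {
    if (nrow(regions) == 0L)
        return(data.frame(chromosome = character(0), bin = integer(0),
            binStart = numeric(0), binEnd = numeric(0),
            traits = character(0), nTraits = integer(0),
            multiTrait = logical(0), members = character(0)))
    out <- list()
    for (chr in unique(regions$chromosome)) {
        r <- regions[regions$chromosome == chr, ]
        r <- r[order(r$peakCM, r$trait, r$peakMarker), ]
        grp <- cumsum(c(1, diff(r$peakCM) > gap))
        for (g in unique(grp)) {
            b <- r[grp == g, ]
            traits <- sort(unique(b$trait))
            out[[length(out) + 1L]] <- data.frame(
                chromosome = chr, bin = g,
                binStart = min(b$peakCM), binEnd = max(b$peakCM),
                traits = paste(traits, collapse = ","),
                nTraits = length(traits),
                multiTrait = length(traits) > 1L,
                members = paste(paste0(b$trait, ":", b$peakMarker),
                                collapse = ","),
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    res[order(res$chromosome, res$bin), ]
}

#' Classify the sign pattern of per-family allele effects
#'
#' Over the estimable (non-NA) effects at a peak: all_negative /
#' all_positive when every effect has that sign; all_but_k_negative /
#' all_but_k_positive when k effects (k < half) break an otherwise
#' uniform sign; mixed otherwise. Effects exactly zero count as
#' neither sign.
#'
#' @param effects numeric vector of per-family effects (NA = not
#'   estimable).
#' @return list with \code{label}, \code{nPositive}, \code{nNegative},
#'   \code{nEstimable}.
#' @export
classifyAllelePattern <- function(effects) {
    e <- effects[!is.na(effects)]
    if (length(e) == 0L)
        return(list(label = "undefined", nPositive = 0L, nNegative = 0L,
                    nEstimable = 0L))
    np <- sum(e > 0)
    nn <- sum(e < 0)
    signed <- np + nn
    label <- if (signed == 0L) "mixed"
        else if (np == 0L) "all_negative"
        else if (nn == 0L) "all_positive"
        else if (np < nn && np < signed / 2)
            sprintf("all_but_%d_negative", np)
        else if (nn < np && nn < signed / 2)
            sprintf("all_but_%d_positive", nn)
        else "mixed"
    list(label = label, nPositive = np, nNegative = nn,
         nEstimable = length(e))
}

#' Founder-group summaries of allele effects
#'
#' Arithmetic mean effect per founder group and overall, over all
#' estimable (family, marker) pairs — each pair weighted equally. Also
#' flags group-unique positive alleles: (marker, family) pairs with a
#' positive effect in a BX or PI family at markers where no EL family
#' has a positive effect (exotic alleles absent from the elite pool).
#'
#' @param effectTable long-format table from
#'   [estimateFamilyEffects()] (columns group, effect, marker, family).
#' @return list with \code{groupMeans} (data.frame group, meanEffect,
#'   n), \code{overallMean} and \code{exoticPositives} (subset of the
#'   input rows).
#' @export
groupEffectSummary <- function(effectTable) {
    et <- effectTable[!is.na(effectTable$effect), ]
    if (nrow(et) == 0L) stop("no estimable effects")
    gm <- stats::aggregate(effect ~ group, et, mean)
    names(gm) <- c("group", "meanEffect")
    gm$n <- as.integer(table(et$group)[gm$group])
    elPos <- unique(et$marker[et$group == "EL" & et$effect > 0])
    ex <- et[et$group %in% c("BX", "PI") & et$effect > 0 &
             !(et$marker %in% elPos), ]
    list(groupMeans = gm, overallMean = mean(et$effect),
         exoticPositives = ex)
}
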