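#' @include AllGenerics.R
NULL

# ---- GeneticMap ----

#' @describeIn GeneticMap marker ids, in map order.
#' @param x a GeneticMap.
#' @export
setMethod("markerIds", "GeneticMap", function(x) x@marker)

#' @describeIn GeneticMap chromosome labels (unique, in order).
#' @export
setMethod("chromosomes", "GeneticMap", function(x) unique(x@chromosome))

#' @describeIn GeneticMap number of markers.
#' @export
setMethod("nMarkers", "GeneticMap", function(x) length(x@marker))

#' Coerce a GeneticMap to data.frame
#'
#' @param x a GeneticMap.
#' @param ... ignored.
#' @return data.frame with columns marker, chromosome, bp, cM.
#' @export
as.data.frame.GeneticMap <- function(x, ...) {
    data.frame(marker = x@marker, chromosome = x@chromosome, bp = x@bp,
               cM = x@cM, stringsAsFactors = FALSE)
}

setMethod("show", "GeneticMap", function(object) {
    cat(sprintf("GeneticMap: %d markers on %d chromosome(s), %.1f cM total\n",
        nMarkers(object), length(chromosomes(object)),
        sum(vapply(split(object@cM, object@chromosome), max, 0))))
})

# ---- FounderPanel ----

#' @describeIn FounderPanel founder ids.
#' @param x a FounderPanel.
#' @export
setMethod("founderIds", "FounderPanel", function(x) colnames(x@haplotypes))

#' @describeIn FounderPanel named group labels (EL/BX/PI/COMMON).
#' @export
setMethod("founderGroups", "FounderPanel",
    function(x) stats::setNames(x@group, colnames(x@haplotypes)))

#' @describeIn FounderPanel id of the common (hub) parent.
#' @export
setMethod("commonParent", "FounderPanel",
    function(x) colnames(x@haplotypes)[x@group == "COMMON"])

#' @describeIn FounderPanel markers x founders 0/1 haplotype matrix.
#' @export
setMethod("haplotypes", "FounderPanel", function(x) x@haplotypes)

#' @describeIn FounderPanel number of markers.
#' @export
setMethod("nMarkers", "FounderPanel", function(x) nrow(x@haplotypes))

setMethod("show", "FounderPanel", function(object) {
    tb <- table(factor(object@group, c("COMMON", "EL", "BX", "PI")))
    cat(sprintf(
        "FounderPanel: %d founders (%d COMMON + %d EL, %d BX, %d PI), %d markers\n",
        ncol(object@haplotypes), tb["COMMON"], tb["EL"], tb["BX"], tb["PI"],
        nrow(object@haplotypes)))
})

# ---- TraitArchitecture ----

#' @describeIn TraitArchitecture trait ids.
#' @param x a TraitArchitecture.
#' @export
setMethod("traitNames", "TraitArchitecture", function(x) names(x@traits))

#' Per-trait architecture component
#'
#' @param arch a [TraitArchitecture-class].
#' @param trait trait id.
#' @return list with qtl, effects (founders x QTL) and polyVar.
#' @export
traitQtl <- function(arch, trait) {
    stopifnot(trait %in% names(arch@traits))
    arch@traits[[trait]]
}

setMethod("show", "TraitArchitecture", function(object) {
    nq <- vapply(object@traits, function(a) length(a$qtl), 0L)
    cat(sprintf("TraitArchitecture: %d trait(s) [%s]\n", length(nq),
        paste(sprintf("%s: %d QTL", names(nq), nq), collapse = ", ")))
})

# ---- RILPopulation ----

#' @describeIn RILPopulation markers x RILs allele-dose matrix.
#' @param x a RILPopulation.
#' @export
setMethod("doseMatrix", "RILPopulation", function(x) assay(x, "dose"))

#' @describeIn RILPopulation markers x RILs parental-origin matrix.
#' @export
setMethod("originMatrix", "RILPopulation", function(x) assay(x, "origin"))

#' @describeIn RILPopulation named per-RIL family labels.
#' @export
setMethod("families", "RILPopulation",
    function(x) stats::setNames(colData(x)$family, colnames(x)))

#' @describeIn RILPopulation the marker map as a [GeneticMap-class].
#' @export
setMethod("getMap", "RILPopulation", function(x) {
    rd <- rowData(x)
    GeneticMap(rd$chromosome, rownames(x), rd$bp, rd$cM)
})

#' @describeIn RILPopulation number of markers (rows).
#' @export
setMethod("nMarkers", "RILPopulation", function(x) nrow(x))

setMethod("show", "RILPopulation", function(object) {
    cat(sprintf("RILPopulation: %d RILs in %d families, %d markers\n",
        ncol(object), length(unique(colData(object)$family)), nrow(object)))
})

# ---- TrialDesign / PlotTable ----

#' Layout of a trial design (one row per plot)
#' @param design a [TrialDesign-class].
#' @return data.frame layout.
#' @export
trialLayout <- function(design) design@layout

#' Set membership of a trial design
#' @param design a [TrialDesign-class].
#' @return data.frame (set, family, entry, type).
#' @export
trialSets <- function(design) design@sets

setMethod("show", "TrialDesign", function(object) {
    cat(sprintf(
        "TrialDesign: %d sets, %d environments, %d blocks, %d plots\n",
        length(unique(object@sets$set)),
        length(unique(object@layout$environment)),
        length(unique(object@layout$block)), nrow(object@layout)))
})

#' Plot-level data of a PlotTable
#' @param x a [PlotTable-class].
#' @return data.frame, one row per plot.
#' @export
plotData <- function(x) x@plots

#' @describeIn PlotTable trait column names.
#' @param x a PlotTable.
#' @export
setMethod("traitNames", "PlotTable", function(x) x@traits)

setMethod("show", "PlotTable", function(object) {
    cat(sprintf("PlotTable: %d plots, %d environments, traits: %s\n",
        nrow(object@plots), length(unique(object@plots$environment)),
        paste(object@traits, collapse = ", ")))
})

# ---- model results ----

#' @describeIn BlockEffectEstimates named block BLUPs.
#' @param x a BlockEffectEstimates.
#' @export
setMethod("blockEffects", "BlockEffectEstimates", function(x) x@blockBlups)

#' @describeIn BlockEffectEstimates stage-1 variance components.
#' @export
setMethod("varComp", "BlockEffectEstimates",
    function(x) c(varBlk = x@varBlk, varRes = x@varRes))

#' Check BLUEs from the stage-1 fit
#' @param x a [BlockEffectEstimates-class].
#' @export
checkBlues <- function(x) x@checkBlues

setMethod("show", "BlockEffectEstimates", function(object) {
    cat(sprintf(
        "BlockEffectEstimates: %d blocks; varBlk = %.4g, varRes = %.4g\n",
        length(object@blockBlups), object@varBlk, object@varRes))
})

#' @describeIn EntryBlups long data.frame of entry BLUPs.
#' @param x an EntryBlups.
#' @export
setMethod("entryBlups", "EntryBlups", function(x) x@blups)

#' @describeIn EntryBlups per-trait variance components and covariate
#'   coefficients.
#' @export
setMethod("varComp", "EntryBlups", function(x) x@varcomp)

#' @describeIn EntryBlups trait ids present.
#' @export
setMethod("traitNames", "EntryBlups", function(x) unique(x@blups$trait))

#' Per-entry environment counts of an EntryBlups fit
#' @param x an [EntryBlups-class].
#' @export
envCounts <- function(x) x@envCounts

#' Entry metadata (entry, family, type) of an EntryBlups fit
#' @param x an [EntryBlups-class].
#' @export
entryInfo <- function(x) x@entryInfo

#' BLUPs of one trait as a named vector
#' @param x an [EntryBlups-class].
#' @param trait trait id.
#' @export
blupVector <- function(x, trait) {
    b <- x@blups[x@blups$trait == trait, ]
    if (nrow(b) == 0L) stop("no BLUPs for trait ", trait)
    stats::setNames(b$blup, b$entry)
}

setMethod("show", "EntryBlups", function(object) {
    cat(sprintf("EntryBlups: %d entries, traits: %s\n",
        length(unique(object@blups$entry)),
        paste(unique(object@blups$trait), collapse = ", ")))
})

setMethod("show", "HeritabilityEstimate", function(object) {
    cat(sprintf("H (%s basis) = %.3f (%.3f, %.3f), eBar = %.2f\n",
        object@basis, object@H, object@ci[1], object@ci[2], object@eBar))
})

#' @describeIn KinshipMatrix the relationship matrix.
#' @param x a KinshipMatrix.
#' @export
setMethod("kinship", "KinshipMatrix", function(x) x@K)

setMethod("show", "KinshipMatrix", function(object) {
    cat(sprintf(
        "KinshipMatrix: %d entries, mean diagonal %.3f, %d markers excluded\n",
        nrow(object@K), mean(diag(object@K)), length(object@excluded)))
})

#' @describeIn GwasScanResult per-marker scan table.
#' @param x a GwasScanResult.
#' @export
setMethod("scanTable", "GwasScanResult", function(x) x@scan)

#' @describeIn GwasScanResult families x markers allele-substitution
#'   effect matrix (NA = not estimable).
#' @export
setMethod("familyEffects", "GwasScanResult", function(x) x@effects)

setMethod("show", "GwasScanResult", function(object) {
    thr <- object@config$threshold %||% 3
    cat(sprintf(
        "GwasScanResult [%s]: %d markers scanned, %d above -log10(p) >= %g\n",
        object@trait, nrow(object@scan),
        sum(object@scan$negLog10P >= thr, na.rm = TRUE), thr))
})
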