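#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Genetic map of SNP markers
#'
#' Marker coordinates in both physical (bp, 1-based) and genetic (cM)
#' units, the frame for recombination simulation, cM interpolation and
#' linkage-window arithmetic. Within a chromosome markers are stored in
#' physical order; bp must be strictly increasing and cM non-decreasing.
#'
#' @slot chromosome character, chromosome label per marker.
#' @slot marker character, unique marker identifiers.
#' @slot bp integer, 1-based physical positions.
#' @slot cM numeric, non-negative genetic positions.
#' @exportClass GeneticMap
setClass("GeneticMap",
    representation(chromosome = "character", marker = "character",
                   bp = "integer", cM = "numeric"))

setValidity("GeneticMap", function(object) {
    n <- length(object@marker)
    if (length(object@chromosome) != n || length(object@bp) != n ||
        length(object@cM) != n)
        return("chromosome, marker, bp and cM must have equal length")
    if (anyDuplicated(object@marker))
        return("marker ids must be unique")
    if (any(object@bp < 1L))
        return("bp positions are 1-based and must be >= 1")
    if (any(object@cM < 0))
        return("cM positions must be non-negative")
    for (chr in unique(object@chromosome)) {
        i <- object@chromosome == chr
        if (is.unsorted(object@bp[i], strictly = TRUE))
            return(sprintf("bp not strictly increasing on chromosome %s", chr))
        if (is.unsorted(object@cM[i]))
            return(sprintf("cM not non-decreasing on chromosome %s", chr))
    }
    TRUE
})

#' Construct a GeneticMap
#'
#' @param chromosome chromosome label per marker.
#' @param marker unique marker ids.
#' @param bp 1-based physical positions (integer-like).
#' @param cM genetic positions in centimorgans.
#' @return A [GeneticMap-class] object with markers ordered by
#'   chromosome then bp.
#' @examples
#' gm <- GeneticMap(rep("1", 3), c("m1", "m2", "m3"),
#'                  bp = c(1e5, 2e5, 3e5), cM = c(0, 5, 10))
#' @export
GeneticMap <- function(chromosome, marker, bp, cM) {
    o <- order(factor(chromosome, levels = unique(chromosome)), bp)
    new("GeneticMap", chromosome = as.character(chromosome)[o],
        marker = as.character(marker)[o], bp = as.integer(bp)[o],
        cM = as.numeric(cM)[o])
}

#' Panel of homozygous founder lines
#'
#' One haplotype per founder (all founders fully inbred), coded 0/1 over
#' the markers of a [GeneticMap-class]. Exactly one founder carries the
#' group label \code{"COMMON"}: the hub parent to which every other
#' founder is mated. The non-common founders fall into the three classes
#' of the soybean NAM design: EL (elite), BX (breeding lines with exotic
#' ancestry) and PI (plant introductions).
#'
#' @slot haplotypes integer matrix, markers x founders, values 0/1.
#' @slot group character vector, one of EL/BX/PI/COMMON per founder.
#' @exportClass FounderPanel
setClass("FounderPanel",
    representation(haplotypes = "matrix", group = "character"))

setValidity("FounderPanel", function(object) {
    h <- object@haplotypes
    if (is.null(rownames(h)) || is.null(colnames(h)))
        return("haplotypes must carry marker rownames and founder colnames")
    if (length(object@group) != ncol(h))
        return("one group label per founder required")
    if (!all(object@group %in% c("EL", "BX", "PI", "COMMON")))
        return("groups must be EL, BX, PI or COMMON")
    if (sum(object@group == "COMMON") != 1L)
        return("exactly one COMMON founder required")
    if (!all(h %in% c(0L, 1L)))
        return("haplotypes must be biallelic 0/1 (founders are homozygous)")
    TRUE
})

#' Construct a FounderPanel
#'
#' @param haplotypes markers x founders matrix of 0/1 alleles with
#'   dimnames.
#' @param group per-founder group label (EL/BX/PI/COMMON).
#' @return A [FounderPanel-class].
#' @export
FounderPanel <- function(haplotypes, group) {
    mode(haplotypes) <- "integer"
    new("FounderPanel", haplotypes = haplotypes,
        group = as.character(group))
}

#' Trait architecture: QTL positions and founder-specific effects
#'
#' For each trait, a set of QTL markers and a complete founders x QTL
#' table of allele-substitution effects expressed relative to the common
#' parent's allele (the common founder's row is identically zero), plus
#' a polygenic variance acting on top of the QTL.
#'
#' @slot traits named list; each element has components \code{qtl}
#'   (marker ids), \code{effects} (founders x QTL numeric matrix) and
#'   \code{polyVar} (non-negative scalar).
#' @slot founders character, founder ids (row order of every effects
#'   matrix).
#' @slot common id of the common founder.
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
    representation(traits = "list", founders = "character",
                   common = "character"))

setValidity("TraitArchitecture", function(object) {
    for (tr in names(object@traits)) {
        a <- object@traits[[tr]]
        if (!all(c("qtl", "effects", "polyVar") %in% names(a)))
            return("each trait needs qtl, effects and polyVar")
        if (!identical(rownames(a$effects), object@founders))
            return("effects rows must match founder ids")
        if (!identical(colnames(a$effects) %||% character(0),
                       as.character(a$qtl)))
            return("effects columns must match qtl ids")
        if (any(a$effects[object@common, ] != 0))
            return("common founder effects must be zero at every QTL")
        if (a$polyVar < 0) return("polygenic variance must be >= 0")
        if (anyNA(a$effects)) return("effect table must be complete")
    }
    TRUE
})

#' Family-structured RIL population
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are mapped markers,
#' columns are recombinant inbred lines. Assay \code{"dose"} holds
#' allele doses in \{0,1,2,NA\} (count of the "1" allele); assay
#' \code{"origin"} holds per-marker parental origin labels:
#' \code{"common"}, \code{"founder"} or \code{"heterozygous"}.
#' \code{colData} carries \code{family} and \code{founder} (the
#' non-common parent of the family); \code{rowData} carries the map
#' columns (chromosome, bp, cM).
#'
#' @exportClass RILPopulation
setClass("RILPopulation", contains = "SummarizedExperiment")

setValidity("RILPopulation", function(object) {
    if (!all(c("dose", "origin") %in% names(assays(object))))
        return("assays 'dose' and 'origin' required")
    if (!all(c("family", "founder") %in% colnames(colData(object))))
        return("colData must contain 'family' and 'founder'")
    if (!all(c("chromosome", "bp", "cM") %in% colnames(rowData(object))))
        return("rowData must contain chromosome, bp and cM")
    d <- assay(object, "dose")
    if (!all(d[!is.na(d)] %in% 0:2))
        return("doses must be 0, 1, 2 or NA")
    o <- assay(object, "origin")
    if (!all(o[!is.na(o)] %in% c("common", "founder", "heterozygous")))
        return("origin labels must be common/founder/heterozygous")
    TRUE
})

#' Construct a RILPopulation
#'
#' @param dose markers x RILs integer matrix of allele doses (0/1/2/NA).
#' @param origin markers x RILs character matrix of parental-origin
#'   labels ("common", "founder", "heterozygous", NA).
#' @param map [GeneticMap-class] covering the rows.
#' @param family per-RIL family id.
#' @param founder per-RIL id of the family's non-common parent.
#' @param panel optional [FounderPanel-class], stored in metadata.
#' @return A [RILPopulation-class].
#' @export
RILPopulation <- function(dose, origin, map, family, founder, panel = NULL) {
    stopifnot(identical(rownames(dose), markerIds(map)))
    rd <- DataFrame(chromosome = map@chromosome, bp = map@bp, cM = map@cM,
                    row.names = map@marker)
    cd <- DataFrame(family = as.character(family),
                    founder = as.character(founder),
                    row.names = colnames(dose))
    md <- if (is.null(panel)) list() else list(founderPanel = panel)
    se <- SummarizedExperiment(
        assays = list(dose = dose, origin = origin),
        rowData = rd, colData = cd, metadata = md)
    new("RILPopulation", se)
}

#' Field-trial design of 40-entry augmented sets
#'
#' Each family's RILs are split into sets of 35, augmented with the
#' family's two parents and three checks (40 entries per set). Sets are
#' assigned to incomplete blocks within environments; unbalanced
#' coverage (not every set in every environment) is carried by the
#' layout. One row of \code{layout} is one field plot.
#'
#' @slot layout data.frame with columns plot, environment, set, block,
#'   entry, type ("ril"/"parent"/"check"), plantingDate (Julian day).
#' @slot sets data.frame with columns set, family, entry, type: set
#'   membership before environment assignment.
#' @exportClass TrialDesign
setClass("TrialDesign",
    representation(layout = "data.frame", sets = "data.frame"))

setValidity("TrialDesign", function(object) {
    need <- c("plot", "environment", "set", "block", "entry", "type",
              "plantingDate")
    if (!all(need %in% names(object@layout)))
        return(paste("layout needs columns:", paste(need, collapse = ", ")))
    # padded sets may repeat a check variety, so count slots, not
    # distinct ids
    sz <- table(object@sets$set)
    if (any(sz != 40L))
        return("every set must contain exactly 40 entries")
    be <- unique(object@layout[c("block", "environment")])
    if (anyDuplicated(be$block))
        return("every block must belong to exactly one environment")
    TRUE
})

#' Plot-level phenotype table
#'
#' One row per field plot with the design structure (environment, set,
#' block, planting date) and one column per trait; NA marks missing
#' plot data. Lodging scores, when present, must lie in [1, 5].
#'
#' @slot plots data.frame: plot, entry, type, family, environment, set,
#'   block, plantingDate, then one numeric column per trait.
#' @slot traits character, names of the trait columns.
#' @exportClass PlotTable
setClass("PlotTable",
    representation(plots = "data.frame", traits = "character"))

setValidity("PlotTable", function(object) {
    need <- c("plot", "entry", "type", "environment", "block",
              "plantingDate")
    if (!all(need %in% names(object@plots)))
        return(paste("plots needs columns:", paste(need, collapse = ", ")))
    if (!all(object@traits %in% names(object@plots)))
        return("every trait must have a column in plots")
    if ("lodging" %in% object@traits) {
        lg <- object@plots$lodging
        if (any(lg < 1 | lg > 5, na.rm = TRUE))
            return("lodging scores must lie in [1, 5]")
    }
    TRUE
})

#' Stage-1 estimates: shrunken block effects from check plots
#'
#' REML fit of the check/block model: fixed planting-date covariate and
#' check effects, random block effects. Block BLUPs are shrunken toward
#' zero; blocks contributing no check data are shrunk fully to zero.
#'
#' @slot blockBlups named numeric, BLUP per block (all blocks).
#' @slot checkBlues named numeric, fixed-effect check means (BLUEs).
#' @slot beta named numeric: intercept and planting-date slope.
#' @slot slopeSE standard error of the planting-date slope (NA when no
#'   date variation).
#' @slot varBlk,varRes non-negative variance components.
#' @slot dateCenter numeric, centering constant used for planting date.
#' @exportClass BlockEffectEstimates
setClass("BlockEffectEstimates",
    representation(blockBlups = "numeric", checkBlues = "numeric",
                   beta = "numeric", slopeSE = "numeric",
                   varBlk = "numeric", varRes = "numeric",
                   dateCenter = "numeric"))

#' Stage-2 estimates: entry BLUPs and variance components
#'
#' Per-trait REML fits of the entry model with planting date and the
#' stage-1 shrunken block value as fixed covariates and entries (RILs
#' and parents) as random effects.
#'
#' @slot blups data.frame: entry, trait, blup (genotypic value on the
#'   trait scale, deviation from the model intercept).
#' @slot varcomp data.frame: trait, varG, varRes, intercept, betaPldate,
#'   betaBlk.
#' @slot envCounts data.frame: entry, trait, nEnv (environments with at
#'   least one non-missing plot for that entry and trait).
#' @slot entryInfo data.frame: entry, family, type.
#' @exportClass EntryBlups
setClass("EntryBlups",
    representation(blups = "data.frame", varcomp = "data.frame",
                   envCounts = "data.frame", entryInfo = "data.frame"))

#' Broad-sense heritability with harmonic-mean replication
#'
#' @slot H heritability in [0, 1].
#' @slot basis "entry_mean" or "family_mean".
#' @slot ci numeric(2), confidence bounds in [0, 1].
#' @slot eBar harmonic mean number of environments.
#' @slot nBar harmonic mean family size (family basis only; NA else).
#' @exportClass HeritabilityEstimate
setClass("HeritabilityEstimate",
    representation(H = "numeric", basis = "character", ci = "numeric",
                   eBar = "numeric", nBar = "numeric"))

setValidity("HeritabilityEstimate", function(object) {
    if (object@H < 0 || object@H > 1) return("H must lie in [0, 1]")
    if (length(object@ci) != 2L || object@ci[1] > object@ci[2])
        return("ci must be (lower, upper) with lower <= upper")
    if (object@ci[1] > object@H || object@ci[2] < object@H)
        return("ci must bracket H")
    if (object@eBar <= 0) return("harmonic mean eBar must be positive")
    TRUE
})

#' VanRaden genomic relationship matrix
#'
#' Additive relationship matrix computed from column-centred allele
#' doses scaled by the sum of 2p(1-p) over included markers.
#'
#' @slot K symmetric numeric matrix over entries.
#' @slot scale the VanRaden denominator sum(2 p (1-p)).
#' @slot excluded marker ids left out of the computation.
#' @exportClass KinshipMatrix
setClass("KinshipMatrix",
    representation(K = "matrix", scale = "numeric", excluded = "character"))

setValidity("KinshipMatrix", function(object) {
    K <- object@K
    if (nrow(K) != ncol(K) || max(abs(K - t(K))) > 1e-8)
        return("K must be square and symmetric")
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
        return("K must be positive semidefinite (within tolerance)")
    if (mean(diag(K)) < mean(K[upper.tri(K)]))
        return("mean diagonal must be >= mean off-diagonal")
    TRUE
})

#' Result of the family-nested random-effect genome scan
#'
#' Per marker: a -log10(p) for the allele-substitution variance, the
#' REML variance components of the scan model, and per-family allele
#' substitution effects (NA where not estimable, i.e. the marker does
#' not segregate in that family).
#'
#' @slot trait trait id.
#' @slot scan data.frame: marker, chromosome, bp, cM, negLog10P,
#'   sigma2Alpha, sigma2Phi, sigma2Eps, mu, nFamEstimable, status.
#' @slot effects families x markers numeric matrix of alpha-hat.
#' @slot pev families x markers prediction-error variances of alpha-hat.
#' @slot config list: window cM, threshold, p-value method label.
#' @exportClass GwasScanResult
setClass("GwasScanResult",
    representation(trait = "character", scan = "data.frame",
                   effects = "matrix", pev = "matrix", config = "list"))
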