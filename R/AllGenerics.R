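#' @include AllClasses.R
NULL

#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @export
setGeneric("founderIds", function(x) standardGeneric("founderIds"))

#' @export
setGeneric("founderGroups", function(x) standardGeneric("founderGroups"))

#' @export
setGeneric("commonParent", function(x) standardGeneric("commonParent"))

#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @export
setGeneric("doseMatrix", function(x) standardGeneric("doseMatrix"))

#' @export
setGeneric("originMatrix", function(x) standardGeneric("originMatrix"))

#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' @export
setGeneric("getMap", function(x) standardGeneric("getMap"))

#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' @export
setGeneric("blockEffects", function(x) standardGeneric("blockEffects"))

#' @export
setGeneric("entryBlups", function(x) standardGeneric("entryBlups"))

#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))

#' @export
setGeneric("kinship", function(x) standardGeneric("kinship"))

#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @export
setGeneric("familyEffects", function(x) standardGeneric("familyEffects"))
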