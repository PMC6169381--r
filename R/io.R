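# File-format plumbing. Dialect: UTF-8, header row, "NA" for missing;
# TSV for maps and reports, CSV for genotype and plot tables; VCF v4.2
# minimal (GT only, unphased).

#' Write / read a genetic map as TSV
#'
#' Columns: marker, chromosome, bp, cM.
#'
#' @param map a [GeneticMap-class].
#' @param path file path.
#' @return \code{readGeneticMap} returns a [GeneticMap-class].
#' @export
writeGeneticMap <- function(map, path) {
    utils::write.table(as.data.frame(map), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGeneticMap
#' @export
readGeneticMap <- function(path) {
    df <- utils::read.delim(path, colClasses = c(
        marker = "character", chromosome = "character"))
    GeneticMap(df$chromosome, df$marker, df$bp, df$cM)
}

#' Write / read a genotype matrix as CSV
#'
#' Rows are lines, columns are markers, values allele doses 0/1/2 with
#' NA for missing.
#'
#' @param x a [RILPopulation-class], [FounderPanel-class] (doses =
#'   2 x haplotype) or a lines x markers matrix.
#' @param path file path.
#' @return \code{readGenotypes} returns a lines x markers integer
#'   matrix.
#' @export
writeGenotypes <- function(x, path) {
    m <- if (is(x, "RILPopulation")) t(doseMatrix(x))
         else if (is(x, "FounderPanel")) 2L * t(haplotypes(x))
         else as.matrix(x)
    utils::write.csv(as.data.frame(m), path, quote = FALSE)
    invisible(path)
}

#' @rdname writeGenotypes
#' @export
readGenotypes <- function(path) {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    mode(m) <- "integer"
    m
}

#' Write / read a plot-level phenotype table as CSV
#'
#' @param x a [PlotTable-class] or its data.frame.
#' @param path file path.
#' @param traits trait column names (for \code{readPlotTable};
#'   defaults to every column after plantingDate).
#' @return \code{readPlotTable} returns a [PlotTable-class].
#' @export
writePlotTable <- function(x, path) {
    df <- if (is(x, "PlotTable")) plotData(x) else x
    utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePlotTable
#' @export
readPlotTable <- function(path, traits = NULL) {
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = c(block = "character",
                                         entry = "character"))
    meta <- c("plot", "entry", "type", "environment", "set", "block",
              "plantingDate", "family")
    if (is.null(traits)) traits <- setdiff(names(df), meta)
    new("PlotTable", plots = df, traits = traits)
}

#' Export genotypes as minimal VCF v4.2
#'
#' One record per marker with REF/ALT placeholder alleles A/T and an
#' unphased GT field (0/0, 0/1, 1/1, ./.).
#'
#' @param x a [RILPopulation-class] or a markers x lines dose matrix
#'   (then \code{map} is required).
#' @param path output path.
#' @param map a [GeneticMap-class] (taken from \code{x} when it is a
#'   population).
#' @export
writeVCF <- function(x, path, map = NULL) {
    if (is(x, "RILPopulation")) {
        map <- getMap(x)
        dose <- doseMatrix(x)
    } else dose <- x
    stopifnot(is(map, "GeneticMap"),
              identical(rownames(dose), markerIds(map)))
    gt <- matrix("./.", nrow(dose), ncol(dose))
    gt[!is.na(dose) & dose == 0L] <- "0/0"
    gt[!is.na(dose) & dose == 1L] <- "0/1"
    gt[!is.na(dose) & dose == 2L] <- "1/1"
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", colnames(dose)),
                   collapse = "\t"))
    body <- paste(map@chromosome, map@bp, map@marker, "A", "T", ".",
                  ".", ".", "GT", apply(gt, 1, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read genotype doses from a VCF file
#'
#' Uses vcfR; counts ALT alleles in the GT field.
#'
#' @param path VCF path.
#' @return markers x lines integer dose matrix, plus a
#'   [GeneticMap-class] (with cM = NA) as attribute \code{"map"}.
#' @export
readVCFGenotypes <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v)
    dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    dose[gt %in% c("0/0", "0|0")] <- 0L
    dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    dose[gt %in% c("1/1", "1|1")] <- 2L
    fix <- vcfR::getFIX(v)
    attr(dose, "map") <- data.frame(marker = fix[, "ID"],
        chromosome = fix[, "CHROM"], bp = as.integer(fix[, "POS"]),
        stringsAsFactors = FALSE)
    dose
}
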