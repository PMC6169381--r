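# End-to-end orchestration: simulate -> prep -> blup -> gwas -> bins,
# driven by a single config with one master seed. Stage seeds are
# derived deterministically so stages rerun identically.

#' Default run configuration
#'
#' A desk-scale demonstration configuration: 5 families x 40 RILs on 2
#' chromosomes of 150 markers each, 3 environments, one yield-like
#' trait. All tunables that the underlying field design fixes keep
#' those values (40-entry sets of 35 RILs + 2 parents + 3 checks, MAF
#' threshold 0.10, 5 cM linkage window, -log10(p) threshold 3, single
#' seed descent to F5).
#'
#' @param seed master seed.
#' @return nested config list (round-trips through YAML losslessly).
#' @export
defaultRunConfig <- function(seed = 1L) {
    list(
        seed = as.integer(seed),
        stages = list(simulate = TRUE, prep = TRUE, blup = TRUE,
                      gwas = TRUE, bins = TRUE),
        simulate = list(
            nChromosomes = 2L, cMLength = 100, nMarkers = 150L,
            spacing = "random", bpModel = "linear", bpPerCM = 1e6,
            groupCounts = list(EL = 17L, BX = 15L, PI = 8L),
            alleleFreq = 0.5, nFamilies = 5L, nPerFamily = 40L,
            finalGeneration = 5L, missingRate = 0,
            nEnvironments = 3L, setsEvaluated = "all",
            plantingDate = list(mean = 140, sd = 7),
            checks = list("check_A", "check_B", "check_C"),
            traits = list(yield = list(
                nQtl = 5L, polyVar = 20000,
                effectDist = list(EL = c(50, 100), BX = c(-100, 150),
                                  PI = c(-250, 150)),
                grandMean = 3000, varEnv = 40000, varBlk = 10000,
                varRes = 60000, slope = -5)),
            missingPlotRate = 0.02),
        prep = list(mafThreshold = 0.10),
        gwas = list(window = 5, threshold = 3),
        bins = list(gap = 5))
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file.
#' @param config config list.
#' @return \code{readRunConfig} returns the config list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' Validate pipeline input files
#'
#' Checks map sortedness, genotype coding (doses 0/1/2/NA), plot-table
#' referential integrity (every non-check plot entry present in the
#' genotype matrix; block/environment fields complete) and unit ranges
#' (lodging within [1, 5]).
#'
#' @param mapPath,genotypesPath,plotsPath file paths (any may be NULL
#'   to skip its checks).
#' @return data.frame of violations (check, severity, detail); zero
#'   rows means clean. Attribute \code{"fatal"} is TRUE when any
#'   violation is fatal.
#' @export
validateInputs <- function(mapPath = NULL, genotypesPath = NULL,
                           plotsPath = NULL) {
    bad <- list()
    note <- function(check, severity, detail)
        bad[[length(bad) + 1L]] <<- data.frame(check = check,
            severity = severity, detail = detail, stringsAsFactors = FALSE)
    map <- geno <- NULL
    if (!is.null(mapPath)) {
        df <- utils::read.delim(mapPath, colClasses = c(
            marker = "character", chromosome = "character"))
        for (chr in unique(df$chromosome)) {
            b <- df$bp[df$chromosome == chr]
            if (is.unsorted(b, strictly = TRUE))
                note("map_sorted", "fatal",
                     sprintf("bp not strictly increasing on chr %s", chr))
            cm <- df$cM[df$chromosome == chr]
            if (is.unsorted(cm))
                note("map_sorted", "fatal",
                     sprintf("cM not monotone on chr %s", chr))
        }
        if (anyDuplicated(df$marker))
            note("map_unique", "fatal", "duplicated marker ids")
        map <- df
    }
    if (!is.null(genotypesPath)) {
        geno <- readGenotypes(genotypesPath)
        v <- geno[!is.na(geno)]
        if (!all(v %in% 0:2))
            note("genotype_coding", "fatal",
                 "doses outside {0,1,2,NA} present")
        if (!is.null(map) && !all(colnames(geno) %in% map$marker))
            note("genotype_markers", "fatal",
                 "genotype markers absent from map")
    }
    if (!is.null(plotsPath)) {
        pt <- utils::read.csv(plotsPath, check.names = FALSE)
        for (col in c("entry", "block", "environment"))
            if (anyNA(pt[[col]]) || any(!nzchar(pt[[col]])))
                note("plot_integrity", "fatal",
                     sprintf("unresolvable %s in plot table", col))
        if (!is.null(geno)) {
            ent <- unique(pt$entry[pt$type == "ril"])
            missing <- setdiff(ent, rownames(geno))
            if (length(missing))
                note("plot_integrity", "fatal", sprintf(
                    "%d plot entries missing from genotypes (e.g. %s)",
                    length(missing), missing[1]))
        }
        if ("lodging" %in% names(pt)) {
            lg <- pt$lodging
            if (any(lg < 1 | lg > 5, na.rm = TRUE))
                note("lodging_range", "fatal",
                     "lodging values outside [1, 5]")
        }
    }
    out <- if (length(bad)) do.call(rbind, bad) else
        data.frame(check = character(0), severity = character(0),
                   detail = character(0))
    attr(out, "fatal") <- any(out$severity == "fatal")
    out
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

#' Run the full pipeline into an output directory
#'
#' Executes the enabled stages in order (simulate, prep, blup, gwas,
#' bins), writes every stage's tables under \code{outDir} and a
#' \code{manifest.json} recording the config hash, master seed, stage
#' status, record counts and per-file MD5 checksums. Reruns with the
#' same config are bit-identical. A stage failure halts the run with
#' the stage name in the error.
#'
#' @param config config list (see [defaultRunConfig()]).
#' @param outDir output directory (created).
#' @param verbose log stage progress.
#' @return invisibly, the manifest list. The in-memory stage objects
#'   are attached as attribute \code{"objects"}.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir,
                        verbose = TRUE) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    seeds <- deriveSeeds(config$seed, 6L)
    manifest <- list(seed = config$seed,
                     configHash = .configHash(config), stages = list())
    obj <- list()
    say <- function(...) if (verbose) message(sprintf(...))
    addStage <- function(name, status, files = character(0),
                         counts = list()) {
        manifest$stages[[name]] <<- list(status = status,
            checksums = as.list(tools::md5sum(files)), counts = counts)
    }
    runStage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }

    sc <- config$simulate
    if (isTRUE(config$stages$simulate)) runStage("simulate", {
        say("[simulate] generating population and trial")
        map <- simulateMap(sc$nChromosomes, sc$cMLength, sc$nMarkers,
                           spacing = sc$spacing, bpModel = sc$bpModel,
                           bpPerCM = sc$bpPerCM, seed = seeds[1])
        panel <- simulateFounders(map,
            unlist(sc$groupCounts), sc$alleleFreq, seed = seeds[1])
        founders <- setdiff(founderIds(panel), commonParent(panel))
        set.seed(seeds[1])
        matings <- if (sc$nFamilies >= length(founders)) founders
                   else sample(founders, sc$nFamilies)
        pop <- deriveRILs(panel, matings, sc$nPerFamily,
                          sc$finalGeneration, map,
                          missingRate = sc$missingRate, seed = seeds[2])
        nQtl <- vapply(sc$traits, function(t) t$nQtl, 0L)
        arch <- assignTraitArchitecture(map, panel, nQtl,
            effectDist = lapply(sc$traits, `[[`, "effectDist"),
            polyVar = vapply(sc$traits, function(t) t$polyVar, 0),
            seed = seeds[3])
        gv <- geneticValues(pop, arch, seed = seeds[3])
        # parents are trial entries too: their genotypic values follow
        # from their own marker genotypes
        pgv <- .parentValues(panel, arch, c(commonParent(panel), matings))
        gvAll <- rbind(gv, pgv)
        design <- designTrial(pop, unlist(sc$checks), sc$nEnvironments,
                              sc$setsEvaluated, sc$plantingDate,
                              seed = seeds[4])
        tr <- sc$traits
        plots <- simulatePlots(design, gvAll,
            grandMean = vapply(tr, function(t) t$grandMean, 0),
            varEnv = vapply(tr, function(t) t$varEnv, 0),
            varBlk = vapply(tr, function(t) t$varBlk, 0),
            varRes = vapply(tr, function(t) t$varRes, 0),
            slope = vapply(tr, function(t) t$slope, 0),
            missingRate = sc$missingPlotRate, seed = seeds[5])
        files <- c(
            writeGeneticMap(map, file.path(outDir, "map.tsv")),
            writeGenotypes(pop, file.path(outDir, "genotypes.csv")),
            writeGenotypes(panel, file.path(outDir, "founders.csv")),
            writePlotTable(plots, file.path(outDir, "plots.csv")),
            .writeTsv(.truthTable(arch), file.path(outDir,
                                                   "truth_qtl.tsv")),
            .writeTsv(data.frame(entry = rownames(gvAll), gvAll,
                                 check.names = FALSE),
                      file.path(outDir, "truth_genetic_values.tsv")))
        obj <- c(obj, list(map = map, panel = panel, pop = pop,
                            arch = arch, gv = gvAll, design = design,
                            plots = plots))
        addStage("simulate", "done", files, list(
            nRILs = ncol(pop), nMarkers = nrow(pop),
            nSets = length(unique(trialSets(design)$set)),
            nPlots = nrow(plotData(plots))))
    }) else addStage("simulate", "skipped")

    if (isTRUE(config$stages$prep)) runStage("prep", {
        say("[prep] marker filtering and RIL QC")
        flt <- filterMarkers(obj$pop, config$prep$mafThreshold)
        qc <- qcRILs(obj$pop)
        # scan markers that segregate cleanly in at least one family;
        # families where a marker does not segregate are simply not
        # estimable in the scan
        keepM <- Reduce(union, flt$keep)
        keepR <- qc$flags$ril[qc$flags$flag == "pass" &
                              !(qc$flags$family %in% qc$familiesToDrop)]
        obj$popFiltered <- obj$pop[keepM, keepR]
        files <- c(
            .writeTsv(flt$report, file.path(outDir, "filter_report.tsv")),
            .writeTsv(qc$flags, file.path(outDir, "qc_report.tsv")))
        addStage("prep", "done", files, list(
            markersKept = length(keepM),
            markersEliminated = length(flt$eliminated),
            rilsKept = length(keepR),
            rilsDropped = ncol(obj$pop) - length(keepR)))
    }) else addStage("prep", "skipped")

    if (isTRUE(config$stages$blup)) runStage("blup", {
        say("[blup] two-stage mixed-model analysis")
        traits <- traitNames(obj$plots)
        beL <- lapply(stats::setNames(traits, traits), function(tr)
            fitCheckBlockModel(obj$plots, tr))
        eb <- fitEntryModel(obj$plots, beL, traits)
        vc <- varComp(eb)
        rows <- lapply(traits, function(tr) {
            v <- vc[vc$trait == tr, ]
            ec <- envCounts(eb)
            ec <- ec$nEnv[ec$trait == tr]
            h <- heritability(v$varG, v$varRes, ec)
            af <- varianceAmongFamilies(eb, trait = tr)
            data.frame(trait = tr, varG = v$varG, varRes = v$varRes,
                H = h@H, ciLower = h@ci[1], ciUpper = h@ci[2],
                eBar = h@eBar, amongFamilyProportion = af$proportion)
        })
        be1 <- beL[[1]]
        files <- c(
            .writeTsv(data.frame(block = names(blockEffects(be1)),
                                 blup = unname(blockEffects(be1))),
                      file.path(outDir, "block_effects.tsv")),
            .writeTsv(entryBlups(eb), file.path(outDir,
                                                "entry_blups.tsv")),
            .writeTsv(do.call(rbind, rows),
                      file.path(outDir, "varcomp.tsv")))
        obj$blockEffects <- beL
        obj$entryBlups <- eb
        addStage("blup", "done", files,
                 list(nEntries = length(unique(entryBlups(eb)$entry))))
    }) else addStage("blup", "skipped")

    if (isTRUE(config$stages$gwas)) runStage("gwas", {
        say("[gwas] family-nested random-effect genome scan")
        cfgS <- scanConfig(config$gwas$window, config$gwas$threshold)
        scans <- list()
        files <- character(0)
        for (tr in traitNames(obj$entryBlups)) {
            sc2 <- genomeScan(obj$entryBlups, obj$popFiltered,
                              cfgS, trait = tr, verbose = verbose)
            scans[[tr]] <- sc2
            eff <- familyEffects(sc2)
            wide <- cbind(scanTable(sc2),
                          stats::setNames(as.data.frame(t(eff)),
                                          paste0("alpha_", rownames(eff))))
            files <- c(files, .writeTsv(wide,
                file.path(outDir, paste0("scan_", tr, ".tsv"))))
        }
        metaPath <- file.path(outDir, "scan_meta.json")
        jsonlite::write_json(list(config = cfgS, seed = config$seed),
                             metaPath, auto_unbox = TRUE)
        obj$scans <- scans
        addStage("gwas", "done", c(files, metaPath),
                 list(nMarkersScanned = nrow(scanTable(scans[[1]]))))
    }) else addStage("gwas", "skipped")

    if (isTRUE(config$stages$bins) && isTRUE(config$stages$gwas))
        runStage("bins", {
        say("[bins] MTA regions and founder-group summaries")
        gap <- config$bins$gap
        regions <- do.call(rbind, lapply(obj$scans, significantRegions,
                                         gap = gap))
        bins <- crossTraitBins(regions, gap = gap)
        effL <- lapply(obj$scans, function(s)
            estimateFamilyEffects(s, obj$popFiltered,
                                  onlySignificant = TRUE))
        eff <- do.call(rbind, effL)
        files <- c(.writeTsv(regions, file.path(outDir, "regions.tsv")),
                   .writeTsv(bins, file.path(outDir, "bins.tsv")))
        if (!is.null(eff) && nrow(eff[!is.na(eff$effect), ]) > 0) {
            gs <- groupEffectSummary(eff)
            files <- c(files, .writeTsv(gs$groupMeans,
                file.path(outDir, "effect_summary.tsv")))
        }
        obj$regions <- regions
        obj$bins <- bins
        addStage("bins", "done", files,
                 list(nRegions = nrow(regions), nBins = nrow(bins)))
    }) else addStage("bins", "skipped")

    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(manifest, "objects") <- obj
    invisible(manifest)
}

# True genotypic values of parent lines under an architecture: parents
# are homozygous, so each is scored like a RIL fixed for its own
# alleles.
.parentValues <- function(panel, arch, parents) {
    haps <- haplotypes(panel)
    common <- commonParent(panel)
    traits <- traitNames(arch)
    out <- matrix(0, length(parents), length(traits),
                  dimnames = list(parents, traits))
    for (tr in traits) {
        a <- traitQtl(arch, tr)
        for (pid in setdiff(parents, common)) {
            seg <- haps[a$qtl, pid] != haps[a$qtl, common]
            out[pid, tr] <- sum(a$effects[pid, a$qtl][seg])
        }
    }
    out
}

.truthTable <- function(arch) {
    rows <- list()
    for (tr in traitNames(arch)) {
        a <- traitQtl(arch, tr)
        for (q in a$qtl)
            rows[[length(rows) + 1L]] <- data.frame(trait = tr,
                marker = q, founder = rownames(a$effects),
                effect = a$effects[, q], stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    yaml::write_yaml(config, tmp)
    unname(tools::md5sum(tmp))
}
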