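#' Design a multi-environment augmented incomplete-block trial
#'
#' Splits each family's RILs into sets of 35, augments every set with
#' the family's two parents (the common parent and the family founder)
#' and three check varieties, and assigns the 40-entry sets to
#' incomplete blocks within environments. RIL slots left over when a
#' family's size is not divisible by 35 are filled with a check
#' variety. Environment coverage may be unbalanced: each environment
#' evaluates either all sets or a configured number of randomly chosen
#' sets. Each evaluated set forms one block within its environment, and
#' every environment receives one Julian planting date.
#'
#' @param pop a [RILPopulation-class].
#' @param checks character vector of at least 3 check variety ids. When
#'   more than 3 are given, each set receives the first check plus two
#'   sampled from the rest (mirroring the uneven check distribution of
#'   real augmented trials).
#' @param nEnvironments number of environments.
#' @param setsEvaluated \code{"all"}, or an integer vector (recycled to
#'   \code{nEnvironments}) giving the number of sets evaluated per
#'   environment.
#' @param plantingDateModel list with \code{mean} and \code{sd} of the
#'   Julian planting day (rounded, one date per environment).
#' @param setSize RILs per set before augmentation (default 35).
#' @param seed optional RNG seed.
#' @return A [TrialDesign-class].
#' @export
designTrial <- function(pop, checks, nEnvironments,
                        setsEvaluated = "all",
                        plantingDateModel = list(mean = 140, sd = 7),
                        setSize = 35L, seed = NULL) {
    stopifnot(is(pop, "RILPopulation"))
    checks <- as.character(checks)
    if (length(checks) < 3L) stop("at least 3 check varieties required")
    if (nEnvironments < 1L) stop("nEnvironments must be positive")
    if (!is.null(seed)) set.seed(seed)

    cd <- colData(pop)
    common <- if (!is.null(metadata(pop)$founderPanel))
        commonParent(metadata(pop)$founderPanel) else "common_parent"

    pickChecks <- function() {
        if (length(checks) == 3L) checks
        else c(checks[1], sample(checks[-1], 2L))
    }

    sets <- list()
    si <- 0L
    for (famId in unique(cd$family)) {
        rils <- rownames(cd)[cd$family == famId]
        founder <- cd$founder[cd$family == famId][1]
        nSets <- ceiling(length(rils) / setSize)
        idx <- split(sample(rils), rep(seq_len(nSets),
                     each = setSize, length.out = length(rils)))
        for (j in seq_len(nSets)) {
            si <- si + 1L
            setId <- sprintf("set_%03d", si)
            members <- idx[[j]]
            pad <- setSize - length(members)
            chk <- pickChecks()
            # short sets: fill empty RIL slots with further check plots
            padChk <- if (pad > 0)
                chk[rep_len(seq_along(chk), pad)] else character(0)
            sets[[si]] <- data.frame(
                set = setId, family = famId,
                entry = c(members, common, founder, chk, padChk),
                type = c(rep("ril", length(members)), "parent", "parent",
                         rep("check", 3L + pad)),
                stringsAsFactors = FALSE)
        }
    }
    sets <- do.call(rbind, sets)
    allSets <- unique(sets$set)

    if (identical(setsEvaluated, "all")) {
        nEval <- rep(length(allSets), nEnvironments)
    } else {
        nEval <- rep_len(as.integer(setsEvaluated), nEnvironments)
        if (any(nEval < 1L | nEval > length(allSets)))
            stop("setsEvaluated out of range")
    }
    pdate <- round(stats::rnorm(nEnvironments, plantingDateModel$mean,
                                plantingDateModel$sd))

    layout <- list()
    for (e in seq_len(nEnvironments)) {
        envId <- sprintf("env_%02d", e)
        evalSets <- if (nEval[e] == length(allSets)) allSets
                    else sample(allSets, nEval[e])
        for (s in sample(evalSets)) {
            mem <- sets[sets$set == s, ]
            ord <- sample(nrow(mem))             # randomize within set
            layout[[length(layout) + 1L]] <- data.frame(
                environment = envId, set = s,
                block = paste0(envId, "_", s),
                entry = mem$entry[ord], type = mem$type[ord],
                plantingDate = pdate[e], stringsAsFactors = FALSE)
        }
    }
    layout <- do.call(rbind, layout)
    layout <- cbind(plot = sprintf("plot_%06d", seq_len(nrow(layout))),
                    layout)
    new("TrialDesign", layout = layout, sets = sets)
}

#' Simulate plot-level phenotypes on a trial design
#'
#' Each plot value is grand mean + environment effect + block effect +
#' entry genotypic value + planting-date slope x (date - mean date) +
#' residual, with independent normal environment, block and residual
#' effects. Check entries receive fixed true values. A configured
#' fraction of plots is dropped completely at random. A trait named
#' \code{"lodging"} is truncated to the 1-5 scoring scale.
#'
#' @param design a [TrialDesign-class].
#' @param genValues entries x traits matrix of true genotypic values
#'   for all RIL and parent entries (from [geneticValues()], with
#'   parents added, or any matrix with matching rownames).
#' @param grandMean named numeric, per-trait grand mean.
#' @param varEnv,varBlk,varRes named numeric (recycled across traits if
#'   scalar): environment, block and residual variance components.
#' @param slope named numeric, planting-date covariate slope per trait
#'   (trait units per day).
#' @param checkValues checks x traits matrix of fixed check values;
#'   defaults to the per-trait grand mean (value 0 deviation).
#' @param missingRate fraction of plots dropped at random.
#' @param seed optional RNG seed.
#' @return A [PlotTable-class].
#' @export
simulatePlots <- function(design, genValues, grandMean, varEnv = 0,
                          varBlk = 0, varRes = 0, slope = 0,
                          checkValues = NULL, missingRate = 0,
                          seed = NULL) {
    stopifnot(is(design, "TrialDesign"))
    traits <- colnames(genValues)
    if (is.null(traits)) stop("genValues must have trait column names")
    expand <- function(x, what) {
        x <- if (length(x) == 1L && is.null(names(x)))
            stats::setNames(rep(x, length(traits)), traits) else x
        if (!all(traits %in% names(x)))
            stop(what, " must be named per trait")
        if (what != "slope" && what != "grandMean" && any(x < 0))
            stop("negative variance components rejected (", what, ")")
        x[traits]
    }
    grandMean <- expand(grandMean, "grandMean")
    varEnv <- expand(varEnv, "varEnv")
    varBlk <- expand(varBlk, "varBlk")
    varRes <- expand(varRes, "varRes")
    slope <- expand(slope, "slope")
    if (!is.null(seed)) set.seed(seed)

    ly <- trialLayout(design)
    nonCheck <- unique(ly$entry[ly$type != "check"])
    miss <- setdiff(nonCheck, rownames(genValues))
    if (length(miss))
        stop("genotypic values missing for entries: ",
             paste(utils::head(miss, 5), collapse = ", "))
    chks <- unique(ly$entry[ly$type == "check"])
    if (is.null(checkValues)) {
        checkValues <- matrix(0, length(chks), length(traits),
                              dimnames = list(chks, traits))
    }
    g <- rbind(genValues[, traits, drop = FALSE],
               checkValues[setdiff(chks, rownames(genValues)), traits,
                           drop = FALSE])

    envs <- unique(ly$environment)
    blks <- unique(ly$block)
    dateCenter <- mean(ly$plantingDate)
    vals <- matrix(NA_real_, nrow(ly), length(traits),
                   dimnames = list(NULL, traits))
    for (tr in traits) {
        envEff <- stats::setNames(stats::rnorm(length(envs), 0,
                                  sqrt(varEnv[tr])), envs)
        blkEff <- stats::setNames(stats::rnorm(length(blks), 0,
                                  sqrt(varBlk[tr])), blks)
        res <- stats::rnorm(nrow(ly), 0, sqrt(varRes[tr]))
        v <- grandMean[tr] + envEff[ly$environment] + blkEff[ly$block] +
            g[ly$entry, tr] + slope[tr] * (ly$plantingDate - dateCenter) +
            res
        if (tr == "lodging") v <- pmin(pmax(v, 1), 5)
        vals[, tr] <- v
    }
    plots <- cbind(ly[c("plot", "entry", "type", "environment", "set",
                        "block", "plantingDate")],
                   as.data.frame(vals))
    fam <- stats::setNames(trialSets(design)$family, trialSets(design)$set)
    plots$family <- fam[plots$set]
    if (missingRate > 0)
        plots <- plots[stats::runif(nrow(plots)) >= missingRate, ,
                       drop = FALSE]
    rownames(plots) <- NULL
    new("PlotTable", plots = plots, traits = traits)
}
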