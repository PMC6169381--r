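#' @importFrom lme4 lmer lmerControl VarCorr ranef fixef
NULL

.quietLmer <- function(formula, data) {
    withCallingHandlers(
        lmer(formula, data = data, REML = TRUE,
             control = lmerControl(check.conv.singular = "ignore",
                                   calc.derivs = FALSE)),
        message = function(m) invokeRestart("muffleMessage"))
}

#' Stage 1: shrunken block effects from check plots
#'
#' Fits the check/block mixed model on check plots only: fixed check
#' means and a fixed planting-date covariate (centred at the mean
#' plot date), with blocks as iid random effects. Returns REML
#' variance components, check BLUEs, the planting-date slope, and
#' shrunken block BLUPs for all requested blocks; blocks without any
#' check observation are shrunk fully to zero.
#'
#' @param plots a [PlotTable-class] (check rows are selected
#'   internally) or a data.frame of check plots.
#' @param trait trait column to analyse.
#' @param allBlocks optional character vector of block ids that must
#'   receive a BLUP (defaults to the blocks present).
#' @return A [BlockEffectEstimates-class].
#' @export
fitCheckBlockModel <- function(plots, trait, allBlocks = NULL) {
    df <- if (is(plots, "PlotTable")) {
        p <- plotData(plots)
        if (is.null(allBlocks)) allBlocks <- unique(p$block)
        p[p$type == "check", ]
    } else plots
    df <- df[!is.na(df[[trait]]), ]
    if (is.null(allBlocks)) allBlocks <- unique(df$block)
    if (length(unique(df$block)) < 2L)
        stop("unidentifiable: need >= 2 blocks with check data ",
             "(all check observations fall in a single block)")
    if (max(table(df$entry)) < 2L)
        stop("at least one check needs 2+ observations")
    # the check/block incidence graph must be connected, else check
    # (fixed) and block effects are confounded
    inc <- unique(df[c("entry", "block")])
    comp <- stats::setNames(seq_along(unique(inc$entry)),
                            unique(inc$entry))
    blkChecks <- split(as.character(inc$entry), inc$block)
    repeat {
        changed <- FALSE
        for (chks in blkChecks) {
            m <- min(comp[chks])
            if (any(comp[chks] != m)) {
                comp[comp %in% comp[chks]] <- m
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    if (length(unique(comp)) > 1L)
        stop("unidentifiable: check effects confounded with blocks")
    dateCenter <- mean(df$plantingDate)
    df$pdateC <- df$plantingDate - dateCenter
    df$entry <- factor(df$entry)
    hasSlope <- length(unique(df$pdateC)) > 1L
    fml <- if (hasSlope) y ~ 0 + entry + pdateC + (1 | block)
           else y ~ 0 + entry + (1 | block)
    df$y <- df[[trait]]
    fit <- .quietLmer(fml, df)
    vc <- as.data.frame(VarCorr(fit))
    varBlk <- vc$vcov[vc$grp == "block"]
    varRes <- vc$vcov[vc$grp == "Residual"]
    fe <- fixef(fit)
    checkBlues <- fe[grep("^entry", names(fe))]
    names(checkBlues) <- sub("^entry", "", names(checkBlues))
    slope <- if (hasSlope) unname(fe["pdateC"]) else 0
    slopeSE <- if (hasSlope)
        sqrt(diag(as.matrix(stats::vcov(fit)))[["pdateC"]]) else NA_real_
    re <- ranef(fit)$block
    blups <- stats::setNames(rep(0, length(allBlocks)), allBlocks)
    blups[rownames(re)] <- re[[1]]
    new("BlockEffectEstimates", blockBlups = blups,
        checkBlues = checkBlues,
        beta = c(intercept = unname(mean(checkBlues)), pldate = slope),
        slopeSE = slopeSE, varBlk = varBlk, varRes = varRes,
        dateCenter = dateCenter)
}

#' Stage 2: entry BLUPs and genotypic variance components
#'
#' Fits, per trait, the entry mixed model on non-check plots (RILs and
#' parents): fixed covariates for planting date and the stage-1
#' shrunken block value (each with its own estimated slope), and iid
#' random entry effects. Returns REML variance components and entry
#' BLUPs; entries observed in a single plot are retained (strongly
#' shrunk), entries with no data are absent from the output.
#'
#' @param plots a [PlotTable-class].
#' @param blockEffects a single [BlockEffectEstimates-class] (applied
#'   to all traits) or a named list with one element per trait.
#' @param traits traits to analyse (default: all in \code{plots}).
#' @return An [EntryBlups-class].
#' @export
fitEntryModel <- function(plots, blockEffects, traits = NULL) {
    stopifnot(is(plots, "PlotTable"))
    if (is.null(traits)) traits <- traitNames(plots)
    p <- plotData(plots)
    p <- p[p$type != "check", ]
    getBE <- function(tr) {
        if (is(blockEffects, "BlockEffectEstimates")) blockEffects
        else blockEffects[[tr]]
    }
    blupL <- list(); vcL <- list(); envL <- list()
    for (tr in traits) {
        be <- getBE(tr)
        df <- p[!is.na(p[[tr]]), ]
        if (nrow(df) == 0L) stop("trait ", tr, " has no non-missing plots")
        df$y <- df[[tr]]
        df$pdateC <- df$plantingDate - be@dateCenter
        bb <- blockEffects(be)
        df$blkVal <- ifelse(df$block %in% names(bb), bb[df$block], 0)
        df$entry <- factor(df$entry)
        terms <- "1"
        if (length(unique(df$pdateC)) > 1L) terms <- c(terms, "pdateC")
        if (length(unique(df$blkVal)) > 1L) terms <- c(terms, "blkVal")
        fml <- stats::as.formula(paste("y ~", paste(terms, collapse = "+"),
                                       "+ (1 | entry)"))
        fit <- .quietLmer(fml, df)
        vc <- as.data.frame(VarCorr(fit))
        fe <- fixef(fit)
        re <- ranef(fit)$entry
        blupL[[tr]] <- data.frame(entry = rownames(re), trait = tr,
                                  blup = re[[1]], stringsAsFactors = FALSE)
        vcL[[tr]] <- data.frame(
            trait = tr,
            varG = vc$vcov[vc$grp == "entry"],
            varRes = vc$vcov[vc$grp == "Residual"],
            intercept = unname(fe["(Intercept)"]),
            betaPldate = if ("pdateC" %in% names(fe))
                unname(fe["pdateC"]) else 0,
            betaBlk = if ("blkVal" %in% names(fe))
                unname(fe["blkVal"]) else 0,
            stringsAsFactors = FALSE)
        ec <- tapply(df$environment, df$entry,
                     function(e) length(unique(e)))
        envL[[tr]] <- data.frame(entry = names(ec), trait = tr,
                                 nEnv = as.integer(ec),
                                 stringsAsFactors = FALSE)
    }
    info <- unique(p[c("entry", "family", "type")])
    rownames(info) <- NULL
    new("EntryBlups", blups = do.call(rbind, c(blupL,
            list(make.row.names = FALSE))),
        varcomp = do.call(rbind, c(vcL, list(make.row.names = FALSE))),
        envCounts = do.call(rbind, c(envL, list(make.row.names = FALSE))),
        entryInfo = info)
}

#' Broad-sense heritability with harmonic-mean replication
#'
#' Entry-mean basis: H = varG / (varG + varRes / eBar), with eBar the
#' harmonic mean of the per-entry environment counts. Family-mean
#' basis: H = varAmong / (varAmong + varWithin / nBar +
#' varRes / (nBar * eBar)), with nBar the harmonic mean family size.
#' Confidence bounds use the F-quantile construction on entry-mean
#' replication: (1 - H) * F_obs follows an F distribution with
#' (groups - 1, groups * (eBar - 1)) degrees of freedom, where
#' F_obs = 1 / (1 - H).
#'
#' @param varG genotypic variance among entries (entry basis) — unused
#'   on the family basis.
#' @param varRes residual variance.
#' @param envCounts per-entry environment counts (positive).
#' @param basis "entry_mean" or "family_mean".
#' @param varAmong,varWithin among-family and within-family genotypic
#'   variances (family basis only).
#' @param familySizes per-family entry counts (family basis only).
#' @param level confidence level (default 0.95).
#' @return A [HeritabilityEstimate-class].
#' @examples
#' heritability(4, 2, envCounts = rep(4, 50))  # H = 4 / 4.5
#' @export
heritability <- function(varG, varRes, envCounts,
                         basis = c("entry_mean", "family_mean"),
                         varAmong = NULL, varWithin = NULL,
                         familySizes = NULL, level = 0.95) {
    basis <- match.arg(basis)
    if (length(envCounts) == 0L) stop("empty environment count vector")
    if (any(envCounts <= 0)) stop("environment counts must be positive")
    if (varRes < 0 || (basis == "entry_mean" && varG < 0))
        stop("variance components must be non-negative")
    eBar <- harmonicMean(envCounts)
    if (basis == "entry_mean") {
        denom <- varG + varRes / eBar
        H <- if (denom > 0) varG / denom else 0
        nGrp <- length(envCounts)
        nBar <- NA_real_
    } else {
        if (is.null(varAmong) || is.null(varWithin) ||
            is.null(familySizes))
            stop("family basis needs varAmong, varWithin and familySizes")
        nBar <- harmonicMean(familySizes)
        denom <- varAmong + varWithin / nBar + varRes / (nBar * eBar)
        H <- if (denom > 0) varAmong / denom else 0
        nGrp <- length(familySizes)
    }
    alpha <- 1 - level
    df1 <- max(1L, nGrp - 1L)
    df2 <- max(1L, round(nGrp * (eBar - 1)))
    Fobs <- 1 / max(1 - H, .Machine$double.eps)
    lo <- 1 - stats::qf(1 - alpha / 2, df1, df2) / Fobs
    hi <- 1 - stats::qf(alpha / 2, df1, df2) / Fobs
    ci <- c(min(max(lo, 0), H), max(min(hi, 1), H))
    new("HeritabilityEstimate", H = H, basis = basis, ci = ci,
        eBar = eBar, nBar = nBar)
}

#' Proportion of genotypic variance among families
#'
#' One-way random-effects decomposition of genotypic values (entry
#' BLUPs or true values) into among-family and within-family variance;
#' returns among / (among + within).
#'
#' @param values named numeric genotypic values, or an
#'   [EntryBlups-class] (with \code{trait} given).
#' @param family per-value family labels (matched by name when
#'   \code{values} is a named vector).
#' @param trait trait id when \code{values} is an EntryBlups.
#' @return list with \code{proportion}, \code{varAmong},
#'   \code{varWithin}.
#' @export
varianceAmongFamilies <- function(values, family = NULL, trait = NULL) {
    if (is(values, "EntryBlups")) {
        if (is.null(trait)) stop("trait required for an EntryBlups input")
        v <- blupVector(values, trait)
        info <- entryInfo(values)
        fm <- stats::setNames(info$family, info$entry)
        keep <- names(v)[info[match(names(v), info$entry), "type"] == "ril"]
        v <- v[keep]
        family <- fm[keep]
    } else {
        v <- values
        if (!is.null(names(v)) && !is.null(names(family)))
            family <- family[names(v)]
    }
    if (length(unique(family)) < 2L)
        stop("undefined: at least 2 families required")
    df <- data.frame(y = as.numeric(v), family = as.character(family))
    fit <- .quietLmer(y ~ 1 + (1 | family), df)
    vc <- as.data.frame(VarCorr(fit))
    among <- vc$vcov[vc$grp == "family"]
    within <- vc$vcov[vc$grp == "Residual"]
    list(proportion = among / (among + within), varAmong = among,
         varWithin = within)
}

#' Genotypic correlations between traits
#'
#' Product-moment correlations of entry BLUPs across traits, computed
#' on the intersection of entries with BLUPs for every trait pair.
#'
#' @param blups an [EntryBlups-class] with at least 2 traits.
#' @param traits traits to include (default all).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
geneticCorrelations <- function(blups, traits = NULL) {
    stopifnot(is(blups, "EntryBlups"))
    if (is.null(traits)) traits <- traitNames(blups)
    if (length(traits) < 2L) stop("at least 2 traits required")
    vl <- lapply(traits, function(tr) blupVector(blups, tr))
    shared <- Reduce(intersect, lapply(vl, names))
    if (length(shared) < 3L) stop("fewer than 3 shared entries")
    m <- vapply(vl, function(v) v[shared], numeric(length(shared)))
    colnames(m) <- traits
    stats::cor(m)
}
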