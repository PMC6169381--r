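#' @useDynLib NAMtools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' VanRaden genomic relationship matrix
#'
#' K = Zc Zc' / c with Zc the column-centred allele-dose matrix
#' (missing doses filled with the marker mean) and c = sum(2 p (1-p))
#' over the included markers. An optional marker set (e.g. a linkage
#' window) is excluded from the computation.
#'
#' @param x a [RILPopulation-class], or an entries x markers dose
#'   matrix (0/1/2, NA allowed).
#' @param exclude marker ids to leave out.
#' @return A [KinshipMatrix-class].
#' @export
computeKinship <- function(x, exclude = NULL) {
    X <- if (is(x, "RILPopulation")) t(doseMatrix(x)) else as.matrix(x)
    if (!is.null(exclude)) {
        keep <- setdiff(colnames(X), exclude)
        if (length(keep) == 0L) stop("all markers excluded")
        X <- X[, keep, drop = FALSE]
    }
    p <- colMeans(X, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(X)) > 0))
        X[is.na(X[, j]), j] <- 2 * p[j]
    cc <- sum(2 * p * (1 - p))
    if (cc <= 0) stop("no segregating markers: VanRaden scale is zero")
    Zc <- sweep(X, 2, 2 * p)
    K <- tcrossprod(Zc) / cc
    new("KinshipMatrix", K = K, scale = cc,
        excluded = as.character(exclude %||% character(0)))
}

#' Genome-scan configuration
#'
#' @param window linkage-window half-width in cM: markers within this
#'   distance of the tested marker are excluded from the relationship
#'   matrix. The default 5 cM preserves power at the tested locus
#'   while keeping the polygenic control intact; 0 means no exclusion
#'   (the tested marker remains in K).
#' @param threshold significance threshold on -log10(p); the default 3
#'   bounds the experiment-wide false-positive probability at 0.1 for
#'   up to 100 tested 5-cM regions (Bonferroni).
#' @param pMethod label of the p-value method (restricted likelihood
#'   ratio with the 50:50 chi-square boundary mixture).
#' @param polygenic keep the kinship polygenic term (default TRUE);
#'   FALSE pins sigma2_phi at zero (diagnostic use, e.g. comparing a
#'   single-family scan against plain marker regression).
#' @return validated config list.
#' @export
scanConfig <- function(window = 5, threshold = 3,
                       pMethod = "RLRT 0.5*chisq(0) + 0.5*chisq(1)",
                       polygenic = TRUE) {
    if (window < 0) stop("window must be >= 0")
    if (threshold <= 0) stop("threshold must be > 0")
    list(window = window, threshold = threshold, pMethod = pMethod,
         polygenic = isTRUE(polygenic))
}

# Precompute everything reusable across markers for one (pop, y) pair:
# centred dose matrix, eigenbasis of the full cross-product, rotated
# response/intercept, per-family founder-allele doses.
.scanContext <- function(pop, y) {
    entries <- intersect(names(y), colnames(pop))
    if (length(entries) < 10L)
        stop("fewer than 10 entries shared between BLUPs and genotypes")
    pop <- pop[, entries]
    y <- y[entries]
    X <- t(doseMatrix(pop))                     # entries x markers
    p <- colMeans(X, na.rm = TRUE) / 2
    Xf <- X
    for (j in which(colSums(is.na(Xf)) > 0))
        Xf[is.na(Xf[, j]), j] <- 2 * p[j]
    contrib <- 2 * p * (1 - p)
    Zc <- sweep(Xf, 2, 2 * p)
    S <- tcrossprod(Zc)
    eg <- eigen(S, symmetric = TRUE)
    d <- pmax(eg$values, 0)

    panel <- metadata(pop)$founderPanel
    if (is.null(panel)) stop("population carries no founder panel")
    haps <- haplotypes(panel)
    common <- commonParent(panel)
    founder <- colData(pop)$founder
    fam <- colData(pop)$family
    famIds <- unique(fam)
    # founder-allele dose (scale 0/0.5/1) per entry and marker
    fdAl <- haps[rownames(doseMatrix(pop)), founder, drop = FALSE]
    cmAl <- haps[rownames(doseMatrix(pop)), common]
    Draw <- doseMatrix(pop)
    FD <- ifelse(fdAl == 1L, Draw, 2L - Draw) / 2
    FD[fdAl == cmAl] <- 0                        # not segregating by design

    map <- getMap(pop)
    # fixed effects: per-family intercepts, so allele-substitution
    # effects are estimated from within-family dose contrasts and
    # family-mean differences cannot masquerade as marker effects
    Xmat <- vapply(famIds, function(f) as.numeric(fam == f),
                   numeric(length(fam)))
    if (!is.matrix(Xmat)) Xmat <- matrix(Xmat, nrow = length(fam))
    list(entries = entries, y = y, fam = fam, famIds = famIds,
         Zc = Zc, contrib = contrib, cFull = sum(contrib),
         U = eg$vectors, d = d,
         ytil = drop(crossprod(eg$vectors, y)),
         Xtil = crossprod(eg$vectors, Xmat),
         FD = t(FD), rawDose = X, map = map,
         constResponse = stats::sd(y) == 0)
}

# Fit null (no marker effect) and full scan models for one marker by
# REML, using the low-rank window downdate in the full eigenbasis.
.scanOne <- function(ctx, mi, config) {
    map <- ctx$map
    mk <- markerIds(map)[mi]
    n <- length(ctx$y)
    famIds <- ctx$famIds
    q0 <- length(famIds)
    # callers drop entries with a missing genotype at the tested marker
    # before building the context, so fd is complete here
    fd <- ctx$FD[, mi]
    fd[is.na(fd)] <- 0
    estimable <- vapply(famIds, function(f) {
        v <- ctx$FD[ctx$fam == f, mi]
        v <- v[!is.na(v)]
        length(unique(v)) >= 2L
    }, logical(1))
    rec <- data.frame(marker = mk, chromosome = map@chromosome[mi],
                      bp = map@bp[mi], cM = map@cM[mi],
                      negLog10P = 0, sigma2Alpha = 0, sigma2Phi = NA_real_,
                      sigma2Eps = NA_real_, mu = NA_real_,
                      nFamEstimable = sum(estimable), status = "ok",
                      stringsAsFactors = FALSE)
    alpha <- pev <- stats::setNames(rep(NA_real_, q0), famIds)
    if (!any(estimable)) {
        rec$status <- "monomorphic"
        return(list(rec = rec, alpha = alpha, pev = pev))
    }
    if (ctx$constResponse) {
        alpha[estimable] <- 0
        pev[estimable] <- 0
        rec$status <- "constant_response"
        return(list(rec = rec, alpha = alpha, pev = pev))
    }

    win <- config$window
    wIdx <- if (win > 0)
        which(map@chromosome == map@chromosome[mi] &
              abs(map@cM - map@cM[mi]) <= win) else integer(0)
    cm <- ctx$cFull - sum(ctx$contrib[wIdx])
    if (cm <= 1e-10) {
        rec$status <- "window_covers_genome"
        return(list(rec = rec, alpha = alpha, pev = pev))
    }

    W <- matrix(0, n, sum(estimable))
    for (k in seq_len(sum(estimable))) {
        f <- famIds[estimable][k]
        sel <- ctx$fam == f
        W[sel, k] <- fd[sel]
    }
    q <- ncol(W)
    Bnull <- if (length(wIdx))
        crossprod(ctx$U, ctx$Zc[, wIdx, drop = FALSE])
        else matrix(0, n, 0)
    Bfull <- cbind(crossprod(ctx$U, W), Bnull)

    usePoly <- !identical(config$polygenic, FALSE)
    fnull <- function(lp) {
        if (abs(lp) > 32) return(Inf)
        .remlEval(0, lp, ctx$d, ctx$ytil, ctx$Xtil, Bnull, 0L, cm)$obj
    }
    onull <- if (usePoly) stats::optimize(fnull, c(-18, 18), tol = 1e-6)
             else list(minimum = -30, objective = fnull(-30))
    ffull <- function(par) {
        if (max(abs(par)) > 32) return(Inf)
        .remlEval(par[1], par[2], ctx$d, ctx$ytil, ctx$Xtil, Bfull,
                  q, cm)$obj
    }
    ofull <- if (usePoly) {
        stats::optim(c(log(0.1), onull$minimum), ffull,
                     method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-10))
    } else {
        o1 <- stats::optimize(function(la) ffull(c(la, -30)),
                              c(-18, 18), tol = 1e-8)
        list(par = c(o1$minimum, -30), value = o1$objective)
    }
    lrt <- max(0, onull$objective - ofull$value)
    pval <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, 1,
                                                     lower.tail = FALSE)
    fit <- .remlEval(ofull$par[1], ofull$par[2], ctx$d, ctx$ytil,
                     ctx$Xtil, Bfull, q, cm, blup = TRUE)
    rec$negLog10P <- -log10(pval)
    rec$sigma2Alpha <- fit$s2a
    rec$sigma2Phi <- fit$s2p
    rec$sigma2Eps <- fit$s2e
    rec$mu <- mean(fit$beta)
    alpha[estimable] <- fit$alpha
    pev[estimable] <- fit$pev
    list(rec = rec, alpha = alpha, pev = pev)
}

#' Scan a single marker
#'
#' Fits the family-nested random allele-substitution model at one
#' marker: entry BLUPs regressed on family-specific founder-allele
#' doses (random, one effect per family in which the marker
#' segregates) with a polygenic term whose relationship matrix
#' excludes markers inside the linkage window around the tested
#' marker. The p-value tests sigma2_alpha = 0 by restricted likelihood
#' ratio against the 50:50 chi-square(0)/chi-square(1) boundary
#' mixture. Effects are reported on the homozygous-substitution scale
#' (founder genotype minus common-parent genotype).
#'
#' @param marker marker id.
#' @param blups named numeric entry BLUPs (or an [EntryBlups-class]
#'   plus \code{trait}).
#' @param pop a [RILPopulation-class] carrying its founder panel.
#' @param config a [scanConfig()] list.
#' @param trait trait id when \code{blups} is an EntryBlups.
#' @return one-row list: \code{rec} (scan record), \code{alpha} and
#'   \code{pev} (named per-family vectors, NA = not estimable).
#' @export
scanMarker <- function(marker, blups, pop, config = scanConfig(),
                       trait = NULL) {
    y <- if (is(blups, "EntryBlups")) blupVector(blups, trait) else blups
    mi0 <- match(marker, rownames(doseMatrix(pop)))
    if (is.na(mi0)) stop("marker not on map: ", marker)
    keep <- colnames(pop)[!is.na(doseMatrix(pop)[mi0, ])]
    ctx <- .scanContext(pop[, keep], y[intersect(names(y), keep)])
    mi <- match(marker, markerIds(ctx$map))
    .scanOne(ctx, mi, config)
}

#' Family-nested random-effect genome scan
#'
#' Applies the per-marker scan model to every marker (or a supplied
#' subset), reusing one eigendecomposition of the full genomic
#' cross-product so that the per-marker linkage-window exclusion is a
#' cheap low-rank downdate. Entries with a missing genotype at the
#' tested marker are dropped for that marker's fit. Per-marker
#' failures are returned as flagged records; the scan never aborts.
#'
#' @param blups named numeric entry BLUPs, or an [EntryBlups-class]
#'   (then give \code{trait}).
#' @param pop a [RILPopulation-class] carrying its founder panel.
#' @param config a [scanConfig()] list.
#' @param trait trait id (label for the result; required for an
#'   EntryBlups input).
#' @param markers marker ids to test (default: all).
#' @param verbose log progress every 50 markers.
#' @return A [GwasScanResult-class].
#' @export
genomeScan <- function(blups, pop, config = scanConfig(), trait = NULL,
                       markers = NULL, verbose = FALSE) {
    y <- if (is(blups, "EntryBlups")) blupVector(blups, trait) else blups
    if (is.null(trait)) trait <- "trait"
    ctx <- .scanContext(pop, y)
    ids <- markerIds(ctx$map)
    if (is.null(markers)) markers <- ids
    mis <- match(markers, ids)
    if (anyNA(mis))
        stop("markers not on map: ",
             paste(markers[is.na(mis)], collapse = ", "))
    recs <- vector("list", length(mis))
    alpha <- pev <- matrix(NA_real_, length(ctx$famIds), length(mis),
                           dimnames = list(ctx$famIds, markers))
    hasNA <- colSums(is.na(ctx$rawDose)) > 0
    for (k in seq_along(mis)) {
        mi <- mis[k]
        res <- tryCatch({
            if (hasNA[mi]) {
                keep <- !is.na(ctx$rawDose[, mi])
                subctx <- .scanContext(pop[, ctx$entries[keep]],
                                       ctx$y[keep])
                .scanOne(subctx, mi, config)
            } else .scanOne(ctx, mi, config)
        }, error = function(e) {
            rec <- data.frame(marker = markers[k],
                chromosome = ctx$map@chromosome[mi],
                bp = ctx$map@bp[mi], cM = ctx$map@cM[mi],
                negLog10P = NA_real_, sigma2Alpha = NA_real_,
                sigma2Phi = NA_real_, sigma2Eps = NA_real_,
                mu = NA_real_, nFamEstimable = 0L,
                status = paste("error:", conditionMessage(e)),
                stringsAsFactors = FALSE)
            list(rec = rec,
                 alpha = stats::setNames(rep(NA_real_,
                     length(ctx$famIds)), ctx$famIds),
                 pev = stats::setNames(rep(NA_real_,
                     length(ctx$famIds)), ctx$famIds))
        })
        recs[[k]] <- res$rec
        alpha[names(res$alpha), k] <- res$alpha
        pev[names(res$pev), k] <- res$pev
        if (verbose && k %% 50 == 0)
            message(sprintf("[scan %s] %d/%d markers", trait, k,
                            length(mis)))
    }
    scan <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
    new("GwasScanResult", trait = trait, scan = scan, effects = alpha,
        pev = pev, config = config)
}

#' Per-family allele-substitution effect table
#'
#' Long-format table of the scan's family effects with founder-group
#' annotation. Positive effects mean the founder allele raises the
#' trait relative to the common-parent allele; not-estimable entries
#' (marker not segregating in the family) are kept as NA.
#'
#' @param scan a [GwasScanResult-class].
#' @param pop the scanned [RILPopulation-class] (for founder ids and
#'   groups).
#' @param onlySignificant restrict to markers at or above the scan's
#'   significance threshold.
#' @return data.frame: marker, family, founder, group, effect, pev,
#'   negLog10P.
#' @export
estimateFamilyEffects <- function(scan, pop, onlySignificant = FALSE) {
    stopifnot(is(scan, "GwasScanResult"))
    eff <- familyEffects(scan)
    st <- scanTable(scan)
    if (onlySignificant) {
        keep <- !is.na(st$negLog10P) &
            st$negLog10P >= scan@config$threshold
        st <- st[keep, ]
        eff <- eff[, st$marker, drop = FALSE]
    }
    cd <- unique(as.data.frame(colData(pop))[c("family", "founder")])
    panel <- metadata(pop)$founderPanel
    grp <- founderGroups(panel)
    fmap <- stats::setNames(cd$founder, cd$family)
    out <- expand.grid(family = rownames(eff), marker = colnames(eff),
                       stringsAsFactors = FALSE)
    out$founder <- fmap[out$family]
    out$group <- unname(grp[out$founder])
    out$effect <- eff[cbind(out$family, out$marker)]
    out$pev <- scan@pev[cbind(out$family, out$marker)]
    out$negLog10P <- st$negLog10P[match(out$marker, st$marker)]
    out[order(out$marker, out$family), ]
}
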