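devVec <- function(x) as.vector(x)    # strip tapply's array shape

# balanced check/block dataset: nChk checks x nBlk blocks x r reps
balancedCheckData <- function(nChk = 2, nBlk = 10, r = 3, varBlk = 4,
                              varRes = 1, seed = 1) {
    set.seed(seed)
    blocks <- sprintf("b%02d", seq_len(nBlk))
    chk <- sprintf("chk%d", seq_len(nChk))
    df <- expand.grid(entry = chk, block = blocks, rep = seq_len(r),
                      stringsAsFactors = FALSE)
    blkEff <- stats::setNames(stats::rnorm(nBlk, 0, sqrt(varBlk)), blocks)
    chkEff <- stats::setNames(seq_len(nChk) * 2, chk)
    df$plantingDate <- 140
    df$y <- 10 + chkEff[df$entry] + blkEff[df$block] +
        stats::rnorm(nrow(df), 0, sqrt(varRes))
    df$type <- "check"
    df
}


# balanced entry dataset: n entries x r reps in one block/environment
balancedEntryData <- function(n = 200, r = 4, varG = 3, varRes = 1,
                              seed = 3) {
    set.seed(seed)
    ent <- sprintf("e%03d", seq_len(n))
    g <- stats::setNames(stats::rnorm(n, 0, sqrt(varG)), ent)
    df <- expand.grid(entry = ent, rep = seq_len(r),
                      stringsAsFactors = FALSE)
    df$environment <- paste0("env", df$rep)
    df$block <- paste0("blk", df$rep)
    df$plantingDate <- 140
    df$family <- "famA"
    df$type <- "ril"
    df$plot <- seq_len(nrow(df))
    df$y <- 5 + g[df$entry] + stats::rnorm(nrow(df), 0, sqrt(varRes))
    list(df = df, g = g)
}

zeroBlockEffects <- function(blocks) {
    new("BlockEffectEstimates",
        blockBlups = stats::setNames(rep(0, length(blocks)), blocks),
        checkBlues = c(chk = 0), beta = c(intercept = 0, pldate = 0),
        slopeSE = NA_real_, varBlk = 0, varRes = 1, dateCenter = 140)
}

asPlotTable <- function(df) new("PlotTable", plots = df, traits = "y")

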