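`%||%` <- function(a, b) if (is.null(a)) b else a

#' Harmonic mean
#'
#' @param x positive values.
#' @return length(x) / sum(1/x).
#' @examples
#' harmonicMean(c(2, 4, 4))  # 3
#' @export
harmonicMean <- function(x) {
    if (length(x) == 0L) stop("empty vector")
    if (any(x <= 0)) stop("harmonic mean requires positive values")
    length(x) / sum(1 / x)
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed.
deriveSeeds <- function(seed, k) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, k)
}
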