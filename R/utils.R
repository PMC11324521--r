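# Internal helpers shared across modules.

# Extract a counts-like matrix from SCE / SummarizedExperiment / matrix input.
.getCounts <- function(x, assay = "counts") {
    if (is(x, "SummarizedExperiment"))
        return(SummarizedExperiment::assay(x, assay))
    x
}

# Per-cell annotation as a data.frame, from SCE colData or a supplied table.
.getAnnotation <- function(x, ann = NULL) {
    if (is.null(ann) && is(x, "SummarizedExperiment"))
        ann <- as.data.frame(SummarizedExperiment::colData(x))
    if (is.null(ann))
        stop("per-cell annotation required (SCE colData or 'ann' argument)")
    ann
}

# Deterministic per-stage seed derivation, kept below 2^31.
.deriveSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

# Clamp p-values away from zero for log-based combination.
.clampP <- function(p) {
    if (any(p <= 0)) {
        message(sum(p <= 0), " zero p-value(s) clamped to smallest ",
                "representable positive value")
        p <- pmax(p, .Machine$double.xmin)
    }
    p
}

# Population / sample row standard deviations of a dense matrix.
.rowSds <- function(m, sample = TRUE) {
    mu <- rowMeans(m)
    ss <- rowSums((m - mu)^2)
    denom <- if (sample) ncol(m) - 1L else ncol(m)
    sqrt(ss / denom)
}

.asDense <- function(x) as.matrix(x)
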