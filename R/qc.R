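# Variant quality control and genotype normalization.

#' Variant QC thresholds
#'
#' @param mafMin minimum minor allele frequency (variants below are removed).
#' @param hwePMin minimum Hardy-Weinberg equilibrium p-value.
#' @param maxMissingRate maximum per-variant missing fraction. The removal
#'   criterion is missingness *greater than* this bound (the standard
#'   reading; removing variants with low missingness would discard
#'   well-called data).
#' @param removeAmbiguous drop strand-ambiguous A/T and C/G variants.
#' @return a classed list of thresholds for [applyQc()].
#' @export
qcThresholds <- function(mafMin = 0.01, hwePMin = 1e-6,
                         maxMissingRate = 0.05, removeAmbiguous = TRUE) {
    stopifnot(mafMin >= 0, mafMin <= 1, hwePMin >= 0, hwePMin <= 1,
              maxMissingRate >= 0, maxMissingRate <= 1,
              is.logical(removeAmbiguous))
    structure(list(mafMin = mafMin, hwePMin = hwePMin,
                   maxMissingRate = maxMissingRate,
                   removeAmbiguous = removeAmbiguous),
              class = "QcThresholds")
}

#' Estimate allele frequencies
#'
#' Allele1 frequency per variant: (sum of non-missing dosages) /
#' (2 x number of non-missing calls).
#'
#' @param g a [GenotypeMatrix-class] or a dosage matrix with NA for missing.
#' @return numeric vector of frequencies in \[0, 1\].
#' @export
estimateFrequencies <- function(g) {
    d <- if (is(g, "GenotypeMatrix")) dosages(g) else g
    nObs <- colSums(!is.na(d))
    if (any(nObs == 0)) {
        which0 <- which(nObs == 0)
        ids <- if (is(g, "GenotypeMatrix")) variants(g)$id[which0]
               else as.character(which0)
        stop("variant(s) with all calls missing: ",
             paste(utils::head(ids, 10), collapse = ", "))
    }
    colSums(d, na.rm = TRUE) / (2 * nObs)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the expected proportions (p^2, 2pq, q^2) with p estimated from
#' the counts. Monomorphic variants return p-value 1 by convention.
#'
#' @param counts numeric vector or 3-column matrix of genotype counts
#'   (n_AA, n_Aa, n_aa), where A is allele1.
#' @return p-value(s).
#' @export
hweTest <- function(counts) {
    if (is.null(dim(counts)))
        counts <- matrix(counts, nrow = 1)
    stopifnot(ncol(counts) == 3)
    n <- rowSums(counts)
    if (any(n <= 0)) stop("total genotype count must be positive")
    p <- (2 * counts[, 1] + counts[, 2]) / (2 * n)
    q <- 1 - p
    expd <- cbind(p^2, 2 * p * q, q^2) * n
    mono <- p == 0 | p == 1
    chi <- rep(0, length(n))
    ok <- !mono
    if (any(ok))
        chi[ok] <- rowSums((counts[ok, , drop = FALSE] -
                            expd[ok, , drop = FALSE])^2 /
                           expd[ok, , drop = FALSE])
    pv <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
    pv[mono] <- 1
    pv
}

.genotypeCounts <- function(d) {
    cbind(colSums(d == 2, na.rm = TRUE),
          colSums(d == 1, na.rm = TRUE),
          colSums(d == 0, na.rm = TRUE))
}

.AMBIGUOUS <- c("A:T", "T:A", "C:G", "G:C")

#' Apply variant quality control
#'
#' Removes variants failing, in order: minor allele frequency below
#' `mafMin`; HWE chi-square p-value below `hwePMin`; missing fraction above
#' `maxMissingRate`; strand-ambiguous allele pair (A/T or C/G). A variant
#' may fail several rules; the report records the first-failing rule per
#' variant and the total per rule.
#'
#' @param g a [GenotypeMatrix-class].
#' @param thresholds a [qcThresholds()] list.
#' @return the filtered [GenotypeMatrix-class]; attribute `qcReport` is a
#'   data.frame (rule, firstFailing, totalFailing) plus `kept`/`removed`
#'   counts in attributes.
#' @export
applyQc <- function(g, thresholds = qcThresholds()) {
    stopifnot(is(g, "GenotypeMatrix"))
    d <- dosages(g)
    v <- variants(g)
    n <- nrow(d)
    nObs <- colSums(!is.na(d))
    p <- ifelse(nObs > 0, colSums(d, na.rm = TRUE) / (2 * pmax(nObs, 1)), 0)
    maf <- pmin(p, 1 - p)
    failMaf <- maf < thresholds$mafMin | nObs == 0
    hwp <- rep(1, ncol(d))
    if (any(nObs > 0))
        hwp[nObs > 0] <- hweTest(.genotypeCounts(d)[nObs > 0, , drop = FALSE])
    failHwe <- hwp < thresholds$hwePMin
    missRate <- 1 - nObs / n
    failMiss <- missRate > thresholds$maxMissingRate
    pair <- paste(v$allele1, v$allele2, sep = ":")
    failAmb <- if (thresholds$removeAmbiguous) pair %in% .AMBIGUOUS
               else rep(FALSE, ncol(d))
    fails <- cbind(maf = failMaf, hwe = failHwe,
                   missing = failMiss, ambiguous = failAmb)
    first <- apply(fails, 1, function(z) if (any(z)) which(z)[1] else 0L)
    keep <- first == 0L
    if (!any(keep))
        stop("quality control removed every variant; relax the thresholds")
    report <- data.frame(rule = colnames(fails),
                         firstFailing = tabulate(first, nbins = 4),
                         totalFailing = colSums(fails))
    rownames(report) <- NULL
    out <- g[, which(keep)]
    attr(out, "qcReport") <- report
    attr(out, "kept") <- sum(keep)
    attr(out, "removed") <- sum(!keep)
    out
}

#' Normalize genotypes to the standardized scale
#'
#' Each dosage is transformed to z = (g - 2p) / sqrt(2 p (1 - p)); missing
#' dosages contribute exactly 0 (the normalized-scale mean). When `p` is
#' omitted it is estimated from `g` itself; supplying discovery frequencies
#' keeps a target cohort on the discovery coordinate system.
#'
#' @param g a [GenotypeMatrix-class] or dosage matrix.
#' @param p optional allele1 frequencies to use verbatim (one per variant,
#'   strictly inside (0, 1)).
#' @return a [NormalizedGenotypes-class].
#' @export
normalizeGenotypes <- function(g, p = NULL) {
    d <- if (is(g, "GenotypeMatrix")) dosages(g) else g
    own <- is.null(p)
    if (own)
        p <- estimateFrequencies(d)
    if (length(p) != ncol(d))
        stop("need one frequency per variant: got ", length(p),
             " for ", ncol(d), " variants")
    degenerate <- p <= 0 | p >= 1
    if (any(degenerate)) {
        ids <- if (is(g, "GenotypeMatrix"))
            variants(g)$id[degenerate] else as.character(which(degenerate))
        stop("cannot normalize monomorphic variant(s) (p of 0 or 1): ",
             paste(utils::head(ids, 10), collapse = ", "))
    }
    z <- scale(d, center = 2 * p, scale = sqrt(2 * p * (1 - p)))
    attributes(z)[c("scaled:center", "scaled:scale")] <- NULL
    z[is.na(z)] <- 0
    new("NormalizedGenotypes", values = z, frequencies = as.numeric(p),
        frequencySource = if (own) "own" else "external")
}
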