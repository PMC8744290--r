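# Conventional clumping + thresholding PRS with PC-adjusted marginal
# effects: S_i = sum_{j in S1} beta_j g_ij on raw dosages.

#' Marginal variant effects adjusted for leading principal components
#'
#' Computes the top `nPcs` left singular vectors of the normalized
#' discovery matrix, then regresses the phenotype on each variant's dosage
#' with an intercept and those PCs as covariates. With nPcs = 0 this is
#' exactly [marginalAssoc()].
#'
#' @param g discovery [GenotypeMatrix-class].
#' @param y phenotype (named or in sample order).
#' @param nPcs number of principal-component covariates (default 10).
#' @return the [marginalAssoc()] table (id, slope, se, t, p, zeroVariance).
#' @export
conventionalEffects <- function(g, y, nPcs = 10) {
    stopifnot(is(g, "GenotypeMatrix"))
    n <- nSamples(g)
    if (nPcs >= n) stop("nPcs must be smaller than the sample size")
    if (n <= nPcs + 2) stop("need n > nPcs + 2 samples")
    if (!is.null(names(y))) {
        ord <- match(sampleIds(g), names(y))
        if (anyNA(ord)) stop("phenotype missing for some samples")
        y <- as.numeric(y[ord])
    }
    covariates <- NULL
    if (nPcs > 0) {
        z <- normalizeGenotypes(g)
        factors <- spectralSvd(z, kMax = nPcs)
        covariates <- factors@U[, seq_len(nPcs), drop = FALSE]
    }
    marginalAssoc(g, y, covariates = covariates)
}

#' Fit the conventional clumping + thresholding PRS
#'
#' Effects come from [conventionalEffects()] (marginal regression with
#' `nPcs` principal components as covariates, computed on the post-QC,
#' pre-clump matrix); clumping and thresholding use the resulting p-values.
#'
#' @param g discovery [GenotypeMatrix-class].
#' @param y phenotype.
#' @param config a [selectionConfig()].
#' @param nPcs principal-component covariates (default 10).
#' @param qc [qcThresholds()] or NULL to skip.
#' @return a [ConventionalPrsModel-class].
#' @export
trainConventional <- function(g, y, config = selectionConfig(), nPcs = 10,
                              qc = qcThresholds()) {
    stopifnot(is(g, "GenotypeMatrix"))
    if (!is.null(names(y))) {
        ord <- match(sampleIds(g), names(y))
        if (anyNA(ord)) stop("phenotype missing for some samples")
        y <- as.numeric(y[ord])
    }
    if (!is.null(qc))
        g <- applyQc(g, qc)
    assoc <- conventionalEffects(g, y, nPcs = nPcs)
    idx <- clumpVariants(assoc, g, config = config)
    sel <- thresholdSelect(assoc, idx, config$theta)
    vtab <- variants(g)[sel, , drop = FALSE]
    vtab$freq <- estimateFrequencies(g[, sel])
    vtab$beta <- assoc$slope[sel]
    vtab$p <- assoc$p[sel]
    rownames(vtab) <- NULL
    new("ConventionalPrsModel", variants = vtab, nPcs = as.integer(nPcs),
        config = list(rho = config$rho, theta = config$theta,
                      windowKb = config$windowKb, clumpP1 = config$clumpP1,
                      nDiscovery = nSamples(g)))
}

#' Score a target cohort with conventional PRS weights
#'
#' S_i = sum_{j in S1} beta_j g_ij on raw target dosages, after harmonizing
#' target variants to the model (allele swaps flip g -> 2 - g). Missing
#' dosages are replaced by the discovery mean dosage 2 p_j.
#'
#' @param target a [GenotypeMatrix-class].
#' @param model a [ConventionalPrsModel-class].
#' @return data.frame (`iid`, `score`) with attribute
#'   `method = "conventional"`.
#' @export
ctScore <- function(target, model) {
    stopifnot(is(target, "GenotypeMatrix"),
              is(model, "ConventionalPrsModel"))
    map <- harmonizeVariants(model@variants, variants(target))
    map <- map[order(map$discoveryIndex), ]
    aligned <- alignTarget(target, map, discovery = model@variants)
    d <- matrix(as.double(dosages(aligned)), nSamples(aligned))
    freq <- model@variants$freq[map$discoveryIndex]
    if (anyNA(d)) {
        idx <- which(is.na(d), arr.ind = TRUE)
        d[idx] <- 2 * freq[idx[, 2]]
    }
    s <- as.numeric(d %*% model@variants$beta[map$discoveryIndex])
    structure(data.frame(iid = sampleIds(target), score = s),
              method = "conventional")
}
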