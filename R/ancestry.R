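# Reference-panel ancestry assignment: PCA on a merged (reference + query)
# cohort, Fisher linear discriminant on the top PCs of the labeled
# reference samples, posterior-probability thresholding.

#' Fit a merged-PCA Fisher discriminant ancestry model
#'
#' PCA (via the Gram-matrix route of [spectralSvd()]) is run on the merged
#' normalized genotype matrix; a linear discriminant with shared pooled
#' covariance and equal class priors is fit on the labeled samples'
#' top-`nPcs` coordinates. Query samples (label NA) contribute to the PCA
#' but not to the discriminant.
#'
#' @param g merged [GenotypeMatrix-class] (reference and query samples,
#'   harmonized and QC'd).
#' @param labels character vector of reference labels (e.g. AFR/EUR), NA
#'   for query samples; either in sample order or named by iid.
#' @param nPcs number of principal components used as predictors
#'   (default 20).
#' @param priorEqual use equal class priors (default) rather than reference
#'   class proportions.
#' @param threshold default posterior threshold stored in the model.
#' @return an [AncestryModel-class].
#' @export
fitAncestryModel <- function(g, labels, nPcs = 20, priorEqual = TRUE,
                             threshold = 0.9) {
    stopifnot(is(g, "GenotypeMatrix"))
    if (!is.null(names(labels)))
        labels <- labels[match(sampleIds(g), names(labels))]
    labels <- as.character(labels)
    if (length(labels) != nSamples(g))
        stop("one label (or NA) per sample required")
    ref <- which(!is.na(labels))
    classes <- sort(unique(labels[ref]))
    if (length(classes) < 2)
        stop("need at least two labeled classes in the reference panel")
    sizes <- table(labels[ref])
    if (any(sizes < nPcs + 1))
        stop("class(es) with fewer than nPcs + 1 = ", nPcs + 1,
             " members (singular within-class scatter): ",
             paste(names(sizes)[sizes < nPcs + 1], collapse = ", "))
    nPcs <- as.integer(nPcs)
    z <- normalizeGenotypes(g)
    factors <- spectralSvd(z, kMax = nPcs)
    scores <- factors@U[, seq_len(nPcs), drop = FALSE]
    colnames(scores) <- paste0("PC", seq_len(nPcs))
    rownames(scores) <- sampleIds(g)
    prior <- if (priorEqual) rep(1 / length(classes), length(classes))
             else as.numeric(sizes[classes] / sum(sizes))
    ldaFit <- MASS::lda(scores[ref, , drop = FALSE],
                        grouping = factor(labels[ref], levels = classes),
                        prior = prior)
    basis <- list(V = rightVectors(z, factors, seq_len(nPcs)),
                  lambdas = factors@lambdas[seq_len(nPcs)],
                  mUsed = factors@mUsed,
                  variants = cbind(variants(g), freq = frequencies(z)))
    new("AncestryModel", lda = ldaFit, nPcs = nPcs, classes = classes,
        scores = scores, basis = basis, threshold = threshold)
}

#' PC coordinates of samples under an ancestry model
#'
#' Samples that were part of the merged PCA are looked up directly (the
#' standard route); new cohorts can be projected out-of-sample through the
#' stored right singular vectors, as in [projectTarget()].
#'
#' @param model an [AncestryModel-class].
#' @param samples character iids (merged-PCA lookup) or a
#'   [GenotypeMatrix-class] (out-of-sample projection).
#' @return matrix of PC coordinates (one row per sample).
#' @export
ancestryCoordinates <- function(model, samples) {
    if (is.character(samples)) {
        hit <- match(samples, rownames(model@scores))
        if (anyNA(hit))
            stop("sample(s) not in the merged PCA: ",
                 paste(utils::head(samples[is.na(hit)], 5), collapse = ", "))
        return(model@scores[hit, , drop = FALSE])
    }
    stopifnot(is(samples, "GenotypeMatrix"))
    map <- harmonizeVariants(model@basis$variants, variants(samples))
    if (nrow(map) < nrow(model@basis$variants))
        stop("query cohort is missing model variants; harmonize first")
    map <- map[order(map$discoveryIndex), ]
    aligned <- alignTarget(samples, map, discovery = model@basis$variants)
    b <- normalizeGenotypes(aligned, p = model@basis$variants$freq)
    u <- (normValues(b) %*% model@basis$V) / sqrt(model@basis$mUsed)
    u <- sweep(u, 2, model@basis$lambdas, `/`)
    colnames(u) <- paste0("PC", seq_len(ncol(u)))
    rownames(u) <- sampleIds(samples)
    u
}

#' Assign ancestry labels by thresholded LDA posteriors
#'
#' Computes Gaussian discriminant posteriors for each sample's PC
#' coordinates; a sample gets the argmax class if its posterior exceeds the
#' threshold, otherwise "unassigned".
#'
#' @param model an [AncestryModel-class].
#' @param coords PC-coordinate matrix (e.g. from [ancestryCoordinates()]),
#'   columns matching the model's predictors.
#' @param threshold posterior threshold (default: the model's stored value).
#' @return data.frame (`iid`, `label`, `posterior`, plus one posterior
#'   column per class).
#' @export
assignAncestry <- function(model, coords, threshold = NULL) {
    if (is.null(threshold)) threshold <- model@threshold
    coords <- as.matrix(coords)
    if (!all(is.finite(coords)))
        stop("non-finite PC coordinates")
    if (ncol(coords) != model@nPcs)
        stop("coordinates must have ", model@nPcs, " columns")
    colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
    post <- stats::predict(model@lda, newdata = as.data.frame(coords))$posterior
    best <- max.col(post, ties.method = "first")
    bestP <- post[cbind(seq_len(nrow(post)), best)]
    label <- ifelse(bestP > threshold, model@classes[best], "unassigned")
    ids <- if (!is.null(rownames(coords))) rownames(coords)
           else as.character(seq_len(nrow(coords)))
    out <- data.frame(iid = ids, label = label, posterior = bestP)
    cbind(out, as.data.frame(post))
}
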