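#' @import methods
NULL

#' GenotypeMatrix: additive genotype dosages with sample and variant metadata
#'
#' Container for an n x m matrix of hard-call dosages coded 0/1/2 (copies of
#' allele1, the counted/effect allele) with `NA` for missing calls, plus a
#' sample table and a variant table mirroring PLINK .fam/.bim content.
#'
#' @slot dosages integer matrix, samples in rows, variants in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @slot samples data.frame with at least columns `fid` and `iid`;
#'   `iid` values are unique.
#' @slot variants data.frame with columns `chrom`, `id`, `cm`, `pos`,
#'   `allele1`, `allele2`; `id` values are unique, `pos` is 1-based bp.
#'
#' @export
setClass("GenotypeMatrix",
         representation(dosages = "matrix",
                        samples = "data.frame",
                        variants = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    d <- object@dosages
    if (!is.numeric(d))
        msg <- c(msg, "dosages must be a numeric matrix")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
        msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
    if (nrow(d) != nrow(object@samples))
        msg <- c(msg, "nrow(dosages) != nrow(samples)")
    if (ncol(d) != nrow(object@variants))
        msg <- c(msg, "ncol(dosages) != nrow(variants)")
    if (!all(c("fid", "iid") %in% names(object@samples)))
        msg <- c(msg, "samples needs columns fid, iid")
    need <- c("chrom", "id", "pos", "allele1", "allele2")
    if (!all(need %in% names(object@variants)))
        msg <- c(msg, paste("variants needs columns:",
                            paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(object@variants$id))
            msg <- c(msg, "variant ids must be unique")
        if (any(object@variants$pos <= 0))
            msg <- c(msg, "variant positions must be positive")
        if (any(!nzchar(object@variants$allele1)) ||
            any(!nzchar(object@variants$allele2)))
            msg <- c(msg, "allele strings must be nonempty")
    }
    if (anyDuplicated(object@samples$iid))
        msg <- c(msg, "sample iids must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric/integer matrix of 0/1/2/NA dosages (samples x
#'   variants).
#' @param samples data.frame with columns `fid`, `iid`, or a character vector
#'   of sample ids (used for both fid and iid).
#' @param variants data.frame with columns `chrom`, `id`, `pos`, `allele1`,
#'   `allele2` (a `cm` column is added as 0 when absent).
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' g <- GenotypeMatrix(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'                     samples = c("s1", "s2"),
#'                     variants = data.frame(chrom = "1", id = c("v1", "v2"),
#'                                           pos = c(100L, 200L),
#'                                           allele1 = "A", allele2 = "G"))
#' nVariants(g)
#' @export
GenotypeMatrix <- function(dosages, samples, variants) {
    if (is.character(samples))
        samples <- data.frame(fid = samples, iid = samples)
    if (is.null(variants$cm))
        variants$cm <- 0
    variants <- variants[, c("chrom", "id", "cm", "pos",
                             "allele1", "allele2"),
                         drop = FALSE]
    variants$chrom <- as.character(variants$chrom)
    variants$id <- as.character(variants$id)
    variants$allele1 <- as.character(variants$allele1)
    variants$allele2 <- as.character(variants$allele2)
    storage.mode(dosages) <- "integer"
    rownames(samples) <- NULL
    rownames(variants) <- NULL
    new("GenotypeMatrix", dosages = dosages,
        samples = samples, variants = variants)
}

#' NormalizedGenotypes: frequency-standardized genotype matrix
#'
#' Holds Z with entries (g - 2p) / sqrt(2 p (1 - p)); missing dosages
#' contribute exactly 0. The allele frequencies used for centering and
#' scaling are retained so a target cohort can be normalized with the
#' discovery frequencies (keeping both cohorts in one coordinate system).
#'
#' @slot values numeric matrix, samples x variants.
#' @slot frequencies numeric vector of allele1 frequencies used per variant.
#' @slot frequencySource "own" when estimated from the same matrix,
#'   "external" when supplied (e.g. discovery frequencies applied to a
#'   target).
#' @export
setClass("NormalizedGenotypes",
         representation(values = "matrix",
                        frequencies = "numeric",
                        frequencySource = "character"))

setValidity("NormalizedGenotypes", function(object) {
    msg <- character()
    if (!all(is.finite(object@values)))
        msg <- c(msg, "all normalized values must be finite")
    if (length(object@frequencies) != ncol(object@values))
        msg <- c(msg, "one frequency per variant required")
    if (any(object@frequencies <= 0 | object@frequencies >= 1))
        msg <- c(msg, "frequencies must lie strictly in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' SvdFactors: left singular system of the scaled genotype matrix
#'
#' Eigen-decomposition of the genetic relatedness matrix K = Z Z^T / m.
#' `lambdas` are singular values of Z / sqrt(m), i.e. sqrt of the eigenvalues
#' of K; under this scaling the bulk of the spectrum for an unstructured
#' cohort sits near 1 and the null EigenCorr cutoff 0.1 is meaningful.
#'
#' @slot U numeric matrix of left singular vectors (columns unit norm,
#'   orthogonal, sign fixed so each column's largest-magnitude entry is
#'   positive).
#' @slot lambdas nonincreasing, nonnegative singular values of Z/sqrt(m).
#' @slot sigma eigenvalues of K (lambdas^2).
#' @slot mUsed the variant count baked into the 1/sqrt(m) scaling.
#' @export
setClass("SvdFactors",
         representation(U = "matrix", lambdas = "numeric",
                        sigma = "numeric", mUsed = "integer"))

setValidity("SvdFactors", function(object) {
    msg <- character()
    if (length(object@lambdas) != ncol(object@U))
        msg <- c(msg, "one singular value per column of U")
    if (is.unsorted(rev(object@lambdas)))
        msg <- c(msg, "lambdas must be nonincreasing")
    if (any(object@lambdas < 0))
        msg <- c(msg, "lambdas must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' SvdPrsModel: fitted SVD-projection PRS model
#'
#' Everything needed to score an independent target cohort: the selected
#' component set S, effect sizes gamma_k, right singular vectors v_k,
#' singular values lambda_k, the discovery variant list with the allele
#' frequencies used for normalization, and the selection configuration.
#' Individual-level discovery genotypes and phenotypes are deliberately
#' absent, so sharing a model does not share the cohort.
#'
#' @slot components integer vector S of selected component indices, ordered
#'   by decreasing squared EigenCorr.
#' @slot gammas least-squares effects for the components in S.
#' @slot mu intercept of the component regression (stored, not added to
#'   scores unless requested).
#' @slot V m x |S| matrix of right singular vectors for S.
#' @slot lambdas singular values (of Z/sqrt(m)) for S.
#' @slot variants discovery variant table restricted to the variants behind
#'   the decomposition, with a `freq` column of discovery frequencies.
#' @slot eigenCorr the full EigenCorr ranking table from the fit.
#' @slot config list: rho, theta, windowKb, clumpP1, cutoff, kMax, nDiscovery.
#' @export
setClass("SvdPrsModel",
         representation(components = "integer", gammas = "numeric",
                        mu = "numeric", V = "matrix", lambdas = "numeric",
                        variants = "data.frame", eigenCorr = "data.frame",
                        config = "list"))

setValidity("SvdPrsModel", function(object) {
    msg <- character()
    k <- length(object@components)
    if (k == 0)
        msg <- c(msg, "component set S must be nonempty")
    if (length(object@gammas) != k || ncol(object@V) != k ||
        length(object@lambdas) != k)
        msg <- c(msg, "gammas, V and lambdas must align with components")
    if (any(object@lambdas <= 0))
        msg <- c(msg, "selected components must have positive singular value")
    if (nrow(object@V) != nrow(object@variants))
        msg <- c(msg, "V rows must match the variant list")
    if (is.null(object@variants$freq))
        msg <- c(msg, "variant table needs a freq column")
    vnorm <- sqrt(colSums(object@V^2))
    if (length(vnorm) && any(abs(vnorm - 1) > 1e-6))
        msg <- c(msg, "V columns must be unit norm")
    if (length(msg)) msg else TRUE
})

#' ConventionalPrsModel: clumping + thresholding PRS weights
#'
#' Per-variant marginal effects (optionally adjusted for leading principal
#' components) for the selected variant set S1, applied to raw target
#' dosages.
#'
#' @slot variants selected variant table with columns `freq` (discovery
#'   allele1 frequency, used as 2p mean imputation at scoring time),
#'   `beta` and `p`.
#' @slot nPcs number of principal-component covariates used when estimating
#'   the marginal effects.
#' @slot config list: rho, theta, windowKb, clumpP1, nDiscovery.
#' @export
setClass("ConventionalPrsModel",
         representation(variants = "data.frame", nPcs = "integer",
                        config = "list"))

setValidity("ConventionalPrsModel", function(object) {
    msg <- character()
    need <- c("chrom", "pos", "id", "allele1", "allele2", "freq", "beta")
    if (!all(need %in% names(object@variants)))
        msg <- c(msg, paste("variant table needs columns:",
                            paste(need, collapse = ", ")))
    else if (!all(is.finite(object@variants$beta)))
        msg <- c(msg, "effects must be finite")
    if (length(msg)) msg else TRUE
})

#' AncestryModel: merged-PCA Fisher discriminant ancestry classifier
#'
#' Principal components are computed on a merged (reference + query)
#' normalized genotype matrix; a linear discriminant with shared pooled
#' covariance and equal class priors is fit on the labeled reference
#' samples' top PC coordinates.
#'
#' @slot lda fitted `MASS::lda` object on the reference coordinates.
#' @slot nPcs number of principal components used as predictors.
#' @slot classes class labels in the reference panel.
#' @slot scores PC coordinates (merged decomposition) for every sample in
#'   the merged matrix, rownames = sample iid.
#' @slot basis list with elements `V`, `lambdas`, `mUsed`, `variants`
#'   (with `freq`), allowing out-of-sample projection of new cohorts.
#' @slot threshold default posterior-probability threshold for assignment.
#' @export
setClass("AncestryModel",
         representation(lda = "ANY", nPcs = "integer", classes = "character",
                        scores = "matrix", basis = "list",
                        threshold = "numeric"))
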