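#' @describeIn GenotypeMatrix dosage matrix accessor
#' @param x object
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @describeIn GenotypeMatrix variant table accessor
#' @export
setMethod("variants", "GenotypeMatrix", function(x) x@variants)

#' @describeIn SvdPrsModel variant table (with discovery frequencies)
#' @param x object
#' @export
setMethod("variants", "SvdPrsModel", function(x) x@variants)

#' @describeIn ConventionalPrsModel selected variants with weights
#' @param x object
#' @export
setMethod("variants", "ConventionalPrsModel", function(x) x@variants)

#' @describeIn GenotypeMatrix sample table accessor
#' @export
setMethod("sampleInfo", "GenotypeMatrix", function(x) x@samples)

#' @describeIn GenotypeMatrix sample id accessor
#' @export
setMethod("sampleIds", "GenotypeMatrix",
          function(x) as.character(x@samples$iid))

#' @describeIn GenotypeMatrix number of samples
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@dosages))

#' @describeIn GenotypeMatrix number of variants
#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) ncol(x@dosages))

#' @describeIn NormalizedGenotypes number of samples
#' @export
setMethod("nSamples", "NormalizedGenotypes", function(x) nrow(x@values))

#' @describeIn NormalizedGenotypes number of variants
#' @export
setMethod("nVariants", "NormalizedGenotypes", function(x) ncol(x@values))

#' @describeIn NormalizedGenotypes normalized matrix accessor
#' @param x object
#' @export
setMethod("normValues", "NormalizedGenotypes", function(x) x@values)

#' @describeIn NormalizedGenotypes frequency accessor
#' @export
setMethod("frequencies", "NormalizedGenotypes", function(x) x@frequencies)

#' @describeIn SvdFactors singular values of Z/sqrt(m)
#' @param x object
#' @export
setMethod("singularValues", "SvdFactors", function(x) x@lambdas)

#' @describeIn SvdPrsModel singular values of the selected components
#' @export
setMethod("singularValues", "SvdPrsModel", function(x) x@lambdas)

#' @describeIn SvdFactors left singular vectors
#' @export
setMethod("leftVectors", "SvdFactors", function(x) x@U)

#' @describeIn SvdPrsModel selected component indices
#' @export
setMethod("selectedComponents", "SvdPrsModel", function(x) x@components)

#' @describeIn SvdPrsModel component effects
#' @export
setMethod("gammas", "SvdPrsModel", function(x) x@gammas)

#' Subset a GenotypeMatrix by samples and/or variants
#'
#' @param x a [GenotypeMatrix-class]
#' @param i sample index (integer, logical or character iid)
#' @param j variant index (integer, logical or character id)
#' @param ... ignored
#' @param drop ignored; subsetting never drops dimensions
#' @return a [GenotypeMatrix-class]
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@dosages))
    if (missing(j)) j <- seq_len(ncol(x@dosages))
    if (is.character(i)) i <- match(i, x@samples$iid)
    if (is.character(j)) j <- match(j, x@variants$id)
    new("GenotypeMatrix",
        dosages = x@dosages[i, j, drop = FALSE],
        samples = x@samples[i, , drop = FALSE],
        variants = x@variants[j, , drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix:", nrow(object@dosages), "samples x",
        ncol(object@dosages), "variants\n")
    miss <- mean(is.na(object@dosages))
    cat(sprintf("  missing rate: %.4f\n", miss))
    chs <- unique(object@variants$chrom)
    cat("  chromosomes:", paste(utils::head(chs, 8), collapse = ", "),
        if (length(chs) > 8) "..." else "", "\n")
})

setMethod("show", "NormalizedGenotypes", function(object) {
    cat("NormalizedGenotypes:", nrow(object@values), "samples x",
        ncol(object@values), "variants ( frequencies:",
        object@frequencySource, ")\n")
})

setMethod("show", "SvdFactors", function(object) {
    k <- length(object@lambdas)
    cat("SvdFactors:", nrow(object@U), "samples,", k,
        "components, m =", object@mUsed, "\n")
    cat("  leading singular values (Z/sqrt(m)):",
        paste(sprintf("%.3f", utils::head(object@lambdas, 5)),
              collapse = ", "),
        if (k > 5) "..." else "", "\n")
})

setMethod("show", "SvdPrsModel", function(object) {
    cat("SvdPrsModel:", length(object@components),
        "components over", nrow(object@variants), "variants\n")
    cat("  S (by squared EigenCorr):",
        paste(object@components, collapse = ", "), "\n")
    cat(sprintf("  rho = %s, theta = %s, cutoff = %s\n",
                object@config$rho, object@config$theta,
                object@config$cutoff))
})

setMethod("show", "ConventionalPrsModel", function(object) {
    cat("ConventionalPrsModel:", nrow(object@variants),
        "variants,", object@nPcs, "PC covariates\n")
})

setMethod("show", "AncestryModel", function(object) {
    cat("AncestryModel:", length(object@classes), "classes (",
        paste(object@classes, collapse = ", "), ") on top",
        object@nPcs, "PCs; threshold", object@threshold, "\n")
})
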