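#' Access the dosage matrix
#' @param x a [GenotypeMatrix-class]
#' @return integer matrix of 0/1/2/NA dosages, samples x variants.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Access the variant table
#' @param x a [GenotypeMatrix-class] or fitted model
#' @return data.frame of per-variant metadata.
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' Access the sample table
#' @param x a [GenotypeMatrix-class]
#' @return data.frame with columns fid, iid.
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' Sample ids
#' @param x a [GenotypeMatrix-class]
#' @return character vector of sample iids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Number of samples
#' @param x a [GenotypeMatrix-class] or [NormalizedGenotypes-class]
#' @return integer count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Number of variants
#' @param x a [GenotypeMatrix-class] or [NormalizedGenotypes-class]
#' @return integer count.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' Normalized values
#' @param x a [NormalizedGenotypes-class]
#' @return numeric matrix Z.
#' @export
setGeneric("normValues", function(x) standardGeneric("normValues"))

#' Allele frequencies used for normalization
#' @param x a [NormalizedGenotypes-class]
#' @return numeric vector of allele1 frequencies.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' Singular values of the scaled matrix Z/sqrt(m)
#' @param x a [SvdFactors-class] or [SvdPrsModel-class]
#' @return numeric vector of singular values.
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' Left singular vectors (principal components)
#' @param x a [SvdFactors-class]
#' @return numeric matrix U.
#' @export
setGeneric("leftVectors", function(x) standardGeneric("leftVectors"))

#' Selected component set S
#' @param x a [SvdPrsModel-class]
#' @return integer vector of component indices, best-ranked first.
#' @export
setGeneric("selectedComponents",
           function(x) standardGeneric("selectedComponents"))

#' Component effect sizes gamma_k
#' @param x a [SvdPrsModel-class]
#' @return numeric vector aligned with [selectedComponents()].
#' @export
setGeneric("gammas", function(x) standardGeneric("gammas"))
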