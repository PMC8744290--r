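# Marginal association scan, greedy LD clumping, p-value thresholding.

#' Variant selection configuration
#'
#' @param rho LD r-squared threshold: a variant within the window whose r^2
#'   with the index variant exceeds `rho` is clumped away.
#' @param theta p-value threshold; variants with p < theta (strict) survive
#'   thresholding. 0.1 is the recommended default for feeding the SVD.
#' @param windowKb clump window half-width in kb; the window is closed
#'   (|pos difference| <= windowKb * 1000, same chromosome).
#' @param clumpP1 p-value ceiling for a variant to become a clump index
#'   (default 1: every variant is eligible).
#' @return a classed list for [clumpVariants()] and friends.
#' @export
selectionConfig <- function(rho = 0.1, theta = 0.1, windowKb = 500,
                            clumpP1 = 1) {
    stopifnot(rho > 0, rho <= 1, theta > 0, theta <= 1, windowKb > 0,
              clumpP1 > 0, clumpP1 <= 1)
    structure(list(rho = rho, theta = theta, windowKb = windowKb,
                   clumpP1 = clumpP1),
              class = "SelectionConfig")
}

# mean-impute missing dosages per column, returning a double matrix
.meanImpute <- function(d) {
    d <- matrix(as.double(d), nrow(d), ncol(d))
    if (anyNA(d)) {
        mu <- colMeans(d, na.rm = TRUE)
        idx <- which(is.na(d), arr.ind = TRUE)
        d[idx] <- mu[idx[, 2]]
    }
    d
}

#' Marginal linear association scan
#'
#' Ordinary least squares of the phenotype on each variant's dosage
#' separately, with an intercept and optional covariates. Missing dosages
#' are mean-imputed per variant (equivalently 0 on the normalized scale).
#' Two-sided t p-values use n - 2 - ncol(covariates) degrees of freedom.
#' Zero-variance variants are flagged with slope 0 and p = 1.
#'
#' @param g a [GenotypeMatrix-class], dosage matrix, or
#'   [NormalizedGenotypes-class].
#' @param y numeric phenotype; if named it is aligned to sample ids.
#' @param covariates optional numeric matrix of covariates (no intercept
#'   column; one row per sample).
#' @return data.frame with columns `id`, `slope`, `se`, `t`, `p`,
#'   `zeroVariance`.
#' @export
marginalAssoc <- function(g, y, covariates = NULL) {
    if (is(g, "GenotypeMatrix")) {
        x <- .meanImpute(dosages(g))
        ids <- variants(g)$id
        if (!is.null(names(y))) {
            ord <- match(sampleIds(g), names(y))
            if (anyNA(ord))
                stop("phenotype missing for sample(s): ",
                     paste(utils::head(sampleIds(g)[is.na(ord)], 5),
                           collapse = ", "))
            y <- as.numeric(y[ord])
        }
    } else if (is(g, "NormalizedGenotypes")) {
        x <- normValues(g)
        ids <- as.character(seq_len(ncol(x)))
    } else {
        x <- .meanImpute(g)
        ids <- if (!is.null(colnames(g))) colnames(g)
               else as.character(seq_len(ncol(g)))
    }
    y <- as.numeric(y)
    n <- nrow(x)
    if (length(y) != n) stop("phenotype length must equal sample count")
    nCov <- if (is.null(covariates)) 0L else ncol(covariates)
    if (n < nCov + 3)
        stop("need at least ", nCov + 3, " samples")
    if (stats::var(y) == 0) stop("phenotype has zero variance")
    if (is.null(covariates)) {
        xc <- scale(x, center = TRUE, scale = FALSE)
        yc <- y - mean(y)
    } else {
        q <- qr.Q(qr(cbind(1, covariates)))
        xc <- x - q %*% crossprod(q, x)
        yc <- as.numeric(y - q %*% crossprod(q, y))
    }
    sxx <- colSums(xc^2)
    zero <- sxx < .Machine$double.eps * n
    sxy <- as.numeric(crossprod(xc, yc))
    slope <- ifelse(zero, 0, sxy / ifelse(zero, 1, sxx))
    df <- n - 2L - nCov
    rss <- pmax(sum(yc^2) - slope^2 * sxx, 0)
    se <- sqrt(rss / df / ifelse(zero, 1, sxx))
    tstat <- ifelse(se > 0, slope / se, 0)
    # exact fits (rss == 0) get the largest representable |t|
    tstat[!zero & se == 0 & slope != 0] <- sign(slope[!zero & se == 0 &
                                                      slope != 0]) * Inf
    p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
    p[zero] <- 1
    se[zero] <- NA_real_
    data.frame(id = ids, slope = slope, se = se, t = tstat, p = p,
               zeroVariance = zero, row.names = NULL)
}

#' Squared Pearson LD between two dosage vectors
#'
#' Computed on mean-imputed raw dosages (PLINK-style). A zero-variance
#' vector yields r^2 = 0 with attribute `degenerate = TRUE` (it cannot be
#' clumped on).
#'
#' @param ga,gb dosage vectors of equal length (NA = missing).
#' @return squared correlation in \[0, 1\].
#' @export
ldR2 <- function(ga, gb) {
    stopifnot(length(ga) == length(gb))
    ga <- as.double(ga); gb <- as.double(gb)
    ga[is.na(ga)] <- mean(ga, na.rm = TRUE)
    gb[is.na(gb)] <- mean(gb, na.rm = TRUE)
    if (stats::var(ga) == 0 || stats::var(gb) == 0)
        return(structure(0, degenerate = TRUE))
    stats::cor(ga, gb)^2
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unprocessed variant with p <= clumpP1 as
#' an index and removes every unprocessed variant on the same chromosome
#' within the closed +/- window whose r^2 with the index exceeds `rho`.
#' Ties on p are broken by (chromosome, position, id). r^2 is computed on
#' mean-imputed raw dosages. After clumping, every retained pair within the
#' window has r^2 <= rho.
#'
#' @param assoc association table from [marginalAssoc()], aligned to
#'   `variants`.
#' @param g a [GenotypeMatrix-class] or dosage matrix supplying the dosages.
#' @param vtab variant table (defaulting to `variants(g)`).
#' @param config a [selectionConfig()].
#' @return integer vector of index-variant positions (columns of `g`), in
#'   genomic order.
#' @export
clumpVariants <- function(assoc, g, vtab = NULL, config = selectionConfig()) {
    if (is(g, "GenotypeMatrix")) {
        if (is.null(vtab)) vtab <- variants(g)
        d <- dosages(g)
    } else {
        d <- g
        if (is.null(vtab)) stop("vtab required when g is a plain matrix")
    }
    m <- ncol(d)
    stopifnot(nrow(assoc) == m, nrow(vtab) == m)
    x <- .meanImpute(d)
    win <- config$windowKb * 1000
    # deterministic processing order: p, then chrom, pos, id
    ord <- order(assoc$p, vtab$chrom, vtab$pos, vtab$id)
    state <- integer(m)  # 0 = unprocessed, 1 = index, -1 = clumped
    sds <- sqrt(colSums(scale(x, scale = FALSE)^2))
    for (j in ord) {
        if (state[j] != 0L) next
        if (assoc$p[j] > config$clumpP1) next
        state[j] <- 1L
        nb <- which(state == 0L &
                    vtab$chrom == vtab$chrom[j] &
                    abs(vtab$pos - vtab$pos[j]) <= win)
        if (!length(nb)) next
        if (sds[j] == 0) next  # degenerate index cannot clump anything
        xj <- x[, j] - mean(x[, j])
        r <- as.numeric(crossprod(x[, nb, drop = FALSE], xj)) /
            (sds[nb] * sds[j])
        r[sds[nb] == 0] <- 0
        state[nb[r^2 > config$rho]] <- -1L
    }
    idx <- which(state == 1L)
    idx[order(vtab$chrom[idx], vtab$pos[idx], vtab$id[idx])]
}

#' P-value thresholding of clump indices
#'
#' Keeps index variants whose marginal p-value is strictly below `theta`.
#'
#' @param assoc association table from [marginalAssoc()].
#' @param indexSet integer variant positions from [clumpVariants()].
#' @param theta p-value threshold.
#' @return integer subset of `indexSet`.
#' @export
thresholdSelect <- function(assoc, indexSet, theta = 0.1) {
    stopifnot(theta > 0, theta <= 1)
    out <- indexSet[assoc$p[indexSet] < theta]
    if (!length(out))
        stop("no variants survive the p-value threshold theta = ", theta,
             "; raise theta")
    out
}
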