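# Core method: spectral-route SVD of the scaled genotype matrix,
# EigenCorr component selection, out-of-sample projection and scoring.
#
# Scaling convention, fixed package-wide: lambdas are singular values of
# Z/sqrt(m) -- equivalently sqrt of eigenvalues of the genetic relatedness
# matrix K = Z Z^T / m. Under this scaling the spectrum bulk of an
# unstructured cohort sits near 1, the largest singular value at
# n = 1000, m = 100000 is ~1.1 (< 5), and the squared-EigenCorr selection
# cutoff 0.1 (= 0.062^2 x 5^2, the null correlation bound times the
# singular-value ceiling) is meaningful. Without the 1/sqrt(m) scaling the
# cutoff would be unusable.

# orient each column so its largest-magnitude entry is positive; purely a
# determinism device -- all method output is invariant to column signs
.fixSigns <- function(U) {
    sgn <- apply(U, 2, function(u) {
        s <- sign(u[which.max(abs(u))])
        if (s == 0) 1 else s
    })
    sweep(U, 2, sgn, `*`)
}

#' Spectral-route SVD of a normalized genotype matrix
#'
#' For tall-thin transposed problems (m >> n) the left singular system of
#' Z/sqrt(m) is obtained from the n x n Gram matrix: eigendecompose
#' Phi = Z Z^T / m, take lambda_k = sqrt(sigma_k). Round-off-negative
#' eigenvalues are clipped to 0; eigenvalues below 1e-12 x sigma_1 are
#' treated as exact zeros.
#'
#' @param z a [NormalizedGenotypes-class] or numeric matrix Z.
#' @param kMax number of leading components to return
#'   (default min(n, 100)).
#' @return a [SvdFactors-class].
#' @export
spectralSvd <- function(z, kMax = NULL) {
    zm <- if (is(z, "NormalizedGenotypes")) normValues(z) else z
    if (!all(is.finite(zm)))
        stop("normalized matrix contains non-finite entries")
    n <- nrow(zm)
    m <- ncol(zm)
    stopifnot(n >= 2, m >= 1)
    if (is.null(kMax)) kMax <- min(n, 100L)
    kMax <- min(kMax, n)
    phi <- tcrossprod(zm) / m
    es <- eigen(phi, symmetric = TRUE)
    sigma <- pmax(es$values, 0)
    sigma[sigma < 1e-12 * sigma[1]] <- 0
    keep <- seq_len(kMax)
    new("SvdFactors", U = .fixSigns(es$vectors[, keep, drop = FALSE]),
        lambdas = sqrt(sigma[keep]), sigma = sigma[keep],
        mUsed = as.integer(m))
}

#' Right singular vectors from the left system
#'
#' v_k = (Z/sqrt(m))^T u_k / lambda_k; each column has unit norm. Only
#' components with positive singular value can be requested.
#'
#' @param z the [NormalizedGenotypes-class] or matrix the factors came from.
#' @param factors a [SvdFactors-class].
#' @param ks component indices (default: all with lambda > 0).
#' @return m x length(ks) matrix of right singular vectors.
#' @export
rightVectors <- function(z, factors, ks = NULL) {
    zm <- if (is(z, "NormalizedGenotypes")) normValues(z) else z
    if (is.null(ks)) ks <- which(factors@lambdas > 0)
    if (any(factors@lambdas[ks] <= 0))
        stop("right singular vectors undefined for zero singular values: ",
             paste(ks[factors@lambdas[ks] <= 0], collapse = ", "))
    v <- crossprod(zm, factors@U[, ks, drop = FALSE]) / sqrt(factors@mUsed)
    sweep(v, 2, factors@lambdas[ks], `/`)
}

#' EigenCorr table: phenotype correlation weighted by singular value
#'
#' EigenCorr_k = cor(u_k, y) x lambda_k. Most components are uncorrelated
#' with the phenotype, so their EigenCorr is bounded by the null correlation
#' bound times the singular-value ceiling; components carrying phenotype
#' signal stand out regardless of their eigenvalue rank. Components with
#' lambda = 0 get EigenCorr 0 by convention.
#'
#' @param factors a [SvdFactors-class].
#' @param y numeric phenotype of length n (names ignored; align first).
#' @return data.frame (`component`, `cor`, `lambda`, `eigenCorr`,
#'   `eigenCorr2`, `rank`), rows in component order, `rank` by decreasing
#'   squared EigenCorr (ties: smaller component index first).
#' @export
eigenCorr <- function(factors, y) {
    y <- as.numeric(y)
    U <- factors@U
    stopifnot(length(y) == nrow(U))
    if (stats::var(y) == 0) stop("phenotype has zero variance")
    lam <- factors@lambdas
    cc <- numeric(ncol(U))
    live <- lam > 0
    if (any(live))
        cc[live] <- as.numeric(stats::cor(U[, live, drop = FALSE], y))
    ec <- cc * lam
    ec2 <- ec^2
    rk <- integer(length(ec2))
    rk[order(-ec2, seq_along(ec2))] <- seq_along(ec2)
    data.frame(component = seq_along(lam), cor = cc, lambda = lam,
               eigenCorr = ec, eigenCorr2 = ec2, rank = rk)
}

#' Null bound for the correlation between a principal component and an
#' uncorrelated phenotype
#'
#' Under the null, cor(u_k, y) behaves as t / sqrt(n - 2 + t^2) with t
#' having n - 2 degrees of freedom; the two-sided bound at the given
#' confidence is t* / sqrt(n - 2 + t*^2). At n = 1000 this is 0.062.
#'
#' @param n sample size (>= 3).
#' @param confidence two-sided confidence level (default 0.95).
#' @return the bound (positive scalar).
#' @export
nullCorrBound <- function(n, confidence = 0.95) {
    stopifnot(n >= 3, confidence > 0, confidence < 1)
    tq <- stats::qt((1 + confidence) / 2, df = n - 2)
    tq / sqrt(n - 2 + tq^2)
}

#' Select components by squared EigenCorr
#'
#' S = components whose squared EigenCorr is strictly above the cutoff,
#' ordered by decreasing squared EigenCorr. The default cutoff 0.1 is the
#' null bound squared (0.062^2 at n = 1000) times the singular-value
#' ceiling squared (5^2).
#'
#' @param table an [eigenCorr()] table.
#' @param cutoff squared-EigenCorr cutoff (default 0.1).
#' @return integer vector of component indices (possibly empty).
#' @export
selectComponents <- function(table, cutoff = 0.1) {
    stopifnot(nrow(table) > 0)
    hit <- table$component[table$eigenCorr2 > cutoff]
    as.integer(hit[order(table$rank[table$eigenCorr2 > cutoff])])
}

#' Least-squares component effects
#'
#' OLS of y on the selected left singular vectors with an intercept. With
#' mean-zero orthonormal u_k the joint solution reduces to
#' gamma_k = u_k^T y and mu = mean(y); the joint solve is used so the
#' identity holds exactly even when missing-data imputation leaves the
#' columns slightly off-center.
#'
#' @param uS n x |S| matrix of selected left singular vectors.
#' @param y numeric phenotype.
#' @return list with `mu` (intercept) and `gammas`.
#' @export
fitGamma <- function(uS, y) {
    uS <- as.matrix(uS)
    y <- as.numeric(y)
    stopifnot(nrow(uS) == length(y))
    if (ncol(uS) == 0) stop("component set S is empty; nothing to fit")
    if (ncol(uS) >= length(y))
        stop("need |S| < n for the component regression")
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, uS), y)
    cf <- fit$coefficients
    list(mu = unname(cf[1]), gammas = unname(cf[-1]))
}

#' Project a target cohort onto discovery singular axes
#'
#' u_k^(B) = (B / sqrt(m)) v_k / lambda_k for each selected component,
#' where B is the target matrix normalized with the model's variant list
#' and discovery frequencies, in the model's variant order.
#'
#' @param b a [NormalizedGenotypes-class] or numeric matrix (target).
#' @param model a [SvdPrsModel-class].
#' @return n_target x |S| matrix of projected coordinates, columns aligned
#'   with `selectedComponents(model)`.
#' @export
projectTarget <- function(b, model) {
    bm <- if (is(b, "NormalizedGenotypes")) normValues(b) else b
    if (ncol(bm) != nrow(model@V))
        stop("target has ", ncol(bm), " variants but the model expects ",
             nrow(model@V),
             "; run harmonizeVariants()/alignTarget() first")
    u <- (bm %*% model@V) / sqrt(nrow(model@V))
    sweep(u, 2, model@lambdas, `/`)
}

#' Score target samples from projected coordinates
#'
#' PRS_i = sum_k gamma_k u_ik^(B) over the selected components. No
#' intercept is added by default; set `addIntercept = TRUE` for scores
#' calibrated to the discovery phenotype location.
#'
#' @param uB projected coordinates from [projectTarget()].
#' @param model a [SvdPrsModel-class].
#' @param sampleIds optional ids for the result.
#' @param addIntercept add the stored intercept mu to every score.
#' @return data.frame (`iid`, `score`) with attribute `method = "svdprs"`.
#' @export
scorePrs <- function(uB, model, sampleIds = NULL, addIntercept = FALSE) {
    uB <- as.matrix(uB)
    if (ncol(uB) != length(model@gammas))
        stop("projected coordinates have ", ncol(uB),
             " columns but the model has ", length(model@gammas),
             " selected components")
    s <- as.numeric(uB %*% model@gammas)
    if (addIntercept) s <- s + model@mu
    if (is.null(sampleIds)) sampleIds <- as.character(seq_along(s))
    structure(data.frame(iid = sampleIds, score = s),
              method = "svdprs")
}

#' Fit the SVD-projection PRS model on a discovery cohort
#'
#' Pipeline: optional variant QC; marginal association scan; greedy LD
#' clumping; p-value thresholding; normalization of the selected variants
#' with discovery-estimated frequencies; Gram-matrix SVD; EigenCorr
#' component selection; right-singular-vector extraction; least-squares
#' component effects. The fitted model carries everything needed to score
#' an independent target -- and nothing individual-level.
#'
#' @param g discovery [GenotypeMatrix-class].
#' @param y named numeric phenotype (names = sample iid) or plain vector in
#'   sample order.
#' @param config a [selectionConfig()]; the defaults rho = 0.1, theta = 0.1
#'   are the recommended operating point.
#' @param cutoff squared-EigenCorr selection cutoff (default 0.1).
#' @param qc [qcThresholds()] applied before selection, or NULL to skip.
#' @param kMax components computed and ranked (default min(n, 100)).
#' @return a [SvdPrsModel-class].
#' @export
trainSvdPrs <- function(g, y, config = selectionConfig(), cutoff = 0.1,
                        qc = qcThresholds(), kMax = NULL) {
    stopifnot(is(g, "GenotypeMatrix"))
    if (!is.null(names(y))) {
        ord <- match(sampleIds(g), names(y))
        if (anyNA(ord))
            stop("phenotype missing for sample(s): ",
                 paste(utils::head(sampleIds(g)[is.na(ord)], 5),
                       collapse = ", "))
        y <- as.numeric(y[ord])
    }
    if (!is.null(qc))
        g <- applyQc(g, qc)
    assoc <- marginalAssoc(g, y)
    idx <- clumpVariants(assoc, g, config = config)
    sel <- thresholdSelect(assoc, idx, config$theta)
    gSel <- g[, sel]
    p <- estimateFrequencies(gSel)
    z <- normalizeGenotypes(gSel, p)
    factors <- spectralSvd(z, kMax = kMax)
    ecTab <- eigenCorr(factors, y)
    S <- selectComponents(ecTab, cutoff)
    S <- S[factors@lambdas[S] > 0]
    if (!length(S))
        stop("no component has squared EigenCorr above ", cutoff,
             "; the phenotype shows no usable component signal ",
             "(lower the cutoff or revisit variant selection)")
    V <- rightVectors(z, factors, S)
    fit <- fitGamma(factors@U[, S, drop = FALSE], y)
    vtab <- variants(gSel)
    vtab$freq <- p
    new("SvdPrsModel", components = as.integer(S), gammas = fit$gammas,
        mu = fit$mu, V = V, lambdas = factors@lambdas[S],
        variants = vtab, eigenCorr = ecTab,
        config = list(rho = config$rho, theta = config$theta,
                      windowKb = config$windowKb, clumpP1 = config$clumpP1,
                      cutoff = cutoff,
                      kMax = if (is.null(kMax)) min(nSamples(g), 100L)
                             else kMax,
                      nDiscovery = nSamples(g)))
}

#' Score a target cohort with a fitted SVD-projection model
#'
#' Harmonizes target variants to the model's variant list (matching on
#' chromosome, position and allele pair; flipping swapped alleles),
#' normalizes with the stored discovery frequencies, projects onto the
#' discovery singular axes and scores. Every model variant must be present
#' in the target.
#'
#' @param model a [SvdPrsModel-class].
#' @param target a [GenotypeMatrix-class].
#' @param addIntercept add the stored intercept to the scores.
#' @return data.frame (`iid`, `score`).
#' @export
applySvdPrs <- function(model, target, addIntercept = FALSE) {
    stopifnot(is(target, "GenotypeMatrix"))
    map <- harmonizeVariants(model@variants, variants(target))
    if (nrow(map) < nrow(model@variants))
        stop(nrow(model@variants) - nrow(map), " model variant(s) absent ",
             "from the target; run harmonizeVariants() to inspect, or ",
             "impute the target to the model's variant list")
    map <- map[order(map$discoveryIndex), ]
    aligned <- alignTarget(target, map, discovery = model@variants)
    b <- normalizeGenotypes(aligned, p = model@variants$freq)
    uB <- projectTarget(b, model)
    scorePrs(uB, model, sampleIds = sampleIds(target),
             addIntercept = addIntercept)
}
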