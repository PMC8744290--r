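test_that("the Gram-matrix route reproduces the direct SVD", {
    # closed form: Z = I2, m = 2 -> both scaled singular values 1/sqrt(2)
    f <- spectralSvd(diag(2))
    expect_equal(singularValues(f), rep(1 / sqrt(2), 2), tolerance = 1e-12)

    set.seed(71)
    z <- matrix(rnorm(20 * 50), 20, 50)
    f <- spectralSvd(z)
    ref <- svd(z / sqrt(50))
    expect_equal(singularValues(f), ref$d, tolerance = 1e-8)
    expect_equal(abs(leftVectors(f)), abs(ref$u), tolerance = 1e-8)

    v <- rightVectors(z, f, 1:20)
    expect_equal(abs(v), abs(ref$v[, 1:20]), tolerance = 1e-8)
    expect_equal(sqrt(colSums(v^2)), rep(1, 20), tolerance = 1e-8)
    # algebraic identity: (Z/sqrt(m)) v_k / lambda_k = u_k
    rec <- sweep((z / sqrt(50)) %*% v, 2, singularValues(f), "/")
    expect_equal(rec, leftVectors(f), tolerance = 1e-8, ignore_attr = TRUE)

    expect_error(spectralSvd(matrix(c(1, NA, 0, 1), 2)), "non-finite")
    # kMax truncates
    expect_identical(ncol(leftVectors(spectralSvd(z, kMax = 5))), 5L)
})

test_that("rank-deficient tails are clipped and refuse right vectors", {
    z <- matrix(rnorm(12 * 4), 12, 4)  # rank 4 < n
    f <- spectralSvd(z)
    expect_true(all(singularValues(f)[5:12] == 0))
    expect_error(rightVectors(z, f, ks = 5), "zero singular values")
})

test_that("EigenCorr weights phenotype correlation by singular value", {
    set.seed(72)
    z <- standardizeCols(matrix(rnorm(30 * 30), 30, 30))
    f <- spectralSvd(z)
    u <- leftVectors(f)
    # y built on u_1: cor = 1, so EigenCorr_1 = lambda_1
    tab <- eigenCorr(f, u[, 1])
    expect_equal(tab$eigenCorr[1], singularValues(f)[1], tolerance = 1e-8)
    expect_equal(tab$rank[1], 1L)
    # orthogonal phenotype: EigenCorr ~ 0
    expect_lt(abs(tab$cor[5]), 1e-8)

    # Lee identity: sum_j cor(z_j, y)^2 = (m/n) sum_k EigenCorr_k^2 for
    # population-sd standardized columns (constant pinned by brute force)
    y <- rnorm(30)
    tab <- eigenCorr(f, y)
    lhs <- sum(apply(z, 2, function(col) cor(col, y))^2)
    expect_equal(lhs, (30 / 30) * sum(tab$eigenCorr2), tolerance = 1e-8)
})

test_that("the Lee identity holds on rectangular standardized matrices", {
    set.seed(73)
    for (i in 1:20) {
        n <- sample(10:40, 1)
        m <- sample(5:60, 1)
        z <- standardizeCols(matrix(rnorm(n * m), n, m))
        y <- rnorm(n)
        f <- spectralSvd(z, kMax = n)
        tab <- eigenCorr(f, y)
        lhs <- sum(apply(z, 2, function(col) cor(col, y))^2)
        expect_equal(lhs, (m / n) * sum(tab$eigenCorr2), tolerance = 1e-8)
    }
})

test_that("the null correlation bound matches the t-quantile form", {
    expect_equal(round(nullCorrBound(1000, 0.95), 3), 0.062)
    # t-quantile oracle at n = 102
    expect_equal(nullCorrBound(102), 0.1946042, tolerance = 1e-6)
    # large-n asymptote 1.96/sqrt(n)
    expect_equal(nullCorrBound(10000), 1.96 / sqrt(10000),
                 tolerance = 0.01 * nullCorrBound(10000))
    expect_error(nullCorrBound(2), "n >= 3")
})

test_that("component selection is a strict cutoff on squared EigenCorr", {
    tab <- data.frame(component = 1:3, cor = 0, lambda = 1,
                      eigenCorr = sqrt(c(0.25, 0.12, 0.09)),
                      eigenCorr2 = c(0.25, 0.12, 0.09), rank = 1:3)
    expect_identical(selectComponents(tab), c(1L, 2L))
    expect_identical(selectComponents(tab, cutoff = 0.3), integer(0))
    # selection follows rank order, not component order
    tab2 <- tab
    tab2$eigenCorr2 <- c(0.12, 0.25, 0.09)
    tab2$rank <- c(2L, 1L, 3L)
    expect_identical(selectComponents(tab2), c(2L, 1L))
    # strictly above: a value exactly at the cutoff is excluded
    tab$eigenCorr2[3] <- 0.1
    expect_identical(selectComponents(tab, cutoff = 0.1), c(1L, 2L))
})

test_that("component effects are orthogonal projections", {
    set.seed(74)
    # centered columns make every u_k with lambda > 0 orthogonal to 1, so
    # the projection shortcut and the joint OLS coincide exactly
    z <- scale(matrix(rnorm(40 * 100), 40, 100), center = TRUE,
               scale = FALSE)
    f <- spectralSvd(z)
    u <- leftVectors(f)[, 1:3]
    y <- 5 + 3 * u[, 1] + rnorm(40, sd = 0.1)
    fit <- fitGamma(u, y)
    expect_equal(fit$gammas[1], unname(crossprod(u[, 1], y)[1]),
                 tolerance = 1e-10)
    expect_equal(fit$mu, mean(y), tolerance = 1e-10)
    # joint OLS oracle
    ref <- coef(lm(y ~ u))
    expect_equal(fit$gammas, unname(ref[-1]), tolerance = 1e-10)
    # exact construction recovers gamma = 3 up to the noise projection
    yExact <- mean(y) + 3 * u[, 1]
    expect_equal(fitGamma(u, yExact)$gammas,
                 c(3, 0, 0), tolerance = 1e-10)
    expect_error(fitGamma(u[, 0, drop = FALSE], y), "empty")
})

test_that("projecting the discovery matrix reproduces its own components", {
    study <- smallStudy(seed = 75)
    g <- study$discovery$genotypes
    y <- study$discovery$phenotype
    model <- trainSvdPrs(g, y)
    # rebuild the discovery Z restricted to the model's variants
    sel <- match(variants(model)$id, variants(g)$id)
    z <- normalizeGenotypes(g[, sel], p = variants(model)$freq)
    uB <- projectTarget(z, model)
    f <- spectralSvd(z)
    expect_equal(uB,
                 leftVectors(f)[, selectedComponents(model), drop = FALSE],
                 tolerance = 1e-8, ignore_attr = TRUE)
    # single-sample linearity: one row projects to that row's coordinates
    one <- projectTarget(normValues(z)[7, , drop = FALSE], model)
    expect_equal(as.numeric(one), uB[7, ], tolerance = 1e-10,
                 ignore_attr = TRUE)

    expect_error(projectTarget(normValues(z)[, 1:5], model), "harmonize")
})

test_that("scores are the gamma-weighted component sums", {
    study <- smallStudy(seed = 76)
    model <- trainSvdPrs(study$discovery$genotypes,
                         study$discovery$phenotype)
    fake <- model
    fake@gammas <- c(2, -1)[seq_along(model@gammas)]
    if (length(model@gammas) >= 2) {
        uB <- matrix(0.5, 1, length(fake@gammas))
        expect_equal(scorePrs(uB, fake)$score,
                     sum(fake@gammas * 0.5), tolerance = 1e-12)
    }
    expect_error(scorePrs(matrix(0, 1, length(model@gammas) + 1), model),
                 "components")
})

test_that("PRS is invariant to singular-vector sign flips", {
    study <- smallStudy(seed = 77)
    g <- study$discovery$genotypes
    y <- study$discovery$phenotype
    model <- trainSvdPrs(g, y)
    flipped <- model
    flipped@V <- -model@V           # flip every (u_k, v_k) pair;
    fitRef <- fitGamma(-projectTarget(normalizeGenotypes(
        g[, match(variants(model)$id, variants(g)$id)],
        p = variants(model)$freq), model), y)
    flipped@gammas <- fitRef$gammas
    p1 <- applySvdPrs(model, study$target$genotypes)
    p2 <- applySvdPrs(flipped, study$target$genotypes)
    expect_equal(p1$score, p2$score, tolerance = 1e-10)
})

test_that("permuting target samples permutes scores identically", {
    study <- smallStudy(seed = 78)
    model <- trainSvdPrs(study$discovery$genotypes,
                         study$discovery$phenotype)
    targ <- study$target$genotypes
    perm <- sample(nSamples(targ))
    p1 <- applySvdPrs(model, targ)
    p2 <- applySvdPrs(model, targ[perm, ])
    expect_equal(p2$score, p1$score[perm], tolerance = 1e-12)
    expect_identical(p2$iid, p1$iid[perm])
})

test_that("self-application equals the in-sample component regression", {
    study <- smallStudy(seed = 79)
    g <- study$discovery$genotypes
    y <- study$discovery$phenotype
    model <- trainSvdPrs(g, y)
    prs <- applySvdPrs(model, g, addIntercept = TRUE)
    # fitted values of the Eq-style PC regression on the same components
    sel <- match(variants(model)$id, variants(g)$id)
    z <- normalizeGenotypes(g[, sel], p = variants(model)$freq)
    f <- spectralSvd(z)
    u <- leftVectors(f)[, selectedComponents(model), drop = FALSE]
    fitted <- unname(fitted(lm(y ~ u)))
    expect_equal(prs$score, fitted, tolerance = 1e-8)
    expect_equal(rSquared(prs, y),
                 summary(lm(y ~ u))$r.squared, tolerance = 1e-8)
})

test_that("target projections preserve ancestry geometry", {
    study <- smallStudy(seed = 80)
    model <- trainSvdPrs(study$discovery$genotypes,
                         study$discovery$phenotype)
    targ <- study$target$genotypes
    map <- harmonizeVariants(variants(model), variants(targ))
    aligned <- alignTarget(targ, map, discovery = variants(model))
    b <- normalizeGenotypes(aligned, p = variants(model)$freq)
    uB <- projectTarget(b, model)
    lab <- study$target$ancestry
    # a positive silhouette on the lead coordinate: within-population
    # spread smaller than the between-population separation
    x <- uB[, 1]
    gap <- abs(mean(x[lab == "pop1"]) - mean(x[lab == "pop2"]))
    spread <- max(sd(x[lab == "pop1"]), sd(x[lab == "pop2"]))
    expect_gt(gap, 2 * spread)
})
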