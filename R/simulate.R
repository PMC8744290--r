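# Structured-GWAS simulator: Balding-Nichols population frequencies,
# binomial hard-call genotypes, and a polygenic phenotype
#   y = mu + Z b + e + shift(ancestry)
# with b ~ N(0, sigma_a^2) on causal variants acting on the normalized
# genotype scale. Used to verify every downstream stage without
# controlled-access cohort data.

#' Simulation configuration
#'
#' @param nDiscovery,nTarget cohort sample sizes.
#' @param m number of variants (drawn independently; no LD is simulated).
#' @param nPopulations number of ancestral populations (>= 1). Samples are
#'   split across populations in contiguous, near-equal blocks.
#' @param fst Balding-Nichols differentiation parameter per population
#'   (recycled; each in \[0, 1)). 0.15 reproduces continental-scale
#'   (AFR/EUR-like) divergence.
#' @param ancestralMafRange range of the uniform ancestral allele-frequency
#'   draw.
#' @param sigmaA2 per-variant effect variance on the normalized scale. The
#'   default emulates a highly polygenic (infinitesimal) trait: with every
#'   variant causal, the aggregate genetic variance is m x sigmaA2 = 0.5
#'   while each individual effect is far too small to detect at n = 1000.
#' @param sigmaE2 residual (environmental) variance.
#' @param mu phenotype intercept.
#' @param causalFraction fraction of variants carrying a nonzero effect
#'   (default 1: the infinitesimal architecture).
#' @param ancestryShift per-population additive phenotype offset (recycled),
#'   the mechanism emulating structure-confounded phenotype differences.
#' @param missingRate fraction of dosages masked missing, uniformly at
#'   random (after phenotype generation).
#' @param seed RNG seed; a fixed seed makes the whole study bit-reproducible.
#' @return a classed configuration list for [simulateCohort()].
#' @export
simulationConfig <- function(nDiscovery = 1000, nTarget = 1000, m = 5000,
                             nPopulations = 2, fst = 0.15,
                             ancestralMafRange = c(0.05, 0.95),
                             sigmaA2 = 1e-4, sigmaE2 = 1, mu = 0,
                             causalFraction = 1, ancestryShift = 0,
                             missingRate = 0, seed = 1L) {
    stopifnot(nDiscovery >= 1, nTarget >= 0, m >= 1, nPopulations >= 1,
              sigmaA2 >= 0, sigmaE2 >= 0,
              causalFraction >= 0, causalFraction <= 1,
              missingRate >= 0, missingRate <= 1,
              length(ancestralMafRange) == 2,
              all(ancestralMafRange > 0), all(ancestralMafRange < 1))
    fst <- rep_len(fst, nPopulations)
    if (any(fst < 0) || any(fst >= 1))
        stop("fst must lie in [0, 1): the Beta frequency model degenerates ",
             "at fst = 1")
    ancestryShift <- rep_len(ancestryShift, nPopulations)
    structure(list(nDiscovery = as.integer(nDiscovery),
                   nTarget = as.integer(nTarget), m = as.integer(m),
                   nPopulations = as.integer(nPopulations), fst = fst,
                   ancestralMafRange = ancestralMafRange,
                   sigmaA2 = sigmaA2, sigmaE2 = sigmaE2, mu = mu,
                   causalFraction = causalFraction,
                   ancestryShift = ancestryShift,
                   missingRate = missingRate, seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' Draw structured population allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies p_j ~ Uniform(ancestralMafRange); population k's
#' frequency is Beta(p_j (1-F_k)/F_k, (1-p_j)(1-F_k)/F_k), so
#' E\[p_kj\] = p_j and Var\[p_kj\] = F_k p_j (1-p_j). F_k = 0 gives
#' p_kj = p_j exactly.
#'
#' @param config a [simulationConfig()]. The caller controls the RNG state;
#'   [simulateCohort()] seeds once and draws frequencies first.
#' @return list with `ancestral` (length m) and `population`
#'   (nPopulations x m matrix).
#' @export
drawStructuredFrequencies <- function(config) {
    m <- config$m
    p <- stats::runif(m, config$ancestralMafRange[1],
                      config$ancestralMafRange[2])
    pop <- matrix(NA_real_, config$nPopulations, m)
    for (k in seq_len(config$nPopulations)) {
        f <- config$fst[k]
        if (f == 0) {
            pop[k, ] <- p
        } else {
            a <- p * (1 - f) / f
            b <- (1 - p) * (1 - f) / f
            pop[k, ] <- stats::rbeta(m, a, b)
        }
    }
    list(ancestral = p, population = pop)
}

# contiguous near-equal split of n samples over nPop populations
.populationBlocks <- function(n, nPop) {
    sizes <- diff(round(seq(0, n, length.out = nPop + 1)))
    rep(seq_len(nPop), times = sizes)
}

# binomial hard calls for one cohort, drawn population-block by
# population-block in column chunks; column-major order makes the stream
# independent of the chunk size
.drawDosages <- function(popIdx, popFreq, chunk = 20000L) {
    n <- length(popIdx)
    m <- ncol(popFreq)
    d <- matrix(NA_integer_, n, m)
    for (start in seq.int(1L, m, by = chunk)) {
        cols <- start:min(start + chunk - 1L, m)
        probs <- popFreq[popIdx, cols, drop = FALSE]
        d[, cols] <- matrix(stats::rbinom(n * length(cols), 2L, probs),
                            n, length(cols))
    }
    d
}

.simVariantTable <- function(m, perChrom = 5000L, spacingBp = 10000L) {
    chrom <- as.character((seq_len(m) - 1L) %/% perChrom + 1L)
    pos <- as.integer(((seq_len(m) - 1L) %% perChrom + 1L) * spacingBp)
    pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                    byrow = TRUE)
    pick <- (seq_len(m) - 1L) %% 4L + 1L
    data.frame(chrom = chrom, id = paste0("snp", seq_len(m)), cm = 0,
               pos = pos, allele1 = pairs[pick, 1], allele2 = pairs[pick, 2])
}

#' Simulate a structured discovery/target study
#'
#' Draws population allele frequencies once, then independent discovery and
#' target cohorts from them; phenotypes follow the polygenic linear model
#' y = mu + Z b + e + shift(ancestry), where Z is the cohort's own
#' frequency-normalized genotype matrix, b is N(0, sigmaA2) on a random
#' causal subset and 0 elsewhere, and the ancestry shift is an additive
#' per-population offset outside the genetic term. Missing masks are applied
#' after phenotype generation. Draw order (frequencies, discovery genotypes,
#' target genotypes, causal set and b, discovery errors, target errors,
#' missing masks) is fixed, so a seed pins the whole study.
#'
#' @param config a [simulationConfig()].
#' @param maxGb refuse to simulate (before any allocation) when the
#'   dosage-plus-normalized storage for both cohorts would exceed this many
#'   gigabytes.
#' @return list of class `SimulatedStudy`: `discovery` and `target` (each a
#'   list with `genotypes` ([GenotypeMatrix-class]), `phenotype` (named
#'   numeric), `ancestry` (labels), `geneticValue` (the noiseless Zb term)),
#'   `trueEffects` b, `frequencies` from
#'   [drawStructuredFrequencies()], and `config`.
#' @export
simulateCohort <- function(config, maxGb = 16) {
    stopifnot(inherits(config, "SimulationConfig"))
    need <- (config$nDiscovery + config$nTarget) * as.double(config$m) * 12
    if (need > maxGb * 1e9)
        stop(sprintf("configured study needs ~%.1f GB (> %g GB budget); ",
                     need / 1e9, maxGb),
             "shrink n or m, or raise maxGb")
    set.seed(config$seed)
    freqs <- drawStructuredFrequencies(config)
    vtab <- .simVariantTable(config$m)

    popD <- .populationBlocks(config$nDiscovery, config$nPopulations)
    popT <- .populationBlocks(config$nTarget, config$nPopulations)
    dD <- .drawDosages(popD, freqs$population)
    dT <- if (config$nTarget > 0) .drawDosages(popT, freqs$population)
          else matrix(NA_integer_, 0, config$m)

    nCausal <- round(config$causalFraction * config$m)
    causal <- sort(sample.int(config$m, nCausal))
    b <- numeric(config$m)
    if (nCausal > 0 && config$sigmaA2 > 0)
        b[causal] <- stats::rnorm(nCausal, 0, sqrt(config$sigmaA2))

    # cohort-frequency normalization for the truth term; a variant that
    # happens to be monomorphic in a finite cohort carries no variance and
    # contributes 0
    safeZ <- function(d) {
        p <- colMeans(d) / 2
        ok <- p > 0 & p < 1
        z <- matrix(0, nrow(d), ncol(d))
        if (any(ok)) {
            zc <- scale(d[, ok, drop = FALSE], center = 2 * p[ok],
                        scale = sqrt(2 * p[ok] * (1 - p[ok])))
            z[, ok] <- zc
        }
        z
    }
    makeSide <- function(d, pop, prefix, err) {
        ids <- sprintf("%s%04d", prefix, seq_len(nrow(d)))
        g <- GenotypeMatrix(d, samples = ids, variants = vtab)
        gv <- if (any(b != 0)) as.numeric(safeZ(d) %*% b)
        else numeric(nrow(d))
        y <- config$mu + gv + err + config$ancestryShift[pop]
        names(y) <- ids
        list(genotypes = g, phenotype = y,
             ancestry = paste0("pop", pop), geneticValue = gv)
    }
    eD <- if (config$sigmaE2 > 0)
        stats::rnorm(config$nDiscovery, 0, sqrt(config$sigmaE2))
    else numeric(config$nDiscovery)
    eT <- if (config$sigmaE2 > 0 && config$nTarget > 0)
        stats::rnorm(config$nTarget, 0, sqrt(config$sigmaE2))
    else numeric(config$nTarget)
    disc <- makeSide(dD, popD, "D", eD)
    targ <- if (config$nTarget > 0) makeSide(dT, popT, "T", eT) else NULL

    if (config$missingRate > 0) {
        mask <- function(g) {
            d <- dosages(g)
            hit <- stats::runif(length(d)) < config$missingRate
            d[hit] <- NA_integer_
            GenotypeMatrix(d, samples = sampleInfo(g),
                           variants = variants(g))
        }
        disc$genotypes <- mask(disc$genotypes)
        if (!is.null(targ)) targ$genotypes <- mask(targ$genotypes)
    }
    structure(list(discovery = disc, target = targ, trueEffects = b,
                   frequencies = freqs, config = config),
              class = "SimulatedStudy")
}

#' Simulate one unstructured (homogeneous) cohort
#'
#' Single population, no differentiation, no phenotype: allele frequencies
#' uniform on `mafRange`, dosages Binomial(2, p). The common benchmark
#' setting n = 1000, m = 100000 gives a largest singular value of
#' Z/sqrt(m) near 1.1, comfortably below 5, with the spectrum bulk near 1.
#'
#' @param n,m sample and variant counts.
#' @param mafRange uniform range for allele frequencies.
#' @param seed RNG seed.
#' @return a [GenotypeMatrix-class].
#' @export
simulateUnstructured <- function(n, m, mafRange = c(0.05, 0.95), seed = 1L) {
    stopifnot(n >= 1, m >= 1)
    set.seed(seed)
    p <- stats::runif(m, mafRange[1], mafRange[2])
    d <- .drawDosages(rep(1L, n), matrix(p, nrow = 1))
    GenotypeMatrix(d, samples = sprintf("S%04d", seq_len(n)),
                   variants = .simVariantTable(m))
}
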