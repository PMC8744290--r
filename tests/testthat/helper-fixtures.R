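# Shared fixture builders and independent oracles. Everything here is
# deliberately naive (loops, byte-by-byte writes) so it can serve as an
# independent reference for the vectorized package code.

randomVariantTable <- function(m, chrom = "1", spacing = 10000L) {
    pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                    byrow = TRUE)
    pick <- (seq_len(m) - 1L) %% 4L + 1L
    data.frame(chrom = rep_len(chrom, m), id = sprintf("rs%d", seq_len(m)),
               cm = rep_len(0, m),
               pos = as.integer(seq_len(m) * spacing),
               allele1 = pairs[pick, 1], allele2 = pairs[pick, 2])
}

randomGenotypeMatrix <- function(n, m, seed = 1, missingRate = 0,
                                 mafRange = c(0.1, 0.9)) {
    set.seed(seed)
    p <- runif(m, mafRange[1], mafRange[2])
    d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
    if (missingRate > 0)
        d[runif(n * m) < missingRate] <- NA_integer_
    GenotypeMatrix(d, samples = sprintf("ind%03d", seq_len(n)),
                   variants = randomVariantTable(m))
}

# Independent PLINK .bed writer built byte-by-byte from the format
# definition: magic 6C 1B, mode 01, SNP-major, 2-bit codes packed
# low-order-first, four samples per byte, zero-padded.
writeBedByHand <- function(dosages, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    n <- nrow(dosages)
    code <- function(g) {
        if (is.na(g)) 1L
        else if (g == 2) 0L
        else if (g == 1) 2L
        else 3L
    }
    for (j in seq_len(ncol(dosages))) {
        bits <- integer(0)
        for (i in seq_len(n)) {
            cd <- code(dosages[i, j])
            bits <- c(bits, cd %% 2L, cd %/% 2L)
        }
        while (length(bits) %% 8L != 0L) bits <- c(bits, 0L)
        for (b in seq_len(length(bits) / 8L)) {
            byte <- sum(bits[(8 * b - 7):(8 * b)] * 2L^(0:7))
            writeBin(as.raw(byte), con)
        }
    }
    invisible(path)
}

# quadratic brute-force greedy clumping: no spatial indexing, recomputes
# pairwise r^2 from scratch
bruteClump <- function(assoc, dosages, vtab, config) {
    m <- ncol(dosages)
    imput <- apply(dosages, 2, function(g) {
        g <- as.double(g)
        g[is.na(g)] <- mean(g, na.rm = TRUE)
        g
    })
    ord <- order(assoc$p, vtab$chrom, vtab$pos, vtab$id)
    state <- rep("un", m)
    for (j in ord) {
        if (state[j] != "un") next
        if (assoc$p[j] > config$clumpP1) next
        state[j] <- "index"
        for (k in seq_len(m)) {
            if (state[k] != "un") next
            if (vtab$chrom[k] != vtab$chrom[j]) next
            if (abs(vtab$pos[k] - vtab$pos[j]) > config$windowKb * 1000)
                next
            r2 <- if (var(imput[, j]) == 0 || var(imput[, k]) == 0) 0
                  else cor(imput[, j], imput[, k])^2
            if (r2 > config$rho) state[k] <- "clumped"
        }
    }
    idx <- which(state == "index")
    idx[order(vtab$chrom[idx], vtab$pos[idx], vtab$id[idx])]
}

# center columns and scale to unit population variance (divisor n)
standardizeCols <- function(x) {
    x <- scale(x, center = TRUE, scale = FALSE)
    sweep(x, 2, sqrt(colMeans(x^2)), "/")
}

# small structured study used by several tests
smallStudy <- function(seed = 11, ...) {
    simulateCohort(simulationConfig(nDiscovery = 300, nTarget = 300,
                                    m = 800, nPopulations = 2, fst = 0.15,
                                    ancestryShift = c(0, 1.3),
                                    sigmaA2 = 0.01, causalFraction = 0.05,
                                    seed = seed, ...))
}
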