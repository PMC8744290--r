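test_that("PLINK filesets round-trip byte-identically", {
    g <- randomGenotypeMatrix(10, 20, seed = 3, missingRate = 0.1)
    pre1 <- file.path(tempdir(), "rt1")
    pre2 <- file.path(tempdir(), "rt2")
    writePlink(g, pre1)
    g2 <- readPlink(pre1)
    expect_identical(dosages(g2), dosages(g))
    expect_identical(variants(g2)$id, variants(g)$id)
    expect_identical(sampleIds(g2), sampleIds(g))
    writePlink(g2, pre2)
    for (ext in c(".bed", ".bim", ".fam"))
        expect_identical(readBin(paste0(pre1, ext), "raw", 1e6),
                         readBin(paste0(pre2, ext), "raw", 1e6),
                         label = ext)
})

test_that("readPlink decodes a fileset written byte-by-byte from the format spec", {
    set.seed(42)
    d <- matrix(sample(c(0L, 1L, 2L, NA), 5 * 7, replace = TRUE), 5, 7)
    pre <- file.path(tempdir(), "byhand")
    writeBedByHand(d, paste0(pre, ".bed"))
    vt <- randomVariantTable(7)
    write.table(vt, paste0(pre, ".bim"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    fam <- data.frame(paste0("f", 1:5), paste0("s", 1:5), "0", "0", 0L, -9)
    write.table(fam, paste0(pre, ".fam"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    g <- readPlink(pre)
    expect_identical(dosages(g), d)
    # n = 5 not divisible by 4: each variant block padded to 2 bytes
    expect_identical(file.size(paste0(pre, ".bed")), 3 + 2 * 7)
    # our writer reproduces the independent writer byte-for-byte
    writePlink(g, paste0(pre, "w"))
    expect_identical(readBin(paste0(pre, ".bed"), "raw", 1e4),
                     readBin(paste0(pre, "w.bed"), "raw", 1e4))
})

test_that("single-genotype 2-bit codes decode per the format", {
    # codes: 0 -> hom allele1 (dosage 2), 2 -> het (1), 3 -> hom allele2 (0),
    # 1 -> missing
    for (case in list(list(code = 0L, dose = 2L), list(code = 2L, dose = 1L),
                      list(code = 3L, dose = 0L),
                      list(code = 1L, dose = NA_integer_))) {
        pre <- file.path(tempdir(), paste0("one", case$code))
        con <- file(paste0(pre, ".bed"), "wb")
        writeBin(as.raw(c(0x6c, 0x1b, 0x01, case$code)), con)
        close(con)
        write.table(data.frame("1", "rs1", 0, 100L, "A", "G"),
                    paste0(pre, ".bim"), sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        write.table(data.frame("f1", "s1", "0", "0", 0L, -9),
                    paste0(pre, ".fam"), sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        expect_identical(dosages(readPlink(pre))[1, 1], case$dose)
    }
})

test_that("readPlink validates file presence, magic bytes and size", {
    expect_error(readPlink(file.path(tempdir(), "nosuch")), "not found")
    g <- randomGenotypeMatrix(4, 3, seed = 1)
    pre <- file.path(tempdir(), "bad")
    writePlink(g, pre)
    raw <- readBin(paste0(pre, ".bed"), "raw", 100)
    raw[1] <- as.raw(0xff)
    writeBin(raw, paste0(pre, ".bed"))
    expect_error(readPlink(pre), "magic")
    writePlink(g, pre)
    writeBin(readBin(paste0(pre, ".bed"), "raw", 4), paste0(pre, ".bed"))
    expect_error(readPlink(pre), "size mismatch")
})

test_that("writePlink emits a header-only .bed for zero variants", {
    g <- GenotypeMatrix(matrix(integer(0), 3, 0),
                        samples = c("a", "b", "c"),
                        variants = randomVariantTable(0))
    pre <- file.path(tempdir(), "empty")
    writePlink(g, pre)
    expect_identical(file.size(paste0(pre, ".bed")), 3)
})

test_that("readPhenotype aligns by id and drops unparseable rows", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("iid\tpheno", "s1\t3", "s2\t0"), f)
    y <- readPhenotype(f)
    expect_identical(as.numeric(y), c(3, 0))
    expect_identical(names(y), c("s1", "s2"))

    writeLines(c("iid\tpheno", "s1\t1.5", "s2\tnot_a_number", "s3\t2"), f)
    expect_warning(y <- readPhenotype(f), "dropped")
    expect_identical(names(y), c("s1", "s3"))
    expect_identical(attr(y, "dropped"), 1L)

    writeLines(c("iid\tpheno", "s1\t1", "s1\t2"), f)
    expect_error(readPhenotype(f), "duplicate")
    writeLines(c("iid\tpheno", "s1\t1"), f)
    expect_error(readPhenotype(f, valueColumn = "score"), "column")

    # values follow ids, not row order: scrambled file gives the same map
    g <- randomGenotypeMatrix(5, 4, seed = 2)
    ids <- sampleIds(g)
    vals <- seq_along(ids) * 1.5
    writeLines(c("iid\tpheno",
                 paste(rev(ids), rev(vals), sep = "\t")), f)
    y <- readPhenotype(f)
    expect_identical(unname(y[ids]), vals)
})

test_that("harmonizeVariants matches on position and allele pair", {
    va <- randomVariantTable(5)
    map <- harmonizeVariants(va, va)
    expect_identical(map$discoveryIndex, 1:5)
    expect_identical(map$targetIndex, 1:5)
    expect_false(any(map$swap))

    vb <- va
    vb$allele1[2] <- va$allele2[2]
    vb$allele2[2] <- va$allele1[2]
    map <- harmonizeVariants(va, vb)
    expect_true(map$swap[2])
    expect_false(any(map$swap[-2]))

    # swapped alleles flip dosage downstream: g -> 2 - g
    g <- randomGenotypeMatrix(6, 5, seed = 4)
    gt <- GenotypeMatrix(dosages(g), sampleInfo(g), vb)
    aligned <- alignTarget(gt, map, discovery = va)
    expect_identical(dosages(aligned)[, 2], 2L - dosages(g)[, 2])
    expect_identical(dosages(aligned)[, 1], dosages(g)[, 1])

    # partial overlap: 3 of 5 positions shared
    vc <- va[c(1, 3, 5), ]
    vc$pos <- vc$pos  # same positions
    map <- harmonizeVariants(va, vc)
    expect_identical(nrow(map), 3L)
    expect_identical(map$discoveryIndex, c(1L, 3L, 5L))
    expect_identical(attr(map, "droppedDiscovery"), 2L)

    # zero overlap errors with build/strand advice
    vd <- va
    vd$pos <- vd$pos + 1L
    expect_error(harmonizeVariants(va, vd), "build")
})

test_that("harmonizeVariants is symmetric up to swap inversion", {
    set.seed(9)
    va <- randomVariantTable(12)
    vb <- va[sample(12, 8), ]
    flip <- sample(8, 3)
    tmp <- vb$allele1[flip]
    vb$allele1[flip] <- vb$allele2[flip]
    vb$allele2[flip] <- tmp
    ab <- harmonizeVariants(va, vb)
    ba <- harmonizeVariants(vb, va)
    pairsAb <- paste(ab$discoveryIndex, ab$targetIndex)
    pairsBa <- paste(ba$targetIndex, ba$discoveryIndex)
    expect_setequal(pairsAb, pairsBa)
    expect_identical(ab$swap[order(ab$discoveryIndex)],
                     ba$swap[order(ba$targetIndex)])
})

test_that("model bundles round-trip bit-identically and hold no genotypes", {
    study <- smallStudy(seed = 21)
    model <- trainSvdPrs(study$discovery$genotypes,
                         study$discovery$phenotype)
    path <- file.path(tempdir(), "bundle")
    saveModel(model, path)
    m2 <- loadModel(path)
    expect_identical(gammas(m2), gammas(model))
    expect_identical(m2@V, model@V)
    expect_identical(singularValues(m2), singularValues(model))
    expect_identical(m2@mu, model@mu)
    expect_identical(variants(m2)$freq, variants(model)$freq)

    # confidentiality: no file in the bundle holds an n x m dosage payload
    n <- nSamples(study$discovery$genotypes)
    for (f in list.files(path, full.names = TRUE)) {
        tab <- tryCatch(read.table(f, header = TRUE, sep = "\t"),
                        error = function(e) NULL)
        if (!is.null(tab))
            expect_false(nrow(tab) == n && ncol(tab) >= n,
                         label = paste("dosage-sized table in", f))
    }

    # scoring with the reloaded model is identical
    prs1 <- applySvdPrs(model, study$target$genotypes)
    prs2 <- applySvdPrs(m2, study$target$genotypes)
    expect_identical(prs1$score, prs2$score)

    # version mismatch rejected
    meta <- jsonlite::read_json(file.path(path, "metadata.json"))
    meta$format_version <- "0.0"
    jsonlite::write_json(meta, file.path(path, "metadata.json"),
                         auto_unbox = TRUE)
    expect_error(loadModel(path), "version")
})

test_that("conventional model bundles round-trip", {
    study <- smallStudy(seed = 22)
    model <- trainConventional(study$discovery$genotypes,
                               study$discovery$phenotype, nPcs = 4)
    path <- file.path(tempdir(), "bundle-ct")
    saveModel(model, path)
    m2 <- loadModel(path)
    expect_identical(variants(m2)$beta, variants(model)$beta)
    expect_identical(m2@nPcs, model@nPcs)
    s1 <- ctScore(study$target$genotypes, model)
    s2 <- ctScore(study$target$genotypes, m2)
    expect_identical(s1$score, s2$score)
})
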