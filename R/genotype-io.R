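# PLINK 1 binary fileset input/output.
#
# .bed layout (SNP-major): magic bytes 0x6c 0x1b, mode byte 0x01, then
# ceiling(n/4) bytes per variant. Each byte packs four samples, two bits
# each, lowest-order bits first. 2-bit codes (value of (byte >> 2s) & 3):
#   0 -> homozygous allele1 (dosage 2)   1 -> missing
#   2 -> heterozygous (dosage 1)         3 -> homozygous allele2 (dosage 0)
# allele1 in the .bim is the counted (effect) allele throughout the package.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))
# 2-bit code -> dosage; index = code + 1
.CODE2DOSE <- c(2L, NA_integer_, 1L, 0L)
# dosage -> 2-bit code; index = dosage + 1; NA handled separately
.DOSE2CODE <- c(3L, 2L, 0L)

#' Read a PLINK 1 binary fileset
#'
#' Reads `prefix.bed` (SNP-major), `prefix.bim` and `prefix.fam` into a
#' [GenotypeMatrix-class]. Dosages count copies of allele1 (the fifth .bim
#' column), the PLINK 1.9 default polarity.
#'
#' @param prefix path prefix of the fileset (without extension).
#' @return a [GenotypeMatrix-class].
#' @seealso [writePlink()]
#' @export
readPlink <- function(prefix) {
    paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
    for (p in paths)
        if (!file.exists(p))
            stop("file not found: ", p)
    fam <- utils::read.table(paths[3], header = FALSE,
                             col.names = c("fid", "iid", "pat", "mat",
                                           "sex", "pheno"),
                             colClasses = c("character", "character",
                                            "character", "character",
                                            "integer", "numeric"))
    bim <- utils::read.table(paths[2], header = FALSE,
                             col.names = c("chrom", "id", "cm", "pos",
                                           "allele1", "allele2"),
                             colClasses = c("character", "character",
                                            "numeric", "integer",
                                            "character", "character"))
    n <- nrow(fam)
    m <- nrow(bim)
    bpv <- as.integer(ceiling(n / 4))
    expected <- 3 + as.double(bpv) * m
    actual <- file.size(paths[1])
    raw <- readBin(paths[1], what = "raw", n = actual)
    if (length(raw) < 3 || !identical(raw[1:2], .BED_MAGIC[1:2]))
        stop("not a PLINK .bed file (bad magic bytes): ", paths[1])
    if (raw[3] != .BED_MAGIC[3])
        stop("unsupported .bed mode byte (only SNP-major 0x01): ", paths[1])
    if (actual != expected)
        stop(sprintf(".bed size mismatch: %s has %d bytes, expected %d (3 + ceil(%d/4)*%d)",
                     paths[1], actual, as.integer(expected), n, m))
    body <- as.integer(raw[-(1:3)])
    doseMat <- matrix(NA_integer_, nrow = n, ncol = m)
    if (m > 0 && n > 0) {
        bytes <- matrix(body, nrow = bpv, ncol = m)
        for (s in 0:3) {
            rows <- seq.int(s + 1L, by = 4L, length.out = bpv)
            keep <- rows <= n
            if (!any(keep)) break
            codes <- (bytes %/% (4L^s)) %% 4L
            doseMat[rows[keep], ] <- matrix(.CODE2DOSE[codes + 1L],
                                            nrow = bpv)[keep, , drop = FALSE]
        }
    }
    GenotypeMatrix(doseMat, samples = fam, variants = bim)
}

#' Write a PLINK 1 binary fileset
#'
#' Writes `prefix.bed` (SNP-major), `prefix.bim` and `prefix.fam` such that
#' [readPlink()] reproduces the input exactly. Sample columns `pat`, `mat`,
#' `sex`, `pheno` are written when present, otherwise as 0/0/0/-9.
#'
#' @param g a [GenotypeMatrix-class].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(g, prefix) {
    stopifnot(is(g, "GenotypeMatrix"))
    dir <- dirname(prefix)
    if (!dir.exists(dir))
        stop("output directory does not exist: ", dir)
    d <- dosages(g)
    n <- nrow(d)
    m <- ncol(d)
    bpv <- as.integer(ceiling(n / 4))
    codes <- matrix(1L, nrow = 4L * bpv, ncol = m)  # placeholder
    dcode <- matrix(1L, nrow = n, ncol = m)
    ok <- !is.na(d)
    dcode[ok] <- .DOSE2CODE[d[ok] + 1L]
    codes[seq_len(n), ] <- dcode
    if (4L * bpv > n)                       # pad trailing samples with 0 bits
        codes[(n + 1L):(4L * bpv), ] <- 0L
    bytes <- integer(0)
    if (m > 0 && bpv > 0) {
        idx <- function(s) seq.int(s + 1L, by = 4L, length.out = bpv)
        bytes <- codes[idx(0), , drop = FALSE] +
            4L * codes[idx(1), , drop = FALSE] +
            16L * codes[idx(2), , drop = FALSE] +
            64L * codes[idx(3), , drop = FALSE]
    }
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(.BED_MAGIC, con)
    if (length(bytes))
        writeBin(as.raw(bytes), con)

    v <- variants(g)
    bim <- data.frame(v$chrom, v$id,
                      if (is.null(v$cm)) 0 else v$cm,
                      v$pos, v$allele1, v$allele2)
    utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    s <- sampleInfo(g)
    fam <- data.frame(s$fid, s$iid,
                      if (is.null(s$pat)) rep("0", n) else s$pat,
                      if (is.null(s$mat)) rep("0", n) else s$mat,
                      if (is.null(s$sex)) rep(0L, n) else s$sex,
                      if (is.null(s$pheno)) rep(-9, n) else s$pheno)
    utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(prefix)
}

#' Read a phenotype table
#'
#' Reads a delimited text file with a header and returns a named numeric
#' vector (names = sample id). Rows whose value does not parse to a finite
#' number are dropped with a warning.
#'
#' @param path file path.
#' @param idColumn name of the sample-id column (default "iid").
#' @param valueColumn name of the phenotype column (default "pheno").
#' @param sep field separator (default: any whitespace).
#' @return named numeric vector; attribute `dropped` counts discarded rows.
#' @export
readPhenotype <- function(path, idColumn = "iid", valueColumn = "pheno",
                          sep = "") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character",
                             check.names = FALSE)
    for (cl in c(idColumn, valueColumn))
        if (!cl %in% names(tab))
            stop("column not found in ", path, ": ", cl)
    ids <- tab[[idColumn]]
    if (anyDuplicated(ids))
        stop("duplicate sample ids in phenotype file: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    vals <- suppressWarnings(as.numeric(tab[[valueColumn]]))
    bad <- !is.finite(vals)
    if (any(bad))
        warning(sum(bad), " phenotype row(s) dropped (non-numeric or ",
                "non-finite values)")
    y <- vals[!bad]
    names(y) <- ids[!bad]
    attr(y, "dropped") <- sum(bad)
    y
}

.variantKey <- function(v) {
    a <- pmin(v$allele1, v$allele2)
    b <- pmax(v$allele1, v$allele2)
    paste(v$chrom, v$pos, a, b, sep = ":")
}

#' Match variants between two cohorts
#'
#' Variants are matched on (chromosome, position, unordered allele pair);
#' id strings are not trusted. Matched variants whose allele1/allele2 are
#' interchanged get `swap = TRUE`, meaning the target dosage must be
#' transformed g -> 2 - g to count the same allele. Unmatched variants are
#' dropped and counted. No strand flipping is attempted: remove ambiguous
#' A/T and C/G variants first (see [applyQc()]).
#'
#' @param discovery,target variant tables (data.frame with `chrom`, `pos`,
#'   `id`, `allele1`, `allele2`) or [GenotypeMatrix-class] objects.
#' @return data.frame with columns `discoveryIndex`, `targetIndex`, `swap`,
#'   ordered by discovery index; attributes `droppedDiscovery` and
#'   `droppedTarget` count unmatched variants.
#' @export
harmonizeVariants <- function(discovery, target) {
    if (is(discovery, "GenotypeMatrix")) discovery <- variants(discovery)
    if (is(target, "GenotypeMatrix")) target <- variants(target)
    kd <- .variantKey(discovery)
    kt <- .variantKey(target)
    # a duplicated key on either side is unusable as a match key: drop all
    kd[kd %in% kd[duplicated(kd)]] <- NA
    kt[kt %in% kt[duplicated(kt)]] <- NA
    hit <- match(kd, kt)
    di <- which(!is.na(hit) & !is.na(kd))
    ti <- hit[di]
    if (length(di) == 0)
        stop("no variants match on (chromosome, position, allele pair); ",
             "check that both cohorts use the same genome build and strand")
    swap <- discovery$allele1[di] == target$allele2[ti] &
        discovery$allele2[di] == target$allele1[ti]
    same <- discovery$allele1[di] == target$allele1[ti] &
        discovery$allele2[di] == target$allele2[ti]
    keep <- swap | same
    di <- di[keep]; ti <- ti[keep]; swap <- swap[keep]
    if (length(di) == 0)
        stop("variants share positions but no allele sets match; ",
             "check strand/allele coding")
    out <- data.frame(discoveryIndex = di, targetIndex = ti, swap = swap)
    attr(out, "droppedDiscovery") <- nrow(discovery) - nrow(out)
    attr(out, "droppedTarget") <- nrow(target) - nrow(out)
    out
}

#' Align a target cohort to a discovery variant list
#'
#' Subsets and reorders target variants following an alignment map from
#' [harmonizeVariants()] and flips swapped dosages (g -> 2 - g) so that
#' target dosages count the discovery allele1.
#'
#' @param target a [GenotypeMatrix-class].
#' @param map alignment map from [harmonizeVariants()].
#' @param discovery optional discovery variant table; when given, the
#'   aligned target adopts the discovery variant metadata.
#' @return a [GenotypeMatrix-class] with one column per map row, in map
#'   order.
#' @export
alignTarget <- function(target, map, discovery = NULL) {
    d <- dosages(target)[, map$targetIndex, drop = FALSE]
    if (any(map$swap))
        d[, map$swap] <- 2L - d[, map$swap, drop = FALSE]
    v <- if (is.null(discovery))
        variants(target)[map$targetIndex, , drop = FALSE]
    else {
        if (is(discovery, "GenotypeMatrix")) discovery <- variants(discovery)
        discovery[map$discoveryIndex, , drop = FALSE]
    }
    GenotypeMatrix(d, samples = sampleInfo(target), variants = v)
}

.fmtNum <- function(x) sprintf("%.17g", x)

.writeNumTable <- function(df, path) {
    isNum <- vapply(df, is.numeric, logical(1))
    out <- df
    out[isNum] <- lapply(df[isNum], .fmtNum)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
}

.BUNDLE_VERSION <- "1.0"

#' Save a fitted PRS model as a plain-text bundle
#'
#' Writes a directory holding a JSON metadata document plus tab-delimited
#' weight tables. Numeric fields are serialized with 17 significant digits,
#' so [loadModel()] reproduces every double bit-identically. The bundle
#' contains no individual-level genotypes or phenotypes: for the SVD model
#' only the singular values, right singular vectors, component effects and
#' the variant list with discovery allele frequencies are shared.
#'
#' @param model a [SvdPrsModel-class] or [ConventionalPrsModel-class].
#' @param path directory to create (must not contain a conflicting bundle).
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    if (is(model, "SvdPrsModel")) {
        meta <- list(format_version = .BUNDLE_VERSION,
                     method = "svdprs",
                     scaling = "Z/sqrt(m)",
                     n = model@config$nDiscovery,
                     m = nrow(model@variants),
                     mu = .fmtNum(model@mu),
                     config = model@config[setdiff(names(model@config),
                                                   "nDiscovery")])
        vtab <- model@variants
        .writeNumTable(vtab, file.path(path, "variants.tsv"))
        V <- as.data.frame(model@V)
        names(V) <- paste0("v", model@components)
        .writeNumTable(V, file.path(path, "V.tsv"))
        comp <- data.frame(component = model@components,
                           lambda = model@lambdas,
                           gamma = model@gammas)
        .writeNumTable(comp, file.path(path, "components.tsv"))
        .writeNumTable(model@eigenCorr, file.path(path, "eigencorr.tsv"))
    } else if (is(model, "ConventionalPrsModel")) {
        meta <- list(format_version = .BUNDLE_VERSION,
                     method = "conventional",
                     n = model@config$nDiscovery,
                     m = nrow(model@variants),
                     n_pcs = model@nPcs,
                     config = model@config[setdiff(names(model@config),
                                                   "nDiscovery")])
        .writeNumTable(model@variants, file.path(path, "variants.tsv"))
    } else stop("unsupported model class: ", class(model))
    jsonlite::write_json(meta, file.path(path, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

.readNumTable <- function(path, charCols = character()) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE)
    for (cl in setdiff(names(tab), charCols))
        tab[[cl]] <- as.numeric(tab[[cl]])
    tab
}

#' Load a model bundle written by [saveModel()]
#'
#' @param path bundle directory.
#' @return a [SvdPrsModel-class] or [ConventionalPrsModel-class].
#' @export
loadModel <- function(path) {
    metaPath <- file.path(path, "metadata.json")
    if (!file.exists(metaPath))
        stop("not a model bundle (no metadata.json): ", path)
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    if (!identical(meta$format_version, .BUNDLE_VERSION))
        stop("model bundle format version mismatch: found ",
             meta$format_version, ", expected ", .BUNDLE_VERSION)
    charCols <- c("chrom", "id", "allele1", "allele2")
    if (identical(meta$method, "svdprs")) {
        vtab <- .readNumTable(file.path(path, "variants.tsv"), charCols)
        vtab$pos <- as.integer(vtab$pos)
        comp <- .readNumTable(file.path(path, "components.tsv"))
        V <- as.matrix(.readNumTable(file.path(path, "V.tsv")))
        dimnames(V) <- NULL
        ec <- .readNumTable(file.path(path, "eigencorr.tsv"))
        cfg <- meta$config
        cfg$nDiscovery <- meta$n
        new("SvdPrsModel",
            components = as.integer(comp$component),
            gammas = comp$gamma, mu = as.numeric(meta$mu),
            V = V, lambdas = comp$lambda, variants = vtab,
            eigenCorr = ec, config = cfg)
    } else if (identical(meta$method, "conventional")) {
        vtab <- .readNumTable(file.path(path, "variants.tsv"), charCols)
        vtab$pos <- as.integer(vtab$pos)
        cfg <- meta$config
        cfg$nDiscovery <- meta$n
        new("ConventionalPrsModel", variants = vtab,
            nPcs = as.integer(meta$n_pcs), config = cfg)
    } else stop("unknown model method in bundle: ", meta$method)
}
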