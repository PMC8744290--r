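# Performance evaluation: R^2, rho x theta grids, EigenCorr rank
# diagnostics.

#' Coefficient of determination between a PRS and a phenotype
#'
#' Squared Pearson correlation over the id intersection -- equivalently the
#' R^2 of the univariate regression of y on the score, and invariant to
#' affine transformation of either argument (scores carry no intercept, so
#' a location-free measure puts every method on the same footing).
#'
#' @param prs data.frame (`iid`, `score`) as returned by the scoring
#'   functions, or a named numeric vector.
#' @param y named numeric phenotype.
#' @return R^2 in \[0, 1\]; 0 with a warning when the score has no variance.
#' @export
rSquared <- function(prs, y) {
    if (is.data.frame(prs)) {
        s <- prs$score
        names(s) <- prs$iid
    } else s <- prs
    if (!is.null(names(s)) && !is.null(names(y))) {
        common <- intersect(names(s), names(y))
        if (length(common) < 3)
            stop("need at least 3 overlapping samples")
        s <- s[common]
        y <- y[common]
    }
    if (stats::var(y) == 0) stop("phenotype has zero variance")
    if (stats::var(s) == 0) {
        warning("PRS has zero variance; R^2 reported as 0")
        return(0)
    }
    stats::cor(as.numeric(s), as.numeric(y))^2
}

#' Grid search over clumping and thresholding cutoffs
#'
#' Full factorial run over methods x rho x theta: each cell trains on the
#' discovery cohort, scores the target, and records R^2 on each subgroup of
#' target samples (always including "combined"). Failing cells are recorded
#' and the run continues. The conventional-method grids used in practice
#' are rho in \{0.01, 0.1, 0.2\} and theta in \{0.0001, 0.001, 0.01, 0.1,
#' 0.2, 0.3, 0.4, 0.5, 1\}.
#'
#' @param discovery,target [GenotypeMatrix-class] cohorts.
#' @param yDiscovery,yTarget named numeric phenotypes.
#' @param methods subset of c("svdprs", "conventional").
#' @param rhoGrid,thetaGrid numeric grids.
#' @param subgroups optional named character vector (names = target iid) of
#'   subgroup labels; each level is evaluated separately in addition to
#'   "combined".
#' @param cutoff squared-EigenCorr cutoff for the svdprs method.
#' @param nPcs PC covariates for the conventional method.
#' @param qc [qcThresholds()] or NULL.
#' @param seed annotation recorded in the result rows (the search itself is
#'   deterministic given the cohorts).
#' @return data.frame (`method`, `rho`, `theta`, `subgroup`, `r2`,
#'   `nSelected`, `seed`, `error`).
#' @export
gridSearch <- function(discovery, target, yDiscovery, yTarget,
                       methods = c("svdprs", "conventional"),
                       rhoGrid = c(0.01, 0.1, 0.2),
                       thetaGrid = c(1e-4, 1e-3, 1e-2, 0.1, 0.2, 0.3,
                                     0.4, 0.5, 1),
                       subgroups = NULL, cutoff = 0.1, nPcs = 10,
                       qc = qcThresholds(), seed = NA_integer_) {
    methods <- match.arg(methods, c("svdprs", "conventional"),
                         several.ok = TRUE)
    groups <- list(combined = sampleIds(target))
    if (!is.null(subgroups)) {
        for (lev in sort(unique(subgroups)))
            groups[[lev]] <- names(subgroups)[subgroups == lev]
    }
    rows <- list()
    for (method in methods) for (rho in rhoGrid) for (theta in thetaGrid) {
        cfg <- selectionConfig(rho = rho, theta = theta)
        cell <- tryCatch({
            if (method == "svdprs") {
                model <- trainSvdPrs(discovery, yDiscovery, config = cfg,
                                     cutoff = cutoff, qc = qc)
                prs <- applySvdPrs(model, target)
                nSel <- nrow(model@variants)
            } else {
                model <- trainConventional(discovery, yDiscovery,
                                           config = cfg, nPcs = nPcs,
                                           qc = qc)
                prs <- ctScore(target, model)
                nSel <- nrow(model@variants)
            }
            list(prs = prs, nSel = nSel, error = NA_character_)
        }, error = function(e)
            list(prs = NULL, nSel = NA_integer_,
                 error = conditionMessage(e)))
        for (gname in names(groups)) {
            r2 <- NA_real_
            if (!is.null(cell$prs)) {
                keep <- cell$prs$iid %in% groups[[gname]]
                sub <- cell$prs[keep, , drop = FALSE]
                r2 <- tryCatch(
                    suppressWarnings(rSquared(sub, yTarget)),
                    error = function(e) NA_real_)
            }
            rows[[length(rows) + 1]] <-
                data.frame(method = method, rho = rho, theta = theta,
                           subgroup = gname, r2 = r2, nSelected = cell$nSel,
                           seed = seed, error = cell$error)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    comb <- out[out$subgroup == "combined" & !is.na(out$r2), , drop = FALSE]
    if (nrow(comb)) {
        best <- do.call(rbind, lapply(split(comb, comb$method),
                                      function(d) d[which.max(d$r2), ]))
        rownames(best) <- NULL
        attr(out, "best") <- best
    }
    out
}

#' EigenCorr rank table
#'
#' The top `topN` squared EigenCorr values against their ranks, with the
#' component index behind each rank -- the diagnostic that separates
#' phenotype-relevant components from large-eigenvalue components.
#'
#' @param table an [eigenCorr()] table.
#' @param topN how many leading ranks to keep (default 100; truncated to
#'   the component count).
#' @param cutoff selection cutoff carried along for plotting/reporting.
#' @return data.frame (`rank`, `component`, `eigenCorr2`, `lambda`,
#'   `selected`), ordered by rank; attribute `cutoff`.
#' @export
eigenCorrRankTable <- function(table, topN = 100, cutoff = 0.1) {
    stopifnot(nrow(table) > 0)
    ord <- order(table$rank)
    top <- utils::head(table[ord, ], topN)
    out <- data.frame(rank = top$rank, component = top$component,
                      eigenCorr2 = top$eigenCorr2, lambda = top$lambda,
                      selected = top$eigenCorr2 > cutoff)
    rownames(out) <- NULL
    attr(out, "cutoff") <- cutoff
    out
}

#' Scatter plot of squared EigenCorr versus rank
#'
#' @param table an [eigenCorr()] table.
#' @param topN leading ranks to display.
#' @param cutoff horizontal cutoff line.
#' @param ... passed to [graphics::plot()].
#' @return the underlying [eigenCorrRankTable()], invisibly.
#' @export
eigenCorrRankPlot <- function(table, topN = 100, cutoff = 0.1, ...) {
    tab <- eigenCorrRankTable(table, topN = topN, cutoff = cutoff)
    graphics::plot(tab$rank, tab$eigenCorr2,
                   xlab = "rank", ylab = expression(EigenCorr^2),
                   pch = ifelse(tab$selected, 19, 1), ...)
    graphics::abline(h = cutoff, lty = 3)
    invisible(tab)
}
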