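#' Replicate-normalized cell proportion
#'
#' The building block of the composition statistic: the number of cells a
#' cluster contributes to one replicate of one sex, divided by that
#' replicate's total cell count for the sex, \eqn{Z_{c,r,s} =
#' n_{c,r,s} / N_{r,s}}.
#'
#' @param n cell count(s) of the cluster in the replicate (vectorised).
#' @param N total cell count(s) of the replicate and sex; must be positive.
#' @return \code{n / N}, in [0, 1].
#' @export
normalizedProportion <- function(n, N) {
    if (any(N <= 0))
        stop("replicate total N must be > 0 (exclude empty replicates upstream)")
    if (any(n < 0) || any(n > N)) stop("need 0 <= n <= N")
    n / N
}

#' Sex-biased cell count (log2 pseudocounted proportion ratio)
#'
#' \deqn{B = \log_2\frac{pseudocount + Z_{female}}{pseudocount + Z_{male}}}
#' The tiny pseudocount (default \code{1e-256}) keeps the ratio finite when
#' one sex contributes no cells; such values are astronomically large and are
#' reported as-is (plot layers clip them separately).
#'
#' @param zFemale,zMale normalized proportions (vectorised).
#' @param pseudocount small positive offset.
#' @return log2 ratio; positive values are female-biased.
#' @examples
#' countBias(0.02, 0.01)  # exactly 1 bit: twice the female proportion
#' @export
countBias <- function(zFemale, zMale, pseudocount = 1e-256) {
    stopifnot(pseudocount > 0)
    if (any(zFemale < 0) || any(zMale < 0)) stop("Z values must be >= 0")
    log2((pseudocount + zFemale) / (pseudocount + zMale))
}

#' Wilcoxon test on per-replicate sex proportions
#'
#' Compares the per-replicate normalized proportions of the two sexes for
#' one cluster. In \code{"unpaired"} mode (default) a two-sided
#' Mann-Whitney rank-sum test is used; \code{"paired"} runs the Wilcoxon
#' signed-rank test on per-replicate differences and requires equal
#' replicate sets. With up to 12 replicates per group the two-sided p-value
#' is computed by exact null enumeration (midranks, so ties are handled
#' exactly); beyond that the normal approximation with tie/continuity
#' correction is used. Completely tied inputs give \eqn{p = 1}.
#'
#' @param zFemale,zMale numeric vectors of per-replicate proportions
#'   (length = number of replicates, at least 2 per sex).
#' @param mode \code{"unpaired"} or \code{"paired"}.
#' @return two-sided p-value.
#' @examples
#' compositionTest(c(3, 4, 5, 6, 7, 8) / 100, c(1, 1, 2, 2, 2, 2) / 100)
#' @export
compositionTest <- function(zFemale, zMale, mode = c("unpaired", "paired")) {
    mode <- match.arg(mode)
    if (length(zFemale) < 2 || length(zMale) < 2)
        stop("need >= 2 replicates per sex")
    if (mode == "paired") {
        if (length(zFemale) != length(zMale))
            stop("paired mode requires equal replicate sets")
        d <- zFemale - zMale
        d <- d[d != 0]
        if (!length(d)) return(1)
        if (length(d) <= 12) return(.exactSignedRankP(d))
        pv <- suppressWarnings(
            stats::wilcox.test(zFemale, zMale, paired = TRUE,
                               correct = TRUE)$p.value)
    } else {
        if (all(c(zFemale, zMale) == zFemale[1])) return(1)
        if (max(length(zFemale), length(zMale)) <= 12)
            return(.exactRankSumP(zFemale, zMale))
        pv <- suppressWarnings(
            stats::wilcox.test(zFemale, zMale, paired = FALSE,
                               correct = TRUE)$p.value)
    }
    min(pv, 1)
}

# Exact two-sided signed-rank p with midranks, enumerating all 2^n sign
# assignments (zero differences already removed).
.exactSignedRankP <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    wObs <- sum(r[d > 0])
    combos <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wAll <- as.vector(combos %*% r)
    min(1, 2 * min(mean(wAll <= wObs + 1e-9), mean(wAll >= wObs - 1e-9)))
}

# Exact two-sided rank-sum p with midranks via a subset-sum dynamic
# programme over doubled (hence integer) midranks; handles ties exactly.
.exactRankSumP <- function(x, y) {
    n <- length(x); m <- length(y); N <- n + m
    r <- rank(c(x, y))
    w <- as.integer(round(2 * r))
    wObs <- sum(w[seq_len(n)])
    S <- sum(w)
    # dp[[k + 1]][s + 1] = number of k-subsets with weight sum s
    dp <- lapply(0:n, function(k) numeric(S + 1))
    dp[[1]][1] <- 1
    for (i in seq_len(N)) {
        for (k in rev(seq_len(min(i, n)))) {
            shifted <- c(numeric(w[i]), dp[[k]][seq_len(S + 1 - w[i])])
            dp[[k + 1]] <- dp[[k + 1]] + shifted
        }
    }
    cnt <- dp[[n + 1]]
    tot <- sum(cnt)
    pLo <- sum(cnt[seq_len(wObs + 1)]) / tot
    pHi <- sum(cnt[(wObs + 1):(S + 1)]) / tot
    min(1, 2 * min(pLo, pHi))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up BH with monotonicity enforcement; order-preserving with
#' the input vector.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return adjusted q-values, same order as \code{p}.
#' @export
bhAdjust <- function(p) {
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Per-cluster sex bias in cell numbers
#'
#' For every retained cluster, computes the per-replicate normalized
#' proportions \eqn{Z_{c,r,s}} of each sex, the sex-biased cell count
#' \eqn{B} (log2 pseudocounted ratio of the mean proportions across
#' replicates), a Wilcoxon p-value comparing the per-replicate female and
#' male proportions, and BH-adjusted q-values across clusters.
#'
#' Replicate totals \eqn{N_{r,s}} are computed over all cells entering the
#' analysis (after cell filtering), so the statistic is invariant to
#' rescaling any replicate's sequencing depth of cells. Replicates with no
#' cells of a sex are dropped from that sex with a message.
#'
#' @param x a \linkS4class{SexedAtlas} (already cell-filtered; cells with
#'   sex \code{"mix"} are ignored).
#' @param clusters cluster ids per cell, aligned with columns of \code{x}.
#' @param clustersUse optional character vector restricting (and ordering)
#'   the clusters tested, e.g. from \code{\link{filterClusters}}.
#' @param pseudocount offset of \code{\link{countBias}}.
#' @param mode test mode, see \code{\link{compositionTest}}.
#' @return \code{data.frame} with one row per cluster: \code{cluster_id},
#'   \code{n_female}, \code{n_male}, \code{mean_Z_female},
#'   \code{mean_Z_male}, \code{pct_female}, \code{pct_male}, \code{B},
#'   \code{p}, \code{q}. The per-replicate Z arrays are attached as
#'   \code{attr(, "Z")} (cluster x replicate x sex).
#' @examples
#' atl <- generateAtlas(synthConfig(nClusters = 3, nGenes = 20,
#'     cellsPerReplicate = 400, compositionBias = c(c1 = 1.5), seed = 2))
#' atl <- filterCells(atl)
#' compositionBias(atl, atl$true_cluster)
#' @export
compositionBias <- function(x, clusters, clustersUse = NULL,
                            pseudocount = 1e-256,
                            mode = c("unpaired", "paired")) {
    mode <- match.arg(mode)
    stopifnot(methods::is(x, "SexedAtlas"), length(clusters) == ncol(x))
    clusters <- as.character(clusters)
    sexed <- x$sex %in% c("female", "male")
    cl <- factor(clusters[sexed],
                 levels = if (is.null(clustersUse)) unique(clusters[sexed])
                          else clustersUse)
    keep <- !is.na(cl)
    cl <- cl[keep]
    sex <- factor(x$sex[sexed][keep], c("female", "male"))
    repl <- factor(x$replicate[sexed][keep])

    n_crs <- table(cluster = cl, replicate = repl, sex = sex)
    N_rs <- apply(n_crs, c(2, 3), sum)
    empty <- which(N_rs == 0, arr.ind = TRUE)
    if (nrow(empty)) {
        message("compositionBias: dropping replicate/sex with zero cells: ",
                paste(sprintf("%s/%s", rownames(N_rs)[empty[, 1]],
                              colnames(N_rs)[empty[, 2]]), collapse = ", "))
    }
    Z <- array(NA_real_, dim = dim(n_crs), dimnames = dimnames(n_crs))
    for (s in c("female", "male")) {
        ok <- N_rs[, s] > 0
        Z[, ok, s] <- sweep(n_crs[, ok, s, drop = FALSE], 2,
                            N_rs[ok, s], "/")
    }

    ids <- levels(cl)
    res <- data.frame(cluster_id = ids, stringsAsFactors = FALSE)
    res$n_female <- apply(n_crs[, , "female", drop = FALSE], 1, sum)
    res$n_male <- apply(n_crs[, , "male", drop = FALSE], 1, sum)
    res$mean_Z_female <- apply(Z[, , "female", drop = FALSE], 1, mean,
                               na.rm = TRUE)
    res$mean_Z_male <- apply(Z[, , "male", drop = FALSE], 1, mean,
                             na.rm = TRUE)
    res$pct_female <- 100 * res$mean_Z_female
    res$pct_male <- 100 * res$mean_Z_male
    res$B <- countBias(res$mean_Z_female, res$mean_Z_male, pseudocount)
    res$p <- vapply(seq_along(ids), function(i) {
        zf <- Z[i, , "female"]; zm <- Z[i, , "male"]
        compositionTest(zf[!is.na(zf)], zm[!is.na(zm)], mode = mode)
    }, numeric(1))
    res$q <- bhAdjust(res$p)
    attr(res, "Z") <- Z
    attr(res, "pseudocount") <- pseudocount
    attr(res, "mode") <- mode
    res
}
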