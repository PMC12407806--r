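#' Library-size normalization and log transform
#'
#' Scales every cell's counts to a common total (\code{targetSum}, default
#' 10,000) and applies \code{log1p}. Zeros map to zeros, so sparsity is
#' preserved. Cells with zero total count cannot be normalized and are
#' excluded with a warning. The transform is recorded in the metadata so
#' downstream statistics can de-log where required.
#'
#' @param x a \linkS4class{SexedAtlas}.
#' @param targetSum per-cell total after scaling.
#' @return \code{x} with an added \code{"logcounts"} assay and
#'   \code{metadata(x)$normalization = list(target_sum, log_applied)}.
#' @examples
#' atl <- generateAtlas(synthConfig(nClusters = 2, nGenes = 20,
#'     cellsPerReplicate = 50, replicatesPerSex = 2, seed = 3))
#' atl <- normalizeExpression(atl)
#' SummarizedExperiment::assayNames(atl)
#' @export
normalizeExpression <- function(x, targetSum = 1e4) {
    stopifnot(methods::is(x, "SexedAtlas"), targetSum > 0)
    counts <- SummarizedExperiment::assay(x, "counts")
    tot <- Matrix::colSums(counts)
    if (any(tot == 0)) {
        warning(sum(tot == 0), " cell(s) with zero total count excluded")
        x <- x[, tot > 0]
        counts <- SummarizedExperiment::assay(x, "counts")
        tot <- tot[tot > 0]
    }
    lx <- log1p(counts %*% Matrix::Diagonal(x = targetSum / tot))
    dimnames(lx) <- dimnames(counts)
    SummarizedExperiment::assay(x, "logcounts") <- lx
    S4Vectors::metadata(x)$normalization <-
        list(target_sum = targetSum, log_applied = TRUE)
    x
}

#' Rank-sum z score of a female/male expression comparison
#'
#' The standardized Wilcoxon rank-sum statistic used as the per-gene sex-bias
#' score: with midranks for ties, \eqn{z = (R_f - \mu)/\sigma} where
#' \eqn{R_f} is the female rank sum, \eqn{\mu = n_f (N + 1)/2} and
#' \eqn{\sigma^2 = n_f n_m \left((N+1) - \sum_t (t^3 - t)/(N(N-1))\right)/12}
#' (tie-corrected). Positive scores mean the gene ranks higher in female
#' cells. The score reflects how consistently a gene's expression differs
#' between the sexes, and is invariant to any monotone transform of the
#' values (logged and de-logged normalized expression give identical
#' scores). When every value ties, \eqn{z = 0}.
#'
#' @param valuesFemale,valuesMale non-empty numeric vectors.
#' @return the z score.
#' @examples
#' rankSumZscore(c(3, 4, 5), c(0, 1, 2))  # 4.5 / sqrt(5.25)
#' @export
rankSumZscore <- function(valuesFemale, valuesMale) {
    nf <- length(valuesFemale); nm <- length(valuesMale)
    if (nf == 0 || nm == 0) stop("both groups must be non-empty")
    v <- c(valuesFemale, valuesMale)
    N <- nf + nm
    r <- rank(v)
    Rf <- sum(r[seq_len(nf)])
    t <- tabulate(match(v, unique(v)))
    tieTerm <- sum(t^3 - t) / (N * (N - 1))
    s2 <- nf * nm / 12 * ((N + 1) - tieTerm)
    if (s2 <= 0) return(0)
    (Rf - nf * (N + 1) / 2) / sqrt(s2)
}

.rankSumZscoreMatrix <- function(m, isFemale) {
    # m: cells x genes (dense); vectorised version of rankSumZscore()
    nf <- sum(isFemale); nm <- sum(!isFemale); N <- nf + nm
    z <- numeric(ncol(m))
    for (j in seq_len(ncol(m))) {
        v <- m[, j]
        r <- rank(v)
        t <- tabulate(match(v, unique(v)))
        s2 <- nf * nm / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
        z[j] <- if (s2 <= 0) 0 else
            (sum(r[isFemale]) - nf * (N + 1) / 2) / sqrt(s2)
    }
    z
}

#' Per-cluster per-gene sex bias in expression
#'
#' For every cluster with at least one cell of each sex, computes for every
#' gene: the mean normalized (de-logged) expression per sex, the
#' pseudocounted log2 expression ratio
#' \deqn{B_{expr} = \log_2\frac{male\_avg + 10^{-9}}{female\_avg + 10^{-9}},}
#' the rank-sum z \code{score} (positive = female-high; computed on the
#' normalized values, to which the monotone log is irrelevant), a two-sided
#' normal-approximation p-value for the score, and BH-adjusted q-values
#' across genes within the cluster. Single-sex clusters are skipped with a
#' message. Genes with zero variance within a cluster get score 0, p 1.
#'
#' Note the stored \code{B_expr} follows the male-over-female orientation of
#' the ratio formula while \code{score} is female-positive;
#' \code{\link{orientBias}} flips reports to a consistent female-positive
#' display.
#'
#' @param x a normalized \linkS4class{SexedAtlas}
#'   (\code{\link{normalizeExpression}}).
#' @param clusters cluster ids per cell, aligned with columns of \code{x}.
#' @param clustersUse optional cluster subset to analyse.
#' @param offset pseudo-expression offset of the log ratio.
#' @return long-format \code{data.frame}: \code{cluster_id}, \code{gene},
#'   \code{female_avg}, \code{male_avg}, \code{B_expr}, \code{score},
#'   \code{p}, \code{q}.
#' @export
geneSexBias <- function(x, clusters, clustersUse = NULL, offset = 1e-9) {
    stopifnot(methods::is(x, "SexedAtlas"), length(clusters) == ncol(x))
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
        stop("run normalizeExpression() first")
    clusters <- as.character(clusters)
    if (is.null(clustersUse)) clustersUse <- unique(clusters)
    lx <- SummarizedExperiment::assay(x, "logcounts")
    out <- vector("list", length(clustersUse))
    for (i in seq_along(clustersUse)) {
        cid <- clustersUse[i]
        inCl <- clusters == cid & x$sex %in% c("female", "male")
        sex <- x$sex[inCl]
        if (!any(sex == "female") || !any(sex == "male")) {
            message("geneSexBias: cluster ", cid,
                    " has cells of one sex only; skipped")
            next
        }
        m <- as.matrix(Matrix::t(lx[, inCl, drop = FALSE]))  # cells x genes
        isF <- sex == "female"
        expr <- expm1(m)  # means computed on de-logged normalized values
        fAvg <- colMeans(expr[isF, , drop = FALSE])
        mAvg <- colMeans(expr[!isF, , drop = FALSE])
        z <- .rankSumZscoreMatrix(m, isF)
        p <- 2 * stats::pnorm(-abs(z))
        out[[i]] <- data.frame(
            cluster_id = cid, gene = colnames(m),
            female_avg = fAvg, male_avg = mAvg,
            B_expr = log2((mAvg + offset) / (fAvg + offset)),
            score = z, p = p, q = bhAdjust(p),
            stringsAsFactors = FALSE, row.names = NULL)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        stop("no cluster had cells of both sexes")
    attr(res, "offset") <- offset
    res
}

#' Orient a gene-bias table for display
#'
#' The stored log ratio \code{B_expr} is male-over-female (its printed
#' form), while the rank \code{score} is female-positive. For reports and
#' figures this flips signs so that positive always means female-biased
#' (\code{orientation = "female"}, the default) or male-biased
#' (\code{"male"}); \code{"printed"} leaves the table untouched.
#'
#' @param bias a \code{data.frame} from \code{\link{geneSexBias}}.
#' @param orientation \code{"female"}, \code{"male"} or \code{"printed"}.
#' @return the table with consistently oriented \code{B_expr} and
#'   \code{score} columns.
#' @export
orientBias <- function(bias, orientation = c("female", "male", "printed")) {
    orientation <- match.arg(orientation)
    if (orientation == "female") {
        bias$B_expr <- -bias$B_expr
    } else if (orientation == "male") {
        bias$score <- -bias$score
    }
    bias
}
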