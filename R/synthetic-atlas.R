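#' Generate a sexed synthetic single-nucleus atlas with known ground truth
#'
#' Simulates a UMI count matrix for a two-sex, multi-replicate atlas in which
#' both the cluster composition and the expression of a designated gene panel
#' can be sex-biased by configurable folds. Counts follow a gene-wise
#' negative binomial (Gamma-Poisson) with cluster-specific multipliers and a
#' log-normal per-cell library-size factor; baseline proportions across
#' clusters are unequal (proportional to \code{1/sqrt(cluster index)}).
#' Female cluster proportions are the baseline proportions multiplied by the
#' configured fold and renormalized; sex-specific clusters receive cells of
#' one sex only. A fraction of cells is labelled \code{"artefact"} and a
#' fraction has sex \code{"mix"}, exercising the cell filters.
#'
#' The generator is fully deterministic: the same \code{SynthConfig}
#' (including its \code{seed}) yields a bit-identical atlas.
#'
#' @param config a \linkS4class{SynthConfig}, see \code{\link{synthConfig}}.
#' @return a \linkS4class{SexedAtlas} with \code{2 * replicatesPerSex *
#'   cellsPerReplicate} cells. Ground truth is stored in
#'   \code{metadata(x)$truth} (see \code{\link{synthTruth}}) and the true
#'   cluster of every cell in \code{colData(x)$true_cluster}.
#' @examples
#' atl <- generateAtlas(synthConfig(nClusters = 3, nGenes = 40,
#'                                  cellsPerReplicate = 200, seed = 7))
#' table(atl$sex)
#' synthTruth(atl)
#' @export
generateAtlas <- function(config) {
    stopifnot(methods::is(config, "SynthConfig"))
    methods::validObject(config)
    set.seed(config@seed)

    K <- config@nClusters
    G <- config@nGenes
    R <- config@replicatesPerSex
    n <- config@cellsPerReplicate
    ids <- .clusterIds(K)

    genes <- c(config@panelGenes,
               sprintf("gene_%03d", seq_len(G - length(config@panelGenes))))
    panelIdx <- seq_along(config@panelGenes)

    # baseline gene means; panel genes are high-expression
    mu <- stats::rlnorm(G, config@logMeanMu, config@logMeanSigma)
    mu[panelIdx] <- mu[panelIdx] * config@panelBaselineFactor

    # cluster x gene multipliers give clusters their identity
    de <- matrix(stats::rlnorm(K * G, 0, config@clusterDeSd), nrow = K,
                 dimnames = list(ids, genes))
    clusterMeans <- de * rep(mu, each = K)

    foldC <- stats::setNames(rep(1, K), ids)
    foldC[names(config@compositionBias)] <- config@compositionBias
    foldP <- stats::setNames(rep(1, K), ids)
    foldP[names(config@panelFold)] <- config@panelFold

    # female panel-gene means shifted by the configured fold
    femaleMeans <- clusterMeans
    if (length(panelIdx))
        femaleMeans[, panelIdx] <- femaleMeans[, panelIdx] * foldP

    sexspec <- stats::setNames(rep("non_sex_specific", K), ids)
    if (length(config@sexspecClusters)) {
        alt <- rep(c("female_specific", "male_specific"),
                   length.out = length(config@sexspecClusters))
        sexspec[config@sexspecClusters] <- alt
    }

    base <- 1 / sqrt(seq_len(K))
    pf <- base * foldC
    pf[sexspec == "male_specific"] <- 0
    pm <- base
    pm[sexspec == "female_specific"] <- 0
    pf <- pf / sum(pf)
    pm <- pm / sum(pm)

    sdlog <- sqrt(log(1 + config@libsizeCV^2))

    blocks <- list(); meta <- list(); bi <- 0L
    for (sex in c("female", "male")) {
        prob <- if (sex == "female") pf else pm
        sexMeans <- if (sex == "female") femaleMeans else clusterMeans
        for (r in seq_len(R)) {
            cl <- sample.int(K, n, replace = TRUE, prob = prob)
            lib <- stats::rlnorm(n, -sdlog^2 / 2, sdlog)
            m <- sexMeans[cl, , drop = FALSE] * lib
            cts <- matrix(stats::rnbinom(n * G, mu = as.vector(m),
                                         size = config@dispersion),
                          nrow = n, ncol = G)
            artefact <- stats::runif(n) < config@fracArtefact
            mix <- stats::runif(n) < config@fracMixSex
            bi <- bi + 1L
            blocks[[bi]] <- cts
            meta[[bi]] <- data.frame(
                cell_id = sprintf("%s_r%d_%05d", sex, r, seq_len(n)),
                sex = ifelse(mix, "mix", sex),
                replicate = paste0("r", r),
                sample = "synthetic",
                annotation = ifelse(artefact, "artefact",
                                    paste0("type_", ids[cl])),
                is_artefact = artefact,
                true_cluster = ids[cl],
                stringsAsFactors = FALSE)
        }
    }
    counts <- do.call(rbind, blocks)
    cd <- do.call(rbind, meta)
    dimnames(counts) <- list(cd$cell_id, genes)

    truth <- S4Vectors::DataFrame(
        cluster = ids,
        true_B = log2(foldC),
        true_panel_shift = log2(foldP),
        sex_specificity = unname(sexspec),
        row.names = ids)

    atl <- SexedAtlas(
        counts = methods::as(Matrix::t(Matrix::Matrix(counts, sparse = TRUE)),
                             "CsparseMatrix"),
        sex = cd$sex, replicate = cd$replicate, sample = cd$sample,
        annotation = cd$annotation, is_artefact = cd$is_artefact,
        true_cluster = cd$true_cluster)
    colnames(atl) <- cd$cell_id
    S4Vectors::metadata(atl) <- list(truth = truth, config = config,
                                     seed = config@seed)
    atl
}

#' Ground truth of a synthetic atlas
#'
#' @param x a \linkS4class{SexedAtlas} produced by \code{\link{generateAtlas}}.
#' @return a \code{DataFrame} with one row per cluster: \code{true_B}
#'   (log2 of the configured female:male composition fold),
#'   \code{true_panel_shift} (log2 of the configured panel expression fold)
#'   and \code{sex_specificity}.
#' @export
synthTruth <- function(x) {
    tr <- S4Vectors::metadata(x)$truth
    if (is.null(tr))
        stop("'x' carries no ground truth; was it made by generateAtlas()?")
    tr
}

#' Write the generator's ground truth as a flat table
#'
#' @param truth a truth \code{DataFrame} from \code{\link{synthTruth}}, or a
#'   \code{SexedAtlas} carrying one.
#' @param file optional path of a CSV to write.
#' @return (invisibly) a \code{data.frame} with columns \code{cluster},
#'   \code{true_B}, \code{true_panel_shift}, \code{sex_specificity}.
#' @export
truthReport <- function(truth, file = NULL) {
    if (methods::is(truth, "SexedAtlas")) truth <- synthTruth(truth)
    df <- as.data.frame(truth, optional = TRUE)
    rownames(df) <- NULL
    if (!is.null(file))
        utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    invisible(df)
}
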