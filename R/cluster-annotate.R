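#' Leiden clustering of a sexed atlas
#'
#' Builds a k-nearest-neighbour graph on the top principal components of the
#' log-normalized expression matrix and partitions it with the Leiden
#' community-detection algorithm (modularity objective, so that the
#' resolution parameter behaves like the one used by the common single-cell
#' toolkits). Higher resolution yields more, finer clusters. Cluster ids are
#' consecutive integers, ordered by decreasing cluster size, returned as
#' \code{"1"}, \code{"2"}, ...
#'
#' The graph-clustering algorithm itself is delegated to
#' \code{\link[igraph]{cluster_leiden}}; this function fixes the
#' preprocessing (library-size normalization to \code{targetSum}, log1p,
#' PCA with \code{ndims} components, \code{k = 15} neighbours by default)
#' and makes the run deterministic given \code{seed}.
#'
#' @param x a \linkS4class{SexedAtlas}.
#' @param resolution positive resolution parameter (the replicated head/body
#'   analyses use 4.0, dissected tissues 1.0).
#' @param seed integer seed controlling PCA initialisation and Leiden
#'   refinement.
#' @param k neighbours in the kNN graph.
#' @param ndims number of principal components (capped by the data).
#' @param targetSum library-size normalization target.
#' @return a factor of cluster ids, named by cell id, with attributes
#'   \code{resolution} and \code{seed}.
#' @examples
#' atl <- generateAtlas(synthConfig(nClusters = 2, nGenes = 60,
#'     cellsPerReplicate = 100, replicatesPerSex = 2, clusterDeSd = 2,
#'     seed = 1))
#' cl <- clusterCells(atl, resolution = 1, seed = 1)
#' table(cl)
#' @export
clusterCells <- function(x, resolution = 1.0, seed = 0L, k = 15,
                         ndims = 50, targetSum = 1e4) {
    stopifnot(methods::is(x, "SexedAtlas"))
    if (ncol(x) == 0) stop("atlas has no cells")
    if (ncol(x) <= k)
        stop("fewer cells (", ncol(x), ") than k + 1 neighbours (", k + 1,
             "); use a smaller k")
    lx <- .logNormalize(SummarizedExperiment::assay(x, "counts"), targetSum)
    ndims <- min(ndims, nrow(lx) - 1L, ncol(lx) - 1L)
    set.seed(seed)
    pcs <- if (ndims < min(dim(lx)) / 3) {
        irlba::prcomp_irlba(Matrix::t(lx), n = ndims, center = TRUE,
                            scale. = FALSE)$x
    } else {
        stats::prcomp(as.matrix(Matrix::t(lx)), center = TRUE,
                      scale. = FALSE)$x[, seq_len(ndims), drop = FALSE]
    }
    nn <- BiocNeighbors::findKNN(pcs, k = k)$index
    # Jaccard-weighted shared-nearest-neighbour graph (standard single-cell
    # construction; unweighted kNN over-fragments under modularity Leiden)
    n <- nrow(nn)
    inc <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1),
                                j = c(as.vector(nn), seq_len(n)),
                                x = 1, dims = c(n, n))
    shared <- Matrix::tcrossprod(inc)
    shared <- methods::as(shared, "TsparseMatrix")
    keep <- shared@i < shared@j
    ii <- shared@i[keep] + 1L; jj <- shared@j[keep] + 1L
    w <- shared@x[keep] / (2 * (k + 1) - shared@x[keep])  # Jaccard
    g <- igraph::graph_from_data_frame(
        data.frame(from = ii, to = jj, weight = w), directed = FALSE,
        vertices = data.frame(name = seq_len(n)))
    set.seed(seed)
    comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution,
                                   n_iterations = 5)
    memb <- igraph::membership(comm)
    ord <- order(tabulate(memb), decreasing = TRUE)
    relabel <- integer(length(ord)); relabel[ord] <- seq_along(ord)
    cl <- factor(relabel[memb], levels = seq_along(ord))
    names(cl) <- colnames(x)
    attr(cl, "resolution") <- resolution
    attr(cl, "seed") <- seed
    cl
}

.logNormalize <- function(counts, targetSum = 1e4) {
    tot <- Matrix::colSums(counts)
    tot[tot == 0] <- 1
    log1p(counts %*% Matrix::Diagonal(x = targetSum / tot))
}

#' Annotate clusters by their predominant cell label
#'
#' Each cluster receives the modal annotation of its member cells. Ties are
#' broken lexicographically (first label in sort order) and flagged.
#'
#' @param clusters factor/character of cluster ids per cell.
#' @param annotations character of cell annotations, aligned with
#'   \code{clusters} (cells without a label should carry
#'   \code{"unannotated"}).
#' @return \code{data.frame} with columns \code{cluster_id},
#'   \code{annotation}, \code{ambiguous}.
#' @export
annotateClusters <- function(clusters, annotations) {
    stopifnot(length(clusters) == length(annotations))
    clusters <- as.character(clusters)
    res <- lapply(split(as.character(annotations), clusters), function(a) {
        tab <- table(a)
        top <- tab[tab == max(tab)]
        data.frame(annotation = sort(names(top))[1],
                   ambiguous = length(top) > 1)
    })
    out <- do.call(rbind, res)
    out <- data.frame(cluster_id = names(res), out,
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(match(out$cluster_id, unique(clusters))), , drop = FALSE]
}

#' Per-cluster profiles: annotation, class, sex specificity and sex counts
#'
#' Combines the predominant-label annotation with an (optional) annotation
#' category table declaring the broad class and sex specificity of each
#' annotation, and tabulates cell numbers per sex and replicate. Sex
#' specificity is declared via the table, not inferred from composition —
#' inference would confound the composition-bias statistic being tested.
#'
#' @param x a \linkS4class{SexedAtlas} (cells with sex \code{"mix"} are
#'   ignored in the sex counts).
#' @param clusters cluster ids per cell (e.g. from
#'   \code{\link{clusterCells}}), aligned with the columns of \code{x}.
#' @param annotationTable optional \code{data.frame} with columns
#'   \code{annotation}, \code{broad_class} (one of the nine classes: blood,
#'   connective, epithelial, germ, immune, muscle, nervous, sensory, stem),
#'   \code{sex_specificity} (\code{male_specific}, \code{female_specific} or
#'   \code{non_sex_specific}).
#' @return \code{data.frame} with one row per cluster: \code{cluster_id},
#'   \code{annotation}, \code{ambiguous}, \code{broad_class},
#'   \code{sex_specificity}, \code{n_cells}, \code{n_female}, \code{n_male};
#'   the full cluster x replicate x sex count array is attached as
#'   \code{attr(, "counts")}.
#' @export
clusterProfiles <- function(x, clusters, annotationTable = NULL) {
    stopifnot(methods::is(x, "SexedAtlas"), length(clusters) == ncol(x))
    clusters <- as.character(clusters)
    ann <- annotateClusters(clusters, x$annotation)
    sexed <- x$sex %in% c("female", "male")
    cnt <- table(cluster = factor(clusters[sexed], unique(clusters)),
                 replicate = x$replicate[sexed],
                 sex = factor(x$sex[sexed], c("female", "male")))
    prof <- ann
    prof$broad_class <- NA_character_
    prof$sex_specificity <- "non_sex_specific"
    if (!is.null(annotationTable)) {
        i <- match(prof$annotation, annotationTable$annotation)
        if ("broad_class" %in% names(annotationTable)) {
            bc <- annotationTable$broad_class[i]
            bad <- setdiff(stats::na.omit(unique(bc)), .BROAD_CLASSES)
            if (length(bad))
                stop("broad_class values outside the nine classes: ",
                     paste(bad, collapse = ", "))
            prof$broad_class <- bc
        }
        if ("sex_specificity" %in% names(annotationTable)) {
            ss <- annotationTable$sex_specificity[i]
            bad <- setdiff(stats::na.omit(unique(ss)), .SEXSPEC_LEVELS)
            if (length(bad))
                stop("unknown sex_specificity value(s): ",
                     paste(bad, collapse = ", "))
            prof$sex_specificity <- ifelse(is.na(ss), "non_sex_specific", ss)
        }
    }
    m <- match(prof$cluster_id, dimnames(cnt)$cluster)
    prof$n_female <- apply(cnt[, , "female", drop = FALSE], 1, sum)[m]
    prof$n_male <- apply(cnt[, , "male", drop = FALSE], 1, sum)[m]
    prof$n_cells <- as.vector(table(factor(clusters,
                                           prof$cluster_id))[prof$cluster_id])
    attr(prof, "counts") <- cnt
    prof
}

#' Cluster-size filter: require a minimum number of male nuclei
#'
#' Clusters with fewer than \code{minMaleNuclei} male nuclei are excluded
#' from sex-difference inference (their composition and expression
#' statistics would be unreliable).
#'
#' @param profiles output of \code{\link{clusterProfiles}} (needs columns
#'   \code{cluster_id} and \code{n_male}).
#' @param minMaleNuclei retention threshold; a cluster is kept when
#'   \code{n_male >= minMaleNuclei}.
#' @return character vector of retained cluster ids; the excluded ids are
#'   attached as \code{attr(, "excluded")} and reported via \code{message()}.
#' @export
filterClusters <- function(profiles, minMaleNuclei = 100) {
    keep <- profiles$n_male >= minMaleNuclei
    excluded <- profiles$cluster_id[!keep]
    if (length(excluded))
        message("filterClusters: excluded ", length(excluded),
                " cluster(s) with < ", minMaleNuclei, " male nuclei: ",
                paste(excluded, collapse = ", "))
    out <- profiles$cluster_id[keep]
    attr(out, "excluded") <- excluded
    out
}
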