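#' Pipeline configuration with the analysis' reference defaults
#'
#' Collects every tunable of the sex-bias pipeline. The defaults reproduce
#' the reference analysis settings exactly: Leiden resolution 4.0 (the
#' replicated head/body setting; dissected tissues use 1.0), cluster filter
#' at 100 male nuclei, composition pseudocount 1e-256, expression
#' normalization to 10,000 counts per cell, expression offset 1e-9, and
#' female-positive display orientation.
#'
#' @param input optional input path (see \code{\link{readDataset}}).
#' @param format input format.
#' @param fieldMap metadata field mapping.
#' @param resolution Leiden resolution.
#' @param clusterBy \code{"leiden"} or the name of a colData column holding
#'   precomputed cluster ids (e.g. \code{"true_cluster"} for synthetic
#'   atlases).
#' @param minMaleNuclei cluster-size filter threshold.
#' @param pseudocount composition-bias pseudocount.
#' @param targetSum expression normalization target.
#' @param offset expression-bias offset.
#' @param panels packaged panel names (or file paths) to score.
#' @param testMode Wilcoxon mode for the composition test.
#' @param orientation display orientation of expression bias.
#' @param sexspecAnnotations annotations removed as sex-specific cell types.
#' @param annotationTable optional annotation category table (see
#'   \code{\link{clusterProfiles}}).
#' @param seed integer seed for the clustering stage.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(input = NULL, format = "mtx_dir",
                           fieldMap = .defaultFieldMap(),
                           resolution = 4.0, clusterBy = "leiden",
                           minMaleNuclei = 100, pseudocount = 1e-256,
                           targetSum = 1e4, offset = 1e-9,
                           panels = c("RP_FBgg0000141", "translation_other",
                                      "genes_of_interest"),
                           testMode = "unpaired", orientation = "female",
                           sexspecAnnotations = character(0),
                           annotationTable = NULL, seed = 0L) {
    structure(list(input = input, format = format, fieldMap = fieldMap,
                   resolution = resolution, clusterBy = clusterBy,
                   minMaleNuclei = minMaleNuclei, pseudocount = pseudocount,
                   targetSum = targetSum, offset = offset, panels = panels,
                   testMode = testMode, orientation = orientation,
                   sexspecAnnotations = sexspecAnnotations,
                   annotationTable = annotationTable,
                   seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' Run the full sex-bias analysis
#'
#' Orchestrates ingest, cell filtering, clustering, composition bias,
#' expression bias and panel scoring, writing one CSV per stage plus a run
#' manifest. Deterministic: a fixed atlas, config and seed give
#' bit-identical tables.
#'
#' @param x a \linkS4class{SexedAtlas}, or \code{NULL} to read
#'   \code{config$input}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outdir output directory, created if needed.
#' @return (invisibly) the report bundle: a list with the result tables
#'   (\code{composition}, \code{gene_bias}, \code{panel_scores},
#'   \code{stoichiometry}, \code{myc_correlation}), the written
#'   \code{files}, and the \code{manifest}.
#' @export
runPipeline <- function(x = NULL, config = pipelineConfig(),
                        outdir = tempfile("scSexBias_run_")) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(x)) {
        if (is.null(config$input)) stop("stage ingest: no atlas and no input path given")
        x <- readDataset(config$input, config$format, config$fieldMap)
    }
    x <- filterCells(x, config$sexspecAnnotations)
    if (ncol(x) == 0) stop("stage filter: no cells left after filtering")

    clusters <- if (identical(config$clusterBy, "leiden")) {
        as.character(clusterCells(x, resolution = config$resolution,
                                  seed = config$seed))
    } else {
        cd <- SummarizedExperiment::colData(x)
        if (!config$clusterBy %in% colnames(cd))
            stop("stage cluster: colData column '", config$clusterBy,
                 "' not found; set clusterBy = \"leiden\" or a valid column")
        as.character(cd[[config$clusterBy]])
    }

    profiles <- clusterProfiles(x, clusters, config$annotationTable)
    retained <- filterClusters(profiles, config$minMaleNuclei)
    nss <- profiles$cluster_id[profiles$sex_specificity == "non_sex_specific"]
    retained <- intersect(retained, nss)

    files <- character(0); bundle <- list()
    writeTab <- function(df, name) {
        path <- file.path(outdir, name)
        utils::write.csv(df, path, row.names = FALSE)
        files[[name]] <<- path
        df
    }

    if (!length(retained)) {
        warning("no cluster passed the filters; composition table is empty")
        comp <- data.frame(cluster_id = character(0), n_female = integer(0),
                           n_male = integer(0), B = numeric(0),
                           p = numeric(0), q = numeric(0))
        writeTab(comp, "composition.csv")
        bundle$composition <- comp
    } else {
        comp <- compositionBias(x, clusters, clustersUse = retained,
                                pseudocount = config$pseudocount,
                                mode = config$testMode)
        comp$annotation <- profiles$annotation[match(comp$cluster_id,
                                                     profiles$cluster_id)]
        writeTab(comp, "composition.csv")
        bundle$composition <- comp

        xn <- normalizeExpression(x, config$targetSum)
        cln <- clusters[match(colnames(xn), colnames(x))]
        gb <- geneSexBias(xn, cln, clustersUse = retained,
                          offset = config$offset)
        gbOut <- orientBias(gb, config$orientation)
        writeTab(gbOut, "gene_bias.csv")
        bundle$gene_bias <- gbOut

        bundle$panel_scores <- list()
        for (p in config$panels) {
            panel <- tryCatch(loadGenePanel(p), error = function(e) NULL)
            if (is.null(panel)) next
            present <- intersect(panel, unique(gb$gene))
            if (!length(present)) next
            ps <- panelScore(gbOut, panel)
            nm <- attr(panel, "name")
            writeTab(ps, paste0("panel_scores_", nm, ".csv"))
            bundle$panel_scores[[nm]] <- ps
            bundle$panels[[nm]] <- panel
        }
        rp <- tryCatch(loadGenePanel(config$panels[1]),
                       error = function(e) NULL)
        if (!is.null(rp) && length(intersect(rp, gb$gene)) >= 2 &&
            length(retained) >= 3) {
            sm <- stoichiometryMatrix(gbOut, rp)
            writeTab(data.frame(gene = rownames(sm), sm,
                                check.names = FALSE), "stoichiometry.csv")
            bundle$stoichiometry <- sm
            if ("Myc" %in% gb$gene && !is.null(bundle$panel_scores[[1]])) {
                ps1 <- bundle$panel_scores[[1]]
                myc <- gbOut$score[gbOut$gene == "Myc"]
                names(myc) <- gbOut$cluster_id[gbOut$gene == "Myc"]
                pv <- stats::setNames(ps1$mean_score, ps1$cluster_id)
                mc <- geneVsPanelCorrelation(myc, pv)
                writeTab(data.frame(gene = "Myc", rho = mc$rho, p = mc$p,
                                    n = mc$n), "myc_correlation.csv")
                bundle$myc_correlation <- mc
            }
        }
    }
    writeTab(profiles[, setdiff(names(profiles), "counts")], "clusters.csv")
    bundle$profiles <- profiles
    bundle$retained <- retained

    checks <- vapply(files, function(f)
        digest::digest(readLines(f), algo = "md5"), character(1))
    manifest <- list(
        package = "scSexBias",
        version = as.character(utils::packageVersion("scSexBias")),
        r_version = R.version.string,
        seed = config$seed,
        config_hash = digest::digest(config, algo = "md5"),
        config = config[setdiff(names(config), c("annotationTable",
                                                 "fieldMap"))],
        table_checksums = as.list(checks),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    bundle$files <- files
    bundle$manifest <- manifest
    bundle$outdir <- outdir
    invisible(bundle)
}

#' Figures of a pipeline run
#'
#' Produces (1) the composition scatter: percent female cells against
#' percent male cells per cluster, with the equality diagonal (dashed),
#' 1.25-fold guide lines (dotted) and 2.0-fold guide lines (solid); and (2)
#' the cluster x gene score heatmap of the first panel with the panel-mean
#' row (and Myc, when present) appended at the bottom. For plot legibility
#' only, composition values are clipped at the 2-fold guide frame;
#' tables are never clipped.
#'
#' @param bundle a result of \code{\link{runPipeline}}.
#' @param outdir where to write the figure files (defaults to the bundle's
#'   output directory).
#' @param format \code{"png"} or \code{"pdf"}.
#' @return character vector of figure paths (empty, with a warning, when
#'   the bundle holds no data to plot).
#' @export
makeFigures <- function(bundle, outdir = bundle$outdir, format = c("png", "pdf")) {
    format <- match.arg(format)
    paths <- character(0)
    comp <- bundle$composition
    if (is.null(comp) || !nrow(comp)) {
        warning("empty composition table; no figure written")
        return(paths)
    }
    lim <- max(comp$pct_female, comp$pct_male) * 1.05
    sc <- ggplot2::ggplot(comp,
            ggplot2::aes(x = pct_male, y = pct_female)) +
        ggplot2::geom_abline(slope = 1, linetype = "dashed",
                             colour = "grey40") +
        ggplot2::geom_abline(slope = 1.25, linetype = "dotted") +
        ggplot2::geom_abline(slope = 1 / 1.25, linetype = "dotted") +
        ggplot2::geom_abline(slope = 2, linetype = "solid") +
        ggplot2::geom_abline(slope = 1 / 2, linetype = "solid") +
        ggplot2::geom_point(ggplot2::aes(colour = B > 0), size = 2,
                            show.legend = FALSE) +
        ggplot2::scale_colour_manual(values = c("TRUE" = "#c23b3b",
                                                "FALSE" = "#3b6fc2")) +
        ggplot2::coord_cartesian(xlim = c(0, lim), ylim = c(0, lim)) +
        ggplot2::labs(x = "% male cells", y = "% female cells") +
        ggplot2::theme_classic()
    f1 <- file.path(outdir, paste0("composition_scatter.", format))
    ggplot2::ggsave(f1, sc, width = 5, height = 5, dpi = 150)
    paths <- c(paths, f1)

    if (!is.null(bundle$gene_bias) && length(bundle$panel_scores)) {
        panel <- bundle$panels[[names(bundle$panel_scores)[1]]]
        extra <- intersect("Myc", bundle$gene_bias$gene)
        hm <- heatmapTable(bundle$gene_bias, panel, extraGenes = extra)
        long <- data.frame(
            gene = factor(rep(rownames(hm), ncol(hm)), rev(rownames(hm))),
            cluster = factor(rep(colnames(hm), each = nrow(hm)),
                             colnames(hm)),
            score = as.vector(hm))
        hp <- ggplot2::ggplot(long,
                ggplot2::aes(x = cluster, y = gene, fill = score)) +
            ggplot2::geom_tile() +
            ggplot2::scale_fill_gradient2(low = "#3b6fc2", mid = "white",
                                          high = "#c23b3b") +
            ggplot2::labs(x = "cluster", y = NULL, fill = "score") +
            ggplot2::theme_minimal(base_size = 8)
        f2 <- file.path(outdir, paste0("score_heatmap.", format))
        ggplot2::ggsave(f2, hp, width = 6,
                        height = max(3, nrow(hm) * 0.14), dpi = 150,
                        limitsize = FALSE)
        paths <- c(paths, f2)
    }
    paths
}
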