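#' Load a gene panel
#'
#' Panels are newline-delimited text files (lines starting with \code{#} are
#' provenance comments). Three panels ship with the package:
#' \describe{
#'   \item{\code{"RP_FBgg0000141"}}{94 ribosomal-protein genes (54 large +
#'     40 small subunit). Membership reconstructed from standard FlyBase
#'     ribosomal-protein nomenclature (synthetic stand-in for the versioned
#'     FlyBase gene group, which is not fetched at runtime).}
#'   \item{\code{"translation_other"}}{61 further translation-associated
#'     genes (initiation/elongation/release factors; reconstructed list).}
#'   \item{\code{"genes_of_interest"}}{the 9 growth-regulator genes DENR,
#'     InR, MCTS1, Myc, Nelf-A, NELF-B, Nelf-E, pix, tor.}
#' }
#'
#' @param panel a packaged panel name (above) or a path to a panel file.
#' @return character vector of unique gene identifiers with attributes
#'   \code{name} and \code{provenance}.
#' @examples
#' length(loadGenePanel("RP_FBgg0000141"))
#' @export
loadGenePanel <- function(panel) {
    builtin <- c(RP_FBgg0000141 = "panel_rp.synthetic.txt",
                 translation_other = "panel_translation.synthetic.txt",
                 genes_of_interest = "panel_genes_of_interest.txt")
    path <- if (panel %in% names(builtin)) {
        system.file("extdata", "panels", builtin[[panel]],
                    package = "scSexBias", mustWork = TRUE)
    } else panel
    if (!file.exists(path)) stop("panel file '", path, "' not found")
    lines <- readLines(path)
    prov <- sub("^#\\s*", "", lines[startsWith(lines, "#")])
    genes <- trimws(lines[!startsWith(lines, "#") & nzchar(trimws(lines))])
    if (!length(genes)) stop("panel '", panel, "' is empty")
    if (anyDuplicated(genes)) stop("panel '", panel, "' has duplicate genes")
    structure(genes, name = if (panel %in% names(builtin)) panel
                             else basename(path),
              provenance = paste(prov, collapse = " "))
}

#' Mean panel score per cluster (ribosomal-protein cell-size proxy)
#'
#' Aggregates per-gene sex-bias scores into a per-cluster panel score: the
#' arithmetic mean of the scores of the panel genes present in the table.
#' With the ribosomal-protein panel this mean score serves as a proxy for
#' the sex bias in cell size (ribosome content scales with cell size).
#' Missing panel genes are listed, never imputed; a cluster covering no
#' panel gene is an error.
#'
#' @param bias gene-bias table from \code{\link{geneSexBias}} (optionally
#'   oriented with \code{\link{orientBias}}).
#' @param panel character vector of panel genes
#'   (\code{\link{loadGenePanel}}).
#' @param scoreCol column to average (default \code{"score"}).
#' @return \code{data.frame}: \code{cluster_id}, \code{mean_score},
#'   \code{n_genes_used}, \code{n_missing}; the missing genes per cluster
#'   are attached as \code{attr(, "missing")}.
#' @export
panelScore <- function(bias, panel, scoreCol = "score") {
    stopifnot(scoreCol %in% names(bias))
    ids <- unique(bias$cluster_id)
    missing <- list()
    rows <- lapply(ids, function(cid) {
        sub <- bias[bias$cluster_id == cid & bias$gene %in% panel, ]
        if (!nrow(sub))
            stop("cluster ", cid, " covers no gene of the panel")
        missing[[cid]] <<- setdiff(panel, sub$gene)
        data.frame(cluster_id = cid, mean_score = mean(sub[[scoreCol]]),
                   n_genes_used = nrow(sub),
                   n_missing = length(panel) - nrow(sub),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "missing") <- missing
    out
}

#' Cross-cluster correlation of panel-gene scores (stoichiometry check)
#'
#' Ribosomal proteins are needed in stoichiometric amounts, so their
#' sex-bias scores should co-vary across cell types. This computes the
#' gene x gene correlation matrix of the panel genes' score vectors across
#' clusters (Pearson by default, Spearman by flag). A gene whose score is
#' constant across clusters has no defined correlation; its entries are
#' \code{NA}, recorded as missing rather than zero.
#'
#' @param bias gene-bias table from \code{\link{geneSexBias}}.
#' @param panel panel gene identifiers.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param scoreCol score column name.
#' @return symmetric correlation matrix (unit diagonal for non-constant
#'   genes) over the panel genes present in \code{bias}.
#' @export
stoichiometryMatrix <- function(bias, panel,
                                method = c("pearson", "spearman"),
                                scoreCol = "score") {
    method <- match.arg(method)
    ids <- unique(bias$cluster_id)
    if (length(ids) < 3) stop("need >= 3 clusters")
    genes <- intersect(panel, unique(bias$gene))
    if (length(genes) < 2) stop("fewer than 2 panel genes present")
    m <- matrix(NA_real_, length(ids), length(genes),
                dimnames = list(ids, genes))
    idx <- cbind(match(bias$cluster_id, ids), match(bias$gene, genes))
    ok <- !is.na(idx[, 2])
    m[idx[ok, , drop = FALSE]] <- bias[[scoreCol]][ok]
    const <- matrixStats::colSds(m, na.rm = TRUE) == 0
    cc <- suppressWarnings(stats::cor(m, method = method,
                                      use = "pairwise.complete.obs"))
    cc[const, ] <- NA_real_; cc[, const] <- NA_real_
    diag(cc)[!const] <- 1
    if (any(const))
        message("stoichiometryMatrix: constant score vector(s), recorded NA: ",
                paste(genes[const], collapse = ", "))
    cc
}

#' Spearman correlation of one gene's score with the panel score
#'
#' Used to relate a growth regulator (e.g. Myc) to the ribosomal-protein
#' panel score across clusters. Midranks handle ties; the p-value is exact
#' for small n without ties and uses the t approximation otherwise.
#'
#' @param geneScore named numeric, per-cluster score of the gene.
#' @param panelScore named numeric, per-cluster panel mean score; names are
#'   matched when present.
#' @return list with \code{rho}, \code{p}, \code{n}.
#' @export
geneVsPanelCorrelation <- function(geneScore, panelScore) {
    if (!is.null(names(geneScore)) && !is.null(names(panelScore))) {
        common <- intersect(names(geneScore), names(panelScore))
        geneScore <- geneScore[common]; panelScore <- panelScore[common]
    }
    if (length(geneScore) != length(panelScore))
        stop("score vectors must be aligned")
    if (length(geneScore) < 3) stop("need >= 3 paired cluster values")
    ct <- suppressWarnings(
        stats::cor.test(geneScore, panelScore, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(geneScore))
}

#' Cluster x gene score matrix with panel-mean and marker rows appended
#'
#' Export helper mirroring the heatmap layout: one row per panel gene, one
#' column per cluster, with the panel mean score and any extra marker genes
#' (e.g. Myc) appended as final rows.
#'
#' @param bias gene-bias table (\code{\link{geneSexBias}}, oriented as
#'   desired).
#' @param panel panel gene identifiers.
#' @param extraGenes genes appended as additional rows.
#' @param scoreCol score column.
#' @return numeric matrix, rows = panel genes + \code{"panel_mean"} +
#'   extra genes, columns = clusters.
#' @export
heatmapTable <- function(bias, panel, extraGenes = character(0),
                         scoreCol = "score") {
    ids <- unique(bias$cluster_id)
    genes <- c(intersect(panel, unique(bias$gene)), extraGenes)
    m <- matrix(NA_real_, length(genes), length(ids),
                dimnames = list(genes, ids))
    sub <- bias[bias$gene %in% genes, ]
    m[cbind(match(sub$gene, genes), match(sub$cluster_id, ids))] <-
        sub[[scoreCol]]
    ps <- panelScore(bias, panel, scoreCol = scoreCol)
    rbind(m[intersect(panel, rownames(m)), , drop = FALSE],
          panel_mean = ps$mean_score[match(ids, ps$cluster_id)],
          m[extraGenes, , drop = FALSE])
}
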