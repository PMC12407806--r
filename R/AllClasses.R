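#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

.SEX_LEVELS <- c("female", "male", "mix")
.BROAD_CLASSES <- c("blood", "connective", "epithelial", "germ", "immune",
                    "muscle", "nervous", "sensory", "stem")
.SEXSPEC_LEVELS <- c("male_specific", "female_specific", "non_sex_specific")

#' SexedAtlas: a sexed single-nucleus expression atlas
#'
#' A \linkS4class{SingleCellExperiment} whose columns are nuclei and whose
#' rows are genes, carrying the per-cell metadata the sex-bias pipeline
#' requires: \code{sex} (one of \code{"female"}, \code{"male"}, \code{"mix"}),
#' \code{replicate}, \code{sample}, \code{annotation} and the logical
#' \code{is_artefact}. The \code{"counts"} assay holds non-negative integer
#' UMI counts. Cells flagged \code{"mix"} or artefact are kept (flagged, never
#' silently dropped) until \code{\link{filterCells}} is applied.
#'
#' @slot int_elementMetadata,int_colData,... inherited from
#'   \code{SingleCellExperiment}; no additional slots are defined.
#'
#' @seealso \code{\link{SexedAtlas}} the constructor,
#'   \code{\link{generateAtlas}}, \code{\link{readDataset}}.
#' @export
setClass("SexedAtlas", contains = "SingleCellExperiment")

.validSexedAtlas <- function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        v <- if (methods::is(cts, "sparseMatrix")) cts@x else as.vector(cts)
        if (length(v) && min(v) < 0)
            msg <- c(msg, "counts must be non-negative")
        if (length(v) && any(abs(v - round(v)) > 1e-8))
            msg <- c(msg, "counts must be integral (UMI counts)")
    }
    cd <- SummarizedExperiment::colData(object)
    needed <- c("sex", "replicate", "sample", "annotation", "is_artefact")
    missing <- setdiff(needed, colnames(cd))
    if (length(missing))
        msg <- c(msg, paste0("missing colData column(s): ",
                             paste(missing, collapse = ", ")))
    if ("sex" %in% colnames(cd)) {
        bad <- setdiff(unique(as.character(cd$sex)), .SEX_LEVELS)
        if (length(bad))
            msg <- c(msg, paste0("unknown sex value(s): ",
                                 paste(bad, collapse = ", ")))
    }
    if (!is.null(colnames(object)) && anyDuplicated(colnames(object)))
        msg <- c(msg, "cell ids (colnames) must be unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("SexedAtlas", .validSexedAtlas)

#' Construct a SexedAtlas
#'
#' @param counts gene x cell matrix (dense or \code{dgCMatrix}) of
#'   non-negative integer UMI counts, with row and column names.
#' @param sex character vector per cell; values in
#'   \code{c("female","male","mix")}.
#' @param replicate,sample,annotation character vectors per cell.
#' @param is_artefact logical per cell; defaults to all \code{FALSE}.
#' @param ... further columns added to \code{colData}.
#'
#' @return a validated \linkS4class{SexedAtlas}.
#' @examples
#' m <- matrix(rpois(12, 2), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("cell", 1:4)))
#' SexedAtlas(m, sex = c("female", "female", "male", "male"),
#'            replicate = c("r1", "r2", "r1", "r2"))
#' @export
SexedAtlas <- function(counts, sex, replicate,
                       sample = "sample1",
                       annotation = "unannotated",
                       is_artefact = FALSE, ...) {
    n <- ncol(counts)
    cd <- S4Vectors::DataFrame(
        sex = rep_len(as.character(sex), n),
        replicate = rep_len(as.character(replicate), n),
        sample = rep_len(as.character(sample), n),
        annotation = rep_len(as.character(annotation), n),
        is_artefact = rep_len(as.logical(is_artefact), n),
        ...)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = cd)
    methods::new("SexedAtlas", sce)
}

#' @describeIn SexedAtlas compact display
#' @param object a \code{SexedAtlas}
#' @export
setMethod("show", "SexedAtlas", function(object) {
    methods::callNextMethod()
    sx <- table(factor(object$sex, .SEX_LEVELS))
    cat("sex:", paste(sprintf("%s=%d", names(sx), sx), collapse = " "),
        "| artefact:", sum(object$is_artefact),
        "| replicates:", length(unique(object$replicate)), "\n")
})

#' Configuration for the synthetic atlas generator
#'
#' Holds all parameters of the negative-binomial atlas simulator. Clusters
#' are identified as \code{"c1"} ... \code{"cK"}; genes are named after
#' \code{panelGenes} first, then filled up with \code{"gene_i"}.
#'
#' @slot nClusters,nGenes,replicatesPerSex,cellsPerReplicate integers.
#' @slot compositionBias named numeric; female:male proportion fold per
#'   cluster (unnamed clusters default to 1).
#' @slot panelGenes character; genes forming the high-expression panel.
#' @slot panelFold named numeric; multiplicative female expression shift
#'   applied to panel genes within the named clusters.
#' @slot logMeanMu,logMeanSigma log-normal parameters for baseline gene
#'   means (UMI per cell).
#' @slot dispersion negative-binomial size parameter.
#' @slot libsizeCV coefficient of variation of the per-cell library factor.
#' @slot fracArtefact,fracMixSex probabilities of the artefact label and of
#'   the "mix" sex label.
#' @slot sexspecClusters character; clusters generated with one sex only.
#' @slot clusterDeSd sd (log scale) of per-cluster gene multipliers; larger
#'   values make clusters more separable.
#' @slot panelBaselineFactor baseline-mean multiplier for panel genes
#'   (ribosomal-protein transcripts are among the most abundant).
#' @slot seed integer RNG seed.
#' @seealso \code{\link{synthConfig}}, \code{\link{generateAtlas}}
#' @export
setClass("SynthConfig", representation(
    nClusters = "integer", nGenes = "integer",
    replicatesPerSex = "integer", cellsPerReplicate = "integer",
    compositionBias = "numeric", panelGenes = "character",
    panelFold = "numeric", logMeanMu = "numeric", logMeanSigma = "numeric",
    dispersion = "numeric", libsizeCV = "numeric",
    fracArtefact = "numeric", fracMixSex = "numeric",
    sexspecClusters = "character", clusterDeSd = "numeric",
    panelBaselineFactor = "numeric", seed = "integer"))

.validSynthConfig <- function(object) {
    msg <- NULL
    chkpos <- function(x, nm) if (length(x) != 1 || is.na(x) || x <= 0)
        paste0("'", nm, "' must be a positive scalar") else NULL
    msg <- c(msg,
             chkpos(object@nClusters, "nClusters"),
             chkpos(object@nGenes, "nGenes"),
             chkpos(object@replicatesPerSex, "replicatesPerSex"),
             chkpos(object@cellsPerReplicate, "cellsPerReplicate"),
             chkpos(object@dispersion, "dispersion"),
             chkpos(object@logMeanSigma, "logMeanSigma"),
             chkpos(object@panelBaselineFactor, "panelBaselineFactor"))
    if (object@replicatesPerSex < 2)
        msg <- c(msg, "'replicatesPerSex' must be >= 2 for any test to be defined")
    ids <- .clusterIds(object@nClusters)
    for (nm in c("compositionBias", "panelFold")) {
        v <- methods::slot(object, nm)
        if (length(v)) {
            if (any(v <= 0)) msg <- c(msg, paste0("'", nm, "' folds must be > 0"))
            if (is.null(names(v)) || !all(names(v) %in% ids))
                msg <- c(msg, paste0("'", nm, "' must be named by cluster ids (",
                                     ids[1], "...", ids[length(ids)], ")"))
        }
    }
    for (nm in c("fracArtefact", "fracMixSex")) {
        v <- methods::slot(object, nm)
        if (v < 0 || v >= 1)
            msg <- c(msg, paste0("'", nm, "' must be in [0, 1)"))
    }
    if (object@libsizeCV < 0) msg <- c(msg, "'libsizeCV' must be >= 0")
    if (length(object@sexspecClusters) &&
        !all(object@sexspecClusters %in% ids))
        msg <- c(msg, "'sexspecClusters' must be cluster ids")
    if (length(object@panelGenes) > object@nGenes)
        msg <- c(msg, "'panelGenes' longer than 'nGenes'")
    if (is.null(msg)) TRUE else msg
}
setValidity("SynthConfig", .validSynthConfig)

.clusterIds <- function(k) paste0("c", seq_len(k))

#' Create a synthetic-atlas configuration
#'
#' @param nClusters,nGenes,replicatesPerSex,cellsPerReplicate dimensions of
#'   the simulated atlas. Six replicates per sex mirror the replicated
#'   head/body samples the composition test is designed for.
#' @param compositionBias named numeric, cluster -> female:male proportion
#'   fold (default 1 everywhere).
#' @param panelGenes identifiers of the simulated high-expression gene panel.
#' @param panelFold named numeric, cluster -> multiplicative female shift on
#'   panel-gene expression.
#' @param logMeanMu,logMeanSigma,dispersion,libsizeCV count-model parameters.
#' @param fracArtefact,fracMixSex label-noise fractions in [0, 1).
#' @param sexspecClusters clusters to generate with cells of one sex only
#'   (alternately female- and male-specific).
#' @param clusterDeSd log-sd of cluster-specific gene multipliers.
#' @param panelBaselineFactor baseline-mean multiplier for panel genes.
#' @param seed integer RNG seed.
#' @return a validated \linkS4class{SynthConfig}.
#' @examples
#' synthConfig(nClusters = 4, nGenes = 50, cellsPerReplicate = 500)
#' @export
synthConfig <- function(nClusters, nGenes, replicatesPerSex = 6L,
                        cellsPerReplicate = 1000L,
                        compositionBias = numeric(0),
                        panelGenes = character(0),
                        panelFold = numeric(0),
                        logMeanMu = -0.5, logMeanSigma = 1,
                        dispersion = 2, libsizeCV = 0.3,
                        fracArtefact = 0.02, fracMixSex = 0.02,
                        sexspecClusters = character(0),
                        clusterDeSd = 0.5,
                        panelBaselineFactor = 8,
                        seed = 1L) {
    methods::new("SynthConfig",
        nClusters = as.integer(nClusters), nGenes = as.integer(nGenes),
        replicatesPerSex = as.integer(replicatesPerSex),
        cellsPerReplicate = as.integer(cellsPerReplicate),
        compositionBias = compositionBias, panelGenes = panelGenes,
        panelFold = panelFold, logMeanMu = logMeanMu,
        logMeanSigma = logMeanSigma, dispersion = dispersion,
        libsizeCV = libsizeCV, fracArtefact = fracArtefact,
        fracMixSex = fracMixSex,
        sexspecClusters = as.character(sexspecClusters),
        clusterDeSd = clusterDeSd,
        panelBaselineFactor = panelBaselineFactor, seed = as.integer(seed))
}

#' @describeIn synthConfig display method
#' @param object a \code{SynthConfig}
#' @export
setMethod("show", "SynthConfig", function(object) {
    cat(sprintf(paste0("SynthConfig: %d clusters x %d genes, ",
                       "%d replicates/sex x %d cells, seed %d\n"),
                object@nClusters, object@nGenes, object@replicatesPerSex,
                object@cellsPerReplicate, object@seed))
    if (length(object@compositionBias))
        cat("  composition folds:",
            paste(sprintf("%s=%.3g", names(object@compositionBias),
                          object@compositionBias), collapse = " "), "\n")
    if (length(object@panelFold))
        cat("  panel folds:",
            paste(sprintf("%s=%.3g", names(object@panelFold),
                          object@panelFold), collapse = " "), "\n")
})
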