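#' Default metadata field mapping for Fly Cell Atlas style files
#'
#' Maps the pipeline's required per-cell fields to metadata column names.
#' \code{artefact} may be \code{NA}, in which case cells are considered
#' artefacts when their annotation equals \code{"artefact"} (the FCA
#' convention); otherwise it names a logical metadata column.
#'
#' @param sex,replicate,sample,annotation,artefact column names in the input
#'   file's per-cell metadata.
#' @return a named list usable as \code{fieldMap} in \code{\link{readDataset}}.
#' @export
fcaFieldMap <- function(sex = "sex", replicate = "batch", sample = "sample_id",
                        annotation = "annotation", artefact = NA_character_) {
    list(sex = sex, replicate = replicate, sample = sample,
         annotation = annotation, artefact = artefact)
}

.defaultFieldMap <- function() {
    list(sex = "sex", replicate = "replicate", sample = "sample",
         annotation = "annotation", artefact = "is_artefact")
}

.buildAtlas <- function(counts, meta, genes, cells, fieldMap, source) {
    for (f in c("sex", "replicate", "sample", "annotation")) {
        col <- fieldMap[[f]]
        if (is.null(col) || is.na(col) || !col %in% colnames(meta))
            stop("metadata column '", fieldMap[[f]], "' (mapped to '", f,
                 "') not found in ", source)
    }
    sex <- as.character(meta[[fieldMap$sex]])
    bad <- setdiff(unique(sex), .SEX_LEVELS)
    if (length(bad))
        stop("unknown sex value(s): ", paste(bad, collapse = ", "),
             " (expected female/male/mix)")
    art <- fieldMap$artefact
    isArt <- if (is.null(art) || is.na(art)) {
        as.character(meta[[fieldMap$annotation]]) == "artefact"
    } else {
        if (!art %in% colnames(meta))
            stop("metadata column '", art, "' (mapped to 'artefact') not found in ",
                 source)
        as.logical(meta[[art]])
    }
    v <- if (methods::is(counts, "sparseMatrix")) counts@x else as.vector(counts)
    if (length(v) && any(abs(v - round(v)) > 1e-8))
        stop("counts in ", source, " are not integral UMI counts")
    dimnames(counts) <- list(genes, cells)
    atl <- SexedAtlas(counts = counts, sex = sex,
                      replicate = as.character(meta[[fieldMap$replicate]]),
                      sample = as.character(meta[[fieldMap$sample]]),
                      annotation = as.character(meta[[fieldMap$annotation]]),
                      is_artefact = isArt)
    colnames(atl) <- cells
    atl
}

#' Read a sexed atlas from MTX, h5ad or loom
#'
#' Supported layouts: \describe{
#'   \item{\code{mtx_dir}}{a directory containing \code{matrix.mtx}
#'     (genes x cells), \code{features.tsv}, \code{barcodes.tsv} and
#'     \code{cell_metadata.tsv} (tab-separated, one row per cell).}
#'   \item{\code{h5ad}}{an AnnData HDF5 file with \code{X} stored dense or as
#'     a \code{csr_matrix}/\code{csc_matrix} group; \code{obs} columns may be
#'     plain arrays or categoricals.}
#'   \item{\code{loom}}{a loom HDF5 file with \code{matrix} plus
#'     \code{row_attrs/Gene} and \code{col_attrs/CellID}; matrix orientation
#'     is inferred from the attribute lengths.}
#' }
#'
#' @param path file (or directory for \code{mtx_dir}) to read.
#' @param format one of \code{"mtx_dir"}, \code{"h5ad"}, \code{"loom"}.
#' @param fieldMap named list mapping \code{sex}, \code{replicate},
#'   \code{sample}, \code{annotation}, \code{artefact} to metadata columns;
#'   see \code{\link{fcaFieldMap}}.
#' @return a validated \linkS4class{SexedAtlas}. Cells with sex
#'   \code{"mix"} or the artefact flag are retained and flagged, never
#'   dropped at read time.
#' @seealso \code{\link{writeDataset}}, \code{\link{filterCells}}
#' @export
readDataset <- function(path, format = c("mtx_dir", "h5ad", "loom"),
                        fieldMap = .defaultFieldMap()) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("input '", path, "' does not exist")
    switch(format,
           mtx_dir = .readMtxDir(path, fieldMap),
           h5ad = .readH5ad(path, fieldMap),
           loom = .readLoom(path, fieldMap))
}

.readMtxDir <- function(dir, fieldMap) {
    need <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "cell_metadata.tsv")
    miss <- need[!file.exists(file.path(dir, need))]
    if (length(miss))
        stop("mtx_dir is missing file(s): ", paste(miss, collapse = ", "))
    counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                          "CsparseMatrix")
    genes <- readLines(file.path(dir, "features.tsv"))
    cells <- readLines(file.path(dir, "barcodes.tsv"))
    meta <- utils::read.delim(file.path(dir, "cell_metadata.tsv"),
                              stringsAsFactors = FALSE)
    if (nrow(counts) != length(genes) || ncol(counts) != length(cells) ||
        nrow(meta) != length(cells))
        stop("dimension mismatch between matrix.mtx (", nrow(counts), " x ",
             ncol(counts), "), features (", length(genes), "), barcodes (",
             length(cells), ") and metadata rows (", nrow(meta), ")")
    .buildAtlas(counts, meta, genes, cells, fieldMap, dir)
}

.h5ReadString <- function(x) {
    if (is.list(x) && !is.null(x$categories)) {
        # anndata categorical encoding: integer codes into categories
        as.character(x$categories[x$codes + 1L])
    } else as.character(x)
}

.readH5ad <- function(path, fieldMap) {
    contents <- rhdf5::h5ls(path)
    xinfo <- contents[contents$group == "/" & contents$name == "X", ]
    obs <- rhdf5::h5read(path, "obs", read.attributes = TRUE)
    var <- rhdf5::h5read(path, "var", read.attributes = TRUE)
    cells <- as.character(obs[["_index"]])
    genes <- as.character(var[["_index"]])
    if (xinfo$otype == "H5I_GROUP") {
        x <- rhdf5::h5read(path, "X")
        enc <- rhdf5::h5readAttributes(path, "X")
        type <- as.character(enc[["encoding-type"]])
        shape <- as.integer(enc[["shape"]])  # (n_obs, n_var)
        if (!length(type)) type <- "csr_matrix"
        if (type == "csr_matrix") {
            # CSR of cells x genes == CSC of genes x cells
            counts <- Matrix::sparseMatrix(
                i = as.integer(x$indices) + 1L, p = as.integer(x$indptr),
                x = as.numeric(x$data), dims = c(shape[2], shape[1]))
        } else if (type == "csc_matrix") {
            counts <- Matrix::t(Matrix::sparseMatrix(
                i = as.integer(x$indices) + 1L, p = as.integer(x$indptr),
                x = as.numeric(x$data), dims = c(shape[1], shape[2])))
        } else stop("unsupported X encoding in h5ad: ", type)
    } else {
        m <- rhdf5::h5read(path, "X")
        # HDF5 row-major (n_obs, n_var) reads into R as n_var x n_obs
        counts <- Matrix::Matrix(m, sparse = TRUE)
        if (nrow(counts) != length(genes)) counts <- Matrix::t(counts)
    }
    counts <- methods::as(counts, "CsparseMatrix")
    if (nrow(counts) != length(genes) || ncol(counts) != length(cells))
        stop("dimension mismatch in h5ad: X is ", nrow(counts), " x ",
             ncol(counts), " but var has ", length(genes), " and obs ",
             length(cells), " entries")
    cols <- setdiff(names(obs), "_index")
    meta <- as.data.frame(lapply(obs[cols], function(v) {
        if (is.list(v) && !is.null(v$categories)) .h5ReadString(v)
        else as.vector(v)
    }), stringsAsFactors = FALSE, optional = TRUE)
    names(meta) <- cols
    .buildAtlas(counts, meta, genes, cells, fieldMap, path)
}

.readLoom <- function(path, fieldMap) {
    m <- rhdf5::h5read(path, "matrix")
    ra <- rhdf5::h5read(path, "row_attrs")
    ca <- rhdf5::h5read(path, "col_attrs")
    genes <- as.character(ra$Gene)
    cells <- as.character(ca$CellID)
    if (nrow(m) != length(genes) && ncol(m) == length(genes)) m <- t(m)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
        stop("dimension mismatch in loom: matrix is ", nrow(m), " x ", ncol(m),
             " but row_attrs/Gene has ", length(genes),
             " and col_attrs/CellID ", length(cells), " entries")
    meta <- as.data.frame(lapply(ca[setdiff(names(ca), "CellID")],
                                 as.vector),
                          stringsAsFactors = FALSE, optional = TRUE)
    counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    .buildAtlas(counts, meta, genes, cells, fieldMap, path)
}

#' Write a sexed atlas to MTX, h5ad or loom
#'
#' Writes the layouts documented in \code{\link{readDataset}}; a round trip
#' through any format reproduces counts and metadata. The generator seed (if
#' the atlas is synthetic) is recorded in the output metadata.
#'
#' @param x a \linkS4class{SexedAtlas}.
#' @param path output directory (\code{mtx_dir}) or file (\code{h5ad},
#'   \code{loom}); overwritten if present.
#' @param format one of \code{"mtx_dir"}, \code{"h5ad"}, \code{"loom"}.
#' @return invisibly, \code{path}.
#' @export
writeDataset <- function(x, path, format = c("mtx_dir", "h5ad", "loom")) {
    format <- match.arg(format)
    stopifnot(methods::is(x, "SexedAtlas"))
    meta <- as.data.frame(SummarizedExperiment::colData(x),
                          optional = TRUE)
    meta <- data.frame(cell_id = colnames(x), meta, stringsAsFactors = FALSE)
    counts <- SummarizedExperiment::assay(x, "counts")
    switch(format,
        mtx_dir = {
            dir.create(path, showWarnings = FALSE, recursive = TRUE)
            Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                            file.path(path, "matrix.mtx"))
            writeLines(rownames(x), file.path(path, "features.tsv"))
            writeLines(colnames(x), file.path(path, "barcodes.tsv"))
            utils::write.table(meta, file.path(path, "cell_metadata.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        },
        h5ad = .writeH5ad(counts, meta, rownames(x), colnames(x), path,
                          seed = S4Vectors::metadata(x)$seed),
        loom = .writeLoom(counts, meta, rownames(x), colnames(x), path,
                          seed = S4Vectors::metadata(x)$seed))
    invisible(path)
}

.h5attr <- function(file, obj, name, value, scalar = length(value) == 1) {
    fid <- rhdf5::H5Fopen(file)
    on.exit(rhdf5::H5Fclose(fid))
    oid <- rhdf5::H5Oopen(fid, obj)
    on.exit(rhdf5::H5Oclose(oid), add = TRUE, after = FALSE)
    rhdf5::h5writeAttribute(value, oid, name, asScalar = scalar,
                            variableLengthString = is.character(value),
                            encoding = "UTF-8")
}

.writeH5ad <- function(counts, meta, genes, cells, path, seed = NULL) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    counts <- methods::as(counts, "CsparseMatrix")
    rhdf5::h5createGroup(path, "X")
    # genes x cells CSC == cells x genes CSR expected by AnnData
    rhdf5::h5write(as.numeric(counts@x), path, "X/data")
    rhdf5::h5write(as.integer(counts@i), path, "X/indices")
    rhdf5::h5write(as.integer(counts@p), path, "X/indptr")
    .h5attr(path, "X", "encoding-type", "csr_matrix")
    .h5attr(path, "X", "encoding-version", "0.1.0")
    .h5attr(path, "X", "shape", c(length(cells), length(genes)),
            scalar = FALSE)
    writeCol <- function(v, name) {
        if (is.logical(v)) v <- as.integer(v)
        if (is.factor(v)) v <- as.character(v)
        rhdf5::h5write(v, path, name)
        .h5attr(path, name, "encoding-type",
                if (is.character(v)) "string-array" else "array")
        .h5attr(path, name, "encoding-version", "0.2.0")
    }
    rhdf5::h5createGroup(path, "obs")
    writeCol(cells, "obs/_index")
    cols <- setdiff(names(meta), "cell_id")
    for (cn in cols) writeCol(meta[[cn]], paste0("obs/", cn))
    .h5attr(path, "obs", "encoding-type", "dataframe")
    .h5attr(path, "obs", "encoding-version", "0.2.0")
    .h5attr(path, "obs", "_index", "_index")
    .h5attr(path, "obs", "column-order", cols, scalar = FALSE)
    rhdf5::h5createGroup(path, "var")
    writeCol(genes, "var/_index")
    writeCol(genes, "var/gene_ids")
    .h5attr(path, "var", "encoding-type", "dataframe")
    .h5attr(path, "var", "encoding-version", "0.2.0")
    .h5attr(path, "var", "_index", "_index")
    .h5attr(path, "var", "column-order", "gene_ids", scalar = FALSE)
    rhdf5::h5createGroup(path, "uns")
    if (!is.null(seed)) rhdf5::h5write(as.integer(seed), path, "uns/seed")
    rhdf5::h5closeAll()
}

.writeLoom <- function(counts, meta, genes, cells, path, seed = NULL) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(as.matrix(counts), path, "matrix")
    rhdf5::h5createGroup(path, "row_attrs")
    rhdf5::h5write(genes, path, "row_attrs/Gene")
    rhdf5::h5createGroup(path, "col_attrs")
    rhdf5::h5write(cells, path, "col_attrs/CellID")
    for (cn in setdiff(names(meta), "cell_id")) {
        v <- meta[[cn]]
        if (is.logical(v)) v <- as.integer(v)
        if (is.factor(v)) v <- as.character(v)
        rhdf5::h5write(v, path, paste0("col_attrs/", cn))
    }
    rhdf5::h5createGroup(path, "attrs")
    if (!is.null(seed)) rhdf5::h5write(as.integer(seed), path, "attrs/seed")
    rhdf5::h5closeAll()
}

#' Apply the cell-level filters of the sex-bias analysis
#'
#' Removes (1) cells annotated as a sex-specific cell type, (2) cells
#' flagged as artefacts and (3) cells whose sex is \code{"mix"}. The order
#' of surviving cells is preserved and the number removed per reason is
#' reported via \code{message()}.
#'
#' Idempotent: applying the filter twice equals applying it once.
#'
#' @param x a \linkS4class{SexedAtlas}.
#' @param sexspecAnnotations character set of annotations considered
#'   sex-specific cell types.
#' @return the filtered \code{SexedAtlas} (possibly with zero cells, with a
#'   warning).
#' @export
filterCells <- function(x, sexspecAnnotations = character(0)) {
    stopifnot(methods::is(x, "SexedAtlas"))
    art <- x$is_artefact
    mix <- x$sex == "mix"
    ss <- x$annotation %in% sexspecAnnotations
    keep <- !(art | mix | ss)
    message(sprintf(
        "filterCells: removed %d artefact, %d mix-sex, %d sex-specific; %d of %d cells retained",
        sum(art), sum(mix & !art), sum(ss & !art & !mix), sum(keep), length(keep)))
    if (!any(keep)) warning("all cells removed by filterCells()")
    x[, keep]
}
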