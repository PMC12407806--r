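mtxFixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 4", "1 1 5", "2 1 1", "1 2 2", "2 3 7"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("geneA", "geneB"), file.path(dir, "features.tsv"))
  writeLines(c("cell1", "cell2", "cell3"), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(cell_id = c("cell1", "cell2", "cell3"),
                         sex = c("female", "male", "mix"),
                         replicate = "r1", sample = "s1",
                         annotation = c("muscle", "muscle", "artefact"),
                         is_artefact = c(FALSE, FALSE, TRUE)),
              file.path(dir, "cell_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dir
}

test_that("a small MTX fixture reads into a flagged, validated atlas", {
  d <- mtxFixture(tempfile("mtx"))
  atl <- readDataset(d, "mtx_dir")
  expect_s4_class(atl, "SexedAtlas")
  expect_equal(dim(atl), c(2L, 3L))
  expect_equal(atl$sex, c("female", "male", "mix"))
  expect_equal(sum(atl$sex == "mix"), 1)   # flagged, not dropped
  expect_equal(sum(atl$is_artefact), 1)
  cts <- SummarizedExperiment::assay(atl, "counts")
  expect_equal(as.numeric(cts["geneA", "cell1"]), 5)
})

test_that("read errors name the offending column or value", {
  d <- mtxFixture(tempfile("mtx"))
  fm <- fcaFieldMap(sex = "sexx", replicate = "replicate",
                    sample = "sample", annotation = "annotation")
  expect_error(readDataset(d, "mtx_dir", fm), "sexx")
  meta <- read.delim(file.path(d, "cell_metadata.tsv"))
  meta$sex[2] <- "hermaphrodite"
  write.table(meta, file.path(d, "cell_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readDataset(d, "mtx_dir"), "hermaphrodite")
})

test_that("every format round-trips a generated atlas exactly", {
  atl <- tinyAtlas(seed = 10)
  for (fmt in c("mtx_dir", "h5ad", "loom")) {
    path <- tempfile(paste0("rt_", fmt))
    writeDataset(atl, path, fmt)
    back <- readDataset(path, fmt)
    expect_equal(unname(as.matrix(SummarizedExperiment::assay(back, "counts"))),
                 unname(as.matrix(SummarizedExperiment::assay(atl, "counts"))),
                 info = fmt)
    expect_equal(rownames(back), rownames(atl), info = fmt)
    expect_equal(colnames(back), colnames(atl), info = fmt)
    expect_equal(back$sex, atl$sex, info = fmt)
    expect_equal(back$replicate, atl$replicate, info = fmt)
    expect_equal(back$annotation, atl$annotation, info = fmt)
    expect_equal(back$is_artefact, atl$is_artefact, info = fmt)
  }
})

test_that("filterCells removes artefact, mix and sex-specific cells only", {
  m <- matrix(1L, nrow = 2, ncol = 10,
              dimnames = list(c("g1", "g2"), paste0("c", 1:10)))
  atl <- SexedAtlas(m,
      sex = c(rep("female", 4), rep("male", 5), "mix"),
      replicate = "r1",
      annotation = c("ovary", rep("neuron", 7), "artefact", "neuron"),
      is_artefact = c(rep(FALSE, 8), TRUE, FALSE))
  kept <- suppressMessages(filterCells(atl, sexspecAnnotations = "ovary"))
  expect_equal(ncol(kept), 7)  # 10 - 1 artefact - 1 mix - 1 sex-specific
  expect_false(any(kept$is_artefact))
  expect_false(any(kept$sex == "mix"))
  expect_false(any(kept$annotation == "ovary"))
  expect_equal(colnames(kept), setdiff(paste0("c", 2:9), "c9"))
})

test_that("filterCells is idempotent and the identity on clean data", {
  atl <- tinyAtlas(seed = 11)
  once <- suppressMessages(filterCells(atl))
  twice <- suppressMessages(filterCells(once))
  expect_identical(colnames(once), colnames(twice))
  clean <- generateAtlas(synthConfig(nClusters = 2, nGenes = 10,
                                     cellsPerReplicate = 50,
                                     replicatesPerSex = 2, fracArtefact = 0,
                                     fracMixSex = 0, seed = 1))
  expect_equal(ncol(suppressMessages(filterCells(clean))), ncol(clean))
})

test_that("filtering everything warns and returns an empty atlas", {
  m <- matrix(1L, 2, 3, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  atl <- SexedAtlas(m, sex = "female", replicate = "r1",
                    annotation = "artefact", is_artefact = TRUE)
  expect_warning(res <- suppressMessages(filterCells(atl)), "all cells")
  expect_equal(ncol(res), 0)
})
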