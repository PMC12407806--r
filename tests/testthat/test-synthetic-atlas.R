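test_that("generator is deterministic: same seed, bit-identical atlas", {
  cfg <- synthConfig(nClusters = 4, nGenes = 25, cellsPerReplicate = 120,
                     replicatesPerSex = 3, seed = 1)
  a <- generateAtlas(cfg)
  b <- generateAtlas(cfg)
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  expect_identical(SummarizedExperiment::colData(a),
                   SummarizedExperiment::colData(b))
  expect_identical(synthTruth(a), synthTruth(b))
  d <- generateAtlas(synthConfig(nClusters = 4, nGenes = 25,
                                 cellsPerReplicate = 120,
                                 replicatesPerSex = 3, seed = 2))
  expect_false(identical(SummarizedExperiment::assay(a, "counts"),
                         SummarizedExperiment::assay(d, "counts")))
})

test_that("atlas dimensions, labels and flags match the configuration", {
  cfg <- synthConfig(nClusters = 3, nGenes = 20, cellsPerReplicate = 200,
                     replicatesPerSex = 4, fracArtefact = 0.1,
                     fracMixSex = 0.1, seed = 3)
  atl <- generateAtlas(cfg)
  expect_equal(ncol(atl), 200 * 2 * 4)
  expect_equal(nrow(atl), 20)
  cts <- SummarizedExperiment::assay(atl, "counts")
  expect_true(all(cts@x >= 0) && all(cts@x == round(cts@x)))
  expect_setequal(unique(atl$sex), c("female", "male", "mix"))
  expect_gt(sum(atl$is_artefact), 0)
  expect_true(all(atl$annotation[atl$is_artefact] == "artefact"))
  expect_equal(length(unique(atl$replicate)), 4)
})

test_that("sex-specific clusters contain one sex only", {
  atl <- generateAtlas(synthConfig(nClusters = 4, nGenes = 15,
                                   cellsPerReplicate = 300,
                                   sexspecClusters = c("c3", "c4"),
                                   fracMixSex = 0, seed = 5))
  tr <- synthTruth(atl)
  expect_equal(tr["c3", "sex_specificity"], "female_specific")
  expect_equal(tr["c4", "sex_specificity"], "male_specific")
  expect_true(all(atl$sex[atl$true_cluster == "c3"] == "female"))
  expect_true(all(atl$sex[atl$true_cluster == "c4"] == "male"))
})

test_that("realized per-sex cluster proportions converge to configured ones", {
  fold <- c(c1 = 2, c3 = 0.5)
  cfg <- synthConfig(nClusters = 4, nGenes = 5, cellsPerReplicate = 25000,
                     replicatesPerSex = 2, compositionBias = fold,
                     fracArtefact = 0, fracMixSex = 0, seed = 7)
  atl <- generateAtlas(cfg)
  base <- 1 / sqrt(1:4)
  pf <- base * c(2, 1, 0.5, 1); pf <- pf / sum(pf)
  pm <- base / sum(base)
  relF <- as.vector(table(factor(atl$true_cluster[atl$sex == "female"],
                                 paste0("c", 1:4)))) / 50000
  relM <- as.vector(table(factor(atl$true_cluster[atl$sex == "male"],
                                 paste0("c", 1:4)))) / 50000
  expect_true(all(abs(relF - pf) < 0.01))
  expect_true(all(abs(relM - pm) < 0.01))
})

test_that("truth report maps folds to exact log2 values", {
  atl <- generateAtlas(synthConfig(nClusters = 3, nGenes = 10,
                                   cellsPerReplicate = 50,
                                   replicatesPerSex = 2,
                                   compositionBias = c(c1 = 1, c2 = 2,
                                                       c3 = 1.5),
                                   seed = 1))
  tf <- tempfile(fileext = ".csv")
  df <- truthReport(atl, tf)
  expect_equal(df$true_B, c(0, 1, log2(1.5)))
  expect_equal(df$true_panel_shift, c(0, 0, 0))
  back <- read.csv(tf)
  expect_equal(back$true_B, df$true_B, tolerance = 1e-12)
})

test_that("invalid configurations fail validation naming the field", {
  expect_error(synthConfig(nClusters = 3, nGenes = 10,
                           compositionBias = c(c1 = -1)),
               "compositionBias")
  expect_error(synthConfig(nClusters = 3, nGenes = 10, fracArtefact = 1.2),
               "fracArtefact")
  expect_error(synthConfig(nClusters = 3, nGenes = 10,
                           replicatesPerSex = 1), "replicatesPerSex")
  expect_error(synthConfig(nClusters = 3, nGenes = 10,
                           panelFold = c(zz = 2)), "panelFold")
})

test_that("panel fold shifts female panel-gene expression in the target cluster", {
  atl <- generateAtlas(synthConfig(nClusters = 2, nGenes = 20,
                                   cellsPerReplicate = 2000,
                                   replicatesPerSex = 2,
                                   panelGenes = c("rpA", "rpB"),
                                   panelFold = c(c1 = 2),
                                   fracArtefact = 0, fracMixSex = 0,
                                   clusterDeSd = 0, libsizeCV = 0,
                                   seed = 9))
  cts <- SummarizedExperiment::assay(atl, "counts")
  inC1 <- atl$true_cluster == "c1"
  fm <- Matrix::rowMeans(cts[c("rpA", "rpB"), inC1 & atl$sex == "female"])
  mm <- Matrix::rowMeans(cts[c("rpA", "rpB"), inC1 & atl$sex == "male"])
  expect_true(all(fm / mm > 1.6 & fm / mm < 2.4))
  inC2 <- atl$true_cluster == "c2"
  fm2 <- Matrix::rowMeans(cts[c("rpA", "rpB"), inC2 & atl$sex == "female"])
  mm2 <- Matrix::rowMeans(cts[c("rpA", "rpB"), inC2 & atl$sex == "male"])
  expect_true(all(fm2 / mm2 > 0.8 & fm2 / mm2 < 1.25))
})
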