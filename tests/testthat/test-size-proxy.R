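test_that("packaged panels carry the documented gene counts", {
  rp <- loadGenePanel("RP_FBgg0000141")
  expect_length(rp, 94)
  expect_equal(sum(startsWith(rp, "RpL") | rp %in% c("Rpp30")), 54)
  expect_equal(sum(startsWith(rp, "RpS") | rp %in% c("sta", "Rack1")), 40)
  expect_length(loadGenePanel("translation_other"), 61)
  goi <- loadGenePanel("genes_of_interest")
  expect_length(goi, 9)
  expect_setequal(goi, c("DENR", "InR", "MCTS1", "Myc", "Nelf-A", "NELF-B",
                         "Nelf-E", "pix", "tor"))
  expect_error(loadGenePanel("no_such_panel"), "not found")
})

biasFixture <- function(scores) {
  # scores: named list cluster -> named numeric gene scores
  do.call(rbind, lapply(names(scores), function(cid)
    data.frame(cluster_id = cid, gene = names(scores[[cid]]),
               score = unname(scores[[cid]]), stringsAsFactors = FALSE)))
}

test_that("panel score is the mean over present genes, missing listed", {
  gb <- biasFixture(list(k1 = c(a = 1, b = 2, c = 3, other = 9)))
  expect_equal(panelScore(gb, c("a", "b", "c"))$mean_score, 2)
  one <- panelScore(gb, "b")
  expect_equal(one$mean_score, 2)
  expect_equal(one$n_genes_used, 1)
  part <- panelScore(gb, c("a", "b", "zz"))
  expect_equal(part$mean_score, 1.5)
  expect_equal(part$n_missing, 1)
  expect_equal(attr(part, "missing")$k1, "zz")
  expect_error(panelScore(gb, c("x", "y")), "no gene of the panel")
})

test_that("panel score is linear over disjoint sub-panels", {
  set.seed(3)
  sc <- setNames(rnorm(10), paste0("g", 1:10))
  gb <- biasFixture(list(k = sc))
  p1 <- paste0("g", 1:4); p2 <- paste0("g", 5:10)
  full <- panelScore(gb, c(p1, p2))$mean_score
  wgt <- (4 * panelScore(gb, p1)$mean_score +
          6 * panelScore(gb, p2)$mean_score) / 10
  expect_equal(full, wgt, tolerance = 1e-12)
})

test_that("stoichiometry matrix: identity, antisymmetry, missing for constants", {
  gb <- biasFixture(list(k1 = c(a = 1, b = 1, c = -1, d = 5),
                         k2 = c(a = 2, b = 2, c = -2, d = 5),
                         k3 = c(a = 3, b = 3, c = -3, d = 5)))
  sm <- suppressMessages(stoichiometryMatrix(gb, c("a", "b", "c", "d")))
  expect_equal(sm["a", "b"], 1)
  expect_equal(sm["a", "c"], -1)
  expect_true(all(is.na(sm["d", ])))  # constant vector: missing, not zero
  expect_equal(diag(sm)[c("a", "b", "c")], c(a = 1, b = 1, c = 1))
  expect_equal(sm, t(sm))
  expect_error(stoichiometryMatrix(gb[gb$cluster_id != "k3", ],
                                   c("a", "b")), ">= 3 clusters")
})

test_that("gene-vs-panel Spearman handles monotone and reversed inputs", {
  up <- geneVsPanelCorrelation(c(1, 2, 3, 5), c(2, 4, 9, 11))
  expect_equal(up$rho, 1)
  down <- geneVsPanelCorrelation(c(1, 2, 3, 5), c(11, 9, 4, 2))
  expect_equal(down$rho, -1)
  expect_error(geneVsPanelCorrelation(1:2, 2:1), ">= 3")
})

test_that("Spearman rho and exact p match the full 5! permutation oracle", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  res <- geneVsPanelCorrelation(x, y)
  expect_equal(res$rho, 1 - 6 * 4 / (5 * 24))  # 0.8 from sum(d^2) = 4
  expect_equal(res$p, oracleSpearmanP(x, y), tolerance = 1e-9)
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(5)
    res <- geneVsPanelCorrelation(a, b)
    expect_equal(res$p, oracleSpearmanP(a, b), tolerance = 1e-9,
                 info = paste("rep", i))
  }
})

test_that("scores are matched by cluster name before correlating", {
  g <- c(k1 = 1, k2 = 2, k3 = 3, k4 = 4)
  p <- c(k4 = 4, k3 = 3, k2 = 2, k1 = 1)  # same data, shuffled names
  expect_equal(geneVsPanelCorrelation(g, p)$rho, 1)
})

test_that("a uniform panel shift in one cluster is detected with correct sign", {
  atl <- generateAtlas(synthConfig(
      nClusters = 4, nGenes = 60, cellsPerReplicate = 600,
      replicatesPerSex = 2, panelGenes = paste0("rp", 1:10),
      panelFold = c(c2 = 1.3), fracArtefact = 0, fracMixSex = 0,
      seed = 61))
  xn <- normalizeExpression(atl)
  gb <- geneSexBias(xn, atl$true_cluster)
  ps <- panelScore(gb, paste0("rp", 1:10))
  i2 <- match("c2", ps$cluster_id)
  expect_equal(which.max(abs(ps$mean_score)), i2)
  expect_gt(ps$mean_score[i2], 0)  # female shift => positive female-high score
})

test_that("heatmap table stacks panel genes, panel mean and marker rows", {
  gb <- biasFixture(list(k1 = c(a = 1, b = 3, Myc = 7),
                         k2 = c(a = 2, b = 4, Myc = 8)))
  hm <- heatmapTable(gb, c("a", "b"), extraGenes = "Myc")
  expect_equal(rownames(hm), c("a", "b", "panel_mean", "Myc"))
  expect_equal(hm["panel_mean", ], c(k1 = 2, k2 = 3))
  expect_equal(hm["Myc", ], c(k1 = 7, k2 = 8))
})
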