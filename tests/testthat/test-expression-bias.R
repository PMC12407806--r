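test_that("normalization scales every cell to the target and preserves zeros", {
  m <- Matrix::Matrix(matrix(c(1, 1, 2, 0,   0, 0, 0, 0,   4, 0, 4, 0),
      nrow = 4,
      dimnames = list(paste0("g", 1:4), paste0("c", 1:3))), sparse = TRUE)
  atl <- SexedAtlas(m, sex = c("female", "male", "female"), replicate = "r1")
  expect_warning(xn <- normalizeExpression(atl), "zero total")
  expect_equal(ncol(xn), 2)  # zero-total cell excluded
  lx <- SummarizedExperiment::assay(xn, "logcounts")
  expect_equal(as.numeric(expm1(lx[, "c1"])), c(2500, 2500, 5000, 0))
  expect_equal(as.numeric(lx["g4", ]), c(0, 0))  # all-zero gene stays zero
  # doubling a cell's counts leaves its normalized vector unchanged
  m2 <- m; m2[, 1] <- m[, 1] * 2
  atl2 <- SexedAtlas(m2, sex = c("female", "male", "female"),
                     replicate = "r1")
  xn2 <- suppressWarnings(normalizeExpression(atl2))
  expect_equal(as.numeric(SummarizedExperiment::assay(xn2, "logcounts")[, "c1"]),
               as.numeric(lx[, "c1"]))
})

test_that("rank-sum z score matches the hand computation and its symmetries", {
  z <- rankSumZscore(c(3, 4, 5), c(0, 1, 2))
  expect_equal(z, 4.5 / sqrt(5.25), tolerance = 1e-9)  # 1.9640...
  expect_equal(rankSumZscore(c(1, 1, 1), c(1, 1, 1)), 0)  # all ties
  set.seed(7)
  for (i in 1:20) {
    f <- rpois(8, 3); m <- rpois(6, 3)
    expect_equal(rankSumZscore(f, m), -rankSumZscore(m, f),
                 tolerance = 1e-12)
  }
  expect_error(rankSumZscore(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum z agrees with the exact enumeration oracle in p and sign", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    f <- rpois(n, 4); g <- rpois(m, 2.5)  # ties likely
    z <- rankSumZscore(f, g)
    expect_equal(sign(z), oracleRankSumSign(f, g), info = paste("rep", i))
    if (z != 0) {
      # normal-approximation p must approach the exact p as groups grow;
      # at these sizes require agreement within a factor consistent with
      # the approximation (checked generously, direction exactly)
      pApprox <- 2 * pnorm(-abs(z))
      pExact <- oracleRankSumP(f, g)
      expect_gt(pApprox, 0)
      expect_lt(abs(log(pApprox / pExact)), log(4), label = paste("rep", i))
    }
  }
})

test_that("gene sex bias: offsets, orientation and tie conventions", {
  set.seed(5)
  counts <- matrix(rpois(400, 5), nrow = 4,
      dimnames = list(c("up_f", "flat", "zero", "const"),
                      paste0("c", 1:100)))
  sex <- rep(c("female", "male"), 50)
  counts["up_f", sex == "female"] <- counts["up_f", sex == "female"] + 40
  counts["zero", ] <- 0
  counts["flat", ] <- rpois(100, 5)
  counts["const", ] <- 3
  atl <- SexedAtlas(Matrix::Matrix(counts, sparse = TRUE), sex = sex,
                    replicate = "r1")
  xn <- normalizeExpression(atl)
  gb <- geneSexBias(xn, rep("k1", 100))
  gz <- gb[gb$gene == "zero", ]
  expect_equal(gz$B_expr, 0)   # log2(1e-9/1e-9)
  expect_equal(gz$score, 0)
  up <- gb[gb$gene == "up_f", ]
  expect_lt(up$B_expr, 0)      # male-over-female orientation as stored
  expect_gt(up$score, 0)       # female-high rank score
  expect_lt(up$q, 0.05)
  disp <- orientBias(gb, "female")
  expect_equal(disp$B_expr, -gb$B_expr)
  expect_equal(disp$score, gb$score)
})

test_that("B_expr equals log2 mean ratio of de-logged normalized expression", {
  atl <- suppressMessages(filterCells(tinyAtlas(seed = 41)))
  xn <- normalizeExpression(atl)
  gb <- geneSexBias(xn, atl$true_cluster, clustersUse = "c1")
  lx <- SummarizedExperiment::assay(xn, "logcounts")
  inC1 <- atl$true_cluster == "c1"
  g <- gb$gene[5]
  fAvg <- mean(expm1(lx[g, inC1 & atl$sex == "female"]))
  mAvg <- mean(expm1(lx[g, inC1 & atl$sex == "male"]))
  expect_equal(gb$B_expr[gb$gene == g],
               log2((mAvg + 1e-9) / (fAvg + 1e-9)), tolerance = 1e-9)
})

test_that("scores are invariant to the monotone log transform", {
  set.seed(9)
  f <- rpois(30, 4); m <- rpois(25, 3)
  expect_equal(rankSumZscore(f, m), rankSumZscore(log1p(f), log1p(m)),
               tolerance = 1e-12)
})

test_that("a single-sex cluster is skipped with a message, not an error", {
  m <- matrix(rpois(60, 3), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:20)))
  atl <- SexedAtlas(Matrix::Matrix(m, sparse = TRUE),
                    sex = c(rep("female", 10), rep(c("female", "male"), 5)),
                    replicate = "r1")
  xn <- normalizeExpression(atl)
  cl <- c(rep("only_f", 10), rep("both", 10))
  expect_message(gb <- geneSexBias(xn, cl), "one sex only")
  expect_setequal(unique(gb$cluster_id), "both")
})

test_that("a 1.5x female shift makes that gene the top-scoring of 100 genes", {
  wins <- 0
  for (s in 1:20) {
    atl <- generateAtlas(synthConfig(
        nClusters = 1, nGenes = 100, cellsPerReplicate = 200,
        replicatesPerSex = 2, panelGenes = "shifted",
        panelFold = c(c1 = 1.5), fracArtefact = 0, fracMixSex = 0,
        seed = 700 + s))
    xn <- normalizeExpression(atl)
    gb <- geneSexBias(xn, atl$true_cluster)
    if (gb$gene[which.max(abs(gb$score))] == "shifted") wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("q-values are BH-monotone within each cluster", {
  atl <- suppressMessages(filterCells(tinyAtlas(seed = 43)))
  xn <- normalizeExpression(atl)
  gb <- geneSexBias(xn, atl$true_cluster)
  for (cid in unique(gb$cluster_id)) {
    sub <- gb[gb$cluster_id == cid, ]
    o <- order(sub$p)
    expect_true(all(diff(sub$q[o]) >= -1e-12))
    expect_true(all(sub$q >= sub$p - 1e-12))
  }
})
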