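test_that("mean-cpm filtering is strict and exact", {
  # sample library sizes pinned to 1e6 with a filler gene so that the
  # boundary gene's cpm is exactly 1.0 in every sample
  counts <- rbind(boundary = rep(1, 12), below = rep(0, 12),
                  above = rep(10, 12), filler = rep(1e6 - 11, 12))
  ee <- toyExperiment(counts)
  kept <- rownames(filterCpm(ee, threshold = 1))
  expect_false("boundary" %in% kept)  # strict >
  expect_false("below" %in% kept)
  expect_true("above" %in% kept)
  # planted pass/fail partition recovered exactly
  set.seed(2)
  lam <- ifelse(runif(200) < 0.5, 0.1, 50)
  cnts <- matrix(rpois(200 * 12, lam), 200, 12,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  colnames(cnts) <- sprintf("s%02d", 1:12)
  ee2 <- toyExperiment(cnts)
  keep <- rowMeans(cpmMatrix(ee2, normalized = FALSE)) > 1
  expect_identical(rownames(filterCpm(ee2)), rownames(cnts)[keep])
})

test_that("TMM factors behave like the reference implementation", {
  set.seed(8)
  base <- matrix(rnbinom(500 * 12, mu = 100, size = 5), 500, 12,
                 dimnames = list(sprintf("g%03d", 1:500),
                                 sprintf("s%02d", 1:12)))
  # identical columns: all factors 1
  same <- matrix(rep(base[, 1], 12), ncol = 12,
                 dimnames = dimnames(base))
  eeS <- tmmFactors(toyExperiment(same))
  expect_equal(unname(SummarizedExperiment::colData(eeS)$tmmFactor),
               rep(1, 12))
  # a doubled column changes no M-values, so factors stay at 1 and the
  # doubled library is handled by its library size alone
  dbl <- base; dbl[, 3] <- base[, 3] * 2
  f <- SummarizedExperiment::colData(tmmFactors(toyExperiment(dbl)))$tmmFactor
  expect_equal(unname(f), rep(1, 12), tolerance = 0.02)
  # spiked composition gene shifts the factor down for the spiked sample,
  # in agreement with the independent edgeR implementation
  spiked <- base
  spiked[1, 5] <- 3e5
  eeA <- tmmFactors(toyExperiment(spiked))
  mine <- SummarizedExperiment::colData(eeA)$tmmFactor
  expect_lt(mine[5], 0.95)
  ref <- edgeR::calcNormFactors(edgeR::DGEList(spiked))$samples$norm.factors
  expect_equal(unname(mine), ref, tolerance = 0.03)
})

test_that("cpm round-trips counts through library size and TMM factor", {
  set.seed(3)
  cnts <- matrix(rnbinom(50 * 12, mu = 50, size = 2), 50, 12,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 sprintf("s%02d", 1:12)))
  ee <- tmmFactors(toyExperiment(cnts))
  cd <- SummarizedExperiment::colData(ee)
  back <- sweep(cpmMatrix(ee), 2, cd$libSize * cd$tmmFactor, "*") / 1e6
  expect_equal(back, cnts, tolerance = 1e-12)
})

test_that("NB LRT finds a planted pair-specific shift and not the others", {
  set.seed(14)
  nG <- 60
  mu0 <- 200
  cnts <- matrix(rnbinom(nG * 12, mu = mu0, size = 10), nG, 12,
                 dimnames = list(sprintf("g%03d", 1:nG),
                                 sprintf("s%02d", 1:12)))
  # 4-fold shift for gene g001 in pair 1 montane samples only
  ee0 <- toyExperiment(cnts)
  cd <- SummarizedExperiment::colData(ee0)
  mIdx <- which(cd$pair == "1" & cd$ecotype == "M")
  cnts["g001", mIdx] <- rnbinom(length(mIdx), mu = 4 * mu0, size = 10)
  de <- deTest(tmmFactors(toyExperiment(cnts)))
  hit <- de[de$gene_id == "g001", ]
  expect_lt(hit$PValue[hit$pair == "1"], 1e-4)
  expect_true(all(hit$PValue[hit$pair != "1"] > 0.001))
  expect_gt(hit$logFC[hit$pair == "1"], 1.5)
  # logFC is exactly 0 when every count is the same constant
  const <- matrix(7, 20, 12, dimnames = list(sprintf("g%02d", 1:20),
                                             sprintf("s%02d", 1:12)))
  deC <- deTest(tmmFactors(toyExperiment(const)))
  expect_equal(deC$logFC, rep(0, nrow(deC)), tolerance = 1e-8)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(5)
  p <- runif(50)
  q <- bhAdjust(p)
  expect_true(all(q >= p) && all(q <= 1))
  expect_true(is.na(bhAdjust(c(0.1, NA))[2]))
})

test_that("DEG set extraction partitions by pair and direction", {
  de <- data.frame(gene_id = rep(c("g1", "g2", "g3"), each = 2),
                   pair = rep(c("1", "3"), 3),
                   logFC = c(2, 2, -1, 0.5, 0.2, -0.2),
                   PValue = 0.001,
                   FDR = c(0.01, 0.01, 0.01, 0.2, 0.2, 0.01))
  sets <- degSets(de, fdr = 0.05)
  expect_setequal(names(geneSets(sets)),
                  c("pair1_over_M", "pair1_under_M",
                    "pair3_over_M", "pair3_under_M"))
  expect_equal(geneSets(sets)$pair1_over_M, "g1")
  expect_equal(geneSets(sets)$pair1_under_M, "g2")
  expect_equal(geneSets(sets)$pair3_under_M, "g3")
  expect_equal(length(background(sets)), 3)
  # sizes equal the FDR<0.05 row counts
  expect_equal(sum(lengths(geneSets(sets))),
               sum(de$FDR < 0.05))
  # nothing significant: 4 empty sets over an intact background
  deN <- de; deN$FDR <- 0.5
  setsN <- degSets(deN)
  expect_true(all(lengths(geneSets(setsN)) == 0))
  expect_equal(length(background(setsN)), 3)
})
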