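test_that("1D folding pools counts into minor-allele classes", {
  # c = 7 of n = 10 folds to class 3; n = 2 polymorphics all land in class 1
  sfs <- foldSFS(toyCounts(c(7, 0, 10, 2), 10), "p1")
  expect_equal(sfsCounts(sfs), c(2, 0, 1, 1, 0, 0))
  sfs2 <- foldSFS(toyCounts(c(1, 1, 0, 1), 2), "p1")
  expect_equal(sfsCounts(sfs2), c(1, 3))
  # conservation: classes sum to the number of sites
  set.seed(4)
  cnt <- sample(0:8, 200, replace = TRUE)
  expect_equal(sum(sfsCounts(foldSFS(toyCounts(cnt, 8), "p1"))), 200)
  # heterogeneous n is an error naming the offending sites
  bad <- toyCounts(c(1, 1), 4)
  bad$n[2] <- 6
  expect_error(foldSFS(bad, "p1"), "heterogeneous")
})

test_that("joint folding merges complementary cells, splitting exact ties", {
  # site fixed in pop1 only (c1=2 of 2, c2=0 of 2): (2,0) and its
  # complement (0,2) are an exact pooled-frequency tie, so the mass is
  # split half-and-half between the two cells
  j <- foldJointSFS(toyCounts2(2, 2, 0, 2), "p1", "p2")
  expect_equal(sfsMatrix(j)[3, 1], 0.5)
  expect_equal(sfsMatrix(j)[1, 3], 0.5)
  # monomorphic site -> cell (0,0); total mass conserved
  j2 <- foldJointSFS(toyCounts2(c(0, 1), 4, c(0, 3), 4), "p1", "p2")
  expect_equal(sfsMatrix(j2)[1, 1], 1)
  expect_equal(sum(sfsMatrix(j2)), 2)
  # transposing populations transposes the matrix
  set.seed(7)
  c1 <- sample(0:4, 50, TRUE); c2 <- sample(0:6, 50, TRUE)
  tab <- rbind(toyCounts(c1, 4, "p1"), toyCounts(c2, 6, "p2"))
  expect_equal(sfsMatrix(foldJointSFS(tab, "p1", "p2")),
               t(sfsMatrix(foldJointSFS(tab, "p2", "p1"))))
  # redundant half is zeroed
  m <- sfsMatrix(foldJointSFS(tab, "p1", "p2"))
  ij <- which(m > 0, arr.ind = TRUE) - 1
  expect_true(all(rowSums(ij) <= (4 + 6) / 2))
})

test_that("window diversity matches hand-computed pi and thetaW", {
  # two haplotypes differing at 1 of 10 covered sites: pi = thetaW = 0.1
  w <- diversityWindows(toyCounts(1, 2), "p1", windowSize = 50000,
                        stepSize = 50000, covered = 10)
  expect_equal(w$pi[1], 0.1)
  expect_equal(w$thetaW[1], 0.1)
  expect_equal(w$S[1], 1)
  # pi == S/a1 per site implies D = 0
  expect_equal(tajimasD(5, 5 / sum(1 / (1:9)), 10), 0)
  # frozen textbook-constant oracle value for n=10, S=16, piTotal=8
  expect_equal(tajimasD(16, 8, 10), 1.918721, tolerance = 1e-6)
  expect_true(is.na(tajimasD(0, 0, 10)))
})

test_that("neutral simulation has pi close to thetaW in expectation", {
  model <- testModel()
  sim <- simulateGenealogies(model, 800, seed = 31, locusLength = 500)
  st <- sim$sites
  p <- st$A1 / 6
  poly <- p > 0 & p < 1
  piTot <- sum(2 * p * (1 - p) * 6 / 5)
  thetaTot <- sum(poly) / sum(1 / (1:5))
  expect_equal(piTot / thetaTot, 1, tolerance = 0.1)
})

test_that("gene FST is the Bhatia ratio of averages", {
  # hand value: p1=0.2, p2=0.8, n1=n2=10, one site
  t1 <- fstGene(toyCounts2(2, 10, 8, 10), "p1", "p2")
  expect_equal(t1$num, 0.36 - 2 * (0.2 * 0.8 / 9), tolerance = 1e-12)
  expect_equal(t1$den, 0.68)
  expect_equal(t1$fst, 0.4771241, tolerance = 1e-6)
  # fixed difference -> FST ~ 1 at large n; identical frequencies -> ~ 0
  expect_equal(fstGene(toyCounts2(1000, 1000, 0, 1000), "p1", "p2")$fst, 1,
               tolerance = 1e-2)
  expect_lt(abs(fstGene(toyCounts2(500, 1000, 500, 1000), "p1", "p2")$fst),
            1e-2)
  # ratio of averages differs from average of ratios on a two-site gene
  tab <- toyCounts2(c(2, 5), 10, c(8, 5), 10)
  t2 <- fstGene(tab, "p1", "p2")
  perSite <- vapply(1:2, function(i)
    fstGene(toyCounts2(c(2, 5)[i], 10, c(8, 5)[i], 10), "p1", "p2")$fst,
    numeric(1))
  expect_false(isTRUE(all.equal(t2$fst, mean(perSite))))
  # zero denominator -> NA fst
  t3 <- fstGene(toyCounts2(0, 10, 0, 10), "p1", "p2")
  expect_true(is.na(t3$fst))
})

test_that("weighted FST over the jSFS equals the per-gene accumulation", {
  set.seed(11)
  c1 <- sample(0:6, 300, TRUE); c2 <- sample(0:6, 300, TRUE)
  tab <- rbind(toyCounts(c1, 6, "p1", "gA"), toyCounts(c2, 6, "p2", "gA"))
  g <- fstGene(tab, "p1", "p2")
  j <- foldJointSFS(tab, "p1", "p2")
  expect_equal(weightedFst(j), sum(g$num) / sum(g$den), tolerance = 1e-12)
})

test_that("top-fraction outlier count obeys the ceiling law", {
  set.seed(3)
  for (G in c(20, 137, 3300, 2811)) {
    for (alpha in c(0.01, 0.05, 0.1)) {
      tab <- data.frame(gene_id = sprintf("g%05d", seq_len(G)),
                        fst = runif(G))
      out <- topFractionOutliers(tab, alpha)
      expect_identical(sum(out$outlier), as.integer(ceiling(alpha * G)))
    }
  }
  # NA-FST genes are excluded from G and never flagged
  tab <- data.frame(gene_id = sprintf("g%03d", 1:10),
                    fst = c(runif(8), NA, NA))
  out <- topFractionOutliers(tab, 0.05)
  expect_identical(sum(out$outlier), 1L)
  expect_false(any(out$outlier & is.na(out$fst)))
  # boundary ties broken by gene id, deterministically
  tab2 <- data.frame(gene_id = c("b", "a", "c"), fst = c(1, 1, 0))
  expect_equal(topFractionOutliers(tab2, 0.05)$outlier, c(FALSE, TRUE, FALSE))
})

test_that("DEG-FST permutation test behaves at its edges", {
  set.seed(5)
  tab <- data.frame(gene_id = sprintf("g%04d", 1:400), fst = rbeta(400, 1, 4))
  # whole-gene-set query: p = 1 by construction
  expect_equal(degFstPermutation(tab, tab$gene_id, nPerm = 99, seed = 1)$p, 1)
  # a set seeded in the top decile is detected
  top <- tab$gene_id[order(-tab$fst)][1:40]
  expect_lt(degFstPermutation(tab, top, nPerm = 199, seed = 2)$p, 0.02)
  expect_error(degFstPermutation(tab, character(0)), "empty")
  # determinism
  r1 <- degFstPermutation(tab, top, nPerm = 99, seed = 3)
  r2 <- degFstPermutation(tab, top, nPerm = 99, seed = 3)
  expect_identical(r1, r2)
})

test_that("allele-frequency PCA separates divergent demes", {
  freq <- rbind(a1 = c(rep(1, 20), rep(0, 20)),
                a2 = c(rep(1, 20), rep(0, 20)),
                b1 = c(rep(0, 20), rep(1, 20)),
                b2 = c(rep(0, 20), rep(1, 20)))
  p <- alleleFreqPCA(freq + matrix(rnorm(160, 0, 0.01), 4))
  expect_gt(abs(mean(p$scores[1:2, 1]) - mean(p$scores[3:4, 1])), 1)
  expect_lte(sum(p$varExplained), 1 + 1e-9)
  # identical demes: PC1 separation collapses
  same <- matrix(rep(runif(30), each = 4), 4) +
    matrix(rnorm(120, 0, 1e-3), 4)
  p2 <- alleleFreqPCA(same)
  expect_lt(diff(range(p2$scores[, 1])), 0.1)
})
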