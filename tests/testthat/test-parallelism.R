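test_that("Jaccard index covers its edge cases", {
  expect_equal(jaccardIndex(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccardIndex(c("a"), c("b")), 0)
  expect_equal(jaccardIndex(c("g1", "g2"), c("g2", "g3")), 1 / 3)
  expect_equal(jaccardIndex(character(0), character(0)), 0)
})

test_that("hypergeometric overlap matches enumeration and sums to one", {
  # N = 4, n1 = n2 = 2: P(X >= 2) = 1/6 (both sets identical, 6/36 pairs)
  expect_equal(hypergeomOverlap(2, 2, 2, 4), 1 / 6)
  expect_equal(hypergeomOverlap(0, 10, 10, 100), 1)
  # tail mass sums to 1 to 1e-12
  for (cfg in list(c(20, 30, 100), c(165, 141, 2766))) {
    x <- 0:min(cfg[1], cfg[2])
    expect_equal(sum(dhyper(x, cfg[1], cfg[3] - cfg[1], cfg[2])), 1,
                 tolerance = 1e-12)
  }
  expect_error(hypergeomOverlap(5, 3, 4, 10), "infeasible")
})

test_that("multi-set exact test reduces to the hypergeometric at k = 2", {
  set.seed(12)
  for (i in 1:40) {
    N <- sample(10:200, 1)
    n1 <- sample.int(N, 1); n2 <- sample.int(N, 1)
    x <- sample(0:min(n1, n2), 1)
    bg <- sprintf("g%04d", seq_len(N))
    p2 <- suppressWarnings(
      multisetExactTest(list(a = bg[1:n1], b = bg[1:n2]), xObs = x,
                        background = bg))
    tol <- if (p2$method == "exact") 1e-6 else 0.01
    expect_equal(p2$p, hypergeomOverlap(x, n1, n2, N), tolerance = tol)
  }
})

test_that("multi-set exact test matches brute-force enumeration at N = 4", {
  bg <- paste0("g", 1:4)
  sets <- utils::combn(4, 2, simplify = FALSE)
  # P(three random 2-subsets of a 4-universe share >= 1 element)
  tot <- 0; hit1 <- 0; hit2 <- 0
  for (a in sets) for (b in sets) for (cc in sets) {
    tot <- tot + 1
    ov <- length(Reduce(intersect, list(a, b, cc)))
    if (ov >= 1) hit1 <- hit1 + 1
    if (ov >= 2) hit2 <- hit2 + 1
  }
  coll <- list(a = bg[1:2], b = bg[1:2], c = bg[1:2])
  expect_equal(multisetExactTest(coll, xObs = 1, background = bg)$p,
               hit1 / tot, tolerance = 1e-12)
  expect_equal(multisetExactTest(coll, xObs = 2, background = bg)$p,
               hit2 / tot, tolerance = 1e-12)
  expect_equal(multisetExactTest(coll, xObs = 0, background = bg)$p, 1)
})

test_that("analytic C-score matches the hypergeometric moments", {
  # x = E gives exactly 0
  expect_equal(cHyper(8, 20, 40, 100), 0)
  # frozen hand computation for the outlier-overlap configuration:
  # E = 165*141/2766 = 8.4115..., sigma from the hypergeometric variance
  expect_equal(cHyper(18, 165, 141, 2766), 3.499322, tolerance = 1e-5)
  # monotone increasing in x
  xs <- vapply(0:20, cHyper, numeric(1), n1 = 30, n2 = 40, N = 200)
  expect_true(all(diff(xs) > 0))
  expect_error(cHyper(0, 0, 10, 100), "degenerate")
})

test_that("global C-score is directional and seed-stable", {
  bg <- sprintf("g%04d", 1:500)
  idSets <- replicate(4, bg[1:40], simplify = FALSE)
  names(idSets) <- paste0("s", 1:4)
  coll <- geneSetCollection(idSets, bg)
  g <- cHyperGlobal(coll, nPerm = 200, seed = 3)
  expect_gt(g$score, 5)          # identical sets: strong repeatability
  expect_identical(g, cHyperGlobal(coll, nPerm = 200, seed = 3))
  # independent random sets centre near zero
  set.seed(9)
  scores <- replicate(10, {
    rs <- lapply(1:4, function(i) sample(bg, 40))
    names(rs) <- paste0("s", 1:4)
    cHyperGlobal(geneSetCollection(rs, bg), nPerm = 150,
                 seed = sample.int(1e6, 1))$score
  })
  expect_lt(abs(mean(scores)), 0.5)
})

test_that("sharing partition counts multiplicities exactly", {
  bg <- paste0("g", 1:50)
  idSets <- replicate(4, bg[1:7], simplify = FALSE)
  names(idSets) <- paste0("s", 1:4)
  sp <- sharingPartition(geneSetCollection(idSets, bg))
  expect_equal(unname(sp$exactly[["4"]]), 7L)
  expect_equal(unname(sp$atLeast[["2"]]), 7L)
  disj <- list(a = bg[1:5], b = bg[6:10], c = bg[11:15])
  spD <- sharingPartition(geneSetCollection(disj, bg))
  expect_true(all(spD$exactly[-1] == 0))
  expect_true(all(spD$sharedPerSet == 0))
  # random construction against a brute-force membership tally
  set.seed(21)
  rs <- lapply(1:4, function(i) sample(bg, sample(5:15, 1)))
  names(rs) <- paste0("s", 1:4)
  sp2 <- sharingPartition(geneSetCollection(rs, bg))
  for (m in 1:4) {
    brute <- sum(vapply(bg, function(g)
      sum(vapply(rs, function(s) g %in% s, logical(1))) == m, logical(1)))
    expect_equal(unname(sp2$exactly[[as.character(m)]]), brute)
  }
})

test_that("category enrichment flags the planted category first", {
  set.seed(17)
  bg <- sprintf("g%04d", 1:400)
  ann <- data.frame(gene_id = bg,
                    category = sample(sprintf("C%02d", 1:10), 400, TRUE))
  planted <- bg[ann$category == "C03"][1:15]
  gs <- c(planted, sample(setdiff(bg, planted), 10))
  lfc <- setNames(rep(1, length(gs)), gs)
  et <- categoryEnrichment(gs, bg, ann, logFC = lfc)
  expect_equal(et$category[1], "C03")
  expect_lt(et$fdr[1], 0.01)
  # all members up-regulated in a category of size n: z = sqrt(n)
  n03 <- et$inSet[et$category == "C03"]
  expect_equal(et$z[et$category == "C03"], sqrt(n03))
  # category = whole background -> p = 1
  annAll <- data.frame(gene_id = bg, category = "ALL")
  expect_equal(categoryEnrichment(gs, bg, annAll)$p, 1)
  # categories absent from background are dropped with a warning
  annX <- rbind(ann, data.frame(gene_id = "zzz", category = "GHOST"))
  expect_warning(categoryEnrichment(gs, bg, annX), "GHOST")
})

test_that("pairwise overlap report is internally consistent", {
  bg <- sprintf("g%03d", 1:200)
  coll <- geneSetCollection(list(a = bg[1:30], b = bg[21:60],
                                 c = bg[100:120]), bg)
  rep <- overlapReport(coll)
  ab <- rep[rep$setA == "a" & rep$setB == "b", ]
  expect_equal(ab$overlap, 10)
  expect_equal(ab$jaccard, 10 / 60)
  expect_equal(ab$expected, 30 * 40 / 200)
  expect_equal(ab$p, hypergeomOverlap(10, 30, 40, 200))
  expect_true(all(rep$expected <= pmin(rep$n1, rep$n2)))
})
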