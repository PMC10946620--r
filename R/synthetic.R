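#' @importFrom stats rnbinom rlnorm rnorm rbinom runif
NULL

#' Describe a synthetic expression scenario
#'
#' Captures the study design the generators emulate: 4 ecotype pairs x
#' 2 ecotypes x 3 replicates of NB-distributed counts, with a controllable
#' fraction of differentially expressed genes per pair and a "redundancy
#' dial" (\code{fracShared}) giving the fraction of each pair's DE genes
#' that are common to all pairs with consistent direction.
#'
#' @param nGenes number of genes (default 2000; the full-data preset is
#'   16389).
#' @param nPairs number of ecotype pairs (default 4).
#' @param reps replicates per pair x ecotype cell (default 3).
#' @param fracDE fraction of genes differentially expressed per pair.
#' @param fracShared fraction of each pair's DE genes shared by all pairs.
#' @param logFCMean,logFCSd log2 fold-change magnitude distribution of DE
#'   genes (sign drawn at random, consistent across pairs for shared
#'   genes).
#' @param dispersion NB dispersion (1/size).
#' @param libSizeMeanLog,libSizeSdLog log-normal library-size parameters
#'   (defaults: median 5e6 reads).
#' @param baselineMeanLog,baselineSdLog log-normal distribution of gene
#'   baseline cpm.
#' @param nCategories,enrichedCategories synthetic annotation: number of
#'   categories and how many of them are enriched among DE genes.
#' @return a list of class \code{expressionScenario}.
#' @export
expressionScenario <- function(nGenes = 2000, nPairs = 4, reps = 3,
                               fracDE = 0.05, fracShared = 0.02,
                               logFCMean = 2, logFCSd = 0.5,
                               dispersion = 0.1,
                               libSizeMeanLog = log(5e6),
                               libSizeSdLog = 0.25,
                               baselineMeanLog = log(30),
                               baselineSdLog = 1.2,
                               nCategories = 20, enrichedCategories = 2) {
  stopifnot(fracDE >= 0, fracDE <= 1, fracShared >= 0, fracShared <= 1,
            reps >= 2, nPairs >= 2)
  structure(as.list(environment()), class = "expressionScenario")
}

#' Generate a synthetic expression experiment with known truth
#'
#' Draws gene baselines log-normally, assigns each pair's DE genes (a
#' shared block common to all pairs with consistent direction, plus
#' pair-private blocks drawn disjointly), and samples NB counts with the
#' scenario dispersion around cpm-scaled means. A truth table records
#' every gene x pair DE status and direction.
#'
#' @param scenario an \code{\link{expressionScenario}}.
#' @param seed integer RNG seed.
#' @return list with \code{experiment} (an
#'   \linkS4class{ExpressionExperiment}), \code{truth} (data.frame
#'   gene_id, pair, isDE, logFC), \code{annotation} (synthetic gene ->
#'   category map with planted enrichment) and \code{scenario}.
#' @export
genExpression <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "expressionScenario"))
  s <- scenario
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(s$nGenes))
  pairs <- as.character(seq_len(s$nPairs))
  nDE <- round(s$fracDE * s$nGenes)
  nShared <- min(nDE, round(s$fracShared * nDE))
  nPrivate <- nDE - nShared
  if (nShared + s$nPairs * nPrivate > s$nGenes)
    stop("infeasible fracDE/fracShared: not enough genes for disjoint sets")
  pool <- sample(genes)
  sharedGenes <- pool[seq_len(nShared)]
  privates <- list()
  off <- nShared
  for (p in pairs) {
    privates[[p]] <- pool[off + seq_len(nPrivate)]
    off <- off + nPrivate
  }
  sharedSign <- sample(c(-1, 1), nShared, replace = TRUE)
  sharedMag <- abs(rnorm(nShared, s$logFCMean, s$logFCSd))
  truth <- list()
  lfcMat <- matrix(0, s$nGenes, s$nPairs, dimnames = list(genes, pairs))
  for (p in pairs) {
    lfcMat[sharedGenes, p] <- sharedSign * sharedMag
    npv <- length(privates[[p]])
    lfcMat[privates[[p]], p] <- sample(c(-1, 1), npv, replace = TRUE) *
      abs(rnorm(npv, s$logFCMean, s$logFCSd))
    truth[[p]] <- data.frame(gene_id = genes, pair = p,
                             isDE = lfcMat[, p] != 0,
                             logFC = lfcMat[, p])
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  baseline <- rlnorm(s$nGenes, s$baselineMeanLog, s$baselineSdLog)  # cpm
  nSamples <- s$nPairs * 2 * s$reps
  sampleSheet <- data.frame(
    sample = sprintf("%s%s%s", rep(c("A", "M"), each = s$reps * s$nPairs),
                     rep(rep(pairs, each = s$reps), 2),
                     rep(letters[seq_len(s$reps)], 2 * s$nPairs)),
    pair = rep(rep(pairs, each = s$reps), 2),
    ecotype = rep(c("A", "M"), each = s$reps * s$nPairs))
  lib <- rlnorm(nSamples, s$libSizeMeanLog, s$libSizeSdLog)
  counts <- matrix(0L, s$nGenes, nSamples,
                   dimnames = list(genes, sampleSheet$sample))
  for (j in seq_len(nSamples)) {
    shift <- if (sampleSheet$ecotype[j] == "M")
      2^lfcMat[, sampleSheet$pair[j]] else 1
    mu <- baseline * shift / 1e6 * lib[j]
    counts[, j] <- rnbinom(s$nGenes, size = 1 / s$dispersion, mu = mu)
  }

  # synthetic annotation with planted enrichment: each enriched category is
  # seeded with DE genes, the rest annotated uniformly
  cats <- sprintf("CAT%03d", seq_len(s$nCategories))
  ann <- data.frame(gene_id = genes,
                    category = sample(cats, s$nGenes, replace = TRUE))
  deGenes <- unique(truth$gene_id[truth$isDE])
  if (s$enrichedCategories > 0 && length(deGenes)) {
    planted <- cats[seq_len(s$enrichedCategories)]
    take <- split(deGenes, rep(planted, length.out = length(deGenes)))
    for (cc in planted)
      ann$category[ann$gene_id %in% take[[cc]]] <- cc
  }
  list(experiment = expressionExperiment(counts, sampleSheet),
       truth = truth, annotation = ann, scenario = s)
}

#' Describe a synthetic genetic scenario
#'
#' @param model a \linkS4class{DemographicModel} (the truth).
#' @param nLoci number of independent loci (default 5000).
#' @param locusLength sites per locus (default 1000).
#' @param meanDepth optional mean sequencing depth per haploid; when set,
#'   sites are dropped per population with the Poisson probability that
#'   depth falls below \code{minDepth}, emulating coverage filtering.
#' @param errorRate per-allele miscall probability applied to the sampled
#'   allele counts (binomial resampling noise).
#' @param minDepth depth threshold used with \code{meanDepth}.
#' @return a list of class \code{geneticScenario}.
#' @export
geneticScenario <- function(model, nLoci = 5000, locusLength = 1000,
                            meanDepth = NULL, errorRate = 0,
                            minDepth = 4) {
  stopifnot(is(model, "DemographicModel"), nLoci >= 1)
  structure(list(model = model, nLoci = nLoci, locusLength = locusLength,
                 meanDepth = meanDepth, errorRate = errorRate,
                 minDepth = minDepth),
            class = "geneticScenario")
}

#' Generate synthetic allele-count data under a divergence model
#'
#' Simulates genealogies for the scenario's model, drops infinite-sites
#' mutations, and emits a long allele-count table for the four demes plus
#' the six folded joint SFS. Optional depth-based dropout and per-allele
#' error emulate noisy low-coverage calls; with zero noise the counts equal
#' the genealogy-derived counts.
#'
#' @param scenario a \code{\link{geneticScenario}}.
#' @param seed integer RNG seed.
#' @return list with \code{counts} (allele-count table: chrom, pos,
#'   gene_id, pop, count, n), \code{jsfs} (named list of six
#'   \linkS4class{JointFoldedSFS}), \code{truth} (the model) and
#'   \code{scenario}.
#' @export
genGenetic <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "geneticScenario"))
  model <- scenario$model
  sim <- simulateGenealogies(model, scenario$nLoci, seed,
                             locusLength = scenario$locusLength,
                             sites = TRUE)
  sites <- sim$sites
  if (!nrow(sites)) stop("no polymorphic sites simulated; increase mu or nLoci")
  set.seed(seed + 1L)
  nD <- length(model@demeNames)
  # one "gene" per locus; site positions within the locus are arbitrary
  sites$pos <- (sites$locus - 1L) * scenario$locusLength +
    as.integer(stats::ave(sites$locus, sites$locus, FUN = seq_along))
  long <- list()
  for (d in seq_len(nD)) {
    cnt <- sites[[model@demeNames[d]]]
    n <- model@sampleSizes[d]
    if (scenario$errorRate > 0) {
      cnt <- rbinom(length(cnt), cnt, 1 - scenario$errorRate) +
             rbinom(length(cnt), n - cnt, scenario$errorRate)
    }
    keep <- rep(TRUE, length(cnt))
    if (!is.null(scenario$meanDepth)) {
      pDrop <- stats::ppois(scenario$minDepth - 1, scenario$meanDepth)
      keep <- runif(length(cnt)) >= pDrop
    }
    long[[d]] <- data.frame(chrom = "chr1", pos = sites$pos[keep],
                            gene_id = sprintf("locus%05d", sites$locus[keep]),
                            pop = model@demeNames[d],
                            count = cnt[keep], n = n)
  }
  counts <- do.call(rbind, long)
  rownames(counts) <- NULL
  prs <- t(utils::combn(nD, 2))
  jsfs <- lapply(seq_len(nrow(prs)), function(r)
    foldJointSFS(counts, model@demeNames[prs[r, 1]],
                 model@demeNames[prs[r, 2]]))
  names(jsfs) <- apply(prs, 1, function(p)
    paste(model@demeNames[p], collapse = "_"))
  list(counts = counts, jsfs = jsfs, truth = model, scenario = scenario)
}
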