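#' @importFrom tools md5sum
NULL

pipelineDefaults <- function() {
  list(
    seed = 1,
    expression = list(nGenes = 2000, nPairs = 4, reps = 3, fracDE = 0.05,
                      fracShared = 0.02, dispersion = 0.1),
    genetic = list(topology = "two_origins", mode = "SI",
                   Ne = c(10000, 2000, 10000, 2000),
                   sampleSizes = c(6, 6, 6, 6),
                   splitTimes = c(T1 = 80000, T2 = 20000, T3 = 10000),
                   migration = 0, mu = 1e-8, nLoci = 2000,
                   locusLength = 1000),
    demography = list(enabled = FALSE,
                      models = c("one_origin_SI", "two_origins_SI"),
                      nSims = 1000, nRestarts = 1, maxit = 40),
    analysis = list(fdr = 0.05, alpha = 0.05, nPerm = 199))
}

mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates the stages end-to-end on synthetic inputs: expression and
#' genetic data generation, differential expression (cpm filter, TMM, NB
#' LRT per pair), gene-reuse repeatability (overlaps, sharing partition,
#' global C-score), conditioned RDA with permutation ANOVA, per-gene FST
#' with top-fraction outliers, outlier repeatability across the two
#' localities, and (optionally) demographic model fitting and selection on
#' the six joint spectra. Each stage derives its seed from the master seed,
#' writes its tables under \code{outDir}, and a run manifest (config
#' snapshot, stage seeds, output checksums, timestamps) plus a markdown
#' summary are written at the end; re-running with the same config and
#' seed reproduces every output byte-for-byte.
#'
#' @param config named list or path to a YAML file; missing entries fall
#'   back to the defaults of \code{pipelineDefaults()} (sections:
#'   \code{seed}, \code{expression}, \code{genetic}, \code{demography},
#'   \code{analysis}).
#' @param outDir output directory (created if needed).
#' @return (invisibly) a list with the per-stage results and the manifest.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- mergeConfig(pipelineDefaults(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  stageSeeds <- list(expression = seed + 11L, genetic = seed + 23L,
                     demography = seed + 37L, analysis = seed + 53L)
  t0 <- Sys.time()
  res <- list()

  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- synthetic expression data
  res$expression <- withStage("expression", {
    sc <- do.call(expressionScenario, cfg$expression)
    gen <- genExpression(sc, seed = stageSeeds$expression)
    write.table(assay(gen$experiment, "counts"),
                file.path(outDir, "counts.tsv"),
                sep = "\t", quote = FALSE)
    write.table(gen$truth, file.path(outDir, "expression_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gen
  })

  # --- synthetic genetic data
  res$genetic <- withStage("genetic", {
    g <- cfg$genetic
    model <- buildModel(g$topology, g$mode, Ne = unlist(g$Ne),
                        sampleSizes = unlist(g$sampleSizes),
                        splitTimes = unlist(g$splitTimes),
                        migration = g$migration, mu = g$mu)
    gen <- genGenetic(geneticScenario(model, nLoci = g$nLoci,
                                      locusLength = g$locusLength),
                      seed = stageSeeds$genetic)
    writeAlleleCounts(gen$counts, file.path(outDir, "allele_counts.tsv"))
    for (nm in names(gen$jsfs))
      writeJointSFSObs(gen$jsfs[[nm]],
                       file.path(outDir, paste0("jsfs_", nm, ".obs")))
    fstW <- vapply(gen$jsfs, weightedFst, numeric(1))
    write.table(data.frame(pair = names(fstW), weightedFst = fstW),
                file.path(outDir, "weighted_fst.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    c(gen, list(weightedFst = fstW))
  })

  # --- demographic model selection (optional, the slow stage)
  if (isTRUE(cfg$demography$enabled)) {
    res$demography <- withStage("demography", {
      d <- cfg$demography
      fits <- lapply(d$models, function(mid) {
        topo <- sub("_(SI|IM)$", "", mid)
        mode <- sub("^.*_", "", mid)
        fitModel(res$genetic$jsfs, topo, mode,
                 sampleSizes = unlist(cfg$genetic$sampleSizes),
                 nRestarts = d$nRestarts, nSims = d$nSims,
                 seed = stageSeeds$demography, maxit = d$maxit)
      })
      sel <- modelSelect(fits)
      write.table(sel, file.path(outDir, "model_selection.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(fits = fits, selection = sel)
    })
  }

  # --- differential expression
  res$de <- withStage("de", {
    ee <- tmmFactors(filterCpm(res$expression$experiment))
    de <- deTest(ee)
    write.table(de, file.path(outDir, "de_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sets <- degSets(de, fdr = cfg$analysis$fdr)
    writeGeneSets(sets, file.path(outDir, "deg_sets.tsv"),
                  file.path(outDir, "deg_background.txt"))
    list(experiment = ee, table = de, sets = sets)
  })

  # --- repeatability of gene reuse
  res$parallelism <- withStage("parallelism", {
    sets <- res$de$sets
    ov <- overlapReport(sets)
    write.table(ov, file.path(outDir, "overlap_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    # direction-merged per-pair DEG sets for the sharing partition
    byPair <- lapply(split(names(geneSets(sets)),
                           sub("_(over|under)_M$", "", names(geneSets(sets)))),
                     function(nm) unique(unlist(geneSets(sets)[nm])))
    pairColl <- geneSetCollection(byPair, background(sets))
    part <- sharingPartition(pairColl)
    glob <- cHyperGlobal(pairColl, nPerm = cfg$analysis$nPerm,
                         seed = stageSeeds$analysis)
    jsonlite::write_json(list(sharing = part, cHyperGlobal = glob),
                         file.path(outDir, "parallelism.json"),
                         auto_unbox = TRUE, digits = NA)
    list(overlaps = ov, sharing = part, cHyperGlobal = glob,
         pairSets = pairColl)
  })

  # --- conditioned RDA
  res$crda <- withStage("crda", {
    ee <- res$de$experiment
    fit <- crdaFit(ee)
    outl <- crdaOutliers(fit)
    anv <- crdaAnova(ee, nPerm = cfg$analysis$nPerm,
                     seed = stageSeeds$analysis)
    write.table(data.frame(gene_id = names(geneScores(fit)),
                           score = geneScores(fit), z = outl$z),
                file.path(outDir, "crda_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(fractions = as.list(inertiaFractions(fit)),
                              pseudoF = fit@pseudoF, anova = anv,
                              nOutliers2 = length(outl$outliers$sd2),
                              nOutliers26 = length(outl$outliers$sd2.6)),
                         file.path(outDir, "crda.json"),
                         auto_unbox = TRUE, digits = NA)
    list(fit = fit, outliers = outl, anova = anv)
  })

  # --- FST outlier scan and outlier repeatability across localities
  res$fstScan <- withStage("fst_scan", {
    cnts <- res$genetic$counts
    t1 <- topFractionOutliers(fstGene(cnts, "A1", "M1"),
                              alpha = cfg$analysis$alpha)
    t3 <- topFractionOutliers(fstGene(cnts, "A3", "M3"),
                              alpha = cfg$analysis$alpha)
    write.table(t1, file.path(outDir, "fst_pair1.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(t3, file.path(outDir, "fst_pair3.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    shared <- intersect(t1$gene_id[!is.na(t1$fst)],
                        t3$gene_id[!is.na(t3$fst)])
    o1 <- intersect(t1$gene_id[t1$outlier], shared)
    o3 <- intersect(t3$gene_id[t3$outlier], shared)
    x <- length(intersect(o1, o3))
    rep1 <- list(sharedBackground = length(shared),
                 outliers1 = length(o1), outliers3 = length(o3),
                 sharedOutliers = x,
                 p = if (min(length(o1), length(o3)) > 0)
                   hypergeomOverlap(x, length(o1), length(o3),
                                    length(shared)) else 1,
                 jaccard = jaccardIndex(o1, o3))
    jsonlite::write_json(rep1, file.path(outDir, "fst_repeatability.json"),
                         auto_unbox = TRUE, digits = NA)
    list(pair1 = t1, pair3 = t3, repeatability = rep1)
  })

  # --- manifest and summary
  outFiles <- list.files(outDir, full.names = TRUE)
  outFiles <- outFiles[!basename(outFiles) %in%
                         c("manifest.json", "summary.md")]
  manifest <- list(
    package = as.character(packageVersion("EcoParallel")),
    config = cfg, stageSeeds = stageSeeds,
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    checksums = as.list(md5sum(outFiles)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest

  degCounts <- vapply(geneSets(res$de$sets), length, integer(1))
  al <- res$parallelism$sharing$atLeast
  sharedAll <- if (as.character(cfg$expression$nPairs) %in% names(al))
    al[[as.character(cfg$expression$nPairs)]] else 0
  summaryLines <- c(
    "# Pipeline summary", "",
    paste0("- DEG counts per set: ",
           paste(sprintf("%s=%d", names(degCounts), degCounts),
                 collapse = ", ")),
    paste0("- genes shared by all pairs: ", sharedAll),
    paste0("- global C-score: ",
           signif(res$parallelism$cHyperGlobal$score, 4)),
    paste0("- cRDA constrained fraction: ",
           signif(inertiaFractions(res$crda$fit)["constrained"], 4),
           " (ANOVA p = ", signif(res$crda$anova$p, 3), ")"),
    paste0("- shared FST outliers across localities: ",
           res$fstScan$repeatability$sharedOutliers,
           " (p = ", signif(res$fstScan$repeatability$p, 3), ")"))
  if (!is.null(res$demography))
    summaryLines <- c(summaryLines,
      paste0("- best demographic model: ",
             res$demography$selection$modelId[1]))
  writeLines(summaryLines, file.path(outDir, "summary.md"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
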