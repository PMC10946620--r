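# shared in-code fixtures

# minimal allele-count table: one population, explicit counts at given n
toyCounts <- function(counts, n, pop = "p1", geneId = NULL, startPos = 1) {
  df <- data.frame(chrom = "chr1",
                   pos = seq(startPos, length.out = length(counts)),
                   pop = pop, count = counts, n = n)
  if (!is.null(geneId)) df$gene_id = rep(geneId, length.out = nrow(df))
  df
}

# two-population table with shared positions
toyCounts2 <- function(c1, n1, c2, n2, geneId = "g1") {
  rbind(toyCounts(c1, n1, "p1", geneId), toyCounts(c2, n2, "p2", geneId))
}

# a folded joint SFS with given mass at given (i, j) 0-based cells
jsfsWith <- function(n1, n2, cells, mass) {
  m <- matrix(0, n1 + 1, n2 + 1)
  for (r in seq_len(nrow(cells))) m[cells[r, 1] + 1, cells[r, 2] + 1] <- mass[r]
  new("JointFoldedSFS", mat = m, n1 = as.integer(n1), n2 = as.integer(n2),
      popNames = c("p1", "p2"))
}

# the standard four-deme test model
testModel <- function(topology = "two_origins", mode = "SI",
                      migration = if (mode == "IM") 1e-5 else 0,
                      Ne = c(10000, 2000, 10000, 2000),
                      splitTimes = c(T1 = 80000, T2 = 20000, T3 = 10000),
                      sampleSizes = c(6, 6, 6, 6), mu = 1e-8) {
  buildModel(topology, mode, Ne = Ne, sampleSizes = sampleSizes,
             splitTimes = splitTimes, migration = migration, mu = mu)
}

# small expression experiment from an explicit count matrix (2 pairs x 2
# ecotypes x `reps` replicates by default)
toyExperiment <- function(counts, nPairs = 2, reps = 3) {
  n <- ncol(counts)
  stopifnot(n == nPairs * 2 * reps)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%02d", 1:n)
  sheet <- data.frame(
    sample = colnames(counts),
    pair = rep(rep(as.character(seq_len(nPairs)), each = reps), 2),
    ecotype = rep(c("A", "M"), each = nPairs * reps))
  expressionExperiment(counts, sheet)
}
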