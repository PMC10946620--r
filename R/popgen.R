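#' @importFrom stats prcomp
NULL

# basic column checks for the long allele-count table
validateAlleleCounts <- function(x, needGene = FALSE) {
  need <- c("chrom", "pos", "pop", "count", "n")
  if (needGene) need <- c(need, "gene_id")
  miss <- setdiff(need, colnames(x))
  if (length(miss))
    stop("allele-count table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(x$n < 2)) stop("all sites need n >= 2 sampled alleles")
  if (any(x$count < 0 | x$count > x$n)) stop("counts must lie in [0, n]")
  invisible(x)
}

# uniform sample size for one population's sites, with an informative error
uniformN <- function(x, population) {
  nn <- unique(x$n)
  if (length(nn) != 1) {
    bad <- utils::head(x[x$n != nn[1], c("chrom", "pos", "n")], 5)
    stop("heterogeneous sample size in population '", population, "'; e.g. ",
         paste(sprintf("%s:%d (n=%d)", bad$chrom, bad$pos, bad$n),
               collapse = ", "))
  }
  as.integer(nn)
}

#' Fold a one-dimensional SFS from allele counts
#'
#' Pools each site's allele count c with its complement n - c into the
#' minor-allele class min(c, n - c). Class 0 is the monomorphic class.
#'
#' @param counts allele-count table (columns chrom, pos, pop, count, n).
#' @param population which population to fold.
#' @return a \linkS4class{FoldedSFS}.
#' @export
foldSFS <- function(counts, population) {
  validateAlleleCounts(counts)
  x <- counts[counts$pop == population, ]
  if (!nrow(x)) stop("no sites for population '", population, "'")
  n <- uniformN(x, population)
  cls <- pmin(x$count, n - x$count)
  tab <- tabulate(cls + 1L, nbins = n %/% 2 + 1L)
  new("FoldedSFS", counts = as.numeric(tab), n = n, nSites = nrow(x))
}

# fold an unfolded (n1+1) x (n2+1) matrix on the pooled minor allele:
# cell (i, j) is pooled with (n1-i, n2-j); the cell with i + j <= (n1+n2)/2
# is kept and exact ties are split half-and-half between the two cells
foldJSFSMatrix <- function(u) {
  n1 <- nrow(u) - 1L; n2 <- ncol(u) - 1L
  half <- (n1 + n2) / 2
  f <- matrix(0, n1 + 1L, n2 + 1L, dimnames = dimnames(u))
  for (i in 0:n1) for (j in 0:n2) {
    s <- i + j
    ci <- n1 - i; cj <- n2 - j
    if (s < half) f[i + 1, j + 1] <- u[i + 1, j + 1] + u[ci + 1, cj + 1]
    else if (s == half) {
      f[i + 1, j + 1] <- if (i == ci && j == cj) u[i + 1, j + 1]
                         else (u[i + 1, j + 1] + u[ci + 1, cj + 1]) / 2
    }
  }
  f
}

#' Fold a joint SFS for two populations
#'
#' Builds the unfolded joint spectrum from sites typed in both populations
#' (the \code{count} column must refer to the same allele in both; sites
#' missing in either population are dropped pairwise) and folds it on the
#' pooled minor allele: cell (i, j) is merged with (n1-i, n2-j), keeping
#' the cell with i + j <= (n1+n2)/2 and splitting exact ties half-and-half.
#'
#' @param counts allele-count table.
#' @param pop1,pop2 the two population labels (pop1 indexes rows).
#' @return a \linkS4class{JointFoldedSFS} of site counts.
#' @export
foldJointSFS <- function(counts, pop1, pop2) {
  validateAlleleCounts(counts)
  a <- counts[counts$pop == pop1, c("chrom", "pos", "count", "n")]
  b <- counts[counts$pop == pop2, c("chrom", "pos", "count", "n")]
  if (!nrow(a) || !nrow(b)) stop("missing population")
  n1 <- uniformN(a, pop1); n2 <- uniformN(b, pop2)
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("1", "2"))
  u <- table(factor(m$count1, levels = 0:n1),
             factor(m$count2, levels = 0:n2))
  u <- matrix(as.numeric(u), n1 + 1L, n2 + 1L)
  new("JointFoldedSFS", mat = foldJSFSMatrix(u), n1 = n1, n2 = n2,
      popNames = c(pop1, pop2))
}

# Tajima (1989) constants for sample size n (haploids)
tajimaConstants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, e1 = e1, e2 = e2)
}

#' Tajima's D from segregating sites and total pairwise diversity
#'
#' @param S number of segregating sites.
#' @param piTotal sum over sites of per-site pairwise diversity (not divided
#'   by covered sites).
#' @param n haploid sample size.
#' @return D, or NA (with attribute \code{reason}) when S = 0.
#' @export
tajimasD <- function(S, piTotal, n) {
  if (S < 1) {
    out <- NA_real_
    attr(out, "reason") <- "undefined: no segregating sites"
    return(out)
  }
  k <- tajimaConstants(n)
  (piTotal - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Sliding-window diversity summaries
#'
#' Computes, per 50-kb window advanced in 10-kb steps (defaults), pairwise
#' nucleotide diversity pi, Watterson's theta and Tajima's D for one
#' population. Per-site pi is the unbiased \code{2 p (1-p) n/(n-1)};
#' window estimates of pi and theta are divided by the number of covered
#' (variant plus invariant) sites in the window. Windows are half-open
#' \code{[start, start + windowSize)} with 1-based starts.
#'
#' @param counts allele-count table for the population's variant sites.
#' @param population population label.
#' @param windowSize,stepSize window geometry in bp.
#' @param covered either a single number of covered sites applying to every
#'   window, a data.frame (chrom, start, covered) with one row per window,
#'   or NULL to use the number of table rows in the window (appropriate
#'   only if the table includes invariant sites).
#' @return data.frame with chrom, start, end, nSites, S, pi, thetaW,
#'   tajimasD; windows with no covered sites get NA estimates.
#' @export
diversityWindows <- function(counts, population, windowSize = 50000,
                             stepSize = 10000, covered = NULL) {
  validateAlleleCounts(counts)
  x <- counts[counts$pop == population, ]
  if (!nrow(x)) stop("no sites for population '", population, "'")
  n <- uniformN(x, population)
  out <- list()
  for (chr in unique(x$chrom)) {
    xc <- x[x$chrom == chr, ]
    starts <- seq(1L, max(1L, max(xc$pos)), by = stepSize)
    for (st in starts) {
      en <- st + windowSize
      w <- xc[xc$pos >= st & xc$pos < en, ]
      cov <- if (is.null(covered)) nrow(w)
             else if (is.data.frame(covered)) {
               hit <- covered$chrom == chr & covered$start == st
               if (any(hit)) covered$covered[which(hit)[1]] else 0
             } else covered
      p <- w$count / w$n
      piSite <- 2 * p * (1 - p) * w$n / (w$n - 1)
      S <- sum(w$count > 0 & w$count < w$n)
      row <- data.frame(chrom = chr, start = st, end = en - 1L,
                        nSites = nrow(w), S = S,
                        pi = NA_real_, thetaW = NA_real_,
                        tajimasD = NA_real_)
      if (cov > 0) {
        row$pi <- sum(piSite) / cov
        row$thetaW <- S / (sum(1 / seq_len(n - 1)) * cov)
        row$tajimasD <- as.numeric(tajimasD(S, sum(piSite), n))
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

# per-site Hudson/Bhatia components: alpha (numerator) and the
# shared-heterozygosity denominator
bhatiaComponents <- function(c1, n1, c2, n2) {
  p1 <- c1 / n1; p2 <- c2 / n2
  alpha <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(alpha = alpha, den = den)
}

#' Per-gene Hudson/Bhatia FST (ratio of averages)
#'
#' Accumulates, per gene, the Bhatia et al. numerator
#' \code{(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)} and denominator
#' \code{p1(1-p2) + p2(1-p1)} over sites typed in both populations, and
#' reports the ratio of sums (never the average of per-site ratios). Genes
#' whose denominator sums to zero get NA FST and are excluded from outlier
#' ranking downstream.
#'
#' @param counts allele-count table with a \code{gene_id} column.
#' @param pop1,pop2 population labels.
#' @return an FST table: data.frame with gene_id, num, den, fst, nSites.
#' @export
fstGene <- function(counts, pop1, pop2) {
  validateAlleleCounts(counts, needGene = TRUE)
  a <- counts[counts$pop == pop1, c("chrom", "pos", "gene_id", "count", "n")]
  b <- counts[counts$pop == pop2, c("chrom", "pos", "count", "n")]
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("1", "2"))
  if (!nrow(m)) stop("no sites shared between the two populations")
  comp <- bhatiaComponents(m$count1, m$n1, m$count2, m$n2)
  num <- tapply(comp$alpha, m$gene_id, sum)
  den <- tapply(comp$den, m$gene_id, sum)
  ns <- tapply(comp$den, m$gene_id, length)
  out <- data.frame(gene_id = names(num), num = as.numeric(num),
                    den = as.numeric(den), nSites = as.integer(ns),
                    stringsAsFactors = FALSE)
  out$fst <- ifelse(out$den > 0, out$num / out$den, NA_real_)
  rownames(out) <- NULL
  out[order(out$gene_id), c("gene_id", "num", "den", "fst", "nSites")]
}

#' Weighted FST from a joint SFS
#'
#' The same Hudson/Bhatia estimator accumulated over the cells of a joint
#' SFS (folded or unfolded; the estimator is invariant to joint allele
#' relabelling), weighting each cell's components by its site count.
#'
#' @param jsfs a \linkS4class{JointFoldedSFS}.
#' @return scalar weighted FST.
#' @export
weightedFst <- function(jsfs) {
  stopifnot(is(jsfs, "JointFoldedSFS"))
  if (sum(jsfs@mat) <= 0) stop("empty spectrum")
  i <- rep(0:jsfs@n1, times = jsfs@n2 + 1L)
  j <- rep(0:jsfs@n2, each = jsfs@n1 + 1L)
  w <- as.vector(jsfs@mat)
  comp <- bhatiaComponents(i, jsfs@n1, j, jsfs@n2)
  sum(w * comp$alpha) / sum(w * comp$den)
}

#' Flag top-fraction FST outlier genes
#'
#' Flags exactly \code{ceiling(alpha * G)} genes, where G is the number of
#' genes with defined FST, ranking by FST with ties at the boundary broken
#' deterministically by gene id. Applied to 3300 and 2811 ranked genes at
#' alpha = 0.05 this flags 165 and 141 genes respectively.
#'
#' @param fstTable data.frame as returned by \code{\link{fstGene}}.
#' @param alpha top fraction in (0, 1); default 0.05.
#' @return the table with a logical \code{outlier} column (NA-FST genes are
#'   never flagged).
#' @export
topFractionOutliers <- function(fstTable, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  def <- which(!is.na(fstTable$fst))
  G <- length(def)
  if (G == 0) stop("no genes with defined FST")
  k <- ceiling(alpha * G)
  ord <- def[order(-fstTable$fst[def], fstTable$gene_id[def])]
  fstTable$outlier <- FALSE
  fstTable$outlier[ord[seq_len(k)]] <- TRUE
  fstTable
}

#' Permutation test: mean FST of DEGs versus random gene sets
#'
#' Statistic: mean FST over the query set. Null: means of \code{nPerm}
#' uniformly drawn gene sets of the same size from the genes with defined
#' FST. Two-sided p-value with the add-one correction
#' \code{(1 + #(|null - center| >= |obs - center|)) / (1 + nPerm)}, where
#' center is the mean of the null distribution, so p is never exactly 0.
#'
#' @param fstTable data.frame from \code{\link{fstGene}}.
#' @param degSet character vector of gene ids (must have defined FST).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @return list with observed (mean FST), p (two-sided) and null (numeric
#'   vector of permuted means).
#' @export
degFstPermutation <- function(fstTable, degSet, nPerm = 1000, seed = 1) {
  ok <- fstTable[!is.na(fstTable$fst), ]
  if (!length(degSet)) stop("empty DEG set")
  if (!all(degSet %in% ok$gene_id))
    stop("DEG set contains genes without defined FST")
  fst <- setNames(ok$fst, ok$gene_id)
  obs <- mean(fst[degSet])
  set.seed(seed)
  null <- replicate(nPerm, mean(sample(fst, length(degSet))))
  ctr <- mean(null)
  p <- (1 + sum(abs(null - ctr) >= abs(obs - ctr))) / (1 + nPerm)
  list(observed = obs, p = p, null = null)
}

#' Principal components of allele frequencies (plumbing)
#'
#' A plain PCA of the centred allele-frequency matrix, for quick structure
#' checks. Signs of the components are arbitrary.
#'
#' @param freq samples x sites numeric matrix of allele frequencies, or an
#'   allele-count table (rows become populations, columns sites).
#' @return list with \code{scores} (samples x PCs) and
#'   \code{varExplained} (per component, sums to <= 1).
#' @export
alleleFreqPCA <- function(freq) {
  if (is.data.frame(freq) && all(c("pop", "count", "n") %in% colnames(freq))) {
    validateAlleleCounts(freq)
    key <- paste(freq$chrom, freq$pos, sep = ":")
    pops <- unique(freq$pop)
    sites <- unique(key)
    mat <- matrix(NA_real_, length(pops), length(sites),
                  dimnames = list(pops, sites))
    mat[cbind(match(freq$pop, pops), match(key, sites))] <- freq$count / freq$n
    mat <- mat[, colSums(is.na(mat)) == 0, drop = FALSE]
    freq <- mat
  }
  if (nrow(freq) < 2) stop("need at least 2 samples")
  keep <- apply(freq, 2, function(v) var(v) > 0)
  if (!any(keep)) {
    warning("degenerate input: no variable sites")
    sc <- matrix(0, nrow(freq), 1, dimnames = list(rownames(freq), "PC1"))
    return(list(scores = sc, varExplained = 0))
  }
  pc <- prcomp(freq[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, varExplained = ve)
}
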