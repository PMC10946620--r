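#' @importFrom stats phyper dhyper fisher.test sd
NULL

#' Build a gene-set collection
#'
#' @param sets named list of character vectors.
#' @param background character vector, the gene universe.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
geneSetCollection <- function(sets, background) {
  new("GeneSetCollection", background = as.character(background),
      sets = lapply(sets, as.character))
}

#' Jaccard index of two gene sets
#'
#' |A intersect B| / |A union B|; 0 by convention when both sets are empty.
#'
#' @param setA,setB character vectors.
#' @return a number in [0, 1].
#' @export
jaccardIndex <- function(setA, setB) {
  u <- length(union(setA, setB))
  if (u == 0) return(0)
  length(intersect(setA, setB)) / u
}

#' Upper-tail hypergeometric overlap test
#'
#' P(X >= x) for the overlap X of two uniformly drawn fixed-size subsets
#' of a universe of N genes.
#'
#' @param x observed overlap.
#' @param n1,n2 set sizes.
#' @param N background (universe) size.
#' @return the exact upper-tail probability.
#' @examples
#' hypergeomOverlap(18, 165, 141, 2766)  # ~0.001
#' @export
hypergeomOverlap <- function(x, n1, n2, N) {
  if (x > min(n1, n2) || n1 > N || n2 > N || x < 0)
    stop("infeasible overlap: need 0 <= x <= min(n1, n2) <= N")
  phyper(x - 1, n1, N - n1, n2, lower.tail = FALSE)
}

# log binomial moments of the k-way intersection size:
# B_j = E[choose(X, j)] = C(N, j) * prod_i C(N-j, n_i - j) / C(N, n_i)
logBinomMoments <- function(j, sizes, N) {
  vapply(j, function(jj) {
    if (jj > min(sizes)) return(-Inf)
    lchoose(N, jj) + sum(lchoose(N - jj, sizes - jj) - lchoose(N, sizes))
  }, numeric(1))
}

# signed log-space sum: returns sum(sign * exp(loga)) plus a cancellation
# diagnostic (the summed magnitude relative to the largest term); heavy
# cancellation means the alternating series has lost its precision
signedLogSum <- function(loga, sign) {
  fin <- is.finite(loga)
  if (!any(fin)) return(list(value = 0, relMagnitude = 1))
  mx <- max(loga[fin])
  s <- sum(sign[fin] * exp(loga[fin] - mx))
  list(value = s * exp(mx), relMagnitude = abs(s))
}

#' Exact multi-set intersection test
#'
#' Exact upper-tail probability P(X >= x) of the k-way intersection size X
#' of k independent, uniformly drawn fixed-size subsets of an N-gene
#' universe, computed by inclusion-exclusion over binomial moments in log
#' space: \code{P(X >= x) = sum_j (-1)^(j-x) C(j-1, x-1) B_j} with
#' \code{B_j = C(N, j) prod_i C(N-j, n_i-j)/C(N, n_i)}. Reduces to the
#' hypergeometric upper tail at k = 2. The alternating series can lose
#' precision for large universes; if the result leaves [0, 1] the function
#' falls back to Monte-Carlo estimation (\code{nSim} draws) with a warning.
#'
#' @param collection a \linkS4class{GeneSetCollection}, or a list of
#'   character vectors plus \code{background}.
#' @param whichSets names or indices of the k >= 2 sets to intersect
#'   (default all).
#' @param xObs observed intersection size; default the actual k-way
#'   intersection of the chosen sets.
#' @param background required when \code{collection} is a plain list.
#' @param nSim Monte-Carlo draws used only in the fallback.
#' @param seed seed for the fallback.
#' @return list with x (intersection size), p (P(X >= x)), expected
#'   (product formula N * prod(n_i/N)) and method ("exact" or
#'   "monte-carlo").
#' @export
multisetExactTest <- function(collection, whichSets = NULL, xObs = NULL,
                              background = NULL, nSim = 1e5, seed = 1) {
  if (is(collection, "GeneSetCollection")) {
    sets <- collection@sets
    N <- length(collection@background)
    bg <- collection@background
  } else {
    sets <- collection
    if (is.null(background)) stop("background required")
    bg <- background
    N <- length(background)
  }
  if (!is.null(whichSets)) sets <- sets[whichSets]
  k <- length(sets)
  if (k < 2) stop("need at least 2 sets")
  sizes <- vapply(sets, length, integer(1))
  if (is.null(xObs)) xObs <- length(Reduce(intersect, sets))
  expected <- N * prod(sizes / N)
  # deterministic lower bound on the intersection: |I| >= sum n_i - (k-1) N
  minPossible <- max(0, sum(sizes) - (k - 1) * N)
  if (xObs <= minPossible)
    return(list(x = as.integer(xObs), p = 1, expected = expected,
                method = "exact"))
  if (xObs > min(sizes)) stop("infeasible intersection size")
  j <- xObs:min(sizes)
  logterm <- lchoose(j - 1, xObs - 1) + logBinomMoments(j, sizes, N)
  s <- signedLogSum(logterm, (-1)^(j - xObs))
  p <- s$value
  method <- "exact"
  if (p < -1e-9 || p > 1 + 1e-9 || s$relMagnitude < 1e-8) {
    warning("inclusion-exclusion unstable; falling back to Monte-Carlo")
    set.seed(seed)
    hits <- replicate(nSim, {
      draw <- lapply(sizes, function(s) sample.int(N, s))
      length(Reduce(intersect, draw)) >= xObs
    })
    p <- mean(hits)
    method <- "monte-carlo"
  }
  list(x = as.integer(xObs), p = min(max(p, 0), 1), expected = expected,
       method = method)
}

#' C-hypergeometric repeatability score (pairwise, analytic)
#'
#' Standardized excess overlap of two gene sets under the hypergeometric
#' null: \code{(x - E) / sigma} with \code{E = n1 n2 / N} and
#' \code{sigma^2 = n1 n2 (N-n1)(N-n2) / (N^2 (N-1))}. Positive scores mean
#' more gene reuse than expected by chance; the score is an effect size,
#' comparable across set sizes and universes.
#'
#' @inheritParams hypergeomOverlap
#' @return the standardized score.
#' @export
cHyper <- function(x, n1, n2, N) {
  E <- n1 * n2 / N
  v <- n1 * n2 * (N - n1) * (N - n2) / (N^2 * (N - 1))
  if (v <= 0) stop("degenerate sets: zero hypergeometric variance")
  (x - E) / sqrt(v)
}

#' Global C-hypergeometric score across all sets
#'
#' Multi-lineage repeatability score: the statistic is the number of genes
#' present in at least two of the sets; the null is built by redrawing
#' same-size uniform random sets from the background \code{nPerm} times,
#' and the score is \code{(obs - mean(null)) / sd(null)}.
#'
#' @param collection a \linkS4class{GeneSetCollection} with >= 3 sets.
#' @param nPerm number of null redraws (default 1000).
#' @param seed integer RNG seed.
#' @return list with observed (count of genes in >= 2 sets), score,
#'   nullMean, nullSd.
#' @export
cHyperGlobal <- function(collection, nPerm = 1000, seed = 1) {
  sets <- collection@sets
  if (length(sets) < 3) stop("need at least 3 sets")
  N <- length(collection@background)
  sizes <- vapply(sets, length, integer(1))
  countShared <- function(ss) {
    tab <- table(unlist(ss, use.names = FALSE))
    sum(tab >= 2)
  }
  obs <- countShared(sets)
  set.seed(seed)
  null <- replicate(nPerm, countShared(
    lapply(sizes, function(s) sample.int(N, s))))
  s <- sd(null)
  if (s == 0) stop("degenerate null: zero variance")
  list(observed = obs, score = (obs - mean(null)) / s,
       nullMean = mean(null), nullSd = s)
}

#' Sharing partition of a gene-set collection
#'
#' Counts genes by the number of sets they belong to: exactly / at least
#' 2, 3, ..., k sets, plus, per set, how many of its genes are shared with
#' at least one other set.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @return list with \code{exactly} and \code{atLeast} (named integer
#'   vectors over multiplicities 1..k) and \code{sharedPerSet}.
#' @export
sharingPartition <- function(collection) {
  sets <- collection@sets
  k <- length(sets)
  memb <- table(factor(unlist(sets, use.names = FALSE),
                       levels = collection@background))
  exactly <- vapply(seq_len(k), function(m) sum(memb == m), integer(1))
  atLeast <- rev(cumsum(rev(exactly)))
  names(exactly) <- names(atLeast) <- seq_len(k)
  sharedGenes <- names(memb)[memb >= 2]
  sharedPerSet <- vapply(sets, function(s)
    sum(s %in% sharedGenes), integer(1))
  list(exactly = exactly, atLeast = atLeast, sharedPerSet = sharedPerSet)
}

#' Category (GO-style) enrichment with directional z-scores
#'
#' One-sided Fisher exact test of over-representation of each annotation
#' category in a gene set against the background, BH-adjusted across
#' categories, plus a direction score
#' \code{z = (nUp - nDown) / sqrt(nUp + nDown)} from the log fold-change
#' signs of the set members annotated to the category (positive z: the
#' category's set members tend to be over-expressed in the montane
#' ecotype). Categories with no background gene are dropped with a
#' warning; the DAG structure of real ontologies is not modelled (flat
#' Fisher + BH).
#'
#' @param geneSet character vector of genes of interest.
#' @param background character vector, the tested universe.
#' @param annotation data.frame with columns gene_id and category.
#' @param logFC optional named numeric vector (per gene) used for z.
#' @return data.frame per category: category, annotated, inSet, p, fdr, z.
#' @export
categoryEnrichment <- function(geneSet, background, annotation,
                               logFC = NULL) {
  stopifnot(all(c("gene_id", "category") %in% colnames(annotation)))
  ann <- annotation[annotation$gene_id %in% background, ]
  dropped <- setdiff(unique(annotation$category), unique(ann$category))
  if (length(dropped))
    warning("categories absent from background dropped: ",
            paste(dropped, collapse = ", "))
  geneSet <- intersect(geneSet, background)
  N <- length(background); n <- length(geneSet)
  cats <- sort(unique(ann$category))
  rows <- lapply(cats, function(cc) {
    inCat <- unique(ann$gene_id[ann$category == cc])
    K <- length(inCat)
    x <- length(intersect(inCat, geneSet))
    tab <- matrix(c(x, K - x, n - x, N - K - n + x), 2, 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    z <- NA_real_
    if (!is.null(logFC) && x > 0) {
      lf <- logFC[intersect(inCat, geneSet)]
      nUp <- sum(lf > 0, na.rm = TRUE); nDown <- sum(lf < 0, na.rm = TRUE)
      if (nUp + nDown > 0) z <- (nUp - nDown) / sqrt(nUp + nDown)
    }
    data.frame(category = cc, annotated = K, inSet = x, p = p, z = z)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p)
  out[order(out$p), c("category", "annotated", "inSet", "p", "fdr", "z")]
}

#' Pairwise overlap report for a collection
#'
#' For every pair of sets: Jaccard index, observed overlap, expectation
#' n1 n2 / N, hypergeometric upper-tail p and the analytic C-score.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @return data.frame with one row per unordered set pair.
#' @export
overlapReport <- function(collection) {
  sets <- collection@sets
  N <- length(collection@background)
  nm <- names(sets)
  cmb <- utils::combn(length(sets), 2)
  rows <- apply(cmb, 2, function(ij) {
    A <- sets[[ij[1]]]; B <- sets[[ij[2]]]
    x <- length(intersect(A, B))
    n1 <- length(A); n2 <- length(B)
    data.frame(setA = nm[ij[1]], setB = nm[ij[2]],
               n1 = n1, n2 = n2, overlap = x,
               jaccard = jaccardIndex(A, B),
               expected = n1 * n2 / N,
               p = if (min(n1, n2) > 0) hypergeomOverlap(x, n1, n2, N)
                   else 1,
               cHyper = if (n1 %in% c(0, N) || n2 %in% c(0, N)) NA_real_
                        else cHyper(x, n1, n2, N))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
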