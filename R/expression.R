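#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
#' @importFrom S4Vectors DataFrame
#' @importFrom stats quantile glm.fit dnbinom pchisq p.adjust optimize var
NULL

#' Construct an ExpressionExperiment
#'
#' @param counts gene x sample matrix of non-negative integers; rownames
#'   are gene ids, colnames sample ids.
#' @param samples data.frame with columns \code{sample}, \code{pair} and
#'   \code{ecotype} ("A"/"M"); rows are matched to count columns by
#'   \code{sample}.
#' @return an \linkS4class{ExpressionExperiment}; library sizes are the
#'   column sums and TMM factors are initialized to 1.
#' @export
expressionExperiment <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%05d", seq_len(nrow(counts)))
  idx <- match(colnames(counts), samples$sample)
  if (anyNA(idx)) stop("sample sheet does not cover all count columns")
  cd <- DataFrame(pair = as.character(samples$pair[idx]),
                  ecotype = as.character(samples$ecotype[idx]),
                  libSize = colSums(counts),
                  tmmFactor = rep(1, ncol(counts)),
                  row.names = colnames(counts))
  if (any(cd$libSize <= 0)) stop("all-zero sample (library size 0)")
  new("ExpressionExperiment",
      SummarizedExperiment(assays = list(counts = counts), colData = cd))
}

#' Counts per million
#'
#' cpm = count / (libSize * tmmFactor) * 1e6. With \code{normalized =
#' FALSE} raw library sizes are used (as in the mean-cpm filter).
#'
#' @param ee an \linkS4class{ExpressionExperiment}.
#' @param normalized multiply library sizes by the stored TMM factors.
#' @return gene x sample matrix of cpm values.
#' @export
cpmMatrix <- function(ee, normalized = TRUE) {
  y <- assay(ee, "counts")
  eff <- colData(ee)$libSize
  if (normalized) eff <- eff * colData(ee)$tmmFactor
  sweep(y, 2, eff, "/") * 1e6
}

#' Filter genes by mean cpm
#'
#' Keeps genes whose mean cpm across all samples is strictly greater than
#' the threshold; cpm is computed on raw library sizes (pre-TMM), so the
#' filter does not depend on normalization.
#'
#' @param ee an \linkS4class{ExpressionExperiment}.
#' @param threshold strict lower bound on mean cpm (default 1).
#' @return the filtered experiment.
#' @export
filterCpm <- function(ee, threshold = 1) {
  keep <- rowMeans(cpmMatrix(ee, normalized = FALSE)) > threshold
  if (!any(keep)) stop("no gene passes the mean-cpm filter")
  ee[keep, ]
}

#' Trimmed mean of M-values normalization factors
#'
#' Self-contained TMM: the reference is the sample whose upper-quartile
#' cpm is closest to the mean upper-quartile across samples; for every
#' other sample, M (log2 cpm ratio to the reference) and A (average log2
#' cpm) values are computed on genes expressed in both, the most extreme
#' 30\% of M and 5\% of A are trimmed two-sided, and the factor is
#' 2^(weighted mean M) with inverse asymptotic-variance (delta-method)
#' weights. Factors are rescaled to geometric mean 1 and stored in
#' \code{colData(ee)$tmmFactor}.
#'
#' @param ee a filtered \linkS4class{ExpressionExperiment}.
#' @param trimM,trimA two-sided trim fractions.
#' @return the experiment with updated TMM factors.
#' @export
tmmFactors <- function(ee, trimM = 0.3, trimA = 0.05) {
  y <- assay(ee, "counts")
  lib <- colData(ee)$libSize
  if (any(lib <= 0)) stop("all-zero sample")
  p <- sweep(y, 2, lib, "/")
  uq <- apply(p, 2, function(v) quantile(v[v > 0], 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(y))
  for (k in seq_len(ncol(y))) {
    if (k == ref) { f[k] <- 1; next }
    use <- y[, k] > 0 & y[, ref] > 0
    if (!any(use)) { f[k] <- 1; next }
    M <- log2(p[use, k] / p[use, ref])
    A <- 0.5 * log2(p[use, k] * p[use, ref])
    w <- (lib[k] - y[use, k]) / (lib[k] * y[use, k]) +
         (lib[ref] - y[use, ref]) / (lib[ref] * y[use, ref])
    keep <- M >= quantile(M, trimM) & M <= quantile(M, 1 - trimM) &
            A >= quantile(A, trimA) & A <= quantile(A, 1 - trimA)
    f[k] <- if (any(keep)) 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
            else 1
  }
  f <- f / exp(mean(log(f)))
  cd <- colData(ee)
  cd$tmmFactor <- f
  colData(ee) <- cd
  ee
}

# negative-binomial log-likelihood at dispersion phi (= 1/size)
nbLogLik <- function(y, mu, phi) {
  sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# fit an NB GLM (log link) at fixed dispersion; returns fitted means and
# the Cox-Reid adjusted profile log-likelihood
nbFit <- function(y, X, offset, phi) {
  fam <- MASS::negative.binomial(theta = 1 / phi, link = "log")
  fit <- suppressWarnings(glm.fit(X, y, family = fam, offset = offset,
                                  control = list(maxit = 50, epsilon = 1e-8)))
  mu <- fit$fitted.values
  w <- mu / (1 + phi * mu)
  XtWX <- crossprod(X * sqrt(w))
  ld <- determinant(XtWX, logarithm = TRUE)$modulus
  list(mu = mu, coef = fit$coefficients,
       ll = nbLogLik(y, mu, phi),
       apl = nbLogLik(y, mu, phi) - 0.5 * as.numeric(ld),
       converged = fit$converged)
}

#' Per-gene negative-binomial differential-expression tests
#'
#' Fits, per gene, an NB log-link GLM with one mean per pair x ecotype
#' cell and offsets log(TMM-effective library size). The dispersion is
#' estimated on a log-spaced grid by Cox-Reid adjusted profile likelihood
#' and moderated toward the across-gene average APL curve with a prior
#' weight equivalent to \code{priorDf} residual degrees of freedom. For
#' each pair, the ecotype contrast is tested by a likelihood-ratio test
#' against the model with that pair's two cell means merged
#' (statistic ~ chi-square(1)). Per pair, p-values are BH-adjusted across
#' genes. log2 fold changes (M vs A) come from the fitted cell means with
#' a 0.5-count offset at the mean effective library size. The default
#' prior weight (20 residual df) is set so that the chi-square reference
#' holds into the far tail for 3-replicate designs: weaker moderation
#' leaves occasional under-estimated dispersions that inflate the extreme
#' LRT quantiles and break FDR control.
#'
#' @param ee a filtered, TMM-normalized \linkS4class{ExpressionExperiment}
#'   with >= 2 replicates per pair x ecotype cell (TMM factors are computed
#'   if still all 1).
#' @param priorDf prior degrees of freedom for dispersion moderation.
#' @param dispGrid dispersion grid (default 15 points, 1e-4 to 5).
#' @return data.frame with one row per gene x pair: gene_id, pair, logFC,
#'   dispersion, LR, PValue, FDR, direction. Genes whose fit does not
#'   converge keep NA statistics.
#' @export
deTest <- function(ee, priorDf = 20,
                   dispGrid = 10^seq(-4, log10(5), length.out = 15)) {
  cd <- colData(ee)
  if (all(cd$tmmFactor == 1)) ee <- tmmFactors(ee)
  cd <- colData(ee)
  y <- assay(ee, "counts")
  cell <- factor(paste(cd$pair, cd$ecotype, sep = "."))
  tabc <- table(cell)
  if (any(tabc < 2))
    stop("need >= 2 replicates per pair x ecotype cell; short: ",
         paste(names(tabc)[tabc < 2], collapse = ", "))
  X <- stats::model.matrix(~ 0 + cell)
  colnames(X) <- levels(cell)
  offset <- log(cd$libSize * cd$tmmFactor)
  pairs <- sort(unique(cd$pair))
  nG <- nrow(y); nGrid <- length(dispGrid)
  dfRes <- ncol(y) - ncol(X)

  # APL over the dispersion grid, per gene
  apl <- matrix(-Inf, nG, nGrid)
  fits <- vector("list", nG)
  for (g in seq_len(nG)) {
    fg <- vector("list", nGrid)
    for (d in seq_len(nGrid)) {
      fg[[d]] <- tryCatch(nbFit(y[g, ], X, offset, dispGrid[d]),
                          error = function(e) NULL)
      if (!is.null(fg[[d]])) apl[g, d] <- fg[[d]]$apl
    }
    fits[[g]] <- fg
  }
  ok <- is.finite(apl)
  aplCommon <- vapply(seq_len(nGrid), function(d)
    mean(apl[ok[, d], d]), numeric(1))
  w <- priorDf / (priorDf + dfRes)
  out <- vector("list", nG)
  meanEff <- mean(cd$libSize * cd$tmmFactor)
  prior <- 0.5  # counts at the mean effective library
  for (g in seq_len(nG)) {
    comb <- (1 - w) * apl[g, ] + w * aplCommon
    comb[!ok[g, ]] <- -Inf
    if (!any(is.finite(comb))) {
      out[[g]] <- data.frame(gene_id = rownames(y)[g], pair = pairs,
                             logFC = NA_real_, dispersion = NA_real_,
                             LR = NA_real_, PValue = NA_real_)
      next
    }
    d <- which.max(comb)
    phi <- dispGrid[d]
    full <- fits[[g]][[d]]
    rows <- lapply(pairs, function(p) {
      cA <- paste(p, "A", sep = "."); cM <- paste(p, "M", sep = ".")
      Xr <- X
      Xr[, cA] <- X[, cA] + X[, cM]
      Xr <- Xr[, colnames(Xr) != cM, drop = FALSE]
      red <- tryCatch(nbFit(y[g, ], Xr, offset, phi),
                      error = function(e) NULL)
      muA <- exp(full$coef[cA]) * meanEff
      muM <- exp(full$coef[cM]) * meanEff
      lfc <- log2((muM + prior) / (muA + prior))
      if (is.null(red) || !full$converged) {
        data.frame(gene_id = rownames(y)[g], pair = p, logFC = lfc,
                   dispersion = phi, LR = NA_real_, PValue = NA_real_)
      } else {
        LR <- max(0, 2 * (full$ll - red$ll))
        data.frame(gene_id = rownames(y)[g], pair = p, logFC = lfc,
                   dispersion = phi, LR = LR,
                   PValue = pchisq(LR, df = 1, lower.tail = FALSE))
      }
    })
    out[[g]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$FDR <- NA_real_
  for (p in pairs) {
    i <- res$pair == p
    res$FDR[i] <- bhAdjust(res$PValue[i])
  }
  res$direction <- sign(res$logFC)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")} (step-up with
#' monotonicity enforcement); NA p-values propagate.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values (always >= raw, <= 1).
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Extract per-pair directional DEG sets
#'
#' Builds the eight gene sets (4 pairs x over/under-expressed in the
#' montane ecotype) at an FDR threshold, over the background of all tested
#' (filter-surviving) genes.
#'
#' @param deResult data.frame from \code{\link{deTest}}.
#' @param fdr FDR threshold (default 0.05).
#' @return a \linkS4class{GeneSetCollection} with sets named
#'   \code{pair<p>_over_M} and \code{pair<p>_under_M}.
#' @export
degSets <- function(deResult, fdr = 0.05) {
  bg <- sort(unique(deResult$gene_id))
  sets <- list()
  for (p in sort(unique(deResult$pair))) {
    x <- deResult[deResult$pair == p & !is.na(deResult$FDR) &
                  deResult$FDR < fdr, ]
    sets[[paste0("pair", p, "_over_M")]] <- x$gene_id[x$logFC > 0]
    sets[[paste0("pair", p, "_under_M")]] <- x$gene_id[x$logFC < 0]
  }
  new("GeneSetCollection", background = bg, sets = sets)
}
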