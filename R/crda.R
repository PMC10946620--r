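#' @importFrom stats model.matrix
NULL

# residualize columns of M on the column space of Z (QR-based hat matrix)
residualizeOn <- function(M, Z) {
  qr.resid(qr(Z), M)
}

#' Conditioned redundancy analysis of expression
#'
#' Two-step partial RDA constrained on ecotype with the ecotype-pair
#' partialled out (the \code{~ ecotype + Condition(pair)} design): (1) the
#' gene x sample response (cpm) is transposed and column-centred; (2) both
#' the response and the ecotype indicator are residualized on the pair
#' indicators; (3) the residualized response is regressed on the
#' residualized ecotype, and the fitted values are decomposed by SVD. With
#' one constraining variable there is a single constrained axis; gene
#' scores are the loadings on that axis scaled by its singular value, and
#' total inertia splits exactly into conditioned + constrained +
#' unconstrained sums of squares.
#'
#' @param x cpm matrix (genes x samples) or an
#'   \linkS4class{ExpressionExperiment} (its normalized cpm is used).
#' @param ecotype character/factor of "A"/"M" per sample (taken from
#'   colData when x is an experiment).
#' @param pair ecotype-pair label per sample (ditto).
#' @return a \linkS4class{CRDAResult}.
#' @export
crdaFit <- function(x, ecotype = NULL, pair = NULL) {
  if (is(x, "ExpressionExperiment")) {
    cd <- colData(x)
    if (is.null(ecotype)) ecotype <- cd$ecotype
    if (is.null(pair)) pair <- cd$pair
    x <- cpmMatrix(x)
  }
  n <- ncol(x)
  stopifnot(length(ecotype) == n, length(pair) == n)
  Y <- t(x)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  Z <- model.matrix(~ factor(pair))
  e <- as.numeric(factor(ecotype, levels = c("A", "M"))) - 1
  Yres <- residualizeOn(Y, Z)
  eres <- residualizeOn(matrix(e, ncol = 1), Z)[, 1]
  if (sum(eres^2) < 1e-12)
    stop("confounded design: ecotype is collinear with pair")
  totalInertia <- sum(Y^2)
  if (totalInertia <= 0)
    stop("degenerate response: the centred matrix has no inertia")
  conditioned <- totalInertia - sum(Yres^2)
  u <- eres / sqrt(sum(eres^2))
  b <- drop(crossprod(u, Yres))          # 1 x genes projection coefficients
  constrained <- sum(b^2)
  unconstrained <- sum(Yres^2) - constrained
  dfRes <- n - ncol(Z) - 1
  pseudoF <- (constrained / 1) / (unconstrained / dfRes)
  geneScores <- b / sqrt(max(1, n - 1))
  names(geneScores) <- rownames(x)
  resid <- Yres - outer(u, b)
  sv <- svd(resid, nu = 1, nv = 0)
  sampleScores <- cbind(RDA1 = u * sqrt(constrained),
                        PC1 = sv$u[, 1] * sv$d[1])
  rownames(sampleScores) <- colnames(x)
  fr <- c(conditioned = conditioned, constrained = constrained,
          unconstrained = unconstrained) / totalInertia
  new("CRDAResult", fractions = fr, totalInertia = totalInertia,
      geneScores = geneScores, sampleScores = sampleScores,
      pseudoF = pseudoF, df = c(1, dfRes))
}

#' Gene outliers on the constrained axis
#'
#' Transforms gene scores to z-scores ((score - mean) / SD over genes) and
#' flags genes beyond the thresholds (default |z| > 2 and |z| > 2.6,
#' roughly p < .05 and p < .01 under normality); the sets are nested.
#'
#' @param result a \linkS4class{CRDAResult}.
#' @param thresholds numeric vector of |z| cutoffs.
#' @return list with z (named vector) and outliers (list of gene-id
#'   vectors, one per threshold). A zero-variance score vector yields empty
#'   sets with attribute \code{degenerate = TRUE}.
#' @export
crdaOutliers <- function(result, thresholds = c(2, 2.6)) {
  s <- geneScores(result)
  sdv <- sd(s)
  if (!is.finite(sdv) || sdv <= 1e-10 * (abs(mean(s)) + max(abs(s)))) {
    out <- list(z = s * 0,
                outliers = setNames(rep(list(character(0)),
                                        length(thresholds)),
                                    paste0("sd", thresholds)))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  z <- (s - mean(s)) / sdv
  outliers <- lapply(thresholds, function(th) names(z)[abs(z) > th])
  names(outliers) <- paste0("sd", thresholds)
  list(z = z, outliers = outliers)
}

# all within-block label arrangements when their number is small
enumerateBlockPerms <- function(ecotype, pair) {
  blocks <- split(seq_along(ecotype), pair)
  perBlock <- lapply(blocks, function(idx) {
    nM <- sum(ecotype[idx] == "M")
    chooseM <- utils::combn(length(idx), nM)
    lapply(seq_len(ncol(chooseM)), function(c) {
      lab <- rep("A", length(idx))
      lab[chooseM[, c]] <- "M"
      lab
    })
  })
  grid <- expand.grid(lapply(perBlock, seq_along))
  lapply(seq_len(nrow(grid)), function(r) {
    out <- character(length(ecotype))
    for (bk in seq_along(blocks))
      out[blocks[[bk]]] <- perBlock[[bk]][[grid[r, bk]]]
    out
  })
}

#' Permutation ANOVA for the constrained term
#'
#' Tests the ecotype constraint by permuting ecotype labels within pair
#' blocks (the pair is the nuisance stratum): pseudo-F =
#' (SS_constrained / 1) / (SS_unconstrained / df_resid). When the number
#' of distinct within-block arrangements is below \code{nPerm}, all of
#' them are enumerated (exact test, with a warning); otherwise random
#' permutations with the add-one correction are used.
#'
#' @inheritParams crdaFit
#' @param nPerm number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @return list with pseudoF, p, nPerm and exact (logical).
#' @export
crdaAnova <- function(x, ecotype = NULL, pair = NULL, nPerm = 1000,
                      seed = 1) {
  if (is(x, "ExpressionExperiment")) {
    cd <- colData(x)
    if (is.null(ecotype)) ecotype <- cd$ecotype
    if (is.null(pair)) pair <- cd$pair
    x <- cpmMatrix(x)
  }
  ecotype <- as.character(ecotype)
  n <- ncol(x)
  Y <- scale(t(x), center = TRUE, scale = FALSE)
  Z <- model.matrix(~ factor(pair))
  Yres <- residualizeOn(Y, Z)
  ssRes <- sum(Yres^2)
  dfRes <- n - ncol(Z) - 1
  statF <- function(lab) {
    e <- as.numeric(lab == "M")
    er <- residualizeOn(matrix(e, ncol = 1), Z)[, 1]
    s2 <- sum(er^2)
    if (s2 < 1e-12) return(NA_real_)
    cons <- sum(drop(crossprod(er / sqrt(s2), Yres))^2)
    (cons / 1) / ((ssRes - cons) / dfRes)
  }
  fObs <- statF(ecotype)
  blocks <- split(ecotype, pair)
  nArr <- prod(vapply(blocks, function(b)
    choose(length(b), sum(b == "M")), numeric(1)))
  if (nArr <= nPerm) {
    warning("only ", nArr, " distinct arrangements; using exact enumeration")
    labs <- enumerateBlockPerms(ecotype, pair)
    fNull <- vapply(labs, statF, numeric(1))
    p <- mean(fNull >= fObs - 1e-12, na.rm = TRUE)
    return(list(pseudoF = fObs, p = p, nPerm = length(labs), exact = TRUE))
  }
  set.seed(seed)
  idxByBlock <- split(seq_along(ecotype), pair)
  fNull <- numeric(nPerm)
  for (r in seq_len(nPerm)) {
    lab <- ecotype
    for (idx in idxByBlock) lab[idx] <- sample(ecotype[idx])
    fNull[r] <- statF(lab)
  }
  p <- (1 + sum(fNull >= fObs, na.rm = TRUE)) / (1 + nPerm)
  list(pseudoF = fObs, p = p, nPerm = nPerm, exact = FALSE)
}
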