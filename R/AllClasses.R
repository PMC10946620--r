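#' @import methods
#' @importFrom stats setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Folded site-frequency spectrum
#'
#' Container for a one-dimensional folded SFS: site counts per minor-allele
#' frequency class \code{0..floor(n/2)}, where class 0 holds monomorphic
#' sites and \code{n} is the number of sampled haploids.
#'
#' @slot counts numeric vector of length \code{floor(n/2) + 1}.
#' @slot n integer, number of sampled haploids.
#' @slot nSites numeric, total number of sites the spectrum covers.
#' @exportClass FoldedSFS
setClass("FoldedSFS",
  representation(counts = "numeric", n = "integer", nSites = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@counts) != object@n %/% 2 + 1)
      msg <- c(msg, "counts must have length floor(n/2) + 1")
    if (any(object@counts < 0)) msg <- c(msg, "negative class counts")
    if (object@n < 2) msg <- c(msg, "n must be >= 2")
    if (is.null(msg)) TRUE else msg
  })

#' Folded joint site-frequency spectrum
#'
#' Two-population folded joint SFS. The matrix has \code{(n1+1) x (n2+1)}
#' cells; folding on the pooled minor allele zeroes the redundant half
#' (cells with \code{i + j} greater than \code{(n1+n2)/2}), and exact ties
#' are split half-and-half between a cell and its complement. Cell (0,0)
#' carries sites monomorphic in the pair.
#'
#' @slot mat numeric matrix of cell masses (site counts or probabilities).
#' @slot n1,n2 integer haploid sample sizes of the two populations.
#' @slot popNames character(2), population labels (rows = pop 1).
#' @exportClass JointFoldedSFS
setClass("JointFoldedSFS",
  representation(mat = "matrix", n1 = "integer", n2 = "integer",
                 popNames = "character"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@mat) == c(object@n1 + 1L, object@n2 + 1L)))
      msg <- c(msg, "mat must be (n1+1) x (n2+1)")
    if (any(object@mat < 0)) msg <- c(msg, "negative cell mass")
    if (is.null(msg)) TRUE else msg
  })

#' Four-deme divergence model
#'
#' A demographic model for two replicated ecotype pairs (four demes, by
#' convention A1, M1, A3, M3: alpine/montane ecotypes at two localities).
#' Looking backward in time, two demes merge at T2, the remaining two at T3,
#' and the two ancestral demes merge at T1 (T1 strictly predates both).
#' Under the \code{one_origin} topology the T2/T3 merges are ecotype-wise
#' (A1+A3, then M1+M3); under \code{two_origins} they are locality-wise
#' (A1+M1, then A3+M3). \code{SI} (strict isolation) forces all migration
#' rates to zero; \code{IM} allows a backward migration matrix between the
#' four contemporary demes.
#'
#' @slot topology "one_origin" or "two_origins".
#' @slot mode "SI" or "IM".
#' @slot demeNames character(4).
#' @slot Ne numeric(4), diploid effective sizes of the contemporary demes.
#' @slot sampleSizes integer(4), sampled haploids per deme (even, >= 2).
#' @slot ancestralNe numeric(3): sizes of the deme created at T2, at T3 and
#'   at the root (T1).
#' @slot splitTimes numeric(3) named T1, T2, T3, in generations.
#' @slot migration numeric 4x4 backward migration rate matrix (diagonal 0).
#' @slot mu per-site per-generation mutation rate.
#' @exportClass DemographicModel
setClass("DemographicModel",
  representation(topology = "character", mode = "character",
                 demeNames = "character", Ne = "numeric",
                 sampleSizes = "integer", ancestralNe = "numeric",
                 splitTimes = "numeric", migration = "matrix",
                 mu = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@topology %in% c("one_origin", "two_origins"))
      msg <- c(msg, "topology must be one_origin or two_origins")
    if (!object@mode %in% c("SI", "IM"))
      msg <- c(msg, "mode must be SI or IM")
    if (length(object@Ne) != 4 || any(object@Ne <= 0))
      msg <- c(msg, "Ne must be 4 positive sizes")
    if (length(object@sampleSizes) != 4 || any(object@sampleSizes < 2) ||
        any(object@sampleSizes %% 2 != 0))
      msg <- c(msg, "sample sizes must be even and >= 2")
    tt <- object@splitTimes
    if (!all(c("T1", "T2", "T3") %in% names(tt)))
      msg <- c(msg, "splitTimes must be named T1, T2, T3")
    else if (tt["T1"] <= max(tt["T2"], tt["T3"]))
      msg <- c(msg, "T1 must strictly predate T2 and T3")
    if (any(object@migration < 0)) msg <- c(msg, "negative migration rate")
    if (object@mode == "SI" && any(object@migration != 0))
      msg <- c(msg, "SI models must have zero migration")
    if (any(diag(object@migration) != 0))
      msg <- c(msg, "migration diagonal must be zero")
    if (length(object@ancestralNe) != 3 || any(object@ancestralNe <= 0))
      msg <- c(msg, "ancestralNe must be 3 positive sizes")
    if (object@mu < 0) msg <- c(msg, "negative mutation rate")
    if (is.null(msg)) TRUE else msg
  })

#' Prior box for demographic parameters
#'
#' Rectangular bounds, one \code{c(lower, upper)} pair per parameter, used
#' both to validate models and to bound the multi-start optimization in
#' \code{\link{fitModel}}. \code{\link{defaultPriors}} returns the study
#' defaults.
#'
#' @slot bounds named list of length-2 numeric vectors (lower, upper).
#' @exportClass PriorBox
setClass("PriorBox",
  representation(bounds = "list"),
  validity = function(object) {
    ok <- vapply(object@bounds, function(b)
      is.numeric(b) && length(b) == 2 && b[1] <= b[2] && b[1] >= 0,
      logical(1))
    if (all(ok)) TRUE else "each bound must be numeric c(lower, upper), lower <= upper, >= 0"
  })

#' Result of one composite-likelihood model fit
#'
#' @slot modelId character label ("topology_mode").
#' @slot topology,mode model class.
#' @slot estimates named list of point estimates on the natural scale.
#' @slot lnCLest maximized composite log-likelihood (natural log).
#' @slot lnCLobs saturated-model composite log-likelihood of the data.
#' @slot k integer, number of free parameters.
#' @slot AIC 2k - 2 lnCLest.
#' @slot restarts data.frame logging every optimizer restart.
#' @slot seed,nSims integers used for reproducibility.
#' @exportClass FitResult
setClass("FitResult",
  representation(modelId = "character", topology = "character",
                 mode = "character", estimates = "list",
                 lnCLest = "numeric", lnCLobs = "numeric", k = "integer",
                 AIC = "numeric", restarts = "data.frame",
                 seed = "integer", nSims = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@lnCLest > object@lnCLobs + 1e-8)
      msg <- c(msg, "lnCLest cannot exceed lnCLobs")
    if (abs(object@AIC - (2 * object@k - 2 * object@lnCLest)) > 1e-6)
      msg <- c(msg, "AIC inconsistent with k and lnCLest")
    if (is.null(msg)) TRUE else msg
  })

#' Expression experiment for replicated ecotype pairs
#'
#' A \linkS4class{SummarizedExperiment} holding a gene x sample integer
#' count matrix (assay \code{"counts"}) and a sample sheet with \code{pair}
#' (ecotype-pair label) and \code{ecotype} ("A" alpine / "M" montane)
#' columns; \code{libSize} and \code{tmmFactor} live in \code{colData}.
#'
#' @exportClass ExpressionExperiment
setClass("ExpressionExperiment",
  contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("pair", "ecotype") %in% colnames(cd)))
      msg <- c(msg, "colData must contain 'pair' and 'ecotype'")
    else if (!all(cd$ecotype %in% c("A", "M")))
      msg <- c(msg, "ecotype must be 'A' or 'M'")
    y <- SummarizedExperiment::assay(object, "counts")
    if (any(y < 0) || any(y != round(y)))
      msg <- c(msg, "counts must be non-negative integers")
    if (is.null(msg)) TRUE else msg
  })

#' Named gene sets over an explicit background universe
#'
#' @slot background character vector, the gene universe (unique ids).
#' @slot sets named list of character vectors, each a subset of background.
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(background = "character", sets = "list"),
  validity = function(object) {
    msg <- NULL
    if (anyDuplicated(object@background))
      msg <- c(msg, "background must not contain duplicates")
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "sets must have unique names")
    inbg <- vapply(object@sets, function(s) all(s %in% object@background),
                   logical(1))
    if (!all(inbg)) msg <- c(msg, "every set must be a subset of background")
    if (is.null(msg)) TRUE else msg
  })

#' Conditioned redundancy analysis result
#'
#' @slot fractions named numeric(3): conditioned, constrained and
#'   unconstrained fractions of total inertia (they sum to 1).
#' @slot totalInertia total sum of squares of the centred response.
#' @slot geneScores per-gene loadings on the constrained axis (scaled by
#'   the singular value).
#' @slot sampleScores matrix of sample coordinates, columns \code{RDA1}
#'   (constrained axis) and \code{PC1} (first unconstrained axis).
#' @slot pseudoF pseudo-F statistic of the constrained term.
#' @slot df numeric(2): constrained and residual degrees of freedom.
#' @exportClass CRDAResult
setClass("CRDAResult",
  representation(fractions = "numeric", totalInertia = "numeric",
                 geneScores = "numeric", sampleScores = "matrix",
                 pseudoF = "numeric", df = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@fractions < -1e-9))
      msg <- c(msg, "negative inertia fraction")
    if (abs(sum(object@fractions) - 1) > 1e-9)
      msg <- c(msg, "inertia fractions must sum to 1")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "FoldedSFS", function(object) {
  cat("FoldedSFS: n =", object@n, "haploids,", object@nSites, "sites,",
      sum(object@counts[-1]), "polymorphic\n")
})

setMethod("show", "JointFoldedSFS", function(object) {
  cat("JointFoldedSFS (", paste(object@popNames, collapse = " x "),
      "): n1 =", object@n1, ", n2 =", object@n2,
      ", total mass =", signif(sum(object@mat), 6), "\n")
})

setMethod("show", "DemographicModel", function(object) {
  tt <- object@splitTimes
  cat("DemographicModel:", object@topology, object@mode, "\n")
  cat("  demes:", paste(sprintf("%s(Ne=%g, n=%d)", object@demeNames,
      object@Ne, object@sampleSizes), collapse = ", "), "\n")
  cat("  splits: T1 =", tt["T1"], "T2 =", tt["T2"], "T3 =", tt["T3"],
      "generations; mu =", object@mu, "\n")
  if (object@mode == "IM")
    cat("  max migration rate:", max(object@migration), "\n")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult", object@modelId, ": lnCL =", round(object@lnCLest, 2),
      "(saturated", round(object@lnCLobs, 2), "), k =", object@k,
      ", AIC =", round(object@AIC, 2), "\n")
  cat("  deltaL =", round(object@lnCLobs - object@lnCLest, 2),
      ";", nrow(object@restarts), "restart(s), nSims =", object@nSims, "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets over a background of",
      length(object@background), "genes\n")
  sz <- vapply(object@sets, length, integer(1))
  cat(" ", paste(sprintf("%s(%d)", names(sz), sz), collapse = ", "), "\n")
})

setMethod("show", "CRDAResult", function(object) {
  f <- round(100 * object@fractions, 2)
  cat("CRDAResult: conditioned", f[1], "% | constrained", f[2],
      "% | unconstrained", f[3], "% of total inertia\n")
  cat("  pseudo-F =", round(object@pseudoF, 3), "on df", object@df[1],
      "and", object@df[2], "\n")
})
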