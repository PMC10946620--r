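#' @useDynLib EcoParallel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim plogis qlogis runif rnorm
NULL

DEME_NAMES <- c("A1", "M1", "A3", "M3")

#' Default prior box for demographic inference
#'
#' Broad rectangular priors: mutation rate in [1e-10, 1e-8], alpine Ne in
#' [50, 50000], montane Ne in [50, 5000] diploids, split times in
#' [1000, 100000] generations and (for IM models) backward migration rate in
#' [1e-9, 2] per lineage per generation.
#'
#' @return a \linkS4class{PriorBox}.
#' @export
defaultPriors <- function() {
  new("PriorBox", bounds = list(
    Ne_A = c(50, 50000),
    Ne_M = c(50, 5000),
    T    = c(1000, 100000),
    mu   = c(1e-10, 1e-8),
    m    = c(1e-9, 2)))
}

#' @rdname defaultPriors
#' @param bounds named list of c(lower, upper) pairs (Ne_A, Ne_M, T, mu, m).
#' @export
priorBox <- function(bounds) new("PriorBox", bounds = bounds)

# merge schedule: which contemporary demes (indices into A1,M1,A3,M3)
# coalesce at T2 and at T3 under each topology
mergeSchedule <- function(topology) {
  if (topology == "one_origin")
    list(T2 = c(1L, 3L), T3 = c(2L, 4L))   # ecotype-wise: alpines, montanes
  else
    list(T2 = c(1L, 2L), T3 = c(3L, 4L))   # locality-wise
}

#' Build a four-deme divergence model
#'
#' Constructs and validates a \linkS4class{DemographicModel}. The merge
#' schedule follows the topology (ecotype-wise merges for
#' \code{one_origin}, locality-wise for \code{two_origins}); both orders
#' T2 > T3 and T3 > T2 are valid, but T1 must strictly predate both.
#' \code{mode = "SI"} zeroes the migration matrix.
#'
#' @param topology "one_origin" or "two_origins".
#' @param mode "SI" or "IM".
#' @param Ne numeric(4) diploid sizes for demes A1, M1, A3, M3.
#' @param sampleSizes integer(4) sampled haploids per deme (even, >= 2).
#' @param splitTimes named numeric(3) (T1, T2, T3) in generations.
#' @param migration scalar rate applied to all off-diagonal entries, or a
#'   4x4 backward-rate matrix. Ignored (forced to 0) under SI.
#' @param mu per-site per-generation mutation rate.
#' @param ancestralNe numeric(3) sizes of the demes created at T2, T3 and
#'   the root; defaults to the sum of the daughter sizes at each merge.
#' @param priors optional \linkS4class{PriorBox}; when given, parameters are
#'   checked against it.
#' @return a validated \linkS4class{DemographicModel}.
#' @examples
#' m <- buildModel("two_origins", "SI", Ne = c(5000, 1000, 5000, 1000),
#'                 sampleSizes = c(6, 6, 6, 6),
#'                 splitTimes = c(T1 = 50000, T2 = 20000, T3 = 10000),
#'                 mu = 1e-9)
#' @export
buildModel <- function(topology = c("one_origin", "two_origins"),
                       mode = c("SI", "IM"),
                       Ne, sampleSizes, splitTimes, migration = 0,
                       mu = 1e-9, ancestralNe = NULL, priors = NULL) {
  topology <- match.arg(topology)
  mode <- match.arg(mode)
  if (is.matrix(migration)) {
    mig <- migration
  } else {
    mig <- matrix(migration, 4, 4)
    diag(mig) <- 0
  }
  if (mode == "SI") mig <- matrix(0, 4, 4)
  sched <- mergeSchedule(topology)
  if (is.null(ancestralNe))
    ancestralNe <- c(sum(Ne[sched$T2]), sum(Ne[sched$T3]), sum(Ne))
  splitTimes <- splitTimes[c("T1", "T2", "T3")]
  if (!is.null(priors)) {
    b <- priors@bounds
    chk <- function(v, bd, what)
      if (any(v < bd[1] - 1e-12) || any(v > bd[2] + 1e-12))
        stop(what, " outside prior box [", bd[1], ", ", bd[2], "]")
    chk(Ne[c(1, 3)], b$Ne_A, "alpine Ne")
    chk(Ne[c(2, 4)], b$Ne_M, "montane Ne")
    chk(splitTimes[c("T2", "T3")], b$T, "split time")
    chk(mu, b$mu, "mutation rate")
    if (mode == "IM") chk(mig[mig > 0], b$m, "migration rate")
  }
  new("DemographicModel", topology = topology, mode = mode,
      demeNames = DEME_NAMES, Ne = as.numeric(Ne),
      sampleSizes = as.integer(sampleSizes),
      ancestralNe = as.numeric(ancestralNe),
      splitTimes = splitTimes, migration = mig, mu = mu)
}

# merge-event matrix for the C++ simulator: (time, source, dest, new Ne of
# dest), 0-based deme indices, sorted by time. The source deme is absorbed
# into the dest deme.
eventsMatrix <- function(model) {
  sched <- mergeSchedule(model@topology)
  tt <- model@splitTimes
  e2 <- c(tt["T2"], sched$T2[2] - 1L, sched$T2[1] - 1L, model@ancestralNe[1])
  e3 <- c(tt["T3"], sched$T3[2] - 1L, sched$T3[1] - 1L, model@ancestralNe[2])
  er <- c(tt["T1"], sched$T3[1] - 1L, sched$T2[1] - 1L, model@ancestralNe[3])
  ev <- rbind(e2, e3, er)
  ev[order(ev[, 1]), , drop = FALSE]
}

#' Simulate genealogies and site data under a divergence model
#'
#' Runs the built-in structured-coalescent simulator: within each deme,
#' k lineages coalesce at rate k(k-1)/(4 Ne) per generation, lineages
#' migrate backward at the model's rates, and demes merge at T2, T3, T1.
#' Mutations are dropped on branches under the infinite-sites model at rate
#' \code{mu} per site per generation.
#'
#' @param model a \linkS4class{DemographicModel}.
#' @param nLoci number of independent loci (genealogies).
#' @param seed integer RNG seed (mandatory; the simulation is reproducible).
#' @param locusLength sites per locus (scales the mutation supply).
#' @param sites if TRUE, return realized per-site derived-allele counts.
#' @param maxEventsPerLocus event budget per locus; once exceeded the
#'   remaining demes are collapsed to their strong-migration (panmictic,
#'   harmonic-mean size) limit. Only migration-dominated loci (high m)
#'   ever reach the budget.
#' @return a list with \code{tmrca} (per-locus height, generations),
#'   \code{configLengths} (4-d array of accumulated branch lengths indexed
#'   by the per-deme counts of subtended samples) and, when
#'   \code{sites = TRUE}, a data.frame \code{sites} with columns
#'   \code{locus} and one derived-allele count column per deme.
#' @export
simulateGenealogies <- function(model, nLoci, seed, locusLength = 1000,
                                sites = TRUE, maxEventsPerLocus = 3000) {
  stopifnot(nLoci >= 1, is.numeric(seed))
  res <- coalescent_sim_cpp(model@sampleSizes, model@Ne, model@migration,
                            eventsMatrix(model), as.integer(nLoci),
                            model@mu, locusLength, as.integer(seed),
                            isTRUE(sites), as.integer(maxEventsPerLocus))
  cl <- array(res$config_lengths, dim = model@sampleSizes + 1L)
  out <- list(tmrca = res$tmrca, configLengths = cl)
  if (isTRUE(sites)) {
    s <- as.data.frame(res$sites)
    colnames(s) <- c("locus", model@demeNames)
    out$sites <- s
  }
  out
}

#' Expected folded joint SFS under a model
#'
#' Monte-Carlo expectation of the folded joint SFS for one deme pair:
#' \code{nSims} genealogies are simulated and branch lengths are
#' accumulated by sample configuration (a Rao-Blackwellized estimate of the
#' infinite-sites expectation, free of mutational noise). The pair margin is
#' folded as in \code{\link{foldJointSFS}}, the monomorphic cell (0,0) is
#' excluded and the remaining cells are normalized to sum 1.
#'
#' @param model a \linkS4class{DemographicModel}.
#' @param popPair integer(2) or character(2): the two demes.
#' @param nSims number of simulated genealogies (>= 1000 recommended).
#' @param seed integer RNG seed.
#' @return a \linkS4class{JointFoldedSFS} of cell probabilities with
#'   attribute \code{nSims}.
#' @export
expectedJointSFS <- function(model, popPair, nSims = 20000, seed = 1) {
  idx <- if (is.character(popPair)) match(popPair, model@demeNames)
         else as.integer(popPair)
  stopifnot(length(idx) == 2, !anyNA(idx), nSims >= 1)
  sim <- simulateGenealogies(model, nSims, seed, sites = FALSE)
  expectedAllJointSFS(model, sim$configLengths,
                      pairs = matrix(sort(idx), 1))[[1]]
}

# fold + normalize every requested pair margin of a configuration-length
# array; pairs is a matrix with one (a, b) row per pair, a < b
expectedAllJointSFS <- function(model, configLengths, pairs = NULL) {
  if (is.null(pairs)) pairs <- t(utils::combn(4, 2))
  out <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    u <- apply(configLengths, c(a, b), sum)
    f <- foldJSFSMatrix(u)
    f[1, 1] <- 0
    tot <- sum(f)
    if (tot <= 0)
      stop("all expected mass is monomorphic for pair (",
           model@demeNames[a], ", ", model@demeNames[b], ")")
    out[[r]] <- new("JointFoldedSFS", mat = f / tot,
                    n1 = model@sampleSizes[a], n2 = model@sampleSizes[b],
                    popNames = model@demeNames[c(a, b)])
  }
  names(out) <- apply(pairs, 1, function(p)
    paste(model@demeNames[p], collapse = "_"))
  out
}

# polymorphic cell masses of a folded joint SFS as a vector ((0,0) dropped)
polymorphicCells <- function(jsfs) {
  v <- as.vector(jsfs@mat)
  v[-1]
}

#' Multinomial composite log-likelihood over folded joint SFS
#'
#' Sums \code{m_cell * log(p_cell)} over the polymorphic cells of one or
#' several observed spectra, with expected cell probabilities renormalized
#' over polymorphic cells and floored at \code{pFloor} before logging so
#' that cells unvisited by the Monte-Carlo expectation do not yield -Inf.
#'
#' @param obs a \linkS4class{JointFoldedSFS} of site counts, or a list of
#'   them (e.g. the six deme-pair spectra).
#' @param expected matching \linkS4class{JointFoldedSFS} (probabilities), or
#'   list; dimensions must match \code{obs}.
#' @param pFloor probability floor; default \code{1/(10 * nSims)} taken from
#'   the \code{nSims} attribute of the expectation, else 1e-8.
#' @return the composite log-likelihood (natural log).
#' @seealso \code{\link{maxObsLogLik}} for the saturated-model value.
#' @export
compositeLogLik <- function(obs, expected, pFloor = NULL) {
  if (is(obs, "JointFoldedSFS")) obs <- list(obs)
  if (is(expected, "JointFoldedSFS")) expected <- list(expected)
  if (length(obs) != length(expected))
    stop("obs and expected must have the same number of spectra")
  tot <- 0
  for (i in seq_along(obs)) {
    o <- obs[[i]]; e <- expected[[i]]
    if (!all(dim(o@mat) == dim(e@mat)))
      stop("dimension mismatch between observed and expected spectrum ", i)
    m <- polymorphicCells(o)
    p <- polymorphicCells(e)
    sp <- sum(p)
    if (sp <= 0) stop("expected spectrum ", i, " has no polymorphic mass")
    p <- p / sp
    fl <- pFloor
    if (is.null(fl)) {
      ns <- attr(e, "nSims")
      fl <- if (is.null(ns)) 1e-8 else 1 / (10 * ns)
    }
    p <- pmax(p, fl)
    tot <- tot + sum(m[m > 0] * log(p[m > 0]))
  }
  tot
}

#' Saturated-model composite log-likelihood
#'
#' The maximum attainable composite log-likelihood for an observed spectrum:
#' the multinomial log-likelihood at the observed cell proportions. Cells
#' with zero counts contribute nothing.
#'
#' @inheritParams compositeLogLik
#' @return the saturated log-likelihood (natural log).
#' @export
maxObsLogLik <- function(obs) {
  if (is(obs, "JointFoldedSFS")) obs <- list(obs)
  tot <- 0
  for (o in obs) {
    m <- polymorphicCells(o)
    M <- sum(m)
    if (M <= 0) stop("empty spectrum: no polymorphic sites")
    tot <- tot + sum(m[m > 0] * log(m[m > 0] / M))
  }
  tot
}

# free-parameter layout for a model class under a prior box; collapsed
# bounds (lower == upper) become fixed constants and do not count in k
fitParamLayout <- function(mode, priors) {
  b <- priors@bounds
  pars <- list(
    Ne_A1 = b$Ne_A, Ne_M1 = b$Ne_M, Ne_A3 = b$Ne_A, Ne_M3 = b$Ne_M,
    T2 = b$T, T3 = b$T, uT1 = c(0, 1), mu = b$mu)
  logscale <- c(rep(TRUE, 4), TRUE, TRUE, FALSE, TRUE)
  if (mode == "IM") {
    pars$m <- b$m
    logscale <- c(logscale, TRUE)
  }
  free <- vapply(pars, function(x) x[1] < x[2], logical(1))
  list(pars = pars, logscale = logscale, free = free)
}

# map unconstrained optimizer coordinates to natural-scale parameters
decodeParams <- function(x, layout) {
  vals <- numeric(length(layout$pars))
  names(vals) <- names(layout$pars)
  j <- 0
  for (i in seq_along(layout$pars)) {
    bd <- layout$pars[[i]]
    if (!layout$free[i]) { vals[i] <- bd[1]; next }
    j <- j + 1
    f <- plogis(x[j])
    vals[i] <- if (layout$logscale[i])
      10^(log10(bd[1]) + f * (log10(bd[2]) - log10(bd[1])))
    else bd[1] + f * (bd[2] - bd[1])
  }
  vals
}

paramsToModel <- function(vals, topology, mode, sampleSizes, priors) {
  Tmax <- priors@bounds$T[2]
  tmx <- max(vals["T2"], vals["T3"])
  T1 <- tmx + max(1, vals["uT1"] * (Tmax - tmx))
  buildModel(topology, mode,
             Ne = vals[c("Ne_A1", "Ne_M1", "Ne_A3", "Ne_M3")],
             sampleSizes = sampleSizes,
             splitTimes = c(T1 = unname(T1), T2 = unname(vals["T2"]),
                            T3 = unname(vals["T3"])),
             migration = if (mode == "IM") unname(vals["m"]) else 0,
             mu = unname(vals["mu"]))
}

#' Fit a divergence model to observed joint spectra
#'
#' Composite-likelihood fit by multi-start bounded Nelder-Mead on
#' log10-transformed parameters. Each likelihood evaluation simulates the
#' expected folded joint SFS for all six deme pairs (\code{nSims}
#' genealogies with a per-restart fixed simulation seed, so the objective
#' is deterministic within a restart) and scores the observed spectra with
#' \code{\link{compositeLogLik}}. Free parameters are the four deme sizes,
#' T2, T3, T1 (through its excess over max(T2, T3)), the mutation rate and,
#' for IM models, one symmetric migration rate; collapsing a prior to a
#' point fixes the parameter and removes it from k.
#'
#' @param obs named list of six observed \linkS4class{JointFoldedSFS} (site
#'   counts), named as \code{demeA_demeB} over demes A1, M1, A3, M3.
#' @param topology,mode the model class to fit.
#' @param sampleSizes integer(4) haploid sample sizes (must match obs).
#' @param priors a \linkS4class{PriorBox}; default \code{defaultPriors()}.
#' @param nRestarts independent optimizer starts (best kept).
#' @param nSims genealogies per likelihood evaluation.
#' @param seed integer master seed (drives starts and simulation seeds).
#' @param maxit Nelder-Mead iteration cap per restart.
#' @param maxEventsPerLocus per-locus event budget for the expectation
#'   simulations (see \code{\link{simulateGenealogies}}); fitting uses a
#'   tighter default so that high-migration corners of the prior box are
#'   evaluated in their strong-migration limit instead of stalling.
#' @return a \linkS4class{FitResult}; all restarts are logged in its
#'   \code{restarts} slot.
#' @export
fitModel <- function(obs, topology, mode, sampleSizes,
                     priors = defaultPriors(), nRestarts = 3,
                     nSims = 20000, seed = 1, maxit = 150,
                     maxEventsPerLocus = 800) {
  stopifnot(nRestarts >= 1, length(obs) == 6)
  layout <- fitParamLayout(mode, priors)
  nFree <- sum(layout$free)
  lnCLobs <- maxObsLogLik(obs)
  pairs <- t(utils::combn(4, 2))
  pFloor <- 1 / (10 * nSims)

  objective <- function(x, simSeed) {
    vals <- decodeParams(x, layout)
    model <- paramsToModel(vals, topology, mode, sampleSizes, priors)
    sim <- simulateGenealogies(model, nSims, simSeed, sites = FALSE,
                               maxEventsPerLocus = maxEventsPerLocus)
    exp6 <- expectedAllJointSFS(model, sim$configLengths, pairs)
    ll <- compositeLogLik(obs, exp6, pFloor = pFloor)
    if (!is.finite(ll))
      stop("non-finite composite likelihood at parameters: ",
           paste(sprintf("%s=%.4g", names(vals), vals), collapse = ", "))
    -ll
  }

  restartLog <- vector("list", nRestarts)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    set.seed(seed + 7919L * r)
    simSeed <- (seed + 104729L * r) %% .Machine$integer.max
    x0 <- rnorm(nFree, 0, 1.2)
    fit <- if (nFree > 1) {
      optim(x0, objective, simSeed = simSeed, method = "Nelder-Mead",
            control = list(maxit = maxit))
    } else if (nFree == 1) {
      # Brent on the (bounded) logistic coordinate for 1-d problems
      optim(x0, objective, simSeed = simSeed, method = "Brent",
            lower = -15, upper = 15, control = list(maxit = maxit))
    } else {
      list(par = numeric(0), value = objective(numeric(0), simSeed),
           convergence = 0L)
    }
    vals <- decodeParams(fit$par, layout)
    restartLog[[r]] <- data.frame(restart = r, lnCL = -fit$value,
                                  convergence = fit$convergence,
                                  simSeed = simSeed,
                                  t(vals))
    if (is.null(best) || -fit$value > best$lnCL)
      best <- list(lnCL = -fit$value, vals = vals, restart = r)
  }
  restarts <- do.call(rbind, restartLog)
  model <- paramsToModel(best$vals, topology, mode, sampleSizes, priors)
  est <- as.list(best$vals)
  est$T1 <- unname(model@splitTimes["T1"])
  est$uT1 <- NULL
  est$lnCL_log10 <- min(best$lnCL, lnCLobs) / log(10)
  k <- as.integer(nFree)
  lnCLest <- min(best$lnCL, lnCLobs)
  new("FitResult", modelId = paste(topology, mode, sep = "_"),
      topology = topology, mode = mode, estimates = est,
      lnCLest = lnCLest, lnCLobs = lnCLobs, k = k,
      AIC = 2 * k - 2 * lnCLest, restarts = restarts,
      seed = as.integer(seed), nSims = as.integer(nSims))
}

#' Rank fitted models by AIC
#'
#' Ranks a set of \linkS4class{FitResult}s fitted to the same observed
#' spectra. Reports, per model, deltaAIC = AIC - min(AIC) (zero for the best
#' model) and deltaL = lnCLobs - lnCLest (distance to the saturated model).
#'
#' @param fits list of \linkS4class{FitResult} (>= 2) on identical data.
#' @return data.frame ordered by AIC with columns modelId, topology, mode,
#'   k, lnCLest, AIC, deltaAIC, deltaL.
#' @export
modelSelect <- function(fits) {
  stopifnot(length(fits) >= 2)
  obsLL <- vapply(fits, function(f) f@lnCLobs, numeric(1))
  if (diff(range(obsLL)) > 1e-6)
    stop("fits were computed on different observed data (lnCLobs differ)")
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(modelId = f@modelId, topology = f@topology, mode = f@mode,
               k = f@k, lnCLest = f@lnCLest, AIC = f@AIC,
               deltaL = f@lnCLobs - f@lnCLest)))
  df$deltaAIC <- df$AIC - min(df$AIC)
  df <- df[order(df$AIC), ]
  rownames(df) <- NULL
  df
}
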