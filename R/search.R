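## Property-guided parameter search: three-component cost (Boolean +
## continuous + parameter penalties) and the two-phase procedure (global
## search over the searchable rates, then minimization of the number of
## modified parameters).

#' Boolean consistency penalty
#'
#' Minus a constant times the number of predictions consistent with the
#' scoreable observations: minimal exactly when all entries are consistent.
#'
#' @param predictions data.frame with \code{line}, \code{property},
#'   \code{satisfied} (and \code{robustness} for [continuousPenalty()]).
#' @param obs an [observationTable()].
#' @param cB positive constant (default 1).
#' @return a single numeric.
#' @export
booleanPenalty <- function(predictions, obs, cB = 1) {
  -cB * countMatches(predictions, obs)$nMatch
}

#' Continuous robustness penalty
#'
#' Sum over scoreable entries of \eqn{w_p \cdot (-\sigma \rho)}, where
#' \eqn{\sigma = +1} if the entry is observed true and \eqn{-1} if observed
#' false, and \eqn{w_p} is a per-property scale weight balancing the
#' properties' typical robustness ranges. The penalty decreases as
#' predictions become more robustly consistent with the observations.
#'
#' @inheritParams booleanPenalty
#' @param scaleWeights named numeric, one weight per property (default all 1;
#'   [costSpec()] calibrates them as 1/range of the reference robustness).
#' @return a single numeric.
#' @export
continuousPenalty <- function(predictions, obs,
                              scaleWeights = c(P1 = 1, P2 = 1, P3 = 1)) {
  sc <- scoreableEntries(obs)
  idx <- match(paste(sc$line, sc$property),
               paste(predictions$line, predictions$property))
  if (anyNA(idx))
    stop("missing prediction for observed entries", call. = FALSE)
  sigma <- ifelse(sc$observed, 1, -1)
  w <- scaleWeights[sc$property]
  sum(w * (-sigma * predictions$robustness[idx]))
}

#' Parameter deviation penalty
#'
#' Sum of absolute log10 fold changes of the free parameters from their
#' reference values; zero exactly at the reference point.
#'
#' @param params named numeric vector (full parameter set).
#' @param reference named numeric reference values.
#' @param freeParams names of searched parameters (default: all of
#'   \code{reference}).
#' @param foldBound maximum allowed fold change (error outside).
#' @return a single numeric.
#' @export
parameterPenalty <- function(params, reference,
                             freeParams = names(reference),
                             foldBound = Inf) {
  dev <- abs(log10(params[freeParams] / reference[freeParams]))
  dev[params[freeParams] == reference[freeParams]] <- 0  # covers 0/0
  if (any(!is.finite(dev)))
    stop("parameter penalty undefined (zero or negative rate vs nonzero ",
         "reference)", call. = FALSE)
  if (any(dev > log10(foldBound) + 1e-9))
    stop("parameter outside the ", foldBound, "-fold bounds: ",
         paste(freeParams[dev > log10(foldBound) + 1e-9], collapse = ", "),
         call. = FALSE)
  sum(dev)
}

#' Predictor over cell lines for the search cost
#'
#' @param net a [ReactionNetwork-class].
#' @param lines named list of [CellLine-class] objects (nominal cells).
#' @param spec a [propertySpec()].
#' @param trailDose,gridStep simulation settings (a coarser grid speeds the
#'   search loop; the default 1-minute grid matches the reported analyses).
#' @return a function mapping a full named parameter vector to the
#'   predictions data.frame of [classifyLines()].
#' @export
earmPredictor <- function(net, lines, spec = propertySpec(), trailDose = 50,
                          gridStep = 1 / 60) {
  function(params) {
    classifyLines(net, lines, spec, trailDose = trailDose,
                  gridStep = gridStep, paramOverrides = params)
  }
}

#' Search objective specification
#'
#' Bundles the predictor, the observation table, the searchable parameters
#' and their bounds, and the three component weights. Weights are calibrated
#' so that at the start of the search the Boolean, continuous and parameter
#' components contribute approximately \code{targetShares} (default
#' 50/30/20\%) of the cost: the Boolean and continuous magnitudes are taken
#' from the reference evaluation, and the expected parameter penalty of a
#' uniform draw in the log10 box (half the log-bound per parameter) stands
#' for the initial population.
#'
#' @param predict function: full named parameter vector to predictions
#'   data.frame (see [earmPredictor()]).
#' @param obs an [observationTable()].
#' @param reference named numeric reference parameter values (full set).
#' @param freeParams searched parameter names (default: all).
#' @param foldBound box half-width as a fold change (default 100).
#' @param cB Boolean reward constant.
#' @param scaleWeights per-property continuous weights; \code{NULL} means
#'   1/range of the reference robustness per property.
#' @param targetShares length-3 numeric: intended initial shares of the
#'   Boolean, continuous and parameter components.
#' @return a list of class \code{"CostSpec"} with the calibrated weights
#'   \code{wB}, \code{wC}, \code{wP} and the reference predictions.
#' @export
costSpec <- function(predict, obs, reference, freeParams = names(reference),
                     foldBound = 100, cB = 1, scaleWeights = NULL,
                     targetShares = c(0.5, 0.3, 0.2)) {
  stopifnot(length(targetShares) == 3, all(targetShares >= 0))
  refPred <- predict(reference)
  if (is.null(scaleWeights)) {
    sc <- scoreableEntries(obs)
    idx <- match(paste(sc$line, sc$property),
                 paste(refPred$line, refPred$property))
    scaleWeights <- vapply(split(refPred$robustness[idx], sc$property),
                           function(v) {
                             r <- diff(range(v))
                             if (r > 0) 1 / r else 1
                           }, numeric(1))
  }
  ## component magnitudes "at the start": the Boolean range (all entries),
  ## the reference continuous magnitude, and the expected parameter penalty
  ## of a uniform draw in the log10 box
  B0 <- cB * nrow(scoreableEntries(obs))
  C0 <- abs(continuousPenalty(refPred, obs, scaleWeights))
  if (C0 == 0) C0 <- 1
  P0 <- length(freeParams) * log10(foldBound) / 2
  share <- function(target, magnitude) {
    if (magnitude <= 0) 0 else target / magnitude
  }
  structure(list(predict = predict, obs = obs, reference = reference,
                 freeParams = freeParams, foldBound = foldBound, cB = cB,
                 scaleWeights = scaleWeights,
                 wB = share(targetShares[1], B0),
                 wC = share(targetShares[2], C0),
                 wP = share(targetShares[3], P0),
                 refPredictions = refPred),
            class = "CostSpec")
}

#' Evaluate the three-component cost
#'
#' @param params full named parameter vector.
#' @param cs a [costSpec()].
#' @return list of class \code{"CostValue"}: \code{total} (the weighted sum
#'   \code{wB*B + wC*C + wP*P}), the raw components \code{B}, \code{C},
#'   \code{P}, \code{nConsistent}, \code{consistent} (logical: all scoreable
#'   entries match) and the per-entry \code{flags}.
#' @export
evaluateCost <- function(params, cs) {
  pred <- cs$predict(params)
  cm <- countMatches(pred, cs$obs)
  B <- -cs$cB * cm$nMatch
  C <- continuousPenalty(pred, cs$obs, cs$scaleWeights)
  P <- parameterPenalty(params, cs$reference, cs$freeParams, cs$foldBound)
  structure(list(total = cs$wB * B + cs$wC * C + cs$wP * P,
                 B = B, C = C, P = P,
                 nConsistent = cm$nMatch,
                 consistent = cm$nMatch == cm$nScoreable,
                 flags = cm$mismatches, predictions = pred),
            class = "CostValue")
}

## ---- seeded differential evolution (bounded, derivative-free) -------------

## Minimizes fn over the box [lower, upper]^d. DE/rand/1/bin with reflection
## at the bounds; the first individual is 'init' (the reference point).
## Returns the best point, a monotone best-so-far trace (one entry per
## function evaluation) and the evaluation count at the first success
## (fn's attribute "success", if set).
.deSearch <- function(fn, lower, upper, budget, seed, init = NULL,
                      popSize = NULL, F = 0.7, CR = 0.9) {
  d <- length(lower)
  if (is.null(popSize)) popSize <- max(10L, 4L * d)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pop <- matrix(stats::runif(popSize * d, lower, upper), nrow = popSize,
                byrow = TRUE)
  if (!is.null(init)) pop[1L, ] <- init
  vals <- numeric(popSize)
  trace <- numeric(0)
  evals <- 0L
  successAt <- NA_integer_
  best <- Inf; bestPar <- pop[1L, ]
  call1 <- function(z) {
    v <- fn(z)
    evals <<- evals + 1L
    if (is.na(successAt) && isTRUE(attr(v, "success")))
      successAt <<- evals
    v <- as.numeric(v)
    if (v < best) { best <<- v; bestPar <<- z }
    trace[evals] <<- best
    v
  }
  for (i in seq_len(popSize)) {
    if (evals >= budget) break
    vals[i] <- call1(pop[i, ])
  }
  while (evals < budget) {
    for (i in seq_len(popSize)) {
      if (evals >= budget) break
      idx <- sample(setdiff(seq_len(popSize), i), 3L)
      mut <- pop[idx[1L], ] + F * (pop[idx[2L], ] - pop[idx[3L], ])
      ## reflect into the box
      for (j in seq_len(d)) {
        while (mut[j] < lower[j] || mut[j] > upper[j]) {
          if (mut[j] < lower[j]) mut[j] <- 2 * lower[j] - mut[j]
          if (mut[j] > upper[j]) mut[j] <- 2 * upper[j] - mut[j]
        }
      }
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mut, pop[i, ])
      v <- call1(trial)
      if (v <= vals[i]) { pop[i, ] <- trial; vals[i] <- v }
    }
  }
  list(par = bestPar, value = best, trace = trace, evals = evals,
       successAt = successAt)
}

.zToParams <- function(z, cs) {
  p <- cs$reference
  p[cs$freeParams] <- p[cs$freeParams] * 10^z
  p
}

#' Phase 1: global property-guided parameter search
#'
#' Minimizes the three-component cost over the searchable rates in log10
#' space, within \code{foldBound}-fold boxes around the reference, using a
#' seeded bounded differential-evolution search (derivative-free and global;
#' the reference point is included in the initial population). The best-so-far
#' cost trace is monotone by construction.
#'
#' @param cs a [costSpec()].
#' @param budget maximum number of cost evaluations.
#' @param seed integer seed.
#' @param popSize optional population size (default \code{max(10, 4d)}).
#' @return list of class \code{"SearchResult"}: \code{par} (full parameter
#'   vector at the optimum), \code{foldChanges} (log10 fold changes of the
#'   free parameters), \code{cost} (the [evaluateCost()] value at the
#'   optimum), \code{trace}, \code{evals}, \code{consistentAt} (evaluation
#'   index of the first fully-consistent point, NA if never), \code{seed}.
#' @export
phase1Search <- function(cs, budget = 2000, seed = 1L, popSize = NULL) {
  stopifnot(inherits(cs, "CostSpec"))
  d <- length(cs$freeParams)
  L <- log10(cs$foldBound)
  fn <- function(z) {
    cv <- evaluateCost(.zToParams(z, cs), cs)
    structure(cv$total, success = cv$consistent)
  }
  de <- .deSearch(fn, lower = rep(-L, d), upper = rep(L, d), budget = budget,
                  seed = seed, init = rep(0, d), popSize = popSize)
  par <- .zToParams(de$par, cs)
  structure(list(par = par,
                 foldChanges = stats::setNames(de$par, cs$freeParams),
                 cost = evaluateCost(par, cs), trace = de$trace,
                 evals = de$evals, consistentAt = de$successAt, seed = seed),
            class = "SearchResult")
}

#' Phase 2: minimal modified-parameter subset
#'
#' From the phase-1 solution, selects the parameters that changed by more
#' than \code{foldThreshold}-fold and re-runs the search restricted to each
#' candidate subset (all other parameters reset to reference), smallest
#' subsets first (singletons, then pairs). The phase-2 cost drops the
#' continuous component (\code{wC = 0}) and re-weights so the Boolean
#' component carries about 90\% of the initial cost, minimizing parameter
#' deviations subject to full agreement. Returns the smallest subset
#' achieving full consistency, or the best-scoring subset with a
#' \code{consistent = FALSE} flag if none does.
#'
#' @param cs the phase-1 [costSpec()].
#' @param phase1 a \code{"SearchResult"} from [phase1Search()].
#' @param foldThreshold candidate selection threshold (default 5).
#' @param budget cost evaluations per subset.
#' @param seed integer seed.
#' @return list of class \code{"SubsetResult"}: \code{subset} (parameter
#'   names), \code{par} (full parameter vector), \code{foldChanges},
#'   \code{consistent}, \code{cost}, \code{candidates}, \code{tried}.
#' @export
phase2MinimalSubset <- function(cs, phase1, foldThreshold = 5, budget = 400,
                                seed = 1L) {
  stopifnot(inherits(cs, "CostSpec"), inherits(phase1, "SearchResult"))
  cand <- names(which(abs(phase1$foldChanges) > log10(foldThreshold)))
  if (!length(cand))
    stop("no phase-1 parameter changed by more than ", foldThreshold,
         "-fold", call. = FALSE)
  subsets <- c(lapply(cand, identity),
               if (length(cand) >= 2L)
                 utils::combn(cand, 2L, simplify = FALSE))
  tried <- list()
  bestAny <- NULL
  for (ss in subsets) {
    cs2 <- cs
    cs2$freeParams <- ss
    cs2$wC <- 0
    ## Boolean ~ 90% of the initial cost magnitude, parameter penalty ~ 10%
    B0 <- cs$cB * nrow(scoreableEntries(cs$obs))
    P0 <- length(ss) * log10(cs$foldBound) / 2
    cs2$wB <- if (B0 > 0) 0.9 / B0 else 0
    cs2$wP <- if (P0 > 0) 0.1 / P0 else 0
    res <- phase1Search(cs2, budget = budget, seed = seed)
    rec <- list(subset = ss, par = res$par,
                foldChanges = res$foldChanges,
                consistent = res$cost$consistent, cost = res$cost)
    tried[[length(tried) + 1L]] <- rec
    if (is.null(bestAny) || res$cost$total < bestAny$cost$total)
      bestAny <- rec
    if (rec$consistent) {
      return(structure(c(rec, list(candidates = cand, tried = tried)),
                       class = "SubsetResult"))
    }
  }
  structure(c(bestAny, list(candidates = cand, tried = tried)),
            class = "SubsetResult")
}
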