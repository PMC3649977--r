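#' @import methods
NULL

#' Time-stamped multi-channel signal
#'
#' A \code{TimedTrace} holds named, time-stamped real-valued signals sampled on
#' a common grid: the output of an ODE simulation together with derived
#' observables, or a robustness signal produced by the STL monitor. Times are
#' in hours, start at 0 and are strictly increasing; the trace horizon is the
#' final sample instant.
#'
#' @slot times numeric vector of sample instants (hours), strictly increasing,
#'   first element 0.
#' @slot channels numeric matrix with one row per sample instant and one named
#'   column per channel.
#' @slot meta list of free-form metadata (e.g. solver settings for simulation
#'   output).
#'
#' @seealso [timedTrace()], [robustnessSignal()], [simulateNetwork()]
#' @export
setClass("TimedTrace",
  slots = c(times = "numeric", channels = "matrix", meta = "list"),
  prototype = list(meta = list()))

setValidity("TimedTrace", function(object) {
  msg <- character()
  n <- length(object@times)
  if (n < 1L) msg <- c(msg, "trace must contain at least one sample instant")
  if (anyNA(object@times)) msg <- c(msg, "times must not contain NA")
  if (n >= 1L && abs(object@times[1L]) > 1e-12)
    msg <- c(msg, "times must start at 0")
  if (n > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (nrow(object@channels) != n)
    msg <- c(msg, "channels must have one row per sample instant")
  if (is.null(colnames(object@channels)) ||
      anyDuplicated(colnames(object@channels)))
    msg <- c(msg, "channels must have unique column names")
  if (length(msg)) msg else TRUE
})

#' Construct a TimedTrace
#'
#' @param times numeric vector of sample instants (hours), starting at 0.
#' @param channels numeric matrix (rows = instants, named columns = channels),
#'   or a named list/data.frame of equal-length numeric vectors.
#' @return a [TimedTrace-class] object.
#' @examples
#' tr <- timedTrace(seq(0, 6, by = 0.5), cbind(x = seq(0, 6, by = 0.5)))
#' traceHorizon(tr)
#' @export
timedTrace <- function(times, channels, meta = list()) {
  if (is.data.frame(channels) || is.list(channels))
    channels <- do.call(cbind, lapply(channels, as.numeric))
  storage.mode(channels) <- "double"
  new("TimedTrace", times = as.numeric(times), channels = channels,
      meta = meta)
}

#' Signal temporal logic formula
#'
#' Abstract syntax tree of an STL formula. Leaf nodes (\code{kind == "pred"})
#' carry a channel name, a comparator (\code{<} or \code{>}) and a numeric
#' threshold. Boolean nodes (\code{not}, \code{and}, \code{or}, \code{implies})
#' and temporal nodes (\code{ev}, \code{alw}, \code{until}, \code{release})
#' carry subformulas; temporal nodes additionally carry a time interval
#' \code{[a, b]} in hours (\code{b} may be \code{Inf}; an untimed operator
#' means \code{[0, Inf)} capped at the trace horizon).
#'
#' @slot kind one of \code{"pred"}, \code{"not"}, \code{"and"}, \code{"or"},
#'   \code{"implies"}, \code{"ev"}, \code{"alw"}, \code{"until"},
#'   \code{"release"}.
#' @slot channel channel name (predicates only).
#' @slot op comparator, \code{"<"} or \code{">"} (predicates only).
#' @slot threshold numeric threshold (predicates only).
#' @slot interval numeric of length 2, \code{c(a, b)} in hours (temporal nodes).
#' @slot subs list of subformulas.
#'
#' @seealso [parseFormula()], [robustnessAt()]
#' @export
setClass("STLFormula",
  slots = c(kind = "character", channel = "character", op = "character",
            threshold = "numeric", interval = "numeric", subs = "list"),
  prototype = list(channel = NA_character_, op = NA_character_,
                   threshold = NA_real_, interval = c(0, Inf), subs = list()))

setValidity("STLFormula", function(object) {
  kinds <- c("pred", "not", "and", "or", "implies", "ev", "alw",
             "until", "release")
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% kinds)
    return(sprintf("kind must be one of: %s", paste(kinds, collapse = ", ")))
  nsub <- c(pred = 0L, not = 1L, and = 2L, or = 2L, implies = 2L,
            ev = 1L, alw = 1L, until = 2L, release = 2L)[[object@kind]]
  if (length(object@subs) != nsub)
    msg <- c(msg, sprintf("'%s' node needs %d subformula(s)", object@kind, nsub))
  if (!all(vapply(object@subs, is, logical(1), class2 = "STLFormula")))
    msg <- c(msg, "subformulas must be STLFormula objects")
  if (object@kind == "pred") {
    if (is.na(object@channel) || !nzchar(object@channel))
      msg <- c(msg, "predicate needs a channel name")
    if (!object@op %in% c("<", ">"))
      msg <- c(msg, "predicate comparator must be '<' or '>'")
    if (!is.finite(object@threshold))
      msg <- c(msg, "predicate threshold must be finite")
  }
  if (object@kind %in% c("ev", "alw", "until", "release")) {
    iv <- object@interval
    if (length(iv) != 2L || anyNA(iv) || iv[1L] < 0 || iv[1L] > iv[2L])
      msg <- c(msg, "interval must satisfy 0 <= a <= b")
  }
  if (length(msg)) msg else TRUE
})

#' Mass-action reaction network
#'
#' Species, reaction groups and rate parameters of a mass-action ODE model.
#' Reaction groups come in three laws: \code{"forward"} (irreversible
#' mass-action step, rate parameter \code{kf}), \code{"reversible"}
#' (association/dissociation pair, parameters \code{kf}/\code{kr}) and
#' \code{"catalytic"} (reversible complex formation followed by an
#' irreversible conversion of the named intermediate, parameters
#' \code{kf}/\code{kr}/\code{kc}). Rate constants are in the model's native
#' time unit (seconds for the bundled apoptosis model), per appropriate
#' reaction order; amounts are molecules per cell.
#'
#' @slot species data.frame with columns \code{name}, \code{role} (one of
#'   \code{"native"}, \code{"complex"}, \code{"ligand"}) and \code{init}
#'   (default initial amount, molecules/cell).
#' @slot reactions list of reaction groups; each a list with fields
#'   \code{reactants}, \code{products} (named positive integer vectors),
#'   \code{law}, \code{params} (named character: kf and optionally kr, kc) and
#'   for catalytic groups \code{intermediate} (complex species name).
#' @slot params named numeric vector of rate-constant values.
#' @slot meta list of free-form metadata (provenance, dose map, time unit).
#'
#' @seealso [reactionNetwork()], [buildEarm()], [loadNetwork()]
#' @export
setClass("ReactionNetwork",
  slots = c(species = "data.frame", reactions = "list", params = "numeric",
            meta = "list"))

setValidity("ReactionNetwork", function(object) {
  msg <- character()
  sp <- object@species
  need <- c("name", "role", "init")
  if (!all(need %in% names(sp)))
    return("species must have columns name, role, init")
  if (anyDuplicated(sp$name)) msg <- c(msg, "species names must be unique")
  if (any(!sp$role %in% c("native", "complex", "ligand")))
    msg <- c(msg, "species role must be native, complex or ligand")
  if (any(sp$init < 0, na.rm = TRUE))
    msg <- c(msg, "initial amounts must be nonnegative")
  if (is.null(names(object@params)) && length(object@params))
    msg <- c(msg, "params must be named")
  if (any(object@params < 0))
    msg <- c(msg, "rate constants must be nonnegative")
  for (i in seq_along(object@reactions)) {
    r <- object@reactions[[i]]
    if (!r$law %in% c("forward", "reversible", "catalytic")) {
      msg <- c(msg, sprintf("reaction %d: unknown law '%s'", i, r$law))
      next
    }
    refs <- c(names(r$reactants), names(r$products),
              if (identical(r$law, "catalytic")) r$intermediate)
    bad <- setdiff(refs, sp$name)
    if (length(bad))
      msg <- c(msg, sprintf("reaction %d references undeclared species: %s",
                            i, paste(bad, collapse = ", ")))
    if (any(c(r$reactants, r$products) %% 1 != 0) ||
        any(c(r$reactants, r$products) <= 0))
      msg <- c(msg, sprintf("reaction %d: stoichiometries must be positive integers", i))
    want <- switch(r$law, forward = "kf", reversible = c("kf", "kr"),
                   catalytic = c("kf", "kr", "kc"))
    if (!all(want %in% names(r$params)))
      msg <- c(msg, sprintf("reaction %d: law '%s' needs params %s",
                            i, r$law, paste(want, collapse = ", ")))
    miss <- setdiff(unlist(r$params), names(object@params))
    if (length(miss))
      msg <- c(msg, sprintf("reaction %d references undeclared parameters: %s",
                            i, paste(miss, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Cell line definition
#'
#' Nominal initial protein amounts (molecules/cell, overriding network
#' defaults), per-species coefficients of variation for population sampling,
#' and optional rate-parameter overrides (used by the feedback-deletion
#' variant, which zeroes the caspase-6 -> caspase-8 cleavage rate).
#'
#' @slot name cell line label, e.g. \code{"HB"} for OE-Bcl2 HCT116.
#' @slot init named numeric vector of nominal initial amounts.
#' @slot cv named numeric vector of coefficients of variation.
#' @slot defaultCV coefficient of variation for species without a stated CV.
#' @slot params named numeric vector of rate-parameter overrides (may be empty).
#'
#' @seealso [cellLine()], [earmCellLines()], [applyVariant()]
#' @export
setClass("CellLine",
  slots = c(name = "character", init = "numeric", cv = "numeric",
            defaultCV = "numeric", params = "numeric"),
  prototype = list(defaultCV = 0.25, params = numeric()))

setValidity("CellLine", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "cell line needs a name")
  if (length(object@init) && is.null(names(object@init)))
    msg <- c(msg, "init must be named")
  if (any(object@init < 0)) msg <- c(msg, "initial amounts must be nonnegative")
  if (any(object@cv <= 0)) msg <- c(msg, "coefficients of variation must be > 0")
  if (length(object@defaultCV) != 1L || object@defaultCV <= 0)
    msg <- c(msg, "defaultCV must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Property or DLE phase diagram
#'
#' Values of an STL property (robustness at time 0) or of the direct
#' finite-time Lyapunov exponent on a 2D grid of initial concentrations, with
#' optional cell-line overlay crosses (center = mean initial concentration,
#' half-extent = standard deviation).
#'
#' @slot x,y grid coordinates (molecules/cell), linearly spaced inclusive of
#'   both endpoints.
#' @slot xName,yName the two slice species.
#' @slot values numeric matrix, \code{values[i, j]} for \code{(x[i], y[j])};
#'   failed grid points are \code{NA}.
#' @slot kind \code{"stl"} or \code{"dle"}.
#' @slot overlays data.frame with columns \code{line}, \code{x}, \code{y},
#'   \code{dx}, \code{dy}.
#' @slot meta list (formula text or DLE horizon, reference line, solver
#'   settings).
#'
#' @seealso [stlDiagram()], [dleDiagram()], [overlayPositions()]
#' @export
setClass("PropertyDiagram",
  slots = c(x = "numeric", y = "numeric", xName = "character",
            yName = "character", values = "matrix", kind = "character",
            overlays = "data.frame", meta = "list"))

setValidity("PropertyDiagram", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@x) ||
      ncol(object@values) != length(object@y))
    msg <- c(msg, "values must be length(x) by length(y)")
  if (!object@kind %in% c("stl", "dle"))
    msg <- c(msg, "kind must be 'stl' or 'dle'")
  if (nrow(object@overlays) &&
      !all(c("line", "x", "y", "dx", "dy") %in% names(object@overlays)))
    msg <- c(msg, "overlays must have columns line, x, y, dx, dy")
  if (any(c(object@overlays$dx, object@overlays$dy) < 0))
    msg <- c(msg, "overlay half-extents must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Sampled heterogeneous cell population
#'
#' Initial-concentration draws for a population of cells of one line. Each
#' protein is drawn from a lognormal distribution whose arithmetic mean equals
#' the line's nominal amount and whose coefficient of variation equals the
#' line's CV (species with nominal 0 stay exactly 0).
#'
#' @slot line the [CellLine-class] sampled from.
#' @slot draws numeric matrix, cells in rows, species in columns.
#' @slot seed integer seed the draws were generated with.
#'
#' @seealso [samplePopulation()], [evaluatePopulation()]
#' @export
setClass("PopulationSample",
  slots = c(line = "CellLine", draws = "matrix", seed = "integer"))

setValidity("PopulationSample", function(object) {
  msg <- character()
  if (nrow(object@draws) < 1L) msg <- c(msg, "population must contain >= 1 cell")
  if (is.null(colnames(object@draws)))
    msg <- c(msg, "draws must have species column names")
  if (any(object@draws < 0)) msg <- c(msg, "sampled amounts must be nonnegative")
  if (length(msg)) msg else TRUE
})
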