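#' @rdname TimedTrace-class
#' @param object,x a \code{TimedTrace}
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname TimedTrace-class
#' @export
setGeneric("traceChannels", function(x) standardGeneric("traceChannels"))
#' @rdname TimedTrace-class
#' @export
setGeneric("traceHorizon", function(x) standardGeneric("traceHorizon"))
#' @rdname TimedTrace-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname TimedTrace-class
#' @export
setMethod("traceTimes", "TimedTrace", function(x) x@times)
#' @rdname TimedTrace-class
#' @export
setMethod("traceChannels", "TimedTrace", function(x) x@channels)
#' @rdname TimedTrace-class
#' @export
setMethod("traceHorizon", "TimedTrace", function(x) x@times[length(x@times)])
#' @rdname TimedTrace-class
#' @export
setMethod("channelNames", "TimedTrace", function(x) colnames(x@channels))

#' Extract one channel of a trace
#'
#' @param x a [TimedTrace-class]
#' @param name channel name
#' @return numeric vector of the channel's values, one per sample instant.
#' @export
channelValues <- function(x, name) {
  stopifnot(is(x, "TimedTrace"))
  if (!name %in% colnames(x@channels))
    stop(sprintf("unknown channel '%s' (available: %s)", name,
                 paste(colnames(x@channels), collapse = ", ")), call. = FALSE)
  x@channels[, name]
}

setMethod("show", "TimedTrace", function(object) {
  cat(sprintf("TimedTrace: %d instants over [0, %g] h, %d channel(s)\n",
              length(object@times), traceHorizon(object),
              ncol(object@channels)))
  nm <- colnames(object@channels)
  cat("  channels:", paste(utils::head(nm, 8L), collapse = ", "),
      if (length(nm) > 8L) sprintf("... (+%d)", length(nm) - 8L) else "", "\n")
})

setMethod("show", "STLFormula", function(object) {
  cat("STLFormula:", formatFormula(object), "\n")
})

#' @rdname ReactionNetwork-class
#' @param x a \code{ReactionNetwork}
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))
#' @rdname ReactionNetwork-class
#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@species$name)

#' @rdname ReactionNetwork-class
#' @export
setGeneric("parameters", function(x) standardGeneric("parameters"))
#' @rdname ReactionNetwork-class
#' @export
setMethod("parameters", "ReactionNetwork", function(x) x@params)
#' @rdname ReactionNetwork-class
#' @export
setMethod("parameters", "CellLine", function(x) x@params)

#' @rdname ReactionNetwork-class
#' @param value named numeric vector of parameter values to set (a subset of
#'   the declared parameters)
#' @export
setGeneric("parameters<-", function(x, value) standardGeneric("parameters<-"))
#' @rdname ReactionNetwork-class
#' @export
setMethod("parameters<-", "ReactionNetwork", function(x, value) {
  stopifnot(!is.null(names(value)))
  bad <- setdiff(names(value), names(x@params))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  x@params[names(value)] <- value
  validObject(x)
  x
})

#' @rdname ReactionNetwork-class
#' @export
setGeneric("defaultInit", function(x) standardGeneric("defaultInit"))
#' @rdname ReactionNetwork-class
#' @export
setMethod("defaultInit", "ReactionNetwork", function(x) {
  stats::setNames(x@species$init, x@species$name)
})

setMethod("show", "ReactionNetwork", function(object) {
  census <- table(factor(vapply(object@reactions, `[[`, "", "law"),
                         levels = c("forward", "reversible", "catalytic")))
  cat(sprintf("ReactionNetwork: %d species, %d reaction groups (%s), %d parameters\n",
              nrow(object@species), length(object@reactions),
              paste(sprintf("%d %s", census, names(census)), collapse = ", "),
              length(object@params)))
  if (!is.null(object@meta$source)) cat("  source:", object@meta$source, "\n")
})

#' @rdname CellLine-class
#' @param x a \code{CellLine}
#' @export
setGeneric("lineName", function(x) standardGeneric("lineName"))
#' @rdname CellLine-class
#' @export
setMethod("lineName", "CellLine", function(x) x@name)

#' @rdname CellLine-class
#' @export
setGeneric("nominalConcentrations", function(x) standardGeneric("nominalConcentrations"))
#' @rdname CellLine-class
#' @export
setMethod("nominalConcentrations", "CellLine", function(x) x@init)

#' @rdname CellLine-class
#' @export
setGeneric("variationCoefficients", function(x) standardGeneric("variationCoefficients"))
#' @rdname CellLine-class
#' @export
setMethod("variationCoefficients", "CellLine", function(x) x@cv)

setMethod("show", "CellLine", function(object) {
  cat(sprintf("CellLine '%s': %d nominal amounts, %d stated CVs (default CV %.2f)%s\n",
              object@name, length(object@init), length(object@cv),
              object@defaultCV,
              if (length(object@params))
                paste0(", param overrides: ",
                       paste(sprintf("%s=%g", names(object@params),
                                     object@params), collapse = ", "))
              else ""))
})

setMethod("show", "PropertyDiagram", function(object) {
  cat(sprintf("PropertyDiagram (%s): %d x %d grid over %s x %s, %d overlay(s)\n",
              object@kind, length(object@x), length(object@y),
              object@xName, object@yName, nrow(object@overlays)))
  v <- object@values[is.finite(object@values)]
  if (length(v))
    cat(sprintf("  values in [%.3g, %.3g], %d failed point(s)\n",
                min(v), max(v), sum(!is.finite(object@values))))
})

setMethod("show", "PopulationSample", function(object) {
  cat(sprintf("PopulationSample: %d cells of line '%s' (seed %d), %d species\n",
              nrow(object@draws), object@line@name, object@seed,
              ncol(object@draws)))
})

#' @rdname PropertyDiagram-class
#' @param x a \code{PropertyDiagram}
#' @export
setGeneric("diagramValues", function(x) standardGeneric("diagramValues"))
#' @rdname PropertyDiagram-class
#' @export
setMethod("diagramValues", "PropertyDiagram", function(x) x@values)

#' @rdname PropertyDiagram-class
#' @export
setGeneric("diagramOverlays", function(x) standardGeneric("diagramOverlays"))
#' @rdname PropertyDiagram-class
#' @export
setMethod("diagramOverlays", "PropertyDiagram", function(x) x@overlays)

#' @rdname PopulationSample-class
#' @param x a \code{PopulationSample}
#' @export
setGeneric("populationDraws", function(x) standardGeneric("populationDraws"))
#' @rdname PopulationSample-class
#' @export
setMethod("populationDraws", "PopulationSample", function(x) x@draws)
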