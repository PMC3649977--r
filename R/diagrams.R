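## STL and DLE phase diagrams over 2D slices of initial-concentration space.

.sliceRangeTable <- list(XIAP = c(0, 6e4), pC3 = c(0, 1e6),
                         pC8 = c(1200, 4500), flip = c(0, 800))

#' Specify a 2D initial-concentration slice
#'
#' @param xName,yName the two slice species (initial amounts varied on the
#'   grid). The bundled default ranges are XIAP \code{[0, 6e4]}, caspase-3
#'   (\code{pC3}) \code{[0, 1e6]}, caspase-8 (\code{pC8}) \code{[1200, 4500]}
#'   and FLIP (\code{flip}) \code{[0, 800]} molecules/cell.
#' @param xRange,yRange numeric \code{c(lo, hi)}; defaults per species above.
#' @param n grid size (n-by-n, linearly spaced inclusive of both endpoints;
#'   default 50).
#' @param refLine reference [CellLine-class]: all non-slice species take its
#'   nominal values.
#' @param variant optional variant context applied to the reference line
#'   (e.g. \code{"oeBcl2"} for survival diagrams), see [applyVariant()].
#' @return a list of class \code{"SliceSpec"}.
#' @export
sliceSpec <- function(xName, yName, refLine, xRange = NULL, yRange = NULL,
                      n = 50, variant = NULL) {
  pick <- function(nm, r) {
    if (is.null(r)) r <- .sliceRangeTable[[nm]]
    if (is.null(r))
      stop("no default range for species '", nm, "'; give a range",
           call. = FALSE)
    stopifnot(length(r) == 2L, is.finite(r), r[1] < r[2])
    r
  }
  stopifnot(n >= 2, is(refLine, "CellLine"))
  structure(list(xName = xName, yName = yName,
                 xRange = pick(xName, xRange), yRange = pick(yName, yRange),
                 n = as.integer(n), refLine = refLine, variant = variant),
            class = "SliceSpec")
}

.sliceReference <- function(slice, net) {
  ln <- slice$refLine
  if (!is.null(slice$variant)) ln <- applyVariant(ln, slice$variant, net)
  ln
}

## loop an evaluator over the slice grid; >1% failed points aborts
.gridEvaluate <- function(slice, pointFun) {
  xs <- seq(slice$xRange[1], slice$xRange[2], length.out = slice$n)
  ys <- seq(slice$yRange[1], slice$yRange[2], length.out = slice$n)
  vals <- matrix(NA_real_, slice$n, slice$n)
  failures <- character()
  for (j in seq_along(ys)) for (i in seq_along(xs)) {
    v <- tryCatch(pointFun(xs[i], ys[j]), error = function(e) {
      failures <<- c(failures, sprintf("(%g, %g): %s", xs[i], ys[j],
                                       conditionMessage(e)))
      NA_real_
    })
    vals[i, j] <- v
  }
  if (length(failures) > 0.01 * slice$n^2)
    stop(sprintf("%d of %d grid points failed; first failure: %s",
                 length(failures), slice$n^2, failures[1]), call. = FALSE)
  list(x = xs, y = ys, values = vals, failures = failures)
}

#' Overlay positions of cell lines on a slice
#'
#' Center = mean (nominal) initial amount of the two slice species,
#' half-extent = standard deviation (mean times coefficient of variation).
#'
#' @param lines named list of [CellLine-class] objects.
#' @param xName,yName slice species.
#' @param net network supplying default amounts for species a line does not
#'   override.
#' @return data.frame with columns \code{line}, \code{x}, \code{y},
#'   \code{dx}, \code{dy}.
#' @examples
#' net <- buildEarm()
#' overlayPositions(earmCellLines(net)["H"], "XIAP", "pC3", net)
#' @export
overlayPositions <- function(lines, xName, yName, net) {
  defaults <- defaultInit(net)
  if (!all(c(xName, yName) %in% names(defaults)))
    stop("slice species missing from the network", call. = FALSE)
  rows <- lapply(lines, function(ln) {
    get1 <- function(nm) {
      m <- if (nm %in% names(ln@init)) ln@init[[nm]] else defaults[[nm]]
      cv <- if (nm %in% names(ln@cv)) ln@cv[[nm]] else ln@defaultCV
      c(mean = m, sd = m * cv)
    }
    gx <- get1(xName); gy <- get1(yName)
    data.frame(line = lineName(ln), x = gx[["mean"]], y = gy[["mean"]],
               dx = gx[["sd"]], dy = gy[["sd"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' STL property phase diagram
#'
#' For each grid point of the slice, the initial state equals the reference
#' line's nominal amounts with the two slice species overridden, the model is
#' simulated and the formula's robustness at time 0 is recorded. Failed grid
#' points are masked as \code{NA} (more than 1\% failures aborts).
#'
#' @param net a [ReactionNetwork-class].
#' @param slice a [sliceSpec()].
#' @param f an [STLFormula-class].
#' @param lines optional named list of [CellLine-class] for overlay crosses.
#' @param trailDose ligand dose (ng/ml).
#' @param horizon,gridStep simulation grid (hours).
#' @param ... passed to [simulateNetwork()].
#' @return a [PropertyDiagram-class] with \code{kind = "stl"}.
#' @export
stlDiagram <- function(net, slice, f, lines = list(), trailDose = 50,
                       horizon = 6, gridStep = 1 / 60, ...) {
  ref <- .sliceReference(slice, net)
  pointFun <- function(xv, yv) {
    init <- stats::setNames(c(xv, yv), c(slice$xName, slice$yName))
    tr <- simulateNetwork(net, ref, trailDose = trailDose, horizon = horizon,
                          gridStep = gridStep, init = init, ...)
    robustnessAt(f, tr, 0)
  }
  g <- .gridEvaluate(slice, pointFun)
  new("PropertyDiagram", x = g$x, y = g$y, xName = slice$xName,
      yName = slice$yName, values = g$values, kind = "stl",
      overlays = if (length(lines))
        overlayPositions(lines, slice$xName, slice$yName, net)
      else data.frame(),
      meta = list(formula = formatFormula(f), refLine = lineName(ref),
                  trailDose = trailDose, horizon = horizon,
                  gridStep = gridStep, failures = g$failures))
}

## ---- direct finite-time Lyapunov exponent ---------------------------------

## flow-map Jacobian d x(T) / d x(0) by central finite differences
## (one-sided at the nonnegativity boundary)
.flowJacobianFD <- function(cmp, x0, k, tEnd, rtol, atol,
                            relStep = 1e-4, absFloor = 1) {
  ns <- length(x0)
  base <- .finalState(cmp, x0, k, tEnd, rtol, atol)
  J <- matrix(0.0, ns, ns)
  for (i in seq_len(ns)) {
    h <- max(relStep * abs(x0[i]), absFloor)
    if (x0[i] - h >= 0) {
      xp <- x0; xp[i] <- x0[i] + h
      xm <- x0; xm[i] <- x0[i] - h
      J[, i] <- (.finalState(cmp, xp, k, tEnd, rtol, atol) -
                 .finalState(cmp, xm, k, tEnd, rtol, atol)) / (2 * h)
    } else {
      xp <- x0; xp[i] <- x0[i] + h
      J[, i] <- (.finalState(cmp, xp, k, tEnd, rtol, atol) - base) / h
    }
  }
  J
}

## flow-map Jacobian by forward-sensitivity (variational) integration,
## one column e_j at a time: s' = (df/dx)(x(t)) s
.flowJacobianSens <- function(cmp, x0, k, tEnd, rtol, atol) {
  ns <- length(x0)
  J <- matrix(0.0, ns, ns)
  func <- function(t, y, p) {
    x <- y[seq_len(ns)]
    s <- y[ns + seq_len(ns)]
    A <- .rhsJacobian(cmp, x, k)
    list(c(.rhs(cmp, x, k), as.vector(A %*% s)))
  }
  for (j in seq_len(ns)) {
    s0 <- numeric(ns); s0[j] <- 1
    out <- deSolve::lsoda(y = c(x0, s0), times = c(0, tEnd), func = func,
                          parms = NULL, rtol = rtol, atol = atol,
                          maxsteps = 50000)
    istate <- attr(out, "istate")[1L]
    if (!is.null(istate) && istate < 0)
      stop("sensitivity integration failed (istate ", istate, ")",
           call. = FALSE)
    J[, j] <- out[2L, 1L + ns + seq_len(ns)]
  }
  J
}

#' Direct finite-time Lyapunov exponent
#'
#' Computes \eqn{\mathrm{DLE} = \frac{1}{2t}\log\lambda_{max}(J^T J)} where
#' \eqn{J = \partial x(t)/\partial x(0)} is the Jacobian of the flow map with
#' respect to the initial concentrations: the exponential growth rate (per
#' hour) of the most-amplified initial perturbation. Negative values indicate
#' contraction; high values mark separatrices between diverging outcomes.
#'
#' @param net a [ReactionNetwork-class].
#' @param line optional [CellLine-class].
#' @param t future time instant in hours (6 or 4 for the apoptosis diagrams).
#' @param init optional named initial-amount overrides.
#' @param trailDose optional ligand dose (ng/ml).
#' @param method \code{"fd"} (default): central finite differences with
#'   relative step \code{relStep} and absolute floor \code{absFloor}
#'   molecules (one-sided at the nonnegativity boundary); \code{"sens"}:
#'   forward-sensitivity (variational) integration, used as the independent
#'   cross-check.
#' @param relStep,absFloor finite-difference step controls.
#' @param paramOverrides optional named parameter overrides.
#' @param rtol,atol solver tolerances.
#' @return a single numeric (per hour).
#' @examples
#' # scalar linear system x' = 0.5 x (X -> 2X): DLE = 0.5 for any t
#' lin <- reactionNetwork(
#'   data.frame(name = "X", role = "native", init = 1),
#'   list(rxn("forward", c(X = 1L), c(X = 2L), c(kf = "a"))),
#'   c(a = 0.5))
#' dle(lin, t = 2)
#' @export
dle <- function(net, line = NULL, t = 6, init = NULL, trailDose = NULL,
                method = c("fd", "sens"), relStep = 1e-4, absFloor = 1,
                paramOverrides = NULL, rtol = 1e-8, atol = 1e-4) {
  stopifnot(t > 0)
  method <- match.arg(method)
  su <- .simSetup(net, line, trailDose, init, paramOverrides)
  cmp <- compileNetwork(net)
  J <- switch(method,
    fd = .flowJacobianFD(cmp, su$x0, su$k, t, rtol, atol, relStep, absFloor),
    sens = .flowJacobianSens(cmp, su$x0, su$k, t, rtol, atol))
  smax <- max(svd(J, nu = 0, nv = 0)$d)   # lambda_max(J^T J) = smax^2
  val <- log(smax^2) / (2 * t)
  if (!is.finite(val))
    stop("DLE is not finite (degenerate flow Jacobian)", call. = FALSE)
  val
}

#' DLE phase diagram
#'
#' As [stlDiagram()], with the point evaluator replaced by the direct
#' finite-time Lyapunov exponent at horizon \code{t}.
#'
#' @inheritParams stlDiagram
#' @param t DLE horizon (hours).
#' @param ... passed to [dle()].
#' @return a [PropertyDiagram-class] with \code{kind = "dle"}.
#' @export
dleDiagram <- function(net, slice, t = 6, lines = list(), trailDose = 50,
                       ...) {
  ref <- .sliceReference(slice, net)
  pointFun <- function(xv, yv) {
    init <- stats::setNames(c(xv, yv), c(slice$xName, slice$yName))
    dle(net, ref, t = t, init = init, trailDose = trailDose, ...)
  }
  g <- .gridEvaluate(slice, pointFun)
  new("PropertyDiagram", x = g$x, y = g$y, xName = slice$xName,
      yName = slice$yName, values = g$values, kind = "dle",
      overlays = if (length(lines))
        overlayPositions(lines, slice$xName, slice$yName, net)
      else data.frame(),
      meta = list(dleHorizon = t, refLine = lineName(ref),
                  trailDose = trailDose, failures = g$failures))
}

#' Write a diagram as CSV plus JSON metadata
#'
#' @param diagram a [PropertyDiagram-class].
#' @param csvPath output CSV (long format: x, y, value).
#' @param jsonPath optional metadata JSON (defaults to csvPath with .json).
#' @return \code{csvPath}, invisibly.
#' @export
writeDiagram <- function(diagram, csvPath,
                         jsonPath = sub("\\.csv$", ".json", csvPath)) {
  long <- expand.grid(x = diagram@x, y = diagram@y, KEEP.OUT.ATTRS = FALSE)
  long$value <- as.vector(diagram@values)
  names(long)[1:2] <- c(diagram@xName, diagram@yName)
  utils::write.csv(long, csvPath, row.names = FALSE)
  meta <- c(diagram@meta, list(kind = diagram@kind,
                               overlays = diagram@overlays))
  jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}
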