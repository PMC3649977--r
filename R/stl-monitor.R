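## Quantitative (robustness) and Boolean STL semantics on sampled traces.
##
## Semantics are taken over sample instants only (no interpolation inside
## temporal operators): sup/inf become max/min over the sample instants that
## fall inside the evaluation window. Windows extending past the trace horizon
## T_f are truncated to [t+a, T_f]; a window starting after T_f is empty.

.stlEps <- function(times) 1e-9 * max(1, abs(times[length(times)]))

## indices of sample instants in [t_i + a, min(t_i + b, Tf)], or integer(0)
.windowIdx <- function(times, i, iv, eps) {
  lo <- times[i] + iv[1]
  Tf <- times[length(times)]
  if (lo > Tf + eps) return(integer(0))
  hi <- min(times[i] + iv[2], Tf)
  which(times >= lo - eps & times <= hi + eps)
}

.tempFold <- function(rho, times, iv, fn) {
  n <- length(times)
  eps <- .stlEps(times)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    js <- .windowIdx(times, i, iv, eps)
    if (length(js)) out[i] <- fn(rho[js])
  }
  out
}

.untilRho <- function(phi, psi, times, iv) {
  n <- length(times)
  eps <- .stlEps(times)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    js <- .windowIdx(times, i, iv, eps)
    if (!length(js)) next
    m <- cummin(phi[i:max(js)])          # inf of phi over [t_i, t_j]
    out[i] <- max(pmin(psi[js], m[js - i + 1L]))
  }
  out
}

## robustness of every subformula kind, vectorized over all sample instants
.stlRho <- function(f, times, ch) {
  sub <- function(k) .stlRho(f@subs[[k]], times, ch)
  switch(f@kind,
    pred = {
      x <- ch[, f@channel]
      if (f@op == ">") x - f@threshold else f@threshold - x
    },
    not     = -sub(1L),
    and     = pmin(sub(1L), sub(2L)),
    or      = pmax(sub(1L), sub(2L)),
    implies = pmax(-sub(1L), sub(2L)),
    ev      = .tempFold(sub(1L), times, f@interval, max),
    alw     = .tempFold(sub(1L), times, f@interval, min),
    until   = .untilRho(sub(1L), sub(2L), times, f@interval),
    release = -.untilRho(-sub(1L), -sub(2L), times, f@interval))
}

## independent Boolean semantics (no reference to robustness values); used as
## the soundness cross-check
.stlBool <- function(f, times, ch) {
  sub <- function(k) .stlBool(f@subs[[k]], times, ch)
  switch(f@kind,
    pred = {
      x <- ch[, f@channel]
      if (f@op == ">") x > f@threshold else x < f@threshold
    },
    not     = !sub(1L),
    and     = sub(1L) & sub(2L),
    or      = sub(1L) | sub(2L),
    implies = !sub(1L) | sub(2L),
    ev = {
      b <- sub(1L)
      n <- length(times); eps <- .stlEps(times)
      out <- rep(NA, n)
      for (i in seq_len(n)) {
        js <- .windowIdx(times, i, f@interval, eps)
        if (length(js)) out[i] <- any(b[js])
      }
      out
    },
    alw = {
      b <- sub(1L)
      n <- length(times); eps <- .stlEps(times)
      out <- rep(NA, n)
      for (i in seq_len(n)) {
        js <- .windowIdx(times, i, f@interval, eps)
        if (length(js)) out[i] <- all(b[js])
      }
      out
    },
    until = {
      b1 <- sub(1L); b2 <- sub(2L)
      n <- length(times); eps <- .stlEps(times)
      out <- rep(NA, n)
      for (i in seq_len(n)) {
        js <- .windowIdx(times, i, f@interval, eps)
        if (!length(js)) next
        out[i] <- any(vapply(js, function(j) b2[j] & all(b1[i:j]), NA))
      }
      out
    },
    release = {
      ## phi R psi == not (not phi U not psi)
      g <- stlNode("until", list(stlNot(f@subs[[1L]]), stlNot(f@subs[[2L]])),
                   f@interval)
      !.stlBool(g, times, ch)
    })
}

.checkFormulaTrace <- function(f, tr) {
  miss <- setdiff(formulaChannels(f), channelNames(tr))
  if (length(miss))
    stop("formula references channel(s) absent from the trace: ",
         paste(miss, collapse = ", "), call. = FALSE)
}

.instantIndex <- function(tr, t) {
  times <- traceTimes(tr)
  i <- which(abs(times - t) <= .stlEps(times))
  if (length(i) != 1L)
    stop(sprintf("t = %g is not a sample instant of the trace (horizon %g h)",
                 t, traceHorizon(tr)), call. = FALSE)
  i
}

#' STL robustness of a formula on a trace
#'
#' \code{robustnessAt} returns the signed robustness degree
#' \eqn{\rho(\varphi, x, t)}: the margin by which the trace satisfies
#' (positive) or violates (negative) the formula at sample instant \code{t},
#' in the units of the formula's predicates. \code{robustnessSignal} evaluates
#' it at every sample instant and returns the result as a one-channel
#' [TimedTrace-class] (instants whose evaluation window lies beyond the
#' horizon are \code{NA}). \code{satisfies} reports the Boolean verdict at
#' time 0: \code{TRUE} for positive robustness, \code{FALSE} for negative;
#' an exact zero is a boundary case, reported as \code{FALSE} with attribute
#' \code{boundary = TRUE}.
#'
#' Robustness values are comparable only within one formula, not across
#' formulas.
#'
#' @param f an [STLFormula-class].
#' @param trace a [TimedTrace-class] whose channels cover the formula's
#'   predicates.
#' @param t a sample instant of the trace (hours).
#' @return \code{robustnessAt}: a single numeric; \code{robustnessSignal}: a
#'   \code{TimedTrace} with channel \code{"rho"}; \code{satisfies}: a logical.
#' @examples
#' tr <- timedTrace(seq(0, 6, 0.5), cbind(x = rep(5, 13)))
#' robustnessAt(parseFormula("alw[0,6](x > 3)"), tr, 0)   # 2
#' satisfies(parseFormula("not (x > 3)"), tr)             # FALSE (rho = -2)
#' @export
setGeneric("robustnessAt",
           function(f, trace, t) standardGeneric("robustnessAt"))

#' @rdname robustnessAt
#' @export
setMethod("robustnessAt", signature("STLFormula", "TimedTrace"),
  function(f, trace, t) {
    .checkFormulaTrace(f, trace)
    i <- .instantIndex(trace, t)
    val <- .stlRho(f, traceTimes(trace), traceChannels(trace))[i]
    if (is.na(val))
      stop(sprintf(paste0("empty evaluation window: a temporal operator's ",
                          "window at t = %g starts beyond the horizon %g h"),
                   t, traceHorizon(trace)), call. = FALSE)
    unname(val)
  })

#' @rdname robustnessAt
#' @export
setGeneric("robustnessSignal",
           function(f, trace) standardGeneric("robustnessSignal"))

#' @rdname robustnessAt
#' @export
setMethod("robustnessSignal", signature("STLFormula", "TimedTrace"),
  function(f, trace) {
    .checkFormulaTrace(f, trace)
    rho <- .stlRho(f, traceTimes(trace), traceChannels(trace))
    timedTrace(traceTimes(trace), cbind(rho = unname(rho)))
  })

#' @rdname robustnessAt
#' @export
setGeneric("satisfies", function(f, trace) standardGeneric("satisfies"))

#' @rdname robustnessAt
#' @export
setMethod("satisfies", signature("STLFormula", "TimedTrace"),
  function(f, trace) {
    val <- robustnessAt(f, trace, traceTimes(trace)[1L])
    out <- val > 0
    if (val == 0) attr(out, "boundary") <- TRUE
    out
  })

## Boolean verdict at time 0 from the independent Boolean evaluator
## (exposed for cross-checks; not part of the monitoring API)
satisfiesBoolean <- function(f, trace) {
  .checkFormulaTrace(f, trace)
  .stlBool(f, traceTimes(trace), traceChannels(trace))[1L]
}
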