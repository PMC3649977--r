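# Independent oracles and random-case generators for property-style tests.

# Brute-force robustness oracle: each node's signal is computed once, then
# the temporal operators take their sup/inf by direct window loops with
# explicit slices (O(n^2 |f|) window traversals). 'release' uses the dual
# min/max closed form directly instead of delegating to 'until'.
bruteSignal <- function(f, times, ch) {
  n <- length(times)
  Tf <- times[n]
  eps <- 1e-9 * max(1, abs(Tf))
  win <- function(i, iv) {
    lo <- times[i] + iv[1]
    if (lo > Tf + eps) return(integer(0))
    hi <- min(times[i] + iv[2], Tf)
    which(times >= lo - eps & times <= hi + eps)
  }
  kids <- lapply(f@subs, bruteSignal, times = times, ch = ch)
  switch(f@kind,
    pred = {
      x <- ch[, f@channel]
      if (f@op == ">") x - f@threshold else f@threshold - x
    },
    not = -kids[[1]],
    and = pmin(kids[[1]], kids[[2]]),
    or = pmax(kids[[1]], kids[[2]]),
    implies = pmax(-kids[[1]], kids[[2]]),
    ev = vapply(seq_len(n), function(i) {
      js <- win(i, f@interval)
      if (!length(js)) NA_real_ else max(kids[[1]][js])
    }, 0),
    alw = vapply(seq_len(n), function(i) {
      js <- win(i, f@interval)
      if (!length(js)) NA_real_ else min(kids[[1]][js])
    }, 0),
    until = vapply(seq_len(n), function(i) {
      js <- win(i, f@interval)
      if (!length(js)) return(NA_real_)
      best <- -Inf
      for (j in js)
        best <- max(best, min(kids[[2]][j], min(kids[[1]][i:j])))
      best
    }, 0),
    release = vapply(seq_len(n), function(i) {
      js <- win(i, f@interval)
      if (!length(js)) return(NA_real_)
      worst <- Inf
      for (j in js)
        worst <- min(worst, max(kids[[2]][j], max(kids[[1]][i:j])))
      worst
    }, 0))
}

bruteRho <- function(f, times, ch, i) bruteSignal(f, times, ch)[i]

# random piecewise-smooth trace with channels x and y
randomTrace <- function(n = 40, Tf = 10) {
  times <- seq(0, Tf, length.out = n)
  mk <- function() cumsum(stats::rnorm(n, sd = 0.5)) + stats::rnorm(1, sd = 2)
  timedTrace(times, cbind(x = mk(), y = mk()))
}

# random formula over channels x/y; maxDepth bounds the AST depth
randomFormula <- function(maxDepth = 3, Tf = 10, positiveOnly = FALSE) {
  pred <- function() {
    ch <- if (positiveOnly) "x" else sample(c("x", "y"), 1)
    op <- if (positiveOnly) ">" else sample(c("<", ">"), 1)
    stlPred(ch, op, stats::runif(1, -3, 3))
  }
  iv <- function() {
    if (stats::runif(1) < 0.4) return(c(0, Inf))
    a <- stats::runif(1, 0, 0.3 * Tf)
    c(a, a + stats::runif(1, 0, 0.7 * Tf))
  }
  go <- function(depth) {
    if (depth <= 0 || stats::runif(1) < 0.3) return(pred())
    kinds <- c("and", "or", "ev", "alw", "until", "release")
    if (!positiveOnly) kinds <- c(kinds, "not", "implies")
    switch(sample(kinds, 1),
      not = stlNot(go(depth - 1)),
      and = stlAnd(go(depth - 1), go(depth - 1)),
      or = stlOr(go(depth - 1), go(depth - 1)),
      implies = stlImplies(go(depth - 1), go(depth - 1)),
      ev = stlEv(go(depth - 1), iv()),
      alw = stlAlw(go(depth - 1), iv()),
      until = stlUntil(go(depth - 1), go(depth - 1), iv()),
      release = stlRelease(go(depth - 1), go(depth - 1), iv()))
  }
  go(maxDepth)
}

# constant-channel trace helper
constTrace <- function(value, Tf = 6, step = 0.5, name = "x") {
  times <- seq(0, Tf, by = step)
  timedTrace(times, matrix(value, nrow = length(times), ncol = 1,
                           dimnames = list(NULL, name)))
}

# tiny toy observation table (plain data.frame in the observation schema)
toyObservations <- function(entries) {
  do.call(rbind, lapply(entries, function(e)
    data.frame(line = e[[1]], property = e[[2]], value = e[[3]],
               provenance = "toy", stringsAsFactors = FALSE)))
}
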