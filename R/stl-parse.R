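## STL formula construction, parsing and printing.
##
## Grammar (hours in intervals; precedence: not > ev/alw/until/release > and
## > or > "=>", with "=>" right-associative):
##   formula  := pred | "not" formula | formula ("and"|"or"|"=>") formula
##             | ("ev"|"alw") interval? "(" formula ")"
##             | formula ("until"|"release") interval? formula
##   interval := "[" num "," num "]"
##   pred     := name ("<"|">") num

stlNode <- function(kind, subs = list(), interval = c(0, Inf),
                    channel = NA_character_, op = NA_character_,
                    threshold = NA_real_) {
  new("STLFormula", kind = kind, subs = subs, interval = as.numeric(interval),
      channel = channel, op = op, threshold = threshold)
}

#' Build STL formulas programmatically
#'
#' Constructors for the STL abstract syntax tree: a predicate compares one
#' trace channel against a threshold; Boolean connectives and
#' interval-annotated temporal operators combine formulas. Omitting the
#' interval of a temporal operator means \code{[0, Inf)}, capped at the trace
#' horizon during evaluation.
#'
#' @param channel channel name the predicate reads.
#' @param op comparator, \code{"<"} or \code{">"}.
#' @param threshold finite numeric threshold, in the channel's units.
#' @param f,g subformulas.
#' @param interval numeric \code{c(a, b)} in hours, \code{0 <= a <= b}
#'   (\code{b} may be \code{Inf}).
#' @return an [STLFormula-class].
#' @examples
#' p1 <- stlAlw(stlPred("cPARP_frac", "<", 0.5), c(0, 6))
#' formatFormula(p1)
#' @export
stlPred <- function(channel, op, threshold) {
  stlNode("pred", channel = as.character(channel), op = op,
          threshold = as.numeric(threshold))
}
#' @rdname stlPred
#' @export
stlNot <- function(f) stlNode("not", list(f))
#' @rdname stlPred
#' @export
stlAnd <- function(f, g) stlNode("and", list(f, g))
#' @rdname stlPred
#' @export
stlOr <- function(f, g) stlNode("or", list(f, g))
#' @rdname stlPred
#' @export
stlImplies <- function(f, g) stlNode("implies", list(f, g))
#' @rdname stlPred
#' @export
stlEv <- function(f, interval = c(0, Inf)) stlNode("ev", list(f), interval)
#' @rdname stlPred
#' @export
stlAlw <- function(f, interval = c(0, Inf)) stlNode("alw", list(f), interval)
#' @rdname stlPred
#' @export
stlUntil <- function(f, g, interval = c(0, Inf))
  stlNode("until", list(f, g), interval)
#' @rdname stlPred
#' @export
stlRelease <- function(f, g, interval = c(0, Inf))
  stlNode("release", list(f, g), interval)

## ---- tokenizer -------------------------------------------------------------

stlTokenize <- function(text) {
  pats <- c(ws = "\\s+",
            num = "-?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?",
            name = "[A-Za-z_][A-Za-z0-9_.*]*",
            sym = "=>|\\[|\\]|\\(|\\)|,|<|>")
  toks <- list(); pos <- 1L; n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    hit <- FALSE
    for (ty in names(pats)) {
      m <- regexpr(paste0("^(", pats[[ty]], ")"), rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        if (ty != "ws") {
          val <- substr(rest, 1L, len)
          kw <- c("not", "and", "or", "ev", "alw", "until", "release",
                  "eventually", "always")
          ty2 <- if (ty == "name" && val %in% kw) "kw" else ty
          toks[[length(toks) + 1L]] <- list(type = ty2, value = val, pos = pos)
        }
        pos <- pos + len
        hit <- TRUE
        break
      }
    }
    if (!hit)
      stop(sprintf("STL syntax error at position %d: unexpected '%s'",
                   pos, substr(text, pos, pos)), call. = FALSE)
  }
  toks
}

## ---- recursive-descent parser ---------------------------------------------

#' Parse an STL formula from text
#'
#' Parses the small STL grammar used throughout the package, e.g.
#' \code{"alw[0,6](cPARP_frac < 0.5)"} or
#' \code{"ev(C8act_frac > 0.01 and alw[0,1] not (C3act_frac > 0.01))"}.
#' \code{eventually}/\code{always} are accepted as synonyms of
#' \code{ev}/\code{alw}. The printer [formatFormula()] and the parser
#' round-trip: \code{parseFormula(formatFormula(f))} is an equivalent formula.
#'
#' @param text formula string.
#' @return an [STLFormula-class].
#' @examples
#' parseFormula("alw[0,6](cPARP_frac < 0.5)")
#' @export
parseFormula <- function(text) {
  st <- new.env(parent = emptyenv())
  st$toks <- stlTokenize(text)
  st$i <- 1L
  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
  advance <- function() { tk <- peek(); st$i <- st$i + 1L; tk }
  expect <- function(value) {
    tk <- peek()
    if (is.null(tk) || tk$value != value)
      stop(sprintf("STL syntax error at position %s: expected '%s', got '%s'",
                   if (is.null(tk)) "end" else tk$pos, value,
                   if (is.null(tk)) "end of input" else tk$value),
           call. = FALSE)
    advance()
  }
  atKw <- function(...) {
    tk <- peek()
    !is.null(tk) && tk$type == "kw" && tk$value %in% c(...)
  }

  parseInterval <- function() {
    tk <- peek()
    if (is.null(tk) || tk$value != "[") return(c(0, Inf))
    expect("[")
    a <- parseNum(); expect(","); b <- parseNum(); expect("]")
    if (a > b)
      stop(sprintf("STL interval error: [%g,%g] has a > b", a, b),
           call. = FALSE)
    if (a < 0)
      stop(sprintf("STL interval error: lower bound %g is negative", a),
           call. = FALSE)
    c(a, b)
  }
  parseNum <- function() {
    tk <- advance()
    if (is.null(tk) || tk$type != "num")
      stop(sprintf("STL syntax error at position %s: expected a number",
                   if (is.null(tk)) "end" else tk$pos), call. = FALSE)
    as.numeric(tk$value)
  }

  parseUnary <- function() {
    if (atKw("not")) { advance(); return(stlNot(parseUnary())) }
    if (atKw("ev", "alw", "eventually", "always")) {
      kw <- advance()$value
      iv <- parseInterval()
      tk <- peek()
      if (!is.null(tk) && tk$value == "(") {
        expect("("); f <- parseImplies(); expect(")")
      } else {
        f <- parseUnary()   # e.g. "alw[0,1] not (x > c)"
      }
      return(stlNode(if (kw %in% c("ev", "eventually")) "ev" else "alw",
                     list(f), iv))
    }
    tk <- peek()
    if (!is.null(tk) && tk$value == "(") {
      expect("("); f <- parseImplies(); expect(")")
      return(f)
    }
    if (is.null(tk) || tk$type != "name")
      stop(sprintf("STL syntax error at position %s: expected a predicate",
                   if (is.null(tk)) "end" else tk$pos), call. = FALSE)
    advance()
    cmp <- advance()
    if (is.null(cmp) || !cmp$value %in% c("<", ">"))
      stop(sprintf("STL syntax error at position %s: expected '<' or '>'",
                   if (is.null(cmp)) "end" else cmp$pos), call. = FALSE)
    stlPred(tk$value, cmp$value, parseNum())
  }

  parseTemporal <- function() {
    f <- parseUnary()
    while (atKw("until", "release")) {
      kw <- advance()$value
      iv <- parseInterval()
      f <- stlNode(kw, list(f, parseUnary()), iv)
    }
    f
  }
  parseAnd <- function() {
    f <- parseTemporal()
    while (atKw("and")) { advance(); f <- stlAnd(f, parseTemporal()) }
    f
  }
  parseOr <- function() {
    f <- parseAnd()
    while (atKw("or")) { advance(); f <- stlOr(f, parseAnd()) }
    f
  }
  parseImplies <- function() {
    f <- parseOr()
    tk <- peek()
    if (!is.null(tk) && tk$value == "=>") { advance(); f <- stlImplies(f, parseImplies()) }
    f
  }

  out <- parseImplies()
  tk <- peek()
  if (!is.null(tk))
    stop(sprintf("STL syntax error at position %d: unexpected '%s'",
                 tk$pos, tk$value), call. = FALSE)
  validObject(out, complete = TRUE)
  out
}

## ---- printer ---------------------------------------------------------------

fmtNum <- function(x) sprintf("%.15g", x)

fmtInterval <- function(iv) {
  if (iv[1] == 0 && is.infinite(iv[2])) ""
  else sprintf("[%s,%s]", fmtNum(iv[1]), fmtNum(iv[2]))
}

#' Print an STL formula as parseable text
#'
#' @param f an [STLFormula-class].
#' @return a single string in the grammar accepted by [parseFormula()].
#' @export
formatFormula <- function(f) {
  stopifnot(is(f, "STLFormula"))
  switch(f@kind,
    pred = sprintf("%s %s %s", f@channel, f@op, fmtNum(f@threshold)),
    not = sprintf("not (%s)", formatFormula(f@subs[[1]])),
    and = sprintf("(%s) and (%s)", formatFormula(f@subs[[1]]),
                  formatFormula(f@subs[[2]])),
    or = sprintf("(%s) or (%s)", formatFormula(f@subs[[1]]),
                 formatFormula(f@subs[[2]])),
    implies = sprintf("(%s) => (%s)", formatFormula(f@subs[[1]]),
                      formatFormula(f@subs[[2]])),
    ev = sprintf("ev%s(%s)", fmtInterval(f@interval),
                 formatFormula(f@subs[[1]])),
    alw = sprintf("alw%s(%s)", fmtInterval(f@interval),
                  formatFormula(f@subs[[1]])),
    until = sprintf("(%s) until%s (%s)", formatFormula(f@subs[[1]]),
                    fmtInterval(f@interval), formatFormula(f@subs[[2]])),
    release = sprintf("(%s) release%s (%s)", formatFormula(f@subs[[1]]),
                      fmtInterval(f@interval), formatFormula(f@subs[[2]])))
}

## Channels referenced by a formula (used for validation against traces).
formulaChannels <- function(f) {
  if (f@kind == "pred") return(f@channel)
  unique(unlist(lapply(f@subs, formulaChannels)))
}
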