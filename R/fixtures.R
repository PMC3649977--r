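## Small analytically-tractable networks used as oracles for the monitor,
## the DLE evaluators and the parameter search.

#' Analytic fixture networks
#'
#' Three toy networks with known behavior, returned together with a
#' reference for oracle-style tests:
#' \describe{
#'   \item{\code{"linear-decay"}}{one reaction A -> B at rate k = 0.1/h,
#'     A0 = 100; \code{reference$A(t)} is the closed form
#'     \eqn{A_0 e^{-kt}}.}
#'   \item{\code{"two-state-switch"}}{two self-replicating, self-limiting,
#'     mutually annihilating species (A -> 2A and 2A -> A, likewise for B,
#'     plus A + B -> 0): a bistable competition with stable states near
#'     (100, 0) and (0, 100); \code{reference$basin(a0, b0)} returns
#'     \code{"A"} or \code{"B"} by long-horizon simulation.}
#'   \item{\code{"mini-cascade"}}{a 3-step activation cascade
#'     E + A -> E + Aa, Aa + B -> Aa + Ba, Ba + C -> Ba + Ca; with the
#'     enzyme E conserved, \code{reference$Aa(t)} is the closed form
#'     \eqn{A_0 (1 - e^{-k_1 E_0 t})}; zero input (E0 = 0) leaves all
#'     downstream species at zero.}
#' }
#' All fixtures use hours as the native time unit.
#'
#' @param kind one of \code{"linear-decay"}, \code{"two-state-switch"},
#'   \code{"mini-cascade"}.
#' @return list with elements \code{network} (a [ReactionNetwork-class]),
#'   \code{reference} (named list of functions) and \code{description}.
#' @examples
#' fx <- makeFixture("linear-decay")
#' fx$reference$A(6)   # 100 * exp(-0.6)
#' @export
makeFixture <- function(kind = c("linear-decay", "two-state-switch",
                                 "mini-cascade")) {
  kind <- match.arg(kind)
  switch(kind,
    "linear-decay" = {
      net <- reactionNetwork(
        species = data.frame(name = c("A", "B"), role = "native",
                             init = c(100, 0)),
        reactions = list(rxn("forward", c(A = 1L), c(B = 1L), c(kf = "k"))),
        params = c(k = 0.1),
        meta = list(time_unit = "h", source = "fixture: linear decay"))
      list(network = net,
           reference = list(A = function(t) 100 * exp(-0.1 * t),
                            B = function(t) 100 * (1 - exp(-0.1 * t))),
           description = "A -> B, k = 0.1/h, A0 = 100")
    },
    "two-state-switch" = {
      net <- reactionNetwork(
        species = data.frame(name = c("A", "B"), role = "native",
                             init = c(30, 30)),
        reactions = list(
          rxn("forward", c(A = 1L), c(A = 2L), c(kf = "rA")),
          rxn("forward", c(A = 2L), c(A = 1L), c(kf = "dA")),
          rxn("forward", c(B = 1L), c(B = 2L), c(kf = "rB")),
          rxn("forward", c(B = 2L), c(B = 1L), c(kf = "dB")),
          rxn("forward", c(A = 1L, B = 1L), stats::setNames(integer(0),
                                                            character(0)),
              c(kf = "c"))),
        params = c(rA = 1, dA = 0.01, rB = 1, dB = 0.01, c = 0.02),
        meta = list(time_unit = "h", source = "fixture: bistable switch"))
      basin <- function(a0, b0, horizon = 200) {
        tr <- simulateNetwork(net, init = c(A = a0, B = b0),
                              horizon = horizon, gridStep = horizon,
                              rtol = 1e-10, atol = 1e-10)
        xa <- channelValues(tr, "A"); xb <- channelValues(tr, "B")
        if (xa[length(xa)] > xb[length(xb)]) "A" else "B"
      }
      list(network = net, reference = list(basin = basin),
           description = "bistable competition, stable states ~(100,0)/(0,100)")
    },
    "mini-cascade" = {
      net <- reactionNetwork(
        species = data.frame(
          name = c("E", "A", "Aa", "B", "Ba", "C", "Ca"),
          role = "native", init = c(10, 100, 0, 100, 0, 100, 0)),
        reactions = list(
          rxn("forward", c(E = 1L, A = 1L), c(E = 1L, Aa = 1L), c(kf = "k1")),
          rxn("forward", c(Aa = 1L, B = 1L), c(Aa = 1L, Ba = 1L), c(kf = "k2")),
          rxn("forward", c(Ba = 1L, C = 1L), c(Ba = 1L, Ca = 1L), c(kf = "k3"))),
        params = c(k1 = 0.02, k2 = 0.005, k3 = 0.005),
        meta = list(time_unit = "h", source = "fixture: activation cascade"))
      list(network = net,
           reference = list(Aa = function(t, E0 = 10, A0 = 100, k1 = 0.02)
                              A0 * (1 - exp(-k1 * E0 * t))),
           description = "3-step cascade E -> Aa -> Ba -> Ca")
    })
}
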