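## Transcription of the extrinsic apoptosis reaction model (EARM1.4 lineage):
## TRAIL receptor engagement, DISC assembly, initiator/effector caspase
## activation with the caspase-3 -> -6 -> -8 feedback loop, XIAP inhibition,
## Bid/Bax-mediated mitochondrial outer membrane permeabilization (MOMP),
## cytochrome-c/Smac release, apoptosome formation and PARP cleavage.
##
## 28 reaction groups (70 elementary reactions), 58 species (17 native
## proteins, 40 modified proteins or complexes, plus the TRAIL ligand).
## Rate constants are per second (2nd order: per molecule per second); the
## mitochondrial-compartment association rates carry the 1/v volume scaling
## (v = 0.07). Amounts are molecules per cell.

.earmV <- 0.07  # mitochondrial compartment volume fraction

.earmSpecies <- function() {
  native <- c(pR = 200, flip = 100, pC8 = 20000, BAR = 1000, pC3 = 10000,
              pC6 = 10000, XIAP = 100000, PARP = 1000000, Bid = 40000,
              Bcl2c = 20000, Bax = 100000, Bcl2 = 20000, M = 500000,
              mCytoC = 500000, mSmac = 100000, Apaf = 100000, pC9 = 100000)
  complexes <- c("L:pR", "DISC", "flip:DISC", "DISC:pC8", "C8", "BAR:C8",
                 "pC3:C8", "C3", "pC6:C3", "C6", "pC8:C6", "XIAP:C3", "C3_U",
                 "PARP:C3", "cPARP", "Bid:C8", "tBid", "tBid:Bcl2c",
                 "Bax:tBid", "aBax", "MBax", "MBax:Bcl2", "Bax2", "Bax2:Bcl2",
                 "Bax4", "Bax4:Bcl2", "Bax4:M", "AMito", "AMito:mCytoC",
                 "ACytoC", "AMito:mSmac", "ASmac", "cCytoC", "Apaf:cCytoC",
                 "aApaf", "Apop", "pC3:Apop", "cSmac", "Apop:XIAP",
                 "cSmac:XIAP")
  data.frame(
    name = c("L", names(native), complexes),
    role = c("ligand", rep("native", length(native)),
             rep("complex", length(complexes))),
    init = c(3000, unname(native), rep(0, length(complexes))),
    stringsAsFactors = FALSE)
}

## one reaction group in the transcription table; i is the group number that
## names its rate constants (k<i>, k_<i>, kc<i>)
.g <- function(i, law, reactants, products, kf, kr = NA, kc = NA,
               intermediate = NULL) {
  params <- c(kf = sprintf("k%d", i))
  vals <- c(kf)
  if (!is.na(kr)) { params <- c(params, kr = sprintf("k_%d", i)); vals <- c(vals, kr) }
  if (!is.na(kc)) { params <- c(params, kc = sprintf("kc%d", i)); vals <- c(vals, kc) }
  list(group = rxn(law, reactants, products, params, intermediate),
       values = stats::setNames(vals, params))
}

.s <- function(...) {
  nm <- c(...)
  stats::setNames(rep(1L, length(nm)), nm)
}

.earmReactionTable <- function() {
  v <- .earmV
  list(
    ## death receptor module
    .g(1,  "catalytic",  .s("L", "pR"),      .s("DISC"),            4e-7, 1e-3, 1e-5, "L:pR"),
    .g(2,  "reversible", .s("flip", "DISC"), .s("flip:DISC"),       1e-6, 1e-3),
    .g(3,  "catalytic",  .s("pC8", "DISC"),  .s("C8", "DISC"),      1e-6, 1e-3, 1,    "DISC:pC8"),
    .g(4,  "reversible", .s("C8", "BAR"),    .s("BAR:C8"),          1e-6, 1e-3),
    ## caspase cascade and feedback (reaction 7: caspase-6 cleaves caspase-8)
    .g(5,  "catalytic",  .s("pC3", "C8"),    .s("C3", "C8"),        1e-7, 1e-3, 1,    "pC3:C8"),
    .g(6,  "catalytic",  .s("pC6", "C3"),    .s("C6", "C3"),        1e-6, 1e-3, 1,    "pC6:C3"),
    .g(7,  "catalytic",  .s("pC8", "C6"),    .s("C8", "C6"),        3e-8, 1e-3, 1,    "pC8:C6"),
    .g(8,  "catalytic",  .s("C3", "XIAP"),   .s("C3_U", "XIAP"),    2e-6, 1e-3, 0.1,  "XIAP:C3"),
    .g(9,  "catalytic",  .s("PARP", "C3"),   .s("cPARP", "C3"),     1e-7, 1e-2, 1,    "PARP:C3"),
    ## mitochondrial pathway: Bid activation, Bax oligomerization, MOMP
    .g(10, "catalytic",  .s("Bid", "C8"),    .s("tBid", "C8"),      1e-7, 1e-3, 1,    "Bid:C8"),
    .g(11, "reversible", .s("tBid", "Bcl2c"), .s("tBid:Bcl2c"),     1e-6, 1e-3),
    .g(12, "catalytic",  .s("Bax", "tBid"),  .s("aBax", "tBid"),    1e-7, 1e-3, 1,    "Bax:tBid"),
    .g(13, "reversible", .s("aBax"),         .s("MBax"),            1e-2, 1e-2),
    .g(14, "reversible", .s("MBax", "Bcl2"), .s("MBax:Bcl2"),       1e-6 / v, 1e-3),
    .g(15, "reversible", stats::setNames(2L, "MBax"), .s("Bax2"),   1e-6 / v, 1e-3),
    .g(16, "reversible", .s("Bax2", "Bcl2"), .s("Bax2:Bcl2"),       1e-6 / v, 1e-3),
    .g(17, "reversible", stats::setNames(2L, "Bax2"), .s("Bax4"),   1e-6 / v, 1e-3),
    .g(18, "reversible", .s("Bax4", "Bcl2"), .s("Bax4:Bcl2"),       1e-6 / v, 1e-3),
    .g(19, "catalytic",  .s("Bax4", "M"),    .s("AMito"),           1e-6 / v, 1e-3, 1, "Bax4:M"),
    .g(20, "catalytic",  .s("AMito", "mCytoC"), .s("AMito", "ACytoC"), 2e-6 / v, 1e-3, 10, "AMito:mCytoC"),
    .g(21, "catalytic",  .s("AMito", "mSmac"),  .s("AMito", "ASmac"),  2e-6 / v, 1e-3, 10, "AMito:mSmac"),
    ## cytoplasmic translocation and apoptosome
    .g(22, "reversible", .s("ACytoC"),       .s("cCytoC"),          1e-2, 1e-2),
    .g(23, "catalytic",  .s("Apaf", "cCytoC"), .s("aApaf", "cCytoC"), 5e-7, 1e-3, 1, "Apaf:cCytoC"),
    .g(24, "reversible", .s("aApaf", "pC9"), .s("Apop"),            5e-8, 1e-3),
    .g(25, "catalytic",  .s("pC3", "Apop"),  .s("C3", "Apop"),      5e-9, 1e-3, 1,    "pC3:Apop"),
    .g(26, "reversible", .s("ASmac"),        .s("cSmac"),           1e-2, 1e-2),
    .g(27, "reversible", .s("Apop", "XIAP"), .s("Apop:XIAP"),       2e-6, 1e-3),
    .g(28, "reversible", .s("cSmac", "XIAP"), .s("cSmac:XIAP"),     7e-6, 1e-3))
}

.earmObservables <- function() {
  list(
    cPARP_frac = list(num = "cPARP",
                      den = c("PARP", "PARP:C3", "cPARP")),
    ## active cleaved caspase-8, excluding the Bar-bound pool
    C8act_frac = list(num = c("C8", "pC3:C8", "Bid:C8"),
                      den = c("pC8", "DISC:pC8", "pC8:C6", "C8", "BAR:C8",
                              "pC3:C8", "Bid:C8")),
    ## active cleaved caspase-3, excluding the XIAP-bound pool and its
    ## ubiquitinated (degraded) product
    C3act_frac = list(num = c("C3", "pC6:C3", "PARP:C3"),
                      den = c("pC3", "pC3:C8", "pC3:Apop", "C3", "pC6:C3",
                              "XIAP:C3", "PARP:C3", "C3_U")),
    Apaf_free_frac = list(num = "Apaf",
                          den = c("Apaf", "Apaf:cCytoC", "aApaf", "Apop",
                                  "pC3:Apop", "Apop:XIAP")))
}

#' Build the bundled extrinsic apoptosis model
#'
#' Constructs the EARM1.4-lineage mass-action network used throughout the
#' package: 58 species (17 native proteins, 40 modified proteins or
#' complexes, and the TRAIL ligand), 28 reaction groups expanding to 70
#' elementary reactions, with the original rate constants and HeLa-derived
#' default initial amounts. Cell-line-specific initial concentrations are
#' applied on top via [earmCellLines()] / [applyVariant()]. The metadata
#' records the TRAIL dose map (50 ng/ml corresponds to 3000 ligand
#' molecules/cell, i.e. 60 molecules per ng/ml) and the derived observables
#' (cleaved-PARP, active-caspase-8, active-caspase-3 and free-Apaf-1
#' fractions) referenced by the apoptosis properties.
#'
#' @return a [ReactionNetwork-class].
#' @examples
#' net <- buildEarm()
#' parameterCensus(net)
#' @export
buildEarm <- function() {
  tab <- .earmReactionTable()
  reactionNetwork(
    species = .earmSpecies(),
    reactions = lapply(tab, `[[`, "group"),
    params = do.call(c, lapply(tab, `[[`, "values")),
    meta = list(
      source = paste("EARM1.0 transcription (Albeck et al. lineage) with",
                     "cell-line adaptations; synthetic stand-in for the",
                     "EARM1.4 distribution"),
      time_unit = "s",
      dose_map = list(ligand = "L", molecules_per_ng_ml = 60),
      observables = .earmObservables()))
}

#' Census of a network's rate parameters and species
#'
#' Classifies rate constants by their role in the reaction groups: forward
#' (association or conversion, \code{kf}), reverse (\code{kr}) and catalytic
#' (\code{kc} of catalytic groups). The searchable set used by the parameter
#' search is the union of forward and catalytic rates.
#'
#' @param net a [ReactionNetwork-class].
#' @return a list with counts (\code{nForward}, \code{nCatalytic},
#'   \code{nReverse}, \code{nSearchable}, \code{nParams}, \code{nSpecies},
#'   \code{nNative}) and the character vector \code{searchable} of parameter
#'   names.
#' @export
parameterCensus <- function(net) {
  stopifnot(is(net, "ReactionNetwork"))
  kf <- vapply(net@reactions, function(r) r$params[["kf"]], "")
  kc <- unlist(lapply(net@reactions,
                      function(r) if (r$law == "catalytic") r$params[["kc"]]))
  kr <- unlist(lapply(net@reactions,
                      function(r) if (r$law != "forward") r$params[["kr"]]))
  searchable <- c(kf, kc)
  list(nForward = length(kf), nCatalytic = length(kc), nReverse = length(kr),
       nSearchable = length(searchable), nParams = length(net@params),
       nSpecies = nrow(net@species),
       nNative = sum(net@species$role == "native"),
       searchable = unname(searchable))
}

## ---- cell lines ------------------------------------------------------------

#' Construct a cell line
#'
#' @param name line label.
#' @param init named numeric vector of nominal initial amounts
#'   (molecules/cell) overriding the network defaults.
#' @param cv named numeric vector of coefficients of variation (species not
#'   listed use \code{defaultCV}).
#' @param defaultCV default coefficient of variation (0.25).
#' @param params named numeric vector of rate-parameter overrides.
#' @return a [CellLine-class].
#' @export
cellLine <- function(name, init = numeric(), cv = numeric(),
                     defaultCV = 0.25, params = numeric()) {
  new("CellLine", name = name, init = init, cv = cv,
      defaultCV = defaultCV, params = params)
}

## Measured initial concentrations (molecules/cell) and CVs for the parental
## lines; species not listed keep network defaults and the 25% default CV.
.earmBaseLines <- function() {
  mk <- function(name, flip, pC8, pC6, pC3, XIAP, PARP, Bid, Bcl2c, Bax,
                 Bcl2, mSmac, cvC3, cvXIAP) {
    cellLine(name,
      init = c(flip = flip, pC8 = pC8, pC6 = pC6, pC3 = pC3, XIAP = XIAP,
               PARP = PARP, Bid = Bid, Bcl2c = Bcl2c, Bax = Bax, Bcl2 = Bcl2,
               mSmac = mSmac),
      cv = c(pC3 = cvC3, XIAP = cvXIAP))
  }
  list(
    H = mk("H", 100, 3500, 10000, 100000, 30000, 1000000, 40000, 1000,
           80000, 20000, 100000, 0.32, 0.52),
    S = mk("S", 591, 3255, 6700, 886000, 11400, 1120000, 74800, 1250,
           786400, 400000, 177000, 0.31, 0.42),
    T = mk("T", 48, 1680, 22500, 351000, 19200, 1040000, 53600, 4640,
           113600, 104000, 139000, 0.25, 0.53))
}

#' Derive a mutant cell line
#'
#' \code{"dXIAP"} sets the initial XIAP amount to 0; \code{"oeBcl2"}
#' multiplies the initial (mitochondrial) Bcl2 amount by 10; \code{"dFB"}
#' zeroes the caspase-6-mediated cleavage rate of caspase-8 (parameter
#' \code{k7}), deleting the caspase feedback loop. Variants touch disjoint
#' quantities, so they compose in any order.
#'
#' @param line a [CellLine-class].
#' @param variant one of \code{"dXIAP"}, \code{"oeBcl2"}, \code{"dFB"}.
#' @param net the network the line belongs to (supplies the default Bcl2
#'   amount if the line does not override it).
#' @return the derived [CellLine-class]; its name gains a suffix
#'   (\code{X}, \code{B}, \code{FB}).
#' @export
applyVariant <- function(line, variant, net = buildEarm()) {
  stopifnot(is(line, "CellLine"))
  switch(variant,
    dXIAP = {
      line@init["XIAP"] <- 0
      line@name <- paste0(line@name, "X")
    },
    oeBcl2 = {
      base <- if ("Bcl2" %in% names(line@init)) line@init[["Bcl2"]]
              else defaultInit(net)[["Bcl2"]]
      line@init["Bcl2"] <- 10 * base
      line@name <- paste0(line@name, "B")
    },
    dFB = {
      line@params["k7"] <- 0
      line@name <- paste0(line@name, "FB")
    },
    stop("unknown variant '", variant,
         "' (expected dXIAP, oeBcl2 or dFB)", call. = FALSE))
  validObject(line)
  line
}

#' The twelve bundled cell lines
#'
#' Parental HCT116 (\code{H}), SKW6.4 (\code{S}) and T47D (\code{T}) lines
#' with their measured initial protein amounts, plus the \code{X}
#' (XIAP-deleted), \code{B} (Bcl2 over-expressing) and \code{BX} derived
#' lines of each. Naming follows H/HX/HB/HBX, S/SX/SB/SBX, T/TX/TB/TBX.
#'
#' @param net the network (supplies defaults to the Bcl2 over-expression).
#' @return named list of 12 [CellLine-class] objects.
#' @export
earmCellLines <- function(net = buildEarm()) {
  base <- .earmBaseLines()
  out <- list()
  for (b in names(base)) {
    ln <- base[[b]]
    out[[ln@name]] <- ln
    lx <- applyVariant(ln, "dXIAP", net)
    out[[lx@name]] <- lx
    lb <- applyVariant(ln, "oeBcl2", net)
    out[[lb@name]] <- lb
    lbx <- applyVariant(lb, "dXIAP", net)
    out[[lbx@name]] <- lbx
  }
  ## canonical order
  out[c("H", "HX", "HB", "HBX", "S", "SX", "SB", "SBX",
        "T", "TX", "TB", "TBX")]
}

#' The published two-parameter revision of the apoptosis model
#'
#' Returns the searchable-parameter revision that restores full agreement
#' with the observed property table: the caspase-feedback cleavage rate
#' \code{k7} increased 2.71-fold and the PARP-cleavage catalytic rate
#' \code{kc9} decreased 55.6-fold.
#'
#' @param net a [ReactionNetwork-class] with parameters \code{k7}, \code{kc9}.
#' @return named numeric vector of revised parameter values.
#' @export
revisedParameters <- function(net = buildEarm()) {
  k <- parameters(net)
  c(k7 = unname(k[["k7"]]) * 2.71, kc9 = unname(k[["kc9"]]) / 55.6)
}
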