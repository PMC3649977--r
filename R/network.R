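## ReactionNetwork construction, JSON interchange, compilation to elementary
## mass-action reactions, and structural analysis (stoichiometry matrix,
## conserved moieties).

#' Construct a reaction network
#'
#' @param species data.frame with columns \code{name}, \code{role}
#'   (\code{"native"}, \code{"complex"} or \code{"ligand"}) and \code{init}.
#' @param reactions list of reaction groups (see [ReactionNetwork-class]).
#' @param params named numeric vector of rate constants.
#' @param meta metadata list; recognised entries: \code{source} (provenance),
#'   \code{time_unit} (\code{"s"} or \code{"h"}, the unit of the rate
#'   constants; the simulation API is always in hours), \code{dose_map}
#'   (ligand dose conversion) and \code{observables} (derived channels, each
#'   \code{list(num = <species>, den = <species>)} meaning
#'   \code{sum(num)/sum(den)}).
#' @return a validated [ReactionNetwork-class].
#' @seealso [buildEarm()], [makeFixture()]
#' @export
reactionNetwork <- function(species, reactions, params, meta = list()) {
  if (is.null(meta$time_unit)) meta$time_unit <- "h"
  species <- data.frame(name = as.character(species$name),
                        role = as.character(species$role),
                        init = as.numeric(species$init),
                        stringsAsFactors = FALSE)
  new("ReactionNetwork", species = species, reactions = reactions,
      params = unlist(params), meta = meta)
}

#' Build one reaction group
#'
#' @param law \code{"forward"}, \code{"reversible"} or \code{"catalytic"}.
#' @param reactants,products named positive integer vectors (stoichiometries).
#' @param params named character vector mapping the law's rate roles
#'   (\code{kf}, and \code{kr}/\code{kc} where applicable) to parameter names.
#' @param intermediate complex species name (catalytic groups only).
#' @return a reaction-group list suitable for [reactionNetwork()].
#' @export
rxn <- function(law, reactants, products, params, intermediate = NULL) {
  out <- list(reactants = reactants, products = products, law = law,
              params = params)
  if (!is.null(intermediate)) out$intermediate <- intermediate
  out
}

## ---- elementary expansion and compilation ---------------------------------

## Expand reaction groups into elementary mass-action reactions, each with a
## single rate parameter. 'role' tags the rate constant's role in its group.
elementaryReactions <- function(net) {
  out <- list()
  for (g in seq_along(net@reactions)) {
    r <- net@reactions[[g]]
    add <- function(reac, prod, par, role)
      out[[length(out) + 1L]] <<- list(reactants = reac, products = prod,
                                       param = par, role = role, group = g)
    switch(r$law,
      forward = add(r$reactants, r$products, r$params[["kf"]], "forward"),
      reversible = {
        add(r$reactants, r$products, r$params[["kf"]], "forward")
        add(r$products, r$reactants, r$params[["kr"]], "reverse")
      },
      catalytic = {
        cx <- stats::setNames(1L, r$intermediate)
        add(r$reactants, cx, r$params[["kf"]], "forward")
        add(cx, r$reactants, r$params[["kr"]], "reverse")
        add(cx, r$products, r$params[["kc"]], "catalytic")
      })
  }
  out
}

#' Stoichiometry matrix of the elementary reactions
#'
#' @param net a [ReactionNetwork-class].
#' @return integer matrix, species in rows, elementary reactions in columns.
#' @export
stoichiometryMatrix <- function(net) {
  sp <- speciesNames(net)
  elems <- elementaryReactions(net)
  N <- matrix(0L, nrow = length(sp), ncol = length(elems),
              dimnames = list(sp, vapply(elems, `[[`, "", "param")))
  for (e in seq_along(elems)) {
    el <- elems[[e]]
    for (s in names(el$reactants))
      N[s, e] <- N[s, e] - as.integer(el$reactants[[s]])
    for (s in names(el$products))
      N[s, e] <- N[s, e] + as.integer(el$products[[s]])
  }
  N
}

## Compile a network into indexed structures for fast rate evaluation.
## Supports elementary molecularity up to 3 (slot indices into c(x, 1)).
compileNetwork <- function(net) {
  sp <- speciesNames(net)
  ns <- length(sp)
  elems <- elementaryReactions(net)
  ne <- length(elems)
  slots <- matrix(ns + 1L, nrow = ne, ncol = 3L)
  for (e in seq_len(ne)) {
    idx <- integer(0)
    for (s in names(elems[[e]]$reactants))
      idx <- c(idx, rep(match(s, sp), elems[[e]]$reactants[[s]]))
    if (length(idx) > 3L)
      stop("mass-action molecularity > 3 is not supported", call. = FALSE)
    if (length(idx)) slots[e, seq_along(idx)] <- idx
  }
  tscale <- switch(net@meta$time_unit, s = 3600, h = 1,
                   stop("meta$time_unit must be 's' or 'h'", call. = FALSE))
  list(speciesNames = sp, ns = ns, ne = ne,
       N = stoichiometryMatrix(net) * 1.0,
       paramIdx = match(vapply(elems, `[[`, "", "param"), names(net@params)),
       slots = slots, tscale = tscale)
}

## rate vector of elementary reactions at state x (model time unit)
.rates <- function(cmp, x, k) {
  xx <- c(x, 1.0)
  k[cmp$paramIdx] * xx[cmp$slots[, 1L]] * xx[cmp$slots[, 2L]] *
    xx[cmp$slots[, 3L]]
}

## RHS in hours: dx/dt = tscale * N v(x)
.rhs <- function(cmp, x, k) {
  as.vector(cmp$N %*% .rates(cmp, x, k)) * cmp$tscale
}

## analytic Jacobian of the RHS (hours), d(dx/dt)/dx
.rhsJacobian <- function(cmp, x, k) {
  xx <- c(x, 1.0)
  kk <- k[cmp$paramIdx]
  dv <- matrix(0.0, nrow = cmp$ne, ncol = cmp$ns)
  s1 <- cmp$slots[, 1L]; s2 <- cmp$slots[, 2L]; s3 <- cmp$slots[, 3L]
  for (m in 1:3) {
    sm <- cmp$slots[, m]
    live <- which(sm <= cmp$ns)
    if (!length(live)) next
    others <- switch(m, xx[s2] * xx[s3], xx[s1] * xx[s3], xx[s1] * xx[s2])
    contrib <- kk[live] * others[live]
    ij <- cbind(live, sm[live])
    dv[ij] <- dv[ij] + contrib
  }
  (cmp$N %*% dv) * cmp$tscale
}

#' Conserved moieties of a network
#'
#' Orthonormal basis of the left null space of the stoichiometry matrix:
#' vectors \eqn{w} with \eqn{w^T N = 0}, so \eqn{w^T x(t)} is constant along
#' every trajectory.
#'
#' @param net a [ReactionNetwork-class].
#' @param tol singular value tolerance for the rank decision.
#' @return numeric matrix with one column per conserved moiety (possibly zero
#'   columns), rows named by species.
#' @export
conservedMoieties <- function(net, tol = 1e-10) {
  N <- stoichiometryMatrix(net) * 1.0
  ## w^T N = 0  <=>  w orthogonal to the column space of N
  qrN <- qr(N)
  r <- qrN$rank
  Q <- qr.Q(qrN, complete = TRUE)
  W <- Q[, seq_len(nrow(N)) > r, drop = FALSE]
  rownames(W) <- rownames(N)
  W
}

## ---- JSON interchange ------------------------------------------------------

#' Read and write reaction networks as JSON
#'
#' The JSON schema mirrors the [ReactionNetwork-class] slots:
#' \code{\{species:[\{name, role, init\}], reactions:[\{reactants, products,
#' law, params, intermediate?\}], params:\{name: value\}, meta:\{...\}\}}.
#' \code{saveNetwork} followed by \code{loadNetwork} is the identity (up to
#' numeric printing precision, which is kept at full double precision).
#'
#' @param path file path.
#' @param net a [ReactionNetwork-class].
#' @return \code{loadNetwork}: a validated [ReactionNetwork-class];
#'   \code{saveNetwork}: the path, invisibly.
#' @export
loadNetwork <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path)
  for (fld in c("species", "reactions", "params"))
    if (is.null(obj[[fld]]))
      stop("network file lacks required field '", fld, "'", call. = FALSE)
  species <- data.frame(
    name = vapply(obj$species, function(s) as.character(s$name), ""),
    role = vapply(obj$species, function(s) as.character(s$role), ""),
    init = vapply(obj$species, function(s) as.numeric(s$init), 0),
    stringsAsFactors = FALSE)
  reactions <- lapply(obj$reactions, function(r) {
    out <- list(reactants = unlist(lapply(r$reactants, as.integer)),
                products = unlist(lapply(r$products, as.integer)),
                law = as.character(r$law),
                params = unlist(lapply(r$params, as.character)))
    if (is.null(out$reactants)) out$reactants <- integer(0)
    if (is.null(out$products)) out$products <- integer(0)
    if (!is.null(r$intermediate)) out$intermediate <- as.character(r$intermediate)
    out
  })
  params <- unlist(lapply(obj$params, as.numeric))
  meta <- .jsonToMeta(obj$meta)
  reactionNetwork(species, reactions, params, meta)
}

.jsonToMeta <- function(m) {
  if (is.null(m)) return(list())
  if (!is.null(m$observables))
    m$observables <- lapply(m$observables, function(o)
      list(num = unlist(o$num), den = unlist(o$den)))
  if (!is.null(m$dose_map))
    m$dose_map <- list(ligand = as.character(m$dose_map$ligand),
                       molecules_per_ng_ml =
                         as.numeric(m$dose_map$molecules_per_ng_ml))
  if (!is.null(m$time_unit)) m$time_unit <- as.character(m$time_unit)
  if (!is.null(m$source)) m$source <- as.character(m$source)
  m
}

#' @rdname loadNetwork
#' @export
saveNetwork <- function(net, path) {
  stopifnot(is(net, "ReactionNetwork"))
  obj <- list(
    species = lapply(seq_len(nrow(net@species)), function(i)
      as.list(net@species[i, ])),
    reactions = lapply(net@reactions, function(r) {
      out <- list(reactants = as.list(r$reactants),
                  products = as.list(r$products),
                  law = r$law, params = as.list(r$params))
      if (!is.null(r$intermediate)) out$intermediate <- r$intermediate
      out
    }),
    params = as.list(net@params),
    meta = net@meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
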