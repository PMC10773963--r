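#' @importFrom stats approx rnorm runif setNames sd var cor ks.test
#' @importFrom utils head tail write.csv read.csv combn
#' @importFrom tools md5sum
NULL

#' Define a single mass-action reaction
#'
#' A reaction is specified by its reactant stoichiometry, catalytic
#' modifiers and product stoichiometry.  Its rate is
#' \eqn{k \prod_r [r]^{s_r} \prod_m [m]} where `k` is the value of the
#' named rate constant, `r` runs over reactants and `m` over modifiers.
#' Modifiers enter the rate law but are not consumed.
#'
#' @param name short identifier, unique within a model
#' @param rate name of the rate constant in the model's parameter set
#' @param reactants named numeric vector of reactant stoichiometries
#'   (may be empty for synthesis reactions)
#' @param modifiers character vector of catalyst species
#' @param products named numeric vector of product stoichiometries
#' @return an object of class `ccReaction`
#' @export
reaction <- function(name, rate, reactants = numeric(0),
                     modifiers = character(0), products = numeric(0)) {
  if (length(reactants) && is.null(names(reactants)))
    stop("reactants must be a named vector")
  if (length(products) && is.null(names(products)))
    stop("products must be a named vector")
  structure(list(name = name, rate = rate,
                 reactants = reactants, modifiers = modifiers,
                 products = products),
            class = "ccReaction")
}

#' Construct a reaction network model
#'
#' Builds a deterministic mass-action ODE model from a reaction list.
#' The right-hand side is compiled once into index tables so repeated
#' evaluation during integration is cheap.
#'
#' @param name model name
#' @param species ordered character vector of species names
#' @param reactions list of [reaction()] objects
#' @param parameters named numeric vector of rate constants (>= 0, finite)
#' @param initial named numeric vector of default initial concentrations
#'   (arbitrary units); must cover all species
#' @param conserved named list of species subsets whose summed
#'   concentration is structurally constant
#' @param clamped character vector of input species held constant during
#'   integration (their derivative is forced to zero); their level is set
#'   through the initial condition or a perturbation schedule
#' @return an object of class `ccModel`
#' @export
reaction_model <- function(name, species, reactions, parameters, initial,
                           conserved = list(), clamped = character(0)) {
  stopifnot(is.character(species), length(species) >= 1)
  if (anyDuplicated(species)) stop("duplicate species names")
  if (!all(names(initial) %in% species) || !all(species %in% names(initial)))
    stop("initial conditions must cover exactly the model species")
  if (any(!is.finite(parameters))) stop("parameters must be finite")
  if (any(parameters < 0)) stop("rate constants must be >= 0")
  for (rx in reactions) {
    refd <- c(names(rx$reactants), rx$modifiers, names(rx$products))
    bad <- setdiff(refd, species)
    if (length(bad))
      stop("reaction '", rx$name, "' references unknown species: ",
           paste(bad, collapse = ", "))
    if (!rx$rate %in% names(parameters))
      stop("reaction '", rx$name, "' references unknown rate constant '",
           rx$rate, "'")
  }
  bad <- setdiff(clamped, species)
  if (length(bad)) stop("unknown clamped species: ", paste(bad, collapse = ", "))
  for (g in conserved) {
    bad <- setdiff(g, species)
    if (length(bad)) stop("conserved group references unknown species: ",
                          paste(bad, collapse = ", "))
  }
  m <- structure(list(name = name, species = species, reactions = reactions,
                      parameters = parameters,
                      initial = initial[species],
                      conserved = conserved, clamped = clamped),
                 class = "ccModel")
  m$compiled <- compile_network(m)
  m
}

# Build index tables: stoichiometry matrix (species x reactions) and a
# factor-index matrix so that reaction rates can be computed as
# k * state[f1] * state[f2] * ... with a padding entry fixed at 1.
compile_network <- function(model) {
  ns <- length(model$species)
  nr <- length(model$reactions)
  S <- matrix(0, ns, nr, dimnames = list(model$species, NULL))
  factors <- vector("list", nr)
  for (j in seq_len(nr)) {
    rx <- model$reactions[[j]]
    for (sp in names(rx$reactants)) S[sp, j] <- S[sp, j] - rx$reactants[[sp]]
    for (sp in names(rx$products))  S[sp, j] <- S[sp, j] + rx$products[[sp]]
    f <- c(rep(names(rx$reactants), times = rx$reactants), rx$modifiers)
    factors[[j]] <- match(f, model$species)
  }
  maxf <- max(1L, vapply(factors, length, 1L))
  fidx <- matrix(ns + 1L, nr, maxf)   # ns+1 indexes the padding value 1
  for (j in seq_len(nr)) {
    f <- factors[[j]]
    if (length(f)) fidx[j, seq_along(f)] <- f
  }
  rate_names <- vapply(model$reactions, function(r) r$rate, "")
  list(S = S, fidx = fidx, rate_names = rate_names, n_species = ns)
}

#' @export
print.ccModel <- function(x, ...) {
  cat("<ccModel> ", x$name, "\n", sep = "")
  cat("  species   : ", length(x$species), "\n", sep = "")
  cat("  reactions : ", length(x$reactions), "\n", sep = "")
  cat("  parameters: ", length(x$parameters), "\n", sep = "")
  if (length(x$clamped))
    cat("  clamped   : ", paste(x$clamped, collapse = ", "), "\n", sep = "")
  if (length(x$conserved))
    cat("  conserved : ", paste(names(x$conserved), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Construct a model from an arbitrary right-hand-side function
#'
#' For models that are not mass-action reaction networks (normal forms,
#' textbook test systems).  Such models support simulation, equilibrium
#' refinement and continuation, but not the structural transforms
#' (knockout, compartmentalisation, SBML export).
#'
#' @param name model name
#' @param species ordered character vector of state-variable names
#' @param rhs function(state, parameters, time) returning the derivative
#'   vector
#' @param parameters named numeric vector (values may be any sign)
#' @param initial named numeric vector over `species`
#' @param conserved,clamped as in [reaction_model()]
#' @return a `ccModel`
#' @export
custom_model <- function(name, species, rhs, parameters, initial,
                         conserved = list(), clamped = character(0)) {
  stopifnot(is.function(rhs))
  structure(list(name = name, species = species, reactions = list(),
                 parameters = parameters, initial = initial[species],
                 conserved = conserved, clamped = clamped,
                 custom_rhs = rhs),
            class = "ccModel")
}

#' Evaluate reaction rates at a state
#' @keywords internal
reaction_rates <- function(model, state, parameters = model$parameters) {
  cm <- model$compiled
  k <- unname(parameters[cm$rate_names])
  ext <- c(unname(state[model$species]), 1.0)
  v <- k
  for (j in seq_len(ncol(cm$fidx))) v <- v * ext[cm$fidx[, j]]
  v
}

#' Right-hand side of the model ODE system
#'
#' @param model a `ccModel`
#' @param state named (or model-ordered) numeric state vector
#' @param parameters parameter values (defaults to the model's)
#' @param clamped_extra additional species to hold constant
#' @return named derivative vector (concentration per minute)
#' @export
model_rhs <- function(model, state, parameters = model$parameters,
                      clamped_extra = character(0)) {
  if (!is.null(model$custom_rhs)) {
    dx <- model$custom_rhs(setNames(unname(state[model$species]),
                                    model$species), parameters, 0)
  } else {
    v <- reaction_rates(model, state, parameters)
    dx <- drop(model$compiled$S %*% v)
  }
  cl <- union(model$clamped, clamped_extra)
  if (length(cl)) dx[match(cl, model$species)] <- 0
  names(dx) <- model$species
  dx
}

# Closure suitable for deSolve: precomputes everything invariant.
make_desolve_rhs <- function(model, parameters, clamped_extra = character(0)) {
  if (!is.null(model$custom_rhs)) {
    cl <- union(model$clamped, clamped_extra)
    ci <- match(cl, model$species)
    rhs <- model$custom_rhs
    spn <- model$species
    return(function(t, y, p) {
      dx <- rhs(setNames(y, spn), parameters, t)
      if (length(ci)) dx[ci] <- 0
      list(unname(dx))
    })
  }
  cm <- model$compiled
  k <- unname(parameters[cm$rate_names])
  if (anyNA(k)) stop("missing rate constants: ",
                     paste(setdiff(cm$rate_names, names(parameters)), collapse = ", "))
  S <- cm$S
  cl <- union(model$clamped, clamped_extra)
  if (length(cl)) S[match(cl, model$species), ] <- 0
  fidx <- cm$fidx
  nf <- ncol(fidx)
  function(t, y, p) {
    ext <- c(y, 1.0)
    v <- k
    for (j in seq_len(nf)) v <- v * ext[fidx[, j]]
    list(drop(S %*% v))
  }
}

#' Sum the declared conserved groups at a state
#'
#' @param model a `ccModel`
#' @param state named state vector (or a matrix with species columns, in
#'   which case a matrix of totals is returned)
#' @return named numeric vector (or matrix) of group totals
#' @export
conserved_totals <- function(model, state) {
  if (length(model$conserved) == 0)
    return(setNames(numeric(0), character(0)))
  if (is.matrix(state)) {
    out <- vapply(model$conserved,
                  function(g) rowSums(state[, g, drop = FALSE]),
                  numeric(nrow(state)))
    return(out)
  }
  vapply(model$conserved, function(g) sum(state[g]), 0)
}

#' Replace selected parameter values
#' @param model a `ccModel`
#' @param values named numeric vector of parameter (or clamped-input
#'   initial) overrides
#' @return the modified model
#' @export
set_parameters <- function(model, values) {
  pk <- intersect(names(values), names(model$parameters))
  ik <- intersect(names(values), names(model$initial))
  unknown <- setdiff(names(values), c(pk, ik))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  model$parameters[pk] <- values[pk]
  model$initial[ik] <- values[ik]
  model
}

# Names of rate constants of pure synthesis reactions (no reactants)
# producing `target`; used for knockout semantics.
synthesis_constants <- function(model, target) {
  out <- character(0)
  for (rx in model$reactions) {
    if (length(rx$reactants) == 0 && target %in% names(rx$products))
      out <- c(out, rx$rate)
  }
  unique(out)
}
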