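#' Describe a perturbation of a model run
#'
#' Three kinds are supported.  `knockout` zeroes every pure-synthesis rate
#' constant of the target species (degradation stays intact, so existing
#' protein decays away).  `clamp_species` holds a species at given levels
#' from given switch times onwards, emulating e.g. mitogen withdrawal by
#' setting CycD to 0 at a chosen time.  `schedule` assigns piecewise
#' constant values to a rate constant.
#'
#' @param kind one of `"knockout"`, `"clamp_species"`, `"schedule"`
#' @param target species name (`knockout`, `clamp_species`) or rate
#'   constant name (`schedule`)
#' @param values levels taken at the corresponding `times`
#' @param times strictly increasing switch times (min); defaults to 0
#' @return an object of class `ccPerturbation`
#' @export
perturbation <- function(kind = c("knockout", "clamp_species", "schedule"),
                         target, values = NULL, times = 0) {
  kind <- match.arg(kind)
  if (kind != "knockout") {
    if (is.null(values)) stop("'values' required for ", kind)
    if (length(values) != length(times))
      stop("'values' and 'times' must have equal length")
    if (length(times) > 1 && any(diff(times) <= 0))
      stop("'times' must be strictly increasing")
  }
  structure(list(kind = kind, target = target, values = values, times = times),
            class = "ccPerturbation")
}

#' Apply a perturbation to a parameter set
#'
#' Knockouts zero the synthesis constants of the target species and
#' return the modified parameter set; the input set is left untouched.
#' Time-dependent perturbations (`clamp_species`, `schedule`) do not
#' modify parameters here — they are resolved segment by segment inside
#' [simulate()] — so they return the set unchanged.
#'
#' @param params named numeric parameter set
#' @param spec a [perturbation()]
#' @param model the `ccModel` the perturbation refers to (needed to
#'   locate synthesis constants of a species)
#' @return a new parameter set
#' @export
apply_perturbation <- function(params, spec, model) {
  stopifnot(inherits(spec, "ccPerturbation"))
  if (spec$kind == "knockout") {
    if (spec$target %in% names(params)) {
      params[spec$target] <- 0
      return(params)
    }
    if (!spec$target %in% model$species)
      stop("unknown knockout target '", spec$target, "'")
    kc <- synthesis_constants(model, spec$target)
    if (length(kc) == 0)
      return(params)  # nothing synthesises it: identity on dynamics
    params[kc] <- 0
    return(params)
  }
  if (spec$kind == "schedule" && !spec$target %in% names(params))
    stop("unknown rate constant '", spec$target, "'")
  if (spec$kind == "clamp_species" && !spec$target %in% model$species)
    stop("unknown species '", spec$target, "'")
  params
}

#' Simulate a reaction model
#'
#' Integrates the mass-action ODE system with a stiff solver
#' (`deSolve::lsoda`, rtol 1e-8 / atol 1e-10 by default — the switch
#' dynamics are fast against slow cyclin accumulation).  Perturbations
#' are applied by splitting the time axis at their switch times and
#' restarting the integration with the state carried over continuously.
#' Metaphase/anaphase transitions are annotated as downward crossings of
#' total cyclin B through a fraction of its cycle maximum (with a
#' hysteresis band to avoid chatter).
#'
#' @param model a `ccModel`
#' @param params named parameter overrides (merged onto the model's)
#' @param perturbations list of [perturbation()] objects
#' @param t_end simulation end time (min), > 0
#' @param dt_out output grid spacing (min)
#' @param init named initial-condition overrides
#' @param rtol,atol solver tolerances
#' @param method deSolve integrator name
#' @return an object of class `ccTrajectory` with fields `times`,
#'   `states` (time x species matrix), `events` (M/A transition times),
#'   `model_name` and `param_hash`
#' @export
simulate_model <- function(model, params = NULL, perturbations = list(),
                           t_end, dt_out = 1, init = NULL,
                           rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(inherits(model, "ccModel"), t_end > 0)
  p <- model$parameters
  if (!is.null(params)) {
    unknown <- setdiff(names(params), names(p))
    if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
    p[names(params)] <- params
  }
  y0 <- model$initial
  if (!is.null(init)) {
    unknown <- setdiff(names(init), model$species)
    if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
    y0[names(init)] <- init
  }
  if (!is.list(perturbations)) perturbations <- list(perturbations)
  for (sp in perturbations) p <- apply_perturbation(p, sp, model)

  # switch times from time-dependent perturbations
  sw <- sort(unique(unlist(lapply(perturbations, function(s)
    if (s$kind %in% c("clamp_species", "schedule")) s$times else NULL))))
  sw <- sw[sw > 0 & sw < t_end]
  seg_bounds <- c(0, sw, t_end)

  grid <- seq(0, t_end, by = dt_out)
  if (tail(grid, 1) < t_end) grid <- c(grid, t_end)
  out_states <- matrix(NA_real_, length(grid), length(model$species),
                       dimnames = list(NULL, model$species))
  state <- y0
  extra_clamped <- character(0)
  filled <- 0L
  for (i in seq_len(length(seg_bounds) - 1)) {
    a <- seg_bounds[i]; b <- seg_bounds[i + 1]
    pp <- p
    for (sp in perturbations) {
      if (sp$kind == "clamp_species") {
        active <- which(sp$times <= a)
        if (length(active)) {
          state[sp$target] <- sp$values[max(active)]
          extra_clamped <- union(extra_clamped, sp$target)
        }
      } else if (sp$kind == "schedule") {
        active <- which(sp$times <= a)
        if (length(active)) pp[sp$target] <- sp$values[max(active)]
      }
    }
    seg_grid <- grid[grid > a & grid <= b]
    tt <- unique(c(a, seg_grid, b))
    rhs <- make_desolve_rhs(model, pp, extra_clamped)
    sol <- deSolve::ode(y = unname(state[model$species]), times = tt,
                        func = rhs, parms = NULL, method = method,
                        rtol = rtol, atol = atol, maxsteps = 50000)
    if (nrow(sol) < length(tt)) {
      e <- simpleError(sprintf(
        "solver failed in segment [%g, %g]; last good time %g",
        a, b, sol[nrow(sol), 1]))
      e$last_good_time <- sol[nrow(sol), 1]
      e$last_good_state <- setNames(sol[nrow(sol), -1], model$species)
      stop(e)
    }
    keep <- match(seg_grid, sol[, 1])
    if (i == 1) {
      out_states[1, ] <- sol[1, -1]
      filled <- 1L
    }
    n <- length(seg_grid)
    if (n) {
      out_states[filled + seq_len(n), ] <- sol[keep, -1, drop = FALSE]
      filled <- filled + n
    }
    state <- setNames(sol[nrow(sol), -1], model$species)
  }
  states <- out_states[seq_len(filled), , drop = FALSE]
  times <- grid[seq_len(filled)]

  events <- numeric(0)
  ma_sp <- intersect(model$ma_species %||% character(0), model$species)
  if (length(ma_sp))
    events <- detect_ma_events(times, rowSums(states[, ma_sp, drop = FALSE]))

  structure(list(times = times, states = states, events = events,
                 model_name = model$name, param_hash = param_hash(p)),
            class = "ccTrajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

param_hash <- function(p) {
  x <- c(p, length(p))
  sprintf("%08x", as.integer(sum((abs(x) * 1e5) %% 97) * 1e4) %% .Machine$integer.max)
}

#' Detect metaphase/anaphase transition events in a cyclin-B signal
#'
#' An event is a downward crossing of the signal through
#' `frac * max(signal)`.  The detector is re-armed only once the signal
#' has risen above `rearm * max(signal)`, so noise near the threshold
#' cannot produce spurious events.  Crossing times are linearly
#' interpolated between grid points.
#'
#' @param times time grid (min)
#' @param signal total cyclin B (or comparable division marker)
#' @param frac threshold as fraction of the cycle maximum (default 0.25)
#' @param rearm re-arming level as fraction of the cycle maximum
#' @return numeric vector of event times
#' @export
detect_ma_events <- function(times, signal, frac = 0.25, rearm = 0.5) {
  stopifnot(length(times) == length(signal))
  mx <- max(signal)
  if (!is.finite(mx) || mx <= 0) return(numeric(0))
  thr <- frac * mx
  hi <- rearm * mx
  armed <- FALSE   # arm only on an upward crossing, so a decaying
  out <- numeric(0) # post-division tail is never counted as an event
  for (i in 2:length(signal)) {
    if (!armed && signal[i] > hi && signal[i] > signal[i - 1]) armed <- TRUE
    if (armed && signal[i - 1] > thr && signal[i] <= thr) {
      w <- (signal[i - 1] - thr) / (signal[i - 1] - signal[i])
      out <- c(out, times[i - 1] + w * (times[i] - times[i - 1]))
      armed <- FALSE
    }
  }
  out
}

#' @export
print.ccTrajectory <- function(x, ...) {
  cat("<ccTrajectory> ", x$model_name, ": ", length(x$times),
      " time points x ", ncol(x$states), " species, ",
      length(x$events), " M/A events\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ccTrajectory <- function(x, ...) {
  data.frame(time_min = x$times, x$states, check.names = FALSE)
}

#' Oscillation period from annotated M/A events
#'
#' The first inter-event interval is discarded (the initial condition is
#' generally off the limit cycle).
#'
#' @param traj a `ccTrajectory` with at least 3 events
#' @return list with `period` (min), `cv` (coefficient of variation of
#'   the retained intervals) and `events`
#' @export
trajectory_period <- function(traj) {
  ev <- traj$events
  if (length(ev) < 3) stop("no sustained oscillation: fewer than 3 M/A events")
  iv <- diff(ev)[-1]
  if (!length(iv)) iv <- diff(ev)
  list(period = mean(iv), cv = stats::sd(iv) / mean(iv), events = ev)
}

#' Duplicate a model into nuclear and cytoplasmic compartments
#'
#' Every species is split into `<name>_nuc` and `<name>_cyt` copies.
#' Reactions act within a compartment and are duplicated per compartment;
#' synthesis reactions (no reactants) can be assigned to one compartment
#' through `location`, and are duplicated symmetrically by default.
#' First-order transport reactions (import: cytoplasm to nucleus; export:
#' the reverse) are added for the species listed in `transport`, with rate
#' constants `kImp_<species>` / `kExp_<species>`.  Conserved groups become
#' sums over both compartments.  Default initial conditions split each
#' species' mass equally.
#'
#' @param model a `ccModel`
#' @param transport named list/vector mapping species to
#'   `c(import, export)` rate constants (1/min, >= 0)
#' @param location optional named character vector assigning synthesis of
#'   a species to `"nuc"`, `"cyt"` or `"both"` (default `"both"`)
#' @return a compartmental `ccModel`
#' @export
compartmentalise <- function(model, transport = list(), location = NULL) {
  bad <- setdiff(names(transport), model$species)
  if (length(bad)) stop("transport keys not in model: ", paste(bad, collapse = ", "))
  for (sp in names(transport)) {
    r <- transport[[sp]]
    if (length(r) != 2 || any(r < 0)) stop("transport rates for ", sp,
                                           " must be two non-negative numbers")
  }
  comp <- c("nuc", "cyt")
  species <- as.vector(vapply(model$species,
                              function(s) paste(s, comp, sep = "_"),
                              character(2)))
  reactions <- list()
  params <- model$parameters
  suffix <- function(v, cc) {
    if (length(v) == 0) return(v)
    setNames(unname(v), paste(names(v), cc, sep = "_"))
  }
  for (rx in model$reactions) {
    is_syn <- length(rx$reactants) == 0
    where <- comp
    if (is_syn && !is.null(location) && length(names(rx$products))) {
      loc <- location[names(rx$products)[1]]
      if (!is.na(loc) && loc %in% comp) where <- loc
    }
    for (cc in where) {
      reactions[[length(reactions) + 1]] <- reaction(
        name = paste(rx$name, cc, sep = "_"), rate = rx$rate,
        reactants = suffix(rx$reactants, cc),
        modifiers = if (length(rx$modifiers)) paste(rx$modifiers, cc, sep = "_")
                    else character(0),
        products = suffix(rx$products, cc))
    }
  }
  for (sp in names(transport)) {
    r <- transport[[sp]]
    kin <- paste0("kImp_", sp); kout <- paste0("kExp_", sp)
    params[kin] <- r[[1]]; params[kout] <- r[[2]]
    reactions[[length(reactions) + 1]] <- reaction(
      paste0("imp_", sp), kin,
      reactants = setNames(1, paste0(sp, "_cyt")),
      products = setNames(1, paste0(sp, "_nuc")))
    reactions[[length(reactions) + 1]] <- reaction(
      paste0("exp_", sp), kout,
      reactants = setNames(1, paste0(sp, "_nuc")),
      products = setNames(1, paste0(sp, "_cyt")))
  }
  initial <- setNames(rep(model$initial / 2, each = 2), species)
  conserved <- lapply(model$conserved, function(g)
    as.vector(vapply(g, function(s) paste(s, comp, sep = "_"), character(2))))
  clamped <- as.vector(vapply(model$clamped,
                              function(s) paste(s, comp, sep = "_"), character(2)))
  m <- reaction_model(paste0(model$name, "_compartmental"), species, reactions,
                      params, initial, conserved, clamped)
  if (!is.null(model$ma_species))
    m$ma_species <- as.vector(vapply(model$ma_species,
                                     function(s) paste(s, comp, sep = "_"),
                                     character(2)))
  m
}
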