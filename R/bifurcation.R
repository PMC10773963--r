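# Steady-state continuation and stability analysis for the toggle-switch
# submodels.  Reaction networks with conservation laws have singular
# Jacobians in full coordinates, so equilibria are solved in reduced
# coordinates: one species per conserved group is eliminated and
# recovered from the group total.

# Reduction bookkeeping: pick one dependent species per conserved group
# (a species belonging to exactly that one group), drop clamped inputs.
reduction_info <- function(model, clamped_extra = character(0)) {
  clamped <- union(model$clamped, clamped_extra)
  dep <- character(0)
  for (lab in names(model$conserved)) {
    g <- setdiff(model$conserved[[lab]], clamped)
    in_one <- vapply(g, function(s)
      sum(vapply(model$conserved, function(h) s %in% h, TRUE)) == 1, TRUE)
    cand <- setdiff(g[in_one], dep)
    if (!length(cand))
      stop("cannot reduce conserved group '", lab, "'")
    dep <- c(dep, cand[[1]])
  }
  names(dep) <- names(model$conserved)
  free <- setdiff(model$species, c(dep, clamped))
  list(free = free, dep = dep, clamped = clamped)
}

# Reconstruct the full state from free coordinates, totals and clamps.
expand_state <- function(model, red, x, totals, fixed) {
  state <- setNames(numeric(length(model$species)), model$species)
  state[red$free] <- x
  state[names(fixed)] <- fixed
  for (lab in names(red$dep)) {
    g <- model$conserved[[lab]]
    others <- setdiff(g, red$dep[[lab]])
    state[red$dep[[lab]]] <- totals[[lab]] - sum(state[others])
  }
  state
}

reduced_rhs <- function(model, red, params, totals, fixed) {
  function(x) {
    state <- expand_state(model, red, x, totals, fixed)
    model_rhs(model, state, params)[red$free]
  }
}

num_jacobian <- function(f, x, eps = 1e-7) {
  f0 <- f(x)
  n <- length(x); m <- length(f0)
  J <- matrix(0, m, n)
  for (j in seq_len(n)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (f(xp) - f0) / h
  }
  J
}

#' Refine an equilibrium of a reaction model by Newton iteration
#'
#' Solves for a steady state in conservation-reduced coordinates (the
#' totals of conserved groups are read off the guess).  Clamped input
#' species keep their guessed value.
#'
#' @param model a `ccModel`
#' @param guess named full state vector used as starting point
#' @param params parameter overrides
#' @param tol infinity-norm tolerance on the reduced right-hand side
#' @param max_iter maximum Newton iterations
#' @return list with `state` (full equilibrium state), `converged`,
#'   `residual`, and `stability` (`"stable"`, `"unstable"` or
#'   `"marginal"` from the reduced Jacobian's eigenvalues)
#' @export
find_equilibrium <- function(model, guess, params = NULL,
                             tol = 1e-10, max_iter = 50) {
  p <- model$parameters
  if (!is.null(params)) p[names(params)] <- params
  red <- reduction_info(model)
  totals <- conserved_totals(model, guess)
  fixed <- guess[red$clamped]
  f <- reduced_rhs(model, red, p, totals, fixed)
  x <- guess[red$free]
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    fx <- f(x)
    if (any(!is.finite(fx))) break
    if (max(abs(fx)) < tol) { conv <- TRUE; break }
    J <- num_jacobian(f, x)
    step <- tryCatch(solve(J, fx), error = function(e)
      stop("singular Jacobian at state [",
           paste(signif(x, 4), collapse = ", "), "]"))
    # damped Newton: halve until the residual does not blow up
    lam <- 1
    repeat {
      xn <- x - lam * step
      fn <- f(xn)
      if (all(is.finite(fn)) &&
          (max(abs(fn)) < max(abs(fx)) || lam < 1e-4)) break
      lam <- lam / 2
    }
    x <- xn
  }
  fx <- f(x)
  if (any(!is.finite(fx))) {
    state <- expand_state(model, red, x, totals, fixed)
    return(list(state = state, converged = FALSE, residual = Inf,
                stability = "marginal", eigenvalues = complex(0)))
  }
  state <- expand_state(model, red, x, totals, fixed)
  J <- num_jacobian(f, x)
  ev <- eigen(J, only.values = TRUE)$values
  mx <- max(Re(ev))
  stability <- if (mx < -1e-8) "stable" else if (mx > 1e-8) "unstable" else "marginal"
  list(state = state, converged = conv && max(abs(fx)) < tol,
       residual = max(abs(fx)), stability = stability, eigenvalues = ev)
}

# Set the bifurcation parameter: a rate constant, a clamped species
# level, or the total of a conserved group (state rescaled accordingly).
set_bif_value <- function(model, params, state, name, value) {
  if (name %in% names(params)) {
    params[name] <- value
  } else if (name %in% model$clamped) {
    state[name] <- value
  } else if (name %in% names(model$conserved)) {
    g <- model$conserved[[name]]
    tot <- sum(state[g])
    if (tot > 0) state[g] <- state[g] * value / tot
    else state[g[length(g)]] <- value
  } else stop("unknown bifurcation parameter '", name, "'")
  list(params = params, state = state)
}

#' Follow an equilibrium branch over a parameter range
#'
#' Natural-parameter continuation: the bifurcation parameter is stepped
#' across `range` and the equilibrium re-solved from the previous state.
#' When Newton fails (or the branch changes discontinuously), the step is
#' halved; after `max_halving` failures the branch is terminated — a fold
#' has been passed.  Each accepted point carries a stability flag and a
#' physicality flag (negative concentrations are retained but flagged).
#'
#' @param model a `ccModel`
#' @param bif_param name of a rate constant, clamped input species, or
#'   conserved-group label
#' @param range numeric length-2: parameter interval to sweep (either
#'   direction)
#' @param n_steps number of steps across the range
#' @param start named full state near the equilibrium at `range[1]`
#' @param params parameter overrides
#' @param max_halving step halvings before declaring the branch ended
#' @param jump_tol relative state-jump tolerance used to detect that the
#'   solver slid onto a different branch
#' @return an `ccBranch` object: data frame `points` (param, stability,
#'   physical, one column per species) and `ended_early` flag
#' @export
continue_branch <- function(model, bif_param, range, n_steps = 100,
                            start = model$initial, params = NULL,
                            max_halving = 12, jump_tol = 0.2) {
  p <- model$parameters
  if (!is.null(params)) p[names(params)] <- params
  sb <- set_bif_value(model, p, start, bif_param, range[1])
  eq <- find_equilibrium(model, sb$state, sb$params)
  if (!eq$converged)
    stop("no equilibrium found at the start of the range")
  pts <- list()
  add_point <- function(val, eq) {
    pts[[length(pts) + 1]] <<- c(param = val,
                                 stable = eq$stability == "stable",
                                 physical = all(eq$state > -1e-9),
                                 eq$state)
  }
  add_point(range[1], eq)
  # state-jump scale: the branch's own magnitude or the parameter span,
  # whichever is larger (a zero start state must not make every
  # parameter-proportional change look like a branch switch)
  scale0 <- max(max(abs(eq$state)), abs(range[2] - range[1]), 1e-3)
  cur_val <- range[1]
  cur_eq <- eq
  h <- (range[2] - range[1]) / n_steps
  ended <- FALSE
  while (if (h > 0) cur_val < range[2] - 1e-12 else cur_val > range[2] + 1e-12) {
    step <- h
    nhalf <- 0
    repeat {
      target <- cur_val + step
      if ((h > 0 && target > range[2]) || (h < 0 && target < range[2]))
        target <- range[2]
      sb <- set_bif_value(model, p, cur_eq$state, bif_param, target)
      eq_try <- find_equilibrium(model, sb$state, sb$params)
      jump <- max(abs(eq_try$state - cur_eq$state)) / scale0
      ok <- eq_try$converged && jump < jump_tol * max(1, abs(step / h))
      if (ok) { cur_val <- target; cur_eq <- eq_try; add_point(target, eq_try); break }
      nhalf <- nhalf + 1
      if (nhalf > max_halving) { ended <- TRUE; break }
      step <- step / 2
    }
    if (ended) break
  }
  points <- as.data.frame(do.call(rbind, pts))
  structure(list(points = points, bif_param = bif_param,
                 species = model$species, ended_early = ended,
                 model_name = model$name),
            class = "ccBranch")
}

#' @export
print.ccBranch <- function(x, ...) {
  cat("<ccBranch> ", x$model_name, " over ", x$bif_param, ": ",
      nrow(x$points), " points [",
      signif(min(x$points$param), 4), ", ", signif(max(x$points$param), 4),
      "]", if (x$ended_early) " (fold-terminated)", "\n", sep = "")
  invisible(x)
}

#' Locate fold points from a pair of continuation branches
#'
#' A natural-parameter branch ends where Newton continuation fails: the
#' fold lies between the last accepted parameter value and the step
#' target.  The endpoint is refined by bisection on "does an equilibrium
#' continuous with the branch still exist".  The bistable window is the
#' parameter interval between the upper branch's fold and the lower
#' branch's fold.
#'
#' @param upper,lower `ccBranch` objects from the same model swept in
#'   opposite directions (each terminated at its fold)
#' @param model the `ccModel` the branches belong to
#' @param params parameter overrides used for the branches
#' @param tol bisection tolerance on the parameter
#' @return list of fold points, each with `param`, `state` and `side`
#'   (`"upper"`/`"lower"` branch); empty if a branch did not terminate
#' @export
detect_folds <- function(upper, lower, model, params = NULL, tol = 1e-4) {
  out <- list()
  for (side in c("upper", "lower")) {
    br <- if (side == "upper") upper else lower
    if (!br$ended_early) next
    fp <- refine_branch_end(model, br, params, tol)
    fp$side <- side
    out[[length(out) + 1]] <- fp
  }
  out
}

refine_branch_end <- function(model, branch, params = NULL, tol = 1e-4) {
  p <- model$parameters
  if (!is.null(params)) p[names(params)] <- params
  pts <- branch$points
  last <- pts[nrow(pts), ]
  state <- setNames(unlist(last[branch$species]), branch$species)
  a <- last$param
  dir <- sign(a - pts$param[1])
  if (dir == 0) dir <- 1
  span <- diff(range(pts$param))
  b <- a + dir * max(span / 5, 10 * tol)
  scale0 <- max(abs(state), 1e-3)
  exists_at <- function(val, ref_state) {
    sb <- set_bif_value(model, p, ref_state, branch$bif_param, val)
    eq <- find_equilibrium(model, sb$state, sb$params)
    ok <- eq$converged && max(abs(eq$state - ref_state)) / scale0 < 0.25
    list(ok = ok, eq = eq)
  }
  cur_state <- state
  while (abs(b - a) > tol) {
    mid <- (a + b) / 2
    r <- exists_at(mid, cur_state)
    if (r$ok) { a <- mid; cur_state <- r$eq$state } else b <- mid
  }
  list(param = (a + b) / 2, state = cur_state)
}

#' Detect Hopf bifurcations along a branch
#'
#' Scans the branch for sign changes of the largest real part of the
#' reduced Jacobian's eigenvalues with a nonzero imaginary part (a
#' complex-conjugate pair crossing the imaginary axis), then refines
#' each crossing by bisection.
#'
#' @param branch a `ccBranch`
#' @param model the `ccModel`
#' @param params parameter overrides
#' @param tol bisection tolerance on the parameter
#' @return numeric vector of parameter values (possibly empty)
#' @export
detect_hopf <- function(branch, model, params = NULL, tol = 1e-6) {
  p <- model$parameters
  if (!is.null(params)) p[names(params)] <- params
  pts <- branch$points
  lead_ev <- function(val, ref_state) {
    sb <- set_bif_value(model, p, ref_state, branch$bif_param, val)
    eq <- find_equilibrium(model, sb$state, sb$params)
    ev <- eq$eigenvalues
    i <- which.max(Re(ev))
    list(re = Re(ev[i]), im = abs(Im(ev[i])), state = eq$state)
  }
  out <- numeric(0)
  for (i in seq_len(nrow(pts) - 1)) {
    s1 <- setNames(unlist(pts[i, branch$species]), branch$species)
    e1 <- lead_ev(pts$param[i], s1)
    e2 <- lead_ev(pts$param[i + 1], s1)
    if (!length(e1$re) || !length(e2$re) || anyNA(c(e1$re, e2$re))) next
    if (sign(e1$re) * sign(e2$re) < 0 && (e1$im > 1e-12 || e2$im > 1e-12)) {
      a <- pts$param[i]; b <- pts$param[i + 1]
      fa <- e1$re; ref <- e1$state
      while (abs(b - a) > tol) {
        mid <- (a + b) / 2
        em <- lead_ev(mid, ref)
        ref <- em$state
        if (sign(em$re) == sign(fa)) a <- mid else b <- mid
      }
      out <- c(out, (a + b) / 2)
    }
  }
  out
}

#' Summarise a limit cycle from a simulated trajectory
#'
#' @param traj a `ccTrajectory` containing at least 3 annotated M/A
#'   events
#' @param transient_periods number of initial inter-event intervals to
#'   discard before measuring
#' @return a `LimitCycleSummary` list: `period` (min, mean inter-event
#'   interval), `period_cv`, `amplitude` (per-species min/max over the
#'   post-transient part) and `events`
#' @export
limit_cycle_summary <- function(traj, transient_periods = 1) {
  ev <- traj$events
  if (length(ev) < 3) stop("no sustained oscillation: fewer than 3 M/A events")
  iv <- diff(ev)
  if (length(iv) > transient_periods) iv <- iv[-seq_len(transient_periods)]
  keep <- traj$times >= ev[min(transient_periods + 1, length(ev))]
  s <- traj$states[keep, , drop = FALSE]
  amplitude <- data.frame(species = colnames(s),
                          min = apply(s, 2, min), max = apply(s, 2, max),
                          row.names = NULL)
  list(period = mean(iv), period_cv = stats::sd(iv) / mean(iv),
       amplitude = amplitude, events = ev)
}

#' Hysteresis analysis of a bistable switch by slow parameter sweeps
#'
#' Quasi-static forward and backward sweeps: at each grid value the model
#' is relaxed by simulation from the previous end state.  Used as the
#' simulation oracle that bistable windows reported by continuation must
#' reproduce.
#'
#' @param model a `ccModel`
#' @param bif_param rate constant, clamped species or conserved-group
#'   label
#' @param values parameter grid (forward order; the backward sweep
#'   reverses it)
#' @param watch species whose level is recorded
#' @param t_relax relaxation time per grid point (min)
#' @param start optional starting state
#' @param params parameter overrides
#' @return data frame with `param`, `forward`, `backward` columns
#' @export
hysteresis_sweep <- function(model, bif_param, values, watch,
                             t_relax = 3000, start = model$initial,
                             params = NULL) {
  p0 <- model$parameters
  if (!is.null(params)) p0[names(params)] <- params
  run <- function(grid) {
    state <- start
    out <- numeric(length(grid))
    for (i in seq_along(grid)) {
      sb <- set_bif_value(model, p0, state, bif_param, grid[i])
      tr <- simulate_model(model, params = sb$params,
                           t_end = t_relax, dt_out = t_relax / 4,
                           init = sb$state)
      state <- tr$states[nrow(tr$states), ]
      out[i] <- state[watch]
    }
    out
  }
  fw <- run(values)
  bw <- rev(run(rev(values)))
  data.frame(param = values, forward = fw, backward = bw)
}
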