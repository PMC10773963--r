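# Parameter estimation: affine antibody observation, Gaussian
# log-posterior with optional signal-dependent noise, gradient-free
# dynamic hill climbing, single-process enhanced scatter search, and
# parameter-recovery experiments.

#' Define an antibody-style observable
#'
#' An observable is an affine readout of the summed concentration of a
#' species set: \eqn{y_k = o_k + s_k \sum_{i \in K} x_i}.  Antibodies
#' differ in affinity, hence the per-observable scale; offsets capture
#' background fluorescence.
#'
#' @param id observable name
#' @param species character vector of model species summed by the
#'   antibody (non-empty)
#' @param offset offset \eqn{o_k} (fluorescence units)
#' @param scale scale \eqn{s_k} (fluorescence per concentration unit,
#'   >= 0)
#' @return a `ccObservable`
#' @export
observable <- function(id, species, offset = 0, scale = 1) {
  stopifnot(length(species) >= 1, scale >= 0)
  structure(list(id = id, species = species, offset = offset, scale = scale),
            class = "ccObservable")
}

#' Apply the observation map to a state matrix
#'
#' @param states time/cells x species matrix with column names
#' @param defs list of [observable()] definitions
#' @return matrix with one column per observable
#' @export
observe <- function(states, defs) {
  out <- matrix(NA_real_, nrow(states), length(defs))
  ids <- character(length(defs))
  for (j in seq_along(defs)) {
    d <- defs[[j]]
    missing <- setdiff(d$species, colnames(states))
    if (length(missing))
      stop("observable '", d$id, "': unknown species ",
           paste(missing, collapse = ", "))
    out[, j] <- d$offset + d$scale *
      rowSums(states[, d$species, drop = FALSE])
    ids[j] <- d$id
  }
  colnames(out) <- ids
  rownames(out) <- rownames(states)
  out
}

#' Signal-dependent measurement noise
#'
#' Standard deviation of the Gaussian measurement error for observable
#' `k`: \eqn{\sigma_k = \sigma_1 + \sigma_{2k} y_k} — an additive floor
#' plus an observable-specific multiplicative term.
#'
#' @param sigma1 additive s.d. (>= 0)
#' @param sigma2 named vector (or scalar) of per-observable
#'   multiplicative s.d. (>= 0)
#' @return a `ccNoiseModel`
#' @export
noise_model <- function(sigma1 = 0.1, sigma2 = 0) {
  stopifnot(sigma1 >= 0, all(sigma2 >= 0))
  structure(list(sigma1 = sigma1, sigma2 = sigma2), class = "ccNoiseModel")
}

noise_sd <- function(nm, y, obs_id) {
  s2 <- if (length(nm$sigma2) > 1) nm$sigma2[obs_id] else rep(nm$sigma2, length(obs_id))
  nm$sigma1 + unname(s2) * y
}

#' Assemble a parameter-estimation problem
#'
#' @param model a `ccModel`
#' @param observables list of [observable()] definitions
#' @param measurements data frame with columns `observable`, `time`
#'   (min), `value`
#' @param estimate character vector of parameter names to estimate; may
#'   include rate constants and initial conditions (species names)
#' @param lower,upper optional named bound vectors; defaults are
#'   `[0.1 theta0, 10 theta0]` for rate constants and
#'   `[eps, 1.5 theta0]` for initial conditions (with a floor of `eps`
#'   when `theta0 = 0`)
#' @param noise a [noise_model()], or a single fixed sigma
#' @param estimate_noise also estimate `sigma1`/`sigma2` jointly
#' @param penalty objective value returned on simulation failure
#' @return a `ccFitProblem`
#' @export
fit_problem <- function(model, observables, measurements, estimate,
                        lower = NULL, upper = NULL, noise = 0.1,
                        estimate_noise = FALSE, penalty = 1e9) {
  stopifnot(all(c("observable", "time", "value") %in% colnames(measurements)))
  ids <- vapply(observables, function(o) o$id, "")
  bad <- setdiff(unique(measurements$observable), ids)
  if (length(bad)) stop("measurements reference undefined observables: ",
                        paste(bad, collapse = ", "))
  is_rate <- estimate %in% names(model$parameters)
  is_ic <- estimate %in% model$species
  if (any(!is_rate & !is_ic))
    stop("unknown parameters: ", paste(estimate[!is_rate & !is_ic], collapse = ", "))
  theta0 <- ifelse(is_rate, model$parameters[estimate], model$initial[estimate])
  names(theta0) <- estimate
  eps <- .Machine$double.eps
  lo <- ifelse(is_rate, pmax(0.1 * theta0, eps), eps)
  hi <- ifelse(is_rate, ifelse(theta0 > 0, 10 * theta0, 1), pmax(1.5 * theta0, 1))
  names(lo) <- names(hi) <- estimate
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(lo >= hi)) stop("lower bounds must be below upper bounds")
  if (is.numeric(noise)) noise <- noise_model(sigma1 = noise, sigma2 = 0)
  structure(list(model = model, observables = observables,
                 measurements = measurements, estimate = estimate,
                 is_rate = is_rate, theta0 = theta0,
                 lower = lo, upper = hi, noise = noise,
                 estimate_noise = estimate_noise, penalty = penalty),
            class = "ccFitProblem")
}

#' @export
print.ccFitProblem <- function(x, ...) {
  cat("<ccFitProblem> ", x$model$name, ": ", length(x$estimate),
      " parameters, ", length(x$observables), " observables, ",
      nrow(x$measurements), " measurements\n", sep = "")
  invisible(x)
}

# Simulate the problem's model at the measurement times under theta.
problem_predictions <- function(problem, theta) {
  m <- problem$model
  pars <- theta[problem$estimate[problem$is_rate]]
  ics <- theta[problem$estimate[!problem$is_rate]]
  tt <- sort(unique(c(0, problem$measurements$time)))
  tr <- simulate_model(m,
                       params = if (length(pars)) pars else NULL,
                       init = if (length(ics)) ics else NULL,
                       t_end = max(tt), dt_out = max(tt) / 400)
  states <- vapply(m$species, function(sp)
    stats::approx(tr$times, tr$states[, sp], xout = problem$measurements$time)$y,
    numeric(nrow(problem$measurements)))
  colnames(states) <- m$species
  y <- observe(states, problem$observables)
  y[cbind(seq_len(nrow(y)), match(problem$measurements$observable, colnames(y)))]
}

#' Negative log-posterior of a fit problem
#'
#' Gaussian likelihood with \eqn{\sigma_k = \sigma_1 + \sigma_{2k} y_k},
#' flat priors inside the bounds.  With a fixed constant sigma this
#' equals scaled least squares plus a constant, so objective differences
#' are `0.5 * dSSR / sigma^2`.  Simulation failures return a large
#' finite penalty (recorded in the attribute `"penalised"`), never an
#' exception, so stochastic search can continue.
#'
#' @param theta named parameter vector (must lie within the problem's
#'   bounds)
#' @param problem a [fit_problem()]
#' @return scalar objective value
#' @export
negative_log_posterior <- function(theta, problem) {
  theta <- theta[problem$estimate]
  if (any(theta < problem$lower - 1e-12) || any(theta > problem$upper + 1e-12))
    stop("theta outside bounds")
  pred <- tryCatch(problem_predictions(problem, theta),
                   error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(pred)))
    return(structure(problem$penalty, penalised = TRUE))
  obs <- problem$measurements$value
  sd <- noise_sd(problem$noise, pred, problem$measurements$observable)
  if (any(sd <= 0)) return(structure(problem$penalty, penalised = TRUE))
  0.5 * sum(((obs - pred) / sd)^2) + sum(log(sd)) +
    0.5 * length(obs) * log(2 * pi)
}

problem_objective <- function(problem) {
  function(x) {
    th <- setNames(x, problem$estimate)
    as.numeric(negative_log_posterior(th, problem))
  }
}

#' Gradient-free dynamic hill climbing
#'
#' Adaptive coordinate search with pattern moves: each coordinate keeps
#' its own step size, doubled after a successful move and halved after
#' failure; after any success the accumulated move direction is tried as
#' a combined "pattern" step.  Candidates are clipped to the bounds.
#' The best objective is monotone non-increasing.
#'
#' @param f objective function of a numeric vector
#' @param x0 start point (within bounds)
#' @param lower,upper bound vectors
#' @param budget maximum number of function evaluations
#' @param step0 initial step as fraction of the bound range
#' @param min_step termination threshold on the relative step size
#' @return an `ccOptResult`: `par`, `value`, `trace` (data frame of
#'   evaluations vs best objective), `evaluations`, `termination`
#' @export
dynamic_hill_climbing <- function(f, x0, lower, upper, budget = 1000,
                                  step0 = 0.1, min_step = 1e-9) {
  d <- length(x0)
  if (budget <= 0)
    return(opt_result(x0, f(x0), data.frame(evals = 1, best = f(x0)), 1, "zero budget"))
  rng <- upper - lower
  step <- step0 * rng
  clip <- function(x) pmin(pmax(x, lower), upper)
  x <- clip(x0)
  fx <- f(x)
  evals <- 1
  trace_e <- evals; trace_f <- fx
  pattern <- rep(0, d)
  termination <- "budget exhausted"
  while (evals < budget) {
    improved <- FALSE
    for (j in seq_len(d)) {
      for (s in c(1, -1)) {
        if (evals >= budget) break
        cand <- x; cand[j] <- cand[j] + s * step[j]
        cand <- clip(cand)
        if (all(cand == x)) next
        fc <- f(cand); evals <- evals + 1
        if (fc < fx) {
          pattern <- pattern + (cand - x)
          x <- cand; fx <- fc
          step[j] <- min(step[j] * 2, rng[j])
          improved <- TRUE
          trace_e <- c(trace_e, evals); trace_f <- c(trace_f, fx)
          break
        } else step[j] <- step[j] / 2
      }
    }
    if (improved && any(pattern != 0) && evals < budget) {
      cand <- clip(x + pattern)
      if (!all(cand == x)) {
        fc <- f(cand); evals <- evals + 1
        if (fc < fx) {
          x <- cand; fx <- fc
          trace_e <- c(trace_e, evals); trace_f <- c(trace_f, fx)
        } else pattern <- rep(0, d)
      }
    } else if (!improved) pattern <- rep(0, d)
    if (all(step < min_step * rng)) { termination <- "step size converged"; break }
  }
  opt_result(x, fx, data.frame(evals = trace_e, best = trace_f), evals,
             termination)
}

opt_result <- function(par, value, trace, evaluations, termination,
                       seed = NULL) {
  structure(list(par = par, value = value, trace = trace,
                 evaluations = evaluations, termination = termination,
                 seed = seed),
            class = "ccOptResult")
}

#' @export
print.ccOptResult <- function(x, ...) {
  cat("<ccOptResult> objective ", signif(x$value, 6), " after ",
      x$evaluations, " evaluations (", x$termination, ")\n", sep = "")
  invisible(x)
}

# Latin hypercube sample within bounds.
lhs_sample <- function(n, lower, upper) {
  d <- length(lower)
  H <- lhs::randomLHS(n, d)
  sweep(sweep(H, 2, upper - lower, `*`), 2, lower, `+`)
}

#' Enhanced scatter search (single process)
#'
#' Population-based global search: Latin-hypercube diversification, a
#' reference set of high-quality plus diverse members, pairwise
#' hyper-rectangle combination, a "go-beyond" intensification step when
#' a child improves on its parents, and periodic local refinement of the
#' best member with [dynamic_hill_climbing()].
#'
#' @param f objective function
#' @param lower,upper bounds
#' @param budget maximum function evaluations
#' @param dim_refset reference-set size (default
#'   `ceiling((1 + sqrt(1 + 8 d)) / 2)`, at least 6 and even)
#' @param n_diverse size of the diversification set (default `10 d`)
#' @param local_budget evaluations per local polish
#' @param local_every run the local solver after this many outer
#'   iterations (0 disables local search)
#' @param seed RNG seed
#' @return an `ccOptResult`
#' @export
scatter_search <- function(f, lower, upper, budget = 5000,
                           dim_refset = NULL, n_diverse = NULL,
                           local_budget = 500, local_every = 5,
                           seed = 1) {
  stopifnot(budget > 0)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  d <- length(lower)
  if (is.null(dim_refset)) {
    dim_refset <- max(6, ceiling((1 + sqrt(1 + 8 * d)) / 2))
    if (dim_refset %% 2) dim_refset <- dim_refset + 1
  }
  if (is.null(n_diverse)) n_diverse <- max(10 * d, 2 * dim_refset)
  evals <- 0
  best_x <- NULL; best_f <- Inf
  trace_e <- numeric(0); trace_f <- numeric(0)
  note <- function(x, fx) {
    if (fx < best_f) {
      best_f <<- fx; best_x <<- x
      trace_e <<- c(trace_e, evals); trace_f <<- c(trace_f, fx)
    }
  }
  ev <- function(x) { fx <- f(x); evals <<- evals + 1; note(x, fx); fx }

  X <- lhs_sample(n_diverse, lower, upper)
  fX <- apply(X, 1, ev)
  nb <- dim_refset %/% 2
  ord <- order(fX)
  ref_x <- X[ord[seq_len(nb)], , drop = FALSE]
  ref_f <- fX[ord[seq_len(nb)]]
  # diverse half: maximise distance to current refset
  pool <- X[-ord[seq_len(nb)], , drop = FALSE]
  pool_f <- fX[-ord[seq_len(nb)]]
  while (nrow(ref_x) < dim_refset && nrow(pool) > 0) {
    dmin <- apply(pool, 1, function(z)
      min(sqrt(colSums((t(ref_x) - z)^2))))
    i <- which.max(dmin)
    ref_x <- rbind(ref_x, pool[i, ]); ref_f <- c(ref_f, pool_f[i])
    pool <- pool[-i, , drop = FALSE]; pool_f <- pool_f[-i]
  }
  clip <- function(x) pmin(pmax(x, lower), upper)
  iter <- 0
  while (evals < budget) {
    iter <- iter + 1
    improved_any <- FALSE
    nr <- nrow(ref_x)
    for (i in seq_len(nr - 1)) {
      for (j in (i + 1):nr) {
        if (evals >= budget) break
        xi <- ref_x[i, ]; xj <- ref_x[j, ]
        better <- if (ref_f[i] <= ref_f[j]) xi else xj
        worse <- if (ref_f[i] <= ref_f[j]) xj else xi
        dvec <- (worse - better) / 2
        child <- clip(better - dvec + stats::runif(d, 0, 1) * 2 * dvec)
        fc <- ev(child)
        wi <- if (ref_f[i] <= ref_f[j]) j else i
        if (fc < ref_f[wi]) {
          # go-beyond: keep stepping past the child while it improves
          gb_from <- better; gb_to <- child; gb_f <- fc
          while (evals < budget) {
            nxt <- clip(gb_to + (gb_to - gb_from))
            if (all(nxt == gb_to)) break
            fn <- ev(nxt)
            if (fn < gb_f) { gb_from <- gb_to; gb_to <- nxt; gb_f <- fn }
            else break
          }
          ref_x[wi, ] <- gb_to; ref_f[wi] <- gb_f
          improved_any <- TRUE
        }
      }
      if (evals >= budget) break
    }
    if (local_every > 0 && iter %% local_every == 0 && evals < budget) {
      lb <- min(local_budget, budget - evals)
      loc <- dynamic_hill_climbing(ev, best_x, lower, upper, budget = lb)
      ibest <- which.max(ref_f)
      if (loc$value < ref_f[ibest]) {
        ref_x[ibest, ] <- loc$par; ref_f[ibest] <- loc$value
      }
    }
    if (!improved_any && evals < budget) {
      # refresh the worst half with new diverse members
      ord <- order(ref_f)
      nrep <- max(1, nr %/% 2)
      fresh <- lhs_sample(nrep, lower, upper)
      for (k in seq_len(nrep)) {
        if (evals >= budget) break
        w <- ord[nr - k + 1]
        ref_x[w, ] <- fresh[k, ]
        ref_f[w] <- ev(fresh[k, ])
      }
    }
  }
  opt_result(best_x, best_f, data.frame(evals = trace_e, best = trace_f),
             evals, "budget exhausted", seed = seed)
}

#' Multistart local optimisation
#'
#' Independent [dynamic_hill_climbing()] runs from Latin-hypercube
#' starts; the baseline a global method must beat.
#'
#' @param f objective function
#' @param lower,upper bounds
#' @param n_starts number of starts
#' @param budget_each evaluation budget per start
#' @param seed RNG seed
#' @return list of `ccOptResult`, sorted by objective
#' @export
multistart <- function(f, lower, upper, n_starts = 10, budget_each = 500,
                       seed = 1) {
  stopifnot(n_starts >= 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  X <- lhs_sample(n_starts, lower, upper)
  res <- lapply(seq_len(n_starts), function(i)
    dynamic_hill_climbing(f, X[i, ], lower, upper, budget = budget_each))
  res[order(vapply(res, function(r) r$value, 0))]
}

#' Parameter-recovery experiment
#'
#' Generates synthetic measurements from known ground-truth parameters,
#' re-estimates them with [scatter_search()] and reports per-parameter
#' recovery ratios, the objective gap to the truth, and the
#' conserved-pair diagnostic (sums of initial conditions that are only
#' jointly identifiable, such as Apc:Cdh + pCdh).
#'
#' @param model a `ccModel`
#' @param estimate names of parameters/initial conditions to recover
#' @param observables observables used as data (default: every species
#'   observed directly)
#' @param n_times number of evenly spaced sample points
#' @param t_end data horizon (min); defaults to two cycle periods when
#'   events are available, else 2x the simulated horizon
#' @param noise a [noise_spec()] applied multiplicatively to the data
#' @param budget scatter-search evaluation budget
#' @param seed RNG seed
#' @param lower,upper optional bound overrides (named)
#' @param conserved_pairs list of species pairs whose initial-condition
#'   sum is reported
#' @param ... passed to [scatter_search()]
#' @return list with `theta_true`, `theta_hat`, `ratio`, `objective`,
#'   `objective_truth`, `pair_sums`, and the `ccOptResult`
#' @export
recovery_experiment <- function(model, estimate, observables = NULL,
                                n_times = 101, t_end = NULL,
                                noise = noise_spec("none"),
                                budget = 3000, seed = 1,
                                lower = NULL, upper = NULL,
                                conserved_pairs = list(), ...) {
  if (is.null(observables))
    observables <- lapply(model$species, function(sp) observable(sp, sp))
  if (is.null(t_end)) {
    # one full cycle of evenly spaced samples (idealised-data design)
    tr0 <- simulate_model(model, t_end = 500, dt_out = 1)
    t_end <- if (length(tr0$events) >= 2) mean(diff(tr0$events)) else 100
  }
  tt <- seq(0, t_end, length.out = n_times)
  tr <- simulate_model(model, t_end = t_end, dt_out = t_end / (n_times - 1))
  states <- tr$states[match(round(tt, 8), round(tr$times, 8)), , drop = FALSE]
  y <- observe(states, observables)
  y <- withr_seed(seed, apply_noise(y, noise))
  meas <- data.frame(
    observable = rep(colnames(y), each = nrow(y)),
    time = rep(tt, ncol(y)),
    value = as.vector(y))
  problem <- fit_problem(model, observables, meas, estimate,
                         lower = lower, upper = upper, noise = 0.1)
  f <- problem_objective(problem)
  res <- scatter_search(f, problem$lower, problem$upper, budget = budget,
                        seed = seed, ...)
  theta_true <- problem$theta0
  theta_hat <- setNames(res$par, problem$estimate)
  pair_sums <- lapply(conserved_pairs, function(pr)
    c(true = sum(theta_true[pr]), estimated = sum(theta_hat[pr])))
  list(theta_true = theta_true, theta_hat = theta_hat,
       ratio = theta_hat / ifelse(theta_true == 0, 1, theta_true),
       objective = res$value, objective_truth = f(unname(theta_true)),
       pair_sums = pair_sums, result = res, problem = problem)
}
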