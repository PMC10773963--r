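# Synthetic asynchronous-population snapshots: cell ages from the
# exponential age density of a perfectly asynchronous population on a
# limit cycle, states read off one simulated period, affine antibody
# observation, multiplicative noise.

#' Age density of a perfectly asynchronous proliferating population
#'
#' In a population of doubling time `T` in which every cell moves along
#' the same circular trajectory, the probability that a random cell had
#' its last division `t` minutes ago is
#' \eqn{p(t) = \bar k (1/2)^{t/T}} on \eqn{[0, T)}, with \eqn{\bar k =
#' \log 2 / (T (1 - 1/2)) = 2 \log 2 / T} normalising the integral to 1:
#' cell density decays exponentially with a half-life of one doubling
#' time.  The corresponding CDF is \eqn{F(t) = 2 (1 - (1/2)^{t/T})}.
#'
#' @param T doubling time (min)
#' @param N population size (used by rank conversions)
#' @return an `AgeDistribution` object
#' @export
age_distribution <- function(T, N = 1) {
  stopifnot(T > 0, N >= 1)
  structure(list(T = T, N = N), class = "ccAgeDistribution")
}

#' Age-density CDF
#' @param dist an [age_distribution()]
#' @param t ages (min)
#' @return cumulative probability
#' @export
age_cdf <- function(dist, t) 2 * (1 - 2^(-t / dist$T))

#' Sample cell ages from the asynchronous age density
#'
#' Inverse-CDF sampling: \eqn{t = -T \log_2(1 - u/2)} with
#' \eqn{u \sim U(0,1)}; all draws lie in `[0, T)`.
#'
#' @param dist an [age_distribution()]
#' @param n number of cells
#' @param seed optional RNG seed (local to this call)
#' @return numeric vector of ages (min)
#' @export
sample_ages <- function(dist, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  u <- stats::runif(n)
  -dist$T * log2(1 - u / 2)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Extract one cycle of a limit-cycle trajectory, anchored at division
#'
#' Takes the segment of a simulated trajectory between two consecutive
#' M/A transition events (the division event defines age 0) and returns
#' it with the time axis rebased to age.
#'
#' @param traj a `ccTrajectory` with at least 2 annotated M/A events
#' @param from index of the anchoring event (defaults to the second-last,
#'   i.e. a post-transient cycle)
#' @return list with `age` (min), `states` (age x species) and `period`
#' @export
extract_cycle <- function(traj, from = NULL) {
  ev <- traj$events
  if (length(ev) < 2) stop("need at least 2 M/A events to define a cycle")
  if (is.null(from)) from <- length(ev) - 1
  t0 <- ev[from]; t1 <- ev[from + 1]
  keep <- traj$times > t0 & traj$times < t1
  # event times are interpolated between grid points: add exact states
  # at both endpoints so the age axis spans [0, period] completely
  interp_at <- function(tt) vapply(colnames(traj$states), function(sp)
    stats::approx(traj$times, traj$states[, sp], xout = tt)$y, 0)
  states <- rbind(interp_at(t0),
                  traj$states[keep, , drop = FALSE],
                  interp_at(t1))
  rownames(states) <- NULL
  list(age = c(0, traj$times[keep] - t0, t1 - t0),
       states = states,
       period = t1 - t0)
}

#' Interpolate limit-cycle states at given cell ages
#'
#' @param cycle output of [extract_cycle()] (one full period, age 0 at
#'   the division event)
#' @param ages vector of ages in `[0, period)`
#' @return matrix (cells x species), linearly interpolated per species
#' @export
cycle_states_at_ages <- function(cycle, ages) {
  if (any(ages < 0) || any(ages >= cycle$period))
    stop("ages must lie in [0, period)")
  out <- vapply(colnames(cycle$states), function(sp)
    stats::approx(cycle$age, cycle$states[, sp], xout = ages)$y,
    numeric(length(ages)))
  out <- matrix(out, nrow = length(ages),
                dimnames = list(paste0("cell_", seq_along(ages)),
                                colnames(cycle$states)))
  # concentrations are non-negative; the integrator may undershoot zero
  # within its absolute tolerance
  pmax(out, 0)
}

#' Specify a multiplicative noise family
#'
#' `"normal"`: each value is multiplied by N(1, sd^2) draws (clipped at
#' zero).  `"lognormal"`: multiplied by a log-normal factor with
#' log-scale standard deviation `sd`, normalised to unit mean (log-mean
#' `-sd^2/2`), so the expected value is unbiased; set
#' `mean_one = FALSE` for a zero log-mean.  `"none"`: no noise.
#'
#' @param family one of `"none"`, `"normal"`, `"lognormal"`
#' @param sd noise scale (s.d. of the factor / of its log)
#' @param mean_one normalise the log-normal factor to mean 1
#' @return a `ccNoiseSpec`
#' @export
noise_spec <- function(family = c("none", "normal", "lognormal"),
                       sd = 0, mean_one = TRUE) {
  family <- match.arg(family)
  stopifnot(sd >= 0)
  structure(list(family = family, sd = sd, mean_one = mean_one),
            class = "ccNoiseSpec")
}

apply_noise <- function(x, noise) {
  if (noise$family == "none" || noise$sd == 0) return(x)
  f <- switch(noise$family,
    normal = matrix(stats::rnorm(length(x), 1, noise$sd), nrow(x)),
    lognormal = {
      mu <- if (noise$mean_one) -noise$sd^2 / 2 else 0
      matrix(exp(stats::rnorm(length(x), mu, noise$sd)), nrow(x))
    },
    stop("unknown noise family"))
  pmax(x * f, 0)
}

#' Generate a synthetic snapshot table from sampled states
#'
#' Applies the affine antibody observation map to each cell's state,
#' corrupts every feature with multiplicative noise, and shuffles the
#' rows (a snapshot carries no time information).  The hidden truth
#' (age, original index) is kept in separate columns prefixed
#' `truth_`.
#'
#' @param states cells x species matrix (e.g. from
#'   [cycle_states_at_ages()])
#' @param ages true ages of the cells (min)
#' @param observables list of [observable()] definitions; `NULL` observes
#'   every species directly
#' @param noise a [noise_spec()]
#' @param seed optional RNG seed
#' @param shuffle permute the rows (default TRUE)
#' @return a `data.frame` with `cell_id`, one column per observable, and
#'   `truth_age` / `truth_index` columns
#' @export
make_snapshot <- function(states, ages, observables = NULL,
                          noise = noise_spec("none"), seed = NULL,
                          shuffle = TRUE) {
  stopifnot(nrow(states) == length(ages))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  if (is.null(observables))
    observables <- lapply(colnames(states), function(sp) observable(sp, sp))
  y <- observe(states, observables)
  y <- apply_noise(y, noise)
  n <- nrow(y)
  ord <- if (shuffle) sample.int(n) else seq_len(n)
  out <- data.frame(cell_id = sprintf("cell_%03d", seq_len(n)),
                    y[ord, , drop = FALSE],
                    truth_age = ages[ord], truth_index = ord,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Feature columns of a snapshot table
#' @param table snapshot data frame
#' @return character vector of feature column names (excludes `cell_id`
#'   and `truth_*`)
#' @export
snapshot_features <- function(table) {
  setdiff(colnames(table), c("cell_id", grep("^truth_", colnames(table), value = TRUE)))
}

#' Convenience wrapper: snapshot of the core-model limit cycle
#'
#' Simulates the core model long enough to obtain a clean post-transient
#' cycle, samples `n` cell ages from the asynchronous age density over
#' that cycle's period, reads off the states and builds the snapshot.
#'
#' @param n number of cells
#' @param noise a [noise_spec()]
#' @param observables optional observable list (default: all species)
#' @param seed RNG seed
#' @param model optional pre-built model (default [build_core_model()])
#' @param dt_out trajectory output resolution (min)
#' @return list with `table` (snapshot data frame), `cycle` and `period`
#' @export
sample_core_snapshot <- function(n = 300, noise = noise_spec("none"),
                                 observables = NULL, seed = 1,
                                 model = NULL, dt_out = 0.2) {
  if (is.null(model)) model <- build_core_model()
  traj <- simulate_model(model, t_end = 250, dt_out = dt_out)
  cyc <- extract_cycle(traj)
  dist <- age_distribution(T = cyc$period, N = n)
  ages <- sample_ages(dist, n, seed = seed)
  states <- cycle_states_at_ages(cyc, ages)
  tab <- make_snapshot(states, ages, observables = observables,
                       noise = noise, seed = seed + 1)
  list(table = tab, cycle = cyc, period = cyc$period)
}
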