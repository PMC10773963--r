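# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

core_model <- function() cached("core", build_core_model())

# long wild-type run used by several tests (starts on the limit cycle)
core_trajectory <- function() cached("core_traj",
  simulate_model(core_model(), t_end = 800, dt_out = 0.5))

core_period <- function() {
  tr <- core_trajectory()
  mean(diff(tr$events)[-1])
}

# 300-cell noise-free snapshot of the core-model limit cycle
core_snapshot <- function() cached("core_snap",
  sample_core_snapshot(n = 300, seed = 1))

# closed-form test systems
cubic_model <- function() custom_model(
  "cubic", "x",
  function(s, p, t) p[["mu"]] + s[["x"]] - s[["x"]]^3,
  c(mu = -1), c(x = -1.2))

hopf_model <- function() custom_model(
  "hopf", c("x", "y"),
  function(s, p, t) {
    r2 <- s[["x"]]^2 + s[["y"]]^2
    c(p[["mu"]] * s[["x"]] - s[["y"]] - s[["x"]] * r2,
      s[["x"]] + p[["mu"]] * s[["y"]] - s[["y"]] * r2)
  },
  c(mu = -0.5), c(x = 0, y = 0))

# multiplicative log-normal corruption with unit mean, as in the noisy
# reconstruction experiments
corrupt_lognormal <- function(table, log_sd, seed) {
  set.seed(seed)
  for (f in snapshot_features(table))
    table[, f] <- pmax(table[, f] *
                         exp(stats::rnorm(nrow(table), -log_sd^2 / 2, log_sd)), 0)
  table
}

# reconstruction score against hidden truth
reconstruction_R <- function(table, period, seed = 1, features = NULL) {
  ord <- reconstruct_order(table, k_clusters = 8, seed = seed,
                           features = features)
  ord <- orient_cycle(ord, table)
  correlation_with_truth(ord, table$truth_age, T = period)$R
}
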