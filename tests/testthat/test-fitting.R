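# Observation map, objective algebra, local and global optimisers,
# PEtab round trip, toy parameter recovery.

test_that("observation map is affine in the summed species", {
  states <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  defs <- list(observable("o1", c("A", "B"), offset = 0.5, scale = 2),
               observable("o2", "C", offset = 0, scale = 1),
               observable("o3", "A", offset = 3, scale = 0))
  y <- observe(states, defs)
  expect_equal(y[, "o1"], 0.5 + 2 * (states[, "A"] + states[, "B"]))
  expect_equal(y[, "o2"], states[, "C"])      # single species, identity
  expect_true(all(y[, "o3"] == 3))            # zero scale: constant offset
  # affine property: observe(a*states) = o + a*(observe(states) - o)
  a <- 1.7
  y2 <- observe(a * states, defs)
  for (j in 1:3) {
    o <- defs[[j]]$offset
    expect_equal(y2[, j], o + a * (y[, j] - o), tolerance = 1e-12)
  }
  expect_error(observe(states, list(observable("bad", "Z"))), "unknown species")
})

make_toy_problem <- function(noise = 0.1) {
  m <- reaction_model(
    "decay2", c("A", "B"),
    list(reaction("synA", "kSynA", products = c(A = 1)),
         reaction("conv", "kConv", reactants = c(A = 1), products = c(B = 1)),
         reaction("degB", "kDegB", reactants = c(B = 1))),
    parameters = c(kSynA = 0.5, kConv = 0.2, kDegB = 0.1),
    initial = c(A = 1, B = 0))
  tt <- seq(2, 40, by = 2)
  tr <- simulate_model(m, t_end = 40, dt_out = 2)
  y <- observe(tr$states, list(observable("A", "A"), observable("B", "B")))
  meas <- data.frame(observable = rep(c("A", "B"), each = length(tt)),
                     time = rep(tt, 2),
                     value = c(y[match(tt, tr$times), "A"],
                               y[match(tt, tr$times), "B"]))
  fit_problem(m, list(observable("A", "A"), observable("B", "B")),
              meas, c("kSynA", "kConv"), noise = noise)
}

test_that("objective equals scaled least squares under fixed sigma", {
  pr <- make_toy_problem(noise = 0.1)
  f <- problem_objective(pr)
  th0 <- unname(pr$theta0)
  # truth reproduces the data: residual sum zero, only the constant left
  n <- nrow(pr$measurements)
  const <- n * log(0.1) + 0.5 * n * log(2 * pi)
  expect_equal(f(th0), const, tolerance = 1e-6)
  # objective differences are 0.5 * dSSR / sigma^2
  th1 <- th0 * c(1.3, 0.8)
  th2 <- th0 * c(0.7, 1.1)
  ssr <- function(th) {
    pred <- mitotime:::problem_predictions(pr, setNames(th, pr$estimate))
    sum((pr$measurements$value - pred)^2)
  }
  expect_equal(f(th1) - f(th2), 0.5 * (ssr(th1) - ssr(th2)) / 0.01,
               tolerance = 1e-8)
  expect_error(negative_log_posterior(setNames(th0 * 100, pr$estimate), pr),
               "outside bounds")
})

test_that("dynamic hill climbing solves standard test functions", {
  # 1-D convex quadratic to 1e-6 in at most 500 evaluations
  r1 <- dynamic_hill_climbing(function(x) (x - 0.37)^2, 3,
                              lower = -5, upper = 5, budget = 500)
  expect_lt(r1$value, 1e-6)
  expect_lte(r1$evaluations, 500)
  # constant objective returns the start unchanged
  rc <- dynamic_hill_climbing(function(x) 1, c(0.3, -0.2),
                              lower = c(-1, -1), upper = c(1, 1), budget = 200)
  expect_equal(rc$par, c(0.3, -0.2))
  expect_equal(rc$value, 1)
  # Rosenbrock from the classic start
  rb <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  r2 <- dynamic_hill_climbing(rb, c(-1.2, 1), c(-5, -5), c(5, 5),
                              budget = 1e5)
  expect_lt(r2$value, 1e-4)
  # zero budget returns the start
  r0 <- dynamic_hill_climbing(function(x) sum(x^2), c(1, 1),
                              c(-2, -2), c(2, 2), budget = 0)
  expect_equal(r0$par, c(1, 1))
})

test_that("optimisers are monotone, bounded and reproducible", {
  calls <- new.env(); calls$X <- list()
  f <- function(x) { calls$X[[length(calls$X) + 1]] <- x; sum(x^2) }
  lo <- rep(-5, 4); hi <- rep(5, 4)
  r <- scatter_search(f, lo, hi, budget = 800, seed = 3)
  # every evaluated point within bounds (instrumented objective)
  for (x in calls$X) expect_true(all(x >= lo - 1e-12 & x <= hi + 1e-12))
  expect_true(all(diff(r$trace$best) <= 0))
  # best never worse than the best diversification point
  expect_lte(r$value, min(head(vapply(calls$X, f, 0), 40)))
  # reproducible given the seed
  r2 <- scatter_search(function(x) sum(x^2), lo, hi, budget = 800, seed = 3)
  expect_identical(r$par, r2$par)
  expect_identical(r$value, r2$value)
})

test_that("scatter search reaches global accuracy on the 10-D sphere", {
  r <- scatter_search(function(x) sum(x^2), rep(-5, 10), rep(5, 10),
                      budget = 1e5, seed = 1)
  expect_lt(r$value, 1e-8)
})

test_that("multistart on a convex problem agrees across starts", {
  f <- function(x) sum((x - c(0.2, -0.4))^2)
  res <- multistart(f, c(-2, -2), c(2, 2), n_starts = 5, budget_each = 600,
                    seed = 2)
  vals <- vapply(res, function(r) r$value, 0)
  expect_true(all(vals < 1e-6))
  expect_true(!is.unsorted(vals))
  # n_starts = 1 equals a single local solve from the same start
  one <- multistart(f, c(-2, -2), c(2, 2), n_starts = 1, budget_each = 600,
                    seed = 2)
  expect_length(one, 1)
})

test_that("toy recovery: tight bounds give near-exact estimates", {
  m <- reaction_model(
    "decay2", c("A", "B"),
    list(reaction("synA", "kSynA", products = c(A = 1)),
         reaction("conv", "kConv", reactants = c(A = 1), products = c(B = 1)),
         reaction("degB", "kDegB", reactants = c(B = 1))),
    parameters = c(kSynA = 0.5, kConv = 0.2, kDegB = 0.1),
    initial = c(A = 1, B = 0))
  rec <- recovery_experiment(
    m, c("kSynA", "kConv"), n_times = 21, t_end = 40,
    budget = 1500, seed = 4,
    lower = c(kSynA = 0.25, kConv = 0.1),
    upper = c(kSynA = 1.0, kConv = 0.4))
  expect_true(all(abs(rec$ratio - 1) < 0.01))
  expect_lte(rec$objective, rec$objective_truth + 1e-6)
})

test_that("PEtab folder round trip preserves the problem", {
  pr <- make_toy_problem()
  dir <- withr::local_tempdir()
  save_problem(pr, dir)
  expect_true(all(file.exists(file.path(dir,
    c("observables.tsv", "measurements.tsv", "parameters.tsv",
      "conditions.tsv", "model.json")))))
  pr2 <- load_problem(dir)
  expect_equal(pr2$estimate, pr$estimate)
  expect_equal(pr2$lower, pr$lower)
  expect_equal(pr2$upper, pr$upper)
  expect_equal(pr2$measurements, pr$measurements)
  f1 <- problem_objective(pr); f2 <- problem_objective(pr2)
  x <- unname(pr$theta0) * 1.2
  expect_equal(f1(x), f2(x), tolerance = 1e-9)
  # corrupting the folder produces named errors
  meas <- mitotime:::read_tsv(file.path(dir, "measurements.tsv"))
  meas$observableId[1] <- "ghost"
  mitotime:::write_tsv(meas, file.path(dir, "measurements.tsv"))
  expect_error(load_problem(dir), "ghost")
  unlink(file.path(dir, "parameters.tsv"))
  expect_error(load_problem(dir), "parameters.tsv")
})

test_that("hand-written minimal problem evaluates a computable objective", {
  dir <- withr::local_tempdir()
  m <- reaction_model("decay1", "A",
                      list(reaction("deg", "kDeg", reactants = c(A = 1))),
                      parameters = c(kDeg = 0.1), initial = c(A = 2))
  write_model_json(m, file.path(dir, "model.json"))
  writeLines(c("observableId\tobservableFormula\toffset\tscale",
               "obsA\tA\t0\t1"), file.path(dir, "observables.tsv"))
  writeLines(c("observableId\ttime\tmeasurement",
               "obsA\t0\t2", "obsA\t10\t0.73", "obsA\t20\t0.27"),
             file.path(dir, "measurements.tsv"))
  writeLines(c("parameterId\tlowerBound\tupperBound\tnominalValue\testimate",
               "kDeg\t0.01\t1\t0.1\t1"), file.path(dir, "parameters.tsv"))
  writeLines("conditionId\ncondition1", file.path(dir, "conditions.tsv"))
  pr <- load_problem(dir)
  f <- problem_objective(pr)
  # hand-computed SSR at kDeg = 0.1: residuals vs 2*exp(-0.1 t)
  pred <- 2 * exp(-0.1 * c(0, 10, 20))
  ssr <- sum((c(2, 0.73, 0.27) - pred)^2)
  const <- 3 * log(0.1) + 1.5 * log(2 * pi)
  expect_equal(f(0.1), 0.5 * ssr / 0.01 + const, tolerance = 1e-4)
})
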