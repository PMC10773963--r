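# Continuation, fold and Hopf detection against closed-form systems and
# the G2M switch; quasi-static simulation as the independent oracle.

test_that("Newton refinement solves closed-form equilibria", {
  lin <- custom_model("lin", "x",
                      function(s, p, t) p[["a"]] - p[["b"]] * s[["x"]],
                      c(a = 3, b = 1.5), c(x = 0))
  eq <- find_equilibrium(lin, c(x = 10))
  expect_true(eq$converged)
  expect_equal(unname(eq$state["x"]), 2, tolerance = 1e-9)
  expect_equal(eq$stability, "stable")
  # rhs == 0 model returns the guess unchanged
  null <- custom_model("null", "x", function(s, p, t) 0, c(k = 1), c(x = 0))
  eq0 <- find_equilibrium(null, c(x = 0.7))
  expect_equal(unname(eq0$state["x"]), 0.7)
})

test_that("equilibrium refinement works in conservation-reduced coordinates", {
  m <- build_submodel("G2M")
  lo <- m$initial; lo["pCb"] <- 0.05
  eq <- find_equilibrium(m, lo)
  expect_true(eq$converged)
  expect_lt(max(abs(model_rhs(m, eq$state))), 1e-9)
  # the conserved totals of the guess are preserved
  expect_equal(conserved_totals(m, eq$state), conserved_totals(m, lo),
               tolerance = 1e-9)
  # long-time simulation lands on the same state (simulation oracle)
  s_inf <- simulate_model(m, t_end = 5000, dt_out = 2500, init = lo)$states[3, ]
  expect_equal(unname(eq$state), unname(s_inf), tolerance = 1e-6)
})

test_that("cubic normal form: folds recovered to closed form", {
  cub <- cubic_model()
  eqU <- find_equilibrium(cub, c(x = 1.3), params = c(mu = 1))
  eqL <- find_equilibrium(cub, c(x = -1.3), params = c(mu = -1))
  brU <- continue_branch(cub, "mu", c(1, -1), n_steps = 200,
                         start = eqU$state, params = c(mu = 1))
  brL <- continue_branch(cub, "mu", c(-1, 1), n_steps = 200,
                         start = eqL$state, params = c(mu = -1))
  expect_true(brU$ended_early)
  expect_true(brL$ended_early)
  folds <- detect_folds(brU, brL, cub, tol = 1e-6)
  expect_length(folds, 2)
  truth <- 2 / (3 * sqrt(3))
  for (fp in folds) expect_lt(abs(abs(fp$param) - truth), 1e-4)
  width <- abs(folds[[1]]$param - folds[[2]]$param)
  expect_lt(abs(width - 2 * truth), 1e-3)
  # fold localisation sharpens with the bisection tolerance
  f4 <- detect_folds(brU, brL, cub, tol = 1e-4)
  f5 <- detect_folds(brU, brL, cub, tol = 5e-5)
  e4 <- abs(abs(f4[[1]]$param) - truth)
  e5 <- abs(abs(f5[[1]]$param) - truth)
  expect_lte(e5, e4 + 1e-12)
  expect_lt(e5, 1e-4)
})

test_that("a monotone 1-species model yields one fold-free branch", {
  lin <- custom_model("lin", "x",
                      function(s, p, t) p[["mu"]] - s[["x"]],
                      c(mu = 0), c(x = 0))
  br <- continue_branch(lin, "mu", c(0, 1), n_steps = 50, start = c(x = 0))
  expect_false(br$ended_early)
  expect_equal(nrow(br$points), 51)
  expect_length(detect_folds(br, br, lin), 0)
  expect_length(detect_hopf(br, lin), 0)  # stable linear system: no Hopf
})

test_that("Hopf normal form: crossing located at mu = 0 within 1e-6", {
  hm <- hopf_model()
  br <- continue_branch(hm, "mu", c(-0.5, 0.5), n_steps = 50,
                        start = c(x = 1e-4, y = 1e-4))
  h <- detect_hopf(br, hm, tol = 1e-7)
  expect_length(h, 1)
  expect_lt(abs(h), 1e-6)
})

test_that("G2M branch stability flags agree with simulation attractors", {
  m <- build_submodel("G2M")
  lo <- m$initial; lo["pCb"] <- 0.04
  eq <- find_equilibrium(m, lo)
  br <- continue_branch(m, "tCycB", c(0.04, 0.6), n_steps = 60,
                        start = eq$state)
  pts <- br$points
  interior <- seq(4, nrow(pts) - 3)   # stay clear of the fold itself
  set.seed(11)
  pick <- sample(interior, 6)
  for (i in pick) {
    state <- unlist(pts[i, m$species])
    kicked <- pmax(state * (1 + stats::runif(length(state), -0.01, 0.01)), 0)
    # restore the exact conserved totals after the kick
    for (g in m$conserved) kicked[g] <- kicked[g] * sum(state[g]) / sum(kicked[g])
    s_end <- simulate_model(m, t_end = 8000, dt_out = 4000,
                            init = kicked)$states[3, ]
    attracted <- max(abs(s_end - state)) < 0.02 * max(state)
    expect_equal(attracted, as.logical(pts$stable[i]))
  }
})

test_that("hysteresis sweep agrees with continuation-detected folds", {
  m <- build_submodel("G2M")
  # continuation from both ends of the total-cyclin-B axis
  lo <- m$initial; lo["pCb"] <- 0.02
  brUp <- continue_branch(m, "tCycB", c(0.02, 0.6), n_steps = 60,
                          start = find_equilibrium(m, lo)$state)
  hi <- m$initial
  hi[c("Cb", "pCb", "Wee1", "pWee1", "Cdc25", "pCdc25", "Gw", "pGw",
       "Ensa", "pEnsa", "B55", "pEB55")] <-
    c(0.6, 0, 0.01, 0.49, 0.01, 0.49, 0.05, 0.35, 0.152, 0.1, 0.002, 0.248)
  brDn <- continue_branch(m, "tCycB", c(0.6, 0.005), n_steps = 60,
                          start = find_equilibrium(m, hi)$state)
  folds <- detect_folds(brUp, brDn, m, tol = 1e-4)
  expect_length(folds, 2)
  fold_vals <- sort(vapply(folds, function(f) f$param, 0))
  # quasi-static sweep oracle
  grid <- seq(0.02, 0.6, by = 0.02)
  sw <- hysteresis_sweep(m, "tCycB", grid, watch = "Cb", t_relax = 2500)
  jump_up <- grid[which(diff(sw$forward > 0.02) == 1)[1] + 1]
  jump_dn <- grid[which(sw$backward > 0.02)[1]] - 0.02
  expect_lt(abs(jump_up - fold_vals[2]), 2 * 0.02 + 1e-9)
  expect_lt(abs(jump_dn - fold_vals[1]), 2 * 0.02 + 1e-9)
  # fold-state ordering of the mitotic switch
  cb_at <- function(side) {
    f <- folds[[which(vapply(folds, function(x) x$side, "") == side)]]
    f$state
  }
  up_state <- cb_at("upper"); dn_state <- cb_at("lower")
  # B55 sequestration: low at the upper fold, high at the lower fold
  expect_lt(up_state["pEB55"], dn_state["pEB55"])
  # active CycB:Cdk1 on the high branch: higher where the low branch
  # disappears (upper fold) than where the high branch disappears
  cb_high_at_upper <- stats::approx(brDn$points$param, brDn$points$Cb,
                                    xout = fold_vals[2])$y
  expect_gt(cb_high_at_upper, dn_state["Cb"])
})
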