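# The four transition switches and the merged core model: bistability,
# oscillation, restriction point, knockouts, checkpoint.

relax <- function(m, init, t_end = 12000, params = NULL) {
  tr <- simulate_model(m, params = params, t_end = t_end,
                       dt_out = t_end / 2, init = init)
  tr$states[nrow(tr$states), ]
}

test_that("RP toggle is bistable and autoactivation widens the window", {
  high_state <- function(m) {
    st <- m$initial; st["CycD"] <- 1.2
    relax(m, st, 25000)
  }
  up_fold <- function(m) {
    state <- m$initial
    for (d in seq(0, 1.2, by = 0.05)) {
      state["CycD"] <- d
      state <- relax(m, state, 8000)
      if (state["CycE"] > 0.2) return(d)
    }
    NA_real_
  }
  m_auto <- build_submodel("RP", e2f_autoactivation = TRUE)
  m_fix <- build_submodel("RP", e2f_autoactivation = FALSE)
  hi_auto <- high_state(m_auto)
  hi_fix <- high_state(m_fix)
  expect_gt(hi_auto["CycE"], 0.5)
  expect_gt(hi_fix["CycE"], 0.5)
  # withdraw mitogen from the high state: only the autoactivating toggle
  # is truly irreversible (reverting would need negative CycD)
  at0 <- function(m, hi) { hi["CycD"] <- 0; relax(m, hi, 25000) }
  expect_gt(at0(m_auto, hi_auto)["CycE"], 0.5)
  expect_lt(at0(m_fix, hi_fix)["CycE"], 0.1)
  # descending sweep locates the fixed variant's positive lower fold
  lo_fix <- {
    state <- hi_fix; dn <- 0
    for (d in seq(1.15, 0, by = -0.05)) {
      state["CycD"] <- d
      state <- relax(m_fix, state, 8000)
      if (state["CycE"] < 0.1) { dn <- d + 0.05; break }
    }
    dn
  }
  up_auto <- up_fold(m_auto)
  up_fix <- up_fold(m_fix)
  expect_false(is.na(up_auto)); expect_false(is.na(up_fix))
  expect_gt(lo_fix, 0)
  expect_lt(lo_fix, up_fix)                 # bistable window exists
  # window widths: [0, up] with autoactivation vs [lo, up] without
  expect_gt(up_auto - 0, up_fix - lo_fix)   # strictly wider range
})

test_that("G1S toggle shows hysteresis in the E2f input", {
  m <- build_submodel("G1S")
  mid <- 0.15   # inside the bistable window
  lo <- m$initial; lo["E2f"] <- mid
  hi <- m$initial
  hi[c("CycA", "Cdh", "pCdh", "CdhEmi", "Emi1", "E2f")] <-
    c(0.4, 0.001, 0.81, 0.06, 2.0, mid)
  s_lo <- relax(m, lo, 20000)
  s_hi <- relax(m, hi, 20000)
  expect_lt(s_lo["CycA"], 0.05)
  expect_gt(s_hi["CycA"], 0.2)
  # total Cdh conserved through both relaxations
  for (s in list(s_lo, s_hi)) {
    start_tot <- if (identical(s, s_lo)) sum(lo[c("Cdh", "pCdh", "CdhEmi")])
                 else sum(hi[c("Cdh", "pCdh", "CdhEmi")])
    expect_equal(unname(sum(s[c("Cdh", "pCdh", "CdhEmi")])), start_tot,
                 tolerance = 1e-8)
  }
})

test_that("MA oscillator has a lower synthesis threshold for cycling", {
  m <- build_submodel("MA")
  run <- function(ks) {
    tr <- simulate_model(m, params = c(kSyCb = ks), t_end = 4000, dt_out = 1)
    sum(tr$events > 2000)   # post-transient events only
  }
  expect_equal(run(0.02), 0)   # below threshold: steady state
  expect_gt(run(0.04), 10)     # inside the oscillatory window
  # limit-cycle summary errors below threshold, works above
  tr_low <- simulate_model(m, params = c(kSyCb = 0.02), t_end = 4000, dt_out = 1)
  expect_error(limit_cycle_summary(tr_low), "no sustained oscillation")
  tr_ok <- simulate_model(m, params = c(kSyCb = 0.04), t_end = 4000, dt_out = 1)
  s <- limit_cycle_summary(tr_ok)
  expect_gt(s$period, 0)
  expect_true(all(s$amplitude$max >= s$amplitude$min))
})

test_that("core model oscillates with a regular period from cycle start", {
  tr <- core_trajectory()
  expect_gte(length(tr$events), 10)
  iv <- diff(tr$events)[-1]
  expect_lt(stats::sd(iv) / mean(iv), 0.01)
})

test_that("limit-cycle period is robust to output resolution", {
  m <- core_model()
  p1 <- limit_cycle_summary(simulate_model(m, t_end = 400, dt_out = 0.5))$period
  p2 <- limit_cycle_summary(simulate_model(m, t_end = 400, dt_out = 0.1))$period
  expect_lt(abs(p1 - p2) / p1, 0.005)
})

test_that("mitogen withdrawal before the restriction point halts the cycle", {
  m <- core_model()
  per <- core_period()
  run_clamp <- function(frac) {
    pert <- perturbation("clamp_species", "CycD", values = 0, times = frac * per)
    tr <- simulate_model(m, perturbations = list(pert), t_end = 6 * per,
                         dt_out = 1)
    length(tr$events)
  }
  expect_equal(run_clamp(0.10), 0)   # before the RP: no further division
  expect_equal(run_clamp(0.70), 1)   # after the RP: exactly one more
  # bisection narrows the boundary inside the period
  lo <- 0.10; hi <- 0.70
  for (i in 1:4) {
    mid <- (lo + hi) / 2
    if (run_clamp(mid) == 0) lo <- mid else hi <- mid
  }
  expect_lt(hi - lo, 0.05)
  expect_gt(lo, 0.05); expect_lt(hi, 0.75)
})

test_that("cyclin knockouts reproduce the observed proliferation phenotypes", {
  m <- core_model()
  wt <- core_trajectory()
  wt_period <- mean(diff(wt$events)[-1])
  wt_cyce <- mean(wt$states[, "CycE"])
  ko <- function(target) simulate_model(
    m, perturbations = list(perturbation("knockout", target)),
    t_end = 3000, dt_out = 1)
  trE <- ko("CycE")
  expect_gte(length(trE$events), 5)          # still proliferates
  perE <- mean(diff(trE$events)[-1])
  expect_gt(perE, 1.2 * wt_period)           # elevated doubling time
  expect_lt(mean(trE$states[, "CycE"]), 0.01)
  trA <- ko("CycA")
  expect_gte(length(trA$events), 5)
  perA <- mean(diff(trA$events)[-1])
  expect_lt(abs(perA - wt_period) / wt_period, 0.10)  # period unaffected
  expect_gt(mean(trA$states[, "CycE"]), 3 * wt_cyce)  # CycE accumulates
})

test_that("TP53 pulse engages a reversible checkpoint with CDKN1A memory", {
  m <- build_core_model(checkpoint = TRUE)
  pert <- perturbation("clamp_species", "TP53", values = c(1, 0),
                       times = c(5, 250))
  tr <- simulate_model(m, perturbations = list(pert), t_end = 600, dt_out = 1)
  arrest <- tr$times >= 100 & tr$times <= 250
  expect_lt(max(tr$states[arrest, "CycA"]), 0.02)   # CCNA held near zero
  expect_lt(max(tr$states[arrest, "Cb"] + tr$states[arrest, "pCb"]), 0.1)
  expect_gt(max(tr$states[arrest, "P21"]), 0.2)     # CDKN1A rises
  expect_gte(length(tr$events[tr$events > 250]), 2) # cycling resumes
  # CDKN1A is above its cycling baseline when CCNA levels rise again
  resume <- which(tr$times > 250 & tr$states[, "CycA"] > 0.05)[1]
  base <- simulate_model(m, t_end = 300, dt_out = 1)
  expect_gt(tr$states[resume, "P21"], mean(base$states[, "P21"]))
  # cdkn1b requires the checkpoint
  expect_error(build_core_model(cdkn1b = TRUE), "requires checkpoint")
  m2 <- build_core_model(checkpoint = TRUE, cdkn1b = TRUE)
  expect_true(all(c("P27", "CeP27") %in% m2$species))
  expect_gte(length(simulate_model(m2, t_end = 300, dt_out = 1)$events), 3)
})

test_that("core species set is the union of the submodels plus fusion species", {
  m <- core_model()
  subs <- unique(unlist(lapply(c("RP", "G1S", "G2M", "MA"),
                               function(s) build_submodel(s)$species)))
  expect_true(all(subs %in% m$species))
})
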