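test_that("decoupled nomads follow the closed-form exponential decay", {
  p <- nc_params(r1 = 1, r2 = 10, rs = 0, A = 0.5)
  traj <- nc_simulate(p, switch_policy("none"), std_init(),
                      sim_options(t_end = 20))
  expected <- 2 * exp(-traj$times)
  # below ~1e3 * atol the absolute solver tolerance dominates the error,
  # so relative comparison is only meaningful above it
  sel <- expected > 1e-3
  expect_lt(max(abs(traj$n1[sel] - expected[sel]) / expected[sel]), 1e-6)
  sel2 <- expected > 1e-8
  expect_lt(max(abs(traj$n1[sel2] - expected[sel2])), 1e-6)
})

test_that("an isolated colony with weak Allee effect stabilises at n2 = K = 1", {
  p <- nc_params(r1 = 1, r2 = 10, rs = 0, A = 0.5)
  traj <- nc_simulate(p, switch_policy("none"), std_init(),
                      sim_options(t_end = 50))
  fin <- final_state(traj)
  expect_equal(fin[["n2"]], 1, tolerance = 1e-4)
  expect_equal(fin[["K"]], 1, tolerance = 1e-4)
})

test_that("pure transfer conserves total population across switching events", {
  p <- nc_params(r1 = 0, r2 = 0, rs = 50, A = 1.001)
  pol <- switch_policy("fixed", L1 = 3, L2 = 4)
  traj <- nc_simulate(p, pol, sim_state(1, 1, 2), sim_options(t_end = 6))
  expect_gte(nrow(traj$events), 2)        # crossings actually happened
  total <- traj$n1 + traj$n2
  expect_lt(max(abs(total - 2)), 1e-7)
})

test_that("reported states are non-negative and respect a finite Kmax", {
  r <- run_scenario("fig2b")
  expect_gte(min(r$trajectory$n1), 0)
  expect_gte(min(r$trajectory$n2), 0)
  for (nm in c("fig6a", "fig7a")) {
    tr <- run_scenario(nm)$trajectory
    expect_lte(max(tr$K), tr$params$Kmax + 1e-8)
    expect_gte(min(tr$n1), 0)
    expect_gte(min(tr$n2), 0)
  }
})

test_that("trajectory bookkeeping is consistent", {
  tr <- run_scenario("fig2b")$trajectory
  expect_true(all(diff(tr$times) > 0))
  expect_equal(length(tr$times), length(tr$n1))
  expect_equal(length(tr$times), length(tr$K))
  expect_true(!is.unsorted(tr$events$time))
  ph <- tr$phases
  expect_equal(ph$start[1], 0)
  expect_equal(ph$end[nrow(ph)], tr$options$t_end)
  expect_equal(ph$start[-1], ph$end[-nrow(ph)])     # contiguous partition
  expect_true(all(ph$phase %in% c("nomadic", "colonial", "switching")))
  expect_setequal(unique(ph$phase), c("nomadic", "colonial", "switching"))
})

test_that("the compiled right-hand side agrees with the R reference", {
  p <- nc_params(r1 = 1, r2 = 10, rs = 0, A = 0.5)
  opts <- sim_options(t_end = 3, n_out = 61)
  traj <- nc_simulate(p, switch_policy("none"), std_init(), opts)
  ref <- deSolve::ode(
    y = c(2, 2, 5), times = traj$times,
    func = function(t, y, parms) {
      st <- sim_state(max(y[1], 0), max(y[2], 0), y[3])
      list(unname(model_rhs(st, p, switch_policy("none"))))
    },
    rtol = 1e-9, atol = 1e-9)
  expect_equal(traj$n2, unname(ref[, 3]), tolerance = 1e-7)
  expect_equal(traj$K, unname(ref[, 4]), tolerance = 1e-7)
})

test_that("fixed-rule events alternate through the switching cycle", {
  tr <- run_scenario("fig2b")$trajectory
  ty <- tr$events$type
  # every cycle: capacity falls through L2 then L1, recovers through L1,
  # grows through L2 -- with an n2 = K intersection inside the colonial phase
  expect_true(all(c("K_crossed_L2_up", "K_crossed_L2_down",
                    "K_crossed_L1_down", "K_crossed_L1_up",
                    "n2_reached_K_growing") %in% ty))
  up <- tr$events$time[ty == "K_crossed_L2_up"]
  expect_gt(length(up), 10)                 # periodic recolonisation
  expect_lt(max(abs(diff(diff(up)))), 1e-3) # near-constant period
})

test_that("adaptive growth eventually drives nomad peaks above the capacity peak", {
  tr <- run_scenario("fig4")$trajectory     # growth run to t = 300
  pk <- phase_peaks(tr)
  late <- utils::tail(pk, 3)
  expect_true(all(late$peak_n1 > late$peak_K))
  # early in the run the capacity still dominates the nomad peak
  expect_true(pk$peak_n1[1] < pk$peak_K[1])
})

test_that("halving tolerances leaves the paradox scenario's final state unchanged to <1%", {
  a <- run_scenario("fig2b")$trajectory
  b <- run_scenario("fig2b", rtol = 5e-10, atol = 5e-10)$trajectory
  d <- guarded_rel_diff(final_state(a)[-1], final_state(b)[-1])
  expect_lt(max(d), 0.01)
})
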