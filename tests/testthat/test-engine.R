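test_that("resistive divider solves to the symmetric midpoint", {
  n <- parse_netlist(c("node n1", "node n2", "node ground reference=0",
                       "component pressure_source ps n1 - 1",
                       "component resistor r1 n1 n2 1",
                       "component resistor r2 n2 ground 1"))
  sys <- assemble_step_system(n, initial_state(n), forcing_none(), dt = 0.1)
  x <- solve(sys$M, sys$b)
  names(x) <- sys$unknowns
  expect_equal(x[["P.n2"]], 0.5, tolerance = 1e-12)
  expect_equal(x[["Q.r1"]], 0.5, tolerance = 1e-12)
})

test_that("one backward-Euler step of the free Windkessel decay is P0/(1+dt/RC)", {
  n <- wk2_decay_netlist()
  st <- initial_state(n)
  sys <- assemble_step_system(n, st, zero_flow_forcing(), dt = 0.1)
  x <- solve(sys$M, sys$b)
  names(x) <- sys$unknowns
  expect_equal(x[["P.inlet"]], 1 / 1.1, tolerance = 1e-12)
  # advance_step agrees with the hand-assembled solve
  cfg <- solver_config(dt = 0.1, duration = 0.1)
  st2 <- advance_step(n, st, zero_flow_forcing(), list(), cfg)
  expect_equal(st2$P[["inlet"]], 1 / 1.1, tolerance = 1e-12)
})

test_that("degenerate systems are rejected with informative errors", {
  floaty <- lpn_netlist(
    list(lpn_component("resistor", "r1", "a", "b", 1),
         lpn_component("resistor", "r2", "b", "a", 1)),
    list(lpn_node("a"), lpn_node("b")))
  expect_error(
    assemble_step_system(floaty, initial_state(floaty), forcing_none(),
                         dt = 0.1),
    "floating")
  n <- wk2_decay_netlist()
  expect_error(
    assemble_step_system(n, initial_state(n), zero_flow_forcing(), dt = 0),
    "dt")
  cfg <- solver_config(dt = 0.1, duration = 1)
  cfg$dt <- 0
  expect_error(advance_step(n, initial_state(n), zero_flow_forcing(),
                            list(), cfg), "dt")
})

test_that("a controller's parameter change is used for the step it precedes", {
  n <- make_windkessel2(1, 1)
  n$components[[1L]]$tag <- "sysR"
  fz <- const_flow_forcing(1)
  cfg <- solver_config(dt = 0.1, duration = 40)
  doubler <- controller_constant("sysR", 2)
  r <- run_simulation(n, fz, list(doubler), cfg)
  # steady pressure reflects the doubled resistance, not the netlist value
  expect_equal(tail(r$P[, "inlet"], 1L), 2, tolerance = 1e-3)
})

test_that("free Windkessel decay matches the closed form", {
  n <- wk2_decay_netlist()
  cfg <- solver_config(dt = 1e-3, duration = 1)
  r <- run_simulation(n, zero_flow_forcing(), list(), cfg)
  expect_equal(tail(r$P[, "inlet"], 1L), exp(-1), tolerance = 1e-3)
})

test_that("three-element Windkessel steady inlet pressure is q(Rp+Rd)", {
  n <- make_windkessel3(0.1, 1, 1)
  cfg <- solver_config(dt = 1e-3, duration = 10)
  r <- run_simulation(n, const_flow_forcing(1), list(), cfg)
  expect_equal(tail(r$P[, "inlet"], 1L), 1.1, tolerance = 1e-3)
})

test_that("diode states resolve to the complementarity-consistent assignment", {
  # forward gradient through diode + resistor: open, Ohmic flow
  fwd <- parse_netlist(c("node a", "node mid", "node ground reference=0",
                         "component pressure_source ps a - 4",
                         "component diode d1 a mid 0",
                         "component resistor r1 mid ground 2"))
  out <- resolve_diode_states(fwd, initial_state(fwd), forcing_none(),
                              dt = 0.1)
  expect_identical(out$diode_states$d1, "open")
  expect_equal(out$state$Q[["d1"]], 2, tolerance = 1e-9)
  # reverse gradient (raised reference downstream): closed, zero flow
  rev <- parse_netlist(c("node a", "node mid", "node ground reference=4",
                         "component pressure_source ps a - 0",
                         "component diode d1 a mid 0",
                         "component resistor r1 mid ground 2"))
  out <- resolve_diode_states(rev, initial_state(rev), forcing_none(),
                              dt = 0.1)
  expect_identical(out$diode_states$d1, "closed")
  expect_equal(out$state$Q[["d1"]], 0, tolerance = 1e-12)
})

test_that("chamber with inlet and outlet valves has a unique consistent assignment", {
  # mid-ejection: stiff chamber pressure above afterload, above preload
  n <- pump_netlist()
  st <- initial_state(n)
  st$params[["ch"]] <- 5e7       # systolic elastance: ejection conditions
  out <- resolve_diode_states(n, st, forcing_none(), dt = 1e-3,
                              params = st$params)
  # enumerate all four assignments and count consistent ones
  model <- cardiolpn:::build_model(n)
  consistent <- 0L
  for (s_in in c("open", "closed")) for (s_out in c("open", "closed")) {
    cand <- list(d_in = s_in, d_out = s_out)
    stc <- cardiolpn:::try_step(model, n, st, forcing_none(), 1e-3,
                                "backward_euler", st$params, cand)
    if (is.null(stc)) next
    dp_in <- stc$P[["src"]] - stc$P[["ch_n"]]
    dp_out <- stc$P[["ch_n"]] - stc$P[["out_n"]]
    tol_q <- 1e-6 * max(abs(stc$Q)); tol_p <- 1e-6 * max(abs(stc$P))
    ok_in <- if (s_in == "open") stc$Q[["d_in"]] >= -tol_q
             else dp_in <= tol_p
    ok_out <- if (s_out == "open") stc$Q[["d_out"]] >= -tol_q
              else dp_out <= tol_p
    if (ok_in && ok_out) {
      consistent <- consistent + 1L
      expect_identical(list(d_in = s_in, d_out = s_out), out$diode_states)
    }
  }
  expect_identical(consistent, 1L)
})

test_that("implicit trajectories track the stiff-ODE oracle on random linear circuits", {
  skip_if_not_installed("deSolve")
  for (seed in 1:5) {
    secs <- gen_ladder(seed)
    n <- ladder_netlist(secs)
    r <- ladder_run(n, dt = 1e-3, 2, scheme = "trapezoidal", stride = 1L)
    Po <- ladder_oracle(secs, r$time)
    expect_lt(ladder_error(r, Po), 1e-4)
  }
})

test_that("measured convergence orders match the schemes' nominal orders", {
  skip_if_not_installed("deSolve")
  secs <- gen_ladder(3)
  n <- ladder_netlist(secs)
  errs <- function(scheme) {
    vapply(c(4e-3, 2e-3), function(dd) {
      r <- ladder_run(n, dd, 2, scheme)
      ladder_error(r, ladder_oracle(secs, r$time))
    }, numeric(1))
  }
  e_be <- errs("backward_euler")
  e_tr <- errs("trapezoidal")
  expect_lt(abs(log2(e_be[1L] / e_be[2L]) - 1), 0.2)
  expect_lt(abs(log2(e_tr[1L] / e_tr[2L]) - 2), 0.4)
})

test_that("KCL residuals vanish at every accepted step", {
  n <- make_windkessel3(0.1, 1, 1)
  cfg <- solver_config(dt = 1e-2, duration = 2)
  fz <- forcing_set(inlet = forcing_at("flow",
                                       gen_inflow_waveform(0.5, 1, 0.35)))
  r <- run_simulation(n, fz, list(), cfg)
  # KCL at the internal node: Q(R_p) - Q(C) - Q(R_d) = 0
  resid <- r$Q[, "R_p"] - r$Q[, "C"] - r$Q[, "R_d"]
  expect_lt(max(abs(resid)), 1e-9 * max(abs(r$Q)))
})

test_that("identical inputs give bit-identical result sets", {
  loop <- make_closed_loop()
  cfg <- solver_config(dt = 2e-3, n_cycles = 2, period = 0.8)
  r1 <- run_simulation(loop$netlist, forcing_none(), loop$controllers, cfg)
  r2 <- run_simulation(loop$netlist, forcing_none(), loop$controllers, cfg)
  expect_identical(r1$P, r2$P)
  expect_identical(r1$Q, r2$Q)
  expect_identical(r1$V, r2$V)
})

test_that("cycle convergence metric behaves as a contraction diagnostic", {
  # periodically forced linear Windkessel: metric decreases monotonically
  n <- make_windkessel3(0.1, 1, 1)
  fz <- forcing_set(inlet = forcing_at("flow",
                                       gen_inflow_waveform(0.5, 1, 0.35)))
  cfg <- solver_config(dt = 1e-3, duration = 8, period = 1)
  r <- run_simulation(n, fz, list(), cfg)
  conv <- check_cycle_convergence(r, 1)
  expect_true(all(diff(conv$metric) < 0))
  expect_lt(tail(conv$metric, 1L), 1e-3)
  # constant forcing: metric decays toward zero after the transient
  rc <- run_simulation(n, const_flow_forcing(1), list(), cfg)
  convc <- check_cycle_convergence(rc, 1)
  expect_lt(tail(convc$metric, 1L), 0.05 * head(convc$metric, 1L))
  expect_true(all(diff(convc$metric) < 0))
  # a deliberately wrong period plateaus at a nonzero floor
  convw <- check_cycle_convergence(r, 0.8)
  expect_gt(tail(convw$metric, 1L), 1e-2)
  # period must be commensurate with the sampling interval
  expect_error(check_cycle_convergence(r, 0.7777), "integer multiple")
})

test_that("closed loops conserve stored volume", {
  loop <- make_closed_loop()
  cfg <- solver_config(dt = 1e-3, n_cycles = 5, period = 0.8,
                       output_stride = 4)
  r <- run_simulation(loop$netlist, forcing_none(), loop$controllers, cfg)
  vol <- stored_volume(loop$netlist, r)
  expect_lt(max(abs(vol - vol[1L])) / vol[1L], 1e-8)
  expect_true(check_complementarity(loop$netlist, r)$ok)
})
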