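test_that("Windkessel builders produce the declared structure", {
  wk3 <- make_windkessel3(0.1, 1, 1)
  expect_length(wk3$components, 3L)
  expect_length(wk3$nodes, 3L)
  roles <- vapply(wk3$nodes, `[[`, "", "role")
  expect_identical(sum(roles == "interface"), 1L)
  expect_false(has_errors(validate_netlist(wk3)))
  expect_false(has_errors(validate_netlist(make_windkessel2(1, 1))))
  expect_error(make_windkessel3(0, 1, 1), "> 0")
  expect_error(make_windkessel2(-1, 1), "> 0")
})

test_that("three-element Windkessel matches its analytic input impedance", {
  # high-frequency limit: pulse amplitude -> q_amp * R_p
  R_p <- 0.1; C <- 1; R_d <- 1
  n <- make_windkessel3(R_p, C, R_d)
  period <- 0.01 * R_d * C      # omega*tau >> 1
  q_amp <- 0.5
  # zero-mean drive: no slow DC charging transient to pollute the
  # amplitude measurement
  fz <- forcing_set(inlet = forcing_at("flow", function(t)
    q_amp * sin(2 * pi * t / period)))
  cfg <- solver_config(dt = period / 200, duration = 30 * period,
                       period = period, scheme = "trapezoidal")
  r <- run_simulation(n, fz, list(), cfg)
  idx <- r$time > 28 * period
  pulse_amp <- (max(r$P[idx, "inlet"]) - min(r$P[idx, "inlet"])) / 2
  # analytic |Z(omega)| = |R_p + R_d/(1+i w R_d C)|
  w <- 2 * pi / period
  Zmag <- Mod(R_p + R_d / (1 + 1i * w * R_d * C))
  expect_equal(pulse_amp, q_amp * Zmag, tolerance = 0.02)
  expect_equal(pulse_amp, q_amp * R_p, tolerance = 0.05)
})

test_that("coronary preset has the tagged microvascular chain", {
  n <- make_coronary_bc(12, 0.05, 12, 6, tag = "lad_micro")
  expect_length(n$components, 4L)
  tags <- vapply(n$components, `[[`, "", "tag")
  tagged <- n$components[[which(!is.na(tags))]]
  expect_identical(tagged$kind, "resistor")
  expect_identical(tagged$tag, "lad_micro")
  expect_false(has_errors(validate_netlist(n)))
  expect_error(make_coronary_bc(0, 1, 1, 1), "> 0")
})

test_that("coronary steady flow and step-response time constant are analytic", {
  R_a <- 20; C_im <- 0.5; R_m <- 0.7; R_v <- 0.3
  n <- make_coronary_bc(R_a, C_im, R_m, R_v)
  P_in <- 10
  fz <- forcing_set(inlet = forcing_at("pressure", function(t)
    rep(P_in, length(t))))
  cfg <- solver_config(dt = 1e-3, duration = 8)
  r <- run_simulation(n, fz, list(), cfg)
  expect_equal(tail(r$Q[, "R_m"], 1L), P_in / (R_a + R_m + R_v),
               tolerance = 1e-3)
  # transient: capacitor sees R_a || (R_m + R_v); with R_a >> R_m + R_v
  # this is within 10% of C_im (R_m + R_v)
  tau_exact <- C_im * 1 / (1 / R_a + 1 / (R_m + R_v))
  q <- r$Q[, "R_m"]
  q_inf <- tail(q, 1L)
  gap <- abs(q - q_inf)
  i_tau <- which(gap <= gap[1L] * exp(-1))[1L]
  tau_meas <- r$time[i_tau]
  expect_equal(tau_meas, tau_exact, tolerance = 0.05)
  expect_equal(tau_meas, C_im * (R_m + R_v), tolerance = 0.1)
})

test_that("closed-loop preset is a single physiologic circuit", {
  loop <- make_closed_loop()
  n <- loop$netlist
  expect_identical(length(unique(netlist_components(n))), 1L)
  kinds <- vapply(n$components, `[[`, "", "kind")
  expect_identical(sum(kinds == "chamber"), 2L)
  expect_gte(sum(kinds == "diode"), 2L)
  roles <- vapply(n$nodes, `[[`, "", "role")
  expect_identical(sum(roles == "interface"), 0L)
  expect_false(has_errors(validate_netlist(n)))
  # initial stored volume equals the declared total blood volume
  cfg <- solver_config(dt = 1e-3, duration = 2e-3)
  r <- run_simulation(n, forcing_none(), loop$controllers, cfg)
  vol0 <- stored_volume(n, r)[1L]
  expect_equal(m3_to_ml(vol0), loop$params$total_volume, tolerance = 1e-9)
})

test_that("post-reperfusion mapping is the identity at zero and monotone in s", {
  p <- closed_loop_params()
  expect_identical(apply_prs(p, 0), p)
  p1 <- apply_prs(p, 1)
  expect_equal(p1$r_sys / p$r_sys, 0.5, tolerance = 1e-12)
  svals <- seq(0, 1, by = 0.25)
  rs <- vapply(svals, function(s) apply_prs(p, s)$r_sys, numeric(1))
  rp <- vapply(svals, function(s) apply_prs(p, s)$r_pul, numeric(1))
  vs <- vapply(svals, function(s) apply_prs(p, s)$venous_volume_shift,
               numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_true(all(diff(rp) > 0))
  expect_true(all(diff(vs) > 0))
  expect_error(apply_prs(p, 1.2), "\\[0, 1\\]")
  expect_error(apply_prs(p, -0.1), "\\[0, 1\\]")
})

test_that("post-reperfusion haemodynamics move in the reported directions", {
  run_means <- function(s) {
    p <- closed_loop_params()
    if (s > 0) p <- apply_prs(p, s)
    loop <- make_closed_loop(p)
    cfg <- solver_config(dt = 2e-3, n_cycles = 12, period = 0.8,
                         output_stride = 2)
    r <- run_simulation(loop$netlist, forcing_none(), loop$controllers,
                        cfg)
    spc <- round(0.8 / (r$time[2L] - r$time[1L]))
    idx <- (length(r$time) - spc + 1L):length(r$time)
    c(map = mean(r$P[idx, "art_n"]), pap = mean(r$P[idx, "pa_n"]),
      cvp = mean(r$P[idx, "ven_n"]))
  }
  base <- run_means(0)
  prs <- run_means(0.6)
  expect_lt(prs[["map"]], base[["map"]])
  expect_gt(prs[["pap"]], base[["pap"]])
  expect_gt(prs[["cvp"]], base[["cvp"]])
})

test_that("pulsatile inflow waveform integrates to one stroke volume", {
  sv <- 7e-5; period <- 0.8
  q <- gen_inflow_waveform(sv, period, 0.35)
  tt <- seq(0, period, length.out = 20001L)
  integral <- sum((q(tt)[-1L] + q(tt)[-length(tt)]) / 2) * diff(tt)[1L]
  expect_equal(integral, sv, tolerance = 1e-6)
  expect_true(all(q(tt) >= 0))
  expect_equal(mean(q(seq(0, 10 * period, by = 1e-4))), sv / period,
               tolerance = 1e-3)
  expect_error(gen_inflow_waveform(-1, 1, 0.3), "> 0")
  expect_error(gen_inflow_waveform(1, 1, 1.2), "systole_fraction")
})

test_that("synthetic observations are exact at zero noise and reproducible", {
  n <- make_windkessel3(0.1, 1, 1)
  fz <- forcing_set(inlet = forcing_at("flow",
                                       gen_inflow_waveform(0.5, 1, 0.35)))
  cfg <- solver_config(dt = 5e-3, duration = 2)
  r <- run_simulation(n, fz, list(), cfg)
  obs0 <- gen_observations(n, fz, list(), cfg, channels = "P.inlet",
                           noise_sd = 0, seed = 3)
  expect_identical(obs0$channels[, "P.inlet"],
                   unname(r$P[, "inlet"]))
  obs_a <- gen_observations(n, fz, list(), cfg, channels = "P.inlet",
                            noise_sd = 0.1, seed = 3)
  obs_b <- gen_observations(n, fz, list(), cfg, channels = "P.inlet",
                            noise_sd = 0.1, seed = 3)
  expect_identical(obs_a$channels, obs_b$channels)
  expect_error(gen_observations(n, fz, list(), cfg, channels = "P.nope",
                                noise_sd = 0, seed = 1), "unknown channel")
})

test_that("empirical observation noise matches the requested level", {
  n <- make_windkessel2(1, 1)
  cfg <- solver_config(dt = 1e-3, duration = 10)
  fz <- const_flow_forcing(1)
  truth <- run_simulation(n, fz, list(), cfg)
  obs <- gen_observations(n, fz, list(), cfg, channels = "P.inlet",
                          noise_sd = 0.25, seed = 11)
  resid <- obs$channels[, "P.inlet"] - truth$P[, "inlet"]
  expect_gt(length(resid), 1e4)
  expect_equal(stats::sd(resid), 0.25, tolerance = 0.05)
})

test_that("observation CSV round trip preserves the record", {
  n <- make_windkessel2(1, 1)
  cfg <- solver_config(dt = 1e-2, duration = 1)
  obs <- gen_observations(n, const_flow_forcing(1), list(), cfg,
                          channels = c("P.inlet", "Q.R"),
                          noise_sd = 0.05, seed = 5)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_observations_csv(obs, tf)
  obs2 <- read_observations_csv(tf)
  expect_equal(obs2$channels, obs$channels, tolerance = 1e-15)
  expect_equal(unname(obs2$noise_sd), unname(obs$noise_sd))
  # non-monotone times rejected
  df <- utils::read.csv(tf, check.names = FALSE)
  df$time[2L] <- df$time[4L]
  utils::write.csv(df, tf, row.names = FALSE)
  expect_error(read_observations_csv(tf), "strictly increase")
})
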