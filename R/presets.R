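#' Two- and three-element Windkessel presets
#'
#' \code{make_windkessel2} builds the parallel R-C outlet model on an
#' interface node; \code{make_windkessel3} adds a proximal resistance
#' between the interface node and the R-C pair (characteristic impedance).
#'
#' @param R,R_d distal resistance (Pa.s/m^3, > 0).
#' @param C compliance (m^3/Pa, > 0).
#' @param R_p proximal resistance (Pa.s/m^3, > 0).
#' @return an \code{\link{lpn_netlist}} that passes
#'   \code{\link{validate_netlist}} cleanly.
#' @export
make_windkessel2 <- function(R, C) {
  if (R <= 0 || C <= 0) stop("Windkessel parameters must be > 0")
  lpn_netlist(
    list(lpn_component("resistor", "R", "inlet", "ground", R),
         lpn_component("capacitor", "C", "inlet", "ground", C)),
    list(lpn_node("inlet", "interface"),
         lpn_node("ground", "reference", 0)),
    metadata = list(name = "windkessel2"))
}

#' @rdname make_windkessel2
#' @export
make_windkessel3 <- function(R_p, C, R_d) {
  if (R_p <= 0 || C <= 0 || R_d <= 0) stop("Windkessel parameters must be > 0")
  lpn_netlist(
    list(lpn_component("resistor", "R_p", "inlet", "mid", R_p),
         lpn_component("capacitor", "C", "mid", "ground", C),
         lpn_component("resistor", "R_d", "mid", "ground", R_d)),
    list(lpn_node("inlet", "interface"),
         lpn_node("mid"),
         lpn_node("ground", "reference", 0)),
    metadata = list(name = "windkessel3"))
}

#' Coronary boundary-condition preset
#'
#' Four-component chain: arterial resistance from the interface node to an
#' intramyocardial node holding a compliance, then the microvascular
#' resistance (carrying the control tag, so the hunger controller can
#' govern it) and the venous resistance to ground.
#'
#' @param R_a arterial resistance (Pa.s/m^3).
#' @param C_im intramyocardial compliance (m^3/Pa).
#' @param R_m microvascular resistance (Pa.s/m^3); tagged.
#' @param R_v venous resistance (Pa.s/m^3).
#' @param tag control tag for the microvascular resistor.
#' @return an \code{\link{lpn_netlist}}.
#' @export
make_coronary_bc <- function(R_a, C_im, R_m, R_v, tag = "cor_micro") {
  if (R_a <= 0 || C_im <= 0 || R_m <= 0 || R_v <= 0)
    stop("coronary parameters must be > 0")
  lpn_netlist(
    list(lpn_component("resistor", "R_a", "inlet", "im", R_a),
         lpn_component("capacitor", "C_im", "im", "ground", C_im),
         lpn_component("resistor", "R_m", "im", "ven", R_m, tag = tag),
         lpn_component("resistor", "R_v", "ven", "ground", R_v)),
    list(lpn_node("inlet", "interface"),
         lpn_node("im"), lpn_node("ven"),
         lpn_node("ground", "reference", 0)),
    metadata = list(name = "coronary_bc"))
}

#' Closed-loop circulation parameters
#'
#' Parameter set for \code{\link{make_closed_loop}}, stated in clinical
#' units (mmHg, mL, s) and converted to SI on construction. Defaults are a
#' generic resting adult calibration chosen so the 20-cycle converged loop
#' sits at physiological operating points (cycle-mean aortic pressure in
#' the 70--110 mmHg band, cardiac output near 5 L/min).
#'
#' @param period heart period (s).
#' @param lv_emax,lv_emin left-ventricular elastance bounds (mmHg/mL).
#' @param rv_emax,rv_emin right-ventricular elastance bounds (mmHg/mL).
#' @param t_peak_frac systolic peak time as a fraction of the period.
#' @param lv_v0,rv_v0 unstressed chamber volumes (mL).
#' @param lv_vinit,rv_vinit initial chamber volumes (mL).
#' @param valve_r valve forward resistance (mmHg.s/mL).
#' @param r_prox,c_art,r_sys systemic proximal resistance, arterial
#'   compliance, systemic vascular resistance (mmHg.s/mL, mL/mmHg).
#' @param c_ven venous compliance (mL/mmHg).
#' @param c_pa,r_pul,c_pv pulmonary arterial compliance, pulmonary
#'   resistance, pulmonary venous compliance.
#' @param r_cor_a,c_im,r_cor_m,r_cor_v coronary branch parameters.
#' @param cor_tag control tag on the coronary microvascular resistor.
#' @param total_volume total stressed blood volume in the loop (mL).
#' @param venous_volume_shift extra volume loaded into the venous
#'   compartment (mL); the post-reperfusion scenario raises it to lift
#'   central venous pressure.
#' @return a \code{closed_loop_params} list (clinical units).
#' @export
closed_loop_params <- function(period = 0.8,
                               lv_emax = 2.0, lv_emin = 0.08,
                               rv_emax = 0.55, rv_emin = 0.05,
                               t_peak_frac = 0.3,
                               lv_v0 = 10, rv_v0 = 10,
                               lv_vinit = 130, rv_vinit = 130,
                               valve_r = 0.005,
                               r_prox = 0.05, c_art = 1.5, r_sys = 1.0,
                               c_ven = 50,
                               c_pa = 4, r_pul = 0.08, c_pv = 8,
                               r_cor_a = 12, c_im = 0.05,
                               r_cor_m = 12, r_cor_v = 6,
                               cor_tag = "cor_micro",
                               total_volume = 800,
                               venous_volume_shift = 0) {
  p <- as.list(environment())
  pos <- c("period", "lv_emax", "lv_emin", "rv_emax", "rv_emin",
           "t_peak_frac", "valve_r", "r_prox", "c_art", "r_sys", "c_ven",
           "c_pa", "r_pul", "c_pv", "r_cor_a", "c_im", "r_cor_m", "r_cor_v",
           "total_volume")
  for (fld in pos) if (p[[fld]] <= 0) stop(sprintf("%s must be > 0", fld))
  if (t_peak_frac >= 1) stop("t_peak_frac must be < 1")
  structure(p, class = "closed_loop_params")
}

#' Build the closed-loop circulation fixture
#'
#' One connected circuit with two time-varying elastance chambers (left and
#' right ventricle), four ideal-diode valves, a systemic Windkessel with a
#' coronary branch, a venous compartment and a pulmonary compartment. The
#' systemic and pulmonary vascular beds are lumped resistive-capacitive
#' elements closing the loop (the desk-scale stand-in for full 3D arterial
#' domains). No interface nodes: the loop is autonomous, driven only by the
#' elastance controllers. Initial compartment pressures are set so the
#' total stored volume equals \code{total_volume + venous_volume_shift}.
#'
#' @param p a \code{\link{closed_loop_params}}.
#' @return list with \code{netlist}, \code{controllers} (two elastance
#'   controllers), and \code{params} (the input, for provenance).
#' @export
make_closed_loop <- function(p = closed_loop_params()) {
  stopifnot(inherits(p, "closed_loop_params"))
  # initial compartment pressures (mmHg)
  p_art0 <- 80; p_pa0 <- 15; p_pv0 <- 8; p_im0 <- 75
  fixed_ml <- p$c_art * p_art0 + p$c_pa * p_pa0 + p$c_pv * p_pv0 +
    p$c_im * p_im0 + p$lv_vinit + p$rv_vinit
  p_ven0 <- (p$total_volume + p$venous_volume_shift - fixed_ml) / p$c_ven
  if (p_ven0 <= 0)
    stop("total_volume too small: venous pressure would be non-positive")

  vr <- rc_to_si(p$valve_r)
  comps <- list(
    lpn_component("chamber", "lv", "lv_n", "ground", ec_to_si(p$lv_emin),
                  tag = "lv_elastance", init_v = ml_to_m3(p$lv_vinit),
                  v0 = ml_to_m3(p$lv_v0)),
    lpn_component("diode", "aortic_valve", "lv_n", "ao_n", 0, r_fwd = vr),
    lpn_component("resistor", "r_prox", "ao_n", "art_n",
                  rc_to_si(p$r_prox)),
    lpn_component("capacitor", "c_art", "art_n", "ground",
                  cc_to_si(p$c_art), init_dp = mmhg_to_pa(p_art0)),
    lpn_component("resistor", "r_sys", "art_n", "ven_n", rc_to_si(p$r_sys)),
    lpn_component("capacitor", "c_ven", "ven_n", "ground",
                  cc_to_si(p$c_ven), init_dp = mmhg_to_pa(p_ven0)),
    lpn_component("resistor", "r_cor_a", "art_n", "cor_m_n",
                  rc_to_si(p$r_cor_a)),
    lpn_component("capacitor", "c_im", "cor_m_n", "ground",
                  cc_to_si(p$c_im), init_dp = mmhg_to_pa(p_im0)),
    lpn_component("resistor", "r_cor_m", "cor_m_n", "cor_v_n",
                  rc_to_si(p$r_cor_m), tag = p$cor_tag),
    lpn_component("resistor", "r_cor_v", "cor_v_n", "ven_n",
                  rc_to_si(p$r_cor_v)),
    lpn_component("diode", "tricuspid_valve", "ven_n", "rv_n", 0,
                  r_fwd = vr),
    lpn_component("chamber", "rv", "rv_n", "ground", ec_to_si(p$rv_emin),
                  tag = "rv_elastance", init_v = ml_to_m3(p$rv_vinit),
                  v0 = ml_to_m3(p$rv_v0)),
    lpn_component("diode", "pulmonary_valve", "rv_n", "pa_n", 0,
                  r_fwd = vr),
    lpn_component("capacitor", "c_pa", "pa_n", "ground", cc_to_si(p$c_pa),
                  init_dp = mmhg_to_pa(p_pa0)),
    lpn_component("resistor", "r_pul", "pa_n", "pv_n", rc_to_si(p$r_pul)),
    lpn_component("capacitor", "c_pv", "pv_n", "ground", cc_to_si(p$c_pv),
                  init_dp = mmhg_to_pa(p_pv0)),
    lpn_component("diode", "mitral_valve", "pv_n", "lv_n", 0, r_fwd = vr))
  nodes <- lapply(c("lv_n", "ao_n", "art_n", "ven_n", "cor_m_n", "cor_v_n",
                    "rv_n", "pa_n", "pv_n"), lpn_node)
  nodes <- c(nodes, list(lpn_node("ground", "reference", 0)))
  n <- lpn_netlist(comps, nodes, metadata = list(name = "closed_loop"))

  t_peak <- p$t_peak_frac * p$period
  ctrls <- list(
    controller_elastance("lv_elastance", ec_to_si(p$lv_emin),
                         ec_to_si(p$lv_emax), p$period, t_peak,
                         name = "lv_E"),
    controller_elastance("rv_elastance", ec_to_si(p$rv_emin),
                         ec_to_si(p$rv_emax), p$period, t_peak,
                         name = "rv_E"))
  list(netlist = n, controllers = ctrls, params = p)
}

#' Post-reperfusion-syndrome parameter perturbation
#'
#' Maps a severity s in [0, 1] onto the closed-loop parameters: systemic
#' vascular resistance scaled by (1 - 0.5 s), pulmonary resistance by
#' (1 + s), and the venous compartment loaded with extra volume
#' (150 s mL) to raise central venous pressure. s = 0 is the identity;
#' every affected parameter moves monotonically in s.
#'
#' @param p a \code{\link{closed_loop_params}}.
#' @param s severity in [0, 1].
#' @return perturbed \code{closed_loop_params}.
#' @export
apply_prs <- function(p, s) {
  stopifnot(inherits(p, "closed_loop_params"))
  if (!is.finite(s) || s < 0 || s > 1) stop("severity s must be in [0, 1]")
  p$r_sys <- p$r_sys * (1 - 0.5 * s)
  p$r_pul <- p$r_pul * (1 + s)
  p$venous_volume_shift <- p$venous_volume_shift + 150 * s
  p
}

#' Default myocardial hunger calibration for the closed-loop preset
#'
#' Gains calibrated once against the baseline closed-loop preset so that
#' resting coronary supply exceeds demand by a few percent (hunger pinned
#' at zero at baseline) while the post-reperfusion perturbation produces a
#' sustained deficit beyond the autoregulatory dilation reserve.
#'
#' @return a \code{\link{hunger_params}}.
#' @export
default_hunger_params <- function() {
  hunger_params(alpha = 1.0, beta = 0.05, k_s = 5.5e5, k_f = 20,
                g_min = 0.9)
}

#' Closed-loop myocardial oxygen supply/demand scenario
#'
#' Assembles the closed-loop circulation with the hunger controller
#' attached to the coronary microvascular resistance. \code{severity = 0}
#' is the calibrated baseline (hunger stays near zero);
#' \code{severity > 0} applies the post-reperfusion perturbation via
#' \code{\link{apply_prs}} (hunger grows continually once the deficit
#' exceeds the autoregulatory reserve).
#'
#' @param p a \code{\link{closed_loop_params}}.
#' @param severity post-reperfusion severity in [0, 1].
#' @param hp a \code{\link{hunger_params}}.
#' @param feedback enable hunger feedback on the coronary resistance.
#' @return list with \code{netlist}, \code{controllers}, \code{params}.
#' @export
hunger_scenario <- function(p = closed_loop_params(), severity = 0,
                            hp = default_hunger_params(), feedback = TRUE) {
  p2 <- if (severity > 0) apply_prs(p, severity) else p
  loop <- make_closed_loop(p2)
  r0 <- rc_to_si(p2$r_cor_m)
  hc <- controller_hunger(p2$cor_tag, r0, hp,
                          chamber_pressure = "P.lv_n",
                          eject_flow = "Q.aortic_valve",
                          coronary_flow = "Q.r_cor_m",
                          feedback = feedback)
  loop$controllers <- c(loop$controllers, list(hc))
  loop$params <- p2
  loop
}

#' Pulsatile inflow waveform
#'
#' Half-sine systolic ejection: zero during diastole, non-negative,
#' periodic, integrating to exactly one stroke volume per period.
#'
#' @param stroke_volume volume ejected per beat (m^3).
#' @param period cardiac period (s).
#' @param systole_fraction fraction of the period spent ejecting, in
#'   (0, 1).
#' @return function of time returning flow (m^3/s).
#' @export
gen_inflow_waveform <- function(stroke_volume, period,
                                systole_fraction = 0.35) {
  if (stroke_volume <= 0 || period <= 0)
    stop("stroke_volume and period must be > 0")
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stop("systole_fraction must be in (0, 1)")
  ts <- systole_fraction * period
  peak <- pi * stroke_volume / (2 * ts)
  function(t) {
    tau <- t %% period
    ifelse(tau < ts, peak * sin(pi * tau / ts), 0)
  }
}

#' Generate synthetic noisy observations from a simulation
#'
#' Runs the simulation and samples the named channels on the output grid,
#' adding i.i.d. zero-mean Gaussian noise per channel. The synthetic
#' stand-in for time-resolved patient pressure/flow measurements consumed
#' by the Kalman-filter calibrator.
#'
#' @param n an \code{\link{lpn_netlist}}.
#' @param forcing a \code{\link{forcing_set}}.
#' @param controllers controller list.
#' @param config a \code{\link{solver_config}}.
#' @param channels character vector of channel names
#'   (\code{"P.<node>"}, \code{"Q.<component>"}, \code{"V.<chamber>"}).
#' @param noise_sd scalar or per-channel named vector of noise standard
#'   deviations (channel units).
#' @param seed integer seed for the noise.
#' @return an \code{lpn_observations}: list with \code{times},
#'   \code{channels} (matrix, one column per channel), \code{noise_sd},
#'   \code{seed}.
#' @export
gen_observations <- function(n, forcing, controllers = list(), config,
                             channels, noise_sd = 0, seed = 1L) {
  r <- run_simulation(n, forcing, controllers, config)
  if (length(noise_sd) == 1L)
    noise_sd <- stats::setNames(rep(noise_sd, length(channels)), channels)
  if (!all(channels %in% names(noise_sd)))
    stop("noise_sd must cover every channel")
  Z <- sapply(channels, function(ch) result_channel(r, ch))
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = length(channels),
                                   dimnames = list(NULL, channels))
  set.seed(seed)
  for (j in seq_along(channels)) {
    sdj <- noise_sd[[channels[j]]]
    if (sdj > 0) Z[, j] <- Z[, j] + stats::rnorm(nrow(Z), 0, sdj)
  }
  structure(list(times = r$time, channels = Z,
                 noise_sd = noise_sd[channels], seed = seed),
            class = "lpn_observations")
}

#' Read/write observation sets as CSV (+ JSON sidecar)
#'
#' CSV columns: \code{time}, then one column per channel; the sidecar
#' stores the noise level and seed.
#'
#' @param obs an \code{lpn_observations}.
#' @param path CSV path; sidecar at \code{<path>.json}.
#' @return \code{read_observations_csv} returns an
#'   \code{lpn_observations}.
#' @export
write_observations_csv <- function(obs, path) {
  df <- data.frame(time = obs$times)
  for (ch in colnames(obs$channels)) df[[ch]] <- obs$channels[, ch]
  cols <- vapply(df, function(col) sprintf("%.17g", col),
                 character(nrow(df)))
  writeLines(c(paste(colnames(df), collapse = ","),
               apply(matrix(cols, nrow = nrow(df)), 1L, paste,
                     collapse = ",")), path)
  jsonlite::write_json(list(noise_sd = as.list(obs$noise_sd),
                            seed = obs$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("observation CSV needs a 'time' column")
  times <- df$time
  if (any(diff(times) <= 0)) stop("observation times must strictly increase")
  Z <- as.matrix(df[setdiff(names(df), "time")])
  side <- paste0(path, ".json")
  noise_sd <- stats::setNames(rep(NA_real_, ncol(Z)), colnames(Z))
  seed <- NA_integer_
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$noise_sd))
      noise_sd[names(meta$noise_sd)] <- unlist(meta$noise_sd)
    if (!is.null(meta$seed)) seed <- meta$seed
  }
  structure(list(times = times, channels = Z, noise_sd = noise_sd,
                 seed = seed), class = "lpn_observations")
}
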