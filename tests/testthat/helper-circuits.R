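# Shared fixtures: small canonical circuits built in code.

wk2_decay_netlist <- function(R = 1, C = 1, P0 = 1) {
  n <- make_windkessel2(R, C)
  n$components[[2L]]$init_dp <- P0
  n
}

zero_flow_forcing <- function(node = "inlet") {
  fz <- list(forcing_at("flow", function(t) rep(0, length(t))))
  names(fz) <- node
  fz
}

const_flow_forcing <- function(q, node = "inlet") {
  fz <- list(forcing_at("flow", function(t) rep(q, length(t))))
  names(fz) <- node
  fz
}

# two-sub-circuit netlist shaped like a boundary-condition set for two
# vessels: each sub-circuit is a Windkessel on its own interface node
two_bc_netlist <- function() {
  parse_netlist(c(
    "node in1 interface",
    "node g1 reference=0",
    "node in2 interface",
    "node m2",
    "node g2 reference=0",
    "component resistor r1 in1 g1 1",
    "component capacitor c1 in1 g1 1",
    "component resistor r2p in2 m2 0.1",
    "component capacitor c2 m2 g2 1",
    "component resistor r2d m2 g2 1"))
}

# chamber pump: elastance chamber with inlet/outlet valves between a
# preload reservoir and an afterload Windkessel
pump_netlist <- function() {
  parse_netlist(c(
    "node src",
    "node ch_n",
    "node out_n",
    "node ground reference=0",
    "component pressure_source preload src - 700",
    "component diode d_in src ch_n 0 r_fwd=1e5",
    "component chamber ch ch_n ground 1e7 tag=pump_E init_v=1.3e-4 v0=1e-5",
    "component diode d_out ch_n out_n 0 r_fwd=1e5",
    "component capacitor c_out out_n ground 1e-8 init_dp=10000",
    "component resistor r_out out_n ground 1.2e8"))
}
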