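#' @title Modified nodal analysis assembly
#' @description
#' The circuit state is the vector x = [P; Q; V]: pressures at every
#' non-reference node, flow through every component, volume of every
#' chamber. One implicit step from t to t+dt solves M x = b where the rows
#' are Kirchhoff current law (KCL) at each non-reference node followed by
#' one constitutive row per component and one volume-evolution row per
#' chamber, all discretised at t+dt (backward Euler) or by the trapezoidal
#' rule. Reference-node pressures are constants folded into b.
#' @name mna
#' @keywords internal
NULL

# Precompute index maps and per-component terminal resolution for a netlist.
build_model <- function(n) {
  node_ids <- netlist_node_ids(n)
  roles <- stats::setNames(vapply(n$nodes, `[[`, "", "role"), node_ids)
  ref_p <- stats::setNames(vapply(n$nodes, function(nd)
    if (nd$role == "reference") nd$pressure else NA_real_, numeric(1)),
    node_ids)
  p_ids <- node_ids[roles != "reference"]
  p_index <- stats::setNames(seq_along(p_ids), p_ids)
  comp_ids <- netlist_component_ids(n)
  nP <- length(p_ids)
  nQ <- length(comp_ids)
  q_index <- stats::setNames(nP + seq_len(nQ), comp_ids)
  chamber_ids <- comp_ids[vapply(n$components, `[[`, "", "kind") == "chamber"]
  v_index <- stats::setNames(nP + nQ + seq_along(chamber_ids), chamber_ids)
  nV <- length(chamber_ids)
  diode_ids <- comp_ids[vapply(n$components, `[[`, "", "kind") == "diode"]

  comps <- lapply(n$components, function(comp) {
    ia <- if (comp$start %in% p_ids) p_index[[comp$start]] else 0L
    pa <- if (ia == 0L) ref_p[[comp$start]] else 0
    if (is.na(comp$end)) {
      ib <- -1L; pb <- 0   # single-node source: no end terminal
    } else if (comp$end %in% p_ids) {
      ib <- p_index[[comp$end]]; pb <- 0
    } else {
      ib <- 0L; pb <- ref_p[[comp$end]]
    }
    list(id = comp$id, kind = comp$kind, ia = ia, ib = ib,
         pa_const = pa, pb_const = pb, r_fwd = comp$r_fwd, v0 = comp$v0,
         iq = q_index[[comp$id]],
         iv = if (comp$id %in% chamber_ids) v_index[[comp$id]] else NA_integer_)
  })
  names(comps) <- comp_ids

  pre <- function(prefix, ids)
    if (length(ids)) paste0(prefix, ids) else character(0)
  unknowns <- c(pre("P.", p_ids), pre("Q.", comp_ids),
                pre("V.", chamber_ids))
  iface_ids <- node_ids[roles == "interface"]
  list(node_ids = node_ids, roles = roles, ref_p = ref_p,
       p_ids = p_ids, p_index = p_index, q_index = q_index,
       v_index = v_index, nP = nP, nQ = nQ, nV = nV,
       n_unknowns = nP + nQ + nV, unknowns = unknowns,
       comps = comps, comp_ids = comp_ids, chamber_ids = chamber_ids,
       diode_ids = diode_ids, iface_ids = iface_ids)
}

# signed pressure-difference coefficients of a component into a matrix row
add_dp <- function(M, row, cmp, sign = 1) {
  if (cmp$ia > 0L) M[row, cmp$ia] <- M[row, cmp$ia] + sign
  if (cmp$ib > 0L) M[row, cmp$ib] <- M[row, cmp$ib] - sign
  M
}

# constant part of the pressure difference (reference-node contributions)
dp_const <- function(cmp) cmp$pa_const - cmp$pb_const

# previous pressure difference from a full state (all nodes present in P)
prev_dp <- function(cmp, model, prev) {
  pa <- if (cmp$ia > 0L) prev$P[[model$p_ids[cmp$ia]]] else cmp$pa_const
  pb <- if (cmp$ib > 0L) prev$P[[model$p_ids[cmp$ib]]]
        else if (cmp$ib == 0L) cmp$pb_const else 0
  pa - pb
}

assemble_matrix <- function(model, params, diode_states, dt, scheme) {
  nU <- model$n_unknowns
  M <- matrix(0, nU, nU)
  # KCL rows: one per non-reference node
  for (cmp in model$comps) {
    if (cmp$ib == -1L) {
      # single-node source injects its flow into the start node
      if (cmp$ia > 0L) M[cmp$ia, cmp$iq] <- M[cmp$ia, cmp$iq] + 1
    } else {
      if (cmp$ia > 0L) M[cmp$ia, cmp$iq] <- M[cmp$ia, cmp$iq] - 1
      if (cmp$ib > 0L) M[cmp$ib, cmp$iq] <- M[cmp$ib, cmp$iq] + 1
    }
  }
  # constitutive rows
  for (cmp in model$comps) {
    row <- cmp$iq
    par <- params[[cmp$id]]
    switch(cmp$kind,
      resistor = {
        M <- add_dp(M, row, cmp)
        M[row, cmp$iq] <- M[row, cmp$iq] - par
      },
      capacitor = {
        if (scheme == "backward_euler") {
          M <- add_dp(M, row, cmp, sign = par / dt)
          M[row, cmp$iq] <- M[row, cmp$iq] - 1
        } else {
          M <- add_dp(M, row, cmp, sign = par)
          M[row, cmp$iq] <- M[row, cmp$iq] - dt / 2
        }
      },
      inductor = {
        fac <- if (scheme == "backward_euler") par / dt else 2 * par / dt
        M <- add_dp(M, row, cmp)
        M[row, cmp$iq] <- M[row, cmp$iq] - fac
      },
      diode = {
        if (identical(diode_states[[cmp$id]], "open")) {
          M <- add_dp(M, row, cmp)
          M[row, cmp$iq] <- M[row, cmp$iq] - cmp$r_fwd
        } else {
          M[row, cmp$iq] <- 1
        }
      },
      pressure_source = {
        if (cmp$ib == -1L) {
          if (cmp$ia > 0L) M[row, cmp$ia] <- 1
          # start on a reference node: row left for rhs consistency (0 = v - p_ref)
        } else {
          M <- add_dp(M, row, cmp)
        }
      },
      flow_source = {
        M[row, cmp$iq] <- 1
      },
      chamber = {
        M <- add_dp(M, row, cmp)
        M[row, cmp$iv] <- -par
        # volume row
        vrow <- cmp$iv
        M[vrow, cmp$iv] <- 1
        M[vrow, cmp$iq] <- if (scheme == "backward_euler") -dt else -dt / 2
      },
      stop(sprintf("unknown component kind '%s'", cmp$kind)))
  }
  M
}

assemble_rhs <- function(model, params, prev, forcing, dt, scheme, t_next) {
  b <- numeric(model$n_unknowns)
  for (cmp in model$comps) {
    row <- cmp$iq
    par <- params[[cmp$id]]
    switch(cmp$kind,
      resistor = { b[row] <- -dp_const(cmp) },
      capacitor = {
        dpp <- prev_dp(cmp, model, prev)
        if (scheme == "backward_euler") {
          b[row] <- (par / dt) * dpp - (par / dt) * dp_const(cmp)
        } else {
          b[row] <- par * dpp + (dt / 2) * prev$Q[[cmp$id]] -
            par * dp_const(cmp)
        }
      },
      inductor = {
        if (scheme == "backward_euler") {
          b[row] <- -(par / dt) * prev$Q[[cmp$id]] - dp_const(cmp)
        } else {
          b[row] <- -(2 * par / dt) * prev$Q[[cmp$id]] -
            prev_dp(cmp, model, prev) - dp_const(cmp)
        }
      },
      diode = {
        if (identical(prev$diode_states_next[[cmp$id]], "open"))
          b[row] <- -dp_const(cmp)
        else b[row] <- 0
      },
      pressure_source = {
        if (cmp$ib == -1L) {
          b[row] <- par - (if (cmp$ia == 0L) cmp$pa_const else 0)
        } else {
          b[row] <- par - dp_const(cmp)
        }
      },
      flow_source = { b[row] <- par },
      chamber = {
        b[row] <- -par * cmp$v0 - dp_const(cmp)
        vrow <- cmp$iv
        b[vrow] <- prev$V[[cmp$id]] +
          (if (scheme == "trapezoidal") (dt / 2) * prev$Q[[cmp$id]] else 0)
      })
  }
  # external forcing at interface nodes
  for (node in names(forcing)) {
    f <- forcing[[node]]
    ip <- model$p_index[[node]]
    if (f$type == "flow") {
      b[ip] <- b[ip] - f$fun(t_next)
    }
    # pressure forcing handled by row replacement in apply_pressure_forcing
  }
  b
}

# Dirichlet-type forcing: replace the KCL row of the node with P = p(t+dt)
apply_pressure_forcing <- function(M, b, model, forcing, t_next) {
  for (node in names(forcing)) {
    f <- forcing[[node]]
    if (f$type != "pressure") next
    ip <- model$p_index[[node]]
    M[ip, ] <- 0
    M[ip, ip] <- 1
    b[ip] <- f$fun(t_next)
  }
  list(M = M, b = b)
}

#' Assemble the implicit step system of a netlist
#'
#' Builds the square linear system M x = b whose solution is the circuit
#' state at t + dt given the state at t, with diode states held fixed.
#' Intended for inspection and testing; \code{\link{run_simulation}} drives
#' it internally.
#'
#' @param n an \code{\link{lpn_netlist}}.
#' @param prev a simulation state as returned by
#'   \code{\link{initial_state}} or \code{\link{advance_step}}.
#' @param forcing a \code{\link{forcing_set}} (external waveforms at
#'   interface nodes).
#' @param dt time step (s, > 0).
#' @param diode_states named character vector/list, \code{"open"} or
#'   \code{"closed"} per diode; defaults to the states carried by
#'   \code{prev}.
#' @param scheme \code{"backward_euler"} or \code{"trapezoidal"}.
#' @param params named parameter vector overriding \code{prev$params}.
#' @param model,check_singular internal.
#' @return list with \code{M}, \code{b}, \code{unknowns} (names of the
#'   solution entries, \code{P.<node>}, \code{Q.<component>},
#'   \code{V.<chamber>}), and the internal \code{model}.
#' @export
assemble_step_system <- function(n, prev, forcing, dt,
                                 diode_states = NULL,
                                 scheme = c("backward_euler", "trapezoidal"),
                                 params = NULL, model = NULL,
                                 check_singular = TRUE) {
  scheme <- match.arg(scheme)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (is.null(model)) model <- build_model(n)
  if (is.null(params)) params <- prev$params
  if (is.null(diode_states)) diode_states <- prev$diode_states
  diode_states <- as.list(diode_states)
  prev$diode_states_next <- diode_states
  t_next <- prev$t + dt
  M <- assemble_matrix(model, params, diode_states, dt, scheme)
  b <- assemble_rhs(model, params, prev, forcing, dt, scheme, t_next)
  fixed <- apply_pressure_forcing(M, b, model, forcing, t_next)
  M <- fixed$M; b <- fixed$b
  if (check_singular && equilibrated_rank(M) < nrow(M)) {
    membership <- netlist_components(n)
    floating <- split(names(membership), membership)
    stop(sprintf(
      "singular step system: floating pressure level; sub-circuits: %s",
      paste(vapply(floating, function(s) paste0("{", paste(s, collapse = ","),
                                                "}"), ""),
            collapse = " ")))
  }
  list(M = M, b = b, unknowns = model$unknowns, model = model)
}
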