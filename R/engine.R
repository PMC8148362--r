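#' Solver configuration
#'
#' @param dt time step (s, > 0).
#' @param duration total simulated time (s); alternatively give
#'   \code{n_cycles} with \code{period}.
#' @param period cardiac period (s); used for cycle-convergence checks and
#'   periodic waveforms. May be \code{NA} for aperiodic runs.
#' @param n_cycles number of cardiac cycles (with \code{period}) instead of
#'   \code{duration}.
#' @param scheme implicit scheme, \code{"backward_euler"} (default, robust
#'   for switched valve systems) or \code{"trapezoidal"} (second order).
#' @param linear_tol relative residual bound for the linear solves.
#' @param max_diode_iters fixed-point valve-state iterations before falling
#'   back to exhaustive enumeration; at least number of diodes + 1 is
#'   recommended.
#' @param output_stride record every \code{output_stride}-th step.
#' @param seed integer seed for any stochastic forcing.
#' @return a \code{solver_config} list.
#' @export
solver_config <- function(dt, duration = NULL, period = NA_real_,
                          n_cycles = NULL,
                          scheme = c("backward_euler", "trapezoidal"),
                          linear_tol = 1e-9, max_diode_iters = 30L,
                          output_stride = 1L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (is.null(duration)) {
    if (is.null(n_cycles) || is.na(period))
      stop("give either duration or n_cycles with period")
    duration <- n_cycles * period
  }
  if (duration <= 0) stop("duration must be > 0")
  if (max_diode_iters < 1L) stop("max_diode_iters must be >= 1")
  if (!is.na(period) && dt >= period / 20)
    warning("dt >= period/20: valve events may be poorly resolved")
  list(dt = dt, duration = duration, period = period, scheme = scheme,
       linear_tol = linear_tol, max_diode_iters = as.integer(max_diode_iters),
       output_stride = as.integer(output_stride), seed = as.integer(seed))
}

#' External forcing at interface nodes
#'
#' Interface nodes stand in for an attached 3D domain under the
#' Dirichlet-to-Neumann contract: the external side either prescribes the
#' flow entering the circuit (\code{type = "flow"}, the usual
#' Neumann-side stand-in) or pins the node pressure
#' (\code{type = "pressure"}).
#'
#' @param ... named entries, one per interface node, each created by
#'   \code{forcing_at}.
#' @param node interface node id.
#' @param type \code{"flow"} or \code{"pressure"}.
#' @param fun function of time returning the flow (m^3/s, positive into the
#'   circuit) or pressure (Pa).
#' @return named list of forcing entries.
#' @export
forcing_set <- function(...) {
  entries <- list(...)
  if (length(entries) && is.null(names(entries)))
    stop("forcing entries must be named by interface node")
  for (e in entries) {
    if (!is.list(e) || !e$type %in% c("flow", "pressure") ||
        !is.function(e$fun))
      stop("each forcing entry needs type ('flow'/'pressure') and fun(t)")
  }
  entries
}

#' @rdname forcing_set
#' @export
forcing_at <- function(type = c("flow", "pressure"), fun) {
  type <- match.arg(type)
  if (!is.function(fun)) stop("fun must be a function of time")
  list(type = type, fun = fun)
}

#' @rdname forcing_set
#' @export
forcing_none <- function() list()

#' Initial simulation state of a netlist
#'
#' Defaults: all pressures at their reference values (0 for plain nodes),
#' all flows 0, chamber volumes at the unstressed volume, diodes closed.
#' Netlist initial conditions override: a capacitor's \code{init_dp} lifts
#' its start node by the stated pressure difference, an inductor's
#' \code{init_q} sets its flow, a chamber's \code{init_v} its volume.
#'
#' @param n an \code{\link{lpn_netlist}}.
#' @param model internal.
#' @return a simulation state: list with \code{t}, named \code{P} (all
#'   nodes, Pa), \code{Q} (all components, m^3/s), \code{V} (chambers, m^3),
#'   \code{diode_states}, \code{params}.
#' @export
initial_state <- function(n, model = NULL) {
  if (is.null(model)) model <- build_model(n)
  P <- stats::setNames(ifelse(is.na(model$ref_p), 0, model$ref_p),
                       model$node_ids)
  Q <- stats::setNames(rep(0, length(model$comp_ids)), model$comp_ids)
  V <- stats::setNames(rep(0, length(model$chamber_ids)), model$chamber_ids)
  params <- stats::setNames(vapply(n$components, `[[`, 0, "param"),
                            model$comp_ids)
  for (comp in n$components) {
    if (comp$kind == "capacitor" && !is.na(comp$init_dp)) {
      base <- if (!is.na(comp$end)) P[[comp$end]] else 0
      P[[comp$start]] <- base + comp$init_dp
    }
    if (comp$kind == "inductor" && !is.na(comp$init_q))
      Q[[comp$id]] <- comp$init_q
    if (comp$kind == "chamber")
      V[[comp$id]] <- if (!is.na(comp$init_v)) comp$init_v else comp$v0
  }
  diode_states <- stats::setNames(
    as.list(rep("closed", length(model$diode_ids))), model$diode_ids)
  list(t = 0, P = P, Q = Q, V = V, diode_states = diode_states,
       params = params)
}

# map a solution vector back into a full state
solution_to_state <- function(x, model, t_next, params, diode_states) {
  P <- stats::setNames(ifelse(is.na(model$ref_p), 0, model$ref_p),
                       model$node_ids)
  if (model$nP) P[model$p_ids] <- x[seq_len(model$nP)]
  Q <- stats::setNames(x[model$nP + seq_len(model$nQ)], model$comp_ids)
  V <- if (model$nV)
    stats::setNames(x[model$nP + model$nQ + seq_len(model$nV)],
                    model$chamber_ids)
  else stats::setNames(numeric(0), character(0))
  list(t = t_next, P = P, Q = Q, V = V, diode_states = diode_states,
       params = params)
}

# Solve one step with fixed diode states; returns state or NULL if singular.
try_step <- function(model, n, prev, forcing, dt, scheme, params,
                     diode_states, cache = NULL) {
  prev$diode_states_next <- diode_states
  t_next <- prev$t + dt
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(c(format(params, digits = 17), unlist(diode_states),
                   scheme, format(dt, digits = 17)), collapse = "|")
    fact <- cache$get(key)
  } else fact <- NULL
  if (is.null(fact)) {
    M <- assemble_matrix(model, params, diode_states, dt, scheme)
    # Dirichlet rows must be fixed before factorisation
    has_dirichlet <- any(vapply(forcing, function(f) f$type == "pressure",
                                logical(1)))
    if (has_dirichlet) {
      for (node in names(forcing)) {
        if (forcing[[node]]$type != "pressure") next
        ip <- model$p_index[[node]]
        M[ip, ] <- 0; M[ip, ip] <- 1
      }
    }
    fact <- equilibrated_factor(M)
    if (is.null(fact)) return(NULL)
    if (!is.null(cache)) cache$set(key, fact)
  }
  b <- assemble_rhs(model, params, prev, forcing, dt, scheme, t_next)
  for (node in names(forcing)) {
    f <- forcing[[node]]
    if (f$type == "pressure") b[model$p_index[[node]]] <- f$fun(t_next)
  }
  x <- fact$solve(b)
  if (is.null(x) || anyNA(x) || any(!is.finite(x))) return(NULL)
  solution_to_state(x, model, t_next, params, diode_states)
}

# Row/column equilibration before QR: SI hydraulic circuits mix entries
# spanning ~16 orders of magnitude (compliances ~1e-9, resistances ~1e8),
# which defeats unscaled rank detection and degrades solve accuracy.
equilibrate <- function(M) {
  rs <- apply(abs(M), 1L, max)
  if (any(rs == 0)) return(NULL)
  Ms <- M / rs
  cs <- apply(abs(Ms), 2L, max)
  if (any(cs == 0)) return(NULL)
  Ms <- sweep(Ms, 2L, cs, "/")
  list(M = Ms, rs = rs, cs = cs)
}

equilibrated_factor <- function(M) {
  eq <- equilibrate(M)
  if (is.null(eq)) return(NULL)
  fact <- tryCatch(qr(eq$M, LAPACK = TRUE), error = function(e) NULL)
  if (is.null(fact)) return(NULL)
  dR <- abs(diag(qr.R(fact)))
  if (min(dR) / max(dR) < 1e-12) return(NULL)
  rs <- eq$rs; cs <- eq$cs
  list(solve = function(b) {
    x <- tryCatch(qr.coef(fact, b / rs), error = function(e) NULL)
    if (is.null(x)) return(NULL)
    x / cs
  })
}

# rank of an equilibrated matrix (validation-time solvability check)
equilibrated_rank <- function(M) {
  eq <- equilibrate(M)
  if (is.null(eq)) return(0L)
  qr(eq$M, tol = 1e-10)$rank
}

# complementarity tolerances scaled from current magnitudes
comp_tols <- function(state, base = 1e-9) {
  sq <- max(1e-6, max(abs(state$Q), 0))
  sp <- max(1e-2, max(abs(state$P), 0))
  list(q = base * sq * 1e3, p = base * sp * 1e3)
}

diode_signals <- function(model, state) {
  res <- lapply(model$diode_ids, function(id) {
    cmp <- model$comps[[id]]
    pa <- if (cmp$ia > 0L) state$P[[model$p_ids[cmp$ia]]] else cmp$pa_const
    pb <- if (cmp$ib > 0L) state$P[[model$p_ids[cmp$ib]]] else cmp$pb_const
    c(q = state$Q[[id]], dp = pa - pb)
  })
  names(res) <- model$diode_ids
  res
}

#' Resolve consistent valve states for one implicit step
#'
#' Finds a diode open/closed assignment such that the implicit step solved
#' under that assignment is complementarity-consistent: every open diode
#' carries non-negative forward flow, every closed diode sees a non-positive
#' forward pressure gradient. Strategy: fixed-point flipping of violated
#' diodes starting from the previous assignment; on a detected cycle or
#' iteration cap, exhaustive enumeration of all 2^d assignments in an order
#' that prefers closed valves (deterministic tie-break). At most 8 diodes.
#'
#' @param n an \code{\link{lpn_netlist}}.
#' @param prev previous simulation state.
#' @param forcing a \code{\link{forcing_set}}.
#' @param dt time step (s).
#' @param scheme integration scheme.
#' @param params named parameter vector (defaults to \code{prev$params}).
#' @param max_diode_iters fixed-point iteration cap.
#' @param model,cache internal.
#' @return list with \code{state} (the solved step) and
#'   \code{diode_states}.
#' @export
resolve_diode_states <- function(n, prev, forcing, dt,
                                 scheme = "backward_euler", params = NULL,
                                 max_diode_iters = 30L, model = NULL,
                                 cache = NULL) {
  if (is.null(model)) model <- build_model(n)
  if (is.null(params)) params <- prev$params
  dids <- model$diode_ids
  if (length(dids) > 8L) stop("at most 8 diodes supported")
  states <- prev$diode_states
  if (length(dids) == 0L) {
    st <- try_step(model, n, prev, forcing, dt, scheme, params, states,
                   cache)
    if (is.null(st))
      stop(step_singular_message(n))
    return(list(state = st, diode_states = states))
  }
  seen <- character(0)
  for (iter in seq_len(max_diode_iters)) {
    key <- paste(unlist(states), collapse = "")
    if (key %in% seen) break   # cycle: fall through to enumeration
    seen <- c(seen, key)
    st <- try_step(model, n, prev, forcing, dt, scheme, params, states,
                   cache)
    if (is.null(st)) break     # singular under this assignment
    tol <- comp_tols(st)
    sigs <- diode_signals(model, st)
    flips <- character(0)
    for (id in dids) {
      sig <- sigs[[id]]
      if (identical(states[[id]], "open") && sig[["q"]] < -tol$q)
        flips <- c(flips, id)
      if (identical(states[[id]], "closed") && sig[["dp"]] > tol$p)
        flips <- c(flips, id)
    }
    if (!length(flips))
      return(list(state = st, diode_states = states))
    for (id in flips)
      states[[id]] <- if (identical(states[[id]], "open")) "closed" else "open"
  }
  # exhaustive enumeration, fewest-open first (ties resolve to closed)
  d <- length(dids)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), d))
  combos <- combos[order(rowSums(combos)), , drop = FALSE]
  for (r in seq_len(nrow(combos))) {
    cand <- stats::setNames(
      as.list(ifelse(unlist(combos[r, ]), "open", "closed")), dids)
    st <- try_step(model, n, prev, forcing, dt, scheme, params, cand, cache)
    if (is.null(st)) next
    tol <- comp_tols(st)
    sigs <- diode_signals(model, st)
    ok <- TRUE
    for (id in dids) {
      sig <- sigs[[id]]
      if (identical(cand[[id]], "open") && sig[["q"]] < -tol$q) ok <- FALSE
      if (identical(cand[[id]], "closed") && sig[["dp"]] > tol$p) ok <- FALSE
      if (!ok) break
    }
    if (ok) return(list(state = st, diode_states = cand))
  }
  stop(sprintf("valve chatter: no consistent diode assignment at t = %g",
               prev$t + dt))
}

step_singular_message <- function(n) {
  membership <- netlist_components(n)
  floating <- split(names(membership), membership)
  sprintf("singular step system: floating pressure level; sub-circuits: %s",
          paste(vapply(floating, function(s)
            paste0("{", paste(s, collapse = ","), "}"), ""),
            collapse = " "))
}

#' Advance the simulation by one implicit step
#'
#' Controllers are applied first (they observe the state at t and set the
#' parameters used for the step to t+dt), then valve states are resolved
#' and the implicit system solved.
#'
#' @param n an \code{\link{lpn_netlist}}.
#' @param state current simulation state.
#' @param forcing a \code{\link{forcing_set}}.
#' @param controllers list of \code{\link{controller_spec}} objects.
#' @param config a \code{\link{solver_config}}.
#' @param model,cache internal.
#' @return the new simulation state (with updated controller internals kept
#'   in attribute \code{"controllers"}).
#' @export
advance_step <- function(n, state, forcing, controllers = list(), config,
                         model = NULL, cache = NULL) {
  if (is.null(model)) model <- build_model(n)
  if (!is.finite(config$dt) || config$dt <= 0) stop("dt must be > 0")
  if (length(controllers)) {
    upd <- apply_controllers(controllers, state, config$dt, n, model)
    state$params <- upd$params
    controllers <- upd$controllers
  }
  res <- resolve_diode_states(n, state, forcing, config$dt,
                              scheme = config$scheme, params = state$params,
                              max_diode_iters = config$max_diode_iters,
                              model = model, cache = cache)
  new_state <- res$state
  if (any(!is.finite(new_state$P)) || any(!is.finite(new_state$Q)))
    stop(sprintf("non-finite state at t = %g", new_state$t))
  attr(new_state, "controllers") <- controllers
  new_state
}

# tiny factorisation cache (environment-backed, bounded)
make_cache <- function(limit = 32L) {
  env <- new.env(parent = emptyenv())
  keys <- character(0)
  list(
    get = function(key) {
      if (exists(key, envir = env, inherits = FALSE))
        get(key, envir = env) else NULL
    },
    set = function(key, val) {
      if (length(keys) >= limit) {
        rm(list = keys[1L], envir = env)
        keys <<- keys[-1L]
      }
      assign(key, val, envir = env)
      keys <<- c(keys, key)
    })
}

#' Run a full 0D simulation
#'
#' Validates the netlist, then advances the implicit stepper over
#' \code{[0, duration]}, applying controllers each step and recording every
#' \code{output_stride}-th state. Deterministic given (netlist, forcing,
#' controllers, config, seed).
#'
#' @inheritParams advance_step
#' @param init optional initial state (default \code{\link{initial_state}}).
#' @param validate run \code{\link{validate_netlist}} first (default TRUE).
#' @return an \code{lpn_result}: list with \code{time} (s), matrices
#'   \code{P} (Pa, one column per node, reference nodes echoed), \code{Q}
#'   (m^3/s per component), \code{V} (m^3 per chamber), \code{diag}
#'   (controller diagnostic channels), \code{config}, \code{netlist_hash}.
#' @export
run_simulation <- function(n, forcing = forcing_none(),
                           controllers = list(), config,
                           init = NULL, validate = TRUE) {
  if (validate) {
    diags <- validate_netlist(n)
    if (has_errors(diags)) {
      msgs <- vapply(Filter(function(d) d$severity == "error", diags),
                     format, "")
      stop(sprintf("netlist validation failed:\n%s",
                   paste(msgs, collapse = "\n")))
    }
  }
  model <- build_model(n)
  # every interface node needs exactly one forcing entry
  missing_f <- setdiff(model$iface_ids, names(forcing))
  if (length(missing_f))
    stop(sprintf("no forcing for interface node(s): %s",
                 paste(missing_f, collapse = ", ")))
  extra_f <- setdiff(names(forcing), model$iface_ids)
  if (length(extra_f))
    stop(sprintf("forcing attached to non-interface node(s): %s",
                 paste(extra_f, collapse = ", ")))

  set.seed(config$seed)
  state <- if (is.null(init)) initial_state(n, model) else init
  # Consistent DAE initialisation: the netlist fixes the differential
  # states (capacitor pressure differences, inductor flows, chamber
  # volumes) but not the algebraic variables (remaining node pressures and
  # component flows). A backward-Euler micro-step pins the states to
  # within dt_micro while solving the algebraic relations and the initial
  # valve configuration; without it the trapezoidal scheme loses an order
  # to the inconsistent start.
  dt_micro <- config$dt * 1e-9
  micro <- tryCatch(
    resolve_diode_states(n, state, forcing, dt_micro,
                         scheme = "backward_euler", params = state$params,
                         max_diode_iters = config$max_diode_iters,
                         model = model),
    error = function(e) NULL)
  if (!is.null(micro)) {
    state <- micro$state
    state$t <- 0
  }
  n_steps <- as.integer(round(config$duration / config$dt))
  stride <- config$output_stride
  n_out <- n_steps %/% stride + 1L
  time <- numeric(n_out)
  Pm <- matrix(NA_real_, n_out, length(model$node_ids),
               dimnames = list(NULL, model$node_ids))
  Qm <- matrix(NA_real_, n_out, length(model$comp_ids),
               dimnames = list(NULL, model$comp_ids))
  Vm <- matrix(NA_real_, n_out, length(model$chamber_ids),
               dimnames = list(NULL, model$chamber_ids))
  diag_names <- controller_channel_names(controllers)
  Dm <- matrix(NA_real_, n_out, length(diag_names),
               dimnames = list(NULL, diag_names))
  Sd <- matrix(NA_integer_, n_out, length(model$diode_ids),
               dimnames = list(NULL, model$diode_ids))

  cache <- make_cache()
  record <- function(row, st, ctrls) {
    time[row] <<- st$t
    Pm[row, ] <<- st$P
    Qm[row, ] <<- st$Q
    if (ncol(Vm)) Vm[row, ] <<- st$V
    if (ncol(Dm)) Dm[row, ] <<- controller_channels(ctrls)
    if (ncol(Sd)) Sd[row, ] <<- as.integer(
      unlist(st$diode_states[model$diode_ids]) == "open")
  }
  record(1L, state, controllers)
  row <- 1L
  for (k in seq_len(n_steps)) {
    state <- tryCatch(
      advance_step(n, state, forcing, controllers, config, model, cache),
      error = function(e) stop(sprintf("step failed at t = %g: %s",
                                       state$t, conditionMessage(e))))
    ctrls_new <- attr(state, "controllers")
    if (!is.null(ctrls_new)) controllers <- ctrls_new
    state$t <- k * config$dt   # avoid accumulated rounding in the time grid
    if (k %% stride == 0L) {
      row <- row + 1L
      record(row, state, controllers)
    }
  }
  structure(list(time = time, P = Pm, Q = Qm, V = Vm, diag = Dm,
                 diode_open = Sd, config = config,
                 netlist_hash = netlist_hash(n), final_state = state),
            class = "lpn_result")
}

#' @export
print.lpn_result <- function(x, ...) {
  cat(sprintf(
    "LPN result: %d samples over [0, %g] s; %d nodes, %d components, %d chambers\n",
    length(x$time), max(x$time), ncol(x$P), ncol(x$Q), ncol(x$V)))
  invisible(x)
}

#' Cycle-to-cycle convergence metric
#'
#' Relative L2 difference between consecutive cardiac cycles over all
#' pressure channels; the run is flagged periodic once the metric falls
#' below \code{threshold}.
#'
#' @param r an \code{lpn_result}.
#' @param period cardiac period (s); must be an integer multiple of the
#'   output sampling interval.
#' @param threshold periodicity threshold on the metric.
#' @return data.frame with columns \code{cycle} (2-based: metric compares
#'   cycle k against k-1), \code{metric}, \code{periodic}.
#' @export
check_cycle_convergence <- function(r, period, threshold = 1e-3) {
  stopifnot(inherits(r, "lpn_result"))
  dt_out <- r$time[2L] - r$time[1L]
  spc_real <- period / dt_out
  spc <- round(spc_real)
  if (abs(spc_real - spc) > 1e-8 * spc_real || spc < 2L)
    stop("period is not an integer multiple of the sampling interval")
  n_cycles <- (length(r$time) - 1L) %/% spc
  if (n_cycles < 2L) stop("need at least 2 full periods")
  metric <- numeric(n_cycles - 1L)
  for (k in 2:n_cycles) {
    idx_prev <- ((k - 2L) * spc + 1L):((k - 1L) * spc)
    idx_cur <- ((k - 1L) * spc + 1L):(k * spc)
    diff2 <- sum((r$P[idx_cur, , drop = FALSE] -
                    r$P[idx_prev, , drop = FALSE])^2)
    ref2 <- sum(r$P[idx_prev, , drop = FALSE]^2)
    metric[k - 1L] <- if (ref2 > 0) sqrt(diff2 / ref2) else sqrt(diff2)
  }
  data.frame(cycle = 2:n_cycles, metric = metric,
             periodic = metric < threshold)
}

#' Total stored volume series of a result
#'
#' Sum over capacitors of C * (pressure difference) plus all chamber
#' volumes; constant in time for closed loops (no sources, no interface
#' nodes), which is the discrete conservation property of the implicit
#' schemes.
#'
#' @param n the netlist the result was computed from.
#' @param r an \code{lpn_result}.
#' @return numeric vector, one value per output sample (m^3).
#' @export
stored_volume <- function(n, r) {
  tot <- rep(0, length(r$time))
  for (comp in n$components) {
    if (comp$kind == "capacitor") {
      pa <- r$P[, comp$start]
      pb <- if (!is.na(comp$end)) r$P[, comp$end] else 0
      # stored volume uses the CURRENT compliance; presets keep C constant
      tot <- tot + comp$param * (pa - pb)
    } else if (comp$kind == "chamber") {
      tot <- tot + r$V[, comp$id]
    }
  }
  tot
}

#' Write a result set as CSV plus a JSON sidecar
#'
#' CSV columns: \code{time}, \code{P_<node>}, \code{Q_<component>},
#' \code{V_<chamber>}, then one column per controller diagnostic channel;
#' numbers at full double precision. The sidecar records the netlist hash,
#' solver config and convergence metrics so runs are self-describing.
#'
#' @param r an \code{lpn_result}.
#' @param path CSV output path; sidecar goes to \code{<path>.json}.
#' @param convergence optional result of \code{\link{check_cycle_convergence}}.
#' @return invisible \code{path}.
#' @export
write_result_csv <- function(r, path, convergence = NULL) {
  df <- result_to_df(r)
  cols <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col)
    else as.character(col)
  }, character(nrow(df)))
  lines <- c(paste(colnames(df), collapse = ","),
             apply(matrix(cols, nrow = nrow(df)), 1L, paste, collapse = ","))
  writeLines(lines, path)
  sidecar <- list(netlist_hash = r$netlist_hash,
                  config = r$config[c("dt", "duration", "period", "scheme",
                                      "linear_tol", "max_diode_iters",
                                      "output_stride", "seed")],
                  convergence = convergence)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

result_to_df <- function(r) {
  df <- data.frame(time = r$time)
  for (j in seq_len(ncol(r$P))) df[[paste0("P_", colnames(r$P)[j])]] <- r$P[, j]
  for (j in seq_len(ncol(r$Q))) df[[paste0("Q_", colnames(r$Q)[j])]] <- r$Q[, j]
  if (ncol(r$V))
    for (j in seq_len(ncol(r$V))) df[[paste0("V_", colnames(r$V)[j])]] <- r$V[, j]
  if (!is.null(r$diag) && ncol(r$diag))
    for (j in seq_len(ncol(r$diag))) df[[colnames(r$diag)[j]]] <- r$diag[, j]
  df
}

#' Sample a named channel from a result
#'
#' Channels are named \code{P.<node>}, \code{Q.<component>},
#' \code{V.<chamber>}, or a diagnostic channel name.
#'
#' @param r an \code{lpn_result}.
#' @param channel channel name.
#' @return numeric vector over the result's time grid.
#' @export
result_channel <- function(r, channel) {
  if (grepl("^P\\.", channel)) {
    id <- sub("^P\\.", "", channel)
    if (!id %in% colnames(r$P)) stop(sprintf("unknown channel '%s'", channel))
    return(r$P[, id])
  }
  if (grepl("^Q\\.", channel)) {
    id <- sub("^Q\\.", "", channel)
    if (!id %in% colnames(r$Q)) stop(sprintf("unknown channel '%s'", channel))
    return(r$Q[, id])
  }
  if (grepl("^V\\.", channel)) {
    id <- sub("^V\\.", "", channel)
    if (!id %in% colnames(r$V)) stop(sprintf("unknown channel '%s'", channel))
    return(r$V[, id])
  }
  if (!is.null(r$diag) && channel %in% colnames(r$diag))
    return(r$diag[, channel])
  stop(sprintf("unknown channel '%s'", channel))
}

#' Check valve complementarity over a recorded run
#'
#' At every recorded sample, an open diode must carry non-negative forward
#' flow and a closed diode must see a non-positive forward pressure
#' gradient (both up to a tolerance scaled to the run's flow and pressure
#' magnitudes).
#'
#' @param n the netlist.
#' @param r an \code{lpn_result}.
#' @param rel_tol relative tolerance on the violation checks.
#' @return list with \code{ok}, \code{max_reverse_flow} (m^3/s),
#'   \code{max_closed_forward_dp} (Pa).
#' @export
check_complementarity <- function(n, r, rel_tol = 1e-6) {
  if (is.null(r$diode_open) || ncol(r$diode_open) == 0L)
    return(list(ok = TRUE, max_reverse_flow = 0, max_closed_forward_dp = 0))
  tol_q <- rel_tol * max(abs(r$Q))
  tol_p <- rel_tol * max(abs(r$P))
  worst_q <- 0; worst_p <- 0
  for (comp in n$components) {
    if (comp$kind != "diode") next
    open <- r$diode_open[, comp$id] == 1L
    q <- r$Q[, comp$id]
    dp <- r$P[, comp$start] -
      (if (!is.na(comp$end)) r$P[, comp$end] else 0)
    if (any(open)) worst_q <- max(worst_q, -min(q[open], 0))
    if (any(!open)) worst_p <- max(worst_p, max(dp[!open], 0))
  }
  list(ok = worst_q <= tol_q && worst_p <= tol_p,
       max_reverse_flow = worst_q, max_closed_forward_dp = worst_p)
}
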