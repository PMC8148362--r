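#' Declare a run-time controller
#'
#' A controller governs one tagged component: each step, before the implicit
#' solve, its pure update rule observes named state channels at time t and
#' returns the parameter value the component uses for the step to t+dt,
#' plus its own persistent internal state. This is the 0D analogue of
#' run-time boundary-condition control: arbitrary user rules adjusting
#' component parameters from the simulation state.
#'
#' @param name controller name; diagnostic channels are exported as
#'   \code{<name>.<internal-state>} and \code{<name>.param}.
#' @param target_tag control tag of the governed component; must match
#'   exactly one component.
#' @param observe character vector of channels the rule may read:
#'   \code{"P.<node>"}, \code{"Q.<component>"}, \code{"V.<chamber>"},
#'   \code{"param"} (current value of the governed parameter).
#' @param update function \code{(t, dt, obs, internal)} returning
#'   \code{list(value = <new parameter, >= 0>, internal = <named numeric>)};
#'   must be side-effect-free.
#' @param internal named numeric vector of initial internal state.
#' @return a \code{controller_spec} object.
#' @export
controller_spec <- function(name, target_tag, observe = character(),
                            update, internal = numeric()) {
  if (!is.function(update)) stop("update must be a function")
  if (!grepl(valid_tag_re, target_tag))
    stop(sprintf("invalid target tag '%s'", target_tag))
  structure(list(name = name, target_tag = target_tag, observe = observe,
                 update = update, internal = internal),
            class = "controller_spec")
}

controller_channel_names <- function(controllers) {
  unlist(lapply(controllers, function(ctrl) {
    c(if (length(ctrl$internal)) paste0(ctrl$name, ".", names(ctrl$internal)),
      paste0(ctrl$name, ".param"))
  }))
}

controller_channels <- function(controllers) {
  unlist(lapply(controllers, function(ctrl) {
    c(ctrl$internal,
      if (!is.null(ctrl$last_value)) ctrl$last_value else NA_real_)
  }))
}

observe_state <- function(channels, state, param) {
  out <- stats::setNames(numeric(length(channels)), channels)
  for (ch in channels) {
    if (ch == "param") { out[[ch]] <- param; next }
    kind <- sub("\\..*$", "", ch)
    id <- sub("^[PQV]\\.", "", ch)
    out[[ch]] <- switch(kind,
      P = { if (!id %in% names(state$P))
              stop(sprintf("unknown observable '%s'", ch)); state$P[[id]] },
      Q = { if (!id %in% names(state$Q))
              stop(sprintf("unknown observable '%s'", ch)); state$Q[[id]] },
      V = { if (!id %in% names(state$V))
              stop(sprintf("unknown observable '%s'", ch)); state$V[[id]] },
      stop(sprintf("unknown observable '%s'", ch)))
  }
  out
}

#' Apply all controllers for one step
#'
#' Controllers run once per step, pre-solve, in registration order. Each
#' must target a tag carried by exactly one component.
#'
#' @param registry list of \code{\link{controller_spec}} objects.
#' @param state current simulation state.
#' @param dt step size (s).
#' @param n the netlist.
#' @param model internal.
#' @return list with updated \code{params} (named vector) and
#'   \code{controllers} (with advanced internal states).
#' @export
apply_controllers <- function(registry, state, dt, n, model = NULL) {
  if (is.null(model)) model <- build_model(n)
  params <- state$params
  tags <- vapply(n$components, `[[`, "", "tag")
  ids <- model$comp_ids
  for (i in seq_along(registry)) {
    ctrl <- registry[[i]]
    hits <- ids[!is.na(tags) & tags == ctrl$target_tag]
    if (length(hits) != 1L)
      stop(sprintf("controller '%s': tag '%s' matches %d components",
                   ctrl$name, ctrl$target_tag, length(hits)))
    obs <- observe_state(ctrl$observe, state, params[[hits]])
    out <- ctrl$update(state$t, dt, obs, ctrl$internal)
    if (!is.list(out) || is.null(out$value))
      stop(sprintf("controller '%s': update must return list(value, internal)",
                   ctrl$name))
    if (!is.finite(out$value) || out$value < 0)
      stop(sprintf("controller '%s' returned a negative or non-finite value",
                   ctrl$name))
    if (!is.null(out$internal) && any(!is.finite(out$internal)))
      stop(sprintf("controller '%s' produced non-finite internal state",
                   ctrl$name))
    params[[hits]] <- out$value
    registry[[i]]$internal <- if (is.null(out$internal)) ctrl$internal
                              else out$internal
    registry[[i]]$last_value <- out$value
  }
  list(params = params, controllers = registry)
}

#' Time-varying elastance waveform
#'
#' Raised-cosine systolic activation: the elastance rises smoothly from
#' \code{E_min} at the start of the cycle to \code{E_max} at \code{t_peak},
#' relaxes back over \code{t_relax}, and stays at \code{E_min} through
#' diastole. Periodic with the given period and continuously
#' differentiable.
#'
#' @param t time (s), scalar or vector.
#' @param E_min,E_max diastolic/systolic elastance bounds (Pa/m^3),
#'   \code{0 < E_min <= E_max}.
#' @param period cardiac period (s).
#' @param t_peak time of peak elastance within the cycle (s),
#'   \code{0 < t_peak < period}.
#' @param t_relax relaxation duration (s); default half of \code{t_peak},
#'   clipped so systole ends before the cycle does.
#' @return elastance values (Pa/m^3).
#' @export
elastance_waveform <- function(t, E_min, E_max, period, t_peak,
                               t_relax = NULL) {
  if (!(E_min > 0 && E_max >= E_min)) stop("need 0 < E_min <= E_max")
  if (!(t_peak > 0 && t_peak < period)) stop("need 0 < t_peak < period")
  if (is.null(t_relax)) t_relax <- min(t_peak / 2, (period - t_peak) * 0.9)
  if (t_peak + t_relax >= period) stop("t_peak + t_relax must be < period")
  tau <- t %% period
  amp <- E_max - E_min
  up <- tau <= t_peak
  down <- tau > t_peak & tau <= t_peak + t_relax
  act <- numeric(length(tau))
  act[up] <- 0.5 * (1 - cos(pi * tau[up] / t_peak))
  act[down] <- 0.5 * (1 + cos(pi * (tau[down] - t_peak) / t_relax))
  E_min + amp * act
}

#' Built-in controllers
#'
#' \code{controller_constant} pins the parameter at a value;
#' \code{controller_step} switches it at a given time;
#' \code{controller_elastance} drives a chamber's elastance with
#' \code{\link{elastance_waveform}}; \code{controller_proportional} applies
#' bounded proportional feedback pushing an observed channel toward a
#' setpoint.
#'
#' @param tag control tag of the governed component.
#' @param value,before,after parameter values (SI units of the component).
#' @param t_switch switch time for the step controller (s).
#' @param E_min,E_max,period,t_peak,t_relax see
#'   \code{\link{elastance_waveform}}.
#' @param observe single channel name to feed back on.
#' @param setpoint target value of the observed channel.
#' @param gain proportional gain (parameter units per channel unit).
#' @param base nominal parameter value.
#' @param lo,hi clamp bounds on the output parameter.
#' @param name controller name.
#' @return a \code{\link{controller_spec}}.
#' @name builtin_controllers
NULL

#' @rdname builtin_controllers
#' @export
controller_constant <- function(tag, value, name = paste0("const_", tag)) {
  controller_spec(name, tag, character(),
                  function(t, dt, obs, internal)
                    list(value = value, internal = internal))
}

#' @rdname builtin_controllers
#' @export
controller_step <- function(tag, t_switch, before, after,
                            name = paste0("step_", tag)) {
  controller_spec(name, tag, character(),
                  function(t, dt, obs, internal)
                    list(value = if (t >= t_switch) after else before,
                         internal = internal))
}

#' @rdname builtin_controllers
#' @export
controller_elastance <- function(tag, E_min, E_max, period, t_peak,
                                 t_relax = NULL,
                                 name = paste0("elastance_", tag)) {
  # evaluate at t+dt so the elastance is consistent with the implicit step
  controller_spec(name, tag, character(),
                  function(t, dt, obs, internal)
                    list(value = elastance_waveform(t + dt, E_min, E_max,
                                                    period, t_peak, t_relax),
                         internal = internal))
}

#' @rdname builtin_controllers
#' @export
controller_proportional <- function(tag, observe, setpoint, gain, base,
                                    lo = 0, hi = Inf,
                                    name = paste0("pfb_", tag)) {
  controller_spec(name, tag, observe,
                  function(t, dt, obs, internal) {
                    v <- base + gain * (obs[[1L]] - setpoint)
                    list(value = min(hi, max(lo, v)), internal = internal)
                  })
}

#' Myocardial hunger model parameters
#'
#' The "hunger" H is the accumulated deficit of myocardial oxygen supply
#' relative to demand, in arbitrary oxygen units. Demand is a ventricular
#' workload proxy d(t) = alpha * max(P_chamber * Q_eject, 0) + beta (the
#' pressure-flow product during ejection plus a basal rate); supply is
#' k_s * q_cor from coronary flow. Feedback dilates the coronary
#' microvasculature as hunger accumulates: the governed resistance is
#' R0 * g(H) with g(H) = max(g_min, 1 / (1 + k_f * H)), a non-increasing
#' multiplier clamped to [g_min, 1].
#'
#' @param alpha workload-to-demand gain (oxygen units per J of
#'   pressure-flow product).
#' @param beta basal demand rate (oxygen units/s).
#' @param k_s supply gain (oxygen units per m^3 of coronary flow).
#' @param k_f feedback gain (1/oxygen units).
#' @param g_min floor of the resistance multiplier, in (0, 1]; the
#'   autoregulatory dilation reserve.
#' @return a \code{hunger_params} list.
#' @export
hunger_params <- function(alpha, beta = 0, k_s, k_f = 1, g_min = 0.9) {
  if (alpha < 0 || beta < 0 || k_s < 0 || k_f < 0)
    stop("hunger parameters must be non-negative")
  if (!(g_min > 0 && g_min <= 1)) stop("g_min must be in (0, 1]")
  structure(list(alpha = alpha, beta = beta, k_s = k_s, k_f = k_f,
                 g_min = g_min), class = "hunger_params")
}

#' One myocardial hunger update
#'
#' H' = max(0, H + dt * (d - k_s * q_cor)): hunger integrates the
#' supply/demand imbalance and is floored at zero (no stored oxygen
#' credit). Returns the updated hunger and the coronary resistance
#' multiplier g(H').
#'
#' @param H current hunger (oxygen units, >= 0).
#' @param dt step (s, > 0).
#' @param demand demand rate d (oxygen units/s, >= 0).
#' @param q_cor coronary flow (m^3/s).
#' @param p a \code{\link{hunger_params}}.
#' @return list with \code{H} and \code{multiplier}.
#' @export
hunger_update <- function(H, dt, demand, q_cor, p) {
  if (H < 0 || dt <= 0 || demand < 0)
    stop("hunger_update: H and demand must be >= 0 and dt > 0")
  H2 <- max(0, H + dt * (demand - p$k_s * q_cor))
  list(H = H2, multiplier = max(p$g_min, 1 / (1 + p$k_f * H2)))
}

#' Myocardial hunger controller
#'
#' Tracks the oxygen supply/demand imbalance of a perfusion territory and
#' feeds back on the tagged coronary microvascular resistance:
#' R = R0 * g(H). Demand observes the ventricular pressure and ejection
#' flow; supply observes the coronary flow.
#'
#' @param tag control tag of the coronary microvascular resistor.
#' @param R0 nominal resistance (Pa.s/m^3).
#' @param p a \code{\link{hunger_params}}.
#' @param chamber_pressure channel name of the ventricular pressure
#'   (\code{"P.<node>"}).
#' @param eject_flow channel name of the ejection flow
#'   (\code{"Q.<component>"}, e.g. the aortic valve).
#' @param coronary_flow channel name of the coronary flow.
#' @param feedback enable the resistance feedback (if \code{FALSE} the
#'   controller only tracks hunger and pins R = R0).
#' @param name controller name; hunger is exported as channel
#'   \code{<name>.H}.
#' @return a \code{\link{controller_spec}}.
#' @export
controller_hunger <- function(tag, R0, p, chamber_pressure, eject_flow,
                              coronary_flow, feedback = TRUE,
                              name = "hunger") {
  controller_spec(
    name, tag,
    observe = c(chamber_pressure, eject_flow, coronary_flow),
    internal = c(H = 0),
    update = function(t, dt, obs, internal) {
      demand <- p$alpha * max(obs[[1L]] * obs[[2L]], 0) + p$beta
      upd <- hunger_update(internal[["H"]], dt, demand, obs[[3L]], p)
      list(value = if (feedback) R0 * upd$multiplier else R0,
           internal = c(H = upd$H))
    })
}
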