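#' Per-cycle summary of a result set
#'
#' For each full cardiac cycle: min/mean/max of every pressure channel,
#' net conveyed volume per component (integral of its flow), chamber
#' volume extrema, and the cycle-to-cycle convergence metric.
#'
#' @param r an \code{lpn_result}.
#' @param period cardiac period (s); must be an integer multiple of the
#'   output sampling interval.
#' @param units \code{"SI"} (Pa, m^3/s, m^3) or \code{"clinical"}
#'   (mmHg, mL/s, mL).
#' @return data.frame, one row per (cycle, channel, statistic-set).
#' @export
summarise_cycles <- function(r, period, units = c("SI", "clinical")) {
  units <- match.arg(units)
  stopifnot(inherits(r, "lpn_result"))
  dt_out <- r$time[2L] - r$time[1L]
  spc_real <- period / dt_out
  spc <- round(spc_real)
  if (abs(spc_real - spc) > 1e-8 * spc_real)
    stop("period is not an integer multiple of the sampling interval")
  n_cycles <- (length(r$time) - 1L) %/% spc
  if (n_cycles < 1L) stop("result shorter than one period")
  conv <- if (n_cycles >= 2L) check_cycle_convergence(r, period) else NULL

  cp <- if (units == "clinical") pa_to_mmhg else identity
  cq <- if (units == "clinical") m3_to_ml else identity
  rows <- list()
  for (k in seq_len(n_cycles)) {
    idx <- ((k - 1L) * spc + 1L):(k * spc + 1L)
    for (ch in colnames(r$P)) {
      v <- cp(r$P[idx, ch])
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = k, channel = paste0("P_", ch), kind = "pressure",
        min = min(v), mean = mean(v), max = max(v),
        net_volume = NA_real_)
    }
    for (ch in colnames(r$Q)) {
      q <- r$Q[idx, ch]
      net <- sum((q[-1L] + q[-length(q)]) / 2) * dt_out
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = k, channel = paste0("Q_", ch), kind = "flow",
        min = cq(min(q)), mean = cq(mean(q)), max = cq(max(q)),
        net_volume = cq(net))
    }
    if (ncol(r$V)) for (ch in colnames(r$V)) {
      v <- cq(r$V[idx, ch])
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = k, channel = paste0("V_", ch), kind = "volume",
        min = min(v), mean = mean(v), max = max(v),
        net_volume = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  out$convergence_metric <- NA_real_
  if (!is.null(conv)) {
    for (k in conv$cycle)
      out$convergence_metric[out$cycle == k] <-
        conv$metric[conv$cycle == k]
  }
  out
}

#' Convert a result data frame between SI and clinical units
#'
#' Applies to report columns only (internal state is always SI): pressure
#' columns \code{P_*} Pa <-> mmHg, flow columns \code{Q_*} m^3/s <->
#' mL/s, volume columns \code{V_*} m^3 <-> mL. Involutive to round-off.
#'
#' @param df data.frame as written by \code{\link{write_result_csv}}.
#' @param to \code{"clinical"} or \code{"SI"}.
#' @return converted data.frame.
#' @export
convert_result_units <- function(df, to = c("clinical", "SI")) {
  to <- match.arg(to)
  fp <- if (to == "clinical") pa_to_mmhg else mmhg_to_pa
  fv <- if (to == "clinical") m3_to_ml else ml_to_m3
  for (nm in names(df)) {
    if (grepl("^P_", nm)) df[[nm]] <- fp(df[[nm]])
    if (grepl("^[QV]_", nm)) df[[nm]] <- fv(df[[nm]])
  }
  df
}
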