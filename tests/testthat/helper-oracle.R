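# Independent oracles used by the property tests.
#
# Random R/C/L ladder networks: the netlist handed to the implicit engine
# and the state-space ODE handed to deSolve are built separately from the
# same section description, so the oracle does not share the engine's
# assembly path.

gen_ladder <- function(seed, n_sections = 2L) {
  set.seed(seed)
  secs <- lapply(seq_len(n_sections), function(k) {
    list(C = 10^runif(1, -0.3, 0.3),
         has_shunt_R = runif(1) < 0.5,
         R_sh = 10^runif(1, -0.3, 0.3),
         R_b = 10^runif(1, -0.3, 0.3),
         has_L = runif(1) < 0.4,
         L = 10^runif(1, -1, -0.3))
  })
  secs
}

ladder_netlist <- function(secs) {
  K <- length(secs)
  lines <- c("node n1 interface",
             if (K > 1) paste0("node n", 2:K),
             "node ground reference=0")
  comps <- character(0)
  for (k in seq_len(K)) {
    nk <- paste0("n", k)
    nxt <- if (k < K) paste0("n", k + 1L) else "ground"
    s <- secs[[k]]
    comps <- c(comps, sprintf("component capacitor c%d %s ground %.17g",
                              k, nk, s$C))
    if (s$has_shunt_R)
      comps <- c(comps, sprintf("component resistor rs%d %s ground %.17g",
                                k, nk, s$R_sh))
    if (s$has_L) {
      lines <- c(lines, sprintf("node m%d", k))
      comps <- c(comps,
                 sprintf("component resistor rb%d %s m%d %.17g",
                         k, nk, k, s$R_b),
                 sprintf("component inductor lb%d m%d %s %.17g",
                         k, k, nxt, s$L))
    } else {
      comps <- c(comps, sprintf("component resistor rb%d %s %s %.17g",
                                k, nk, nxt, s$R_b))
    }
  }
  parse_netlist(c(lines, comps))
}

ladder_forcing <- function() {
  forcing_set(n1 = forcing_at("flow", function(t) 1 + 0.5 * sin(2 * pi * t)))
}

# state-space RHS for deSolve: states P_1..P_K then Q for each L-branch
ladder_oracle <- function(secs, times, rtol = 1e-10) {
  K <- length(secs)
  lidx <- which(vapply(secs, `[[`, TRUE, "has_L"))
  nL <- length(lidx)
  qfun <- function(t) 1 + 0.5 * sin(2 * pi * t)
  rhs <- function(t, y, parms) {
    P <- y[seq_len(K)]
    QL <- if (nL) y[K + seq_len(nL)] else numeric(0)
    Pn <- c(P[-1L], 0)
    Qb <- numeric(K)
    li <- 0L
    for (k in seq_len(K)) {
      s <- secs[[k]]
      if (s$has_L) {
        li <- li + 1L
        Qb[k] <- QL[li]
      } else {
        Qb[k] <- (P[k] - Pn[k]) / s$R_b
      }
    }
    dP <- numeric(K)
    for (k in seq_len(K)) {
      s <- secs[[k]]
      qin <- if (k == 1L) qfun(t) else Qb[k - 1L]
      leak <- if (s$has_shunt_R) P[k] / s$R_sh else 0
      dP[k] <- (qin - Qb[k] - leak) / s$C
    }
    dQ <- numeric(nL)
    li <- 0L
    for (k in lidx) {
      li <- li + 1L
      s <- secs[[k]]
      dQ[li] <- (P[k] - (if (k < K) P[k + 1L] else 0) - s$R_b * QL[li]) / s$L
    }
    list(c(dP, dQ))
  }
  y0 <- rep(0, K + nL)
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = rtol, atol = 1e-12)
  P <- out[, 1L + seq_len(K), drop = FALSE]
  colnames(P) <- paste0("n", seq_len(K))
  P
}

# engine trajectory of the same ladder on the oracle's time grid
ladder_run <- function(n, dt, duration, scheme = "backward_euler",
                       stride = 1L) {
  cfg <- solver_config(dt = dt, duration = duration, period = 1,
                       scheme = scheme, output_stride = stride)
  suppressWarnings(run_simulation(n, ladder_forcing(), list(), cfg))
}

# max relative error of node pressures against the oracle
ladder_error <- function(r, P_oracle) {
  errs <- vapply(colnames(P_oracle), function(nd) {
    ref <- P_oracle[, nd]
    max(abs(r$P[, nd] - ref)) / max(abs(ref))
  }, numeric(1))
  max(errs)
}
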