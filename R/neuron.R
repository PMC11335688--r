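#' Membrane parameters for a striatal neuron
#'
#' Returns the maximal conductances (mS/cm^2) and reversal potentials (mV) of
#' the conductance-based membrane model used for the two striatal cell
#' classes: medium spiny neurons (MSN), which carry a non-inactivating
#' M-type potassium current, and fast-spiking interneurons (FS), which carry
#' a fast-activating, slowly inactivating D-type potassium current.
#'
#' The membrane capacitance `C` defaults to 1 uF/cm^2, the standard
#' Hodgkin-Huxley convention. The M-current reverses at `E_K`; the D-current
#' has its own reversal `E_D`.
#'
#' @param kind `"MSN"` or `"FS"`.
#' @param ... named overrides for any parameter field.
#' @return An object of class `membrane_params`: a list with fields
#'   `kind`, `C`, `g_leak`, `g_K`, `g_Na`, `E_leak`, `E_K`, `E_Na`, and
#'   either `g_M` (MSN) or `g_D`, `E_D` (FS), plus the D-gate kinetic
#'   constants for FS cells.
#' @export
#' @examples
#' membrane_params("MSN")
#' membrane_params("FS", g_D = 0.2)
membrane_params <- function(kind = c("MSN", "FS"), ...) {
  kind <- match.arg(kind)
  p <- if (kind == "MSN") {
    list(
      kind = "MSN", C = 1,
      g_leak = 0.1, g_K = 80, g_Na = 100, g_M = 1.3,
      E_leak = -67, E_K = -100, E_Na = 50
    )
  } else {
    list(
      kind = "FS", C = 1,
      g_leak = 0.25, g_K = 225, g_Na = 112.5, g_D = 0.1,
      E_leak = -70, E_K = -90, E_Na = 50, E_D = -90,
      # D-gate first-order kinetics: sigmoid steady states with fixed time
      # constants (fast activation, slow inactivation). These are modelling
      # defaults for the delayed-firing phenotype, not measured constants.
      mD_half = -50, mD_slope = 20, mD_tau = 2,
      hD_half = -70, hD_slope = -6, hD_tau = 150
    )
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown membrane parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  structure(p, class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat(sprintf("<membrane_params: %s neuron>\n", x$kind))
  flds <- setdiff(names(x), "kind")
  cat(paste(sprintf("  %s = %g", flds, unlist(x[flds])), collapse = "\n"), "\n")
  invisible(x)
}

#' Voltage-dependent opening/closing rates of the gating variables
#'
#' Rate pair (alpha, beta), in 1/ms, for the Hodgkin-Huxley style gating
#' variables of the sodium, delayed-rectifier potassium and M-type potassium
#' currents. The removable singularities of the alpha functions (at
#' V = -54 mV for `m_Na`, V = -27 mV for beta of `m_Na`, V = -52 mV for
#' `m_K` and `m_M`) are evaluated by their analytic limits. As printed in
#' the source model, the M-gate rates coincide with the delayed-rectifier
#' rates.
#'
#' @param gate one of `"m_Na"`, `"h_Na"`, `"m_K"`, `"m_M"`.
#' @param V membrane potential, mV (vectorised).
#' @return list with numeric vectors `a` and `b` (1/ms).
#' @export
#' @examples
#' gate_rates("m_Na", -54)$a  # analytic limit 1.28
gate_rates <- function(gate, V) {
  stopifnot(all(is.finite(V)))
  vexp_ratio <- function(c0, u, d) {
    # c0 * u / (1 - exp(-u/d)) with limit c0*d at u = 0
    out <- ifelse(abs(u) < 1e-7, c0 * d, c0 * u / (1 - exp(-u / d)))
    out
  }
  switch(gate,
    m_Na = list(
      a = vexp_ratio(0.32, V + 54, 4),
      b = ifelse(abs(V + 27) < 1e-7, 0.28 * 5,
                 0.28 * (V + 27) / (exp((V + 27) / 5) - 1))
    ),
    h_Na = list(
      a = 0.128 * exp(-(V + 50) / 18),
      b = 4 / (1 + exp(-(V + 27) / 5))
    ),
    m_K = list(
      a = vexp_ratio(0.032, V + 52, 5),
      b = 0.5 * exp(-(V + 57) / 40)
    ),
    m_M = list(
      a = vexp_ratio(0.032, V + 52, 5),
      b = 0.5 * exp(-(V + 57) / 40)
    ),
    stop("unknown gate: ", gate)
  )
}

#' First-order gating kinetics
#'
#' The canonical Hodgkin-Huxley relaxation `dx/dt = a (1 - x) - b x` for a
#' gating variable `x` with opening rate `a` and closing rate `b`.
#'
#' @param x gating value in \[0, 1\].
#' @param a,b rates, 1/ms.
#' @return dx/dt in 1/ms.
#' @export
gating_rhs <- function(x, a, b) {
  a * (1 - x) - b * x
}

# steady state and relaxation time of a gate at fixed V
gate_inf <- function(gate, V) {
  r <- gate_rates(gate, V)
  r$a / (r$a + r$b)
}

# sigmoid steady states of the FS D-gate
d_gate_inf <- function(V, half, slope) 1 / (1 + exp(-(V - half) / slope))

#' Ionic membrane currents of a single neuron
#'
#' Evaluates the instantaneous ionic currents (uA/cm^2) given the gating
#' state: `I_Na = g_Na m_Na^3 h_Na (V - E_Na)`, `I_K = g_K m_K^4 (V - E_K)`,
#' `I_leak = g_leak (V - E_leak)`, and the class-specific slow current
#' `I_M = g_M m_M (V - E_K)` for MSN or `I_D = g_D m_D^3 h_D (V - E_D)` for
#' FS cells. Note the M-current reverses at the potassium reversal.
#'
#' @param state named list/vector with `V` and the gating variables
#'   (`m_Na`, `h_Na`, `m_K`, and `m_M` for MSN or `m_D`, `h_D` for FS).
#' @param params a [membrane_params()] object of the matching kind.
#' @return named list of currents `I_Na`, `I_K`, `I_leak`, and `I_M` or
#'   `I_D`, in uA/cm^2.
#' @export
membrane_currents <- function(state, params) {
  s <- as.list(state)
  V <- s$V
  out <- list(
    I_Na   = params$g_Na * s$m_Na^3 * s$h_Na * (V - params$E_Na),
    I_K    = params$g_K * s$m_K^4 * (V - params$E_K),
    I_leak = params$g_leak * (V - params$E_leak)
  )
  if (params$kind == "MSN") {
    if (is.null(s$m_M)) stop("MSN state requires m_M")
    out$I_M <- params$g_M * s$m_M * (V - params$E_K)
  } else {
    if (is.null(s$m_D) || is.null(s$h_D)) stop("FS state requires m_D and h_D")
    out$I_D <- params$g_D * s$m_D^3 * s$h_D * (V - params$E_D)
  }
  out
}

#' Right-hand side of the single-neuron membrane equation
#'
#' Current-balance dynamics
#' `C dV/dt = -I_leak - I_K - I_Na - I_{M/D} - I_syn + I_app`
#' together with the gating kinetics. Synaptic activation `s` is governed by
#' [synapse_rhs()] and included here so a full per-neuron state derivative is
#' returned.
#'
#' @param state named list with `V`, gating variables and `s`.
#' @param params [membrane_params()] object.
#' @param I_syn synaptic current, uA/cm^2 (positive = inhibitory here).
#' @param I_app applied current, uA/cm^2 (activation + stimulation).
#' @param syn [synaptic_params()] object used for the `s` kinetics.
#' @return named list of time derivatives (per ms).
#' @export
neuron_rhs <- function(state, params, I_syn = 0, I_app = 0,
                       syn = synaptic_params()) {
  s <- as.list(state)
  cur <- membrane_currents(state, params)
  I_slow <- if (params$kind == "MSN") cur$I_M else cur$I_D
  d <- list(
    V = (-cur$I_leak - cur$I_K - cur$I_Na - I_slow - I_syn + I_app) / params$C
  )
  for (g in c("m_Na", "h_Na", "m_K")) {
    r <- gate_rates(g, s$V)
    d[[g]] <- gating_rhs(s[[g]], r$a, r$b)
  }
  if (params$kind == "MSN") {
    r <- gate_rates("m_M", s$V)
    d$m_M <- gating_rhs(s$m_M, r$a, r$b)
  } else {
    d$m_D <- (d_gate_inf(s$V, params$mD_half, params$mD_slope) - s$m_D) / params$mD_tau
    d$h_D <- (d_gate_inf(s$V, params$hD_half, params$hD_slope) - s$h_D) / params$hD_tau
  }
  if (!is.null(s$s)) {
    d$s <- synapse_rhs(s$s, s$V, params$kind, syn)
  }
  d
}

#' Steady-state current balance of an uncoupled neuron
#'
#' Net outward membrane current at voltage `V` with every gate at its
#' steady state for that voltage; the resting potential of an isolated
#' neuron is a zero of this function.
#'
#' @param V membrane potential, mV (vectorised).
#' @param params [membrane_params()] object.
#' @param I_app applied current, uA/cm^2.
#' @return net current `I_leak + I_K + I_Na + I_{M/D} - I_app` (uA/cm^2).
#' @export
steady_current <- function(V, params, I_app = 0) {
  vapply(V, function(v) {
    st <- list(
      V = v,
      m_Na = gate_inf("m_Na", v), h_Na = gate_inf("h_Na", v),
      m_K = gate_inf("m_K", v)
    )
    if (params$kind == "MSN") {
      st$m_M <- gate_inf("m_M", v)
    } else {
      st$m_D <- d_gate_inf(v, params$mD_half, params$mD_slope)
      st$h_D <- d_gate_inf(v, params$hD_half, params$hD_slope)
    }
    cur <- membrane_currents(st, params)
    sum(unlist(cur)) - I_app
  }, numeric(1))
}

#' Resting potential of an isolated neuron
#'
#' Locates the zero of [steady_current()] by bracketing root search on
#' \[-100, -20\] mV.
#'
#' @inheritParams steady_current
#' @param interval search bracket in mV.
#' @return resting potential, mV.
#' @export
resting_potential <- function(params, I_app = 0, interval = c(-100, -20)) {
  uniroot(function(v) steady_current(v, params, I_app),
          interval = interval, tol = 1e-8)$root
}
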