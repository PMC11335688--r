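#' Deep-brain-stimulation parameters
#'
#' Pulsed stimulation current with Gaussian spatial decay around the
#' electrode: neuron `i` receives
#' `A * exp(-||x_i - x_E||^2 / sigma^2) * pulse(t)` with
#' `pulse(t) = H(sin(omega t)) * (1 - H(sin(omega t + delta)))`, `H` the
#' Heaviside step. The pulse is on for a fraction `delta / 2pi` of each
#' period (a half-wave at `delta = pi`); the default `delta = 0.2 pi`
#' gives short 10%-duty pulses.
#'
#' The stimulation frequency is specified via the period `period_ms`
#' (`omega = 2 pi / period_ms`); `freq_hz` is a convenience alternative.
#' Clinically styled presets are 130 Hz (`period_ms ~ 7.69`) and 200 Hz
#' (`period_ms = 5`); `period_ms = 130` reproduces a literal 130 ms period.
#'
#' @param A pulse amplitude, uA/cm^2.
#' @param freq_hz stimulation frequency, Hz (ignored when `period_ms`
#'   given).
#' @param period_ms stimulation period, ms.
#' @param delta phase shift controlling the pulse width, rad.
#' @param electrode electrode position, mm (x, y, z). The default sits
#'   off-centre inside the default synthetic ellipsoid volume; with
#'   imported atlas-space positions, supply the matching coordinate.
#' @param sigma spatial decay length, mm.
#' @return object of class `dbs_params` (includes derived `omega`, rad/ms).
#' @export
dbs_params <- function(A = 200, freq_hz = 130, period_ms = NULL,
                       delta = 0.2 * pi, electrode = c(2, 1, 1),
                       sigma = 2) {
  if (is.null(period_ms)) period_ms <- 1000 / freq_hz
  stopifnot(A >= 0, sigma > 0, period_ms > 0, length(electrode) == 3)
  structure(list(
    A = A, period_ms = period_ms, omega = 2 * pi / period_ms,
    delta = delta, electrode = as.numeric(electrode), sigma = sigma
  ), class = "dbs_params")
}

#' Proportional feedback controller parameters
#'
#' Closed-loop adjustment of the stimulation amplitude,
#' `dA/dt = -Kp (S(t) - S_target)`, active after `t_on`; before `t_on` the
#' amplitude is held at `A_init` (open-loop stimulation). The amplitude is
#' clamped to `[A_min, A_max]`.
#'
#' @param Kp proportional gain (amplitude units per unit S per ms).
#' @param S_target macroscopic setpoint — typically the unstable
#'   low-activation fixed point from the equation-free analysis.
#' @param A_init initial amplitude (the open-loop value).
#' @param A_min,A_max actuator bounds.
#' @param t_on control activation time, ms.
#' @return object of class `controller_params`.
#' @export
controller_params <- function(Kp, S_target, A_init = 200, A_min = 0,
                              A_max = 400, t_on = 150) {
  stopifnot(Kp >= 0, A_min <= A_init, A_init <= A_max)
  structure(list(
    Kp = Kp, S_target = S_target, A_init = A_init,
    A_min = A_min, A_max = A_max, t_on = t_on
  ), class = "controller_params")
}

# Gaussian spatial weights (amplitude-independent part of the DBS current)
dbs_spatial_weights <- function(positions, dbs) {
  d2 <- (positions[, 1] - dbs$electrode[1])^2 +
    (positions[, 2] - dbs$electrode[2])^2 +
    (positions[, 3] - dbs$electrode[3])^2
  exp(-d2 / dbs$sigma^2)
}

#' Instantaneous DBS current
#'
#' @param positions n x 3 neuron coordinate matrix, mm.
#' @param t time, ms (scalar or vector).
#' @param dbs a [dbs_params()].
#' @return per-neuron current vector (or n x length(t) matrix), uA/cm^2.
#' @export
dbs_current <- function(positions, t, dbs) {
  w <- dbs$A * dbs_spatial_weights(positions, dbs)
  pulse <- as.numeric(sin(dbs$omega * t) > 0) *
    (1 - as.numeric(sin(dbs$omega * t + dbs$delta) > 0))
  if (length(t) == 1) w * pulse else outer(w, pulse)
}

#' Simulate the network under closed-loop DBS
#'
#' Open-loop pulsed stimulation at `ctrl$A_init` until `ctrl$t_on`, then
#' proportional amplitude feedback co-integrated with the network using the
#' instantaneous restriction `S(t)`. With `ctrl = NULL` (or `Kp = 0`) the
#' run is plain constant-amplitude DBS.
#'
#' @param graph a `striatum_graph`.
#' @param state0 initial n x 7 state (or `NULL` for a seeded draw).
#' @param sim a [sim_config()].
#' @param dbs a [dbs_params()].
#' @param ctrl a [controller_params()] or `NULL`.
#' @param ... passed to [integrate_network()].
#' @return a `trajectory` whose `A_dbs` field holds the amplitude series.
#' @export
closed_loop_simulate <- function(graph, state0 = NULL, sim = sim_config(),
                                 dbs = dbs_params(), ctrl = NULL, ...) {
  integrate_network(graph, state0, sim, dbs = dbs, ctrl = ctrl, ...)
}

#' Population synchrony index
#'
#' Binned coincidence measure on the spike raster: spikes are binned per
#' neuron into `bin_ms` windows (binary trains) and the index is the
#' variance of the population-averaged train normalised by the mean
#' single-train variance (a chi-square-type synchrony measure). Identical
#' trains give 1; independent trains give a value of order `1/n`.
#'
#' @param spikes data.frame with `t_ms` and `neuron_id` (a raster).
#' @param n_neurons number of neurons in the population.
#' @param t_range time window c(start, end), ms; defaults to the raster
#'   span.
#' @param bin_ms bin width, ms.
#' @return synchrony index in \[0, 1\], or `NA` (with a warning) for an
#'   empty or constant raster.
#' @export
synchrony_index <- function(spikes, n_neurons, t_range = NULL, bin_ms = 2) {
  if (nrow(spikes) == 0) {
    warning("empty raster: synchrony undefined")
    return(NA_real_)
  }
  if (is.null(t_range)) t_range <- range(spikes$t_ms)
  sel <- spikes$t_ms >= t_range[1] & spikes$t_ms <= t_range[2]
  sp <- spikes[sel, ]
  if (nrow(sp) == 0) {
    warning("no spikes in window: synchrony undefined")
    return(NA_real_)
  }
  breaks <- seq(t_range[1], t_range[2] + bin_ms, by = bin_ms)
  nb <- length(breaks) - 1
  bin <- pmin(nb, pmax(1L, findInterval(sp$t_ms, breaks,
                                        rightmost.closed = TRUE)))
  # binary train per neuron x bin
  mat <- matrix(0L, n_neurons, nb)
  mat[cbind(sp$neuron_id, bin)] <- 1L
  active <- rowSums(mat) > 0
  mat <- mat[active, , drop = FALSE]
  if (nrow(mat) < 2) {
    warning("fewer than 2 spiking neurons: synchrony undefined")
    return(NA_real_)
  }
  pop <- colMeans(mat)
  v_pop <- mean(pop^2) - mean(pop)^2
  v_ind <- mean(rowMeans(mat^2) - rowMeans(mat)^2)
  if (v_ind <= 0) {
    warning("constant trains: synchrony undefined")
    return(NA_real_)
  }
  min(1, max(0, v_pop / v_ind))
}
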