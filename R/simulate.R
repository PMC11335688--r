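#' Simulation configuration
#'
#' @param dt integration step, ms (fixed-step RK4).
#' @param duration simulated time, ms.
#' @param I0 network activation current, uA/cm^2 — the cortico-striatal
#'   drive and the bifurcation parameter of the macroscopic analysis.
#' @param i0_msn_only if `TRUE`, `I0` is applied to MSNs only; the default
#'   drives both populations (cortex projects to both).
#' @param record_every observable sampling interval, ms (snapshots are
#'   decimated; spikes are detected on the full-resolution trace).
#' @param spike_threshold spike detection threshold, mV.
#' @param seed seed for the initial-condition draw.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.025, duration = 100, I0 = 0,
                       i0_msn_only = FALSE, record_every = 0.5,
                       spike_threshold = -15, seed = 1L) {
  stopifnot(dt > 0, duration >= dt, record_every >= dt)
  structure(list(
    dt = dt, duration = duration, I0 = I0,
    i0_msn_only = isTRUE(i0_msn_only),
    record_every = record_every,
    spike_threshold = spike_threshold, seed = as.integer(seed)
  ), class = "sim_config")
}

state_cols <- c("V", "m_Na", "h_Na", "m_K", "g1", "g2", "s")

#' Draw a network initial condition
#'
#' Membrane potentials uniform on \[-80, -60\] mV, every gating variable at
#' its steady state for the drawn voltage, synaptic activation zero.
#'
#' @param graph a `striatum_graph`.
#' @param seed integer seed.
#' @param membrane list with `MSN` and `FS` [membrane_params()].
#' @return n x 7 state matrix with columns
#'   `V, m_Na, h_Na, m_K, g1, g2, s` where `g1`/`g2` hold `m_M`/unused for
#'   MSN and `m_D`/`h_D` for FS neurons.
#' @export
initial_state <- function(graph, seed = 1L,
                          membrane = default_membrane()) {
  n <- graph$n_total
  with_seed(seed, {
    V <- runif(n, -80, -60)
    st <- matrix(0, n, 7, dimnames = list(NULL, state_cols))
    st[, "V"] <- V
    st[, "m_Na"] <- gate_inf("m_Na", V)
    st[, "h_Na"] <- gate_inf("h_Na", V)
    st[, "m_K"] <- gate_inf("m_K", V)
    is_msn <- graph$kinds == "MSN"
    st[is_msn, "g1"] <- gate_inf("m_M", V[is_msn])
    fsp <- membrane$FS
    st[!is_msn, "g1"] <- d_gate_inf(V[!is_msn], fsp$mD_half, fsp$mD_slope)
    st[!is_msn, "g2"] <- d_gate_inf(V[!is_msn], fsp$hD_half, fsp$hD_slope)
    st
  })
}

#' Default membrane parameter pair
#' @return list with `MSN` and `FS` [membrane_params()].
#' @export
default_membrane <- function() {
  list(MSN = membrane_params("MSN"), FS = membrane_params("FS"))
}

# incoming-edge CSR (0-based) over postsynaptic neurons
incoming_csr <- function(graph) {
  n <- graph$n_total
  e <- graph$edges
  ind <- tabulate(e$target, nbins = n)
  ptr <- c(0L, cumsum(ind))
  ord <- order(e$target)
  list(ptr = as.integer(ptr), src = as.integer(e$source[ord] - 1L))
}

#' Integrate the full coupled network
#'
#' Advances every neuron's membrane, gating and synaptic state with
#' fixed-step RK4 (the microscopic flow over the requested duration).
#' Optional deep-brain-stimulation input and closed-loop amplitude control
#' are co-integrated when `dbs` (and `ctrl`) are supplied.
#'
#' @param graph a `striatum_graph`.
#' @param state0 n x 7 state matrix (see [initial_state()]); if `NULL`, a
#'   fresh initial condition is drawn from `sim$seed`.
#' @param sim a [sim_config()].
#' @param membrane list with `MSN` and `FS` [membrane_params()].
#' @param syn a [synaptic_params()].
#' @param dbs optional [dbs_params()]; adds the pulsed spatially decaying
#'   stimulation current.
#' @param ctrl optional [controller_params()]; requires `dbs`, switches the
#'   amplitude to proportional feedback after `ctrl$t_on`.
#' @param I_ext optional static per-neuron extra current, uA/cm^2.
#' @param t0 start time, ms (affects only time stamps and the DBS phase).
#' @param store_v,store_s also store the per-neuron V / s snapshot matrices
#'   (memory-heavy; meant for small fixtures).
#' @return object of class `trajectory`: list with `times`, `v_mean`, `S`
#'   (mean MSN synaptic activity), `A_dbs`, `spikes` (data.frame
#'   `t_ms`, `neuron_id`), `final_state`, `gate_min`/`gate_max` (running
#'   bounds of the gating/synaptic variables over every step), and the
#'   configuration used.
#' @export
integrate_network <- function(graph, state0 = NULL, sim = sim_config(),
                              membrane = default_membrane(),
                              syn = synaptic_params(),
                              dbs = NULL, ctrl = NULL, I_ext = NULL,
                              t0 = 0, store_v = FALSE, store_s = FALSE) {
  n <- graph$n_total
  if (is.null(state0)) state0 <- initial_state(graph, sim$seed, membrane)
  stopifnot(nrow(state0) == n, ncol(state0) == 7)
  if (!is.null(ctrl) && is.null(dbs)) stop("ctrl requires dbs")
  csr <- incoming_csr(graph)
  n_steps <- round(sim$duration / sim$dt)
  record_every <- max(1L, round(sim$record_every / sim$dt))

  if (!is.null(dbs)) {
    w <- dbs_spatial_weights(graph$positions, dbs)
    omega <- dbs$omega
    delta <- dbs$delta
    if (is.null(ctrl)) {
      ctrl_on <- 0L; kp <- 0; s_target <- 0; t_on <- 0
      a_min <- 0; a_max <- Inf; A0 <- dbs$A
    } else {
      ctrl_on <- 1L; kp <- ctrl$Kp; s_target <- ctrl$S_target
      t_on <- ctrl$t_on; a_min <- ctrl$A_min; a_max <- ctrl$A_max
      A0 <- ctrl$A_init
    }
  } else {
    w <- numeric(0); omega <- 0; delta <- 0; A0 <- 0
    ctrl_on <- 0L; kp <- 0; s_target <- 0; t_on <- 0; a_min <- 0; a_max <- 0
  }

  res <- .net_integrate_cpp(
    state0, as.integer(graph$kinds == "MSN"), csr$ptr, csr$src,
    unclass(membrane$MSN), unclass(membrane$FS), unclass(syn),
    sim$dt, as.integer(n_steps), as.integer(record_every),
    t0, sim$I0, as.integer(sim$i0_msn_only),
    if (is.null(I_ext)) numeric(0) else as.numeric(I_ext),
    w, omega, delta, A0,
    ctrl_on, kp, s_target, t_on, a_min, a_max,
    sim$spike_threshold, isTRUE(store_v), isTRUE(store_s)
  )
  colnames(res$final_state) <- state_cols
  names(res$gate_min) <- names(res$gate_max) <- state_cols[2:7]
  traj <- list(
    times = res$times, v_mean = res$v_mean, S = res$S, A_dbs = res$A_dbs,
    spikes = data.frame(t_ms = res$spike_t, neuron_id = res$spike_i),
    final_state = res$final_state,
    gate_min = res$gate_min, gate_max = res$gate_max,
    V = res$V, s = res$s,
    sim = sim, n = n
  )
  class(traj) <- "trajectory"
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory: %d neurons, %.1f ms (dt = %g ms), %d spikes>\n",
    x$n, max(x$times) - min(x$times), x$sim$dt, nrow(x$spikes)
  ))
  invisible(x)
}

#' Detect spikes as upward threshold crossings
#'
#' A spike is registered when a membrane trace crosses the threshold from
#' below; the same neuron cannot fire again until its trace has fallen back
#' below the threshold.
#'
#' @param V numeric vector (one neuron) or time x neurons matrix of
#'   membrane potentials, mV.
#' @param times time stamps, ms.
#' @param threshold detection threshold, mV.
#' @return data.frame with `t_ms` and `neuron_id`.
#' @export
detect_spikes <- function(V, times, threshold = -15) {
  if (is.vector(V)) V <- matrix(V, ncol = 1)
  stopifnot(nrow(V) == length(times))
  out_t <- numeric(0)
  out_i <- integer(0)
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
    out_t <- c(out_t, times[up])
    out_i <- c(out_i, rep.int(j, length(up)))
  }
  ord <- order(out_t, out_i)
  data.frame(t_ms = out_t[ord], neuron_id = out_i[ord])
}

#' Mean observables of a trajectory
#'
#' The neuron-averaged membrane potential and the mean MSN synaptic
#' activity (the macroscopic variable of the equation-free analysis).
#'
#' @param trajectory a `trajectory`.
#' @return data.frame `t_ms`, `V_mean_mV`, `S_mean`.
#' @export
mean_observables <- function(trajectory) {
  data.frame(
    t_ms = trajectory$times,
    V_mean_mV = trajectory$v_mean,
    S_mean = trajectory$S
  )
}

#' Periodogram of an observable series
#'
#' Mean-removed periodogram with the dominant (largest non-DC) spectral
#' peak above a frequency floor. A peak is flagged as no dominant rhythm
#' when it does not exceed 10x the median spectral power.
#'
#' @param series numeric observable series (e.g. mean membrane potential).
#' @param dt sampling interval of `series`, ms.
#' @param floor_hz lowest frequency considered for the dominant peak, Hz.
#' @return list with `freq_hz`, `power`, `dominant_hz`, `dominant_power`,
#'   `has_rhythm`.
#' @export
power_spectrum <- function(series, dt, floor_hz = 1) {
  m <- length(series)
  if (m < 256) stop("need at least 256 samples, got ", m)
  x <- series - mean(series)
  sp <- Mod(fft(x))^2 / m
  nf <- floor(m / 2)
  freq <- (seq_len(nf)) * 1000 / (m * dt)   # Hz; excludes DC
  pw <- sp[2:(nf + 1)]
  sel <- freq >= floor_hz
  idx <- which(sel)[which.max(pw[sel])]
  list(
    freq_hz = freq, power = pw,
    dominant_hz = freq[idx], dominant_power = pw[idx],
    has_rhythm = pw[idx] > 10 * stats::median(pw)
  )
}

#' Write a network state checkpoint
#'
#' Plain-text snapshot of a full n x 7 state matrix (`V`, gating
#' variables, `s`), restorable with [read_state()].
#'
#' @param state n x 7 state matrix.
#' @param path output CSV path.
#' @export
write_state <- function(state, path) {
  write.csv(as.data.frame(state), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a network state checkpoint written by [write_state()]
#' @param path CSV path.
#' @return n x 7 state matrix.
#' @export
read_state <- function(path) {
  tab <- read.csv(path)
  if (!identical(names(tab), state_cols)) {
    stop("not a state checkpoint: expected columns ",
         paste(state_cols, collapse = ","))
  }
  as.matrix(tab)
}

#' Export a spike raster
#' @param trajectory a `trajectory`.
#' @param path output CSV path (`t_ms,neuron_id`).
#' @export
write_raster <- function(trajectory, path) {
  write.csv(trajectory$spikes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the observable series
#' @param trajectory a `trajectory`.
#' @param path output CSV path (`t_ms,V_mean_mV,S_mean`).
#' @export
write_observables <- function(trajectory, path) {
  write.csv(mean_observables(trajectory), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
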