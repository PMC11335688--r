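#' GABAergic synapse parameters
#'
#' Activation/inactivation rates of the presynaptic gating variable and the
#' four class-to-class coupling conductances. `alpha_M = 2`,
#' `beta_M = 1/13` (MSN) and `alpha_F = 4`, `beta_F = 1/13` (FS);
#' conductances `g_MM = g_MF = 0.02` and `g_FF = g_FM = 0.005` mS/cm^2, with
#' a common GABA-A reversal at -80 mV. In `g_XY`, `X` is the postsynaptic
#' and `Y` the presynaptic class.
#'
#' @param ... named overrides.
#' @return object of class `synaptic_params`.
#' @export
synaptic_params <- function(...) {
  p <- list(
    alpha_M = 2, beta_M = 1 / 13,
    alpha_F = 4, beta_F = 1 / 13,
    g_MM = 0.02, g_MF = 0.02, g_FF = 0.005, g_FM = 0.005,
    E_GABA = -80
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown synaptic parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$alpha_M > 0, p$beta_M > 0, p$alpha_F > 0, p$beta_F > 0,
            p$g_MM >= 0, p$g_MF >= 0, p$g_FF >= 0, p$g_FM >= 0)
  structure(p, class = "synaptic_params")
}

#' Presynaptic release sigmoid
#'
#' Voltage dependence of transmitter release: `H_M(V) = 1 + tanh(V/4)` for
#' MSN terminals and `H_F(V) = 1 + tanh(V/10)` for FS terminals. Ranges over
#' \[0, 2\] (saturating at 2 for a depolarised terminal), as printed in the
#' source model — it is deliberately not normalised to \[0, 1\].
#'
#' @param kind `"MSN"` or `"FS"`.
#' @param V presynaptic membrane potential, mV (vectorised).
#' @return dimensionless value in \[0, 2\].
#' @export
sigmoid_H <- function(kind = c("MSN", "FS"), V) {
  kind <- match.arg(kind)
  if (kind == "MSN") 1 + tanh(V / 4) else 1 + tanh(V / 10)
}

#' Synaptic activation kinetics
#'
#' `ds/dt = alpha_X (1 - s) H_X(V_pre) - beta_X s` for a presynaptic neuron
#' of class X. `s` stays in \[0, 1\] along any trajectory.
#'
#' @param s activation in \[0, 1\].
#' @param V_pre presynaptic membrane potential, mV.
#' @param kind presynaptic class, `"MSN"` or `"FS"`.
#' @param params [synaptic_params()] object.
#' @return ds/dt, 1/ms.
#' @export
synapse_rhs <- function(s, V_pre, kind = c("MSN", "FS"),
                        params = synaptic_params()) {
  kind <- match.arg(kind)
  if (kind == "MSN") {
    params$alpha_M * (1 - s) * sigmoid_H("MSN", V_pre) - params$beta_M * s
  } else {
    params$alpha_F * (1 - s) * sigmoid_H("FS", V_pre) - params$beta_F * s
  }
}

#' Per-neuron GABAergic input currents
#'
#' Total inhibitory current each neuron receives from its presynaptic
#' partners, `I_syn,i = sum_Y g_XY (V_i - E_GABA) sum_{j in Y} A_ij s_j`,
#' where `X` is the class of the postsynaptic neuron `i`, the inner sum runs
#' over presynaptic neurons `j` of class `Y` with an edge j -> i, and
#' `A` is the directed adjacency. Evaluated sparsely over the edge list.
#'
#' @param V per-neuron membrane potentials, mV.
#' @param s per-neuron synaptic activations.
#' @param graph a [striatum_graph()] object.
#' @param params [synaptic_params()] object.
#' @return numeric vector of synaptic currents, uA/cm^2 (>= 0 whenever
#'   `V_i > E_GABA`: the current is inhibitory and enters the membrane
#'   equation with a minus sign).
#' @export
synaptic_currents <- function(V, s, graph, params = synaptic_params()) {
  n <- graph$n_total
  stopifnot(length(V) == n, length(s) == n)
  is_msn <- graph$kinds == "MSN"
  # accumulate presynaptic drive split by presynaptic class
  sum_m <- numeric(n)
  sum_f <- numeric(n)
  if (nrow(graph$edges) > 0) {
    src <- graph$edges$source
    tgt <- graph$edges$target
    from_msn <- is_msn[src]
    contrib <- s[src]
    sum_m <- as.numeric(tapply_sum(contrib[from_msn], tgt[from_msn], n))
    sum_f <- as.numeric(tapply_sum(contrib[!from_msn], tgt[!from_msn], n))
  }
  drive <- V - params$E_GABA
  ifelse(is_msn,
         params$g_MM * drive * sum_m + params$g_MF * drive * sum_f,
         params$g_FM * drive * sum_m + params$g_FF * drive * sum_f)
}

# sum `x` into bins 1..n given integer bin ids (sparse accumulation)
tapply_sum <- function(x, bin, n) {
  out <- numeric(n)
  if (length(x)) {
    agg <- rowsum(x, group = bin)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}
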