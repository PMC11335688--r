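#' Configuration of the equation-free coarse timestepper
#'
#' @param T coarse horizon, ms: the short microscopic burst length over
#'   which the lifted state is integrated before restriction. Chosen long
#'   enough that the fast microscopic variables become enslaved to the mean
#'   synaptic activity, short enough that the macroscopic variable changes
#'   little.
#' @param settle_time pre-run used to record the reference microstate, ms.
#' @param lift_noise standard deviation of the per-neuron randomisation
#'   applied to the MSN synaptic variables during lifting.
#' @param ensemble number of independent lifted realizations per mesh point.
#' @param S_mesh mesh of macroscopic states in \[0, 1\].
#' @param dt microscopic integration step, ms.
#' @param restrict_over `"msn"` (mean over MSNs, the default) or `"all"`.
#' @param seed master seed; every mesh point and ensemble member draws from
#'   a deterministic substream so results are independent of execution
#'   order.
#' @return object of class `eqfree_config`.
#' @export
eqfree_config <- function(T = 5, settle_time = 20, lift_noise = 0.05,
                          ensemble = 20, S_mesh = seq(0, 1, by = 0.05),
                          dt = 0.025, restrict_over = c("msn", "all"),
                          seed = 1L) {
  restrict_over <- match.arg(restrict_over)
  stopifnot(T > 0, ensemble >= 1, settle_time >= 0,
            all(S_mesh >= 0), all(S_mesh <= 1), !is.unsorted(S_mesh))
  structure(list(
    T = T, settle_time = settle_time, lift_noise = lift_noise,
    ensemble = as.integer(ensemble), S_mesh = S_mesh, dt = dt,
    restrict_over = restrict_over, seed = as.integer(seed)
  ), class = "eqfree_config")
}

#' Restriction operator: microstate to macrostate
#'
#' The macroscopic variable is the mean synaptic activity of the medium
#' spiny neurons, `S = (1/N_MSN) sum_{i in MSN} s_i` (akin to a local field
#' potential). Optionally the mean over all neurons.
#'
#' @param state n x 7 state matrix.
#' @param graph a `striatum_graph`.
#' @param over `"msn"` or `"all"`.
#' @return scalar macrostate S in \[0, 1\].
#' @export
restrict_state <- function(state, graph, over = c("msn", "all")) {
  over <- match.arg(over)
  s <- state[, "s"]
  if (over == "msn") {
    idx <- graph$kinds == "MSN"
    if (!any(idx)) stop("graph has no MSNs to restrict over")
    mean(s[idx])
  } else {
    mean(s)
  }
}

#' Record a reference microstate
#'
#' Integrates the network from a seeded default initial condition for a
#' short settling period at the given activation current and returns the
#' terminal microstate. The lifting operator reuses this realisation for
#' all non-synaptic degrees of freedom, so one reference is recorded per
#' value of `I0`.
#'
#' @param graph a `striatum_graph`.
#' @param I0 activation current, uA/cm^2.
#' @param config an [eqfree_config()].
#' @param membrane,syn model parameters as in [integrate_network()].
#' @param seed seed for the initial-condition draw (defaults to a
#'   substream of the config master seed).
#' @return n x 7 state matrix.
#' @export
make_reference_state <- function(graph, I0, config = eqfree_config(),
                                 membrane = default_membrane(),
                                 syn = synaptic_params(), seed = NULL) {
  if (is.null(seed)) seed <- substream_seed(config$seed, 101L)
  st0 <- initial_state(graph, seed = seed, membrane = membrane)
  if (config$settle_time <= 0) return(st0)
  sim <- sim_config(dt = config$dt, duration = config$settle_time, I0 = I0,
                    record_every = config$settle_time)
  integrate_network(graph, st0, sim, membrane = membrane,
                    syn = syn)$final_state
}

#' Lifting operator: macrostate to microstate
#'
#' Copies the reference microstate and overwrites each MSN's synaptic
#' activation with `S + lift_noise * Z_i`, `Z_i` iid standard normal,
#' clipped to \[0, 1\] (values outside the unit interval are dynamically
#' meaningless). All other microscopic degrees of freedom — membrane
#' potentials, gating variables and FS synapses — are left unchanged.
#'
#' @param S target macrostate in \[0, 1\].
#' @param reference reference n x 7 state matrix.
#' @param graph a `striatum_graph`.
#' @param lift_noise randomisation standard deviation.
#' @param seed optional seed for the noise draw.
#' @return n x 7 state matrix consistent with `S` (up to sampling and
#'   clipping bias of order `lift_noise / sqrt(n_MSN)`).
#' @export
lift_state <- function(S, reference, graph, lift_noise = 0.05, seed = NULL) {
  stopifnot(S >= 0, S <= 1)
  draw <- function() {
    st <- reference
    idx <- graph$kinds == "MSN"
    s_new <- S + lift_noise * rnorm(sum(idx))
    st[idx, "s"] <- pmin(1, pmax(0, s_new))
    st
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Coarse timestepper for the striatal network
#'
#' Returns a stepper object encapsulating lift -> integrate(T) ->
#' restrict for a fixed graph, activation current and reference state.
#' [coarse_step()], [estimate_f()] and [bifurcation_scan()] accept any
#' stepper with the same contract, which is how the synthetic-drift oracle
#' ([drift_stepper()]) plugs in.
#'
#' @param graph a `striatum_graph`.
#' @param I0 activation current, uA/cm^2.
#' @param config an [eqfree_config()].
#' @param references optional list of precomputed reference states. By
#'   default one independent reference microstate is recorded per ensemble
#'   member (seeded substreams), so the ensemble spread reflects
#'   microstate variability and not merely the lifting noise.
#' @param membrane,syn model parameters.
#' @return object of class `coarse_stepper`: list with `T`, `param`
#'   (= `I0`) and `step(S, seed, member)` returning one realization of
#'   `S_T` using the `member`-th reference.
#' @export
network_stepper <- function(graph, I0, config = eqfree_config(),
                            references = NULL,
                            membrane = default_membrane(),
                            syn = synaptic_params()) {
  if (is.null(references)) {
    references <- lapply(seq_len(config$ensemble), function(m) {
      make_reference_state(graph, I0, config, membrane, syn,
                           seed = substream_seed(config$seed, 200L + m))
    })
  }
  sim <- sim_config(dt = config$dt, duration = config$T, I0 = I0,
                    record_every = config$T)
  force(graph); force(membrane); force(syn)
  step <- function(S, seed = NULL, member = 1L) {
    ref <- references[[(member - 1L) %% length(references) + 1L]]
    st <- lift_state(S, ref, graph, config$lift_noise, seed)
    tr <- integrate_network(graph, st, sim, membrane = membrane, syn = syn)
    restrict_state(tr$final_state, graph, config$restrict_over)
  }
  structure(list(T = config$T, param = I0, step = step,
                 references = references),
            class = "coarse_stepper")
}

#' Synthetic-drift plug-in stepper
#'
#' Replaces the network with an exactly known macroscopic drift: the
#' microstate is a cloud of `n_particles` scalar activations, lifting adds
#' iid noise to the macrostate, each particle evolves by the scalar ODE
#' `x' = drift(x)` (RK4), and restriction averages the cloud. Used as an
#' independent oracle for the drift-reconstruction and bifurcation
#' machinery.
#'
#' @param drift function of a scalar state returning its time derivative.
#' @param T coarse horizon.
#' @param lift_noise per-particle lifting noise.
#' @param n_particles cloud size.
#' @param param parameter value recorded on the stepper (for scans).
#' @param dt internal RK4 step.
#' @return a `coarse_stepper`.
#' @export
drift_stepper <- function(drift, T = 1, lift_noise = 0.02,
                          n_particles = 100, param = NA_real_, dt = 0.01) {
  step <- function(S, seed = NULL, member = 1L) {
    run <- function() {
      x <- S + lift_noise * rnorm(n_particles)
      nst <- max(1L, round(T / dt))
      h <- T / nst
      for (k in seq_len(nst)) {
        k1 <- drift(x)
        k2 <- drift(x + h / 2 * k1)
        k3 <- drift(x + h / 2 * k2)
        k4 <- drift(x + h * k3)
        x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      mean(x)
    }
    if (is.null(seed)) run() else with_seed(seed, run())
  }
  structure(list(T = T, param = param, step = step),
            class = "coarse_stepper")
}

#' One ensemble-averaged coarse step
#'
#' Runs `n_ens` independent lift-integrate-restrict realizations from the
#' same macrostate and returns the ensemble mean of `S_T` with its standard
#' error.
#'
#' @param S macrostate.
#' @param stepper a `coarse_stepper`.
#' @param n_ens ensemble size.
#' @param seed master seed; member seeds are derived deterministically.
#' @return list with `S_T` (ensemble mean), `se`, `values`.
#' @export
coarse_step <- function(S, stepper, n_ens = 20, seed = 1L) {
  vals <- vapply(seq_len(n_ens), function(m) {
    stepper$step(S, seed = substream_seed(seed, m), member = m)
  }, numeric(1))
  list(S_T = mean(vals),
       se = if (n_ens > 1) sd(vals) / sqrt(n_ens) else NA_real_,
       values = vals)
}

#' Reconstruct the macroscopic drift f(S)
#'
#' Approximates the right-hand side of the effective macroscopic equation
#' `S' = f(S)` by the finite difference `(F_T(S) - S) / T`, where `F_T` is
#' the ensemble-averaged coarse timestepper, independently at every mesh
#' point (independent substream seeds per point).
#'
#' @param stepper a `coarse_stepper` ([network_stepper()] or
#'   [drift_stepper()]).
#' @param config an [eqfree_config()] supplying mesh, ensemble size and
#'   master seed.
#' @return object of class `f_curve`: data.frame with columns `S`, `f`,
#'   `stderr`, `S_T`, `se_ST`; attributes `param` (I0), `T`, `ensemble`,
#'   `seed`.
#' @export
estimate_f <- function(stepper, config = eqfree_config()) {
  mesh <- config$S_mesh
  rows <- lapply(seq_along(mesh), function(k) {
    # substream keyed by the mesh value, so a repeated point reproduces
    # exactly and results do not depend on mesh ordering
    cs <- coarse_step(mesh[k], stepper, n_ens = config$ensemble,
                      seed = substream_seed(config$seed,
                                            1000L + round(mesh[k] * 1e5)))
    data.frame(S = mesh[k],
               f = (cs$S_T - mesh[k]) / stepper$T,
               stderr = cs$se / stepper$T,
               S_T = cs$S_T, se_ST = cs$se)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("f_curve", "data.frame"),
            param = stepper$param, T = stepper$T,
            ensemble = config$ensemble, seed = config$seed)
}

#' @export
print.f_curve <- function(x, ...) {
  cat(sprintf(
    "<f_curve: %d mesh points, I0 = %s, T = %g ms, ensemble = %d>\n",
    nrow(x), format(attr(x, "param")), attr(x, "T"), attr(x, "ensemble")
  ))
  print.data.frame(x, ...)
  invisible(x)
}

#' Coarse-horizon convergence diagnostic
#'
#' Reconstructs the drift at two horizons (`T` and `factor * T`) and
#' compares them pointwise: if the finite-difference estimate has
#' converged in `T`, the two curves agree within their combined standard
#' errors on the mesh interior. Disagreement flags residual dependence on
#' the horizon — un-enslaved slow degrees of freedom or chord bias.
#'
#' @param stepper_factory function of a horizon `T` returning a
#'   `coarse_stepper` at that horizon (all else fixed).
#' @param config an [eqfree_config()]; its `T` is the base horizon.
#' @param factor horizon multiplier for the comparison curve.
#' @return data.frame with `S`, `f_T`, `se_T`, `f_2T`, `se_2T`, `agree`,
#'   plus attribute `frac_agree` (fraction of interior points agreeing
#'   within 2 combined standard errors).
#' @export
horizon_diagnostic <- function(stepper_factory, config = eqfree_config(),
                               factor = 2) {
  c1 <- estimate_f(stepper_factory(config$T), config)
  cfg2 <- config
  cfg2$T <- config$T * factor
  c2 <- estimate_f(stepper_factory(cfg2$T), cfg2)
  comb <- sqrt(c1$stderr^2 + c2$stderr^2)
  agree <- abs(c1$f - c2$f) <= 2 * comb
  out <- data.frame(S = c1$S, f_T = c1$f, se_T = c1$stderr,
                    f_2T = c2$f, se_2T = c2$stderr, agree = agree)
  interior <- seq_len(nrow(out)) %in% 2:(nrow(out) - 1)
  attr(out, "frac_agree") <- mean(agree[interior])
  out
}

#' Fixed points of a reconstructed drift curve
#'
#' Zeros of `f` located by sign changes between mesh points, refined on a
#' monotone cubic interpolant by bisection to `|dS| <= tol`; the slope of
#' the interpolant at the zero gives macroscopic stability (stable iff
#' negative). A zero whose neighbourhood satisfies `|f| < 2 x local
#' standard error` is flagged `marginal` (indistinguishable from a
#' tangency at the available ensemble resolution).
#'
#' @param curve an `f_curve` (or data.frame with `S`, `f`, `stderr`).
#' @param tol refinement tolerance on S.
#' @return data.frame with `S_star`, `slope`, `stable`, `marginal`; zero
#'   rows when `f` has no sign change.
#' @export
find_fixed_points <- function(curve, tol = 1e-3) {
  S <- curve$S
  f <- curve$f
  if (length(S) < 3) stop("need at least 3 mesh points")
  itp <- splinefun(S, f, method = "monoH.FC")
  roots <- list()
  for (i in seq_len(length(S) - 1)) {
    if (f[i] == 0 && i == 1) {
      roots[[length(roots) + 1]] <- list(x = S[i], i = i)
    } else if (f[i] * f[i + 1] < 0) {
      r <- uniroot(itp, c(S[i], S[i + 1]), tol = tol / 10)$root
      roots[[length(roots) + 1]] <- list(x = r, i = i)
    } else if (f[i + 1] == 0) {
      roots[[length(roots) + 1]] <- list(x = S[i + 1], i = i)
    }
  }
  if (!length(roots)) {
    return(data.frame(S_star = numeric(0), slope = numeric(0),
                      stable = logical(0), marginal = logical(0)))
  }
  out <- do.call(rbind, lapply(roots, function(r) {
    slope <- itp(r$x, deriv = 1)
    nb <- max(1, r$i - 1):min(length(S), r$i + 2)
    se_loc <- if (!is.null(curve$stderr)) curve$stderr[nb] else rep(0, length(nb))
    marginal <- all(is.finite(se_loc)) && length(se_loc) > 0 &&
      all(abs(f[nb]) < 2 * se_loc)
    data.frame(S_star = r$x, slope = slope, stable = slope < 0,
               marginal = marginal)
  }))
  rownames(out) <- NULL
  out
}

#' Scan the drift over a parameter grid and locate the saddle-node
#'
#' Reconstructs `f` and its fixed points at every grid value of the scan
#' parameter (the activation current `I0` for the network), then brackets
#' the saddle-node bifurcation between the neighbouring grid values where
#' the fixed-point count drops between two-or-more and zero, and refines
#' the bracket by bisection on the parameter until it is narrower than
#' `crit_tol`.
#'
#' @param param_grid increasing parameter values.
#' @param make_stepper function(param) returning a `coarse_stepper`
#'   (e.g. a closure over [network_stepper()] that rebuilds the reference
#'   state per `I0`).
#' @param config an [eqfree_config()].
#' @param crit_tol bisection tolerance on the bracket width.
#' @param max_iter cap on bisection iterations.
#' @return object of class `bifurcation_diagram`: list with `branches`
#'   (data.frame `param`, `S_star`, `slope`, `stable`, `marginal`),
#'   `counts` (data.frame `param`, `n_fixed`), `I_crit`, `bracket`,
#'   `consistent`.
#' @export
bifurcation_scan <- function(param_grid, make_stepper,
                             config = eqfree_config(),
                             crit_tol = 0.05, max_iter = 25L) {
  stopifnot(!is.unsorted(param_grid))
  eval_param <- function(p) {
    fps <- find_fixed_points(estimate_f(make_stepper(p), config))
    fps
  }
  fps_list <- lapply(param_grid, eval_param)
  counts <- vapply(fps_list, nrow, integer(1))

  # monotone-pattern sanity along the grid (e.g. 2 -> 1 -> 2 is suspect)
  two <- counts >= 2
  zero <- counts == 0
  consistent <- TRUE
  if (any(two) && any(zero)) {
    rng2 <- range(which(two))
    if (any(zero[rng2[1]:rng2[2]])) {
      consistent <- FALSE
      warning("inconsistent fixed-point counts along the grid; bracket widened")
    }
  }

  I_crit <- NA_real_
  bracket <- c(NA_real_, NA_real_)
  pair <- NULL
  for (i in seq_len(length(param_grid) - 1)) {
    a <- counts[i] >= 2
    b <- counts[i + 1] >= 2
    if ((a && counts[i + 1] == 0) || (counts[i] == 0 && b)) {
      pair <- c(i, i + 1)
      if (a) break   # prefer the collide-and-disappear direction
    }
  }
  extra <- list()
  if (!is.null(pair)) {
    lo <- param_grid[pair[1]]
    hi <- param_grid[pair[2]]
    lo_two <- counts[pair[1]] >= 2
    it <- 0L
    while (abs(hi - lo) > crit_tol && it < max_iter) {
      mid <- (lo + hi) / 2
      fp_mid <- eval_param(mid)
      extra[[length(extra) + 1]] <- list(param = mid, fps = fp_mid)
      mid_two <- nrow(fp_mid) >= 2
      if (mid_two == lo_two) lo <- mid else hi <- mid
      it <- it + 1L
    }
    bracket <- sort(c(lo, hi))
    I_crit <- mean(bracket)
  }

  all_params <- c(param_grid, vapply(extra, `[[`, numeric(1), "param"))
  all_fps <- c(fps_list, lapply(extra, `[[`, "fps"))
  branches <- do.call(rbind, lapply(seq_along(all_params), function(k) {
    fp <- all_fps[[k]]
    if (nrow(fp) == 0) return(NULL)
    cbind(param = all_params[k], fp)
  }))
  if (is.null(branches)) {
    branches <- data.frame(param = numeric(0), S_star = numeric(0),
                           slope = numeric(0), stable = logical(0),
                           marginal = logical(0))
  }
  branches <- branches[order(branches$param, branches$S_star), ]
  rownames(branches) <- NULL
  structure(list(
    branches = branches,
    counts = data.frame(param = all_params,
                        n_fixed = vapply(all_fps, nrow, integer(1))),
    I_crit = I_crit, bracket = bracket, consistent = consistent
  ), class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf(
    "<bifurcation_diagram: %d parameter values, I_crit = %s (bracket [%s, %s])>\n",
    nrow(x$counts), format(x$I_crit), format(x$bracket[1]),
    format(x$bracket[2])
  ))
  invisible(x)
}

#' Export a reconstructed drift curve
#'
#' CSV `S,f,stderr` plus a JSON sidecar with the run metadata.
#'
#' @param curve an `f_curve`.
#' @param csv_path output CSV path.
#' @param json_path optional metadata JSON path.
#' @export
write_fcurve <- function(curve, csv_path, json_path = NULL) {
  write.csv(curve[, c("S", "f", "stderr")], csv_path, row.names = FALSE,
            quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      I0 = attr(curve, "param"), T = attr(curve, "T"),
      ensemble = attr(curve, "ensemble"), seed = attr(curve, "seed")
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Export a bifurcation diagram
#' @param diagram a `bifurcation_diagram`.
#' @param csv_path output CSV path (`I0,S_star,stability,slope`).
#' @param json_path optional JSON with `I_crit` and bracket.
#' @export
write_bifurcation <- function(diagram, csv_path, json_path = NULL) {
  b <- diagram$branches
  write.csv(data.frame(
    I0 = b$param, S_star = b$S_star,
    stability = ifelse(b$stable, "stable", "unstable"), slope = b$slope
  ), csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(I_crit = diagram$I_crit,
                              bracket = diagram$bracket),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
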