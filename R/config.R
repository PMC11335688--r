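#' Full default run configuration
#'
#' Nested list mirroring every module's parameter block with the model's
#' default values: builder (network geometry and connectivity), membrane
#' (MSN/FS conductances and reversals), synapse, sim, eqfree, dbs and
#' control sections, plus a master seed.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  mem <- default_membrane()
  list(
    seed = 1L,
    builder = unclass(builder_config()),
    membrane = list(MSN = unclass(mem$MSN), FS = unclass(mem$FS)),
    synapse = unclass(synaptic_params()),
    sim = unclass(sim_config()),
    eqfree = unclass(eqfree_config()),
    dbs = unclass(dbs_params()),
    control = list(Kp = 50, S_target = 0.09, A_init = 200, A_min = 0,
                   A_max = 400, t_on = 150)
  )
}

# deterministic FNV-1a hash of the canonicalised config (hex string)
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else {
      x
    }
  }
  raw <- serialize(canon(config), NULL, version = 2, ascii = TRUE)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

check_section <- function(user, defaults, section) {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) {
    stop(sprintf("unknown key(s) in section '%s': %s", section,
                 paste(bad, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      defaults[[k]] <- check_section(user[[k]], defaults[[k]],
                                     paste(section, k, sep = "."))
    } else {
      v <- user[[k]]
      if (is.list(v)) v <- unlist(v)
      if (is.numeric(defaults[[k]]) && !is.numeric(v)) {
        stop(sprintf("key '%s' in section '%s' must be numeric", k, section))
      }
      defaults[[k]] <- v
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' YAML (or JSON) file with any subset of the sections of
#' [default_config()]; missing fields take the model defaults, unknown
#' keys are rejected with the offending section named. An empty file
#' yields the full default configuration.
#'
#' @param path config file path.
#' @return object of class `run_config`: the defaulted nested list with a
#'   `hash` attribute recorded in all outputs.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- check_section(user, default_config(), "top")
  cfg$builder$n_total <- as.integer(cfg$builder$n_total)
  cfg$builder$n_msn <- as.integer(cfg$builder$n_msn)
  if (cfg$builder$n_total < 1) stop("builder.n_total must be positive")
  if (cfg$builder$n_msn < 0 || cfg$builder$n_msn > cfg$builder$n_total) {
    stop("builder.n_msn must lie in [0, n_total]")
  }
  if (cfg$builder$p_rewire < 0 || cfg$builder$p_rewire > 1) {
    stop("builder.p_rewire must lie in [0, 1]")
  }
  if (cfg$sim$dt <= 0) stop("sim.dt must be positive")
  structure(cfg, class = "run_config", hash = config_hash(cfg))
}

#' Normalised dump of a configuration
#' @param config a `run_config` or plain nested list.
#' @param path output YAML path.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Desk-scale network fixtures
#'
#' Deterministic miniature networks for tests and examples:
#' `two_neuron` — a single MSN -> MSN pair; `ring16` — 16 neurons (15 MSN,
#' 1 FS) on a ring, each connected to both ring neighbours; and
#' `mini_striatum` — 200 neurons (186 MSN, matching the full-model MSN
#' fraction) in a small ellipsoid with scaled degrees (`k_msn = 8`,
#' `k_fs = 40`).
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @return list with `graph` (a `striatum_graph`) and `state` (an initial
#'   n x 7 state matrix).
#' @export
make_fixture <- function(name = c("two_neuron", "ring16", "mini_striatum"),
                         seed = 1L) {
  if (!is.character(name) || !name[1] %in%
      c("two_neuron", "ring16", "mini_striatum")) {
    stop("unknown fixture '", name[1],
         "'; available: two_neuron, ring16, mini_striatum")
  }
  name <- name[1]
  graph <- switch(name,
    two_neuron = {
      pos <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE,
                    dimnames = list(NULL, c("x", "y", "z")))
      structure(list(
        positions = pos, kinds = c("MSN", "MSN"),
        edges = data.frame(source = 1L, target = 2L),
        n_total = 2L, n_msn = 2L, n_fs = 0L,
        config = builder_config(n_total = 2, n_msn = 2, k_msn = 1,
                                k_fs = 0, p_rewire = 0, seed = seed)
      ), class = "striatum_graph")
    },
    ring16 = {
      n <- 16L
      th <- 2 * pi * (seq_len(n) - 1) / n
      r <- 2 / (2 * sin(pi / n))   # ring radius for 2 mm spacing
      pos <- cbind(x = r * cos(th), y = r * sin(th), z = rep(0, n))
      kinds <- c(rep("MSN", 15), "FS")
      nxt <- c(2:n, 1L)
      prv <- c(n, 1:(n - 1L))
      edges <- data.frame(source = rep(seq_len(n), 2L),
                          target = c(nxt, prv))
      structure(list(
        positions = pos, kinds = kinds, edges = edges,
        n_total = n, n_msn = 15L, n_fs = 1L,
        config = builder_config(n_total = n, n_msn = 15, k_msn = 2,
                                k_fs = 2, p_rewire = 0, seed = seed)
      ), class = "striatum_graph")
    },
    mini_striatum = build_network(builder_config(
      n_total = 200, n_msn = 186, k_msn = 8, k_fs = 40,
      volume = c(4, 3, 2.5), p_rewire = 0.05, seed = seed
    ))
  )
  list(graph = graph, state = initial_state(graph, seed = seed))
}

#' Run a full pipeline command
#'
#' Executes one module chain on a configuration and writes its artifacts
#' plus a manifest (config hash, seed, package version, wall time) to the
#' output directory. Commands: `build` (graph + summary), `simulate`
#' (raster + observables), `fcurve` (drift curve at `sim$I0`),
#' `bifurcation` (scan over `i0_grid`), `dbs` (open-loop stimulation run)
#' and `control` (closed-loop run).
#'
#' @param config a `run_config` (see [load_config()]) or the list from
#'   [default_config()].
#' @param command one of `build`, `simulate`, `fcurve`, `bifurcation`,
#'   `dbs`, `control`.
#' @param out_dir output directory (created if needed).
#' @param i0_grid activation-current grid for `bifurcation`.
#' @return invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(config, command = c("build", "simulate", "fcurve",
                                             "bifurcation", "dbs",
                                             "control"),
                         out_dir, i0_grid = NULL) {
  command <- match.arg(command)
  t_start <- Sys.time()
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("output directory not writable: ", out_dir)
  }
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE)
  if (!ok) stop("output directory not writable: ", out_dir)
  unlink(probe)

  hash <- attr(config, "hash")
  if (is.null(hash)) hash <- config_hash(unclass(config))
  mem <- list(MSN = do.call(membrane_params, c(list(kind = "MSN"),
                config$membrane$MSN[setdiff(names(config$membrane$MSN), "kind")])),
              FS = do.call(membrane_params, c(list(kind = "FS"),
                config$membrane$FS[setdiff(names(config$membrane$FS), "kind")])))
  syn <- do.call(synaptic_params, config$synapse)
  bc <- do.call(builder_config, config$builder)
  files <- character(0)
  emit <- function(path) { files <<- c(files, path); path }

  graph <- build_network(bc)
  if (command == "build") {
    write_edges(graph, emit(file.path(out_dir, "edges.csv")))
    write_positions(graph$positions,
                    emit(file.path(out_dir, "positions.csv")))
    summ <- graph_summary(graph)
    jsonlite::write_json(
      list(config_hash = hash,
           n_total = graph$n_total, n_msn = graph$n_msn,
           n_fs = graph$n_fs, n_edges = nrow(graph$edges),
           mean_clustering = summ$mean_clustering,
           mean_path_length = summ$mean_path_length,
           connected = summ$connected),
      emit(file.path(out_dir, "graph_summary.json")),
      auto_unbox = TRUE, digits = NA)
  } else if (command %in% c("simulate", "dbs", "control")) {
    sim <- do.call(sim_config, config$sim)
    dbs <- if (command != "simulate") do.call(dbs_params,
      config$dbs[setdiff(names(config$dbs), "omega")]) else NULL
    ctrl <- if (command == "control") do.call(controller_params,
                                              config$control) else NULL
    traj <- integrate_network(graph, NULL, sim, membrane = mem, syn = syn,
                              dbs = dbs, ctrl = ctrl)
    write_raster(traj, emit(file.path(out_dir, "raster.csv")))
    write_observables(traj, emit(file.path(out_dir, "observables.csv")))
    if (command != "simulate") {
      write.csv(data.frame(t_ms = traj$times, A_dbs = traj$A_dbs),
                emit(file.path(out_dir, "amplitude.csv")),
                row.names = FALSE, quote = FALSE)
    }
  } else if (command == "fcurve") {
    ef <- do.call(eqfree_config, config$eqfree)
    curve <- estimate_f(network_stepper(graph, config$sim$I0, ef,
                                        membrane = mem, syn = syn), ef)
    write_fcurve(curve, emit(file.path(out_dir, "fcurve.csv")),
                 emit(file.path(out_dir, "fcurve_meta.json")))
  } else if (command == "bifurcation") {
    ef <- do.call(eqfree_config, config$eqfree)
    if (is.null(i0_grid)) i0_grid <- seq(8, 14, by = 1)
    mk <- function(p) network_stepper(graph, p, ef, membrane = mem,
                                      syn = syn)
    diag <- bifurcation_scan(i0_grid, mk, ef)
    write_bifurcation(diag, emit(file.path(out_dir, "bifurcation.csv")),
                      emit(file.path(out_dir, "bifurcation_meta.json")))
  }

  jsonlite::write_json(list(
    command = command, config_hash = hash, seed = config$seed,
    package_version = as.character(utils::packageVersion("striatnet")),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    files = basename(files)
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(files, file.path(out_dir, "manifest.json")))
}
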