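#' Configuration for the striatal network builder
#'
#' Defaults follow the full-scale model: 1995 neurons of which 1856 are
#' medium spiny neurons (MSN) and the rest fast-spiking interneurons (FS);
#' each MSN sends edges to its `k_msn = 20` nearest neighbours inside a
#' local neighbourhood of 5 mm diameter, each FS to `k_fs = 100` (the
#' five-fold higher interneuron-to-MSN connectivity); each local edge
#' spawns, with probability `p_rewire`, an additional edge to a uniformly
#' chosen remote neuron (small-world shortcut; the local edge is kept).
#'
#' The stated total/MSN counts (1995/1856) and the nominal 95%/5% split are
#' mutually inconsistent (1856/1995 is about 93%); the explicit counts are
#' the defaults and both are configurable.
#'
#' @param n_total total neuron count.
#' @param n_msn number of MSNs (rest are FS).
#' @param k_msn,k_fs local out-degree of MSN / FS sources.
#' @param neighbourhood local neighbourhood size, mm.
#' @param neighbourhood_type `"diameter"` (default: targets within
#'   `neighbourhood / 2` mm) or `"radius"`.
#' @param p_rewire per-local-edge probability of adding a remote shortcut.
#' @param volume either a numeric vector of 3 ellipsoid semi-axes (mm) or a
#'   path to a position CSV with columns `id,x_mm,y_mm,z_mm`. The default
#'   semi-axes (6, 4, 3) mm give a compact striatum-like synthetic volume
#'   dense enough that every neuron finds its full neighbour complement.
#' @param seed integer master seed for positions, labels and rewiring.
#' @return object of class `builder_config`.
#' @export
builder_config <- function(n_total = 1995, n_msn = 1856,
                           k_msn = 20, k_fs = 100,
                           neighbourhood = 5,
                           neighbourhood_type = c("diameter", "radius"),
                           p_rewire = 0.05,
                           volume = c(6, 4, 3),
                           seed = 1L) {
  neighbourhood_type <- match.arg(neighbourhood_type)
  if (n_msn > n_total) stop("n_msn must not exceed n_total")
  stopifnot(n_total >= 1, k_msn >= 0, k_fs >= 0,
            p_rewire >= 0, p_rewire <= 1, neighbourhood > 0)
  if (is.numeric(volume)) {
    if (length(volume) != 3 || any(volume <= 0)) {
      stop("volume must be 3 positive ellipsoid semi-axes or a CSV path")
    }
  } else if (!is.character(volume)) {
    stop("volume must be 3 positive ellipsoid semi-axes or a CSV path")
  }
  structure(list(
    n_total = as.integer(n_total), n_msn = as.integer(n_msn),
    k_msn = as.integer(k_msn), k_fs = as.integer(k_fs),
    neighbourhood = neighbourhood, neighbourhood_type = neighbourhood_type,
    p_rewire = p_rewire, volume = volume, seed = as.integer(seed)
  ), class = "builder_config")
}

# run expr under a local seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# derive a deterministic 31-bit substream seed from a master seed
substream_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647
}

#' Sample neuron positions in a striatum-like volume
#'
#' Uniform rejection sampling inside the configured ellipsoid, or verbatim
#' import from a position CSV (`id,x_mm,y_mm,z_mm`). Deterministic for a
#' fixed seed.
#'
#' @param config a [builder_config()].
#' @return n x 3 numeric matrix of coordinates in mm (columns x, y, z).
#' @export
generate_positions <- function(config) {
  if (is.character(config$volume)) {
    return(read_positions(config$volume, n_expected = config$n_total))
  }
  ax <- config$volume
  n <- config$n_total
  with_seed(substream_seed(config$seed, 1L), {
    out <- matrix(NA_real_, n, 3)
    got <- 0L
    while (got < n) {
      m <- max(2L * (n - got), 64L)
      cand <- cbind(runif(m, -ax[1], ax[1]),
                    runif(m, -ax[2], ax[2]),
                    runif(m, -ax[3], ax[3]))
      keep <- (cand[, 1] / ax[1])^2 + (cand[, 2] / ax[2])^2 +
        (cand[, 3] / ax[3])^2 <= 1
      cand <- cand[keep, , drop = FALSE]
      take <- min(nrow(cand), n - got)
      if (take > 0) {
        out[(got + 1):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
        got <- got + take
      }
    }
    colnames(out) <- c("x", "y", "z")
    out
  })
}

#' Assign MSN/FS labels
#'
#' Exactly `n_msn` MSN labels placed on a seeded random permutation of the
#' neuron indices; the remaining neurons are FS interneurons.
#'
#' @param config a [builder_config()].
#' @return character vector of `"MSN"` / `"FS"` labels.
#' @export
assign_kinds <- function(config) {
  if (config$n_msn > config$n_total) stop("n_msn must not exceed n_total")
  with_seed(substream_seed(config$seed, 2L), {
    kinds <- rep("FS", config$n_total)
    kinds[sample.int(config$n_total, config$n_msn)] <- "MSN"
    kinds
  })
}

#' Build the directed small-world striatal graph
#'
#' Each neuron sends edges to its `k` nearest neighbours (Euclidean
#' distance, ties broken by lower index) within the local neighbourhood —
#' `k = k_msn` for MSN sources, `k = k_fs` for FS sources. Each local edge
#' then spawns, with probability `p_rewire`, an additional edge from the
#' same source to a uniformly chosen remote neuron (outside the local
#' neighbourhood, no self-edges, no duplicates); local edges are kept. An
#' edge `j -> i` means neuron `j` is presynaptic to neuron `i`
#' (adjacency `A_ij = 1`).
#'
#' If a neuron has fewer than `k` neighbours inside its neighbourhood it is
#' connected to all of them and a warning summarises the deficient sources.
#'
#' @param positions n x 3 matrix from [generate_positions()].
#' @param kinds label vector from [assign_kinds()].
#' @param config a [builder_config()].
#' @return object of class `striatum_graph`: list with `positions`,
#'   `kinds`, `edges` (data.frame `source`, `target`), counts and `config`.
#' @export
build_graph <- function(positions, kinds, config) {
  n <- nrow(positions)
  stopifnot(length(kinds) == n, n == config$n_total)
  cutoff <- if (config$neighbourhood_type == "diameter") {
    config$neighbourhood / 2
  } else {
    config$neighbourhood
  }
  dmat <- as.matrix(stats::dist(positions))
  with_seed(substream_seed(config$seed, 3L), {
    src_list <- vector("list", n)
    deficient <- 0L
    for (i in seq_len(n)) {
      k <- if (kinds[i] == "MSN") config$k_msn else config$k_fs
      d <- dmat[i, ]
      local <- which(d <= cutoff & seq_len(n) != i)
      if (length(local) < k) deficient <- deficient + 1L
      ord <- local[order(d[local], local)]
      tgt <- ord[seq_len(min(k, length(ord)))]
      if (config$p_rewire > 0 && length(tgt) > 0) {
        n_new <- sum(runif(length(tgt)) < config$p_rewire)
        if (n_new > 0) {
          remote <- which(d > cutoff)           # excludes i itself (d = 0)
          if (length(remote) > 0) {
            extra <- sample(remote, min(n_new, length(remote)),
                            replace = FALSE)
            tgt <- c(tgt, extra)
          }
        }
      }
      src_list[[i]] <- tgt
    }
    if (deficient > 0) {
      warning(sprintf(
        "%d neuron(s) had fewer than k neighbours inside the %g mm %s neighbourhood; connected to all available",
        deficient, config$neighbourhood, config$neighbourhood_type
      ))
    }
    edges <- data.frame(
      source = rep.int(seq_len(n), lengths(src_list)),
      target = unlist(src_list, use.names = FALSE)
    )
    structure(list(
      positions = positions, kinds = kinds, edges = edges,
      n_total = n, n_msn = sum(kinds == "MSN"), n_fs = sum(kinds == "FS"),
      config = config
    ), class = "striatum_graph")
  })
}

#' Build positions, labels and graph in one call
#'
#' @param config a [builder_config()].
#' @return a `striatum_graph`.
#' @export
build_network <- function(config = builder_config()) {
  pos <- generate_positions(config)
  kinds <- assign_kinds(config)
  build_graph(pos, kinds, config)
}

#' @export
print.striatum_graph <- function(x, ...) {
  cat(sprintf(
    "<striatum_graph: %d neurons (%d MSN, %d FS), %d directed edges>\n",
    x$n_total, x$n_msn, x$n_fs, nrow(x$edges)
  ))
  invisible(x)
}

#' Per-neuron out-degrees
#' @param graph a `striatum_graph`.
#' @return integer vector of out-degrees indexed by neuron.
#' @export
out_degrees <- function(graph) {
  tabulate(graph$edges$source, nbins = graph$n_total)
}

#' In-degrees (number of presynaptic partners)
#' @param graph a `striatum_graph`.
#' @return integer vector of in-degrees indexed by neuron.
#' @export
in_degrees <- function(graph) {
  tabulate(graph$edges$target, nbins = graph$n_total)
}

as_igraph <- function(graph, directed = TRUE) {
  g <- igraph::graph_from_data_frame(
    graph$edges,
    directed = directed,
    vertices = data.frame(name = seq_len(graph$n_total), kind = graph$kinds)
  )
  g
}

#' Structural summary of a striatal graph
#'
#' Degree histograms per neuron class, mean local clustering coefficient
#' and mean shortest-path length on the undirected skeleton. For a
#' disconnected skeleton the path length is computed on the largest
#' component and flagged.
#'
#' @param graph a `striatum_graph`.
#' @return list with `out_degree_by_kind`, `in_degree_by_kind` (tables),
#'   `mean_clustering`, `mean_path_length`, `connected`,
#'   `largest_component_frac`.
#' @export
graph_summary <- function(graph) {
  if (graph$n_total == 0) stop("empty graph")
  g <- as_igraph(graph, directed = FALSE)
  g <- igraph::simplify(g)
  comps <- igraph::components(g)
  connected <- comps$no == 1
  if (!connected) {
    keep <- which(comps$membership == which.max(comps$csize))
    gc <- igraph::induced_subgraph(g, keep)
  } else {
    gc <- g
  }
  outd <- out_degrees(graph)
  ind <- in_degrees(graph)
  list(
    out_degree_by_kind = tapply(outd, graph$kinds, function(d) {
      c(mean = mean(d), min = min(d), max = max(d))
    }),
    in_degree_by_kind = tapply(ind, graph$kinds, function(d) {
      c(mean = mean(d), min = min(d), max = max(d))
    }),
    mean_clustering = igraph::transitivity(g, type = "localaverage",
                                           isolates = "zero"),
    mean_path_length = igraph::mean_distance(gc, directed = FALSE),
    connected = connected,
    largest_component_frac = max(comps$csize) / graph$n_total
  )
}

#' Read a neuron position table
#'
#' CSV with header `id,x_mm,y_mm,z_mm`.
#'
#' @param path file path.
#' @param n_expected optional expected row count.
#' @return n x 3 coordinate matrix (mm).
#' @export
read_positions <- function(path, n_expected = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x_mm", "y_mm", "z_mm")
  if (!identical(names(tab), need)) {
    stop("position file must have columns id,x_mm,y_mm,z_mm; got: ",
         paste(names(tab), collapse = ","))
  }
  for (cl in c("x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at row %d of %s", cl, bad[1], path))
    }
    tab[[cl]] <- v
  }
  if (!is.null(n_expected) && nrow(tab) != n_expected) {
    stop(sprintf("expected %d positions, file has %d", n_expected, nrow(tab)))
  }
  out <- as.matrix(tab[, c("x_mm", "y_mm", "z_mm")])
  colnames(out) <- c("x", "y", "z")
  out
}

#' Write a neuron position table
#' @param positions n x 3 coordinate matrix.
#' @param path output CSV path.
#' @export
write_positions <- function(positions, path) {
  write.csv(
    data.frame(id = seq_len(nrow(positions)),
               x_mm = positions[, 1], y_mm = positions[, 2],
               z_mm = positions[, 3]),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Export the directed edge list
#'
#' CSV `source,target`, meaning source (presynaptic j) -> target
#' (postsynaptic i), i.e. `A_ij = 1`.
#'
#' @param graph a `striatum_graph`.
#' @param path output CSV path.
#' @export
write_edges <- function(graph, path) {
  write.csv(graph$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the graph as GraphML with a `kind` node attribute
#' @param graph a `striatum_graph`.
#' @param path output .graphml path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}
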