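# shared desk-scale fixtures, built once per test run

fx_two <- make_fixture("two_neuron", seed = 1)
fx_ring <- make_fixture("ring16", seed = 1)
fx_mini <- suppressWarnings(make_fixture("mini_striatum", seed = 3))

# a single isolated neuron of the given class, as a degenerate graph
single_neuron_graph <- function(kind = "MSN") {
  structure(list(
    positions = matrix(0, 1, 3, dimnames = list(NULL, c("x", "y", "z"))),
    kinds = kind,
    edges = data.frame(source = integer(0), target = integer(0)),
    n_total = 1L, n_msn = as.integer(kind == "MSN"),
    n_fs = as.integer(kind == "FS"), config = NULL
  ), class = "striatum_graph")
}

# hand-built graph from an explicit position matrix and edge list
graph_from_parts <- function(positions, kinds, edges) {
  structure(list(
    positions = positions, kinds = kinds, edges = edges,
    n_total = nrow(positions), n_msn = sum(kinds == "MSN"),
    n_fs = sum(kinds == "FS"), config = NULL
  ), class = "striatum_graph")
}
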