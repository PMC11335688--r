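test_that("positions are sampled inside the requested volume, deterministically", {
  cfg <- builder_config(n_total = 1, n_msn = 1, volume = c(1, 1, 1), seed = 4)
  p <- generate_positions(cfg)
  expect_lte(sqrt(sum(p^2)), 1)
  cfg2 <- builder_config(n_total = 50, n_msn = 47, volume = c(3, 2, 1),
                         seed = 9)
  expect_identical(generate_positions(cfg2), generate_positions(cfg2))
})

test_that("uniform sampling fills the ellipsoid evenly", {
  cfg <- builder_config(n_total = 10000, n_msn = 9500,
                        volume = c(25, 12, 10), seed = 12)
  p <- generate_positions(cfg)
  ax <- cfg$volume
  expect_true(all((p[, 1] / ax[1])^2 + (p[, 2] / ax[2])^2 +
                    (p[, 3] / ax[3])^2 <= 1))
  # each coordinate half-volume holds about half the points
  for (j in 1:3) expect_lt(abs(mean(p[, j] > 0) - 0.5), 0.02)
})

test_that("class labels split exactly into the configured MSN/FS counts", {
  k <- assign_kinds(builder_config(seed = 1))
  expect_equal(sum(k == "MSN"), 1856)
  expect_equal(sum(k == "FS"), 139)          # 1995 - 1856
  k2 <- assign_kinds(builder_config(n_total = 100, n_msn = 95, seed = 1))
  expect_equal(sum(k2 == "FS"), 5)           # the nominal 95%/5% split
  k3 <- assign_kinds(builder_config(n_total = 4, n_msn = 4, k_fs = 0,
                                    seed = 1))
  expect_true(all(k3 == "MSN"))
  expect_error(builder_config(n_total = 4, n_msn = 5), "n_msn")
})

test_that("local wiring connects each source to its k nearest in-range neighbours", {
  pos <- cbind(x = c(0, 1, 2), y = 0, z = 0)
  cfg <- builder_config(n_total = 3, n_msn = 3, k_msn = 2, k_fs = 0,
                        neighbourhood = 5, p_rewire = 0, seed = 1)
  g <- build_graph(pos, rep("MSN", 3), cfg)
  expect_equal(out_degrees(g), c(2, 2, 2))
  expect_false(any(g$edges$source == g$edges$target))
  # spacing beyond the neighbourhood: empty graph with a warning
  pos10 <- cbind(x = c(0, 10, 20), y = 0, z = 0)
  expect_warning(g0 <- build_graph(pos10, rep("MSN", 3), cfg),
                 "fewer than k")
  expect_equal(nrow(g0$edges), 0)
})

test_that("nearest-neighbour ties break toward the lower neuron index", {
  # targets 2 and 3 are both exactly 1 mm from source 1
  pos <- cbind(x = c(0, 1, -1, 3), y = 0, z = 0)
  cfg <- builder_config(n_total = 4, n_msn = 4, k_msn = 1, k_fs = 0,
                        p_rewire = 0, seed = 1)
  g <- build_graph(pos, rep("MSN", 4), cfg)
  expect_equal(g$edges$target[g$edges$source == 1], 2)
})

test_that("the full-scale defaults reproduce the prescribed out-degrees", {
  g <- build_network(builder_config(p_rewire = 0, seed = 7))
  od <- out_degrees(g)
  expect_equal(mean(od[g$kinds == "MSN"]), 20)
  expect_equal(mean(od[g$kinds == "FS"]), 100)
  # degree contract is exact in a dense-enough volume
  expect_true(all(od[g$kinds == "MSN"] == 20))
  expect_true(all(od[g$kinds == "FS"] == 100))
  # every local edge respects the 5 mm diameter neighbourhood
  d <- sqrt(rowSums((g$positions[g$edges$source, ] -
                       g$positions[g$edges$target, ])^2))
  expect_true(all(d <= 2.5))
})

test_that("rewiring adds remote edges without removing local ones", {
  base <- builder_config(n_total = 200, n_msn = 186, k_msn = 8, k_fs = 40,
                         volume = c(4, 3, 2.5), seed = 11, p_rewire = 0)
  g0 <- suppressWarnings(build_network(base))
  counts <- sapply(c(0.05, 0.2, 0.5), function(p) {
    cfg <- base; cfg$p_rewire <- p
    suppressWarnings(nrow(build_network(cfg)$edges))
  })
  expect_true(all(diff(c(nrow(g0$edges), counts)) >= 0))
  # local edges are kept: the p = 0 edge set is a subset of the p > 0 set
  cfg <- base; cfg$p_rewire <- 0.2
  g1 <- suppressWarnings(build_network(cfg))
  key <- function(g) paste(g$edges$source, g$edges$target)
  expect_true(all(key(g0) %in% key(g1)))
  # added edges are remote (outside the local neighbourhood)
  extra <- g1$edges[!(key(g1) %in% key(g0)), ]
  d <- sqrt(rowSums((g1$positions[extra$source, , drop = FALSE] -
                       g1$positions[extra$target, , drop = FALSE])^2))
  expect_true(all(d > 2.5))
})

test_that("identical configuration and seed give identical graphs", {
  cfg <- builder_config(n_total = 150, n_msn = 140, k_msn = 6, k_fs = 12,
                        volume = c(4, 3, 2.5), seed = 21)
  g1 <- build_network(cfg)
  g2 <- build_network(cfg)
  expect_identical(g1$positions, g2$positions)
  expect_identical(g1$kinds, g2$kinds)
  expect_identical(g1$edges, g2$edges)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_edges(g1, f1); write_edges(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("graph summaries report clustering and path length", {
  # complete graph on 4 nodes: clustering 1
  e <- expand.grid(source = 1:4, target = 1:4)
  e <- e[e$source != e$target, ]
  gc <- graph_from_parts(cbind(x = 1:4, y = 0, z = 0), rep("MSN", 4), e)
  expect_equal(graph_summary(gc)$mean_clustering, 1)
  # ring: clustering 0
  expect_equal(graph_summary(fx_ring$graph)$mean_clustering, 0)
  expect_error(graph_summary(graph_from_parts(
    matrix(numeric(0), 0, 3), character(0),
    data.frame(source = integer(0), target = integer(0)))), "empty")
})

test_that("small-world shortcuts shorten the mean path length", {
  base <- builder_config(n_total = 200, n_msn = 186, k_msn = 8, k_fs = 40,
                         volume = c(4, 3, 2.5), seed = 31, p_rewire = 0)
  withp <- base; withp$p_rewire <- 0.2
  s0 <- graph_summary(suppressWarnings(build_network(base)))
  s1 <- graph_summary(suppressWarnings(build_network(withp)))
  expect_lt(s1$mean_path_length, s0$mean_path_length)
})

test_that("GraphML export carries the neuron class as a node attribute", {
  f <- tempfile(fileext = ".graphml")
  write_graphml(fx_ring$graph, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), 16)
  expect_equal(igraph::gsize(g), 32)
  expect_equal(sum(igraph::vertex_attr(g, "kind") == "FS"), 1)
})

test_that("state checkpoints round-trip through CSV", {
  st <- initial_state(fx_ring$graph, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_state(st, f)
  expect_equal(read_state(f), st, tolerance = 1e-12, ignore_attr = TRUE)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_state(bad), "checkpoint")
})

test_that("position tables round-trip through CSV and reject malformed files", {
  pos <- fx_mini$graph$positions
  f <- tempfile(fileext = ".csv")
  write_positions(pos, f)
  back <- read_positions(f, n_expected = nrow(pos))
  expect_equal(back, pos, ignore_attr = TRUE, tolerance = 1e-12)
  # imported positions drive the builder verbatim
  cfg <- builder_config(n_total = nrow(pos), n_msn = 186, k_msn = 4,
                        k_fs = 8, volume = f, seed = 2)
  expect_equal(generate_positions(cfg), back)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3"), bad)
  expect_error(read_positions(bad), "id,x_mm,y_mm,z_mm")
  bad2 <- tempfile(fileext = ".csv")
  writeLines(c("id,x_mm,y_mm,z_mm", "1,0.1,0.2,0.3", "2,oops,0,0"), bad2)
  expect_error(read_positions(bad2), "row 2")
})
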