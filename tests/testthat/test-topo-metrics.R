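test_that("betti deviation follows its normalized formula", {
  tri <- toy_triangle_graph()
  expect_equal(betti_deviation(tri, tri), 0)
  # reference with (b0, b1) = (1, 2) against (2, 1): (1+1)/3
  ref <- vascular_graph(
    nodes = data.frame(id = 1:4, x_mm = 0:3, y_mm = 0, kind = "junction"),
    edges = data.frame(from = c(1, 2, 3, 1, 2), to = c(2, 3, 1, 3, 4),
                       length_mm = 1, diameter_mm = 1, confidence = 0.9,
                       conductance = 1))
  stopifnot(identical(unname(betti_numbers(ref)), c(1L, 2L)))
  rec <- vascular_graph(
    nodes = data.frame(id = 1:5, x_mm = 0:4, y_mm = 0, kind = "junction"),
    edges = data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 1, 5),
                       length_mm = 1, diameter_mm = 1, confidence = 0.9,
                       conductance = 1))
  stopifnot(identical(unname(betti_numbers(rec)), c(2L, 1L)))
  expect_equal(betti_deviation(rec, ref), 2 / 3, tolerance = 1e-12)
  # empty reconstruction against (1, 0)
  empty <- vascular_graph(
    nodes = data.frame(id = integer(), x_mm = numeric(), y_mm = numeric(),
                       kind = character()),
    edges = data.frame(from = integer(), to = integer(), length_mm = numeric(),
                       diameter_mm = numeric(), confidence = numeric(),
                       conductance = numeric()))
  expect_equal(betti_deviation(empty, toy_edge_graph()), 1)
})

test_that("branch completeness counts recovered reference edges", {
  ph <- small_phantom(seed = 3)
  g <- extract_graph(ph$image, 0.12, min_length_mm = 2.5)
  expect_equal(branch_completeness(ph$graph, ph$graph), 1)
  empty <- vascular_graph(
    nodes = data.frame(id = integer(), x_mm = numeric(), y_mm = numeric(),
                       kind = character()),
    edges = data.frame(from = integer(), to = integer(), length_mm = numeric(),
                       diameter_mm = numeric(), confidence = numeric(),
                       conductance = numeric()))
  expect_equal(branch_completeness(empty, ph$graph), 0)
  expect_error(branch_completeness(g, empty), "no edges")
  # drop one of four far-apart edges -> 0.75
  segs <- list(cbind(c(0, 10), c(0, 0)), cbind(c(0, 10), c(20, 20)),
               cbind(c(20, 30), c(0, 0)), cbind(c(20, 30), c(20, 20)))
  ref4 <- vascular_graph(
    nodes = data.frame(id = 1:8, x_mm = 0, y_mm = 0, kind = "terminal"),
    edges = data.frame(from = c(1, 3, 5, 7), to = c(2, 4, 6, 8),
                       length_mm = 10, diameter_mm = 1, confidence = 1,
                       conductance = 1),
    polylines = segs)
  g3 <- vascular_graph(ref4$nodes[1:6, ], ref4$edges[1:3, ], segs[1:3])
  expect_equal(branch_completeness(g3, ref4), 0.75)
  bc <- branch_completeness(g, ph$graph)
  expect_gte(bc, 0); expect_lte(bc, 1)
})

test_that("topology uncertainty averages diagram distances", {
  tri <- toy_triangle_graph()
  ref <- superlevel_persistence(tri)
  expect_equal(topology_uncertainty(list(ref, ref), ref), 0)
  # two realizations at hand-computable distances from the reference
  g1 <- toy_triangle_graph(c(0.9, 0.8, 0.7))   # cycle birth moves 0.5 -> 0.7
  g2 <- toy_triangle_graph(c(0.9, 0.8, 0.1))   # cycle birth moves 0.5 -> 0.1
  p1 <- superlevel_persistence(g1); p2 <- superlevel_persistence(g2)
  d1 <- angiotopo:::diagram_pair_distance(p1, ref)
  d2 <- angiotopo:::diagram_pair_distance(p2, ref)
  expect_equal(d1, 0.2); expect_equal(d2, 0.4)
  expect_equal(topology_uncertainty(list(p1, p2), ref), 0.3)
})

test_that("persistence stability is the clamped complement of uncertainty", {
  tri <- toy_triangle_graph()
  ref <- superlevel_persistence(tri)
  expect_equal(persistence_stability(list(ref, ref), ref), 1)
  expect_equal(persistence_stability(U = 0.05, normalizer = 0.5), 0.9)
  expect_equal(persistence_stability(U = 0.5, normalizer = 0.5), 0)
  expect_equal(persistence_stability(U = 2, normalizer = 0.5), 0)
})

test_that("macro uncertainty is the fixed weighted combination", {
  expect_equal(macro_uncertainty(0, 1, 0), 0)
  expect_equal(macro_uncertainty(0.1, 0.8, 0.04), 0.116, tolerance = 1e-12)
  # strictly increasing as branch completeness degrades
  u1 <- macro_uncertainty(0.1, 0.9, 0.04)
  u2 <- macro_uncertainty(0.1, 0.7, 0.04)
  expect_gt(u2, u1)
  expect_error(macro_uncertainty(-0.1, 0.5, 0), "non-negative")
  expect_error(macro_uncertainty(0.1, 1.5, 0), "BC")
})
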