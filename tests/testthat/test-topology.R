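# constructed tube images for graph-extraction checks
draw_tube <- function(grid = 64, vox = 0.5, segments, diameter = 1.5,
                      contrast = 4) {
  g <- vascular_graph(
    nodes = data.frame(id = seq_len(2 * length(segments)),
                       x_mm = 0, y_mm = 0, kind = "terminal"),
    edges = data.frame(from = seq_along(segments) * 2 - 1,
                       to = seq_along(segments) * 2,
                       length_mm = 1, diameter_mm = diameter,
                       confidence = 1, conductance = 1),
    polylines = segments)
  angiotopo:::rasterize_graph(g, c(grid, grid), vox, contrast)
}

test_that("vesselness highlights tubes and vanishes on constant images", {
  flat <- image_volume(matrix(2, 64, 64), 0.5)
  expect_true(all(vesselness(flat)$values == 0))

  tube <- draw_tube(segments = list(cbind(seq(4, 28, 0.25), 16)))
  v <- vesselness(tube)
  center_vals <- v$values[cbind(round(seq(10, 54, 2)), 33)]
  expect_gt(min(center_vals), 5 * max(median(v$values), 1e-6))
})

test_that("vesselness scale selection tracks the tube radius", {
  # radius 1.25 mm tube; the argmax scale should lie within one scale step
  tube <- draw_tube(grid = 96, segments = list(cbind(seq(6, 42, 0.25), 24)),
                    diameter = 2.5)
  scales <- seq(0.5, 3, by = 0.5)
  v <- vesselness(tube, scales_mm = scales, return_scales = TRUE)
  sc <- attr(v, "scale_mm")
  on_axis <- v$values[cbind(round(seq(20, 76, 4)), 49)] > 0.5
  picked <- median(sc[cbind(round(seq(20, 76, 4)), 49)][on_axis])
  expect_lte(abs(picked - 1.25), 0.5 + 1e-9)
})

test_that("graph extraction recovers canonical shapes", {
  # straight segment: two terminals, one edge
  tube <- draw_tube(segments = list(cbind(seq(6, 26, 0.25), 16)))
  g1 <- extract_graph(tube, 0.2, min_length_mm = 2.5)
  expect_identical(nrow(g1$edges), 1L)
  expect_identical(sum(g1$nodes$kind == "terminal"), 2L)

  # Y junction: one bifurcation, three terminals, three edges
  yimg <- draw_tube(segments = list(
    cbind(seq(4, 16, 0.25), 16),
    cbind(seq(16, 26, 0.25), 16 + (seq(16, 26, 0.25) - 16) * 0.7),
    cbind(seq(16, 26, 0.25), 16 - (seq(16, 26, 0.25) - 16) * 0.7)))
  gy <- extract_graph(yimg, 0.2, min_length_mm = 2.5)
  expect_identical(nrow(gy$edges), 3L)
  expect_identical(sum(gy$nodes$kind == "bifurcation"), 1L)
  expect_identical(sum(gy$nodes$kind == "terminal"), 3L)

  # ring: cycle rank 1
  th <- seq(0, 2 * pi, length.out = 200)
  ring <- draw_tube(segments = list(cbind(16 + 8 * cos(th), 16 + 8 * sin(th))))
  gr <- extract_graph(ring, 0.2, min_length_mm = 2.5)
  b <- betti_numbers(gr)
  expect_identical(unname(b[2]), 1L)

  # empty segmentation is an empty graph, not an error
  ge <- extract_graph(image_volume(matrix(1, 48, 48), 0.5), 0.5)
  expect_identical(nrow(ge$edges), 0L)
})

test_that("pruning removes short spurs but never cycle edges", {
  trunk <- cbind(seq(4, 28, 0.25), 16)
  spur_short <- cbind(16, seq(16, 17.5, 0.25))       # 1.5 mm spur
  img <- draw_tube(segments = list(trunk, spur_short))
  g <- extract_graph(img, 0.2, min_length_mm = 0)
  gp <- prune_graph(g, 2.5)
  expect_identical(nrow(gp$edges), 1L)

  spur_long <- cbind(16, seq(16, 20.5, 0.25))        # 4.5 mm spur
  img2 <- draw_tube(segments = list(trunk, spur_long))
  g2 <- prune_graph(extract_graph(img2, 0.2, min_length_mm = 0), 2.5)
  expect_gte(nrow(g2$edges), 3L)  # trunk split at the junction + spur

  # idempotence
  expect_identical(prune_graph(gp, 2.5), gp)

  # ring edges survive pruning even when short
  th <- seq(0, 2 * pi, length.out = 100)
  ring <- toy_triangle_graph()
  expect_identical(prune_graph(ring, 10), ring)
})

test_that("threshold sensitivity reports one row per threshold", {
  ph <- small_phantom(seed = 3)
  ths <- c(0.1, 0.15, 0.2)
  tab <- threshold_sensitivity(ph$image, ths,
                               topology_config(vesselness_threshold = 0.12))
  expect_identical(nrow(tab), 3L)
  # brute-force recount of beta0 at each threshold
  vm <- vesselness(ph$image)
  for (k in seq_along(ths)) {
    g <- extract_graph(ph$image, ths[k], vessel_map = vm, min_length_mm = 2.5)
    expect_identical(tab$beta0[k], unname(betti_numbers(g)[1]))
  }
  # identical thresholds give identical rows
  tab2 <- threshold_sensitivity(ph$image, c(0.15, 0.15))
  expect_identical(tab2$beta0[1], tab2$beta0[2])
  expect_identical(tab2$total_persistence[1], tab2$total_persistence[2])
})
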