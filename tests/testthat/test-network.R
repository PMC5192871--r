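test_that("dissolving toy mosaics matches brute-force arrangement enumeration", {
  # one isolated square: no junctions, a single closed ring of length 4
  n1 <- polygons_to_network(list(unit_square(0, 0)))
  expect_equal(nrow(n1), 1)
  expect_equal(network_length(n1), 4)
  m <- n1$geometry[[1]]
  expect_equal(m[1, ], m[nrow(m), ])
  expect_equal(length(unique(oracle_arrangement_edges(list(unit_square(0, 0))))), 4)

  # two squares sharing an edge: 7 distinct edges, the shared one exactly once
  polys2 <- list(unit_square(0, 0), unit_square(1, 0))
  n2 <- polygons_to_network(polys2)
  edges2 <- network_edges(n2)
  expect_equal(sort(unique(edges2$edge_key)), sort(oracle_arrangement_edges(polys2)))
  expect_equal(length(unique(edges2$edge_key)), 7)
  expect_equal(max(table(edges2$edge_key)), 1)
  expect_equal(network_length(n2), 7)
  # junction-to-junction chaining: shared edge + two 3-edge arcs
  expect_equal(nrow(n2), 3)
  expect_equal(sort(n2$length), c(1, 3, 3))

  # 2x2 mosaic: 12 unit edges in the dissolved arrangement
  polys4 <- list(unit_square(0, 0), unit_square(1, 0),
                 unit_square(0, 1), unit_square(1, 1))
  n4 <- polygons_to_network(polys4)
  edges4 <- network_edges(n4)
  expect_equal(sort(unique(edges4$edge_key)), sort(oracle_arrangement_edges(polys4)))
  expect_equal(length(unique(edges4$edge_key)), 12)
  expect_equal(network_length(n4), 12)
  expect_true(is_noded(n4))
})

test_that("dissolved networks are noded and ids deterministic", {
  polys <- list(unit_square(0, 0), unit_square(1, 0), unit_square(0, 1))
  a <- polygons_to_network(polys)
  b <- polygons_to_network(rev(polys))  # input order must not matter
  expect_true(is_noded(a))
  expect_equal(a$segment_id, b$segment_id)
  expect_equal(network_length(a), network_length(b))
})

test_that("self-intersecting polygons are rejected with their index", {
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygons_to_network(list(unit_square(0, 0), bowtie)), "polygon 2")
})

test_that("generalization simplifies by perpendicular distance and preserves endpoints", {
  # tolerance 0 leaves the network unchanged
  net <- wlf_network(list(rbind(c(0, 0), c(1, 0.4), c(2, 0))))
  expect_equal(generalize_network(net, 0), net)

  # collinear interior vertex always dropped, length preserved
  col3 <- wlf_network(list(rbind(c(0, 0), c(1, 0), c(2, 0))))
  g <- generalize_network(col3, 0.01)
  expect_equal(nrow(g$geometry[[1]]), 2)
  expect_equal(g$length, col3$length)

  # right-angle detour of depth 1: the deepest vertices sit 1 m off the
  # chord, so tolerance above the depth collapses it to the chord
  detour <- wlf_network(list(rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1), c(2, 0), c(3, 0))))
  flat <- generalize_network(detour, 1.01)
  expect_equal(flat$geometry[[1]], rbind(c(0, 0), c(3, 0)),
               ignore_attr = TRUE)
  kept <- generalize_network(detour, 0.5)
  expect_gt(nrow(kept$geometry[[1]]), 2)

  # simplification never lengthens a segment
  set.seed(1)
  wig <- wlf_network(list(cbind(0:20, rnorm(21))))
  for (tol in c(0.1, 0.5, 2)) {
    expect_lte(network_length(generalize_network(wig, tol)), network_length(wig))
  }
  expect_error(generalize_network(net, -1), "tolerance")
})

test_that("splitting cuts crossings and T-junctions and conserves length", {
  # X crossing
  x <- wlf_network(list(rbind(c(0, 0.5), c(1, 0.5)), rbind(c(0.5, 0), c(0.5, 1))))
  xs <- split_segments(x)
  expect_equal(nrow(xs), 4)
  expect_true(is_noded(xs))
  expect_equal(network_length(xs), network_length(x), tolerance = 1e-6)
  # all four pieces meet at the crossing
  ends <- unlist(lapply(xs$geometry, function(m) {
    apply(m[c(1, nrow(m)), ], 1, paste, collapse = ",")
  }))
  expect_equal(sum(ends == "0.5,0.5"), 4)

  # T-junction: one segment ends on another's interior
  tj <- wlf_network(list(rbind(c(0, 0), c(2, 0)), rbind(c(1, 0), c(1, 1))))
  tjs <- split_segments(tj)
  expect_equal(nrow(tjs), 3)
  expect_true(is_noded(tjs))
  expect_equal(network_length(tjs), 3, tolerance = 1e-6)

  # already-noded network is unchanged apart from ids
  noded <- polygons_to_network(list(unit_square(0, 0), unit_square(1, 0)))
  again <- split_segments(noded)
  expect_equal(nrow(again), nrow(noded))
  expect_equal(network_length(again), network_length(noded), tolerance = 1e-6)
})

test_that("length is conserved by splitting on random crossing ensembles", {
  set.seed(7)
  for (rep in 1:5) {
    geoms <- lapply(1:8, function(i) {
      a <- runif(2, 0, 10); b <- runif(2, 0, 10)
      rbind(a, b)
    })
    net <- wlf_network(geoms)
    sp <- split_segments(net)
    expect_equal(network_length(sp), network_length(net), tolerance = 1e-6)
    expect_true(is_noded(sp))
  }
})

test_that("networks round-trip through GeoJSON with attributes", {
  net <- wlf_network(
    list(rbind(c(0, 0), c(100, 0)), rbind(c(0, 50), c(60, 80), c(120, 50))),
    label = c("woody", "other"), min_h = c(0.2, NA), max_h = c(4.1, NA),
    mean_h = c(2.2, NA), square_id = c("sq_000_000", NA),
    crs_note = "test planar"
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  write_network_geojson(net, path)
  back <- read_network_geojson(path)
  expect_equal(back$geometry, net$geometry)
  expect_equal(back$label, net$label)
  expect_equal(back$min_h, net$min_h)
  expect_equal(back$square_id, net$square_id)
  expect_equal(attr(back, "crs_note"), "test planar")

  polys <- list(unit_square(0, 0), unit_square(1, 0))
  ppath <- withr::local_tempfile(fileext = ".geojson")
  write_polygons_geojson(polys, ppath)
  back_p <- read_polygons_geojson(ppath)
  expect_equal(lapply(back_p, function(m) m[1:4, ]), polys, ignore_attr = TRUE)
})
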