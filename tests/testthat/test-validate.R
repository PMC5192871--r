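test_that("woody features dominate when collapsing multi-feature boundaries", {
  expect_equal(dominant_label(c("fence", "hedge")), "woody")
  expect_equal(dominant_label(c("wall", "fence")), "other")
  expect_equal(dominant_label("hedge"), "woody")
  expect_equal(dominant_label("line_of_trees"), "woody")
  expect_error(dominant_label(character(0)), "empty")
})

test_that("the agreement region is the intersection of the two 5-m buffers", {
  line <- function(y) wlf_network(list(rbind(c(0, y), c(100, y))))
  # identical networks: region is one network's buffer
  same <- agreement_region(line(0), line(0), radius = 5)
  expect_true(all(region_contains(same, c(0, 50, 100), c(4.9, -4.9, 0))))
  expect_false(any(region_contains(same, c(50, -6), c(5.1, 0))))
  # parallel lines 20 m apart: disjoint buffers, empty region
  far <- agreement_region(line(0), line(20), radius = 5)
  expect_false(any(region_contains(far, seq(0, 100, 10), rep(10, 11))))
  expect_equal(region_area(far, resolution = 1), 0)
  # 6 m apart: a lens; area matches the independent raster oracle within 1%
  near_a <- line(0); near_b <- line(6)
  lens <- agreement_region(near_a, near_b, radius = 5)
  got <- region_area(lens, resolution = 0.1)
  want <- oracle_buffer_intersection_area(near_a, near_b, 5, res = 0.1)
  expect_lt(abs(got - want) / want, 0.01)
  expect_gt(got, 0)
  expect_error(agreement_region(line(0), line(0), radius = 0), "radius")
})

test_that("point sampling places points at interval multiples inside the region", {
  seg20 <- wlf_network(list(rbind(c(10, 0), c(30, 0))), label = "woody")
  pts <- sample_labeled_points(seg20, region = NULL, interval = 5)
  expect_equal(nrow(pts), 5)                       # arcs 0,5,10,15,20
  expect_equal(pts$x, c(10, 15, 20, 25, 30))
  expect_equal(unique(pts$label), "woody")

  other <- wlf_network(list(rbind(c(10, 3), c(30, 3))))
  region <- agreement_region(seg20, other, radius = 5)
  inside <- sample_labeled_points(seg20, region, interval = 5)
  expect_equal(nrow(inside), 5)

  # segment fully outside the region yields no points
  faraway <- wlf_network(list(rbind(c(0, 100), c(20, 100))), label = "other")
  expect_equal(nrow(sample_labeled_points(faraway, region, interval = 5)), 0)

  # partial overlap: retained points equal the brute-force point-in-region test
  half <- wlf_network(list(rbind(c(-40, 0), c(30, 0))), label = "woody")
  kept <- sample_labeled_points(half, region, interval = 5)
  all_pts <- sample_labeled_points(half, NULL, interval = 5)
  manual <- region_contains(region, all_pts$x, all_pts$y)
  expect_equal(kept$x, all_pts$x[manual])
})

test_that("nearest-neighbour matching equals the quadratic oracle", {
  set.seed(13)
  for (k in 1:5) {
    n_m <- sample(20:200, 1); n_t <- sample(20:200, 1)
    model_pts <- tibble::tibble(x = runif(n_m, 0, 100), y = runif(n_m, 0, 100),
                                label = sample(c("woody", "other"), n_m, TRUE))
    truth_pts <- tibble::tibble(x = runif(n_t, 0, 100), y = runif(n_t, 0, 100),
                                label = sample(c("woody", "other"), n_t, TRUE))
    got <- match_points(model_pts, truth_pts, max_dist = 10)
    want <- oracle_match_points(model_pts, truth_pts, 10)
    expect_equal(unclass(got), unclass(want))
  }
})

test_that("identical point sets give a diagonal matrix; distant points drop out", {
  pts <- tibble::tibble(x = c(0, 10, 20), y = c(0, 0, 0),
                        label = c("woody", "other", "woody"))
  cm <- match_points(pts, pts, max_dist = 5)
  expect_equal(cm$n_ww, 2); expect_equal(cm$n_oo, 1)
  expect_equal(cm$n_wo + cm$n_ow, 0)
  lone <- tibble::tibble(x = 500, y = 500, label = "woody")
  cm2 <- match_points(pts, dplyr::bind_rows(pts, lone), max_dist = 5)
  expect_equal(cm2$n_ww + cm2$n_wo + cm2$n_ow + cm2$n_oo, 3)
})

test_that("percent agreement reproduces the published national point-match table", {
  cm <- gb_validation_counts()
  expect_equal(percent_agreement(cm, "woody", rounded = TRUE), 58)
  expect_equal(percent_agreement(cm, "other", rounded = TRUE), 66)
  zero_row <- confusion_matrix(0, 5, 2, 3)
  expect_equal(percent_agreement(zero_row, "woody"), 0)
  expect_error(percent_agreement(confusion_matrix(0, 0, 1, 1), "woody"), "zero")
})

test_that("kappa matches direct hand computation and its invariances", {
  # perfect agreement
  expect_equal(cohen_kappa(confusion_matrix(10, 0, 0, 7)), 1)
  # independence: counts proportional to marginal products
  expect_equal(cohen_kappa(confusion_matrix(10, 10, 10, 10)), 0)
  # published counts against the arithmetic oracle
  cm <- gb_validation_counts()
  expect_equal(cohen_kappa(cm),
               oracle_kappa(109854, 80623, 146737, 288115), tolerance = 1e-12)
  expect_equal(kappa_band(cohen_kappa(cm)), "fair")
  # symmetric under simultaneous swap of both class labels
  swapped <- confusion_matrix(cm$n_oo, cm$n_ow, cm$n_wo, cm$n_ww)
  expect_equal(cohen_kappa(swapped), cohen_kappa(cm), tolerance = 1e-12)
  # kappa = 1 iff off-diagonals are zero (both classes present)
  set.seed(3)
  for (k in 1:20) {
    n <- sample(0:30, 4, TRUE)
    if (sum(n) == 0) next
    cmk <- confusion_matrix(n[1] + 1, n[2], n[3], n[4] + 1)
    if (n[2] == 0 && n[3] == 0) expect_equal(cohen_kappa(cmk), 1)
    else expect_lt(cohen_kappa(cmk), 1)
  }
  # degenerate single-class matrices
  expect_equal(cohen_kappa(confusion_matrix(9, 0, 0, 0)), 1)
  expect_equal(cohen_kappa(confusion_matrix(9, 1, 0, 0)), 0)
  expect_error(cohen_kappa(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("density raster conserves clipped woody length", {
  net <- wlf_network(
    list(rbind(c(100, 500), c(1100, 500)),    # 1000 m over two cells
         rbind(c(1500, 1200), c(1500, 1500)), # 300 m in one cell
         rbind(c(200, 200), c(900, 200))),
    label = c("woody", "woody", "other")
  )
  d <- density_map(net, cell_size = 1000)
  expect_equal(d$values[2, 1], 900)   # m/km^2 in the south-west cell
  expect_equal(d$values[2, 2], 100)
  expect_equal(d$values[1, 2], 300)
  expect_equal(sum(d$values) * 1, woody_length(net), tolerance = 1e-6)
  empty <- density_map(wlf_network(list(rbind(c(0, 0), c(10, 0))),
                                   label = "other"),
                       cell_size = 1000, n_cols = 2, n_rows = 2)
  expect_true(all(empty$values == 0))
  # diagonal across two cells splits per geometric clipping
  diag_net <- wlf_network(list(rbind(c(500, 500), c(1500, 1500))),
                          label = "woody")
  dd <- density_map(diag_net, cell_size = 1000, n_cols = 2, n_rows = 2)
  expect_equal(dd$values[2, 1], sqrt(2) * 500, tolerance = 1e-6)
  expect_equal(dd$values[1, 2], sqrt(2) * 500, tolerance = 1e-6)
})

test_that("stratum density means average cells by land class", {
  net <- wlf_network(list(rbind(c(100, 500), c(600, 500))), label = "woody")
  d <- density_map(net, cell_size = 1000, n_cols = 2, n_rows = 1)
  cs <- tibble::tibble(square_id = c("sq_000_000", "sq_001_000"),
                       stratum_id = c("a", "a"))
  out <- stratum_density_means(d, cs)
  expect_equal(out$mean_density, 250)
})

test_that("end-to-end validation of a degraded truth still matches nearly all points", {
  ls <- generate_landscape(clean_params(extent_km = 2, seed = 23))
  chm <- apply_mask(canopy_height(ls$dsm, ls$dtm), ls$landcover, ls$dtm)
  cl <- classify_network(ls$truth, chm)
  deg <- degrade_truth(ls$truth, drop_prob = 0, jitter_sd = 1, seed = 4)
  v <- validate_networks(cl, deg, radius = 5, interval = 5)
  expect_gt(v$n_matched / v$n_truth_pts, 0.95)
  g <- glance(v)
  expect_gt(g$kappa, 0.9)
  expect_gt(g$pct_agreement_woody, 95)
})
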