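test_that("per-square woody totals add up and clip across square borders", {
  net <- wlf_network(
    list(rbind(c(100, 100), c(200, 100)),     # 100 m inside sq_000_000
         rbind(c(300, 200), c(300, 450)),     # 250 m inside sq_000_000
         rbind(c(850, 500), c(1150, 500)),    # 300 m straddling the border
         rbind(c(500, 600), c(500, 700))),    # non-woody
    label = c("woody", "woody", "woody", "other")
  )
  clipped <- clip_to_squares(net)
  expect_equal(network_length(clipped), network_length(net), tolerance = 1e-9)
  # geometric clipping oracle: 150 m falls in each square
  expect_equal(square_woody_length(clipped, "sq_000_000"), 100 + 250 + 150)
  expect_equal(square_woody_length(clipped, "sq_001_000"), 150)
  expect_error(square_woody_length(clipped, "sq_009_009"), "unknown")
  sl <- square_lengths(clipped)
  expect_equal(sum(sl$woody_m), 650)
})

test_that("squares with no woody segments total zero", {
  net <- wlf_network(list(rbind(c(10, 10), c(20, 10))), label = "other")
  clipped <- clip_to_squares(net)
  expect_equal(square_woody_length(clipped, "sq_000_000"), 0)
})

test_that("stratified expansion reproduces hand arithmetic", {
  strata <- stratum_table("lc1", 10, list(c("a", "b")))
  est <- stratified_total(c(a = 1000, b = 3000), strata)
  expect_equal(as.numeric(est), 20)  # 10 squares x 2 km mean
  expect_equal(as.numeric(stratified_total(c(a = 0, b = 0), strata)), 0)
  # unweighted variant just sums the sample
  expect_equal(as.numeric(stratified_total(c(a = 1000, b = 3000), strata,
                                           weighted = FALSE)), 4)
  # linearity and stratum-order invariance
  s2 <- stratum_table(c("u", "v"), c(4, 6), list(c("a"), c("b", "c")))
  s2r <- s2[2:1, ]
  class(s2r) <- class(s2)
  lens <- c(a = 500, b = 1500, c = 2500)
  expect_equal(as.numeric(stratified_total(lens, s2)),
               as.numeric(stratified_total(lens, s2r)))
  expect_equal(as.numeric(stratified_total(lens * 3, s2)),
               3 * as.numeric(stratified_total(lens, s2)))
  expect_error(stratified_total(c(a = 1), strata), "absent")
})

test_that("census sampling recovers the true total exactly", {
  ls <- generate_landscape(clean_params(extent_km = 2, seed = 11))
  chm <- apply_mask(canopy_height(ls$dsm, ls$dtm), ls$landcover, ls$dtm)
  cl <- classify_network(ls$truth, chm)
  clipped <- clip_to_squares(cl)
  est <- stratified_total(square_lengths(clipped), ls$strata)
  expect_equal(as.numeric(est), woody_length(ls$truth) / 1000, tolerance = 1e-9)
})

test_that("stratified estimator is unbiased over repeated random samples", {
  ls <- generate_landscape(clean_params(extent_km = 4, seed = 19))
  chm <- apply_mask(canopy_height(ls$dsm, ls$dtm), ls$landcover, ls$dtm)
  cl <- classify_network(ls$truth, chm)
  sl <- square_lengths(clip_to_squares(cl))
  truth_km <- woody_length(cl) / 1000
  set.seed(99)
  n_rep <- 200
  ests <- replicate(n_rep, {
    strata <- ls$strata
    strata$sampled_square_ids <- lapply(strata$sampled_square_ids, function(ids) {
      sample(ids, max(2, floor(length(ids) / 2)))
    })
    as.numeric(stratified_total(sl, strata))
  })
  se <- sd(ests) / sqrt(n_rep)
  expect_lt(abs(mean(ests) - truth_km), 2 * se + 1e-12)
})

test_that("calibration returns the start when the target is already met", {
  cases <- data.frame(min = c(0, 0, 0), mean = c(2, 3, 0.1), max = c(4, 5, 1))
  net <- attributed_net(cases)
  net$square_id <- "sq_000_000"
  strata <- stratum_table("s1", 1, list("sq_000_000"))
  start <- threshold_set()
  labels <- classify_labels(net$min_h, net$max_h, net$mean_h, start)
  target <- sum(net$length[labels == "woody"]) / 1000  # segments 1-2 woody
  expect_equal(target, 0.2)
  res <- calibrate_thresholds(net, strata, target_km = target, start = start)
  expect_equal(res$thresholds$mean_h_floor, start$mean_h_floor)
  expect_equal(res$objective_km, 0)
})

test_that("calibration never worsens the objective and respects ranges", {
  cases <- data.frame(min = rep(0, 6), mean = seq(0.5, 3, by = 0.5),
                      max = rep(4, 6))
  net <- attributed_net(cases)
  net$square_id <- "sq_000_000"
  strata <- stratum_table("s1", 1, list("sq_000_000"))
  start <- threshold_set()
  start_est <- {
    labels <- classify_labels(net$min_h, net$max_h, net$mean_h, start)
    sum(net$length[labels == "woody"]) / 1000
  }
  res <- calibrate_thresholds(net, strata, target_km = 0.2, start = start)
  expect_lte(res$objective_km, abs(start_est - 0.2))
  expect_error(
    calibrate_thresholds(net, strata, 1, start = threshold_set(mean_h_floor = 9),
                         ranges = list(min_h_floor = c(-2, 2),
                                       mean_h_floor = c(0, 5),
                                       max_h_ceiling = c(10, 100))),
    "outside"
  )
})

test_that("an infeasible target drives the search to a range boundary", {
  cases <- data.frame(min = rep(0, 4), mean = c(1, 2, 3, 4), max = rep(5, 4))
  net <- attributed_net(cases)
  net$square_id <- "sq_000_000"
  strata <- stratum_table("s1", 1, list("sq_000_000"))
  # target far above the total network length: lowering the mean floor to its
  # range bottom captures everything, objective stays positive
  res <- calibrate_thresholds(
    net, strata, target_km = 100,
    start = threshold_set(mean_h_floor = 3.5),
    ranges = list(min_h_floor = c(-0.2, 0), mean_h_floor = c(0, 5),
                  max_h_ceiling = c(58, 60))
  )
  expect_equal(res$thresholds$mean_h_floor, 0)
  expect_gt(res$objective_km, 0)
  expect_equal(res$estimate_km, network_length(net) / 1000)
})

test_that("stratum tables round-trip through CSV", {
  strata <- stratum_table(c("lc1", "lc2"), c(12, 30),
                          list(c("sq_000_000", "sq_001_000"), "sq_002_000"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_strata_csv(strata, path)
  back <- read_strata_csv(path)
  expect_equal(back$stratum_id, strata$stratum_id)
  expect_equal(back$population_squares, strata$population_squares)
  expect_equal(back$sampled_square_ids, strata$sampled_square_ids)
  expect_error(stratum_table(c("a", "a"), c(1, 1), list("x", "y")), "unique")
  expect_error(stratum_table("a", 1, list(c("x", "y"))), ">=")
})
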