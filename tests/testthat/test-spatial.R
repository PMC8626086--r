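lattice_alternating <- function(n = 10) {
  as_spatial_point_set(data.frame(
    x_um = seq_len(n), y_um = 0,
    label = rep(c("A", "B"), length.out = n)))
}

test_that("neighborhood proportions follow hand-enumerable geometries", {
  # all one label: the proportion curve is identically 1
  mono <- as_spatial_point_set(data.frame(x_um = runif(30), y_um = runif(30),
                                          label = "A"))
  cv <- neighborhood_composition(mono, 1, 5)
  expect_true(all(cv$curve$mean == 1))

  # alternating collinear points: every nearest neighbor is the other label
  cv2 <- neighborhood_composition(lattice_alternating(10), 1, 1)
  same1 <- vapply(seq_len(10), function(i)
    cv2$raw[i, 1, cv2$center_label[i]], numeric(1))
  expect_true(all(same1 == 0))

  # proportions over all labels sum to one for every center and size
  sm <- simulate_spatial_map(sim_spatial_config(n_points = 120, seed = 7,
                                                labels = c("A", "B", "C")))
  cv3 <- neighborhood_composition(as_spatial_point_set(sm), 1, 15)
  sums <- apply(cv3$raw, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  expect_error(neighborhood_composition(lattice_alternating(10), 1, 40),
               "more than n_max")
})

test_that("random-labeling expectation is the count-based formula", {
  s <- as_spatial_point_set(data.frame(x_um = runif(100), y_um = runif(100),
                                       label = rep(c("A", "B"), each = 50)))
  expect_equal(unname(expected_random_proportion(s, "A")["A"]), 49 / 99)
  expect_equal(unname(expected_random_proportion(s, "A")["B"]), 50 / 99)
  expect_equal(unname(expected_random_proportion(s)["A"]), 0.5)

  # permuting coordinates does not change the expectation
  s2 <- s; s2$x_um <- rev(s2$x_um)
  expect_equal(expected_random_proportion(s2), expected_random_proportion(s))

  mono <- as_spatial_point_set(data.frame(x_um = 1:5, y_um = 0, label = "A"))
  expect_equal(unname(expected_random_proportion(mono)["A"]), 1)
})

test_that("csr curves sit on the random expectation within sampling error", {
  sm <- simulate_spatial_map(sim_spatial_config(n_points = 900, mode = "csr",
                                                seed = 12))
  cv <- neighborhood_composition(as_spatial_point_set(sm), 1, 20)
  same <- cv$curve[cv$curve$center_label == cv$curve$target_label, ]
  expect_true(all(abs(same$mean - same$expected) <= 3 * same$sem))

  # subsampled centers estimate the full-data curve without bias
  half <- which(seq_len(nrow(sm)) %% 2 == 0)
  m_half <- colMeans(cv$raw[half, , "A", drop = FALSE][, , 1])
  full <- cv$curve[cv$curve$center_label == "A" & cv$curve$target_label == "A", ]
  expect_true(all(abs(m_half - cv$curve$mean[cv$curve$target_label == "A" &
                                             cv$curve$center_label == "A"]) <
                  4 * full$sem / sqrt(0.5)))
})

test_that("the one-tailed test separates aggregated maps from random ones", {
  th <- simulate_spatial_map(sim_spatial_config(n_points = 500, mode = "thomas",
                                                n_parents = 10,
                                                parent_sigma = 50, seed = 13))
  ct <- clustering_test(neighborhood_composition(as_spatial_point_set(th), 1, 20))
  expect_lt(ct$max_p, 1e-6)
  expect_true(all(c("target_label", "n", "U", "p") %in% colnames(ct$table)))

  cs <- simulate_spatial_map(sim_spatial_config(n_points = 500, mode = "csr",
                                                seed = 14))
  ct0 <- clustering_test(neighborhood_composition(as_spatial_point_set(cs), 5, 5))
  expect_gt(ct0$max_p, 0.05)

  mono <- as_spatial_point_set(data.frame(x_um = runif(30), y_um = runif(30),
                                          label = "A"))
  expect_error(clustering_test(neighborhood_composition(mono, 1, 3)),
               "non-empty")
})

test_that("permutation null is bounded, powerful on clustered maps and
           calibrated on csr maps", {
  th <- simulate_spatial_map(sim_spatial_config(n_points = 300, mode = "thomas",
                                                n_parents = 10,
                                                parent_sigma = 50, seed = 15))
  pn <- permutation_null(as_spatial_point_set(th), n_sizes = 10,
                         n_perm = 999, seed = 1)
  expect_equal(pn$p, 1 / 1000)                 # add-one lower bound attained
  expect_gte(min(pn$p), 1 / 1000)

  rates <- vapply(1:200, function(s) {
    cs <- simulate_spatial_map(sim_spatial_config(n_points = 120, mode = "csr",
                                                  seed = 5000 + s))
    permutation_null(as_spatial_point_set(cs), n_sizes = 10,
                     n_perm = 199, seed = s)$p
  }, numeric(1))
  rej <- mean(rates <= 0.05)
  expect_gte(rej, 0.02); expect_lte(rej, 0.09)
  expect_error(permutation_null(as_spatial_point_set(th), 10, n_perm = 50),
               "n_perm")
})
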