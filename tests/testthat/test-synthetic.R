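# Generators: determinism, closed-form structure, and ground-truth sanity.

test_that("follicle generator honours polarized_fraction limits and determinism", {
  # all unpolarized: Sox9 is a full ring around every core
  sim0 <- sim_follicle_image(n_follicles = 6, polarized_fraction = 0,
                             noise_sd = 0, seed = 11)
  expect_true(all(!sim0$truth$polarized))
  for (i in seq_len(6)) {
    with(sim0$truth[i, ], {
      idx <- which(sim0$image[, , 2] > 30, arr.ind = TRUE)
      phi <- pixel_angle(idx[, 2] - 0.5, idx[, 1] - 0.5, cx, cy)
      d <- sqrt((idx[, 2] - 0.5 - cx)^2 + (idx[, 1] - 0.5 - cy)^2)
      expect_equal(angular_coverage(phi[d <= 17], bin_width = 10), 360)
    })
  }
  # degenerate von Mises pins every angle at the mean
  sim1 <- sim_follicle_image(n_follicles = 8, polarized_fraction = 1,
                             angle_mean = 0, angle_concentration = 1e6,
                             seed = 2)
  expect_true(all(sim1$truth$polarized))
  expect_lt(max(abs(angle_diff(sim1$truth$angle_deg, 0))), 1)
  # same seed regenerates bit-identical image and truth
  a <- sim_follicle_image(n_follicles = 10, seed = 7)
  b <- sim_follicle_image(n_follicles = 10, seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("follicle placement respects separation and errors at excess density", {
  sim <- sim_follicle_image(image_size = 520, n_follicles = 25,
                            follicle_radius = 16, seed = 3)
  d <- as.matrix(dist(sim$truth[, c("cx", "cy")]))
  diag(d) <- Inf
  expect_gt(min(d), 2 * 16)
  expect_error(
    sim_follicle_image(image_size = 100, n_follicles = 50,
                       follicle_radius = 16, seed = 1),
    "density|too small"
  )
})

test_that("polarized fraction of a large draw stays within binomial bounds", {
  sim <- sim_follicle_image(image_size = 1200, n_follicles = 50,
                            polarized_fraction = 0.7, seed = 1)
  phat <- mean(sim$truth$polarized)
  se <- sqrt(0.7 * 0.3 / 50)
  expect_lt(abs(phat - 0.7), 3 * se)
  # regeneration with the same seed gives the same flags
  sim2 <- sim_follicle_image(image_size = 1200, n_follicles = 50,
                             polarized_fraction = 0.7, seed = 1)
  expect_identical(sim$truth$polarized, sim2$truth$polarized)
})

test_that("mesh generator matches the brute-force pixel-sum oracle", {
  m <- sim_cell_mesh(n_cells = 16, domain_size = 140,
                     modulation_amplitude = 100, base_intensity = 100,
                     polarity_axis = 0, noise_sd = 0, seed = 4)
  interior <- m$truth$cell_id[!m$truth$border_cell]
  for (id in interior[1:4]) {
    px <- extract_boundary_pixels(m$labels, id, ring_width = 10,
                                  intensity = m$intensity)
    px <- px[px$intensity > 0, ]
    bf <- brute_force_nematic(px$phi_deg, px$intensity)
    ours <- compute_cell_polarity(px)
    expect_equal(ours$magnitude, bf$magnitude, tolerance = 1e-9)
    expect_lt(abs(angle_diff(ours$axis_deg, bf$axis_deg, 180)), 1e-7)
  }
  # determinism
  m2 <- sim_cell_mesh(n_cells = 16, domain_size = 140,
                      modulation_amplitude = 100, base_intensity = 100,
                      polarity_axis = 0, noise_sd = 0, seed = 4)
  expect_identical(m$intensity, m2$intensity)
  expect_identical(m$labels, m2$labels)
})

test_that("unmodulated meshes carry near-zero nematic order in truth", {
  m <- sim_cell_mesh(n_cells = 64, domain_size = 250,
                     modulation_amplitude = 0, noise_sd = 0, seed = 9)
  expect_lt(max(m$truth$expected_magnitude[!m$truth$border_cell]), 0.05)
})

test_that("cell-pair fixture has the constructed junction/membrane contrast", {
  p <- sim_cell_pair(enrichment_factor = 1, noise_sd = 0, seed = 1)
  jm <- mean(p$image[p$rois$junction[[1]]])
  mm <- mean(p$image[p$rois$cell[[1]]])
  expect_equal(jm, mm)

  p4 <- sim_cell_pair(enrichment_factor = 4, noise_sd = 0,
                      background_level = 0, seed = 1)
  jm4 <- mean(p4$image[p4$rois$junction[[1]]])
  mm4 <- mean(p4$image[p4$rois$cell[[1]]])
  expect_equal(jm4, 4 * mm4)

  # downstream JE equals the oracle ratio of background-corrected ROI means
  p2 <- sim_cell_pair(enrichment_factor = 2, noise_sd = 0,
                      background_level = 0, seed = 1)
  je <- junction_enrichment(p2$image, p2$rois)
  corr <- p2$image - mean(p2$image[p2$rois$background[[1]]])
  oracle <- mean(corr[p2$rois$junction[[1]]]) / mean(corr[p2$rois$cell[[1]]])
  expect_equal(je$je, oracle)
  expect_equal(je$je, 2)
})

test_that("FRAP generator obeys its closed-form limits", {
  # full recovery limit: k*t >> 1 drives the normalized trace to 1
  s1 <- sim_frap_traces(mobile_fraction = 1, rate_k = 0.1,
                        acquisition_bleach_rate = 0, noise_sd = 0)
  n1 <- frap_normalize(frap_correct(s1$traces))
  expect_equal(n1$value[which.max(n1$time_s)], 1, tolerance = 1e-6)
  # no mobile pool: post-bleach normalized trace is identically 0
  s0 <- sim_frap_traces(mobile_fraction = 0, rate_k = 0.05, noise_sd = 0)
  n0 <- frap_normalize(frap_correct(s0$traces))
  expect_equal(max(abs(n0$value)), 0)
  # closed-form point: mobile 0.6, k = 0.02 at t = 50 s
  s <- sim_frap_traces(mobile_fraction = 0.6, rate_k = 0.02, noise_sd = 0)
  n <- frap_normalize(frap_correct(s$traces))
  expect_equal(n$value[n$time_s == 50], 0.6 * (1 - exp(-1)), tolerance = 1e-12)
  # determinism with noise
  a <- sim_frap_traces(n_traces = 3, noise_sd = 5, seed = 6)
  b <- sim_frap_traces(n_traces = 3, noise_sd = 5, seed = 6)
  expect_identical(a$traces, b$traces)
})

test_that("noiseless generator outputs match their pixel/sample models exactly", {
  # follicle: foreground pixels are exactly background + foreground
  sim <- sim_follicle_image(n_follicles = 4, noise_sd = 0,
                            background_level = 30, foreground_level = 200,
                            seed = 5)
  expect_setequal(unique(as.vector(sim$image)), c(30, 230))
  # frap raw series follow the stated model
  s <- sim_frap_traces(mobile_fraction = 0.4, rate_k = 0.03,
                       bleach_depth = 0.8, acquisition_bleach_rate = 0.001,
                       signal_level = 1000, background_level = 50,
                       noise_sd = 0)
  tr <- s$traces
  post <- tr[tr$phase == "post", ]
  D <- exp(-0.001 * (post$time_s - min(tr$time_s)))
  expect_equal(post$bleach,
               50 + 1000 * D * frap_model(post$time_s, 0.8, 0.4, 0.03),
               tolerance = 1e-12)
  expect_equal(post$reference, 50 + 1000 * D, tolerance = 1e-12)
  expect_equal(unique(tr$background), 50)
})
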