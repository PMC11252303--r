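# Map simulation, correlation scoring and rigid-body fitting.

test_that("simulated maps respect the grid Nyquist precondition", {
  m <- blob_model()
  expect_error(simulate_map(m, resolution = 9.9, voxel_size = 5,
                            box = c(24, 24, 24)), "2 \\* voxel_size")
  v <- simulate_map(m, resolution = 10, voxel_size = 5, box = c(24, 24, 24))
  expect_s3_class(v, "volume_grid")
})

test_that("correlation scores behave as a normalized similarity", {
  v <- simulate_map(blob_model(), 16, 4, c(40, 40, 40))
  expect_equal(as.numeric(correlation_score(v, v)), 1)
  neg <- v; neg$values <- -neg$values
  expect_equal(as.numeric(correlation_score(v, neg, mask_mode = "none")), -1)
  # affine intensity rescaling of either map leaves the score unchanged
  w <- simulate_map(blob_model(seed = 7), 16, 4, c(40, 40, 40))
  s0 <- as.numeric(correlation_score(v, w))
  w2 <- w; w2$values <- 3.7 * w2$values + 11
  expect_equal(as.numeric(correlation_score(v, w2)), s0, tolerance = 1e-12)
  # overlap mask is symmetric under swapping
  so1 <- as.numeric(correlation_score(v, w, mask_mode = "overlap"))
  so2 <- as.numeric(correlation_score(w, v, mask_mode = "overlap"))
  expect_equal(so1, so2, tolerance = 1e-12)
  empty <- volume_grid(array(0, dim(v$values)), v$voxel_size)
  expect_error(correlation_score(v, empty, mask_mode = "overlap"), "mask")
  small <- volume_grid(array(1, c(8, 8, 8)), 4)
  expect_error(correlation_score(v, small), "identical grids")
})

test_that("a model fits its own simulated map at the identity", {
  m <- blob_model()
  target <- simulate_map(m, 16, 4, c(40, 40, 40))
  fit <- rigid_body_fit(m, target, resolution = 16,
                        search = list(angle_step = 30, beta = c(0, 60)))
  expect_gte(fit$score, 0.999)
  expect_lt(rotation_angle(fit$rotation_matrix), 2)
  expect_lt(max(abs(fit$translation)), 4)   # within one voxel
  expect_error(rigid_body_fit(m, volume_grid(array(-1, c(16, 16, 16)), 4)),
               "no positive density")
})

test_that("known rigid transforms are recovered within tolerance", {
  m <- blob_model()
  self_score <- as.numeric(correlation_score(
    simulate_map(m, 16, 4, c(40, 40, 40)),
    simulate_map(m, 16, 4, c(40, 40, 40))))
  angles <- list(c(25, 40, 0), c(0, 55, 10), c(12, 20, 30))
  for (ang in angles) {
    R <- euler_zyz(ang[1], ang[2], ang[3])
    rotated <- transform_model(m, R)
    target <- simulate_map(rotated, 16, 4, c(40, 40, 40))
    fit <- rigid_body_fit(m, target, resolution = 16,
                          search = list(angle_step = 20, beta = c(0, 60)))
    expect_lt(rotation_angle(fit$rotation_matrix, R), 2)
    expect_gte(fit$score, self_score - 0.01)
  }
})

test_that("maps of one model at different voxel sizes agree after resampling", {
  m <- blob_model()
  a <- simulate_map(m, 16, 4, c(40, 40, 40))
  b <- simulate_map(m, 16, 3, c(52, 52, 52))
  res <- resample_volume(b, a)
  ok <- a$values > 0.05 * max(a$values)
  expect_gt(stats::cor(res$values[ok], a$values[ok]), 0.99)
})

test_that("a bare core model under-fills a decorated filament map", {
  spec <- filament_spec(helical_symmetry(27.5, -162), subunit_radius = 25,
                        n_subunits = 24)
  decorated <- build_decorated_filament_model(spec)
  target <- simulate_map(decorated, 20, 5, c(48, 48, 160))
  srch <- list(angle_step = 15, beta = c(0, 0), gamma = c(0, 0))
  bare_fit <- rigid_body_fit(build_filament_model(spec), target,
                             resolution = 20, search = srch,
                             mask_ref = "target")
  deco_fit <- rigid_body_fit(decorated, target, resolution = 20,
                             search = srch, mask_ref = "target")
  expect_lt(bare_fit$score, deco_fit$score - 0.1)
  expect_gte(deco_fit$score, 0.999)
})

test_that("a noisy helical reconstruction docks its generating model", {
  spec <- class1_filament_spec()
  vol <- render_filament(spec)
  model <- build_filament_model(spec)
  keep <- abs(model$xyz[, 3]) <= 275
  segment <- atomic_model(model$xyz[keep, , drop = FALSE])
  noisy <- add_noise_and_wedge(vol, noise_model(snr = 1, seed = 0))
  rec <- helical_average(crop_to_object(noisy), helical_symmetry(27.5, -162),
                         n_units = 40)
  fit <- rigid_body_fit(segment, rec$map, resolution = 20,
                        search = list(angle_step = 10, beta = c(0, 0),
                                      gamma = c(0, 0)),
                        lowpass = TRUE)
  expect_gte(fit$score, 0.9)
})
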