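# Generator geometry, rendering convention, noise and wedge behaviour.

# independent oracle: walk subunits until the accumulated long-pitch
# rotation (180 - |twist| per subunit) reaches 180 degrees; the crossover is
# the axial distance covered
crossover_by_counting <- function(rise, twist) {
  per <- 180 - abs(twist)
  rise * 180 / per
}

test_that("crossover identity matches the subunit-counting oracle", {
  expect_equal(crossover_spacing(helical_symmetry(27.5, -162)),
               crossover_by_counting(27.5, -162))
  expect_equal(crossover_spacing(helical_symmetry(27.5, -162)), 275)
  cx <- crossover_spacing(helical_symmetry(27.5, -166.6))
  expect_equal(cx, crossover_by_counting(27.5, -166.6))
  expect_equal(cx, 369.403, tolerance = 1e-5)
  expect_gt(cx, 350); expect_lt(cx, 370)   # inside the canonical band
})

test_that("degenerate symmetry parameters are rejected", {
  expect_error(helical_symmetry(27.5, -180), "twist")
  expect_error(helical_symmetry(27.5, 0), "twist")
  expect_error(helical_symmetry(-1, -162), "rise")
  expect_error(filament_spec(helical_symmetry(27.5, -162), n_subunits = 10),
               "two crossovers")
})

test_that("filament models realize the generative helix", {
  spec <- filament_spec(helical_symmetry(27.5, -162), subunit_radius = 32,
                        n_subunits = 25)
  m <- build_filament_model(spec)
  expect_equal(nrow(m$xyz), 25L)
  # consecutive z spacing = rise, radius constant, azimuth steps = twist
  z <- m$xyz[, 3]
  expect_equal(diff(z), rep(27.5, 24))
  expect_equal(sqrt(m$xyz[, 1]^2 + m$xyz[, 2]^2), rep(32, 25))
  az <- atan2(m$xyz[, 2], m$xyz[, 1]) * 180 / pi
  step <- (diff(az) + 360) %% 360
  expect_equal(step, rep((-162) %% 360, 24), tolerance = 1e-8)
})

test_that("rendering normalizes mass and is deterministic", {
  one <- atomic_model(matrix(0, 1, 3), mass_weight = 2.5)
  v <- render_density(one, voxel_size = 2, box = c(32, 32, 32),
                      resolution = 16)
  expect_equal(sum(v$values), 2.5, tolerance = 0.01)
  v2 <- render_density(one, voxel_size = 2, box = c(32, 32, 32),
                       resolution = 16)
  expect_identical(v$values, v2$values)
  far <- atomic_model(rbind(c(0, 0, 0), c(500, 0, 0)))
  expect_error(render_density(far, 2, c(32, 32, 32), 16), "2 atom")
})

test_that("rendering resolutions compose as Gaussian low-passes", {
  spec <- class1_filament_spec(24)
  box <- c(40, 40, 180)
  hi <- render_filament(spec, voxel_size = 4, resolution = 10, box = box)
  lo <- render_filament(spec, voxel_size = 4, resolution = 20, box = box)
  # 20 A kernel = 10 A kernel convolved with a sqrt(20^2 - 10^2) kernel
  matched <- lowpass_volume(hi, sqrt(20^2 - 10^2))
  expect_gt(stats::cor(as.vector(matched$values), as.vector(lo$values)), 0.99)
})

test_that("microtubule cross-sections have the generating rotational symmetry", {
  mt <- microtubule_volume(13)
  r13 <- rotational_average(mt, 13)
  expect_gt(r13$self_correlation, 0.99)
  expect_error(microtubule_spec(10), "11..17")
  expect_error(
    microtubule_spec(13, wall_radius = 40,
                     lumen_filament = class1_filament_spec(22)),
    "too wide")
})

test_that("lumen filaments break lumen symmetry but leave the wall intact", {
  spec <- microtubule_spec(13, length = 600,
                           lumen_filament = class1_filament_spec(21))
  vol <- render_density(build_microtubule_model(spec), 5, c(64, 64, 120), 20)
  # wall annulus: still C13
  wall <- rotational_average(vol, 13)
  expect_gt(wall$self_correlation, 0.99)
  # lumen region alone is not C13-symmetric
  d <- dim(vol$values)
  xs <- (seq_len(d[1]) - (d[1] + 1) / 2) * 5
  ys <- (seq_len(d[2]) - (d[2] + 1) / 2) * 5
  lum <- sqrt(outer(xs^2, ys^2, "+")) < 60
  lum_mask <- array(lum, dim = d)
  rot <- helixline:::rotate_about_axis(vol$values, 5, 360 / 13,
                                       c((d[1] + 1) / 2, (d[2] + 1) / 2))
  ok <- lum_mask & rot$inside
  expect_lt(stats::cor(vol$values[ok], rot$values[ok]), 0.95)
})

test_that("noise scaling, determinism and the vanishing-noise limit hold", {
  vol <- render_filament(class1_filament_spec(24))
  near <- add_noise_and_wedge(vol, noise_model(snr = 1e9, seed = 1))
  expect_gt(stats::cor(as.vector(near$values), as.vector(vol$values)), 0.999)
  a <- add_noise_and_wedge(vol, noise_model(snr = 1, wedge_half_angle = 60,
                                            seed = 7))
  b <- add_noise_and_wedge(vol, noise_model(snr = 1, wedge_half_angle = 60,
                                            seed = 7))
  expect_identical(a$values, b$values)
  # requested snr is realized inside the object mask
  noisy <- add_noise_and_wedge(vol, noise_model(snr = 2, seed = 3))
  mask <- vol$values > 0.1 * max(vol$values)
  noise_var <- stats::var(as.vector((noisy$values - vol$values)))
  expect_equal(stats::var(as.vector(vol$values[mask])) / noise_var, 2,
               tolerance = 0.1)
})

test_that("the missing wedge zeroes the stated Fourier region", {
  vol <- render_filament(class1_filament_spec(24))
  wedged <- add_noise_and_wedge(vol, noise_model(snr = 1e9,
                                                 wedge_half_angle = 60,
                                                 seed = 0))
  ft <- fft(wedged$values)
  d <- dim(ft)
  freq <- function(n) c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
  kx <- freq(d[1]); kz <- freq(d[3])
  ang <- atan2(abs(kx)[rep(seq_len(d[1]), times = d[3])],
               abs(kz)[rep(seq_len(d[3]), each = d[1])]) * 180 / pi
  missing <- array(FALSE, dim = d)
  for (j in seq_len(d[2])) missing[, j, ] <- array(ang < 30, c(d[1], d[3]))
  expect_lt(max(Mod(ft[missing])) / max(Mod(ft)), 1e-10)
  expect_gt(max(Mod(ft[!missing])), 0)
})

test_that("noisy wedged volumes still yield the generator crossover", {
  hits <- vapply(0:9, function(s) {
    v <- add_noise_and_wedge(render_filament(class1_filament_spec()),
                             noise_model(snr = 1, wedge_half_angle = 60,
                                         seed = s))
    ll <- detect_layer_lines(compute_power_spectrum(
      project_filament(crop_to_object(v))))
    if (nrow(ll) == 0) return(FALSE)
    abs(derive_helical_parameters(ll)$crossover - 275) / 275 < 0.05
  }, logical(1))
  expect_gte(sum(hits), 9)
})
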