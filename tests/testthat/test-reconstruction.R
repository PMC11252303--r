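# Straightening, contrast inversion, helical averaging, symmetry refinement.

# filament bent along a circular arc (in the x-z plane) of radius
# `bend_radius`, plus the matching centerline control points in the frame
# of the rendered volume
bent_filament <- function(spec, bend_radius, voxel_size = 5) {
  rise <- spec$symmetry$rise; twist <- spec$symmetry$twist
  r <- spec$subunit_radius
  k <- seq_len(spec$n_subunits) - 1
  s <- k * rise
  phi <- s / bend_radius
  Cx <- bend_radius * (1 - cos(phi)); Cz <- bend_radius * sin(phi)
  th <- k * twist * pi / 180
  Nx <- cos(phi); Nz <- -sin(phi)
  xyz <- cbind(Cx + r * cos(th) * Nx,
               r * sin(th),
               Cz + r * cos(th) * Nz)
  ctr <- colMeans(xyz)
  model <- atomic_model(sweep(xyz, 2, ctr))
  ext <- apply(model$xyz, 2, function(x) diff(range(x)))
  box <- 2 * ceiling((ext / 2 + 50) / voxel_size)
  vol <- render_density(model, voxel_size, box, 20)
  ns <- seq(0, max(s), by = 55)
  pts <- cbind(bend_radius * (1 - cos(ns / bend_radius)), 0,
               bend_radius * sin(ns / bend_radius))
  pts <- sweep(pts, 2, ctr)
  list(vol = vol, trace = centerline_trace(pts))
}

test_that("straightening an already straight filament is the identity", {
  vol <- render_filament(class1_filament_spec(40))
  d <- dim(vol$values)
  vx <- vol$voxel_size
  # trace symmetric about a plane of voxel centres so the resampling grid
  # registers exactly with the input grid
  z_mid <- vol$origin[3] + round(d[3] / 2) * vx
  trace <- centerline_trace(rbind(c(0, 0, z_mid - 400), c(0, 0, z_mid),
                                  c(0, 0, z_mid + 400)))
  st <- straighten(vol, trace, out_length_px = 128, out_width_px = d[1])
  usable <- attr(st, "usable_z")
  mid <- st$values[, , usable]
  # corresponding crop of the input: output slice k samples input index
  # (z_mid - origin)/vx - out_length/2 + k
  i0 <- round((z_mid - vol$origin[3]) / vx) - 64
  ref <- vol$values[, , i0 + seq_len(sum(usable))]
  expect_gt(stats::cor(as.vector(mid), as.vector(ref)), 0.99)
  expect_error(centerline_trace(matrix(c(0, 0, 0), 1, 3)), "2 points")
  bad <- centerline_trace(rbind(c(0, 0, -1e5), c(0, 0, 1e5)))
  expect_error(straighten(vol, bad), "outside")
})

test_that("straightening a bent filament restores its layer lines", {
  spec <- class1_filament_spec(40)
  bend_radius <- 10 * (40 * 27.5)
  bf <- bent_filament(spec, bend_radius)
  st <- straighten(bf$vol, bf$trace, out_length_px = 200, out_width_px = 26)
  img <- project_filament(st)
  m <- derive_helical_parameters(detect_layer_lines(
    compute_power_spectrum(img)))
  straight <- derive_helical_parameters(detect_layer_lines(
    compute_power_spectrum(project_filament(render_filament(spec)))))
  expect_lt(abs(m$crossover - straight$crossover) / straight$crossover, 0.02)
  expect_lt(abs(m$rise - straight$rise) / straight$rise, 0.02)
})

test_that("density inversion is an involution up to the mean", {
  vol <- render_filament(class1_filament_spec(22))
  dark <- vol; dark$values <- -dark$values     # protein-dark contrast
  bright <- invert_density(dark)
  # protein-bright: the densest voxels sit on the filament
  expect_gt(stats::cor(as.vector(bright$values), as.vector(vol$values)),
            0.999)
  twice <- invert_density(invert_density(vol))
  expect_equal(twice$values, vol$values - mean(vol$values), tolerance = 1e-12)
  const <- invert_density(volume_grid(array(3, c(8, 8, 8)), 5))
  expect_equal(max(abs(const$values)), 0)
})

test_that("helical averaging reproduces the noiseless structure", {
  vol <- render_filament(class1_filament_spec(60))
  rec <- helical_average(vol, helical_symmetry(27.5, -162), n_units = 20)
  d <- dim(vol$values)
  zc <- round(d[3] * 0.3):round(d[3] * 0.7)
  expect_gt(stats::cor(as.vector(rec$map$values[, , zc]),
                       as.vector(vol$values[, , zc])), 0.99)
  expect_gt(rec$self_consistency, 0.98)
  expect_equal(rec$n_units_averaged, 20L)
  # n_units = 1 is the identity
  one <- helical_average(vol, helical_symmetry(27.5, -162), n_units = 1)
  expect_identical(one$map$values, vol$values)
  # imposed-symmetry identity: one further operation changes little
  expect_lt(1 - rec$self_consistency, 0.02)
  # symmetry mismatch lowers self-consistency
  wrong <- helical_average(vol, helical_symmetry(27.5, -150), n_units = 20)
  expect_lt(wrong$self_consistency, rec$self_consistency)
  expect_error(helical_average(vol, helical_symmetry(27.5, -162),
                               n_units = 1000), "at most")
})

test_that("averaging more units improves noisy reconstructions", {
  clean <- render_filament(class1_filament_spec(60))
  wins <- vapply(0:4, function(s) {
    noisy <- add_noise_and_wedge(clean, noise_model(snr = 0.5, seed = s))
    r2 <- helical_average(noisy, helical_symmetry(27.5, -162), n_units = 2)
    r20 <- helical_average(noisy, helical_symmetry(27.5, -162), n_units = 20)
    c2 <- stats::cor(as.vector(r2$map$values), as.vector(clean$values))
    c20 <- stats::cor(as.vector(r20$map$values), as.vector(clean$values))
    c20 > c2
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("symmetry refinement recovers the generating parameters", {
  clean <- render_filament(class1_filament_spec(60))
  hits <- vapply(0:9, function(s) {
    noisy <- crop_to_object(add_noise_and_wedge(clean,
                                                noise_model(snr = 1, seed = s)))
    sr <- symmetry_refine(noisy, helical_symmetry(27, -160),
                          rise_window = c(-1.5, 2), twist_window = c(-3, 5))
    abs(sr$rise - 27.5) <= 0.5 && abs(abs(sr$twist) - 162) <= 1
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("refinement flags boundary hits and fails on pure noise", {
  clean <- crop_to_object(render_filament(class1_filament_spec(30)))
  sr <- symmetry_refine(clean, helical_symmetry(25, -156),
                        rise_window = c(-1, 1), twist_window = c(-2, 2))
  expect_true(attr(sr, "boundary_hit"))
  for (s in 0:2) {
    noise <- volume_grid(with_seed_local(s, array(stats::rnorm(20 * 20 * 120),
                                                  c(20, 20, 120))), 5)
    expect_error(symmetry_refine(noise, helical_symmetry(27.5, -162)),
                 "refinement failed")
  }
})

test_that("traces parse from CSV and point text", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "0,0,0", "0,0,50", "0,1,100"), csv)
  tr <- read_trace(csv)
  expect_equal(nrow(tr$points), 3L)
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0", "0 0 50", "0 1 100"), txt)
  tr2 <- read_trace(txt)
  expect_equal(tr$points, tr2$points)
})
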