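# Layer-line detection, helical-parameter derivation and classification.

# brute-force helical lattice oracle: layer lines of a u-subunit / t-turn
# helix sit at l / (u * rise) with l = t*n + u*m; returns the axial
# frequencies (1/A) of the lines with |n| <= nmax inside the band
selection_rule_lines <- function(u, t, rise, nmax = 2, lmax = 25) {
  l <- outer(t * (-nmax:nmax), u * (-3:3), "+")
  l <- sort(unique(l[l > 0 & l <= lmax]))
  l / (u * rise)
}

test_that("projection preserves geometry and rejects thin volumes", {
  # uniform cylinder along z: projection is a constant band along z
  vals <- array(0, c(24, 24, 64))
  xs <- (1:24) - 12.5
  disk <- outer(xs^2, xs^2, "+") < 8^2
  for (k in 1:64) vals[, , k] <- disk * 1
  cyl <- volume_grid(vals, 5)
  img <- project_filament(cyl)
  expect_equal(dim(img), c(24, 64))
  expect_lt(stats::sd(colSums(img)), 1e-10)
  thin <- volume_grid(array(1, c(24, 2, 64)), 5)
  expect_error(project_filament(thin), "thinner")
})

test_that("power spectra are calibrated and Friedel-symmetric", {
  # pure axial cosine of period 275 A at 5 A pixels
  n <- 256
  img <- matrix(rep(cos(2 * pi * (1:n) * 5 / 275), each = 32), 32, n)
  img <- structure(img, pixel_size = 5, class = "filament_projection")
  ps <- compute_power_spectrum(img, pad_factor = 4, taper_fraction = 0.1)
  pos <- ps$freq_axial > 1e-9
  peak <- ps$freq_axial[pos][which.max(colSums(ps$amplitudes)[pos])]
  expect_lt(abs(peak - 1 / 275), ps$step_axial + 1e-12)
  # real input -> |F(-q)| = |F(q)|
  flipped <- ps$amplitudes[rev(seq_len(nrow(ps$amplitudes))),
                           rev(seq_len(ncol(ps$amplitudes)))]
  sub <- ps$amplitudes[2:nrow(ps$amplitudes), 2:ncol(ps$amplitudes)]
  subf <- flipped[seq_len(nrow(sub)), seq_len(ncol(sub))]
  expect_lt(max(abs(sub - subf)) / max(sub), 1e-6)
  # padding refines but does not move the peak
  ps1 <- compute_power_spectrum(img, pad_factor = 1, taper_fraction = 0.1)
  pos1 <- ps1$freq_axial > 1e-9
  peak1 <- ps1$freq_axial[pos1][which.max(colSums(ps1$amplitudes)[pos1])]
  expect_lt(abs(peak1 - peak), ps1$step_axial + 1e-12)
})

test_that("detected layer lines match the helical selection rule", {
  # rise 27.5 / twist -162 is a 20-subunit / 9-turn helix
  lines <- class1_lines()
  expected <- selection_rule_lines(u = 20, t = 9, rise = 27.5)
  for (f in c(1 / 275, 1 / 61.1, 1 / 27.5)) {
    expect_true(any(abs(expected - f) / f < 0.01))    # oracle self-check
    expect_true(any(abs(lines$axial_frequency - f) / f < 0.01),
                label = sprintf("line at %.1f A detected", 1 / f))
  }
  mer <- lines[lines$on_meridian, ]
  expect_equal(mer$spacing[which.max(mer$peak_amplitude)], 27.5,
               tolerance = 0.005)

  # rise 27.5 / twist -166.6 is (approximately) a 13/6 helix: lowest line
  # at the 369 A crossover and the genetic pitch line at 59.4 A
  clines <- canonical_lines()
  for (f in c(1 / 369.4, 1 / 59.42)) {
    expect_true(any(abs(clines$axial_frequency - f) / f < 0.01),
                label = sprintf("canonical line at %.1f A detected", 1 / f))
  }
  # a flat image yields no lines
  flat <- structure(matrix(1, 32, 128), pixel_size = 5,
                    class = "filament_projection")
  expect_equal(nrow(detect_layer_lines(compute_power_spectrum(flat))), 0L)
})

test_that("helical parameters derive from lines by the stated arithmetic", {
  mk <- function(spacing, mer) {
    data.frame(axial_frequency = 1 / spacing, spacing = spacing,
               peak_amplitude = 1, snr = 100,
               transverse_frequency = ifelse(mer, 0, 0.015),
               on_meridian = mer)
  }
  m <- derive_helical_parameters(mk(c(276.6, 27.5), c(FALSE, TRUE)))
  expect_equal(m$crossover, 276.6)
  expect_equal(m$rise, 27.5)
  expect_equal(m$twist_magnitude, 180 * (1 - 27.5 / 276.6), tolerance = 1e-12)
  expect_equal(m$twist_magnitude, 162.1, tolerance = 0.01)

  m2 <- derive_helical_parameters(mk(c(275, 61.1, 27.5),
                                     c(FALSE, FALSE, TRUE)))
  expect_equal(m2$twist_magnitude, 162, tolerance = 0.05)
  expect_equal(m2$twist_from_pitch, 360 * 27.5 / 61.1, tolerance = 1e-12)
  expect_true(m2$consistent)

  m3 <- derive_helical_parameters(mk(370, FALSE))
  expect_equal(m3$crossover, 370)
  expect_true(is.na(m3$rise))
  expect_true(is.na(m3$twist_magnitude))

  expect_error(derive_helical_parameters(mk(370, FALSE)[0, ]), "unavailable")
})

test_that("noise peaks cannot displace a dominant crossover line", {
  lines <- data.frame(
    axial_frequency = c(1 / 548, 1 / 275, 1 / 61),
    spacing = c(548, 275, 61), peak_amplitude = c(264, 1143, 884),
    snr = c(5.5, 25, 20), transverse_frequency = c(0.012, 0.015, 0.01),
    on_meridian = FALSE)
  expect_equal(derive_helical_parameters(lines)$crossover, 275)
})

test_that("real-space width autocorrelation agrees with the spectral route", {
  px <- class1_volume()$voxel_size
  cx1 <- measure_crossover_realspace(class1_projection())
  expect_lt(abs(cx1 - 275), px)
  cx2 <- measure_crossover_realspace(canonical_projection())
  expect_lt(abs(cx2 - 369.4), px)
  # spectral vs real-space agreement on both presets
  expect_lt(abs(cx1 - derive_helical_parameters(class1_lines())$crossover) / cx1,
            0.03)
  expect_lt(abs(cx2 - derive_helical_parameters(canonical_lines())$crossover) / cx2,
            0.03)
  # a constant-width band has no crossover period
  band <- structure(matrix(rep(exp(-((1:32) - 16)^2 / 18), 128), 32, 128),
                    pixel_size = 5, class = "filament_projection")
  expect_error(measure_crossover_realspace(band), "constant-width|insufficient")
})

test_that("crossover bands assign the expected class labels", {
  expect_equal(classify_filament(list(crossover = 276.6)), "CLASS_I")
  expect_equal(classify_filament(list(crossover = 370)), "CANONICAL")
  expect_equal(classify_filament(list(crossover = 320)), "UNCLASSIFIED")
  expect_error(classify_filament(list(crossover = NA)), "unavailable")
})

test_that("generate -> render -> measure round-trips rise and twist", {
  for (rise in c(26, 29)) for (twist in c(-157, -167)) {
    spec <- filament_spec(helical_symmetry(rise, twist), subunit_radius = 28,
                          n_subunits = 100)
    m <- derive_helical_parameters(detect_layer_lines(compute_power_spectrum(
      project_filament(render_filament(spec)))))
    expect_lt(abs(m$rise - rise) / rise, 0.02)
    expect_lt(abs(m$twist_magnitude - abs(twist)), 1)
  }
})

test_that("measured crossover increases with twist magnitude at fixed rise", {
  cx <- vapply(c(-157, -162, -167, -171), function(tw) {
    spec <- filament_spec(helical_symmetry(27.5, tw), subunit_radius = 28,
                          n_subunits = 100)
    derive_helical_parameters(detect_layer_lines(compute_power_spectrum(
      project_filament(render_filament(spec)))))$crossover
  }, numeric(1))
  expect_true(all(diff(cx) > 0))
})

test_that("classification of the presets survives noise at snr 0.5", {
  lab1 <- vapply(0:19, function(s)
    classify_noisy(class1_filament_spec(), s, snr = 0.5), character(1))
  lab2 <- vapply(0:19, function(s)
    classify_noisy(canonical_filament_spec(), s, snr = 0.5), character(1))
  expect_gte(sum(lab1 == "CLASS_I"), 18)
  expect_gte(sum(lab2 == "CANONICAL"), 18)
})

test_that("projections of pure noise yield no layer lines", {
  false_pos <- vapply(0:9, function(s) {
    v <- volume_grid(with_seed_local(s, array(stats::rnorm(26 * 26 * 256),
                                              c(26, 26, 256))), 5)
    nrow(detect_layer_lines(compute_power_spectrum(project_filament(v))))
  }, numeric(1))
  expect_lte(stats::median(false_pos), 1)
  expect_gte(sum(false_pos == 0), 5)
})
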