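# Forward model: pseudo-atomic helical filaments and microtubules rendered
# as noisy density volumes, standing in for tomographic data.
#
# A filament is generated as its 1-start ("genetic") helix: subunit k sits at
# (r cos(k*twist + phi0), r sin(k*twist + phi0), k*rise). Because the twist of
# actin-like filaments is close to 180 degrees, consecutive subunits land on
# nearly opposite sides of the axis and the familiar two-strand ("long-pitch")
# appearance with its crossover pattern emerges from this single helix.

#' Helical symmetry (rise / twist pair)
#'
#' The axial rise (Angstrom) and rotation (degrees, signed; negative =
#' left-handed genetic helix) relating consecutive subunits. Two derived
#' periodicities are used throughout: the crossover spacing
#' `C = rise * 180 / (180 - |twist|)` (axial distance between successive
#' apparent crossings of the two long-pitch strands) and the genetic pitch
#' `360 * rise / |twist|` (the ~59-61 A layer line of actin-like filaments).
#'
#' @param rise axial rise per subunit, Angstrom (> 0).
#' @param twist rotation per subunit, degrees, `0 < |twist| < 180`.
#' @return An object of class `helical_symmetry`.
#' @examples
#' sym <- helical_symmetry(rise = 27.5, twist = -162)
#' crossover_spacing(sym)   # 275 A
#' genetic_pitch(sym)       # ~61.1 A
#' @export
helical_symmetry <- function(rise, twist) {
  if (!is.finite(rise) || rise <= 0) stop("`rise` must be positive (Angstrom)")
  if (!is.finite(twist) || abs(twist) <= 0 || abs(twist) >= 180)
    stop("`twist` must satisfy 0 < |twist| < 180 degrees")
  structure(list(rise = as.numeric(rise), twist = as.numeric(twist)),
            class = "helical_symmetry")
}

#' @rdname helical_symmetry
#' @param sym a `helical_symmetry`.
#' @export
crossover_spacing <- function(sym) sym$rise * 180 / (180 - abs(sym$twist))

#' @rdname helical_symmetry
#' @export
genetic_pitch <- function(sym) 360 * sym$rise / abs(sym$twist)

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("<helical_symmetry> rise %.3f A, twist %.3f deg (crossover %.1f A, genetic pitch %.2f A)\n",
              x$rise, x$twist, crossover_spacing(x), genetic_pitch(x)))
  invisible(x)
}

#' Filament generator parameters
#'
#' Geometry of a synthetic helical filament: its symmetry, the radial
#' distance of the subunit centre of mass from the axis, an optional extra
#' Gaussian footprint per subunit, the subunit count and a small axis tilt
#' for realism. The subunit count must cover at least two crossovers so that
#' a crossover period is measurable from the render.
#'
#' @param symmetry a [helical_symmetry].
#' @param subunit_radius distance of subunit centres from the axis, Angstrom.
#' @param subunit_sigma extra per-subunit Gaussian width (A) added in
#'   quadrature to the rendering kernel; 0 = point pseudo-atoms.
#' @param n_subunits number of subunits.
#' @param axis_tilt tilt of the filament axis away from +z, degrees.
#' @return An object of class `filament_spec`.
#' @export
filament_spec <- function(symmetry, subunit_radius = 25, subunit_sigma = 0,
                          n_subunits = 40, axis_tilt = 0) {
  stopifnot(inherits(symmetry, "helical_symmetry"))
  if (subunit_radius <= 0) stop("`subunit_radius` must be positive")
  if (subunit_sigma < 0) stop("`subunit_sigma` must be >= 0")
  units_per_crossover <- 180 / (180 - abs(symmetry$twist))
  if (n_subunits < 2 * units_per_crossover)
    stop(sprintf("`n_subunits` must be >= %.1f (two crossovers at this twist)",
                 2 * units_per_crossover))
  structure(list(symmetry = symmetry, subunit_radius = subunit_radius,
                 subunit_sigma = subunit_sigma, n_subunits = as.integer(n_subunits),
                 axis_tilt = axis_tilt),
            class = "filament_spec")
}

#' Preset: short-crossover (cofilin-bound) filament
#'
#' Rise 27.5 A, twist -162 degrees (crossover 275 A); subunit radius 32 A
#' reflecting the wider, smoother outline of a decorated filament. The
#' default 120 subunits give a 330 nm filament (twelve crossovers),
#' comparable to the mean length of lumenal filaments traced in situ.
#' @param n_subunits subunit count.
#' @return A [filament_spec].
#' @export
class1_filament_spec <- function(n_subunits = 120) {
  filament_spec(helical_symmetry(27.5, -162), subunit_radius = 32,
                n_subunits = n_subunits)
}

#' Preset: canonical F-actin filament
#'
#' Rise 27.5 A, twist -166.6 degrees, giving a crossover of 369.4 A inside
#' the canonical 35-37 nm range. The default 120 subunits give a 330 nm
#' filament (about nine crossovers), matching the short-crossover preset.
#' @param n_subunits subunit count.
#' @return A [filament_spec].
#' @export
canonical_filament_spec <- function(n_subunits = 120) {
  filament_spec(helical_symmetry(27.5, -166.6), subunit_radius = 25,
                n_subunits = n_subunits)
}

#' Build a pseudo-atomic filament model
#'
#' Places one pseudo-atom per subunit on the 1-start helix defined by the
#' spec's symmetry, centred on the origin with the axis along +z (optionally
#' tilted by `axis_tilt` about x).
#'
#' @param spec a [filament_spec].
#' @return An [atomic_model] with `n_subunits` atoms.
#' @export
build_filament_model <- function(spec) {
  stopifnot(inherits(spec, "filament_spec"))
  k <- seq_len(spec$n_subunits) - 1
  ang <- k * spec$symmetry$twist * pi / 180
  xyz <- cbind(spec$subunit_radius * cos(ang),
               spec$subunit_radius * sin(ang),
               k * spec$symmetry$rise - (spec$n_subunits - 1) * spec$symmetry$rise / 2)
  if (spec$axis_tilt != 0) xyz <- xyz %*% t(rot_x(spec$axis_tilt))
  m <- atomic_model(xyz, label = "SUB")
  attr(m, "subunit_sigma") <- spec$subunit_sigma
  m
}

#' Microtubule generator parameters
#'
#' An n-protofilament microtubule: straight columns of subunits equally
#' spaced on a circle of `wall_radius`, with exact n-fold rotational symmetry
#' of the cross-section, and optionally a helical filament placed in the
#' lumen on the same axis.
#'
#' @param n_protofilaments integer in 11..17.
#' @param wall_radius radius of the protofilament circle, Angstrom. Default
#'   105 A for 13 protofilaments, scaled proportionally for other counts.
#' @param pf_subunit_rise axial spacing of subunits within a protofilament,
#'   Angstrom (tubulin monomer spacing ~40 A).
#' @param length microtubule length, Angstrom.
#' @param lumen_filament optional [filament_spec] for a lumenal filament.
#' @return An object of class `microtubule_spec`.
#' @export
microtubule_spec <- function(n_protofilaments, wall_radius = NULL,
                             pf_subunit_rise = 40, length = 800,
                             lumen_filament = NULL) {
  n <- as.integer(n_protofilaments)
  if (is.na(n) || n < 11L || n > 17L)
    stop("`n_protofilaments` must be an integer in 11..17")
  if (is.null(wall_radius)) wall_radius <- 105 * n / 13
  if (!is.null(lumen_filament)) {
    stopifnot(inherits(lumen_filament, "filament_spec"))
    if (wall_radius <= lumen_filament$subunit_radius + 10)
      stop("lumen filament too wide: wall_radius must exceed the filament ",
           "subunit_radius by more than 10 A")
  }
  structure(list(n_protofilaments = n, wall_radius = wall_radius,
                 pf_subunit_rise = pf_subunit_rise, length = length,
                 lumen_filament = lumen_filament),
            class = "microtubule_spec")
}

#' Build a pseudo-atomic microtubule model
#'
#' Protofilament j is a straight column of subunits at azimuth `360*j/n`
#' on the wall circle, so the wall cross-section is exactly Cn-symmetric.
#' When a lumen filament is specified its helical model is appended on the
#' same axis (truncated to the microtubule length), which breaks the lumen
#' symmetry but leaves the wall untouched.
#'
#' @param spec a [microtubule_spec].
#' @return An [atomic_model]; wall atoms are labelled `"WALL"`, lumen atoms
#'   `"SUB"`.
#' @export
build_microtubule_model <- function(spec) {
  stopifnot(inherits(spec, "microtubule_spec"))
  n_z <- max(2L, floor(spec$length / spec$pf_subunit_rise))
  z <- (seq_len(n_z) - 1) * spec$pf_subunit_rise
  z <- z - mean(z)
  ang <- 2 * pi * (seq_len(spec$n_protofilaments) - 1) / spec$n_protofilaments
  wall <- cbind(rep(spec$wall_radius * cos(ang), each = n_z),
                rep(spec$wall_radius * sin(ang), each = n_z),
                rep(z, times = spec$n_protofilaments))
  xyz <- wall
  lab <- rep("WALL", nrow(wall))
  if (!is.null(spec$lumen_filament)) {
    fil <- build_filament_model(spec$lumen_filament)
    keep <- abs(fil$xyz[, 3]) <= max(abs(z))
    if (sum(keep) >= 2) {
      xyz <- rbind(xyz, fil$xyz[keep, , drop = FALSE])
      lab <- c(lab, rep("SUB", sum(keep)))
    }
  }
  atomic_model(xyz, label = lab)
}

#' Render an atomic model as a density volume
#'
#' Sum of isotropic Gaussians, one per atom, with kernel width
#' `sigma = resolution / (pi * sqrt(2))` (so that the Fourier amplitude falls
#' to 1/e of its peak at spatial frequency 1/resolution). Each atom's
#' Gaussian is normalized to integrate to its mass weight, making the total
#' integrated density proportional to total mass. Rendering is deterministic.
#'
#' @param model an [atomic_model]. A per-atom `subunit_sigma` attribute (set
#'   by [build_filament_model()]) is added in quadrature to the kernel.
#' @param voxel_size voxel edge, Angstrom.
#' @param box integer length-3 grid dimensions (nx, ny, nz).
#' @param resolution nominal resolution of the render, Angstrom.
#' @param center center the model in the box? Default `TRUE`.
#' @return A [volume_grid] with origin chosen so the grid is centred on the
#'   (centred) model.
#' @export
render_density <- function(model, voxel_size, box, resolution = 20,
                           center = TRUE) {
  stopifnot(inherits(model, "atomic_model"))
  if (length(box) != 3L || any(box < 8))
    stop("`box` must give three grid dimensions, each >= 8")
  box <- as.integer(box)
  sigma <- resolution / (pi * sqrt(2))
  extra <- attr(model, "subunit_sigma")
  if (!is.null(extra) && extra > 0) sigma <- sqrt(sigma^2 + extra^2)

  xyz <- model$xyz
  if (center) xyz <- sweep(xyz, 2, colMeans(xyz))
  # physical box spans [-box/2, box/2] * voxel_size around the model centre
  origin <- -box * voxel_size / 2
  idx <- sweep(xyz, 2, origin) / voxel_size + 0.5   # fractional voxel index
  outside <- idx[, 1] < 1 | idx[, 1] > box[1] |
             idx[, 2] < 1 | idx[, 2] > box[2] |
             idx[, 3] < 1 | idx[, 3] > box[3]
  if (any(outside))
    stop(sum(outside), " atom(s) fall outside the rendering box; ",
         "enlarge `box` or recentre the model")

  vals <- array(0, dim = box)
  cut <- ceiling(4 * sigma / voxel_size)
  amp <- model$mass_weight / (sqrt(2 * pi) * sigma)^3 * voxel_size^3
  for (a in seq_len(nrow(xyz))) {
    i0 <- pmax(1L, floor(idx[a, ] - cut)); i1 <- pmin(box, ceiling(idx[a, ] + cut))
    xs <- i0[1]:i1[1]; ys <- i0[2]:i1[2]; zs <- i0[3]:i1[3]
    gx <- exp(-((xs - idx[a, 1]) * voxel_size)^2 / (2 * sigma^2))
    gy <- exp(-((ys - idx[a, 2]) * voxel_size)^2 / (2 * sigma^2))
    gz <- exp(-((zs - idx[a, 3]) * voxel_size)^2 / (2 * sigma^2))
    vals[xs, ys, zs] <- vals[xs, ys, zs] +
      amp[a] * (gx %o% gy %o% gz)
  }
  volume_grid(vals, voxel_size = voxel_size, origin = origin)
}

#' Convenience: render a filament spec directly
#'
#' Builds the pseudo-atomic model and renders it with an automatically sized
#' box (transverse extent padded well beyond the filament envelope).
#'
#' @param spec a [filament_spec].
#' @param voxel_size voxel edge, Angstrom.
#' @param resolution render resolution, Angstrom.
#' @param box optional explicit grid dimensions.
#' @return A [volume_grid].
#' @export
render_filament <- function(spec, voxel_size = 5, resolution = 20, box = NULL) {
  model <- build_filament_model(spec)
  if (is.null(box)) {
    half_xy <- spec$subunit_radius + resolution + 10
    nxy <- 2 * ceiling(half_xy / voxel_size)
    span_z <- diff(range(model$xyz[, 3])) + 2 * resolution + 20
    nz <- ceiling(span_z / voxel_size)
    box <- c(nxy, nxy, nz)
  }
  render_density(model, voxel_size, box, resolution)
}

#' Tomographic noise model
#'
#' Additive white Gaussian noise at a stated signal-to-noise ratio plus an
#' optional missing wedge. `snr` is the ratio of signal variance (inside the
#' object support, taken as voxels above 10 percent of the maximum) to noise
#' variance. `wedge_half_angle` is the tomographic tilt half-range: with the
#' tilt axis along y and the beam along z, Fourier components whose (kx, kz)
#' direction lies within `90 - wedge_half_angle` degrees of the kz axis are
#' unmeasured and are zeroed; 90 means no wedge.
#'
#' @param snr positive signal-to-noise ratio.
#' @param wedge_half_angle degrees in (0, 90].
#' @param seed integer seed making the noise reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(snr = 1, wedge_half_angle = 90, seed = 0) {
  if (!is.finite(snr) || snr <= 0) stop("`snr` must be positive")
  if (wedge_half_angle <= 0 || wedge_half_angle > 90)
    stop("`wedge_half_angle` must be in (0, 90] degrees")
  structure(list(snr = snr, wedge_half_angle = wedge_half_angle,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# fft frequency coordinates (cycles per sample), unshifted DFT order
fft_freq <- function(n) {
  f <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
  f[seq_len(n)]
}

#' Degrade a volume with noise and a missing wedge
#'
#' Adds Gaussian noise scaled to the requested SNR, then (if
#' `wedge_half_angle < 90`) zeroes the Fourier components inside the missing
#' wedge. Deterministic for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param vol a [volume_grid].
#' @param noise a [noise_model].
#' @return A [volume_grid] of the same geometry.
#' @export
add_noise_and_wedge <- function(vol, noise) {
  stopifnot(inherits(vol, "volume_grid"), inherits(noise, "noise_model"))
  v <- vol$values
  mask <- v > 0.1 * max(v)
  if (!any(mask)) mask <- rep(TRUE, length(v))
  sig_var <- stats::var(as.vector(v[mask]))
  noise_sd <- sqrt(sig_var / noise$snr)
  out <- v + with_seed(noise$seed, array(stats::rnorm(length(v), sd = noise_sd),
                                         dim = dim(v)))
  if (noise$wedge_half_angle < 90) {
    d <- dim(out)
    kx <- fft_freq(d[1]); kz <- fft_freq(d[3])
    # angle of (kx, kz) from the kz axis, per (x, z) pair
    ang <- atan2(abs(kx)[rep(seq_len(d[1]), times = d[3])],
                 abs(kz)[rep(seq_len(d[3]), each = d[1])]) * 180 / pi
    missing <- ang < (90 - noise$wedge_half_angle)
    miss_xz <- array(missing, dim = c(d[1], d[3]))
    miss3 <- aperm(array(miss_xz, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
    ft <- stats::fft(out)
    ft[miss3] <- 0
    out <- Re(stats::fft(ft, inverse = TRUE)) / length(ft)
  }
  vol$values <- out
  vol
}

# run code with a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a decorated (cofilactin-like) filament model
#'
#' The core helix of `spec` plus one decorator pseudo-atom per subunit at a
#' larger radius, sharing the core symmetry -- a minimal stand-in for a
#' fully decorated filament, where a bound protein thickens the filament
#' without changing its helical lattice. Fitting only the core model into a
#' map rendered from the decorated model leaves the decorator shell
#' unexplained, which is what drives the under-fit score contrast between
#' bare and decorated candidate models.
#'
#' @param spec a [filament_spec] for the core.
#' @param decorator_radius radial position of decorator atoms, Angstrom.
#' @param decorator_weight mass weight of each decorator atom relative to a
#'   core subunit.
#' @param decorator_azimuth azimuthal offset of the decorator from its core
#'   subunit, degrees.
#' @return An [atomic_model]; core atoms are labelled `"SUB"`, decorator
#'   atoms `"DEC"`.
#' @export
build_decorated_filament_model <- function(spec, decorator_radius = 48,
                                           decorator_weight = 0.8,
                                           decorator_azimuth = 25) {
  core <- build_filament_model(spec)
  k <- seq_len(spec$n_subunits) - 1
  ang <- (k * spec$symmetry$twist + decorator_azimuth) * pi / 180
  dec <- cbind(decorator_radius * cos(ang),
               decorator_radius * sin(ang),
               k * spec$symmetry$rise)
  dec[, 3] <- dec[, 3] - mean(dec[, 3])
  m <- atomic_model(rbind(core$xyz, dec),
                    mass_weight = c(core$mass_weight,
                                    rep(decorator_weight, nrow(dec))),
                    label = c(core$label, rep("DEC", nrow(dec))))
  attr(m, "subunit_sigma") <- spec$subunit_sigma
  m
}
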