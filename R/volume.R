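# 3D density volumes on a regular grid.
#
# Conventions used throughout the package:
#   * right-handed coordinates, helix/filament axis along +z;
#   * the grid is stored as an R array with dim = c(nx, ny, nz), so the x
#     index is fastest in memory, matching the MRC column/row/section layout
#     (slowest -> fastest = z, y, x);
#   * voxel (1,1,1) occupies the corner at `origin`; the center of voxel
#     (i,j,k) is at origin + (c(i,j,k) - 0.5) * voxel_size (Angstrom).

#' Construct a density volume
#'
#' A `volume_grid` carries a 3D scalar field together with its physical
#' calibration: an isotropic voxel size in Angstrom and the position of the
#' grid corner. It is the common currency of every stage of the pipeline,
#' from synthetic tomogram generation to helical reconstruction and map
#' fitting.
#'
#' @param values 3D numeric array, dim = c(nx, ny, nz); x index fastest.
#' @param voxel_size isotropic voxel edge length in Angstrom (> 0).
#' @param origin physical position (Angstrom, length-3) of the grid corner.
#' @return An object of class `volume_grid` with fields `values`,
#'   `voxel_size` and `origin`.
#' @examples
#' v <- volume_grid(array(0, c(8, 8, 8)), voxel_size = 5)
#' dim(v$values)
#' @export
volume_grid <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || !is.finite(voxel_size) ||
      voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (Angstrom)")
  if (!all(is.finite(values)))
    stop("volume values must all be finite")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be a finite length-3 vector (Angstrom)")
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.4g A/voxel (%.0f x %.0f x %.0f A)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  cat(sprintf("  origin (A): %.2f %.2f %.2f; range: %.4g .. %.4g\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# physical coordinates (A) of voxel centers along one axis
axis_coords <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$voxel_size
}

#' Read an MRC2014 volume
#'
#' Reads a density map in MRC2014 format. Modes 0 (int8), 1 (int16),
#' 2 (float32) and 6 (uint16) are accepted and converted to numeric; only
#' cubic/orthorhombic cells with isotropic voxels are supported. The voxel
#' size is taken from the header cell dimensions divided by the sampling
#' (CELLA / MX), and the physical origin from the ORIGIN header words.
#'
#' @param path path to an MRC file.
#' @return A [volume_grid].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")

  nxyz <- ri(3)                      # NX NY NZ
  mode <- ri(1)
  ri(3)                              # NXSTART..
  mxyz <- ri(3)                      # MX MY MZ
  cella <- rf(3)                     # cell edges, A
  cellb <- rf(3)                     # cell angles
  mapcrs <- ri(3)                    # axis correspondence
  rf(3)                              # DMIN DMAX DMEAN
  ri(1)                              # ISPG
  nsymbt <- ri(1)
  ri(25)                             # EXTRA (incl. EXTTYP/NVERSION)
  org <- rf(3)                       # ORIGIN
  readBin(con, "raw", n = 4)         # "MAP "
  readBin(con, "raw", n = 4)         # MACHST
  rf(1)                              # RMS
  ri(1)                              # NLABL
  readBin(con, "raw", n = 800)       # labels

  if (any(nxyz < 1L) || any(is.na(nxyz)))
    stop("malformed MRC header: NX/NY/NZ must be positive (got ",
         paste(nxyz, collapse = " "), ")")
  if (!mode %in% c(0L, 1L, 2L, 6L))
    stop("malformed MRC header: unsupported MODE ", mode,
         " (modes 0, 1, 2, 6 are readable)")
  if (any(mxyz < 1L))
    stop("malformed MRC header: MX/MY/MZ must be positive")
  if (any(!is.finite(cella)) || any(cella <= 0))
    stop("malformed MRC header: CELLA cell dimensions must be positive")
  if (any(abs(cellb - 90) > 1e-3))
    stop("malformed MRC header: CELLB angles must be 90 degrees ",
         "(orthorhombic cells only)")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("malformed MRC header: MAPC/MAPR/MAPS must be 1 2 3")
  vox <- cella / mxyz
  if (max(vox) - min(vox) > 1e-3 * mean(vox))
    stop("anisotropic voxels are not supported (voxel sizes ",
         paste(signif(vox, 6), collapse = " x "), " A)")
  if (nsymbt > 0L) readBin(con, "raw", n = nsymbt)

  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                             endian = "little")))
  if (length(vals) != n)
    stop("truncated MRC data block: expected ", n, " voxels, got ", length(vals))
  volume_grid(array(vals, dim = nxyz), voxel_size = mean(vox), origin = org)
}

#' Write an MRC2014 volume
#'
#' Writes a [volume_grid] as MRC2014 mode 2 (32-bit float). Data written in
#' mode 2 round-trips bit-exactly through [read_volume()] once the values are
#' representable in single precision.
#'
#' @param vol a [volume_grid].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  d <- dim(vol$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")

  wi(d); wi(2L)                                  # NX NY NZ, MODE 2
  wi(c(0L, 0L, 0L))                              # NXSTART..
  wi(d)                                          # MX MY MZ
  wf(d * vol$voxel_size)                         # CELLA
  wf(c(90, 90, 90))                              # CELLB
  wi(1:3)                                        # MAPC MAPR MAPS
  wf(c(min(vol$values), max(vol$values), mean(vol$values)))
  wi(c(1L, 0L))                                  # ISPG, NSYMBT
  wi(rep(0L, 2))                                 # EXTRA words 26-27
  wi(20140L)                                     # NVERSION
  wi(rep(0L, 22))                                # EXTRA words 29-49 (22 words)
  wf(vol$origin)                                 # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(vol$values))                      # RMS
  wi(1L)                                         # NLABL
  lab <- charToRaw(sprintf("%-80s", "helixline"))
  writeBin(c(lab, raw(800 - length(lab))), con)
  wf(vol$values)
  invisible(path)
}

#' Invert the density contrast of a volume
#'
#' Cryo-tomograms of unstained specimens are protein-dark; reconstruction and
#' fitting operate on protein-positive maps. This negates every voxel and
#' re-centers the mean at zero, so applying it twice returns the input up to
#' a mean shift.
#'
#' @param vol a [volume_grid].
#' @return A [volume_grid] with inverted, zero-mean values.
#' @export
invert_density <- function(vol) {
  stopifnot(inherits(vol, "volume_grid"))
  v <- -vol$values
  vol$values <- v - mean(v)
  vol
}

# Trilinear interpolation of `values` at fractional voxel indices (1-based,
# voxel centers at integer indices). Returns values (0 outside) and an
# inside-support mask. Workhorse behind straightening, helical averaging and
# rotational averaging.
trilinear_sample <- function(values, x, y, z) {
  d <- dim(values)
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  # points exactly on the far grid plane interpolate from the last cell
  x0 <- ifelse(x0 >= d[1], d[1] - 1, x0)
  y0 <- ifelse(y0 >= d[2], d[2] - 1, y0)
  z0 <- ifelse(z0 >= d[3], d[3] - 1, z0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x0c <- pmin(pmax(x0, 1L), d[1] - 1L)
  y0c <- pmin(pmax(y0, 1L), d[2] - 1L)
  z0c <- pmin(pmax(z0, 1L), d[3] - 1L)
  nxy <- d[1] * d[2]
  base <- (x0c) + (y0c - 1) * d[1] + (z0c - 1) * nxy
  v000 <- values[base]
  v100 <- values[base + 1]
  v010 <- values[base + d[1]]
  v110 <- values[base + d[1] + 1]
  v001 <- values[base + nxy]
  v101 <- values[base + nxy + 1]
  v011 <- values[base + nxy + d[1]]
  v111 <- values[base + nxy + d[1] + 1]
  w <- (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
       (v010 * (1 - fx) + v110 * fx) * fy       * (1 - fz) +
       (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
       (v011 * (1 - fx) + v111 * fx) * fy       * fz
  w[!inside] <- 0
  list(values = w, inside = inside)
}

#' Crop a volume to its object support in x and y
#'
#' Finds the transverse support of the object from the volume's summed x
#' and y intensity profiles (above `threshold` of the profile maximum),
#' then crops to a window centred on the support's intensity centroid with
#' a symmetric half-width covering the support plus `margin` Angstrom.
#' Centring matters: downstream rotational operations (helical averaging,
#' protofilament scans) rotate about the grid centre, so the object axis
#' must land there. Tightening the box around an extracted filament also
#' removes empty, noise-only voxels and materially improves layer-line
#' contrast on noisy data.
#'
#' @param vol a [volume_grid].
#' @param margin padding around the detected support, Angstrom.
#' @param threshold fraction of the profile maximum defining the support.
#' @return A cropped [volume_grid] (origin adjusted accordingly).
#' @export
crop_to_object <- function(vol, margin = 15, threshold = 0.2) {
  stopifnot(inherits(vol, "volume_grid"))
  v <- vol$values
  m <- ceiling(margin / vol$voxel_size)
  window <- function(prof, n) {
    sup <- which(prof > threshold * max(prof))
    w <- pmax(prof[sup] - threshold * max(prof), 0)
    ctr <- sum(sup * w) / sum(w)
    half <- max(abs(range(sup) - ctr)) + m
    lo <- max(1, floor(ctr - half))
    hi <- min(n, ceiling(ctr + half))
    c(lo, hi)
  }
  rx <- window(apply(v, 1, sum), dim(v)[1])
  ry <- window(apply(v, 2, sum), dim(v)[2])
  vol$origin <- vol$origin + c(rx[1] - 1, ry[1] - 1, 0) * vol$voxel_size
  vol$values <- v[rx[1]:rx[2], ry[1]:ry[2], , drop = FALSE]
  vol
}

#' Low-pass filter a volume to a stated resolution
#'
#' Multiplies the Fourier transform by the same Gaussian kernel used for
#' rendering (`sigma = resolution / (pi * sqrt(2))` in real space), i.e.
#' `exp(-2 pi^2 sigma^2 q^2)`. Matching a noisy map to the resolution of a
#' simulated model map before correlation scoring removes the noise power
#' beyond the band that carries signal.
#'
#' @param vol a [volume_grid].
#' @param resolution target resolution, Angstrom.
#' @return A filtered [volume_grid].
#' @export
lowpass_volume <- function(vol, resolution) {
  stopifnot(inherits(vol, "volume_grid"))
  d <- dim(vol$values)
  sigma <- resolution / (pi * sqrt(2))
  fx <- fft_freq(d[1]) / vol$voxel_size
  fy <- fft_freq(d[2]) / vol$voxel_size
  fz <- fft_freq(d[3]) / vol$voxel_size
  q2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
  ft <- stats::fft(vol$values) * exp(-2 * pi^2 * sigma^2 * q2)
  vol$values <- Re(stats::fft(ft, inverse = TRUE)) / length(ft)
  vol
}

#' Resample a volume onto another volume's grid
#'
#' Trilinear interpolation of `vol` at the physical voxel-centre positions
#' of `ref`; positions outside `vol` become zero. Use before
#' [correlation_score()] when two maps live on different grids.
#'
#' @param vol the [volume_grid] to resample.
#' @param ref the [volume_grid] whose grid geometry to adopt.
#' @return A [volume_grid] with `ref`'s dimensions, voxel size and origin.
#' @export
resample_volume <- function(vol, ref) {
  stopifnot(inherits(vol, "volume_grid"), inherits(ref, "volume_grid"))
  d <- dim(ref$values)
  cx <- axis_coords(ref, 1); cy <- axis_coords(ref, 2); cz <- axis_coords(ref, 3)
  xi <- (cx - vol$origin[1]) / vol$voxel_size + 0.5
  yi <- (cy - vol$origin[2]) / vol$voxel_size + 0.5
  zi <- (cz - vol$origin[3]) / vol$voxel_size + 0.5
  x3 <- array(rep(xi, times = d[2] * d[3]), dim = d)
  y3 <- array(rep(rep(yi, each = d[1]), times = d[3]), dim = d)
  z3 <- array(rep(zi, each = d[1] * d[2]), dim = d)
  sm <- trilinear_sample(vol$values, x3, y3, z3)
  volume_grid(array(sm$values, dim = d), ref$voxel_size, ref$origin)
}
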