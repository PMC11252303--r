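# Layer-line analysis: crossover spacing, genetic pitch and axial rise
# measured from the power spectrum of a projected filament, and the class
# assignment derived from the crossover.
#
# For a helix with rise h and twist t (degrees), three periodicities matter:
#   crossover   C = h * 180 / (180 - |t|)   (lowest layer line, ~2-start)
#   genetic pitch   360 * h / |t|           (strong ~60 A layer line)
#   rise        h                           (meridional layer line)
# and the twist can be recovered two independent ways:
#   t = 180 * (1 - h / C)  and  t = 360 * h / pitch.

#' Project a filament volume to a 2D image
#'
#' Sums the volume along one transverse axis (default y, i.e. the viewing
#' direction), producing an image whose columns run along the filament axis
#' z. The filament must already be straight and axis-aligned (see
#' [straighten()]).
#'
#' @param vol a [volume_grid] with the filament axis along z.
#' @param axis projection axis, `"y"` or `"x"`.
#' @return A numeric matrix (transverse x axial) of class
#'   `filament_projection` with attribute `pixel_size` (Angstrom).
#' @export
project_filament <- function(vol, axis = c("y", "x")) {
  stopifnot(inherits(vol, "volume_grid"))
  axis <- match.arg(axis)
  d <- dim(vol$values)
  ax <- if (axis == "y") 2L else 1L
  if (d[ax] < 3)
    stop("volume is thinner than 3 voxels along the projection axis")
  img <- apply(vol$values, c(if (axis == "y") 1L else 2L, 3L), sum)
  structure(img, pixel_size = vol$voxel_size, class = "filament_projection")
}

# split-cosine (Tukey) taper of length n with tapered fraction `frac` per end
tukey_window <- function(n, frac) {
  if (frac <= 0) return(rep(1, n))
  m <- max(1L, round(frac * n))
  w <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 0.5) / m))
  w[seq_len(m)] <- ramp
  w[n + 1 - seq_len(m)] <- ramp
  w
}

#' Power spectrum of a projected filament
#'
#' Modulus of the 2D discrete Fourier transform of the mean-subtracted,
#' edge-tapered, zero-padded image, with DC shifted to the grid centre and
#' both frequency axes calibrated in 1/Angstrom from the pixel size.
#'
#' @param img a `filament_projection` (or matrix with a `pixel_size`
#'   attribute), transverse x axial.
#' @param pad_factor zero-padding factor (>= 1); padding refines the
#'   frequency sampling used by sub-pixel peak interpolation.
#' @param taper_fraction fraction of each image edge blended to zero with a
#'   split-cosine ramp before transforming.
#' @return An object of class `power_spectrum` with fields `amplitudes`
#'   (transverse x axial, DC at centre), `freq_transverse`, `freq_axial`
#'   (1/Angstrom), `pixel_size` and the pre-padding image dimensions.
#' @export
compute_power_spectrum <- function(img, pad_factor = 4, taper_fraction = 0.2) {
  px <- attr(img, "pixel_size")
  if (is.null(px)) stop("`img` must carry a `pixel_size` attribute (Angstrom)")
  img <- unclass(img)
  d <- dim(img)
  if (d[2] < 64)
    stop("image must be at least 64 pixels along the filament axis")
  if (pad_factor < 1) stop("`pad_factor` must be >= 1")
  img <- img - mean(img)
  img <- img * (tukey_window(d[1], taper_fraction) %o%
                tukey_window(d[2], taper_fraction))
  np <- round(d * pad_factor)
  padded <- matrix(0, np[1], np[2])
  padded[seq_len(d[1]), seq_len(d[2])] <- img
  ft <- stats::fft(padded)
  amp <- Mod(ft)
  # shift DC to the centre
  cx <- floor(np[1] / 2); cz <- floor(np[2] / 2)
  amp <- amp[c((cx + 1):np[1], 1:cx), c((cz + 1):np[2], 1:cz)]
  freq_t <- (seq_len(np[1]) - (np[1] - cx + 1)) / (np[1] * px)
  freq_a <- (seq_len(np[2]) - (np[2] - cz + 1)) / (np[2] * px)
  structure(list(amplitudes = amp, freq_transverse = freq_t, freq_axial = freq_a,
                 pixel_size = px, image_dim = d,
                 step_transverse = 1 / (np[1] * px),
                 step_axial = 1 / (np[2] * px)),
            class = "power_spectrum")
}

# 3-point parabolic sub-pixel refinement on log-amplitude; returns the
# fractional offset of the true peak from the integer maximum
parabolic_offset <- function(lm1, l0, lp1) {
  den <- lm1 - 2 * l0 + lp1
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (lm1 - lp1) / den
  max(-0.5, min(0.5, off))
}

#' Detect layer lines in a power spectrum
#'
#' Collapses the spectrum onto the axial frequency axis by averaging the
#' spectral power (squared amplitude) over a transverse band (meridian
#' included, so both meridional and off-meridional lines register),
#' excluding the equator's immediate neighbourhood, and returns every local
#' maximum of the collapsed profile exceeding `median + noise_k * MAD`.
#' Power rather than amplitude is averaged because a layer line confined to
#' a few transverse frequency cells then stands further above the flat
#' noise background of a tomographic projection. Peak positions are refined by 3-point
#' parabolic interpolation of the log amplitude; a peak is flagged meridional
#' when the transverse position of its amplitude maximum lies within one
#' transverse frequency step of the meridian.
#'
#' @param ps a [compute_power_spectrum()] result.
#' @param noise_k detection threshold in robust standard deviations above
#'   the median of the collapsed profile.
#' @param r_max transverse band half-width, 1/Angstrom.
#' @param exclude_equator number of pre-padding frequency rows next to the
#'   equator excluded from the search (the filament envelope dominates
#'   there).
#' @param min_rel relative floor: peaks weaker than this fraction of the
#'   strongest in-band power are ignored, which suppresses window sidelobes
#'   in noise-free spectra where the MAD of the profile is tiny.
#' @return A data frame of class `layer_lines` with columns
#'   `axial_frequency` (1/A), `spacing` (A), `peak_amplitude`, `snr` (the
#'   peak's height above the profile median in robust standard deviations),
#'   `transverse_frequency` of the in-row amplitude maximum, and
#'   `on_meridian`; sorted by axial frequency. Zero rows when nothing
#'   exceeds the threshold.
#' @export
detect_layer_lines <- function(ps, noise_k = 5, r_max = 0.025,
                               exclude_equator = 2, min_rel = 0.05) {
  stopifnot(inherits(ps, "power_spectrum"))
  band <- abs(ps$freq_transverse) <= r_max
  prof <- colMeans(ps$amplitudes[band, , drop = FALSE]^2)
  excl <- exclude_equator / (ps$image_dim[2] * ps$pixel_size)
  use <- ps$freq_axial > excl & ps$freq_axial < max(ps$freq_axial) - ps$step_axial
  idx <- which(use)
  if (length(idx) < 3)
    return(.empty_layer_lines())
  p <- prof[idx]
  thr <- max(stats::median(p) + noise_k * stats::mad(p), min_rel * max(p))
  is_peak <- p > thr &
    p >= c(-Inf, p[-length(p)]) & p > c(p[-1], -Inf)
  peaks <- idx[is_peak]
  if (length(peaks) == 0) return(.empty_layer_lines())
  med <- stats::median(p)
  sdev <- stats::mad(p)
  rows <- lapply(peaks, function(i) {
    off <- parabolic_offset(log(prof[i - 1]), log(prof[i]), log(prof[i + 1]))
    f <- ps$freq_axial[i] + off * ps$step_axial
    rb <- which(band)
    tmax <- rb[which.max(ps$amplitudes[rb, i])]
    tf <- ps$freq_transverse[tmax]
    data.frame(axial_frequency = f, spacing = 1 / f, peak_amplitude = prof[i],
               snr = if (sdev > 0) (prof[i] - med) / sdev else Inf,
               transverse_frequency = tf,
               on_meridian = abs(tf) <= ps$step_transverse + 1e-12)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$axial_frequency), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("layer_lines", "data.frame")
  out
}

.empty_layer_lines <- function() {
  out <- data.frame(axial_frequency = numeric(0), spacing = numeric(0),
                    peak_amplitude = numeric(0), snr = numeric(0),
                    transverse_frequency = numeric(0),
                    on_meridian = logical(0))
  class(out) <- c("layer_lines", "data.frame")
  out
}

#' Derive helical parameters from detected layer lines
#'
#' The crossover spacing is read as the real-space spacing of the dominant
#' low-frequency layer line: among detected lines with spacing above
#' `min_crossover` the one with the strongest peak is taken (two-strand
#' crossovers of actin-like filaments lie at 24-41 nm, far above the
#' genetic-pitch and subunit-repeat lines, and marginal noise peaks or
#' higher-order lines in that region are always weaker); when no line lies
#' in that region the lowest-frequency detected line is used. The rise is
#' the spacing of the strongest meridional line; the genetic pitch the
#' spacing of the line nearest 60 A (within 40-90 A). The twist magnitude
#' is computed from crossover and rise as `180 * (1 - rise / crossover)`
#' and, when a genetic-pitch line is present, cross-checked against
#' `360 * rise / pitch`; a discrepancy of 2 degrees or more is flagged
#' (`consistent = FALSE`) and the crossover-route value retained.
#'
#' @param lines a [detect_layer_lines()] result with at least one row.
#' @param min_crossover lower bound (Angstrom) of the spacing region
#'   searched for the crossover line.
#' @return An object of class `helical_measurement` with fields `crossover`,
#'   `genetic_pitch`, `rise`, `twist_magnitude` (each possibly `NA`),
#'   `twist_from_pitch`, `consistent` and `route`.
#' @export
derive_helical_parameters <- function(lines, min_crossover = 150) {
  if (!inherits(lines, "data.frame") || nrow(lines) == 0)
    stop("measurement unavailable: no layer lines detected")
  low <- lines[lines$spacing > min_crossover, , drop = FALSE]
  crossover <- if (nrow(low) > 0)
    low$spacing[which.max(low$peak_amplitude)]
  else lines$spacing[which.min(lines$axial_frequency)]
  rise <- NA_real_
  mer <- lines[lines$on_meridian, , drop = FALSE]
  if (nrow(mer) > 0) rise <- mer$spacing[which.max(mer$peak_amplitude)]
  pitch <- NA_real_
  cand <- lines[lines$spacing > 40 & lines$spacing < 90, , drop = FALSE]
  if (nrow(cand) > 0) pitch <- cand$spacing[which.min(abs(cand$spacing - 60))]
  twist <- NA_real_
  twist_pitch <- NA_real_
  consistent <- NA
  route <- "crossover"
  if (is.finite(rise)) {
    twist <- 180 * (1 - rise / crossover)
    route <- "crossover+meridional"
    if (is.finite(pitch)) {
      twist_pitch <- 360 * rise / pitch
      consistent <- abs(twist - twist_pitch) < 2
      route <- "crossover+meridional+pitch"
    }
  }
  structure(list(crossover = crossover, genetic_pitch = pitch, rise = rise,
                 twist_magnitude = twist, twist_from_pitch = twist_pitch,
                 consistent = consistent, route = route),
            class = "helical_measurement")
}

#' @export
print.helical_measurement <- function(x, ...) {
  cat(sprintf("<helical_measurement> crossover %.1f A (%.2f nm)\n",
              x$crossover, x$crossover / 10))
  if (is.finite(x$rise)) cat(sprintf("  rise %.2f A", x$rise))
  if (is.finite(x$genetic_pitch))
    cat(sprintf("  genetic pitch %.2f A", x$genetic_pitch))
  if (is.finite(x$twist_magnitude))
    cat(sprintf("  twist %.2f deg [%s%s]", x$twist_magnitude, x$route,
                if (isFALSE(x$consistent)) ", INCONSISTENT" else ""))
  cat("\n")
  invisible(x)
}

#' Real-space crossover measurement (independent of the spectral route)
#'
#' Measures the crossover as the period of the axial autocorrelation of the
#' projection's transverse-width profile: in projection the filament is
#' narrow at strand crossings and wide between them, so the intensity-
#' weighted width oscillates with the crossover period. Serves as the
#' independent oracle for the layer-line route.
#'
#' The image is first blurred along the axis (sigma `blur_sigma` Angstrom)
#' so the subunit repeat does not punch holes in the intensity-weighted
#' width, and the width profile is then low-pass filtered (`smooth_sigma`)
#' before autocorrelation so subunit-scale beats cannot masquerade as the
#' crossover period.
#'
#' @param img a `filament_projection`.
#' @param min_peak minimum normalized autocorrelation at the period for it
#'   to count as a detection.
#' @param blur_sigma axial image blur, Angstrom.
#' @param smooth_sigma width-profile smoothing, Angstrom.
#' @return Crossover spacing in Angstrom.
#' @export
measure_crossover_realspace <- function(img, min_peak = 0.15,
                                        blur_sigma = 12, smooth_sigma = 25) {
  px <- attr(img, "pixel_size")
  if (is.null(px)) stop("`img` must carry a `pixel_size` attribute")
  im <- unclass(img)
  gauss_smooth_rows <- function(mat, sigma_px) {
    hw <- ceiling(3 * sigma_px)
    kern <- stats::dnorm(seq(-hw, hw), sd = sigma_px)
    kern <- kern / sum(kern)
    t(apply(mat, 1, function(row) {
      n0 <- length(row)
      rp <- c(rev(row[seq_len(hw)]), row, rev(row[n0 + 1 - seq_len(hw)]))
      as.numeric(stats::filter(rp, kern, sides = 2))[hw + seq_len(n0)]
    }))
  }
  if (blur_sigma > 0) im <- gauss_smooth_rows(im, blur_sigma / px)
  x <- seq_len(nrow(im))
  tot <- colSums(im)
  core <- which(tot > 0.5 * max(tot))
  cols <- core[1]:core[length(core)]
  w <- vapply(cols, function(j) {
    col <- im[, j]
    col[col < 0] <- 0
    if (sum(col) <= 0) return(NA_real_)
    mu <- sum(x * col) / sum(col)
    sqrt(sum((x - mu)^2 * col) / sum(col))
  }, numeric(1))
  w <- w[is.finite(w)]
  if (smooth_sigma > 0 && length(w) > 6) {
    hw <- ceiling(3 * smooth_sigma / px)
    kern <- stats::dnorm(seq(-hw, hw), sd = smooth_sigma / px)
    kern <- kern / sum(kern)
    n0 <- length(w)
    wp <- c(rev(w[seq_len(min(hw, n0))]), w, rev(w[n0 + 1 - seq_len(min(hw, n0))]))
    if (length(wp) >= 2 * hw + n0)
      w <- as.numeric(stats::filter(wp, kern, sides = 2))[hw + seq_len(n0)]
  }
  w <- w - mean(w)
  if (stats::sd(w) < 1e-9)
    stop("constant-width profile: no crossover period measurable")
  n <- length(w)
  ac <- stats::acf(w, lag.max = floor(n / 2), plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  ac <- ac / ac[1]
  # first local maximum beyond the initial decay
  lm <- which(diff(sign(diff(ac))) == -2) + 1
  lm <- lm[ac[lm] > min_peak]
  if (length(lm) == 0)
    stop("insufficient length: no crossover repeat found in the ",
         "autocorrelation (need at least two crossovers)")
  i <- lm[1]
  off <- parabolic_offset(ac[i - 1], ac[i], ac[i + 1])
  (i - 1 + off) * px
}

#' Classify a filament by its crossover spacing
#'
#' Short-crossover (cofilin-decorated morphology) filaments are labelled
#' `CLASS_I` when the crossover falls in the 24-31 nm band; canonical
#' F-actin in the 33-41 nm band; anything else is `UNCLASSIFIED`.
#'
#' @param m a [helical_measurement] (or a list with element `crossover` in
#'   Angstrom).
#' @param thresholds list with elements `class1` and `canonical`, each a
#'   length-2 crossover interval in Angstrom.
#' @return Character label: `"CLASS_I"`, `"CANONICAL"` or `"UNCLASSIFIED"`.
#' @export
classify_filament <- function(m, thresholds = list(class1 = c(240, 310),
                                                   canonical = c(330, 410))) {
  cx <- if (is.list(m)) m$crossover else m
  if (is.null(cx) || !is.finite(cx))
    stop("classification unavailable: crossover not set")
  if (cx >= thresholds$class1[1] && cx <= thresholds$class1[2]) "CLASS_I"
  else if (cx >= thresholds$canonical[1] && cx <= thresholds$canonical[2]) "CANONICAL"
  else "UNCLASSIFIED"
}

#' Meridional prominence of a spectrum
#'
#' Ratio of the strongest meridional layer-line amplitude to the strongest
#' off-meridional one. Filaments deviating from the F-actin-like pattern by
#' an unusually prominent meridional line can be annotated with this ratio;
#' it is reported as a diagnostic only, never as a class label.
#'
#' @param lines a [detect_layer_lines()] result.
#' @return Ratio (numeric), `NA` when either line set is empty.
#' @export
meridional_prominence <- function(lines) {
  mer <- lines$peak_amplitude[lines$on_meridian]
  off <- lines$peak_amplitude[!lines$on_meridian]
  if (length(mer) == 0 || length(off) == 0) return(NA_real_)
  max(mer) / max(off)
}
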