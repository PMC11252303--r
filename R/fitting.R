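# Rigid-body fitting of an atomic model into a density map, scored by
# normalized (Pearson) cross-correlation over a mask.

#' Simulate a density map from an atomic model
#'
#' Renders the model at the stated resolution on a grid matching `box` and
#' `voxel_size`, using the same Gaussian kernel convention as
#' [render_density()] (`sigma = resolution / (pi * sqrt(2))`).
#'
#' @param model an [atomic_model].
#' @param resolution target resolution, Angstrom; must be at least
#'   `2 * voxel_size` (the grid Nyquist limit).
#' @param voxel_size voxel edge, Angstrom.
#' @param box grid dimensions (3 integers).
#' @param center center the model in the box? Default `TRUE`.
#' @return A [volume_grid].
#' @export
simulate_map <- function(model, resolution, voxel_size, box, center = TRUE) {
  if (resolution < 2 * voxel_size)
    stop("`resolution` must be >= 2 * voxel_size (got ", resolution,
         " A at ", voxel_size, " A voxels)")
  render_density(model, voxel_size, box, resolution, center = center)
}

# robust maximum: upper quantile, insensitive to isolated hot voxels
robust_max <- function(x) stats::quantile(x, 0.999, names = FALSE)

#' Normalized cross-correlation between two maps
#'
#' Pearson correlation of voxel values over a mask. `mask_mode`
#' `"threshold_a"` (default) masks to voxels where the first map exceeds
#' half its robust maximum -- the first map is conventionally the simulated
#' model map, so the score measures agreement where the model predicts
#' density. `"overlap"` masks to voxels where both maps exceed their half
#' robust maxima (symmetric under swapping the maps); `"none"` uses every
#' voxel. The score is invariant under affine intensity rescaling of either
#' map.
#'
#' @param map_a,map_b [volume_grid]s on identical grids.
#' @param mask_mode `"threshold_a"`, `"overlap"` or `"none"`.
#' @return Correlation in `[-1, 1]`, with attribute `n_voxels_in_mask`.
#' @export
correlation_score <- function(map_a, map_b,
                              mask_mode = c("threshold_a", "overlap", "none")) {
  stopifnot(inherits(map_a, "volume_grid"), inherits(map_b, "volume_grid"))
  mask_mode <- match.arg(mask_mode)
  if (!identical(dim(map_a$values), dim(map_b$values)))
    stop("maps must be on identical grids (resample first)")
  a <- map_a$values; b <- map_b$values
  mask <- switch(mask_mode,
    threshold_a = a > 0.5 * robust_max(a),
    overlap     = a > 0.5 * robust_max(a) & b > 0.5 * robust_max(b),
    none        = rep(TRUE, length(a)))
  n <- sum(mask)
  if (n < 2) stop("empty correlation mask")
  r <- stats::cor(as.vector(a[mask]), as.vector(b[mask]))
  attr(r, "n_voxels_in_mask") <- n
  r
}

# integer-shift circular cross-correlation via FFT; returns the shift (in
# voxels, length 3) of `probe` that best aligns it to `target`
best_shift <- function(target_ft, probe) {
  pf <- stats::fft(probe - mean(probe))
  cc <- Re(stats::fft(target_ft * Conj(pf), inverse = TRUE))
  i <- which.max(cc)
  d <- dim(probe)
  i0 <- i - 1
  sx <- i0 %% d[1]
  sy <- (i0 %/% d[1]) %% d[2]
  sz <- i0 %/% (d[1] * d[2])
  s <- c(sx, sy, sz)
  ifelse(s > d / 2, s - d, s)
}

#' Rigid-body fit of a model into a density map
#'
#' Exhaustive coarse search over a uniform z-y-z Euler-angle grid; at each
#' orientation the optimal translation is found exactly (up to grid
#' precision) by the cross-correlation theorem, and orientations are ranked
#' by the whole-volume correlation at that optimum (the matched-filter
#' statistic, which varies smoothly with orientation). The `n_starts`
#' best-ranked candidates are polished by Nelder-Mead over all six rigid
#' parameters, again on the whole-volume correlation; the reported `score`
#' is the masked [correlation_score()] at the best refined pose. The angle
#' grid is enumerated in a fixed order (beta outer, then alpha, then gamma;
#' the alpha/gamma redundancy at beta = 0 or 180 is removed by fixing
#' alpha = 0 there) and ties keep the first candidate found, so the fit is
#' deterministic.
#'
#' @param model an [atomic_model].
#' @param target a protein-positive [volume_grid].
#' @param resolution resolution at which the model map is simulated,
#'   Angstrom.
#' @param search list of search options: `angle_step` (degrees, default 15),
#'   `alpha`, `beta`, `gamma` (optional numeric ranges, degrees, to restrict
#'   the grid, e.g. `beta = c(0, 30)`), `refine` (logical, default TRUE),
#'   `n_starts` (how many of the best coarse candidates to polish, default
#'   3), `maxit` (Nelder-Mead iterations per start).
#' @param mask_ref which map defines the correlation mask: `"probe"`
#'   (default) thresholds the simulated model map, measuring whether the
#'   model lands in density; `"target"` thresholds the experimental map,
#'   measuring whether the model explains all of the density -- the
#'   criterion that separates an under-filling bare model from a decorated
#'   one.
#' @param lowpass low-pass the target to `resolution` (via
#'   [lowpass_volume()]) before scoring. Recommended for noisy targets:
#'   the simulated probe is band-limited, so the out-of-band content of the
#'   target is pure noise as far as the score is concerned.
#' @return An object of class `fit_result`: `rotation` (Euler angles,
#'   degrees, z-y-z), `rotation_matrix`, `translation` (Angstrom), `score`,
#'   `n_voxels_in_mask` and the transformed model as `fitted_model`.
#' @export
rigid_body_fit <- function(model, target, resolution = 20, search = list(),
                           mask_ref = c("probe", "target"), lowpass = FALSE) {
  stopifnot(inherits(model, "atomic_model"), inherits(target, "volume_grid"))
  mask_ref <- match.arg(mask_ref)
  if (max(target$values) <= 0)
    stop("fit failed: no positive density in target map")
  opts <- utils::modifyList(list(angle_step = 15, alpha = c(0, 360),
                                 beta = c(0, 180), gamma = c(0, 360),
                                 refine = TRUE, n_starts = 3, maxit = 200),
                            search)
  if (isTRUE(lowpass)) target <- lowpass_volume(target, resolution)
  d <- dim(target$values)
  vx <- target$voxel_size
  tv <- target$values
  target_ft <- stats::fft(tv - mean(tv))

  seq_range <- function(r, step) {
    s <- seq(r[1], r[2], by = step)
    if (diff(r) >= 360) s <- s[-length(s)]   # drop the 360 == 0 duplicate
    s
  }
  alphas <- seq_range(opts$alpha, opts$angle_step)
  betas <- seq(opts$beta[1], opts$beta[2], by = opts$angle_step)
  gammas <- seq_range(opts$gamma, opts$angle_step)

  center0 <- colMeans(model$xyz)
  render_pose <- function(ang, tr) {
    m <- transform_model(model, euler_zyz(ang[1], ang[2], ang[3]),
                         translation = tr, center = center0)
    m$xyz <- sweep(m$xyz, 2, center0)  # model frame: grid centre
    tryCatch(render_density(m, vx, d, resolution, center = FALSE),
             error = function(e) NULL)
  }
  score_pose <- function(ang, tr) {
    probe <- render_pose(ang, tr)
    if (is.null(probe)) return(NULL)
    s <- tryCatch(
      if (mask_ref == "probe") correlation_score(probe, target)
      else correlation_score(target, probe),
      error = function(e) NULL)
    if (is.null(s)) return(NULL)
    list(score = as.numeric(s), n = attr(s, "n_voxels_in_mask"), probe = probe)
  }

  n_vox <- length(tv)
  sd_t <- stats::sd(tv)
  cands <- list()
  for (b in betas) {
    as_here <- if (b %in% c(0, 180)) 0 else alphas
    for (a in as_here) for (g in gammas) {
      probe <- render_pose(c(a, b, g), c(0, 0, 0))
      if (is.null(probe)) next
      pf <- stats::fft(probe$values - mean(probe$values))
      cc <- Re(stats::fft(target_ft * Conj(pf), inverse = TRUE)) / n_vox
      i0 <- which.max(cc) - 1
      sh <- c(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
      sh <- ifelse(sh > d / 2, sh - d, sh)
      gcor <- max(cc) * n_vox / ((n_vox - 1) * sd_t * stats::sd(probe$values))
      cands[[length(cands) + 1]] <- list(gcor = gcor, ang = c(a, b, g),
                                         tr = sh * vx)
    }
  }
  if (length(cands) == 0)
    stop("fit failed: no orientation produced a valid score")
  ord <- order(-vapply(cands, `[[`, 0, "gcor"))

  best <- NULL
  consider <- function(ang, tr) {
    cand <- score_pose(ang, tr)
    if (is.null(cand)) return(invisible(NULL))
    if (is.null(best) || cand$score > best$score)
      best <<- list(score = cand$score, ang = ang, tr = tr, n = cand$n)
    invisible(NULL)
  }
  tvec <- as.vector(tv)
  for (i in seq_len(min(opts$n_starts, length(cands)))) {
    start <- cands[[ord[i]]]
    consider(start$ang, start$tr)
    if (isTRUE(opts$refine)) {
      # optimize the whole-volume correlation: unlike the masked score it
      # varies smoothly with pose, so Nelder-Mead converges reliably
      obj <- function(p) {
        probe <- render_pose(p[1:3], p[4:6])
        if (is.null(probe)) return(1e6)
        -stats::cor(as.vector(probe$values), tvec)
      }
      op <- stats::optim(c(start$ang, start$tr), obj, method = "Nelder-Mead",
                         control = list(maxit = opts$maxit,
                                        parscale = c(5, 5, 5, vx, vx, vx),
                                        reltol = 1e-10))
      # restart once from the optimum: a fresh simplex escapes the
      # collapsed one and tightens the pose by another order of magnitude
      op <- stats::optim(op$par, obj, method = "Nelder-Mead",
                         control = list(maxit = opts$maxit,
                                        parscale = c(1, 1, 1, vx / 5, vx / 5,
                                                     vx / 5),
                                        reltol = 1e-10))
      consider(op$par[1:3], op$par[4:6])
    }
  }
  if (is.null(best))
    stop("fit failed: no orientation produced a valid score")

  fitted <- transform_model(model,
                            euler_zyz(best$ang[1], best$ang[2], best$ang[3]),
                            translation = best$tr, center = center0)
  structure(list(rotation = best$ang,
                 rotation_matrix = euler_zyz(best$ang[1], best$ang[2], best$ang[3]),
                 translation = best$tr, score = best$score,
                 n_voxels_in_mask = best$n, fitted_model = fitted),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> score %.4f over %d voxels\n", x$score,
              x$n_voxels_in_mask))
  cat(sprintf("  Euler z-y-z (deg): %.2f %.2f %.2f; translation (A): %.2f %.2f %.2f\n",
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}
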