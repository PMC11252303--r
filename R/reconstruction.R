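# Real-space helical reconstruction: straighten a traced filament, impose a
# (rise, twist) symmetry by rotate-and-shift averaging, and refine the
# symmetry by a deterministic grid search.

#' Filament centerline trace
#'
#' Ordered control points (Angstrom, volume frame) along a filament axis.
#'
#' @param points numeric n x 3 matrix of control points.
#' @return An object of class `centerline_trace`.
#' @export
centerline_trace <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("a centerline trace needs at least 2 points")
  if (ncol(points) != 3L || !all(is.finite(points)))
    stop("trace points must be finite x,y,z triples")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg <= 0))
    stop("consecutive trace points must be distinct (zero-length segment at ",
         "index ", which(seg <= 0)[1], ")")
  structure(list(points = unname(points), length = sum(seg)),
            class = "centerline_trace")
}

#' Read a centerline trace
#'
#' Accepts a CSV with header columns `x,y,z` or whitespace-separated
#' three-column point text (the subset of IMOD point files with one point
#' per line). Coordinates are Angstrom in the volume frame.
#'
#' @param path input file.
#' @return A [centerline_trace].
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1)
  pts <- if (grepl(",", first)) {
    df <- utils::read.csv(path)
    if (!all(c("x", "y", "z") %in% names(df)))
      stop("trace CSV must have columns x,y,z")
    as.matrix(df[, c("x", "y", "z")])
  } else {
    as.matrix(utils::read.table(path)[, 1:3])
  }
  centerline_trace(pts)
}

#' Straighten a filament along its traced centerline
#'
#' Fits a smooth cubic-spline curve through the trace, builds a
#' minimally-rotating (parallel-transported) frame along it, and resamples
#' the volume on planes normal to the curve so that the filament axis maps
#' to +z of the output. Interpolation is trilinear. A straight, axis-aligned
#' trace reproduces the corresponding crop of the input to interpolation
#' error.
#'
#' Output samples beyond the traced curve are zero and recorded in the
#' `usable_z` attribute, so short filaments are zero-padded to the requested
#' segment length rather than truncated.
#'
#' @param vol a [volume_grid].
#' @param trace a [centerline_trace] inside the volume.
#' @param out_length_px output length along z in pixels (default 512, a
#'   common segment length for per-filament reconstruction).
#' @param out_width_px transverse output size in pixels; defaults to the
#'   smaller transverse dimension of the input.
#' @return A [volume_grid] (voxel size preserved) with attribute `usable_z`,
#'   a logical vector marking output slices covered by the trace.
#' @export
straighten <- function(vol, trace, out_length_px = 512, out_width_px = NULL) {
  stopifnot(inherits(vol, "volume_grid"), inherits(trace, "centerline_trace"))
  d <- dim(vol$values)
  vx <- vol$voxel_size
  pts <- trace$points
  lo <- vol$origin
  hi <- vol$origin + d * vx
  out_of_bounds <- which(pts[, 1] < lo[1] | pts[, 1] > hi[1] |
                         pts[, 2] < lo[2] | pts[, 2] > hi[2] |
                         pts[, 3] < lo[3] | pts[, 3] > hi[3])
  if (length(out_of_bounds) > 0)
    stop("trace point ", out_of_bounds[1], " lies outside the volume")
  if (is.null(out_width_px)) out_width_px <- min(d[1], d[2])

  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  fx <- stats::splinefun(s, pts[, 1], method = "natural")
  fy <- stats::splinefun(s, pts[, 2], method = "natural")
  fz <- stats::splinefun(s, pts[, 3], method = "natural")
  total <- s[length(s)]

  n_out <- out_length_px
  t_out <- (seq_len(n_out) - (n_out + 1) / 2) * vx + total / 2
  usable <- t_out >= 0 & t_out <= total
  tc <- pmin(pmax(t_out, 0), total)

  centers <- cbind(fx(tc), fy(tc), fz(tc))
  tang <- cbind(fx(tc, deriv = 1), fy(tc, deriv = 1), fz(tc, deriv = 1))
  tang <- tang / sqrt(rowSums(tang^2))
  # parallel-transported normal frame
  u <- matrix(0, n_out, 3)
  pick <- which.min(abs(tang[1, ]))
  e <- c(0, 0, 0); e[pick] <- 1
  u0 <- e - sum(e * tang[1, ]) * tang[1, ]
  u[1, ] <- u0 / sqrt(sum(u0^2))
  for (k in seq_len(n_out)[-1]) {
    up <- u[k - 1, ] - sum(u[k - 1, ] * tang[k, ]) * tang[k, ]
    nu <- sqrt(sum(up^2))
    u[k, ] <- if (nu > 1e-8) up / nu else u[k - 1, ]
  }
  v <- cbind(tang[, 2] * u[, 3] - tang[, 3] * u[, 2],
             tang[, 3] * u[, 1] - tang[, 1] * u[, 3],
             tang[, 1] * u[, 2] - tang[, 2] * u[, 1])

  w <- out_width_px
  off <- (seq_len(w) - (w + 1) / 2) * vx
  # sample positions: centers[k] + off_i * u[k] + off_j * v[k]
  out <- array(0, dim = c(w, w, n_out))
  oi <- rep(off, times = w)
  oj <- rep(off, each = w)
  for (k in seq_len(n_out)) {
    if (!usable[k]) next
    px <- centers[k, 1] + oi * u[k, 1] + oj * v[k, 1]
    py <- centers[k, 2] + oi * u[k, 2] + oj * v[k, 2]
    pz <- centers[k, 3] + oi * u[k, 3] + oj * v[k, 3]
    sm <- trilinear_sample(vol$values,
                           (px - lo[1]) / vx + 0.5,
                           (py - lo[2]) / vx + 0.5,
                           (pz - lo[3]) / vx + 0.5)
    out[, , k] <- sm$values
  }
  res <- volume_grid(out, voxel_size = vx)
  attr(res, "usable_z") <- usable
  res
}

# Sample `vol` after rotating it by `angle` degrees about the z axis through
# the grid centre and shifting it by `shift` Angstrom along z. Pull-back
# trilinear sampling; returns values and inside-support mask.
helical_op_sample <- function(values, vx, angle, shift) {
  d <- dim(values)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  a <- -angle * pi / 180
  xs <- (seq_len(d[1]) - cx) * vx
  ys <- (seq_len(d[2]) - cy) * vx
  X <- matrix(xs, d[1], d[2])
  Y <- matrix(ys, d[1], d[2], byrow = TRUE)
  Xr <- (cos(a) * X - sin(a) * Y) / vx + cx
  Yr <- (sin(a) * X + cos(a) * Y) / vx + cy
  zi <- seq_len(d[3]) - shift / vx
  x3 <- array(Xr, dim = d)
  y3 <- array(Yr, dim = d)
  z3 <- array(rep(zi, each = d[1] * d[2]), dim = d)
  trilinear_sample(values, x3, y3, z3)
}

#' Impose helical symmetry by real-space averaging
#'
#' Averages the volume over `n_units` helical symmetry operations
#' `j * (rise, twist)` with `j` centred on zero, using trilinear resampling;
#' samples falling outside the volume are excluded with per-voxel weight
#' normalization, so the map has no wrap-around artifacts. The returned
#' `self_consistency` is the Pearson correlation of the averaged map with
#' itself after one further (rise, twist) operation, evaluated over the
#' overlap region.
#'
#' @param vol a straightened, protein-positive [volume_grid], axis along z.
#' @param sym a [helical_symmetry].
#' @param n_units number of asymmetric units averaged (>= 2 for a
#'   meaningful reconstruction; `n_units = 1` returns the input).
#' @return An object of class `reconstruction_result`: fields `map`
#'   ([volume_grid]), `symmetry_used`, `n_units_averaged` and
#'   `self_consistency`.
#' @export
helical_average <- function(vol, sym, n_units = 20) {
  stopifnot(inherits(vol, "volume_grid"), inherits(sym, "helical_symmetry"))
  d <- dim(vol$values)
  usable_len <- d[3] * vol$voxel_size
  if (n_units * sym$rise > usable_len)
    stop("n_units * rise exceeds the filament length; at most ",
         floor(usable_len / sym$rise), " units are usable")
  js <- seq_len(n_units) - 1 - floor((n_units - 1) / 2)
  acc <- array(0, dim = d)
  wt <- array(0, dim = d)
  for (j in js) {
    if (j == 0) {
      acc <- acc + vol$values
      wt <- wt + 1
    } else {
      sm <- helical_op_sample(vol$values, vol$voxel_size,
                              j * sym$twist, j * sym$rise)
      acc <- acc + sm$values
      wt <- wt + sm$inside
    }
  }
  avg <- acc / pmax(wt, 1e-12)
  avg[wt == 0] <- 0
  map <- volume_grid(avg, vol$voxel_size, vol$origin)
  sc <- .self_consistency(map, sym)
  structure(list(map = map, symmetry_used = sym,
                 n_units_averaged = as.integer(n_units),
                 self_consistency = sc),
            class = "reconstruction_result")
}

.self_consistency <- function(map, sym) {
  sm <- helical_op_sample(map$values, map$voxel_size, sym$twist, sym$rise)
  ok <- sm$inside
  if (sum(ok) < 10) return(NA_real_)
  stats::cor(map$values[ok], sm$values[ok])
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("<reconstruction_result> %d units averaged at rise %.2f A / twist %.2f deg\n",
              x$n_units_averaged, x$symmetry_used$rise, x$symmetry_used$twist))
  cat(sprintf("  self-consistency %.4f\n", x$self_consistency))
  invisible(x)
}

# split-half helical coherence: correlation between the averages over the
# even-j and odd-j symmetry operations, evaluated on a fixed subsampled
# point set. Unbiased for pure noise (the halves share no voxels of the
# input), unlike the self-correlation of the full average.
.split_half_objective <- function(values, vx, rise, twist, n_units, pts) {
  js <- seq_len(n_units) - 1 - floor((n_units - 1) / 2)
  acc <- list(e = 0, o = 0)
  wt <- list(e = 0, o = 0)
  for (idx in seq_along(js)) {
    j <- js[idx]
    half <- if (idx %% 2 == 0) "e" else "o"
    a <- -j * twist * pi / 180
    x <- cos(a) * pts$x - sin(a) * pts$y
    y <- sin(a) * pts$x + cos(a) * pts$y
    sm <- trilinear_sample(values, x / vx + pts$cx, y / vx + pts$cy,
                           pts$zi - j * rise / vx)
    acc[[half]] <- acc[[half]] + sm$values
    wt[[half]] <- wt[[half]] + sm$inside
  }
  ok <- wt$e > 0 & wt$o > 0
  if (sum(ok) < 10) return(NA_real_)
  stats::cor(acc$e[ok] / wt$e[ok], acc$o[ok] / wt$o[ok])
}

.refine_points <- function(d, vx, stride = 2) {
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  ix <- seq(1, d[1], by = stride)
  iy <- seq(1, d[2], by = stride)
  iz <- seq(max(1, round(0.1 * d[3])), min(d[3], round(0.9 * d[3])), by = stride)
  g <- expand.grid(x = (ix - cx) * vx, y = (iy - cy) * vx, zi = iz)
  r2 <- g$x^2 + g$y^2
  keep <- r2 <= (0.45 * min(d[1], d[2]) * vx)^2
  list(x = g$x[keep], y = g$y[keep], zi = g$zi[keep], cx = cx, cy = cy)
}

#' Refine helical symmetry by deterministic grid search
#'
#' Searches a (rise, twist) grid bracketing the initial estimate for the
#' parameters that maximize the split-half helical coherence: the
#' correlation between the maps averaged over the even-numbered and
#' odd-numbered symmetry operations. A coarse pass at (`rise_step`,
#' `twist_step`) is followed by a local pass at a quarter of each step. The
#' grid is enumerated in a fixed order and ties are broken toward the
#' smaller twist magnitude, so the result is reproducible.
#'
#' @param vol a straightened, protein-positive [volume_grid].
#' @param sym_initial starting [helical_symmetry] (e.g. from layer lines).
#' @param rise_window,twist_window numeric length-2 search offsets around
#'   the initial values (Angstrom, degrees).
#' @param rise_step,twist_step coarse grid steps.
#' @param n_units symmetry operations used by the objective.
#' @return The refined [helical_symmetry], with attributes `objective`
#'   (the split-half coherence at the optimum) and `boundary_hit` (TRUE if
#'   the optimum lies on the search-window edge).
#' @export
symmetry_refine <- function(vol, sym_initial, rise_window = c(-1.5, 1.5),
                            twist_window = c(-4, 4), rise_step = 0.5,
                            twist_step = 1, n_units = 12) {
  stopifnot(inherits(vol, "volume_grid"), inherits(sym_initial, "helical_symmetry"))
  d <- dim(vol$values)
  vx <- vol$voxel_size
  pts <- .refine_points(d, vx)
  tsign <- sign(sym_initial$twist)

  eval_grid <- function(rises, twists) {
    best <- NULL
    for (tw in twists) for (rs in rises) {
      obj <- .split_half_objective(vol$values, vx, rs, tsign * tw, n_units, pts)
      if (is.na(obj)) next
      if (is.null(best) || obj > best$obj + 1e-12 ||
          (abs(obj - best$obj) <= 1e-12 && tw < best$twist_mag)) {
        best <- list(obj = obj, rise = rs, twist_mag = tw)
      }
    }
    best
  }
  collect_range <- function(center, window, step) {
    seq(center + window[1], center + window[2], by = step)
  }

  rises <- collect_range(sym_initial$rise, rise_window, rise_step)
  twists <- collect_range(abs(sym_initial$twist), twist_window, twist_step)
  coarse <- eval_grid(rises, twists)
  if (is.null(coarse) || !is.finite(coarse$obj))
    stop("refinement failed: objective undefined over the search window")

  fine <- eval_grid(seq(coarse$rise - rise_step, coarse$rise + rise_step,
                        by = rise_step / 4),
                    seq(coarse$twist_mag - twist_step, coarse$twist_mag + twist_step,
                        by = twist_step / 4))
  if (fine$obj < 0.15)
    stop("refinement failed: no consistent helical signal in the search ",
         sprintf("window (best split-half coherence %.3f)", fine$obj))
  out <- helical_symmetry(fine$rise, tsign * fine$twist_mag)
  attr(out, "objective") <- fine$obj
  attr(out, "boundary_hit") <-
    fine$rise <= min(rises) || fine$rise >= max(rises) ||
    fine$twist_mag <= min(twists) || fine$twist_mag >= max(twists)
  out
}
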