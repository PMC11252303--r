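# Protofilament counting by rotational averaging, lumen-occupancy
# quantification and incidence comparison.

# in-plane rotation of every z slice about the axis centre (pull-back,
# bilinear via the trilinear sampler with exact z planes)
rotate_about_axis <- function(values, vx, angle, axis_center_idx) {
  d <- dim(values)
  a <- -angle * pi / 180
  xs <- seq_len(d[1]) - axis_center_idx[1]
  ys <- seq_len(d[2]) - axis_center_idx[2]
  X <- matrix(xs, d[1], d[2])
  Y <- matrix(ys, d[1], d[2], byrow = TRUE)
  Xr <- cos(a) * X - sin(a) * Y + axis_center_idx[1]
  Yr <- sin(a) * X + cos(a) * Y + axis_center_idx[2]
  x3 <- array(Xr, dim = d)
  y3 <- array(Yr, dim = d)
  z3 <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  trilinear_sample(values, x3, y3, z3)
}

# annular mask spanning the microtubule wall; the wall radius is taken from
# the peak of the rotationally averaged radial density profile
wall_annulus_mask <- function(values, vx, axis_center_idx, half_width = 30) {
  d <- dim(values)
  xs <- (seq_len(d[1]) - axis_center_idx[1]) * vx
  ys <- (seq_len(d[2]) - axis_center_idx[2]) * vx
  R <- sqrt(outer(xs^2, ys^2, "+"))
  zproj <- apply(values, c(1, 2), sum)
  rb <- seq(0, max(R), by = vx)
  prof <- vapply(seq_len(length(rb) - 1), function(i) {
    sel <- R >= rb[i] & R < rb[i + 1]
    if (!any(sel)) return(0)
    mean(zproj[sel])
  }, numeric(1))
  r_wall <- rb[which.max(prof)] + vx / 2
  ring <- R >= r_wall - half_width & R <= r_wall + half_width
  array(ring, dim = d)
}

#' Rotationally average a microtubule segment
#'
#' Averages the volume over k * 360/n rotations about the z axis through
#' `axis_center` (k = 0..n-1). The reported `self_correlation` is the
#' Pearson correlation between the input and its single 360/n rotation,
#' evaluated over an annular mask spanning the microtubule wall (wall
#' radius located from the radial density profile, +/- `annulus_half_width`
#' Angstrom), so lumenal content does not influence the symmetry score.
#'
#' @param vol a [volume_grid] with the microtubule axis along z.
#' @param n fold symmetry to impose (>= 2).
#' @param axis_center physical x,y of the axis in Angstrom relative to the
#'   grid corner; defaults to the grid centre.
#' @param annulus_half_width half-width of the wall mask, Angstrom.
#' @return List with `average` ([volume_grid]) and `self_correlation`.
#' @export
rotational_average <- function(vol, n, axis_center = NULL,
                               annulus_half_width = 30) {
  stopifnot(inherits(vol, "volume_grid"))
  if (!is.numeric(n) || n < 2 || n != round(n))
    stop("`n` must be an integer >= 2")
  d <- dim(vol$values)
  vx <- vol$voxel_size
  if (is.null(axis_center)) {
    ci <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
  } else {
    ci <- axis_center / vx + 0.5
    if (ci[1] < 1 || ci[1] > d[1] || ci[2] < 1 || ci[2] > d[2])
      stop("`axis_center` lies outside the grid")
  }
  acc <- vol$values
  wt <- array(1, dim = d)
  for (k in seq_len(n - 1)) {
    sm <- rotate_about_axis(vol$values, vx, k * 360 / n, ci)
    acc <- acc + sm$values
    wt <- wt + sm$inside
  }
  avg <- acc / wt
  mask <- wall_annulus_mask(vol$values, vx, ci, annulus_half_width)
  one <- rotate_about_axis(vol$values, vx, 360 / n, ci)
  ok <- mask & one$inside
  sc <- if (sum(ok) >= 10)
    stats::cor(vol$values[ok], one$values[ok]) else NA_real_
  list(average = volume_grid(avg, vx, vol$origin), self_correlation = sc)
}

#' Count protofilaments by rotational symmetry scan
#'
#' Evaluates the rotational self-correlation of the microtubule wall for
#' each candidate fold and picks the argmax. A margin below `ambiguous_margin`
#' between the best and runner-up candidates flags the call as ambiguous.
#'
#' @param vol a [volume_grid], microtubule axis along z.
#' @param candidates integer vector of folds to evaluate.
#' @param axis_center,annulus_half_width passed to [rotational_average()].
#' @param ambiguous_margin margin threshold for the `ambiguous` flag.
#' @return An object of class `protofilament_result`: `best_n`, `scores`
#'   (named numeric), `margin`, `ambiguous`.
#' @export
count_protofilaments <- function(vol, candidates = 12:16, axis_center = NULL,
                                 annulus_half_width = 30,
                                 ambiguous_margin = 0.02) {
  stopifnot(inherits(vol, "volume_grid"))
  d <- dim(vol$values)
  vx <- vol$voxel_size
  ci <- if (is.null(axis_center)) c((d[1] + 1) / 2, (d[2] + 1) / 2)
        else axis_center / vx + 0.5
  mask <- wall_annulus_mask(vol$values, vx, ci, annulus_half_width)
  scores <- vapply(candidates, function(n) {
    one <- rotate_about_axis(vol$values, vx, 360 / n, ci)
    ok <- mask & one$inside
    if (sum(ok) < 10) return(NA_real_)
    stats::cor(vol$values[ok], one$values[ok])
  }, numeric(1))
  names(scores) <- candidates
  if (all(is.na(scores))) stop("no usable wall mask: all symmetry scores undefined")
  best <- which.max(scores)
  margin <- if (length(scores) > 1)
    scores[best] - max(scores[-best], na.rm = TRUE) else NA_real_
  structure(list(best_n = as.integer(candidates[best]), scores = scores,
                 margin = as.numeric(margin),
                 ambiguous = is.finite(margin) && margin < ambiguous_margin),
            class = "protofilament_result")
}

#' @export
print.protofilament_result <- function(x, ...) {
  cat(sprintf("<protofilament_result> best n = %d (margin %.3f%s)\n",
              x$best_n, x$margin, if (x$ambiguous) ", AMBIGUOUS" else ""))
  print(round(x$scores, 4))
  invisible(x)
}

#' Lumen occupancy statistics
#'
#' Sums filament and microtubule lengths from an annotation table and
#' reports what fraction of the total microtubule length is occupied by
#' lumenal filaments, with a per-class breakdown. All lengths in
#' micrometres; percentages are full precision (round at presentation).
#'
#' @param table an [annotation_table].
#' @return An object of class `occupancy_stats`: `total_filament_length`,
#'   `total_microtubule_length`, `occupancy_percent`, `per_class` (data
#'   frame of class, count, total length, percent of microtubule length),
#'   `n_filaments`, `n_microtubules`.
#' @export
occupancy_stats <- function(table) {
  table <- annotation_table(table)
  fil <- table[table$object_kind == "filament", , drop = FALSE]
  mt <- table[table$object_kind == "microtubule", , drop = FALSE]
  if (nrow(mt) == 0 || sum(mt$length_um) <= 0)
    stop("zero total microtubule length: occupancy undefined")
  tot_f <- sum(fil$length_um)
  tot_m <- sum(mt$length_um)
  per_class <- if (nrow(fil) > 0) {
    agg <- stats::aggregate(length_um ~ class_label, data = fil, FUN = sum)
    cnt <- as.data.frame(base::table(class_label = fil$class_label),
                         stringsAsFactors = FALSE)
    df <- merge(agg, cnt, by = "class_label")
    names(df) <- c("class_label", "length_um", "count")
    df$percent_of_microtubule <- 100 * df$length_um / tot_m
    df[order(-df$length_um), c("class_label", "count", "length_um",
                               "percent_of_microtubule")]
  } else {
    data.frame(class_label = character(0), count = integer(0),
               length_um = numeric(0), percent_of_microtubule = numeric(0))
  }
  structure(list(total_filament_length = tot_f,
                 total_microtubule_length = tot_m,
                 occupancy_percent = 100 * tot_f / tot_m,
                 per_class = per_class,
                 n_filaments = nrow(fil), n_microtubules = nrow(mt)),
            class = "occupancy_stats")
}

#' @export
print.occupancy_stats <- function(x, ...) {
  cat(sprintf("<occupancy_stats> %d filaments totalling %.1f um in %d microtubules totalling %.1f um\n",
              x$n_filaments, x$total_filament_length, x$n_microtubules,
              x$total_microtubule_length))
  cat(sprintf("  lumen occupancy: %.1f%%\n", x$occupancy_percent))
  if (nrow(x$per_class) > 0) {
    df <- x$per_class
    df$length_um <- round(df$length_um, 2)
    df$percent_of_microtubule <- round(df$percent_of_microtubule, 1)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Compare two incidence proportions (Fisher's exact test)
#'
#' Two-sided exact test for a difference between proportions k1/n1 and
#' k2/n2, e.g. the fraction of microtubules containing a lumenal filament
#' under two conditions. The p-value sums the hypergeometric probabilities
#' of every 2x2 table with the observed margins whose probability does not
#' exceed that of the observed table (with a 1e-7 relative tolerance for
#' floating-point ties), i.e. the standard two-sided Fisher construction by
#' full enumeration of the support.
#'
#' @param k1,n1 successes and trials in group 1 (`0 <= k1 <= n1`).
#' @param k2,n2 successes and trials in group 2.
#' @return List with `p_value`, `estimate1`, `estimate2` and `method`.
#' @export
compare_incidence <- function(k1, n1, k2, n2) {
  for (v in list(c(k1, n1), c(k2, n2))) {
    if (v[2] <= 0) stop("group sizes must be positive")
    if (v[1] < 0 || v[1] > v[2] || v[1] != round(v[1]))
      stop("counts must be integers in [0, n]")
  }
  m <- k1 + k2
  support <- max(0, m - n2):min(m, n1)
  probs <- stats::dhyper(support, n1, n2, m)
  p_obs <- stats::dhyper(k1, n1, n2, m)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p), estimate1 = k1 / n1, estimate2 = k2 / n2,
       method = "two-sided Fisher exact test (full enumeration of the hypergeometric support)")
}
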