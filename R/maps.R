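#' Evaluate the pair-interaction logit on a grid
#'
#' Evaluates the attention network's antisymmetrized pair-interaction
#' subnetwork (the aggregation weight is ignored) over a grid of neighbour
#' positions, relative orientations and speeds, at a fixed focal context.
#' The neighbour velocity is composed from `(v_i, theta)` with
#' `vx = v_i sin(theta)`, `vy = v_i cos(theta)`. Raw grid coordinates are
#' standardized with the model's stored training statistics before
#' evaluation.
#'
#' @param model a trained attention `fish_model`.
#' @param x,y neighbour position axes in BL (defaults: the 8 x 8 grid of
#'   odd coordinates from -7 to 7).
#' @param theta relative-orientation axis in radians (default 64 uniform
#'   values over `[-pi, pi)`).
#' @param v_i neighbour speed axis in BL/s (default `c(1, 2, 4, 8)`).
#' @param focal_speed fixed focal speed in BL/s (default 3.04, the median
#'   speed of the recordings this analysis was developed on).
#' @param a_perp fixed focal normal acceleration (default 0).
#' @param extra named list of fixed values for any further pair variables
#'   (e.g. `topo`).
#' @return an object of class `"pair_logit_map"`: the logit array `z` with
#'   dimensions `[x, y, theta, v_i]` plus the axes.
#' @export
pair_logit_map <- function(model, x = seq(-7, 7, by = 2),
                           y = seq(-7, 7, by = 2),
                           theta = seq(-pi, pi, length.out = 65)[1:64],
                           v_i = c(1, 2, 4, 8), focal_speed = 3.04,
                           a_perp = 0, extra = list()) {
  stopifnot(model$kind == "attention")
  grid <- expand.grid(x = x, y = y, theta = theta, v_i = v_i,
                      KEEP.OUT.ATTRS = FALSE)
  pair_cols <- names(model$stats$pair$mean)
  raw <- matrix(0, nrow(grid), length(pair_cols),
                dimnames = list(NULL, pair_cols))
  fill <- function(nm, value) if (nm %in% pair_cols) raw[, nm] <<- value
  fill("v", focal_speed)
  fill("a_perp", a_perp)
  fill("a_par", 0)
  fill("x", grid$x)
  fill("y", grid$y)
  fill("vx", grid$v_i * sin(grid$theta))
  fill("vy", grid$v_i * cos(grid$theta))
  fill("ax", 0); fill("ay", 0)
  for (nm in names(extra)) fill(nm, extra[[nm]])
  std <- sweep(sweep(raw, 2, model$stats$pair$mean), 2,
               model$stats$pair$sd, "/")
  z <- cpp_pair_logit(std, model$odd_pair, model$params$pi)
  structure(list(z = array(z, dim = c(length(x), length(y), length(theta),
                                      length(v_i))),
                 x = x, y = y, theta = theta, v_i = v_i,
                 focal_speed = focal_speed, a_perp = a_perp),
            class = "pair_logit_map")
}

#' Attraction-repulsion score
#'
#' `sign(x)` times the average of the logit over all relative orientation
#' angles: positive means the focal tends to turn toward the neighbour's
#' side (attraction), negative away from it (repulsion). At `x = 0` the
#' score is 0 by convention (the neighbour is on the body axis).
#'
#' @param z logits sampled on a uniform theta grid covering `[-pi, pi)`.
#' @param x lateral neighbour coordinate (BL).
#' @return scalar score.
#' @export
attraction_repulsion_score <- function(z, x) {
  sign(x) * mean(z)
}

#' Alignment score
#'
#' `max over theta of z sign(theta)` minus `max over theta of
#' -z sign(theta)`: positive when the focal turns toward the side the
#' neighbour is heading to (alignment), negative for the reversed pattern
#' (anti-alignment), zero for orientation-insensitive logits.
#'
#' @param z logits sampled on a theta grid covering `[-pi, pi)`.
#' @param theta the matching orientation grid (radians).
#' @return scalar score.
#' @export
alignment_score <- function(z, theta) {
  s <- sign(theta)
  max(z * s) - max(-z * s)
}

#' Classify map cells into interaction regions
#'
#' A spatial cell (at each neighbour speed) is an orientation cell when
#' the logit changes sign across the relative orientation angle; its class
#' is then `"alignment"` or `"anti-alignment"` by the sign of the
#' alignment score. Otherwise the cell is `"attraction"` or `"repulsion"`
#' by the sign of the attraction-repulsion score. The alignment score is
#' reported only for orientation cells; the attraction-repulsion score is
#' reported everywhere. Cells whose maximum |logit| falls below
#' `eps_frac` times the map's maximum |logit| are flagged low-confidence.
#'
#' @param map a [pair_logit_map()].
#' @param eps_frac noise-floor fraction (default 0.01).
#' @return a data frame with one row per (x, y, v_i) cell: `class`,
#'   `ar_score`, `alignment_score` (NA outside orientation cells),
#'   `low_confidence`.
#' @export
classify_regions <- function(map, eps_frac = 0.01) {
  stopifnot(inherits(map, "pair_logit_map"))
  eps <- eps_frac * max(abs(map$z))
  grid <- expand.grid(x = map$x, y = map$y, v_i = map$v_i,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    ix <- match(grid$x[k], map$x); iy <- match(grid$y[k], map$y)
    iv <- match(grid$v_i[k], map$v_i)
    zt <- map$z[ix, iy, , iv]
    ar <- attraction_repulsion_score(zt, grid$x[k])
    orientation <- max(zt) > 0 && min(zt) < 0
    if (orientation) {
      al <- alignment_score(zt, map$theta)
      cls <- if (al >= 0) "alignment" else "anti-alignment"
    } else {
      al <- NA_real_
      cls <- if (ar >= 0) "attraction" else "repulsion"
    }
    data.frame(class = cls, ar_score = ar, alignment_score = al,
               low_confidence = max(abs(zt)) < eps)
  })
  cbind(grid, do.call(rbind, res))
}

#' Plot a pair-logit map slice
#'
#' Image of the logit over neighbour positions at one relative orientation
#' and neighbour speed (the nearest grid values are used); red = evidence
#' for turning right, blue = left.
#'
#' @param x a [pair_logit_map()].
#' @param theta_at,v_i_at orientation (rad) and neighbour speed (BL/s) of
#'   the displayed slice.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.pair_logit_map <- function(x, theta_at = 0, v_i_at = x$v_i[1], ...) {
  it <- which.min(abs(x$theta - theta_at))
  iv <- which.min(abs(x$v_i - v_i_at))
  z <- x$z[, , it, iv]
  lim <- max(abs(z))
  graphics::image(x$x, x$y, z, zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  xlab = "x (BL)", ylab = "y (BL)",
                  main = sprintf("pair logit, theta = %.2f, v_i = %g BL/s",
                                 x$theta[it], x$v_i[iv]), ...)
  invisible(x)
}

#' Evaluate the aggregation weight on a spatial grid
#'
#' Evaluates the raw weighting-subnetwork readout (log W) over neighbour
#' positions at fixed focal and neighbour speed, for plotting weight maps.
#'
#' @param model a trained attention `fish_model`.
#' @param x,y neighbour position axes in BL.
#' @param focal_speed,neighbour_speed fixed speeds in BL/s.
#' @param extra named list of fixed values for further weighting inputs
#'   (e.g. `topo`).
#' @return list with `log_w` matrix `[x, y]` and the axes.
#' @export
weight_map <- function(model, x = seq(-7, 7, by = 2), y = seq(-7, 7, by = 2),
                       focal_speed = 3.04, neighbour_speed = 3.04,
                       extra = list()) {
  stopifnot(model$kind == "attention")
  grid <- expand.grid(x = x, y = y, KEEP.OUT.ATTRS = FALSE)
  w_cols <- names(model$stats$w$mean)
  raw <- matrix(0, nrow(grid), length(w_cols),
                dimnames = list(NULL, w_cols))
  fill <- function(nm, value) if (nm %in% w_cols) raw[, nm] <<- value
  fill("v", focal_speed)
  fill("vi", neighbour_speed)
  fill("absx", abs(grid$x))
  fill("y", grid$y)
  for (nm in names(extra)) fill(nm, extra[[nm]])
  std <- sweep(sweep(raw, 2, model$stats$w$mean), 2, model$stats$w$sd, "/")
  lw <- cpp_weight_logit(std, model$params$w)
  list(log_w = matrix(lw, length(x), length(y)), x = x, y = y)
}
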